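#' Read a genus count table
#'
#' Reads a TSV whose first column is `sample_id` and whose remaining columns
#' are genus counts, and validates it: unique sample ids, non-negative integer
#' counts, positive row totals.
#'
#' @param path Path to the counts TSV.
#' @return A counts tibble (`sample_id` plus genus columns).
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  counts <- validate_counts(counts)
  dplyr::mutate(counts, dplyr::across(-"sample_id", as.integer))
}

#' Validate a genus count table
#'
#' @param counts Counts tibble (`sample_id` first, genus columns after).
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_counts <- function(counts) {
  if (!is.data.frame(counts) || names(counts)[1] != "sample_id") {
    abort("counts must be a data frame whose first column is `sample_id`")
  }
  if (ncol(counts) < 2) abort("counts table has no genus columns")
  if (anyDuplicated(counts$sample_id)) {
    abort(sprintf(
      "duplicate sample ids: %s",
      paste(unique(counts$sample_id[duplicated(counts$sample_id)]), collapse = ", ")
    ))
  }
  m <- counts_matrix(counts)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "counts must be non-negative integers; first offender at sample '%s', genus '%s'",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
    ))
  }
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty) > 0) {
    abort(sprintf("samples with zero total count: %s", paste(empty, collapse = ", ")))
  }
  tibble::as_tibble(counts)
}

#' Read and validate a sample metadata table
#'
#' Expects columns `sample_id`, `status` (HHS/LHS), `sample_type`, `farm_id`.
#'
#' @param path Path to the metadata TSV.
#' @return A metadata tibble.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "status", "sample_type", "farm_id")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    abort(sprintf("metadata is missing columns: %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort(sprintf(
      "duplicate sample ids in metadata: %s",
      paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", ")
    ))
  }
  check_status(meta$status, "metadata status")
  tibble::as_tibble(meta[, need])
}

#' Read a simulation ground-truth table
#'
#' @param path Path to a TSV with columns `genus_id`, `effect`.
#' @return A tibble; zero rows when the simulated dataset carried no signal.
#' @export
read_truth <- function(path) {
  truth <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(genus_id = readr::col_character(),
                            effect = readr::col_double()))
  stopifnot(all(c("genus_id", "effect") %in% names(truth)))
  tibble::as_tibble(truth)
}

# Every sample in the counts table must have exactly one metadata row; the
# metadata is then returned in counts order.
align_metadata <- function(counts, metadata) {
  missing <- setdiff(counts$sample_id, metadata$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("metadata missing for samples: %s", paste(missing, collapse = ", ")))
  }
  metadata[match(counts$sample_id, metadata$sample_id), , drop = FALSE]
}
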