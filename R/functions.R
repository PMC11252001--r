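#' Read a genus-to-function mapping table
#'
#' Parses a two-column TSV (`genus`, `function`) such as an export from a
#' taxon-to-function database. Keys are whitespace-trimmed and
#' case-preserving; duplicate pairs are collapsed. A genus may map to several
#' functions, and genera absent from the map are simply not aggregated.
#'
#' @param path Path to the mapping TSV.
#' @return A tibble with columns `genus` and `fn`, one row per unique pair.
#' @export
read_function_map <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("genus", "function") %in% names(raw))) {
    abort("function map must have columns `genus` and `function`")
  }
  map <- tibble::tibble(
    genus = trimws(raw$genus),
    fn = trimws(raw[["function"]]),
    line = seq_len(nrow(raw)) + 1L # header is line 1
  )
  bad <- map$line[is.na(map$genus) | is.na(map$fn) | map$genus == "" | map$fn == ""]
  if (length(bad) > 0) {
    abort(sprintf("malformed function-map rows at line(s): %s",
                  paste(bad, collapse = ", ")))
  }
  dplyr::distinct(map, .data$genus, .data$fn)
}

#' Per-status functional profile from a genus count table
#'
#' Aggregates genus relative abundance into functional groups per status:
#' within each status the per-sample relative abundances are averaged per
#' genus, each genus's abundance is added to every function it maps to (a
#' genus mapped to k functions is counted k times, consistent with
#' function-table semantics), and the function totals are normalised so each
#' status column sums to 100%. A function observed in exactly one status is
#' flagged exclusive to it.
#'
#' @param counts Counts tibble (`sample_id` first).
#' @param metadata Metadata with `status`.
#' @param map Mapping tibble from [read_function_map()] (columns `genus`,
#'   `fn`).
#' @return A tibble of class `function_profile` with columns `fn`, `HHS_pct`,
#'   `LHS_pct`, `exclusive_to` (NA when present in both statuses). Errors if
#'   no genus in the table is mapped.
#' @export
function_profile <- function(counts, metadata, map) {
  meta <- align_metadata(counts, metadata)
  check_status(meta$status)
  stopifnot(all(c("genus", "fn") %in% names(map)))
  rel <- relative_abundance(counts)
  mapped <- intersect(colnames(rel), unique(map$genus))
  if (length(mapped) == 0) abort("no genus in the count table is present in the function map")

  genus_by_status <- tibble::as_tibble(rel, rownames = "sample_id") |>
    dplyr::mutate(status = meta$status) |>
    tidyr::pivot_longer(-c("sample_id", "status"),
                        names_to = "genus", values_to = "rel_abund") |>
    dplyr::group_by(.data$status, .data$genus) |>
    dplyr::summarise(rel_abund = mean(.data$rel_abund), .groups = "drop")

  prof <- dplyr::inner_join(map, genus_by_status, by = "genus",
                            relationship = "many-to-many") |>
    dplyr::group_by(.data$status, .data$fn) |>
    dplyr::summarise(mass = sum(.data$rel_abund), .groups = "drop") |>
    dplyr::group_by(.data$status) |>
    dplyr::mutate(pct = 100 * .data$mass / sum(.data$mass)) |>
    dplyr::ungroup() |>
    dplyr::select("fn", "status", "pct") |>
    tidyr::pivot_wider(names_from = "status", values_from = "pct",
                       values_fill = 0, names_glue = "{status}_pct")
  for (col in c("HHS_pct", "LHS_pct")) {
    if (!col %in% names(prof)) prof[[col]] <- 0
  }
  prof <- prof |>
    dplyr::mutate(exclusive_to = dplyr::case_when(
      .data$HHS_pct > 0 & .data$LHS_pct == 0 ~ "HHS",
      .data$LHS_pct > 0 & .data$HHS_pct == 0 ~ "LHS",
      TRUE ~ NA_character_
    )) |>
    dplyr::arrange(dplyr::desc(.data$HHS_pct + .data$LHS_pct))
  class(prof) <- c("function_profile", class(prof))
  prof
}
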