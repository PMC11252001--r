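#' Exclude genera that are too sparse within either status group
#'
#' A genus is retained only if its fraction of zero counts is below
#' `max_zero_fraction` within *both* status groups; a genus at or above the
#' threshold in either group is excluded. Sample set and genus order are
#' unchanged.
#'
#' @param counts Counts tibble (`sample_id` plus genus columns).
#' @param metadata Metadata tibble with a `status` column (HHS/LHS).
#' @param max_zero_fraction Exclusion threshold on the within-status zero
#'   fraction (default 0.25).
#' @return The filtered counts tibble. Errors if every genus would be
#'   excluded, listing the per-genus zero fractions.
#' @export
filter_sparse_genera <- function(counts, metadata, max_zero_fraction = 0.25) {
  if (max_zero_fraction <= 0 || max_zero_fraction > 1) {
    abort("max_zero_fraction must be in (0, 1]")
  }
  meta <- align_metadata(counts, metadata)
  check_status(meta$status)
  m <- counts_matrix(counts)
  zero_frac <- vapply(
    split(seq_len(nrow(m)), meta$status),
    function(idx) colMeans(m[idx, , drop = FALSE] == 0),
    numeric(ncol(m))
  )
  keep <- apply(zero_frac < max_zero_fraction, 1, all)
  if (!any(keep)) {
    diag_tbl <- tibble::as_tibble(zero_frac, rownames = "genus_id")
    abort(c(
      "all genera excluded by the sparsity filter",
      paste(utils::capture.output(print(diag_tbl, n = 20)), collapse = "\n")
    ))
  }
  counts[, c(TRUE, keep), drop = FALSE]
}

#' Replace zero counts ahead of log-ratio transformation
#'
#' Two conventions are supported: `pseudocount_one` turns every zero into 1
#' and leaves all other counts untouched (the usual choice for count tables);
#' `half_minimum` replaces the zeros of each genus by half of that genus's
#' smallest nonzero value.
#'
#' @param counts Counts tibble, already sparse-filtered.
#' @param mode Replacement rule.
#' @return A tibble of strictly positive abundances with the same shape.
#' @export
replace_zeros <- function(counts, mode = c("pseudocount_one", "half_minimum")) {
  mode <- match.arg(mode)
  m <- counts_matrix(counts)
  all_zero <- colnames(m)[colSums(m > 0) == 0]
  if (length(all_zero) > 0) {
    abort(sprintf("all-zero genera cannot be zero-replaced: %s",
                  paste(all_zero, collapse = ", ")))
  }
  if (mode == "pseudocount_one") {
    m[m == 0] <- 1
  } else {
    for (j in seq_len(ncol(m))) {
      z <- m[, j] == 0
      if (any(z)) m[z, j] <- min(m[!z, j]) / 2
    }
  }
  matrix_to_counts(m)
}

#' Choose the ALR reference genus by lowest coefficient of variation
#'
#' The CV (SD/mean, sample SD) of each genus's relative abundance is computed
#' across all samples pooled; the genus with the lowest CV is returned. Exact
#' ties break to the lexicographically smaller genus id.
#'
#' @param abundances Strictly positive abundance tibble (after
#'   [replace_zeros()]).
#' @return The reference genus id (length-1 character).
#' @export
select_alr_reference <- function(abundances) {
  m <- counts_matrix(abundances)
  if (ncol(m) < 2) abort("need at least 2 genera to pick an ALR reference")
  if (any(m <= 0)) abort("abundances must be strictly positive; run replace_zeros() first")
  rel <- m / rowSums(m)
  cv <- apply(rel, 2, function(x) sd(x) / mean(x))
  ord <- order(cv, colnames(m)) # lexicographic tie-break on genus id
  colnames(m)[ord[1]]
}

#' Additive log-ratio (ALR) transformation
#'
#' Maps each sample's composition to `log(x_j) - log(x_ref)` for every genus
#' `j` other than the reference (natural log). The reference column is
#' dropped. The transform is invariant to sample-wise rescaling (closure), so
#' counts and relative abundances give identical output.
#'
#' @param abundances Strictly positive abundance tibble.
#' @param reference Reference genus id, typically from
#'   [select_alr_reference()].
#' @return A tibble (`sample_id` plus `G - 1` genus columns) with attributes
#'   `reference` (the genus id) and class `alr_matrix`.
#' @export
alr_transform <- function(abundances, reference) {
  m <- counts_matrix(abundances)
  if (any(m <= 0)) abort("ALR requires strictly positive abundances")
  if (!reference %in% colnames(m)) {
    abort(sprintf("reference genus '%s' not found", reference))
  }
  alr <- log(m[, setdiff(colnames(m), reference), drop = FALSE]) - log(m[, reference])
  out <- matrix_to_counts(alr)
  attr(out, "reference") <- reference
  class(out) <- c("alr_matrix", class(out))
  out
}

#' Centred log-ratio (CLR) transformation
#'
#' `log(x_j) - mean_j log(x_j)` per sample; the isometric representation used
#' as the comparison partner in [procrustes_isometry_check()].
#'
#' @inheritParams alr_transform
#' @return A tibble (`sample_id` plus one column per genus).
#' @export
clr_transform <- function(abundances) {
  m <- counts_matrix(abundances)
  if (any(m <= 0)) abort("CLR requires strictly positive abundances")
  matrix_to_counts(log(m) - rowMeans(log(m)))
}

#' Procrustes correlation between ALR and CLR sample configurations
#'
#' ALR is not an isometry of the simplex; this check quantifies how much the
#' chosen reference distorts the sample geometry. The ALR configuration is
#' compared against the centred log-ratio configuration of the same strictly
#' positive abundances via the symmetric Procrustes correlation (1 = identical
#' geometry after translation, rotation and scaling).
#'
#' @param alr An `alr_matrix` from [alr_transform()].
#' @param abundances The strictly positive abundances the ALR came from.
#' @return The Procrustes correlation, a real in \[0, 1\].
#' @export
procrustes_isometry_check <- function(alr, abundances) {
  stopifnot(identical(alr$sample_id, abundances$sample_id))
  if (nrow(alr) < 3) abort("Procrustes check needs at least 3 samples")
  clr <- clr_transform(abundances)
  procrustes_correlation(counts_matrix(alr), counts_matrix(clr))
}

#' Symmetric Procrustes correlation of two point configurations
#'
#' @param x,y Numeric matrices with matching rows (points); column counts may
#'   differ (the narrower configuration is padded with zero columns).
#' @return Correlation in \[0, 1\]: `sqrt(1 - ss)` with `ss` the symmetric
#'   Procrustes sum of squares.
#' @export
procrustes_correlation <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  d <- ncol(x) - ncol(y)
  if (d > 0) y <- cbind(y, matrix(0, nrow(y), d))
  if (d < 0) x <- cbind(x, matrix(0, nrow(x), -d))
  pr <- vegan::procrustes(x, y, symmetric = TRUE)
  sqrt(max(0, 1 - pr$ss))
}

#' Autoscale (column-standardise) an ALR matrix
#'
#' Centres every column to mean 0 and scales to SD 1 (sample SD, `n - 1`
#' denominator), as expected by PLS-DA and by the Bayesian per-genus model so
#' that posterior mean differences are in SD units of each variable.
#'
#' @param alr ALR tibble (or any `sample_id` + numeric columns tibble).
#' @return A list with `values` (scaled tibble, retaining the `reference`
#'   attribute if present) and `scaling` (tibble `genus_id`, `mean`, `sd`).
#'   Errors on zero-variance columns, naming the genus.
#' @export
autoscale <- function(alr) {
  m <- counts_matrix(alr)
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  flat <- colnames(m)[s == 0 | !is.finite(s)]
  if (length(flat) > 0) {
    abort(sprintf("zero-variance columns cannot be autoscaled: %s",
                  paste(flat, collapse = ", ")))
  }
  scaled <- sweep(sweep(m, 2, mu, "-"), 2, s, "/")
  out <- matrix_to_counts(scaled)
  attr(out, "reference") <- attr(alr, "reference")
  list(
    values = out,
    scaling = tibble::tibble(genus_id = colnames(m), mean = unname(mu), sd = unname(s))
  )
}

#' Run the full compositional preprocessing chain
#'
#' Fixed order: sparse-genus filter, zero replacement, lowest-CV reference
#' selection, ALR transformation, Procrustes isometry check, autoscaling.
#'
#' @inheritParams filter_sparse_genera
#' @inheritParams replace_zeros
#' @return A list of class `preprocessed`: `scaled` (samples x (G-1) tibble),
#'   `scaling`, `alr`, `filtered_counts`, `reference`, `procrustes_r`,
#'   `n_retained` (retained genus count, i.e. PLS-DA columns + 1),
#'   `max_zero_fraction`, `zero_mode`.
#' @export
preprocess <- function(counts, metadata, max_zero_fraction = 0.25,
                       mode = c("pseudocount_one", "half_minimum")) {
  mode <- match.arg(mode)
  filtered <- filter_sparse_genera(counts, metadata, max_zero_fraction)
  positive <- replace_zeros(filtered, mode)
  reference <- select_alr_reference(positive)
  alr <- alr_transform(positive, reference)
  pr <- procrustes_isometry_check(alr, positive)
  scaled <- autoscale(alr)
  structure(
    list(
      scaled = scaled$values,
      scaling = scaled$scaling,
      alr = alr,
      filtered_counts = filtered,
      positive = positive,
      reference = reference,
      procrustes_r = pr,
      n_retained = ncol(filtered) - 1L,
      max_zero_fraction = max_zero_fraction,
      zero_mode = mode
    ),
    class = "preprocessed"
  )
}

#' @export
print.preprocessed <- function(x, ...) {
  cat(sprintf(
    "<preprocessed> %d samples, %d retained genera (reference '%s'), Procrustes r = %.3f\n",
    nrow(x$scaled), x$n_retained, x$reference, x$procrustes_r
  ))
  invisible(x)
}
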