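# Alpha diversity (Shannon, inverse Simpson) with two-group rank tests, and
# beta diversity (Bray-Curtis, NMDS, PERMANOVA on the first two ordination
# dimensions). Indices and ordination are computed on relative abundances of
# the retained genera: Shannon and Bray-Curtis are undefined on signed
# log-ratio values, so the compositional transform feeds only the
# discriminant and Bayesian stages. An alternative beta-diversity route on
# Euclidean distances of the ALR coordinates is exposed through `beta_on`.

relative_abundance <- function(counts) {
  m <- counts_matrix(counts)
  m / rowSums(m)
}

#' Shannon diversity of one composition
#'
#' `H = -sum(p * ln p)` in nats, zeros skipped.
#'
#' @param proportions Non-negative vector summing to 1 (within 1e-9).
#' @return Shannon index `H >= 0`.
#' @export
shannon <- function(proportions) {
  if (any(proportions < 0)) abort("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9) abort("proportions must sum to 1")
  as.numeric(vegan::diversity(rbind(proportions), index = "shannon"))
}

#' Inverse Simpson diversity of one composition
#'
#' `D2 = 1 / sum(p^2)`; equals the number of genera under perfect evenness.
#'
#' @inheritParams shannon
#' @return Inverse Simpson index `D2 >= 1`.
#' @export
inverse_simpson <- function(proportions) {
  if (any(proportions < 0)) abort("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9) abort("proportions must sum to 1")
  as.numeric(vegan::diversity(rbind(proportions), index = "invsimpson"))
}

#' Two-group rank test (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test: exact enumeration when the combined sample
#' size is at most 12 and there are no ties, otherwise the tie-corrected
#' normal approximation (no continuity correction, so the p-value coincides
#' with the two-group Kruskal-Wallis p-value).
#'
#' @param a,b Numeric vectors, both nonempty.
#' @return A tibble with `U` (number of (a, b) pairs with a > b) and
#'   `p_value`.
#' @export
rank_test_two_groups <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  tibble::tibble(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Per-sample alpha diversity with a two-group rank test per index
#'
#' Computes Shannon and inverse Simpson diversity on each sample's relative
#' abundances and tests for a status difference in each index with
#' [rank_test_two_groups()].
#'
#' @param counts Counts (or positive abundances) tibble, `sample_id` first.
#' @param metadata Metadata with `status`.
#' @return A list of class `diversity_report`: `samples` (tibble `sample_id`,
#'   `status`, `shannon`, `inverse_simpson`) and `tests` (tibble `index`, `U`,
#'   `p_value`).
#' @export
alpha_diversity <- function(counts, metadata) {
  meta <- align_metadata(counts, metadata)
  check_status(meta$status)
  rel <- relative_abundance(counts)
  samples <- tibble::tibble(
    sample_id = counts$sample_id,
    status = meta$status,
    shannon = as.numeric(vegan::diversity(rel, index = "shannon")),
    inverse_simpson = as.numeric(vegan::diversity(rel, index = "invsimpson"))
  )
  tests <- dplyr::bind_rows(
    dplyr::mutate(rank_test_two_groups(
      samples$shannon[samples$status == "HHS"],
      samples$shannon[samples$status == "LHS"]
    ), index = "shannon", .before = 1),
    dplyr::mutate(rank_test_two_groups(
      samples$inverse_simpson[samples$status == "HHS"],
      samples$inverse_simpson[samples$status == "LHS"]
    ), index = "inverse_simpson", .before = 1)
  )
  structure(list(samples = samples, tests = tests), class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("<diversity_report>\n")
  print(x$tests)
  invisible(x)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(s, t) = sum |x_s - x_t| / sum (x_s + x_t)` on non-negative abundances,
#' taken exactly as supplied (no internal normalisation); [beta_diversity()]
#' passes per-sample relative abundances so that sequencing depth does not
#' drive the dissimilarity.
#'
#' @param x Abundance tibble (`sample_id` first) or non-negative matrix.
#' @return A symmetric matrix with zero diagonal and values in \[0, 1\],
#'   sample ids as dimnames when available.
#' @export
bray_curtis <- function(x) {
  m <- as_X(x)
  if (any(m < 0)) abort("abundances must be non-negative")
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 minimisation with monotone regression of configuration
#' distances on dissimilarities, restarted from `restarts` random
#' initialisations; the best configuration is returned.
#'
#' @param dissimilarity Symmetric dissimilarity matrix (e.g. [bray_curtis()]).
#' @param dims Embedding dimension (default 2).
#' @param restarts Random restarts (default 20).
#' @param max_iter Iteration cap per restart.
#' @param tol Stress convergence tolerance.
#' @param seed Integer seed.
#' @return A list of class `ordination_result`: `coordinates` (tibble
#'   `sample_id`, `NMDS1`, `NMDS2`, ...), `stress` (final Kruskal stress-1,
#'   as a fraction), `converged` (logical; the best configuration is returned
#'   either way), `dissimilarity`.
#' @export
nmds <- function(dissimilarity, dims = 2, restarts = 20, max_iter = 500,
                 tol = 1e-6, seed = 1L) {
  d <- stats::as.dist(dissimilarity)
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = dims, try = restarts, trymax = restarts,
                        maxit = max_iter, sfgrmin = tol, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  coords <- tibble::as_tibble(vegan::scores(fit, display = "sites"),
                              rownames = "sample_id")
  if (!fit$converged) {
    warn("NMDS did not meet the convergence criterion; returning the best configuration found")
  }
  structure(
    list(coordinates = coords, stress = fit$stress,
         converged = isTRUE(as.logical(fit$converged)),
         dissimilarity = as.matrix(dissimilarity)),
    class = "ordination_result"
  )
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d samples, stress %.4f%s\n",
              nrow(x$coordinates), x$stress,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' One-way PERMANOVA on ordination coordinates
#'
#' Permutational multivariate ANOVA on Euclidean distances among the supplied
#' coordinates (by convention, the first two NMDS dimensions): pseudo-F from
#' the distance-based sum-of-squares decomposition, p-value as
#' `(1 + #permuted F >= observed) / (1 + n_permutations)` with label
#' permutations from the seeded generator.
#'
#' @param coordinates Tibble with `sample_id` and numeric axis columns, or a
#'   numeric matrix.
#' @param status HHS/LHS labels aligned with the coordinate rows.
#' @param n_permutations Number of label permutations (default 9,999; at
#'   least 99).
#' @param seed Integer seed.
#' @return A tibble with `pseudo_F`, `p_value`, `df_between`, `df_within`,
#'   `n_permutations`.
#' @export
permanova_on_axes <- function(coordinates, status, n_permutations = 9999,
                              seed = 1L) {
  X <- as_X(coordinates)
  status <- as.character(status)
  check_status(status)
  if (any(table(status) < 2)) abort("each group needs at least 2 samples")
  if (n_permutations < 99) abort("n_permutations must be at least 99")
  set.seed(seed)
  grp <- factor(status)
  fit <- vegan::adonis2(dist(X) ~ grp, permutations = n_permutations)
  tibble::tibble(
    pseudo_F = fit$F[1],
    p_value = fit$`Pr(>F)`[1],
    df_between = fit$Df[1],
    df_within = fit$Df[2],
    n_permutations = as.integer(n_permutations)
  )
}

#' Beta diversity: dissimilarity, NMDS and PERMANOVA in one call
#'
#' @param counts Counts tibble (`sample_id` first).
#' @param metadata Metadata with `status`.
#' @param beta_on Dissimilarity basis: `"proportions"` (Bray-Curtis on
#'   relative abundances, the default) or `"alr_euclidean"` (Euclidean
#'   distance on ALR coordinates supplied via `alr`).
#' @param alr ALR tibble, required for `beta_on = "alr_euclidean"`.
#' @inheritParams nmds
#' @inheritParams permanova_on_axes
#' @return A list of class `beta_diversity`: `dissimilarity`, `ordination`
#'   (`ordination_result` with a `status` column joined onto the
#'   coordinates), `permanova` (tibble).
#' @export
beta_diversity <- function(counts, metadata,
                           beta_on = c("proportions", "alr_euclidean"),
                           alr = NULL, restarts = 20, n_permutations = 9999,
                           seed = 1L) {
  beta_on <- match.arg(beta_on)
  meta <- align_metadata(counts, metadata)
  check_status(meta$status)
  diss <- if (beta_on == "proportions") {
    rel <- relative_abundance(counts)
    bray_curtis(rel)
  } else {
    if (is.null(alr)) abort("beta_on = 'alr_euclidean' requires the `alr` matrix")
    as.matrix(dist(counts_matrix(alr)))
  }
  ord <- nmds(diss, dims = 2, restarts = restarts, seed = derive_seed(seed, 11L))
  ord$coordinates <- dplyr::left_join(
    ord$coordinates,
    dplyr::select(meta, "sample_id", "status"),
    by = "sample_id"
  )
  perm <- permanova_on_axes(
    dplyr::select(ord$coordinates, dplyr::starts_with("NMDS")) |>
      as.matrix(),
    meta$status, n_permutations, seed = derive_seed(seed, 13L)
  )
  structure(
    list(dissimilarity = diss, ordination = ord, permanova = perm,
         beta_on = beta_on),
    class = "beta_diversity"
  )
}

#' @export
print.beta_diversity <- function(x, ...) {
  cat(sprintf("<beta_diversity> (%s) stress %.4f; PERMANOVA F = %.2f, p = %.4f\n",
              x$beta_on, x$ordination$stress,
              x$permanova$pseudo_F, x$permanova$p_value))
  invisible(x)
}
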