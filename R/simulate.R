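#' Simulation settings for two-status genus count tables
#'
#' Bundles the knobs of the synthetic-data generator. The defaults mirror the
#' sampling design the package targets: 3 high-health-status (HHS) and 3
#' low-health-status (LHS) farms, with 2 pooled environmental samples per farm
#' per sample type, sequenced to a desk-scale mean depth of 10,000 reads.
#'
#' @param n_farms_per_status Farms per status group (default 3).
#' @param n_pools_per_farm Pooled samples per farm (default 2), so a dataset
#'   has `2 * n_farms_per_status * n_pools_per_farm` samples.
#' @param n_genera Number of genera simulated.
#' @param n_differential Number of genera given a status effect.
#' @param effect_size Status shift per differential genus, in units of that
#'   genus's between-sample log-abundance SD (noise, farm effect and counting
#'   noise combined). `0` disables all differential signal.
#' @param depth_mean Mean sequencing depth per sample (Poisson).
#' @param zero_inflation Structural-zero (detection dropout) intensity in
#'   \[0, 1\]: each sampled count is zeroed with probability
#'   `zero_inflation * exp(-(count / count0)^2)`, `count0` being the count of
#'   an average genus (`depth_mean / n_genera`), so dropout concentrates in
#'   low-abundance genera.
#' @param overdispersion Between-sample log-abundance SD; larger values give
#'   noisier, more overdispersed counts.
#' @param farm_sd_ratio SD of the shared per-farm log-abundance perturbation,
#'   expressed as a fraction of `overdispersion`, so pools from one farm are
#'   correlated.
#' @param sample_type Sample type label written into the metadata
#'   (`"wall"`, `"slat"` or `"slurry"`).
#' @param seed Integer seed; the full dataset is reproducible given the config.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genera,
                       n_differential = 0L,
                       effect_size = 1,
                       n_farms_per_status = 3L,
                       n_pools_per_farm = 2L,
                       depth_mean = 10000L,
                       zero_inflation = 0.05,
                       overdispersion = 0.5,
                       farm_sd_ratio = 0.25,
                       sample_type = c("wall", "slat", "slurry"),
                       seed = 1L) {
  sample_type <- match.arg(sample_type)
  if (n_differential > n_genera) {
    abort("n_differential must not exceed n_genera")
  }
  if (depth_mean <= 0) abort("depth_mean must be positive")
  if (zero_inflation < 0 || zero_inflation > 1) {
    abort("zero_inflation must be a probability in [0, 1]")
  }
  if (overdispersion <= 0) abort("overdispersion must be positive")
  if (n_farms_per_status < 1 || n_pools_per_farm < 1) {
    abort("need at least one farm per status and one pool per farm")
  }
  structure(
    list(
      n_farms_per_status = as.integer(n_farms_per_status),
      n_pools_per_farm = as.integer(n_pools_per_farm),
      n_genera = as.integer(n_genera),
      n_differential = as.integer(n_differential),
      effect_size = effect_size,
      depth_mean = depth_mean,
      zero_inflation = zero_inflation,
      overdispersion = overdispersion,
      farm_sd_ratio = farm_sd_ratio,
      sample_type = sample_type,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate a synthetic two-status genus count table with known ground truth
#'
#' Draws a genus count table under a compositional count model: a shared
#' log-normal baseline relative-abundance profile, a signed status effect on a
#' chosen subset of genera, a shared per-farm random effect, independent
#' between-sample log-abundance noise, multinomial count sampling at a
#' Poisson-distributed depth, and abundance-dependent Bernoulli detection
#' dropout applied to the sampled counts.
#'
#' @param config A [sim_config()].
#' @return A list with class `farmbiome_dataset`:
#'   \describe{
#'     \item{counts}{tibble, `sample_id` plus one column per genus
#'       (non-negative integer counts).}
#'     \item{metadata}{tibble with `sample_id`, `status`, `sample_type`,
#'       `farm_id`.}
#'     \item{truth}{tibble with `genus_id` and signed `effect`
#'       (positive = enriched in HHS); empty when `effect_size = 0`.}
#'   }
#' @examples
#' ds <- generate_dataset(sim_config(n_genera = 30, n_differential = 5, seed = 7))
#' dim(ds$counts)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  G <- config$n_genera
  genus_ids <- sprintf("genus_%03d", seq_len(G))
  statuses <- status_levels()
  meta <- tidyr::expand_grid(
    status = statuses,
    farm = seq_len(config$n_farms_per_status),
    pool = seq_len(config$n_pools_per_farm)
  ) |>
    dplyr::mutate(
      farm_id = sprintf("%s_farm%d", .data$status, .data$farm),
      sample_id = sprintf("%s_p%d", .data$farm_id, .data$pool),
      sample_type = config$sample_type
    ) |>
    dplyr::select("sample_id", "status", "sample_type", "farm_id")

  n <- nrow(meta)
  sigma <- config$overdispersion

  # Baseline log relative-abundance profile shared across all samples; the
  # SD of 1.5 log units gives the strongly uneven genus inventory typical of
  # 16S genus tables.
  baseline <- rnorm(G, mean = 0, sd = 1.5)

  # Between-sample SD of each genus's log abundance: the noise knob plus the
  # farm effect plus the Poisson counting noise at the genus's expected count.
  # Effect sizes are expressed in units of this per-genus SD, so a given
  # effect_size is equally detectable for rare and abundant genera.
  p_base <- exp(baseline) / sum(exp(baseline))
  expected_count <- config$depth_mean * p_base
  sd_g <- sqrt(sigma^2 * (1 + config$farm_sd_ratio^2) + log1p(1 / expected_count))

  if (config$effect_size > 0 && config$n_differential > 0) {
    diff_idx <- sort(sample.int(G, config$n_differential))
    signs <- rep_len(c(1, -1), config$n_differential)[sample.int(config$n_differential)]
    effects <- signs * config$effect_size * sd_g[diff_idx]
    truth <- tibble::tibble(genus_id = genus_ids[diff_idx], effect = effects)
  } else {
    diff_idx <- integer(0)
    effects <- numeric(0)
    truth <- tibble::tibble(genus_id = character(0), effect = numeric(0))
  }

  shift <- numeric(G)
  shift[diff_idx] <- effects / 2 # +e/2 in HHS, -e/2 in LHS => difference e

  farms <- unique(meta$farm_id)
  farm_eff <- matrix(rnorm(length(farms) * G, 0, config$farm_sd_ratio * sigma),
    nrow = length(farms), dimnames = list(farms, NULL)
  )

  counts <- matrix(0L, nrow = n, ncol = G, dimnames = list(meta$sample_id, genus_ids))
  for (i in seq_len(n)) {
    sgn <- if (meta$status[i] == "HHS") 1 else -1
    loga <- baseline + sgn * shift + farm_eff[meta$farm_id[i], ] + rnorm(G, 0, sigma)
    prob <- exp(loga - max(loga))
    depth <- rpois(1, config$depth_mean)
    x <- as.integer(rmultinom(1, size = depth, prob = prob))
    if (config$zero_inflation > 0) {
      # detection-dropout zeros: Bernoulli per entry, with a probability that
      # decays with the sampled count so structural zeros concentrate in
      # low-abundance genera (abundant taxa are never "undetected")
      count0 <- config$depth_mean / G
      p_drop <- config$zero_inflation * exp(-(x / count0)^2)
      x[runif(G) < p_drop] <- 0L
    }
    if (sum(x) == 0) {
      abort("simulated sample with zero total count; increase depth_mean or lower zero_inflation")
    }
    counts[i, ] <- x
  }

  structure(
    list(
      counts = matrix_to_counts(counts),
      metadata = meta,
      truth = truth,
      config = config
    ),
    class = "farmbiome_dataset"
  )
}

#' @export
print.farmbiome_dataset <- function(x, ...) {
  cat(sprintf(
    "<farmbiome_dataset> %d samples x %d genera, %d differential, seed %d\n",
    nrow(x$counts), ncol(x$counts) - 1L, nrow(x$truth), x$config$seed
  ))
  invisible(x)
}

#' Write a synthetic dataset to TSV files
#'
#' Emits three tab-separated files that round-trip losslessly through
#' [read_counts()], [read_metadata()] and [read_truth()]: `counts.tsv`
#' (`sample_id` then genus columns), `metadata.tsv` (`sample_id`, `status`,
#' `sample_type`, `farm_id`) and `truth.tsv` (`genus_id`, `effect`).
#'
#' @param dataset A `farmbiome_dataset` from [generate_dataset()].
#' @param dir Output directory, created if absent.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "farmbiome_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(dataset$counts, paths[["counts"]])
  readr::write_tsv(dataset$metadata, paths[["metadata"]])
  readr::write_tsv(dataset$truth, paths[["truth"]])
  invisible(paths)
}
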