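---
title: "Discriminating farm sanitary status from genus-level environmental microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating farm sanitary status from genus-level environmental microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farmbiome)
```

farmbiome implements a complete statistical workflow for genus-level
microbiome count tables collected in a two-level sanitary-status design —
environmental samples (wall, slat, slurry) from high-health-status (HHS) and
low-health-status (LHS) pig farms. The interesting statistical problems are
all downstream of sequencing: the data are compositional counts with many
zeros, there are very few biological replicates (a handful of farms, a couple
of pooled samples each), and the scientific questions are simultaneously
discriminative (which genera separate the two statuses?), estimative (how big
is each genus's difference, with honest uncertainty?) and ecological (do
diversity and community structure differ?).

This vignette is the package's own account of the methods: the models, the
assumptions behind them, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The compositional preprocessing chain

Sequencing counts carry no information about absolute abundance: only the
relative composition of each sample is meaningful, so ordinary Euclidean
statistics on raw counts confound depth with biology. `preprocess()` applies
a fixed chain:

1. **Sparse-genus filter** (`filter_sparse_genera()`). A genus is kept only
   when its fraction of zero counts is below `max_zero_fraction` (default
   0.25) within *both* status groups. The rule is intentionally two-sided: a
   genus reliably present in one group but absent in the other would
   otherwise enter the log-ratio machinery on the strength of imputed zeros.
   The threshold is exposed because "25%" is a convention, not a law.
2. **Zero replacement** (`replace_zeros()`). Log-ratios are undefined at
   zero. Two standard conventions are implemented: `pseudocount_one`
   (default for count tables; every 0 becomes 1) and `half_minimum` (each
   genus's zeros become half its smallest nonzero value, the usual choice
   for already-normalised data). Both are exposed rather than silently
   chosen, because the two rules can disagree noticeably for abundant genera
   with occasional zeros.
3. **ALR transformation** (`alr_transform()`). Each genus is expressed as
   `ln(x_j) - ln(x_ref)`, dropping the reference column. The reference is
   the genus with the lowest coefficient of variation of relative abundance
   across all samples pooled (`select_alr_reference()`; sample SD, exact
   ties broken lexicographically by genus id). CV is computed on relative
   abundances because the reference must be insensitive to depth; it is
   computed on both groups pooled because a single common reference is
   needed. Natural log is used throughout — any base change is a per-column
   constant that the subsequent autoscaling absorbs.
4. **Isometry check** (`procrustes_isometry_check()`). ALR is not an
   isometry of the simplex: distances between samples are distorted by the
   choice of reference. The check computes the symmetric Procrustes
   correlation between the ALR configuration and the centred log-ratio (CLR)
   configuration of the same data. CLR is the conventional isometric
   benchmark; a correlation near 1 means the chosen reference preserves the
   sample geometry and downstream distance-based conclusions are not
   reference artifacts.
5. **Autoscaling** (`autoscale()`). Every ALR column is centred to mean 0
   and scaled to sample SD 1 (n−1 denominator everywhere in the package).
   This puts all genera on the same footing for PLS-DA and makes the
   Bayesian effect estimates directly interpretable in SD units.

## PLS-DA with iterative VIP pruning

The discriminant engine is a partial least-squares fit of the autoscaled ALR
matrix against a single ±1 encoding of status (HHS = +1; with balanced
groups this is equivalent to the two-column dummy formulation). Components
are extracted by deflation; with one response column each weight vector is
`X'y` normalised, which also provides the package's brute-force test oracle.

Classification happens in latent-score space: a sample is assigned to the
class whose centroid is nearer in **Mahalanobis distance** under the pooled
within-class covariance of the training scores (`classify_mahalanobis()`).
The covariance estimator had to be chosen — pooling is the natural choice
with 6 samples per class, and a ridge fallback (`1e-8 × trace/A`) guards the
singular case. Exact ties go to the lexicographically smaller label.

Model size and variable selection are driven by the **balanced error rate**
(BER, the mean of the two per-class error rates) under stratified 4-fold
cross-validation repeated `repetitions` times (default 100). Stratification
is essential at these sample sizes: unstratified folds can produce
single-class training sets. The number of components is the BER argmin
(smallest on ties; searched up to `min(p, smallest training size − 1, 5)`).

`iterative_vip_selection()` then alternates model fitting with pruning:
variables with a VIP score below 1 are dropped and the model refit, until no
variable falls below the threshold, the cross-validated BER stops improving,
or fewer than two variables would remain. "Until the lowest BER" is not by
itself an operational stopping rule, so the loop records every iteration and
returns the one with the lowest mean BER — the *earliest* such iteration on
ties, so that a BER plateau never forces additional pruning. VIP scores use
the standard formulation weighted by each component's explained class
variance, normalised so that the mean squared VIP is 1; the threshold of 1
is therefore the "average importance" line.

Two caveats are deliberate and documented rather than corrected:

* Autoscaling is fit once on the full dataset before cross-validation,
  mirroring the sequential methodology the package reproduces. This leaks a
  small amount of information into the folds.
* Variables are selected on the full dataset, and the final confusion matrix
  is computed by cross-validating *the selected set*. At n = 12 this
  selection-induced optimism is substantial — on pure-noise data the
  observed per-class true-positive rates typically exceed chance by tens of
  points. This is precisely why the workflow's final validation is the
  **permuted confusion matrix** (`confusion_matrices()`): labels are
  re-shuffled before every repetition, and any persistent deviation of the
  permuted true-positive rates from the two-class chance level of 50% would
  indicate a broken procedure. The honest reading of results is therefore
  comparative — observed versus permuted — never the observed rate alone.
  Confusion repetitions default to 500 (desk scale); the full-scale 10,000
  is a parameter away.

## The Bayesian single-effect model

For each selected genus the package fits

`y_i = mu + delta * I(status_i = HHS) + e_i,  e_i ~ N(0, sigma^2)`

with improper flat priors on `mu`, `delta` and `log sigma`, by Gibbs
sampling — all full conditionals are conjugate (normal, normal, scaled
inverse chi-square), and the posterior is proper for ≥ 2 samples per group.
This prior choice keeps the model analytically transparent: the marginal
posterior of `delta` is a scaled-and-shifted t distribution centred at the
observed mean difference, which the test suite uses as an exact oracle.

Per genus the report gives the posterior mean difference `meanDiff`
(HHS − LHS; in SD units because the inputs are autoscaled), the 95% highest
posterior density interval (shortest sorted-draw window, `hpd_interval()`),
and `P0` — the posterior probability that the difference exceeds zero in the
direction of its own sign. A genus is flagged *relevant* when `P0 > 0.95`.
No multiplicity correction is applied (the per-genus rule is reported as-is,
with the number of genera tested recorded); note that `P0 > 0.95` is roughly
a one-sided 5% rule and will flag ~10% of truly null genera.

Chains run independently from derived sub-seeds; a split-chain potential
scale reduction factor above 1.01 triggers a warning. The desk-scale default
is 4 chains × 5,000 iterations (burn-in 1,000, thinning 10); the full-scale
profile of 4 × 50,000 is available via `mcmc_config(paper_scale = TRUE)` or
`run_pipeline(scale_profile = "paper")`.

A sample-size reality worth stating explicitly: with 6 + 6 samples, the
posterior SE of `delta` is about `s_p * sqrt(1/3) ≈ 0.4` SD units, so only
genera whose realised standardised difference exceeds roughly 0.75 SD get
flagged. Moderate true effects hover near the threshold and are flagged in
only a fraction of replicate datasets — relevance lists at this design size
are conservative and somewhat unstable, which is why the package reports the
full posterior summary and not just the star.

## Ecology: diversity and ordination

Alpha diversity uses Shannon entropy (nats) and inverse Simpson on
per-sample **relative abundances** of the retained genera, with a two-sided
Mann–Whitney U test per index (exact enumeration for combined n ≤ 12 without
ties, tie-corrected normal approximation otherwise — without continuity
correction, so the two-group p-value coincides with Kruskal–Wallis). Beta
diversity is Bray–Curtis on relative abundances, embedded by NMDS (Kruskal
stress-1, monotone regression, default 20 random restarts, best retained),
followed by one-way PERMANOVA on the first two ordination axes (pseudo-F
from the Euclidean distance decomposition; p-value from label permutations,
default 9,999, computed as `(1 + #{F* ≥ F}) / (1 + n_perm)`).

One deviation is deliberate: the source methodology describes diversity
"calculated using the ALR", but Shannon, inverse Simpson and Bray–Curtis are
mathematically undefined or meaningless on signed log-ratio values. The
package computes them on relative abundances of the retained genera and
offers `beta_on = "alr_euclidean"` (Euclidean distance on the ALR matrix)
as the closest well-defined reading of the literal text. PERMANOVA on two
NMDS axes rather than on the full dissimilarity is itself a methodological
quirk inherited from the workflow being reproduced — it discards whatever
structure the embedding does not capture — and is kept because reproducing
the procedure is the point.

## Functional profiles

`function_profile()` aggregates genus relative abundance into user-supplied
functional groups (any two-column genus→function TSV, e.g. an export from a
taxon-to-function database; the database itself is not redistributed). Per
status, genus abundances are averaged across samples, added into every
function the genus maps to (a genus with k functions is counted k times —
standard function-table semantics), and normalised so each status column
sums to 100%. The normalisation basis is over function-assigned mass, the
only convention consistent with near-100 column totals in the table format
this mirrors. Functions with zero abundance in exactly one status are
flagged exclusive to the other.

## The synthetic-data generator

`generate_dataset()` exists so every downstream stage can be tested against
known ground truth without any sequencing data. It emulates the target
design: 2 statuses × 3 farms × 2 pooled samples (all configurable), a
log-normal baseline relative-abundance profile (SD 1.5 log units, the
typical unevenness of 16S genus tables), a shared per-farm random effect
(SD 0.25 × the between-sample SD, making pools from one farm correlated), a
signed status effect on a chosen genus subset, multinomial sampling at
Poisson-distributed depth (default mean 10,000 reads — scaled down from the
~100,000 of a real run for desk-scale testing), and detection-dropout zeros:
each count is zeroed with probability `zero_inflation * exp(-(count/count0)^2)`
where `count0` is the depth share of an average genus. Dropout concentrates
in low-abundance genera because that is where structural zeros occur in real
genus tables; a uniform dropout rate would plant zeros in abundant genera,
which (via pseudocount replacement) produces log-ratio outliers of several
log units that no real post-filter dataset shows.

Effect sizes are specified in units of each genus's own between-sample
log-abundance SD — the noise knob, farm effect and Poisson counting noise
combined — so `effect_size = 2` is equally detectable for rare and abundant
genera and the ground truth stores the resulting signed log-unit shift.

What the generator does **not** emulate: taxonomic structure (genera are
exchangeable), phylogenetic or co-occurrence correlation between genera,
ecological differences between sample types beyond a label, library-size
artifacts, or overdispersion beyond log-normal-multinomial. Passing tests
therefore demonstrate that the statistical machinery behaves as specified
under a realistic compositional count model — not that any particular real
dataset will show the same power or error rates.

## Numerical choices and problem sizes

* Sample SD (n−1) everywhere; natural log everywhere.
* Seeds: every stochastic function takes an explicit seed; nested stages use
  sub-seeds derived by a fixed affine map, so a single pipeline seed
  reproduces the whole report bundle byte for byte (the stage log contains
  no timestamps for the same reason).
* NMDS: 20 restarts, convergence tolerance 1e-6; non-convergence returns
  the best configuration found, with a warning.
* Ridge fallback for singular score covariances: `1e-8 × trace/A`.
* HPD intervals require ≥ 100 draws; the sliding-window estimator is
  slightly inward-biased at small draw counts, which matters only if you
  compare endpoints at precision below their Monte-Carlo error.
* The test suite runs at desk scale: CV repetitions 10–100, confusion
  repetitions 40–500, MCMC 2 × 3,000 to 4 × 5,000 iterations, PERMANOVA
  99–999 permutations, parameter-recovery simulations with 57 genera and 12
  samples over 10 seeds, and a PERMANOVA type-I-error study of 1,000 null
  replicates at 999 permutations each.

## Known limitations

* With 12 samples, cross-validated BER saturates at 0 whenever the signal is
  strong, so the pruning loop's stopping behaviour (and hence the selected
  set size) is driven by ties; the earliest-minimum rule keeps the selection
  conservative.
* The single-effect Bayesian model ignores the farm grouping; with 3 farms
  per status the farm effect mildly inflates the apparent precision of
  `delta`. A mixed model would be the next step but is outside the
  reproduced methodology.
* The P0 > 0.95 rule is per-genus and uncorrected; its relevance lists
  should be read as ranked candidates, not as a multiplicity-controlled
  discovery set.
* Bray–Curtis is not a metric (triangle-inequality violations are allowed
  and not asserted anywhere).
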