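#' Configuration for the synthetic bisulfite-data simulator
#'
#' Defaults mirror the benchmark conditions used throughout the package:
#' 1000 features, 20 samples in a balanced two-condition x two-batch layout,
#' 100 truly differentially methylated features with a +10 percentage-point
#' effect under condition 2, and a grid of batch disturbances — a cross-batch
#' mean shift of 0/2/5/10 percentage points and a precision fold of 1/2/5/10
#' applied to batch 2 around a baseline beta precision of 10.
#'
#' @param n_features,n_samples Matrix dimensions (samples must be divisible
#'   by 4 for the balanced 2 x 2 layout).
#' @param n_dm Number of truly differentially methylated features.
#' @param effect_pct Percentage points added to DM features under condition 2.
#' @param batch_mean_diff_pct Cross-batch mean shift in percentage points,
#'   one of 0/2/5/10; the sign alternates per feature by a seeded coin flip.
#' @param batch_precision_fold Batch-2 precision multiplier, one of 1/2/5/10.
#' @param baseline_precision Beta precision of batch 1.
#' @param mean_coverage Mean sequencing depth (negative binomial, size 5,
#'   floored at 1).
#' @param seed RNG seed; the whole dataset is a deterministic function of it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_features = 1000L, n_samples = 20L, n_dm = 100L,
                       effect_pct = 10, batch_mean_diff_pct = 0,
                       batch_precision_fold = 1,
                       baseline_precision = 10, mean_coverage = 30,
                       seed = 1L) {
  if (n_samples %% 4L != 0L) stop("n_samples must be divisible by 4")
  if (n_dm > n_features) stop("n_dm cannot exceed n_features")
  if (!batch_mean_diff_pct %in% c(0, 2, 5, 10)) {
    stop("batch_mean_diff_pct must be one of 0, 2, 5, 10")
  }
  if (!batch_precision_fold %in% c(1, 2, 5, 10)) {
    stop("batch_precision_fold must be one of 1, 2, 5, 10")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a bisulfite methylation dataset with batch effects
#'
#' Per feature, a base methylation proportion is drawn from the bimodal
#' mixture `0.5 Beta(0.6, 2.4) + 0.5 Beta(2.4, 0.6)` (real CpG methylation is
#' strongly bimodal). Differentially methylated features gain
#' `effect_pct / 100` under condition 2; batch-2 samples are shifted by
#' `+/- batch_mean_diff_pct / 100` (sign per feature) and use precision
#' `baseline_precision * batch_precision_fold`. True proportions are clamped
#' to `[0.001, 0.999]`. Per cell, coverage is negative binomial (mean
#' `mean_coverage`, size 5, floor 1), the realized proportion is
#' beta-distributed around the true one with the batch's precision, and the
#' methylated count is binomial. Beta-values are the methylated/coverage
#' ratios, squeezed off the boundaries.
#'
#' @param config A [sim_config()].
#' @return List with `coverage`, `methylated`, `beta` (features x samples
#'   matrices), `design` (a [sample_design()]), and `truth` (list with
#'   `is_dm`, `true_base_prop`, `dm_sign` of the batch shift per feature,
#'   and the injected `mean_shift`/`precision_fold`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  Fn <- config$n_features; S <- config$n_samples
  per <- S %/% 4L
  batch <- rep(c("B1", "B2"), each = S %/% 2L)
  condition <- rep(rep(c("C1", "C2"), each = per), 2L)
  sample_ids <- sprintf("S%02d", seq_len(S))
  feature_ids <- sprintf("f%04d", seq_len(Fn))
  design <- sample_design(sample_ids, batch, condition)

  mix <- stats::runif(Fn) < 0.5
  p_base <- ifelse(mix, stats::rbeta(Fn, 0.6, 2.4), stats::rbeta(Fn, 2.4, 0.6))
  is_dm <- seq_len(Fn) %in% sample(Fn, config$n_dm)
  shift_sign <- ifelse(stats::runif(Fn) < 0.5, 1, -1)

  effect <- config$effect_pct / 100
  bshift <- config$batch_mean_diff_pct / 100
  phi_b <- c(B1 = config$baseline_precision,
             B2 = config$baseline_precision * config$batch_precision_fold)

  p_cell <- matrix(p_base, Fn, S)
  p_cell[, condition == "C2"] <- p_cell[, condition == "C2"] +
    effect * is_dm
  p_cell[, batch == "B2"] <- p_cell[, batch == "B2"] + bshift * shift_sign
  p_cell <- pmin(pmax(p_cell, 0.001), 0.999)

  coverage <- matrix(stats::rnbinom(Fn * S, mu = config$mean_coverage, size = 5),
                     Fn, S)
  while (any(coverage == 0)) {
    z <- coverage == 0
    coverage[z] <- stats::rnbinom(sum(z), mu = config$mean_coverage, size = 5)
  }
  phi_cell <- matrix(phi_b[batch], Fn, S, byrow = TRUE)
  prop <- matrix(stats::rbeta(Fn * S, p_cell * phi_cell,
                              (1 - p_cell) * phi_cell), Fn, S)
  prop <- pmin(pmax(prop, 1e-6), 1 - 1e-6)
  methylated <- matrix(stats::rbinom(Fn * S, coverage, prop), Fn, S)
  dimnames(coverage) <- dimnames(methylated) <- list(feature_ids, sample_ids)
  beta <- counts_to_beta(methylated, coverage)
  list(coverage = coverage, methylated = methylated, beta = beta,
       design = design,
       truth = list(is_dm = is_dm, true_base_prop = p_base,
                    dm_sign = shift_sign,
                    mean_shift = bshift,
                    precision_fold = config$batch_precision_fold))
}

#' Adversarial boundary instance for Gaussian-vs-beta adjustment
#'
#' Builds a 20-sample, two-batch, two-condition beta-value matrix in which
#' one block of features sits near 0.5 (where a Gaussian working model is
#' harmless) and another sits close to the upper boundary with a strong
#' cross-batch precision difference. Rescaling the tight boundary batch to
#' the pooled scale pushes Gaussian-adjusted values above 1, while the
#' quantile map of the beta model cannot leave (0, 1).
#'
#' @param seed RNG seed.
#' @param n_features Total features (half mid-range, half boundary).
#' @return List with `beta` (matrix) and `design`.
#' @export
make_boundary_instance <- function(seed = 1L, n_features = 60L) {
  set.seed(seed)
  S <- 20L
  batch <- rep(c("B1", "B2"), each = 10L)
  condition <- rep(rep(c("C1", "C2"), each = 5L), 2L)
  design <- sample_design(sprintf("S%02d", 1:S), batch, condition)
  half <- n_features %/% 2L
  mu <- c(rep(0.5, half), rep(0.93, n_features - half))
  # batch 1 diffuse, batch 2 concentrated just under the boundary
  beta <- matrix(NA_real_, n_features, S,
                 dimnames = list(sprintf("f%03d", seq_len(n_features)),
                                 sprintf("S%02d", 1:S)))
  for (f in seq_len(n_features)) {
    phi1 <- 8; phi2 <- 300
    m1 <- mu[f]
    m2 <- if (mu[f] > 0.7) 0.965 else mu[f]
    beta[f, batch == "B1"] <- stats::rbeta(10L, m1 * phi1, (1 - m1) * phi1)
    beta[f, batch == "B2"] <- stats::rbeta(10L, m2 * phi2, (1 - m2) * phi2)
  }
  beta <- squeeze_beta(beta)
  attr(beta, "squeezed") <- NULL
  list(beta = beta, design = design)
}
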