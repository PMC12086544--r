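#' Proportion of variance explained by batch, per feature
#'
#' One-way decomposition on the M-value scale: per feature,
#' `R^2 = between-batch SS / total SS`. A constant feature has `R^2 = 0` by
#' convention. The mean across features summarizes how batch-affected a
#' matrix is, before vs after correction.
#'
#' @param matrix Features x samples matrix; values in (0, 1) are treated as
#'   beta-values and logit-transformed unless `transform = "none"`.
#' @param batch Batch label per sample (or a [sample_design()]).
#' @param transform `"auto"` (logit if all values are inside (0, 1)),
#'   `"mvalue"`, or `"none"`.
#' @return List with `r2` (per feature) and `mean_r2`.
#' @export
variance_explained <- function(matrix, batch, transform = c("auto", "mvalue", "none")) {
  transform <- match.arg(transform)
  if (inherits(batch, "sample_design")) batch <- batch$batch
  batch <- factor(batch)
  if (nlevels(batch) < 2L) stop("need >= 2 batches")
  if (transform == "mvalue" ||
      (transform == "auto" && all(matrix > 0 & matrix < 1, na.rm = TRUE))) {
    matrix <- beta_to_m(squeeze_beta(matrix))
  }
  r2 <- apply(matrix, 1L, function(y) {
    ok <- !is.na(y)
    tot <- sum((y[ok] - mean(y[ok]))^2)
    if (tot == 0) return(0)
    gm <- tapply(y[ok], batch[ok], mean)
    n <- tabulate(batch[ok], nbins = nlevels(batch))
    between <- sum(n[n > 0] * (gm[!is.na(gm)] - mean(y[ok]))^2)
    between / tot
  })
  list(r2 = unname(r2), mean_r2 = mean(r2))
}

.bench_methods <- c("no_adjust", "combat_met", "combat_met_shrink",
                    "mvalue_combat", "onestep", "combat_biseq")

#' Run the batch-correction benchmark grid
#'
#' For every scenario (cross-batch mean difference x precision fold) and
#' replicate: simulate a dataset ([simulate_dataset()]), apply each requested
#' correction route to the *same* data, test every feature's condition effect
#' (M-value linear model with variance moderation, or the beta-binomial LRT
#' for the count route), and score TPR/FPR at `p < alpha` against the
#' simulation truth. Medians and IQRs are taken across replicates.
#' Replicate seeds are drawn once from the master seed, so results are
#' reproducible and every method sees identical data within a replicate.
#'
#' @param methods Subset of `no_adjust`, `combat_met` (the beta-regression
#'   quantile adjustment), `combat_met_shrink` (same with EB shrinkage),
#'   `mvalue_combat`, `onestep` (batch as covariate), `combat_biseq`
#'   (count-level adjustment + LRT).
#' @param mean_diffs,folds Grid values (subsets of 0/2/5/10 and 1/2/5/10).
#' @param n_reps Replicates per scenario.
#' @param n_samples,n_features,n_dm,effect_pct Passed to [sim_config()].
#' @param alpha Significance threshold for scoring.
#' @param seed Master seed.
#' @param n_jobs Worker processes for the beta-regression fits.
#' @return Data frame with one row per scenario x method: `mean_diff_pct`,
#'   `precision_fold`, `method`, `n_reps`, `n_failed`, `median_tpr`,
#'   `median_fpr`, `iqr_tpr`, `iqr_fpr`. The attribute `"replicates"` holds
#'   the replicate-level TPR/FPR table behind the medians.
#' @export
run_grid <- function(methods = c("no_adjust", "combat_met", "mvalue_combat"),
                     mean_diffs = c(0, 2, 5, 10), folds = c(1, 2, 5, 10),
                     n_reps = 50L, n_samples = 20L, n_features = 1000L,
                     n_dm = NULL, effect_pct = 10, alpha = 0.05,
                     seed = 1L, n_jobs = 1L) {
  methods <- match.arg(methods, .bench_methods, several.ok = TRUE)
  if (is.null(n_dm)) n_dm <- max(1L, round(n_features / 10))
  grid <- expand.grid(mean_diff = mean_diffs, fold = folds,
                      KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  seed_mat <- matrix(sample.int(.Machine$integer.max - 1L,
                                nrow(grid) * n_reps),
                     nrow(grid), n_reps)
  rows <- list()
  reps_out <- list()
  for (g in seq_len(nrow(grid))) {
    res <- matrix(NA_real_, n_reps, 2L * length(methods))
    failed <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      cfg <- sim_config(n_features = n_features, n_samples = n_samples,
                        n_dm = n_dm, effect_pct = effect_pct,
                        batch_mean_diff_pct = grid$mean_diff[g],
                        batch_precision_fold = grid$fold[g],
                        seed = seed_mat[g, r])
      sim <- simulate_dataset(cfg)
      scores <- tryCatch(
        unlist(lapply(methods, function(m) {
          run_one_method(m, sim, alpha = alpha,
                         seed = seed_mat[g, r] %% 1000003L, n_jobs = n_jobs)
        })),
        error = function(e) NULL)
      if (is.null(scores)) failed[r] <- TRUE else res[r, ] <- scores
    }
    for (mi in seq_along(methods)) {
      tpr <- res[!failed, 2L * mi - 1L]; fpr <- res[!failed, 2L * mi]
      reps_out[[length(reps_out) + 1L]] <- data.frame(
        mean_diff_pct = grid$mean_diff[g], precision_fold = grid$fold[g],
        method = methods[mi], rep = which(!failed), tpr = tpr, fpr = fpr)
      rows[[length(rows) + 1L]] <- data.frame(
        mean_diff_pct = grid$mean_diff[g], precision_fold = grid$fold[g],
        method = methods[mi], n_reps = sum(!failed), n_failed = sum(failed),
        median_tpr = stats::median(tpr, na.rm = TRUE),
        median_fpr = stats::median(fpr, na.rm = TRUE),
        iqr_tpr = stats::IQR(tpr, na.rm = TRUE),
        iqr_fpr = stats::IQR(fpr, na.rm = TRUE))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "replicates") <- do.call(rbind, reps_out)
  out
}

run_one_method <- function(method, sim, alpha, seed, n_jobs = 1L) {
  p <- switch(method,
    no_adjust = mvalue_lm_test(sim$beta, sim$design)$p_value,
    onestep = mvalue_lm_test(sim$beta, sim$design,
                             extra_covariates = onestep_design(sim$design))$p_value,
    combat_met = {
      adj <- suppressWarnings(beta_combat(sim$beta, sim$design, n_jobs = n_jobs))
      mvalue_lm_test(adj$adjusted, sim$design)$p_value
    },
    combat_met_shrink = {
      adj <- suppressWarnings(beta_combat(sim$beta, sim$design, shrink = TRUE,
                                          seed = seed, n_jobs = n_jobs))
      mvalue_lm_test(adj$adjusted, sim$design)$p_value
    },
    mvalue_combat = mvalue_lm_test(mvalue_combat(sim$beta, sim$design),
                                   sim$design)$p_value,
    combat_biseq = {
      adj <- adjust_counts(sim$methylated, sim$coverage, sim$design)
      bb_lrt(adj$methylated, adj$coverage, sim$design)
    })
  tpr_fpr(p, sim$truth$is_dm, alpha = alpha)
}
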