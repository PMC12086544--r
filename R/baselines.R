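# Parametric empirical-Bayes location/scale batch adjustment on a Gaussian
# working scale (the classic microarray ComBat model). Implemented here so
# the empirical-Bayes step can be switched off, which reduces to exact
# per-batch standardization and gives a closed-form oracle for testing.

# EB iterative solver for (gamma*, delta*) of one batch (Johnson-style)
.eb_it_sol <- function(sdat, g_hat, d_hat, g_bar, t2, a_prior, b_prior,
                       conv = 1e-4, maxit = 100L) {
  n <- rowSums(!is.na(sdat))
  g_old <- g_hat; d_old <- d_hat
  for (it in seq_len(maxit)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((sdat - g_new)^2, na.rm = TRUE)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / abs(g_old), abs(d_new - d_old) / d_old)
    g_old <- g_new; d_old <- d_new
    if (is.finite(change) && change < conv) break
  }
  list(gamma_star = g_old, delta_star = d_old)
}

#' Gaussian location/scale batch adjustment (classic ComBat)
#'
#' Per-feature standardization against a batch-free fit, per-batch location
#' (`gamma`) and scale (`delta`) estimation, optional parametric
#' empirical-Bayes shrinkage (normal prior on `gamma`, inverse-gamma on
#' `delta`, hyperparameters by moment matching, posteriors by the standard
#' iterative solver to tolerance 1e-4), and back-transformation. Condition
#' and covariate effects are preserved. Used here as the baseline the beta
#' model is compared against; apply it to M-values for the usual methylation
#' workflow ([mvalue_combat()]).
#'
#' @param data Features x samples numeric matrix (any real scale).
#' @param design A [sample_design()].
#' @param eb Apply empirical-Bayes shrinkage of the batch parameters
#'   (default `TRUE`); `eb = FALSE` uses the per-batch estimates directly,
#'   i.e. exact per-batch standardization.
#' @param mean_only Adjust locations only, leaving scales untouched.
#' @param ref_batch Optional reference batch: its samples are returned
#'   unchanged and all other batches are moved to its location/scale.
#' @return Adjusted matrix, same shape and dimnames. Values are not clamped
#'   to any interval.
#' @export
gaussian_combat <- function(data, design, eb = TRUE, mean_only = FALSE,
                            ref_batch = NULL) {
  check_matrix_design(data, design)
  batch <- design$batch
  nb <- nlevels(batch)
  if (nb < 2L) return(data)
  if (!is.null(ref_batch) && !ref_batch %in% levels(batch)) {
    stop("unknown reference batch: ", ref_batch)
  }
  B <- stats::model.matrix(~0 + batch)
  colnames(B) <- levels(batch)
  Xc <- mean_model_matrix(batch = factor(rep(1, ncol(data))),
                          condition = design$condition,
                          covariates = design$covariates)[, -1L, drop = FALSE]
  X <- cbind(B, Xc)
  if (qr(X)$rank < ncol(X)) stop("confounded design")
  n_i <- design$batch_sizes
  S <- ncol(data)

  # per-feature OLS of batch means + covariate effects
  fit <- stats::lm.fit(X, t(data))
  beta_hat <- t(fit$coefficients)               # F x ncol(X)
  grand_mean <- if (is.null(ref_batch)) {
    drop(beta_hat[, seq_len(nb), drop = FALSE] %*% (n_i / S))
  } else {
    beta_hat[, ref_batch]
  }
  cov_part <- if (ncol(Xc)) {
    beta_hat[, nb + seq_len(ncol(Xc)), drop = FALSE] %*% t(Xc)
  } else 0
  stand_mean <- outer(grand_mean, rep(1, S)) + cov_part
  resid <- data - t(X %*% t(beta_hat))
  var_pooled <- if (is.null(ref_batch)) {
    rowMeans(resid^2)
  } else {
    ridx <- batch == ref_batch
    rowSums(resid[, ridx, drop = FALSE]^2) / sum(ridx)
  }
  var_pooled <- pmax(var_pooled, 1e-12)
  sdat <- (data - stand_mean) / sqrt(var_pooled)

  out_s <- sdat
  for (b in levels(batch)) {
    idx <- batch == b
    sb <- sdat[, idx, drop = FALSE]
    g_hat <- rowMeans(sb, na.rm = TRUE)
    d_hat <- apply(sb, 1L, stats::var, na.rm = TRUE)
    d_hat <- pmax(d_hat, 1e-12)
    if (mean_only) d_hat <- rep(1, length(d_hat))
    if (eb) {
      g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
      m <- mean(d_hat); v <- stats::var(d_hat)
      if (!is.finite(t2) || t2 <= 0 || !is.finite(v) || v <= 0) {
        # too few features to estimate priors: fall back to raw estimates
        out_s[, idx] <- (sb - g_hat) / sqrt(d_hat)
        next
      }
      a_prior <- (2 * v + m^2) / v
      b_prior <- (m * v + m^3) / v
      if (mean_only) {
        n <- sum(idx)
        g_star <- (t2 * n * g_hat + g_bar) / (t2 * n + 1)
        d_star <- d_hat
      } else {
        sol <- .eb_it_sol(sb, g_hat, d_hat, g_bar, t2, a_prior, b_prior)
        g_star <- sol$gamma_star; d_star <- sol$delta_star
      }
    } else {
      g_star <- g_hat; d_star <- d_hat
    }
    out_s[, idx] <- (sb - g_star) / sqrt(d_star)
  }
  out <- out_s * sqrt(var_pooled) + stand_mean
  if (!is.null(ref_batch)) out[, batch == ref_batch] <- data[, batch == ref_batch]
  dimnames(out) <- dimnames(data)
  out
}

#' Gaussian ComBat applied directly to beta-values
#'
#' Deliberately applies the Gaussian location/scale model to raw proportions
#' and does NOT clamp the output: with batch means near the boundaries and
#' unequal precisions, adjusted values can leave `[0, 1]`, which is the
#' failure mode the beta-regression adjustment avoids.
#'
#' @inheritParams gaussian_combat
#' @param matrix Beta-value matrix in (0, 1).
#' @return Real-valued matrix, possibly outside `[0, 1]`.
#' @export
naive_combat <- function(matrix, design, eb = TRUE, ref_batch = NULL) {
  gaussian_combat(matrix, design, eb = eb, ref_batch = ref_batch)
}

#' Gaussian ComBat on M-values
#'
#' Logit-transforms beta-values to M-values, runs [gaussian_combat()], and
#' transforms back, so the result is always inside (0, 1). This is the
#' standard Gaussian workflow for methylation arrays.
#'
#' @inheritParams naive_combat
#' @return Beta-value matrix strictly in (0, 1).
#' @export
mvalue_combat <- function(matrix, design, eb = TRUE, ref_batch = NULL) {
  m <- beta_to_m(squeeze_beta(matrix))
  m_to_beta(gaussian_combat(m, design, eb = eb, ref_batch = ref_batch))
}

#' Batch-indicator columns for "one-step" covariate adjustment
#'
#' Instead of correcting the data, the one-step approach puts the batch
#' variable straight into the differential model. This helper returns the
#' full-rank batch dummy columns to pass as `extra_covariates` to
#' [mvalue_lm_test()]; with a single batch the result has zero columns.
#'
#' @param design A [sample_design()].
#' @return Numeric matrix (samples x (n_batches - 1)).
#' @export
onestep_design <- function(design) {
  if (design$n_batches < 2L) {
    return(matrix(0, length(design$sample_ids), 0L))
  }
  X <- stats::model.matrix(~batch, data.frame(batch = design$batch))[, -1L, drop = FALSE]
  full <- cbind(mean_model_matrix(batch = factor(rep(1, nrow(X))),
                                  condition = design$condition,
                                  covariates = design$covariates), X)
  if (qr(full)$rank < ncol(full)) stop("batch confounded with condition/covariates")
  rownames(X) <- design$sample_ids
  X
}
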