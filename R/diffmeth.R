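#' Per-feature differential methylation test on M-values
#'
#' Logit-transforms beta-values to M-values and fits a per-feature linear
#' model (intercept + condition + design covariates + optional extra
#' columns, e.g. batch dummies from [onestep_design()]) via limma. With
#' `moderation = TRUE` the residual variances are squeezed by limma's
#' empirical-Bayes inverse-chi-square scheme and the moderated t is used;
#' otherwise the ordinary t-statistic on the residual degrees of freedom.
#' Only two-level conditions are supported.
#'
#' @param matrix Features x samples beta-value matrix (or already-M-valued
#'   matrix if `is_mvalue = TRUE`).
#' @param design A [sample_design()].
#' @param extra_covariates Optional samples x k numeric matrix appended to
#'   the design (the "one-step" batch covariate route).
#' @param moderation Use the moderated t (default) or the ordinary t.
#' @param is_mvalue Set if `matrix` is already on the M-value scale.
#' @return Data frame with `feature`, `estimate` (condition effect on the
#'   M-value scale), `p_value`, and BH-adjusted `q_value`.
#' @export
mvalue_lm_test <- function(matrix, design, extra_covariates = NULL,
                           moderation = TRUE, is_mvalue = FALSE) {
  check_matrix_design(matrix, design)
  if (nlevels(design$condition) != 2L) {
    stop("only two-level conditions are supported")
  }
  M <- if (is_mvalue) matrix else beta_to_m(squeeze_beta(matrix))
  X <- mean_model_matrix(batch = factor(rep(1L, ncol(M))),
                         condition = design$condition,
                         covariates = design$covariates)
  coef_name <- colnames(X)[2L]
  if (!is.null(extra_covariates)) {
    X <- cbind(X, as.matrix(extra_covariates))
    if (qr(X)$rank < ncol(X)) stop("extra covariates make the design rank deficient")
  }
  fit <- limma::lmFit(M, X)
  est <- fit$coefficients[, coef_name]
  if (moderation) {
    eb <- limma::eBayes(fit)
    p <- eb$p.value[, coef_name]
  } else {
    tstat <- est / (fit$stdev.unscaled[, coef_name] * fit$sigma)
    p <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)
  }
  data.frame(feature = rownames(M) %||% seq_len(nrow(M)),
             estimate = unname(est), p_value = unname(p),
             q_value = stats::p.adjust(p, method = "BH"),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' True/false positive rates against simulation truth
#'
#' A feature counts as significant when `p < alpha` (the benchmark uses raw
#' p-values, no multiplicity correction). `NA` p-values are excluded from
#' both numerator and denominator.
#'
#' @param pvals Numeric p-values, one per feature.
#' @param is_dm Logical ground-truth flags of the same length.
#' @param alpha Significance threshold (default 0.05).
#' @return Named numeric vector `c(tpr = , fpr = )`; `tpr` is `NA` when no
#'   feature is truly differentially methylated.
#' @export
tpr_fpr <- function(pvals, is_dm, alpha = 0.05) {
  if (length(pvals) != length(is_dm)) stop("length mismatch")
  ok <- !is.na(pvals)
  sig <- ok & pvals < alpha
  n_dm <- sum(is_dm & ok); n_null <- sum(!is_dm & ok)
  c(tpr = if (n_dm == 0L) NA_real_ else sum(sig & is_dm) / n_dm,
    fpr = if (n_null == 0L) NA_real_ else sum(sig & !is_dm) / n_null)
}
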