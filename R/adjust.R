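#' Batch-free distribution parameters for one feature
#'
#' Removes the estimated batch effect from the fitted mean on the logit
#' scale, `logit(mu_star_j) = logit(mu_hat_ij) - gamma_hat_i`, and pools the
#' batch precisions by sample size, `phi_star = sum(n_i phi_i) / sum(n_i)`.
#' With a reference batch, the reference's own mean parameterization and
#' precision are adopted instead, so reference-batch samples are left where
#' they are.
#'
#' @param fit A converged [fit_feature()] result.
#' @param design The [sample_design()] used for the fit.
#' @param ref_batch Optional reference batch label (must match the fit's).
#' @return List with `mu_star` (per sample, `NA` where the input was `NA`)
#'   and scalar `phi_star`.
#' @export
batch_free_params <- function(fit, design, ref_batch = NULL) {
  if (!isTRUE(fit$converged)) stop("batch_free_params() needs a converged fit")
  if (!is.null(ref_batch) && !ref_batch %in% levels(design$batch)) {
    stop("unknown reference batch: ", ref_batch)
  }
  g <- fit$gamma_hat[as.character(design$batch)]
  mu_star <- stats::plogis(stats::qlogis(fit$mu_hat) - g)
  phi_star <- if (is.null(ref_batch)) {
    n_i <- tabulate(design$batch[fit$keep], nbins = nlevels(design$batch))
    sum(n_i * fit$phi_hat) / sum(n_i)
  } else {
    unname(fit$phi_hat[ref_batch])
  }
  list(mu_star = unname(mu_star), phi_star = phi_star)
}

#' Map observations onto a batch-free beta distribution by quantile matching
#'
#' Each value's cumulative probability under its estimated distribution
#' `Beta(mu_hat * phi_hat, (1 - mu_hat) * phi_hat)` is evaluated and inverted
#' under the batch-free distribution `Beta(mu_star * phi_star,
#' (1 - mu_star) * phi_star)`. Because beta-values are continuous the
#' "closest quantile" match is an exact inverse-CDF evaluation, which is
#' monotone in `y`. Quantiles are clamped to `[1e-12, 1 - 1e-12]` so squeezed
#' boundary cells can never map to exactly 0 or 1.
#'
#' @param y Observed proportions in (0, 1) (vectorized; `NA` passes through).
#' @param mu_hat,phi_hat Estimated mean/precision per observation.
#' @param mu_star,phi_star Batch-free mean/precision per observation.
#' @return Adjusted proportions, strictly inside (0, 1).
#' @export
match_quantiles <- function(y, mu_hat, phi_hat, mu_star, phi_star) {
  q <- stats::pbeta(y, mu_hat * phi_hat, (1 - mu_hat) * phi_hat)
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  out <- stats::qbeta(q, mu_star * phi_star, (1 - mu_star) * phi_star)
  if (any(!is.finite(out) & !is.na(y))) {
    stop("non-finite quantile map (mu_star near boundary or phi_star <= 0)")
  }
  pmin(pmax(out, 1e-12), 1 - 1e-12)
}

#' Batch correction of beta-values by beta regression and quantile matching
#'
#' The workhorse of the package. For every feature a beta regression with
#' logit mean model (condition and covariates retained, additive batch
#' effect) and batch-specific precision is fitted by maximum likelihood
#' ([fit_feature()]); the batch-free distribution is computed per sample
#' ([batch_free_params()]); and each observation is mapped onto it by
#' quantile matching ([match_quantiles()]). Biological covariate effects are
#' kept in the batch-free mean — only the batch term is removed. Adjusted
#' values are therefore guaranteed to stay in (0, 1).
#'
#' Non-converged features pass through unadjusted with a flag; `NA` cells
#' stay `NA`.
#'
#' @param matrix Features x samples beta-value matrix strictly in (0, 1)
#'   (apart from `NA`); see [read_beta_matrix()]/[squeeze_beta()].
#' @param design A [sample_design()].
#' @param ref_batch Optional batch label: adjust every batch to the mean and
#'   precision of this batch (its samples are returned unchanged), allowing
#'   new batches to be harmonized later without touching earlier results.
#' @param shrink Apply nonparametric empirical-Bayes shrinkage of the batch
#'   parameters across features ([eb_shrink()]) before adjusting. Off by
#'   default: with the beta model it under-corrects batch effects.
#' @param n_mc_features Number of Monte-Carlo donor features for shrinkage
#'   (default `min(F, 500)`).
#' @param seed RNG seed, required when `shrink = TRUE`.
#' @param n_jobs Worker processes for the fitting step.
#' @param mode Precision model, see [fit_feature()].
#' @return List of class `batch_adjustment` with `adjusted` (matrix, same
#'   dimnames/orientation as the input), `status` (per feature: `"adjusted"`,
#'   `"passthrough_nonconverged"`, or `"passthrough_na"`), and `fits`.
#' @export
beta_combat <- function(matrix, design, ref_batch = NULL, shrink = FALSE,
                        n_mc_features = NULL, seed = NULL, n_jobs = 1L,
                        mode = c("per_batch_precision", "pooled_precision")) {
  mode <- match.arg(mode)
  check_matrix_design(matrix, design)
  if (shrink && is.null(seed)) stop("shrink = TRUE requires a seed")
  fits <- fit_all(matrix, design, n_jobs = n_jobs, mode = mode,
                  ref_batch = ref_batch)
  if (shrink) {
    if (is.null(n_mc_features)) n_mc_features <- min(nrow(matrix), 500L)
    fits <- eb_shrink(fits, design, n_mc_features = n_mc_features, seed = seed)
  }
  adjusted <- matrix
  status <- stats::setNames(rep("adjusted", nrow(matrix)), rownames(matrix))
  batch_chr <- as.character(design$batch)
  for (f in seq_len(nrow(matrix))) {
    fit <- fits[[f]]
    if (all(is.na(matrix[f, ]))) { status[f] <- "passthrough_na"; next }
    if (!isTRUE(fit$converged)) { status[f] <- "passthrough_nonconverged"; next }
    bfp <- batch_free_params(fit, design, ref_batch = ref_batch)
    phi_obs <- unname(fit$phi_hat[batch_chr])
    # no batch effect estimated (e.g. single batch): identity by construction
    if (all(fit$gamma_hat == 0) && diff(range(fit$phi_hat)) == 0) next
    adj <- match_quantiles(matrix[f, ], fit$mu_hat, phi_obs,
                           bfp$mu_star, bfp$phi_star)
    keep <- fit$keep
    adjusted[f, keep] <- adj[keep]
  }
  if (any(status == "passthrough_nonconverged")) {
    warning(sum(status == "passthrough_nonconverged"),
            " feature(s) did not converge and were passed through unadjusted")
  }
  structure(list(adjusted = adjusted, status = status, fits = fits,
                 ref_batch = ref_batch, shrink = shrink),
            class = "batch_adjustment")
}

#' @export
print.batch_adjustment <- function(x, ...) {
  tab <- table(x$status)
  cat(sprintf("batch_adjustment: %d features x %d samples (%s)\n",
              nrow(x$adjusted), ncol(x$adjusted),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Nonparametric empirical-Bayes shrinkage of batch parameters
#'
#' Pools information across features in the Monte-Carlo style of the
#' count-based ComBat lineage: for each feature, a random subset of
#' `n_mc_features` other converged features acts as donors, and the feature's
#' batch effects `(gamma_i, phi_i)` are replaced by a likelihood-weighted
#' average of the donors' estimates, the weight being the beta likelihood of
#' the feature's own data under the donor's batch parameters (with the
#' feature's own batch-free mean retained). Deterministic given `seed`.
#'
#' @param fits List of [fit_feature()] results (>= 2 converged).
#' @param design The [sample_design()] used for the fits.
#' @param n_mc_features Donors sampled per feature (>= 2).
#' @param seed RNG seed for donor sampling.
#' @return List of fits with `gamma_hat`, `phi_hat`, `mu_hat` replaced by
#'   their shrunken versions (`shrunk = TRUE` marks touched fits).
#' @export
eb_shrink <- function(fits, design, n_mc_features, seed) {
  if (n_mc_features < 2L) stop("n_mc_features must be >= 2")
  conv <- which(vapply(fits, function(f) isTRUE(f$converged), TRUE))
  if (length(conv) < 2L) stop("need at least two converged fits to shrink")
  n_mc_features <- min(n_mc_features, length(conv) - 1L)
  batch_chr <- as.character(design$batch)
  set.seed(seed)
  donor_sets <- lapply(conv, function(f) {
    pool <- setdiff(conv, f)
    if (length(pool) <= n_mc_features) pool else
      sample(pool, n_mc_features)
  })
  # batch-free linear predictor of each feature under its own fit
  eta0 <- lapply(fits, function(fit) {
    if (!isTRUE(fit$converged)) return(NULL)
    stats::qlogis(fit$mu_hat) - fit$gamma_hat[batch_chr]
  })
  out <- fits
  for (k in seq_along(conv)) {
    f <- conv[k]
    fit <- fits[[f]]
    keep <- fit$keep
    yk <- fit$y[keep]
    e0 <- eta0[[f]][keep]
    bk <- batch_chr[keep]
    donors <- donor_sets[[k]]
    lw <- vapply(donors, function(g) {
      gam <- fits[[g]]$gamma_hat
      phi <- fits[[g]]$phi_hat
      mu <- stats::plogis(e0 + gam[bk])
      mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
      beta_loglik(yk, mu, unname(phi[bk]))
    }, 0)
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    gmat <- do.call(rbind, lapply(fits[donors], `[[`, "gamma_hat"))
    pmat <- do.call(rbind, lapply(fits[donors], `[[`, "phi_hat"))
    gam_s <- drop(crossprod(gmat, w))
    phi_s <- drop(crossprod(pmat, w))
    if (is.null(fit$ref_batch)) {
      n_i <- tabulate(design$batch[keep], nbins = nlevels(design$batch))
      gam_s <- gam_s - sum(n_i * gam_s) / sum(n_i)
    } else {
      gam_s <- gam_s - gam_s[fit$ref_batch]
    }
    names(gam_s) <- names(fit$gamma_hat)
    names(phi_s) <- names(fit$phi_hat)
    fit$gamma_hat <- gam_s
    fit$phi_hat <- phi_s
    fit$mu_hat <- stats::plogis(eta0[[f]] + gam_s[batch_chr])
    fit$shrunk <- TRUE
    out[[f]] <- fit
  }
  out
}
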