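#' Beta log-likelihood in the mean/precision parameterization
#'
#' Uses the convention `var(y) = mu * (1 - mu) / (1 + phi)`, i.e. shape
#' parameters `(mu * phi, (1 - mu) * phi)`. Larger `phi` means tighter values
#' around the mean.
#'
#' @param y Proportions strictly in (0, 1).
#' @param mu Means strictly in (0, 1), recycled or per-observation.
#' @param phi Precisions > 0, recycled or per-observation.
#' @return Scalar sum of log beta densities.
#' @export
beta_loglik <- function(y, mu, phi) {
  n <- length(y)
  mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  if (any(y <= 0 | y >= 1) || any(mu <= 0 | mu >= 1) || any(phi <= 0)) {
    stop("beta_loglik(): y and mu must be in (0,1), phi > 0")
  }
  sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

# negative log-likelihood and analytic gradient for the logit-mean /
# per-batch log-precision parameterization; par = (coefs, log phi_1..NB).
# Returns paired fn/gr closures that share one evaluation (optim calls them
# separately at the same point).
.br_objective <- function(y, X, bidx, nb, batch_rows) {
  k <- ncol(X)
  ly <- log(y); l1y <- log1p(-y)
  last_par <- NULL; last <- NULL
  eval_both <- function(par) {
    eta <- drop(X %*% par[seq_len(k)])
    mu <- stats::plogis(eta)
    phi <- exp(par[k + bidx])
    a <- mu * phi; b <- (1 - mu) * phi
    ll <- sum(lgamma(phi) - lgamma(a) - lgamma(b) + (a - 1) * ly + (b - 1) * l1y)
    if (!is.finite(ll)) {
      return(list(value = 1e10, grad = numeric(length(par))))
    }
    dga <- digamma(a); dgb <- digamma(b)
    dmu <- phi * (ly - l1y - dga + dgb) * mu * (1 - mu)
    dlphi_obs <- phi * (digamma(phi) - mu * dga - (1 - mu) * dgb +
                          mu * ly + (1 - mu) * l1y)
    glphi <- vapply(batch_rows, function(rows) sum(dlphi_obs[rows]), 0)
    list(value = -ll, grad = c(-drop(crossprod(X, dmu)), -glphi))
  }
  get <- function(par) {
    if (is.null(last_par) || !identical(par, last_par)) {
      last <<- eval_both(par)
      last_par <<- par
    }
    last
  }
  list(fn = function(par) get(par)$value,
       gr = function(par) get(par)$grad)
}

#' Fit a per-feature beta regression with batch-specific precision
#'
#' The mean model is `logit(mu_ij) = alpha + X_j beta + gamma_i`, where
#' `gamma_i` is the additive batch effect on the M-value scale, and the
#' precision `phi_i` is estimated per batch (or pooled). Estimation is by
#' maximum likelihood: quasi-Newton (BFGS) with analytic gradients,
#' initialized from OLS on `logit(y)` for the mean coefficients and a
#' method-of-moments precision per batch.
#'
#' Identifiability: without a reference batch, the batch effects are centered
#' so that `sum(n_i * gamma_i) = 0`, so `alpha` is the sample-size-weighted
#' cross-batch average M-value. With `ref_batch`, `gamma_ref = 0` exactly and
#' `alpha` is the reference-batch average, with the other `gamma_i` offsets
#' from it.
#'
#' @param y Proportions in (0, 1), one per sample; `NA` samples are dropped.
#' @param design A [sample_design()].
#' @param mode `"per_batch_precision"` (one `phi_i` per batch, the default) or
#'   `"pooled_precision"`.
#' @param ref_batch Optional batch label used as reference.
#' @return A list of class `feature_fit`: `alpha_hat`, `beta_hat` (condition
#'   and covariate coefficients), `gamma_hat` (named per batch), `phi_hat`
#'   (named per batch), `mu_hat` (fitted means per sample, `NA` where the
#'   input was `NA`), `converged`, `loglik`, `n_iter`, `n_dropped`, and the
#'   data/design bookkeeping used by the adjustment step.
#' @export
fit_feature <- function(y, design,
                        mode = c("per_batch_precision", "pooled_precision"),
                        ref_batch = NULL, .ctx = NULL) {
  mode <- match.arg(mode)
  S <- length(design$sample_ids)
  if (length(y) != S) stop("y must have one value per design sample")
  batch_levels <- levels(design$batch)
  if (!is.null(ref_batch) && !ref_batch %in% batch_levels) {
    stop("unknown reference batch: ", ref_batch)
  }
  keep <- !is.na(y)
  yk <- y[keep]
  if (any(yk <= 0 | yk >= 1)) stop("y must be strictly in (0, 1); squeeze first")
  if (is.null(.ctx) || !all(keep)) {
    .ctx <- .fit_context(design, mode, ref_batch, keep)
    if (is.null(.ctx)) {
      return(failed_fit(design, y, reason = "batch emptied by missing values"))
    }
  }
  batch <- .ctx$batch; X <- .ctx$X; bidx_phi <- .ctx$bidx_phi
  nb_phi <- .ctx$nb_phi; ord_levels <- .ctx$ord_levels

  z <- stats::qlogis(yk)
  c0 <- qr.coef(qr(X), z)
  mu0 <- stats::plogis(drop(X %*% c0))
  v <- tapply((yk - mu0)^2, bidx_phi, mean)
  mv <- tapply(mu0 * (1 - mu0), bidx_phi, mean)
  phi0 <- pmin(pmax(mv / pmax(v, 1e-10) - 1, 0.5), 1e4)
  par0 <- c(c0, log(phi0))
  nb <- nb_phi
  obj <- .br_objective(yk, X, bidx_phi, nb, .ctx$batch_rows)
  opt <- tryCatch(
    stats::optim(par0, fn = obj$fn, gr = obj$gr, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-8)),
    error = function(e) NULL)
  if (is.null(opt) || any(!is.finite(opt$par))) {
    return(failed_fit(design, y, reason = "optimizer failure"))
  }
  k <- ncol(X)
  coefs <- opt$par[seq_len(k)]
  names(coefs) <- colnames(X)
  lphi <- opt$par[k + seq_len(nb)]
  phi_hat <- exp(lphi)
  if (nb == 1L) phi_hat <- rep(phi_hat, length(batch_levels))
  names(phi_hat) <- if (nb == 1L) batch_levels else ord_levels
  phi_hat <- phi_hat[batch_levels]

  # batch effects: dummy coding with baseline 0, then center (or keep
  # reference at exactly zero)
  gamma_raw <- stats::setNames(numeric(length(batch_levels)), ord_levels)
  bcols <- grep("^batch", colnames(X))
  if (length(bcols)) {
    gamma_raw[sub("^batch", "", colnames(X)[bcols])] <- coefs[bcols]
  }
  gamma_raw <- gamma_raw[batch_levels]
  n_i <- as.integer(table(batch))  # per batch, in level order, NA-dropped
  alpha <- coefs[1L]
  if (is.null(ref_batch)) {
    gbar <- sum(n_i * gamma_raw) / sum(n_i)
    gamma_hat <- gamma_raw - gbar
    alpha <- alpha + gbar
  } else {
    gamma_hat <- gamma_raw
  }

  eta <- drop(X %*% coefs)
  mu_fit <- stats::plogis(eta)
  mu_hat <- rep(NA_real_, S)
  mu_hat[keep] <- mu_fit
  converged <- opt$convergence == 0L && all(phi_hat < 1e6) &&
    all(mu_fit > 1e-10 & mu_fit < 1 - 1e-10)
  structure(list(
    alpha_hat = unname(alpha),
    beta_hat = coefs[setdiff(seq_len(k), c(1L, bcols))],
    gamma_hat = gamma_hat,
    phi_hat = phi_hat,
    mu_hat = mu_hat,
    converged = converged,
    loglik = -opt$value,
    n_iter = opt$counts[["function"]],
    n_dropped = sum(!keep),
    y = y,
    keep = keep,
    ref_batch = ref_batch,
    mode = mode
  ), class = "feature_fit")
}

# precompute the design-side quantities shared by every feature with the
# same missingness pattern (fit_all hoists this for the no-NA case)
.fit_context <- function(design, mode, ref_batch, keep) {
  batch_levels <- levels(design$batch)
  batch <- factor(design$batch[keep], levels = batch_levels)
  if (any(table(batch) == 0L)) return(NULL)
  cov_keep <- if (is.null(design$covariates)) NULL else
    design$covariates[keep, , drop = FALSE]
  X <- mean_model_matrix(batch = batch, condition = design$condition[keep],
                         covariates = cov_keep, ref_batch = ref_batch)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design after dropping missing samples")
  }
  ord_levels <- if (is.null(ref_batch)) batch_levels else
    c(ref_batch, setdiff(batch_levels, ref_batch))
  bidx <- match(as.character(batch), ord_levels)
  nb_phi <- if (mode == "per_batch_precision") length(batch_levels) else 1L
  bidx_phi <- if (nb_phi == 1L) rep(1L, sum(keep)) else bidx
  list(batch = batch, X = X, bidx_phi = bidx_phi, nb_phi = nb_phi,
       ord_levels = ord_levels,
       batch_rows = lapply(seq_len(nb_phi), function(i) which(bidx_phi == i)))
}

failed_fit <- function(design, y, reason) {
  bl <- levels(design$batch)
  structure(list(
    alpha_hat = NA_real_, beta_hat = NULL,
    gamma_hat = stats::setNames(rep(NA_real_, length(bl)), bl),
    phi_hat = stats::setNames(rep(NA_real_, length(bl)), bl),
    mu_hat = rep(NA_real_, length(y)),
    converged = FALSE, loglik = NA_real_, n_iter = 0L,
    n_dropped = sum(is.na(y)), y = y, keep = !is.na(y),
    ref_batch = NULL, mode = NA_character_, reason = reason
  ), class = "feature_fit")
}

#' @export
print.feature_fit <- function(x, ...) {
  cat(sprintf("feature_fit: alpha=%.4f, gamma=(%s), phi=(%s), %s\n",
              x$alpha_hat,
              paste(sprintf("%.3f", x$gamma_hat), collapse = ", "),
              paste(sprintf("%.2f", x$phi_hat), collapse = ", "),
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit beta regressions for every feature of a matrix
#'
#' Features are independent, so fitting parallelizes trivially; results are
#' identical for any `n_jobs` because no randomness is involved.
#'
#' @param matrix Features x samples beta-value matrix, strictly in (0, 1)
#'   apart from `NA` cells.
#' @param design A [sample_design()].
#' @param n_jobs Number of worker processes (forked; 1 = serial).
#' @inheritParams fit_feature
#' @return Named list of [fit_feature()] results, one per feature.
#' @export
fit_all <- function(matrix, design, n_jobs = 1L,
                    mode = c("per_batch_precision", "pooled_precision"),
                    ref_batch = NULL) {
  mode <- match.arg(mode)
  check_matrix_design(matrix, design)
  ctx <- .fit_context(design, mode, ref_batch,
                      keep = rep(TRUE, ncol(matrix)))
  fit_one <- function(f) fit_feature(matrix[f, ], design, mode = mode,
                                     ref_batch = ref_batch, .ctx = ctx)
  idx <- seq_len(nrow(matrix))
  fits <- if (n_jobs > 1L) {
    parallel::mclapply(idx, fit_one, mc.cores = n_jobs)
  } else {
    lapply(idx, fit_one)
  }
  names(fits) <- rownames(matrix)
  fits
}
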