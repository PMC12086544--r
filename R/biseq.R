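# Beta-binomial machinery for bisulfite sequencing counts. Overdispersion is
# parameterized by the intraclass correlation rho in (0, 1), with beta shape
# parameters a = mu (1 - rho) / rho and b = (1 - mu) (1 - rho) / rho, so
# rho -> 0 recovers the binomial.

#' Beta-binomial density and distribution function
#'
#' @param k Methylated counts (vectorized).
#' @param n Coverages.
#' @param mu Mean proportions in (0, 1).
#' @param rho Intraclass correlation in (0, 1).
#' @param log Return log density.
#' @return `dbetabinom()`: (log-)density; `pbetabinom()`: `P(K <= k)`.
#' @export
dbetabinom <- function(k, n, mu, rho, log = FALSE) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  ll <- lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
  if (log) ll else exp(ll)
}

#' @rdname dbetabinom
#' @export
pbetabinom <- function(k, n, mu, rho) {
  len <- max(length(k), length(n), length(mu), length(rho))
  k <- rep_len(k, len); n <- rep_len(n, len)
  mu <- rep_len(mu, len); rho <- rep_len(rho, len)
  vapply(seq_len(len), function(i) {
    if (is.na(k[i]) || is.na(n[i])) return(NA_real_)
    sum(dbetabinom(0:k[i], n[i], mu[i], rho[i]))
  }, 0)
}

.bb_negll <- function(par, k, n, X, bidx, nbp) {
  p <- ncol(X)
  mu <- stats::plogis(drop(X %*% par[seq_len(p)]))
  rho <- stats::plogis(par[p + bidx])
  mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
  rho <- pmin(pmax(rho, 1e-8), 1 - 1e-8)
  ll <- sum(dbetabinom(k, n, mu, rho, log = TRUE))
  if (!is.finite(ll)) 1e10 else -ll
}

.bb_fit_raw <- function(k, n, X, bidx, nbp) {
  y0 <- squeeze_beta((k + 0.5) / (n + 1))
  c0 <- qr.coef(qr(X), stats::qlogis(y0))
  par0 <- c(c0, rep(stats::qlogis(0.05), nbp))
  opt <- tryCatch(
    stats::optim(par0, .bb_negll, k = k, n = n, X = X, bidx = bidx, nbp = nbp,
                 method = "BFGS", control = list(maxit = 300, reltol = 1e-10)),
    error = function(e) NULL)
  opt
}

#' Per-feature beta-binomial regression on methylated counts
#'
#' Count-level analogue of [fit_feature()]: the mean methylation proportion
#' follows the same logit model (condition + covariates + additive batch
#' effect, sample-size-weighted centering or reference parameterization) and
#' each batch gets its own overdispersion `rho_i`.
#'
#' @param methylated,coverage Integer vectors, one per sample; samples with
#'   zero or missing coverage are dropped.
#' @param design A [sample_design()].
#' @param ref_batch Optional reference batch label.
#' @return List of class `bb_feature_fit` with `alpha_hat`, `beta_hat`,
#'   `gamma_hat`, `rho_hat`, `mu_hat`, `converged`, `loglik`, `n_dropped`.
#' @export
fit_bb_feature <- function(methylated, coverage, design, ref_batch = NULL) {
  S <- length(design$sample_ids)
  if (length(methylated) != S || length(coverage) != S) {
    stop("counts must have one value per design sample")
  }
  if (any(methylated > coverage, na.rm = TRUE)) stop("methylated > coverage")
  keep <- !is.na(coverage) & !is.na(methylated) & coverage > 0
  if (sum(!keep & !(is.na(coverage) | is.na(methylated))) > 0) {
    warning("dropping ", sum(!keep), " sample(s) with zero/missing coverage")
  }
  batch_levels <- levels(design$batch)
  batch <- factor(design$batch[keep], levels = batch_levels)
  cov_keep <- if (is.null(design$covariates)) NULL else
    design$covariates[keep, , drop = FALSE]
  X <- mean_model_matrix(batch = batch, condition = design$condition[keep],
                         covariates = cov_keep, ref_batch = ref_batch)
  ord_levels <- if (is.null(ref_batch)) batch_levels else
    c(ref_batch, setdiff(batch_levels, ref_batch))
  bidx <- match(as.character(batch), ord_levels)
  nbp <- length(batch_levels)
  opt <- .bb_fit_raw(methylated[keep], coverage[keep], X, bidx, nbp)
  bl_fail <- function() structure(list(
    alpha_hat = NA_real_, beta_hat = NULL,
    gamma_hat = stats::setNames(rep(NA_real_, nbp), batch_levels),
    rho_hat = stats::setNames(rep(NA_real_, nbp), batch_levels),
    mu_hat = rep(NA_real_, S), converged = FALSE, loglik = NA_real_,
    n_dropped = sum(!keep), keep = keep, ref_batch = ref_batch
  ), class = "bb_feature_fit")
  if (is.null(opt) || any(!is.finite(opt$par))) return(bl_fail())
  p <- ncol(X)
  coefs <- stats::setNames(opt$par[seq_len(p)], colnames(X))
  rho_hat <- stats::setNames(stats::plogis(opt$par[p + seq_len(nbp)]), ord_levels)
  rho_hat <- rho_hat[batch_levels]
  gamma_raw <- stats::setNames(numeric(nbp), ord_levels)
  bcols <- grep("^batch", colnames(X))
  if (length(bcols)) gamma_raw[sub("^batch", "", colnames(X)[bcols])] <- coefs[bcols]
  gamma_raw <- gamma_raw[batch_levels]
  alpha <- coefs[1L]
  if (is.null(ref_batch)) {
    n_i <- tabulate(batch, nbins = nbp)
    gbar <- sum(n_i * gamma_raw) / sum(n_i)
    gamma_hat <- gamma_raw - gbar
    alpha <- alpha + gbar
  } else {
    gamma_hat <- gamma_raw
  }
  mu_hat <- rep(NA_real_, S)
  mu_hat[keep] <- stats::plogis(drop(X %*% coefs))
  structure(list(
    alpha_hat = unname(alpha),
    beta_hat = coefs[setdiff(seq_len(p), c(1L, bcols))],
    gamma_hat = gamma_hat, rho_hat = rho_hat, mu_hat = mu_hat,
    converged = opt$convergence == 0L, loglik = -opt$value,
    n_dropped = sum(!keep), keep = keep, ref_batch = ref_batch
  ), class = "bb_feature_fit")
}

#' Batch-adjust methylated counts by discrete quantile matching
#'
#' Count-level batch correction: per feature a beta-binomial regression is
#' fitted ([fit_bb_feature()]), the batch-free parameters are formed by
#' removing the batch effect from the logit mean and pooling the per-batch
#' overdispersions weighted by batch total coverage, and each methylated
#' count is replaced by the integer `k` in `[0, coverage]` whose batch-free
#' CDF is closest to the observed count's CDF — a discrete search, so the
#' output retains the integer nature of the data. CDF ties are broken toward
#' the original count. Coverages are unchanged.
#'
#' @param methylated,coverage Features x samples integer matrices.
#' @param design A [sample_design()].
#' @param ref_batch Optional reference batch.
#' @param fits Optional precomputed list of [fit_bb_feature()] results.
#' @return List with `methylated` (adjusted integer matrix), `coverage`
#'   (unchanged), and `status` per feature.
#' @export
adjust_counts <- function(methylated, coverage, design, ref_batch = NULL,
                          fits = NULL) {
  check_matrix_design(methylated, design)
  if (!identical(dim(methylated), dim(coverage))) stop("shape mismatch")
  if (is.null(fits)) {
    fits <- lapply(seq_len(nrow(methylated)), function(f) {
      fit_bb_feature(methylated[f, ], coverage[f, ], design, ref_batch = ref_batch)
    })
  }
  adj <- methylated
  status <- stats::setNames(rep("adjusted", nrow(methylated)), rownames(methylated))
  batch_chr <- as.character(design$batch)
  for (f in seq_len(nrow(methylated))) {
    fit <- fits[[f]]
    if (!isTRUE(fit$converged)) { status[f] <- "passthrough_nonconverged"; next }
    g <- fit$gamma_hat[batch_chr]
    mu_star <- stats::plogis(stats::qlogis(fit$mu_hat) - g)
    if (is.null(ref_batch)) {
      cov_b <- tapply(coverage[f, fit$keep], design$batch[fit$keep], sum)
      cov_b[is.na(cov_b)] <- 0
      rho_star <- sum(cov_b * fit$rho_hat[names(cov_b)]) / sum(cov_b)
    } else {
      rho_star <- unname(fit$rho_hat[ref_batch])
    }
    if (all(fit$gamma_hat == 0) && diff(range(fit$rho_hat)) == 0) next
    for (s in which(fit$keep)) {
      n <- coverage[f, s]; kobs <- methylated[f, s]
      q <- pbetabinom(kobs, n, fit$mu_hat[s], fit$rho_hat[batch_chr[s]])
      cdf <- cumsum(dbetabinom(0:n, n, mu_star[s], rho_star))
      if (!is.finite(q) || any(!is.finite(cdf))) next  # keep original cell
      d <- abs(cdf - q)
      cand <- which(d <= min(d) + 1e-12) - 1L
      adj[f, s] <- cand[which.min(abs(cand - kobs))]
    }
  }
  list(methylated = adj, coverage = coverage, status = status)
}

#' Likelihood-ratio test for a condition effect on methylated counts
#'
#' Fits beta-binomial models with and without the condition term (pooled
#' overdispersion, no batch term — intended for already batch-adjusted
#' counts) and compares twice the log-likelihood difference to a chi-square
#' with `nlevels(condition) - 1` degrees of freedom.
#'
#' @param methylated,coverage Features x samples integer matrices.
#' @param design A [sample_design()].
#' @return Numeric vector of p-values (NA when either model fails).
#' @export
bb_lrt <- function(methylated, coverage, design) {
  check_matrix_design(methylated, design)
  cond <- design$condition
  if (nlevels(cond) < 2L) stop("condition needs >= 2 levels")
  df <- nlevels(cond) - 1L
  one_batch <- factor(rep(1L, length(cond)))
  vapply(seq_len(nrow(methylated)), function(f) {
    k <- methylated[f, ]; n <- coverage[f, ]
    keep <- !is.na(k) & !is.na(n) & n > 0
    if (sum(keep) < 3L) return(NA_real_)
    kk <- k[keep]; nn <- n[keep]
    cov_keep <- if (is.null(design$covariates)) NULL else
      design$covariates[keep, , drop = FALSE]
    Xf <- mean_model_matrix(batch = one_batch[keep], condition = cond[keep],
                            covariates = cov_keep)
    X0 <- mean_model_matrix(batch = one_batch[keep],
                            condition = factor(rep(1L, sum(keep))),
                            covariates = cov_keep)
    bidx <- rep(1L, sum(keep))
    of <- .bb_fit_raw(kk, nn, Xf, bidx, 1L)
    o0 <- .bb_fit_raw(kk, nn, X0, bidx, 1L)
    if (is.null(of) || is.null(o0) || of$convergence != 0L || o0$convergence != 0L) {
      return(NA_real_)
    }
    lr <- max(0, 2 * (o0$value - of$value))
    stats::pchisq(lr, df = df, lower.tail = FALSE)
  }, 0)
}
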