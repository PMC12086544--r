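# shared fixture builders; everything is generated in code at test time

# balanced two-condition x two-batch design
make_design <- function(n = 20L, n_batches = 2L) {
  per <- n %/% (2L * n_batches)
  batch <- rep(paste0("B", seq_len(n_batches)), each = n %/% n_batches)
  condition <- rep(rep(c("C1", "C2"), each = per), n_batches)
  sample_design(sprintf("s%03d", seq_len(n)), batch, condition)
}

# one beta-distributed feature under the logit batch-effect model
sim_beta_feature <- function(design, alpha = qlogis(0.4), cond_effect = 0,
                             gamma = c(0, 0), phi = c(10, 10)) {
  b <- as.integer(design$batch)
  mu <- plogis(alpha + cond_effect * (design$condition == "C2") + gamma[b])
  squeeze_beta(rbeta(length(b), mu * phi[b], (1 - mu) * phi[b]))
}

# matrix of such features (no differential effect unless asked)
sim_beta_matrix <- function(design, n_features, gamma = c(0, 0),
                            phi = c(10, 10), alpha_range = c(-1.5, 1.5)) {
  m <- t(vapply(seq_len(n_features), function(f) {
    sim_beta_feature(design, alpha = runif(1, alpha_range[1], alpha_range[2]),
                     gamma = gamma, phi = phi)
  }, numeric(length(design$sample_ids))))
  dimnames(m) <- list(sprintf("f%04d", seq_len(n_features)), design$sample_ids)
  m
}

# hand-built converged fit object, for exercising the adjustment algebra
# without running the optimizer
fake_fit <- function(design, mu_hat, gamma_hat, phi_hat, y = mu_hat) {
  structure(list(
    alpha_hat = 0, beta_hat = NULL,
    gamma_hat = setNames(gamma_hat, levels(design$batch)),
    phi_hat = setNames(phi_hat, levels(design$batch)),
    mu_hat = mu_hat, converged = TRUE, loglik = 0, n_iter = 1L,
    n_dropped = 0L, y = y, keep = rep(TRUE, length(mu_hat)),
    ref_batch = NULL, mode = "per_batch_precision"
  ), class = "feature_fit")
}

# independent quantile inverter: bisection on the regularized incomplete
# beta function (pbeta), never using qbeta
bisect_beta_quantile <- function(q, shape1, shape2, tol = 1e-12) {
  lo <- 0; hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (pbeta(mid, shape1, shape2) < q) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
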