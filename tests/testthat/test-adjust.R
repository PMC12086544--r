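test_that("batch-free parameters implement the logit shift and pooled precision", {
  d <- make_design(20)
  # equal batches n = (10, 10), phi = (10, 20): pooled precision is 15
  fit <- fake_fit(d, mu_hat = rep(0.5, 20), gamma_hat = c(0, 0),
                  phi_hat = c(10, 20))
  bfp <- batch_free_params(fit, d)
  expect_equal(bfp$phi_star, (10 * 10 + 10 * 20) / 20)
  expect_equal(bfp$mu_star, rep(0.5, 20))
  # removing gamma = log 3 from logit(0.5) lands at 1/4
  fit2 <- fake_fit(d, mu_hat = rep(0.5, 20), gamma_hat = c(log(3), log(3)),
                   phi_hat = c(10, 10))
  expect_equal(batch_free_params(fit2, d)$mu_star, rep(0.25, 20))
  # reference mode adopts the reference batch precision
  expect_equal(batch_free_params(fit, d, ref_batch = "B2")$phi_star, 20)
  expect_error(batch_free_params(fit, d, ref_batch = "nope"), "unknown")
})

test_that("quantile matching is the identity for identical distributions", {
  set.seed(30)
  y <- runif(50, 0.01, 0.99)
  # limited by the pbeta/qbeta round-trip accuracy, not by the method
  expect_equal(match_quantiles(y, 0.3, 10, 0.3, 10), y, tolerance = 1e-8)
  expect_equal(match_quantiles(0.5, 0.5, 2, 0.5, 2), 0.5)
})

test_that("quantile matching agrees with an independent bisection inverter", {
  # value at the 0.25 quantile of Beta(mu=0.3, phi=10) must map to the 0.25
  # quantile of Beta(mu=0.5, phi=10)
  y <- qbeta(0.25, 0.3 * 10, 0.7 * 10)
  got <- match_quantiles(y, 0.3, 10, 0.5, 10)
  want <- bisect_beta_quantile(0.25, 5, 5)
  expect_equal(got, want, tolerance = 1e-9)
  # a spread of quantiles and parameter pairs
  set.seed(31)
  for (i in 1:20) {
    mu1 <- runif(1, 0.1, 0.9); mu2 <- runif(1, 0.1, 0.9)
    p1 <- runif(1, 3, 40); p2 <- runif(1, 3, 40)
    q <- runif(1, 0.02, 0.98)
    y <- bisect_beta_quantile(q, mu1 * p1, (1 - mu1) * p1)
    expect_equal(match_quantiles(y, mu1, p1, mu2, p2),
                 bisect_beta_quantile(q, mu2 * p2, (1 - mu2) * p2),
                 tolerance = 1e-8)
  }
})

test_that("quantile map is monotone in y and stays inside (0,1)", {
  set.seed(32)
  for (i in 1:20) {
    mu1 <- runif(1, 0.05, 0.95); mu2 <- runif(1, 0.05, 0.95)
    p1 <- runif(1, 2, 60); p2 <- runif(1, 2, 60)
    y <- sort(c(1e-8, runif(30, 0.001, 0.999), 1 - 1e-8))
    out <- match_quantiles(y, mu1, p1, mu2, p2)
    expect_true(all(diff(out) >= 0))
    expect_true(all(out > 0 & out < 1))
  }
})

test_that("adjustment is the identity when no batch effect was estimated", {
  set.seed(33)
  d <- make_design(20)
  m <- sim_beta_matrix(d, 5)
  # force zero batch effect and equal precisions through fabricated fits
  fit <- fake_fit(d, mu_hat = rep(0.4, 20), gamma_hat = c(0, 0),
                  phi_hat = c(12, 12))
  bfp <- batch_free_params(fit, d)
  y <- m[1, ]
  expect_equal(unname(match_quantiles(y, fit$mu_hat, 12, bfp$mu_star, bfp$phi_star)),
               unname(y), tolerance = 1e-10)
  # single batch: returned exactly unchanged
  d1 <- sample_design(sprintf("s%d", 1:10), rep("B1", 10),
                      rep(c("C1", "C2"), each = 5))
  m1 <- sim_beta_matrix(d1, 5)[, 1:10]
  colnames(m1) <- d1$sample_ids
  res <- suppressWarnings(beta_combat(m1, d1))
  expect_identical(res$adjusted, m1)
})

test_that("correction removes injected batch effects without leaving (0,1)", {
  set.seed(34)
  d <- make_design(20)
  m <- sim_beta_matrix(d, 120, gamma = c(-0.4, 0.4), phi = c(5, 40))
  res <- suppressWarnings(beta_combat(m, d))
  adj <- res$adjusted
  expect_true(all(adj > 0 & adj < 1))
  before <- variance_explained(m, d)$mean_r2
  after <- variance_explained(adj, d)$mean_r2
  expect_lt(after, before)
  # passthrough features, if any, are returned verbatim
  pt <- res$status != "adjusted"
  if (any(pt)) expect_identical(adj[pt, ], m[pt, ])
})

test_that("near-null data are close to unchanged after correction", {
  set.seed(35)
  d <- make_design(20)
  m <- sim_beta_matrix(d, 60, gamma = c(0, 0), phi = c(10, 10))
  res <- suppressWarnings(beta_combat(m, d))
  ok <- res$status == "adjusted"
  # only estimation noise moves the values
  expect_lt(mean(abs(res$adjusted[ok, ] - m[ok, ])), 0.05)
})

test_that("reference-batch mode leaves the reference essentially fixed", {
  set.seed(36)
  d <- make_design(20)
  m <- sim_beta_matrix(d, 40, gamma = c(-0.5, 0.5), phi = c(8, 30))
  res <- suppressWarnings(beta_combat(m, d, ref_batch = "B1"))
  ok <- res$status == "adjusted"
  ref_cols <- d$batch == "B1"
  # reference samples: gamma_ref = 0 and phi* = phi_ref make the map identity
  expect_equal(res$adjusted[ok, ref_cols], m[ok, ref_cols], tolerance = 1e-6)
  # other batch moves toward the reference batch mean level
  v0 <- variance_explained(m, d)$mean_r2
  v1 <- variance_explained(res$adjusted, d)$mean_r2
  expect_lt(v1, v0)
})

test_that("empirical-Bayes shrinkage pools outlying batch effects toward the bulk", {
  set.seed(37)
  d <- make_design(20)
  n_feat <- 60
  m <- sim_beta_matrix(d, n_feat, gamma = c(-0.25, 0.25), phi = c(10, 10))
  # one outlier with a much larger batch effect
  m[1, ] <- sim_beta_feature(d, alpha = 0, gamma = c(-1.2, 1.2), phi = c(10, 10))
  fits <- fit_all(m, d)
  shr <- eb_shrink(fits, d, n_mc_features = 40, seed = 99)
  bulk <- mean(vapply(fits[-1], function(f) unname(f$gamma_hat["B2"]), 0))
  raw_dev <- abs(unname(fits[[1]]$gamma_hat["B2"]) - bulk)
  shr_dev <- abs(unname(shr[[1]]$gamma_hat["B2"]) - bulk)
  expect_lt(shr_dev, raw_dev)
  # shrunk effects still satisfy the weighted zero-sum constraint
  n_i <- tabulate(d$batch)
  expect_lt(abs(sum(n_i * shr[[1]]$gamma_hat)), 1e-8)
  # identical donors leave a feature untouched
  m_same <- m[rep(2, 6), ]
  rownames(m_same) <- paste0("g", 1:6)
  fits_same <- fit_all(m_same, d)
  shr_same <- eb_shrink(fits_same, d, n_mc_features = 5, seed = 1)
  expect_equal(shr_same[[1]]$gamma_hat, fits_same[[1]]$gamma_hat, tolerance = 1e-10)
  expect_equal(shr_same[[1]]$phi_hat, fits_same[[1]]$phi_hat, tolerance = 1e-10)
  # deterministic given the seed
  shr2 <- eb_shrink(fits, d, n_mc_features = 40, seed = 99)
  expect_identical(shr, shr2)
  expect_error(eb_shrink(fits, d, n_mc_features = 1, seed = 1), ">= 2")
})
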