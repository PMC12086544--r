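test_that("beta-binomial density and CDF behave like a proper distribution", {
  n <- 25L; mu <- 0.3; rho <- 0.15
  dens <- dbetabinom(0:n, n, mu, rho)
  expect_equal(sum(dens), 1, tolerance = 1e-12)
  expect_equal(pbetabinom(n, n, mu, rho), 1, tolerance = 1e-12)
  expect_equal(sum((0:n) * dens), n * mu, tolerance = 1e-10)  # mean n*mu
  # small rho approaches the binomial
  expect_equal(dbetabinom(0:10, 10, 0.4, 1e-7), dbinom(0:10, 10, 0.4),
               tolerance = 1e-4)
  # overdispersion: variance exceeds binomial for rho away from 0
  v <- sum((0:n)^2 * dens) - (n * mu)^2
  expect_gt(v, n * mu * (1 - mu))
})

test_that("beta-binomial fit recovers parameters and beats a grid oracle", {
  set.seed(61)
  n_s <- 500L
  d <- sample_design(sprintf("s%d", 1:n_s), rep("B1", n_s), rep("C1", n_s))
  coverage <- rep(40L, n_s)
  mu <- 0.3; rho <- 0.1
  a <- mu * (1 - rho) / rho; b <- (1 - mu) * (1 - rho) / rho
  p <- rbeta(n_s, a, b)
  meth <- rbinom(n_s, coverage, p)
  fit <- fit_bb_feature(meth, coverage, d)
  expect_true(fit$converged)
  expect_equal(mean(fit$mu_hat), 0.3, tolerance = 0.05)
  expect_equal(unname(fit$rho_hat[1]), 0.1, tolerance = 0.2)
  # 2-D grid oracle over (logit mu, logit rho)
  grid <- expand.grid(lm = qlogis(seq(0.1, 0.6, by = 0.025)),
                      lr = qlogis(seq(0.02, 0.3, by = 0.01)))
  best <- max(apply(grid, 1, function(g) {
    sum(dbetabinom(meth, coverage, plogis(g[1]), plogis(g[2]), log = TRUE))
  }))
  expect_gte(fit$loglik, best - 1e-4)
})

test_that("symmetric two-batch counts give a centered, near-zero batch effect", {
  set.seed(62)
  d <- make_design(20)
  coverage <- rep(30L, 20)
  meth <- rbinom(20, 30, 0.5)
  fit <- fit_bb_feature(meth, coverage, d)
  expect_equal(mean(fit$mu_hat), 0.5, tolerance = 0.1)
  n_i <- tabulate(d$batch)
  expect_lt(abs(sum(n_i * fit$gamma_hat)), 1e-8)
  # zero-coverage sample is dropped, not fatal
  cov2 <- coverage; cov2[3] <- 0L
  met2 <- meth; met2[3] <- 0L
  fit2 <- suppressWarnings(fit_bb_feature(met2, cov2, d))
  expect_equal(fit2$n_dropped, 1L)
})

test_that("count adjustment preserves support, integers, and monotonicity", {
  set.seed(63)
  d <- make_design(20)
  sim <- simulate_dataset(sim_config(n_features = 30L, n_dm = 3L, batch_mean_diff_pct = 10,
                                     batch_precision_fold = 5, seed = 64))
  adj <- adjust_counts(sim$methylated, sim$coverage, sim$design)
  expect_true(all(adj$methylated == round(adj$methylated)))
  expect_true(all(adj$methylated >= 0))
  expect_true(all(adj$methylated <= adj$coverage))
  expect_identical(adj$coverage, sim$coverage)
  # monotone in the original count for fixed cell parameters
  fit <- fit_bb_feature(sim$methylated[1, ], sim$coverage[1, ], sim$design)
  if (fit$converged) {
    n <- 30L; mu1 <- fit$mu_hat[1]; rho1 <- unname(fit$rho_hat[1])
    mu2 <- 0.45; rho2 <- 0.08
    cdf_star <- cumsum(dbetabinom(0:n, n, mu2, rho2))
    mapped <- vapply(0:n, function(k) {
      q <- pbetabinom(k, n, mu1, rho1)
      d_ <- abs(cdf_star - q)
      cand <- which(d_ <= min(d_) + 1e-12) - 1L
      cand[which.min(abs(cand - k))]
    }, 0L)
    expect_true(all(diff(mapped) >= 0))
  }
})

test_that("discrete quantile matching equals exhaustive search on a toy cell", {
  # independent oracle: CDF assembled from first principles via beta functions
  oracle_cdf <- function(k, n, mu, rho) {
    a <- mu * (1 - rho) / rho; b <- (1 - mu) * (1 - rho) / rho
    sum(exp(lchoose(n, 0:k) + lbeta(0:k + a, n - (0:k) + b) - lbeta(a, b)))
  }
  d <- sample_design(paste0("s", 1:6), rep(c("B1", "B2"), each = 3),
                     rep(c("C1", "C2"), 3))
  coverage <- matrix(12L, 1, 6, dimnames = list("f1", d$sample_ids))
  meth <- matrix(c(2L, 4L, 3L, 9L, 10L, 8L), 1, 6, dimnames = dimnames(coverage))
  fit <- fit_bb_feature(meth[1, ], coverage[1, ], d)
  adj <- adjust_counts(meth, coverage, d, fits = list(fit))
  if (fit$converged && adj$status[1] == "adjusted") {
    g <- fit$gamma_hat[as.character(d$batch)]
    mu_star <- plogis(qlogis(fit$mu_hat) - g)
    cov_b <- tapply(coverage[1, ], d$batch, sum)
    rho_star <- sum(cov_b * fit$rho_hat[names(cov_b)]) / sum(cov_b)
    for (s in 1:6) {
      q <- oracle_cdf(meth[1, s], 12L, fit$mu_hat[s],
                      unname(fit$rho_hat[as.character(d$batch[s])]))
      dist <- vapply(0:12, function(k) {
        abs(oracle_cdf(k, 12L, mu_star[s], rho_star) - q)
      }, 0)
      cand <- which(dist <= min(dist) + 1e-12) - 1L
      want <- cand[which.min(abs(cand - meth[1, s]))]
      expect_identical(as.integer(adj$methylated[1, s]), as.integer(want))
    }
  }
  # identity when the batch-free distribution equals the estimated one
  fit_id <- fit
  fit_id$gamma_hat[] <- 0
  fit_id$rho_hat[] <- mean(fit$rho_hat)
  adj_id <- adjust_counts(meth, coverage, d, fits = list(fit_id))
  expect_identical(adj_id$methylated, meth)
})

test_that("the count-level likelihood-ratio test is calibrated and powerful", {
  set.seed(65)
  d <- make_design(20)
  # null: no condition effect; p-values should be close to uniform
  n_feat <- 250L
  cov_m <- matrix(rnbinom(n_feat * 20, mu = 30, size = 5) + 1L, n_feat, 20,
                  dimnames = list(sprintf("f%03d", 1:n_feat), d$sample_ids))
  p0 <- matrix(rbeta(n_feat * 20, 0.4 * 10, 0.6 * 10), n_feat, 20)
  met <- matrix(rbinom(n_feat * 20, cov_m, p0), n_feat, 20,
                dimnames = dimnames(cov_m))
  pv <- bb_lrt(met, cov_m, d)
  expect_gt(suppressWarnings(ks.test(pv[!is.na(pv)], "punif"))$p.value, 0.01)
  # permuting condition labels leaves the p-value distribution unchanged
  dp <- sample_design(d$sample_ids, d$batch,
                      d$condition[c(6:10, 1:5, 16:20, 11:15)])
  pv_perm <- bb_lrt(met[1:50, ], cov_m[1:50, ], dp)
  expect_gt(suppressWarnings(ks.test(pv[1:50], pv_perm))$p.value, 0.01)
  # strong signal: delta-beta 0.3 at coverage 50, n = 100 per arm
  n_s <- 200L
  d2 <- sample_design(sprintf("s%d", 1:n_s), rep(c("B1", "B2"), n_s / 2),
                      rep(c("C1", "C2"), each = n_s / 2))
  hits <- vapply(1:40, function(i) {
    cv <- matrix(50L, 1, n_s)
    pr <- ifelse(d2$condition == "C2", 0.6, 0.3)
    mm <- matrix(rbinom(n_s, 50L, rbeta(n_s, pr * 30, (1 - pr) * 30)), 1, n_s)
    colnames(mm) <- colnames(cv) <- d2$sample_ids
    rownames(mm) <- rownames(cv) <- "f1"
    bb_lrt(mm, cv, d2) < 1e-6
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
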