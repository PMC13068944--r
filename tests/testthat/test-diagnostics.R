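test_that("hdi reproduces windowed examples and tie-breaks low", {
  # uniform grid: all 95% windows tie in width; lowest start wins
  expect_equal(hdi(seq(0.01, 1, by = 0.01), 0.95),
               c(lower = 0.01, upper = 0.95), ignore_attr = TRUE)
  # mass 1 returns the full range for any sample size
  expect_equal(hdi(c(0.4, 0.5, 0.6), 1), c(lower = 0.4, upper = 0.6),
               ignore_attr = TRUE)
  expect_error(hdi(rnorm(50), 0.95), "too few samples")
  expect_error(hdi(numeric(0), 1), "too few samples")
  expect_error(hdi(rnorm(200), 1.5), "mass")
})

test_that("hdi matches a brute-force quantile-grid oracle on Beta(22, 2)", {
  set.seed(61)
  want <- grid_hdi_oracle(qbeta, 0.95, 1e4, shape1 = 22, shape2 = 2)
  got <- hdi(rbeta(1e6, 22, 2), 0.95)
  expect_lt(abs(got[["lower"]] - want[["lower"]]), 0.005)
  expect_lt(abs(got[["upper"]] - want[["upper"]]), 0.005)
})

test_that("hdi is never wider than the equal-tailed interval and is
           affine-equivariant", {
  set.seed(62)
  for (i in 1:20) {
    x <- switch(1 + i %% 3,
                rnorm(500), rbeta(500, 2, 8), rexp(500))
    h <- hdi(x, 0.9)
    s <- sort(x)
    w <- ceiling(0.9 * length(x))
    start_et <- floor((length(x) - w) / 2) + 1
    expect_lte(h[["upper"]] - h[["lower"]],
               s[start_et + w - 1] - s[start_et] + 1e-12)
    # monotone affine map
    a <- runif(1, -5, 5)
    b <- runif(1, 0.1, 4)
    h2 <- hdi(a + b * x, 0.9)
    expect_equal(unname(h2), unname(a + b * h), tolerance = 1e-10)
  }
})

test_that("ess is near N for independent draws and matches AR(1) theory", {
  set.seed(71)
  draws <- matrix(rnorm(1e4), ncol = 4)  # iid: full information
  expect_equal(ess(draws), 1e4, tolerance = 0.15)
  # AR(1), coefficient .9: ESS ~ N (1 - rho) / (1 + rho)
  x <- ar1_chain(1e5, 0.9, seed = 72)
  expect_equal(ess(x), 1e5 * 0.1 / 1.9, tolerance = 0.2)
})

test_that("ess flags degenerate chains and enforces preconditions", {
  expect_warning(e0 <- ess(matrix(2.5, 1000, 4)), "constant")
  expect_equal(e0, 0)
  expect_error(ess(rnorm(500)), ">= 2 chains")
  # invariant under chain relabeling
  set.seed(73)
  m <- matrix(rnorm(4000) + rep(rnorm(4), each = 1000), ncol = 4)
  expect_equal(ess(m), ess(m[, c(3, 1, 4, 2)]))
})

test_that("split-Rhat is ~1 when converged and large when not", {
  set.seed(81)
  good <- matrix(rnorm(4e4), ncol = 4)
  r <- split_rhat(good)
  expect_gte(r, 0.999)  # can undershoot 1 by O(1/n) sampling noise
  expect_lte(r, 1.01)
  bad <- cbind(rnorm(1000), rnorm(1000) + 10)  # 10 sd apart
  expect_gt(split_rhat(bad), 1.5)
  expect_error(split_rhat(list(rnorm(100), rnorm(99))), "equal lengths")
  # invariant under chain relabeling
  expect_equal(split_rhat(good), split_rhat(good[, c(2, 4, 1, 3)]))
})

test_that("split-Rhat matches an independently coded textbook formula", {
  set.seed(82)
  for (i in 1:10) {
    m <- matrix(rnorm(2000, sd = runif(1, 0.5, 2)) +
                  rep(rnorm(4, sd = 0.2), each = 500), ncol = 4)
    # textbook split-chain PSRF, written out directly
    half <- 250
    z <- cbind(m[1:half, ], m[251:500, ])
    W <- mean(apply(z, 2, var))
    B <- half * var(colMeans(z))
    want <- sqrt(((half - 1) / half * W + B / half) / W)
    expect_equal(split_rhat(m), want, tolerance = 1e-10)
  }
})

test_that("summarize_group pools theta draws into point + error bar", {
  # hand-built draws object: point mass at 0.7
  fake <- structure(list(
    omega = matrix(0.7, 200, 2), kappa = matrix(10, 200, 2),
    theta = array(0.7, c(200, 2, 3)),
    group = make_group(c(14, 14, 14)),
    diagnostics = list(ess = c(omega = 0, kappa = 0), rhat = c(1, 1))
  ), class = "mf_draws")
  s <- summarize_group(fake)
  expect_equal(s$mean_theta, 0.7)
  expect_equal(c(s$hdi_lower, s$hdi_upper), c(0.7, 0.7))
  expect_equal(s$n_plates, 3)
})

test_that("symmetric single-plate data give a symmetric pooled posterior", {
  g <- make_group(10, n = 20)
  fit <- sample_posterior(g, hyper_prior(alpha = 1, beta = 1),
                          sampler_settings(seed = 3))
  s <- summarize_group(fit)
  expect_equal(s$mean_theta, 0.5, tolerance = 0.02)
  expect_lt(s$hdi_lower, 0.5)
  expect_gt(s$hdi_upper, 0.5)
})
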