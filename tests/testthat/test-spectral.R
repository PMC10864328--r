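test_that("timescale grids are log-equidistant with exact endpoints", {
  g <- timescale_grid(3, 1, 100)
  expect_equal(g$taus, c(1, 10, 100), tolerance = 1e-12)
  g2 <- timescale_grid(2, 0.5, 7)
  expect_equal(g2$taus, c(0.5, 7))
  expect_error(timescale_grid(1, 1, 10), ">= 2")
  expect_error(timescale_grid(10, -1, 10))
  expect_error(timescale_grid(10, 5, 2))
})

test_that("grid presets match the peptide N-H and detergent C-H definitions", {
  nh <- timescale_grid("NH")
  expect_equal(nh$n, 100L)
  expect_equal(nh$taus[1], 1)
  expect_equal(nh$taus[100], 1e5)
  ratios <- nh$taus[-1] / nh$taus[-100]
  expect_equal(ratios, rep(10^(5 / 99), 99), tolerance = 1e-9)

  ch <- timescale_grid("CH")
  expect_equal(ch$n, 500L)
  expect_equal(ch$taus[1], 1e-3)   # 1 fs
  expect_equal(ch$taus[500], 1e6)  # 1 us
})

test_that("mono-exponential construct-and-refit concentrates weight at the truth", {
  g <- timescale_grid(45, 1, 1e4)   # contains tau = 10 ps exactly
  expect_true(any(abs(g$taus - 10) < 1e-9))
  cf <- analytic_correlation(1, 10, 0:200)
  fit <- fit_exponentials(cf, g)
  expect_lt(fit$residual, 1e-6)
  step <- g$taus[2] / g$taus[1]
  near <- g$taus >= 10 / step & g$taus <= 10 * step
  expect_gt(sum(fit$weights[near]), 0.95 * sum(fit$weights))
  expect_lt(max(abs(predict(fit) - cf$values)), 1e-5)
})

test_that("two-exponential refit on the NH preset recovers decade weights", {
  cf <- analytic_correlation(c(0.5, 0.5), c(1e3, 1e5), seq(0, 2e4, by = 10))
  fit <- fit_exponentials(cf, timescale_grid("NH"))
  taus <- fit$grid$taus
  dec1 <- abs(log10(taus) - 3) <= 0.5   # decade around 1 ns
  dec2 <- abs(log10(taus) - 5) <= 0.5   # decade around 100 ns
  expect_equal(sum(fit$weights[dec1]), 0.5, tolerance = 0.02)
  expect_equal(sum(fit$weights[dec2]), 0.5, tolerance = 0.02)
})

test_that("a constant correlation function loads the slowest timescale", {
  cf <- correlation_function(0:99, rep(1, 100))
  fit <- fit_exponentials(cf, timescale_grid(20, 1, 1e5))
  expect_gt(fit$weights[20] / sum(fit$weights), 0.999)
})

test_that("fit preconditions are enforced", {
  g <- timescale_grid(10, 1, 100)
  expect_error(fit_exponentials(correlation_function(0:5, rep(1, 6)), g), "10 lag")
  expect_error(fit_exponentials(correlation_function(0:20, rep(0, 21)), g), "all-zero")
})

test_that("multi-exponential fit never loses to the best single exponential", {
  set.seed(23)
  g <- timescale_grid("NH")
  cf <- analytic_correlation(c(0.3, 0.4, 0.3), c(50, 800, 6000),
                             seq(0, 5000, by = 5), noise_sd = 0.005, seed = 31)
  fit <- fit_exponentials(cf, g)
  single_best <- min(vapply(g$taus, function(tau) {
    a <- sum(cf$values * exp(-cf$lags / tau)) / sum(exp(-2 * cf$lags / tau))
    sqrt(mean((cf$values - max(a, 0) * exp(-cf$lags / tau))^2))
  }, numeric(1)))
  expect_lte(fit$residual, single_best + 1e-12)
})

test_that("artificial slow-timescale filter zeroes only sub-threshold weight", {
  g <- timescale_grid(10, 1, 1e5)
  f1 <- expfit(c(rep(0.1, 9), 0.005), g)
  out <- filter_artificial_slow(f1)
  expect_equal(out$weights[10], 0)
  expect_true(out$flags[10])
  expect_equal(sum(out$flags), 1L)

  f2 <- expfit(c(rep(0.1, 9), 0), g)
  expect_identical(filter_artificial_slow(f2)$weights, f2$weights)

  f3 <- expfit(c(rep(0.08, 9), 0.2), g)
  expect_warning(out3 <- filter_artificial_slow(f3), "exceeds")
  expect_equal(out3$weights, f3$weights)

  fk <- expfit(c(rep(0.2, 8), 0.004, 0.006), g)
  outk <- filter_artificial_slow(fk, k = 2)
  expect_equal(outk$weights[9:10], c(0, 0))
})

test_that("spectral density follows the analytic Lorentzian sum", {
  g <- timescale_grid(2, 5000, 50000)
  f <- expfit(c(1, 0), g)
  expect_equal(spectral_density(f, 0), 2 * 5000, tolerance = 1e-12)  # J(0) = 2 tau

  g2 <- timescale_grid(2, 1000, 10000)
  f2 <- expfit(c(0.5, 0.5), g2)
  w <- 2 * pi * 0.0862e-3  # 15N Larmor at 850 MHz 1H, rad/ps
  hand <- 2 * (0.5 * 1000 / (1 + w^2 * 1000^2) + 0.5 * 10000 / (1 + w^2 * 10000^2))
  expect_equal(spectral_density(f2, w), hand, tolerance = 1e-12)

  om <- 10^seq(-6, 0, length.out = 40)
  expect_true(all(diff(spectral_density(f, om)) < 0))
})

test_that("effective correlation time is the weighted timescale sum and J(0)/2", {
  f <- expfit(c(1, 0), timescale_grid(2, 5000, 50000))
  expect_equal(effective_correlation_time(f), 5000)
  f2 <- expfit(c(0.5, 0.5), timescale_grid(2, 1000, 10000))
  expect_equal(effective_correlation_time(f2), 5500)
  set.seed(41)
  w <- runif(30); w <- 0.9 * w / sum(w)
  f3 <- expfit(w, timescale_grid(30, 1, 1e5))
  expect_equal(effective_correlation_time(f3), spectral_density(f3, 0) / 2,
               tolerance = 1e-12)
  quad <- stats::integrate(function(t) predict(f3, t), 0, Inf,
                           rel.tol = 1e-10, subdivisions = 2000L)$value
  expect_equal(effective_correlation_time(f3), quad, tolerance = 1e-3)
})

test_that("expfit model methods are coherent", {
  cf <- analytic_correlation(c(0.6, 0.4), c(100, 2000), seq(0, 4000, 4))
  fit <- fit_exponentials(cf, timescale_grid("NH"))
  expect_length(coef(fit), 100)
  expect_equal(fitted(fit), predict(fit, cf$lags))
  expect_equal(residuals(fit), cf$values - fitted(fit))
  expect_equal(sqrt(mean(residuals(fit)^2)), fit$residual, tolerance = 1e-12)
  s <- summary(fit)
  expect_s3_class(s, "summary.expfit")
  expect_equal(s$tau_eff_ps, effective_correlation_time(fit))
})
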