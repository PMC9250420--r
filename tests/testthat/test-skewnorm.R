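test_that("skew-normal density matches its closed form and reduces to the normal", {
  # at the location with alpha = 0: 2 * phi(0) * Phi(0) = phi(0)
  expect_equal(dskewnorm(0, 0, 1, 0, log = TRUE), -0.5 * log(2 * pi))
  # alpha = 0 is the normal density everywhere
  x <- seq(-4, 8, by = 0.37)
  expect_equal(dskewnorm(x, 2, 1.7, 0), dnorm(x, 2, 1.7), tolerance = 1e-12)
  # general point value against the defining formula computed independently
  expect_equal(dskewnorm(1, 0, 1, 2), 2 * dnorm(1) * pnorm(2),
               tolerance = 1e-12)
  expect_error(dskewnorm(0, 0, -1, 0), "sigma")
})

test_that("density integrates to one over a parameter grid", {
  # split at the location so narrow peaks are not missed by the quadrature
  total_mass <- function(mu, sigma, alpha) {
    stats::integrate(dskewnorm, -Inf, mu, mu = mu, sigma = sigma,
                     alpha = alpha, rel.tol = 1e-10)$value +
      stats::integrate(dskewnorm, mu, Inf, mu = mu, sigma = sigma,
                       alpha = alpha, rel.tol = 1e-10)$value
  }
  for (mu in c(-3, 0, 55)) {
    for (sigma in c(0.2, 1, 4)) {
      for (alpha in c(-5, 0, 3)) {
        expect_equal(total_mass(mu, sigma, alpha), 1, tolerance = 1e-6)
      }
    }
  }
})

test_that("mean and variance transforms agree with analytic values", {
  expect_equal(skewnorm_mean(10, 2, 0), 10)
  expect_equal(skewnorm_var(3, 3, 0), 9)
  expect_equal(skewnorm_mean(0, 1, 1), 1 / sqrt(pi), tolerance = 1e-12)
  expect_equal(skewnorm_var(0, 1, 1), 1 - 1 / pi, tolerance = 1e-12)
  # half-normal limit
  expect_equal(skewnorm_mean(0, 1, 1e9), sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(skewnorm_var(0, 1, 1e9), 1 - 2 / pi, tolerance = 1e-12)
})

test_that("mean is odd and variance even in the shape parameter", {
  for (a in c(0.3, 1, 2.5, 7)) {
    expect_equal(skewnorm_mean(5, 1.3, a) - 5, -(skewnorm_mean(5, 1.3, -a) - 5))
    expect_equal(skewnorm_var(5, 1.3, a), skewnorm_var(5, 1.3, -a))
  }
  # variance strictly decreasing in |alpha|
  a <- c(0, 0.5, 1, 2, 4, 8)
  v <- skewnorm_var(0, 1.5, a)
  expect_true(all(diff(v) < 0))
})

test_that("random deviates match the analytic moments", {
  set.seed(42)
  x <- rskewnorm(1e5, 0, 1, 5)
  m <- skewnorm_mean(0, 1, 5)
  se <- sqrt(skewnorm_var(0, 1, 5) / 1e5)
  expect_lt(abs(mean(x) - m), 4 * se)
  expect_equal(var(x), skewnorm_var(0, 1, 5), tolerance = 0.05)
})

test_that("credible interval handles degenerate, normal and discrete draws", {
  ci <- credible_interval(rep(3.2, 50), 0.94)
  expect_equal(c(ci$lower, ci$center, ci$upper), c(3.2, 3.2, 3.2))

  set.seed(1)
  z <- rnorm(1e5)
  ci <- credible_interval(z, 0.94)
  q <- qnorm(0.97) # symmetric 94% normal quantile, ~1.8808
  expect_equal(ci$lower, -q, tolerance = 0.03)
  expect_equal(ci$upper, q, tolerance = 0.03)

  ci <- credible_interval(1:100, 0.5)
  expect_equal(ci$upper - ci$lower, 50, tolerance = 1)
})

test_that("HDI agrees with a brute-force shortest-window oracle", {
  set.seed(9)
  for (r in 1:5) {
    draws <- rskewnorm(400, 0, 1, 4 * r - 10)
    got <- credible_interval(draws, 0.8)
    want <- hdi_bruteforce(draws, 0.8)
    expect_equal(c(got$lower, got$upper), want)
  }
})

test_that("credible interval is invariant to draw order", {
  set.seed(3)
  draws <- rnorm(999)
  a <- credible_interval(draws, 0.94)
  b <- credible_interval(sample(draws), 0.94)
  expect_identical(a, b)
})

test_that("equal-tailed interval is available and differs for skewed draws", {
  set.seed(5)
  draws <- rskewnorm(5e4, 0, 1, 10)
  hdi <- credible_interval(draws, 0.9, method = "hdi")
  eti <- credible_interval(draws, 0.9, method = "eti")
  expect_lt(hdi$upper - hdi$lower, eti$upper - eti$lower)
})
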