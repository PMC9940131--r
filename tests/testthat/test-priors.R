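numeric_moments <- function(prior, lower, upper) {
  m <- stats::integrate(function(x) x * prior_pdf(prior, x), lower, upper,
                        rel.tol = 1e-10)$value
  v <- stats::integrate(function(x) (x - m)^2 * prior_pdf(prior, x),
                        lower, upper, rel.tol = 1e-10)$value
  list(mean = m, variance = v)
}

test_that("densities take their known special forms", {
  expect_equal(prior_pdf(prior_beta(1, 1), c(0.1, 0.5, 0.9)), rep(1, 3))
  expect_equal(prior_pdf(prior_gamma(1, 2), c(0.3, 1.7)),
               2 * exp(-2 * c(0.3, 1.7)))
  # heavy truncation: TN(0.5, 10) is near-uniform on [0, 1]
  tn <- prior_truncnorm(0.5, 10)
  expect_equal(prior_pdf(tn, c(0.05, 0.5, 0.95)), rep(1, 3),
               tolerance = 2e-3)
  # outside the support the density is 0, not an error
  expect_equal(prior_pdf(tn, c(-0.2, 1.2)), c(0, 0))
  expect_equal(prior_pdf(prior_gamma(2, 1), -1), 0)
})

test_that("densities integrate to one and moments match quadrature", {
  set.seed(31)
  priors <- list(
    prior_truncnorm(runif(1, -0.2, 0.6), runif(1, 0.02, 0.5)),
    prior_truncnorm(0.1, 0.01),
    prior_beta(runif(1, 0.4, 5), runif(1, 0.4, 5)),
    prior_beta(2, 8),
    prior_gamma(75, 10),
    prior_gamma(runif(1, 0.5, 20), runif(1, 0.5, 20)))
  uppers <- c(1, 1, 1, 1, Inf, Inf)
  for (i in seq_along(priors)) {
    mass <- stats::integrate(function(x) prior_pdf(priors[[i]], x),
                             0, uppers[i], rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-8)
    closed <- prior_moments(priors[[i]])
    numeric <- numeric_moments(priors[[i]], 0, uppers[i])
    expect_equal(closed$mean, numeric$mean, tolerance = 1e-6)
    expect_equal(closed$variance, numeric$variance, tolerance = 1e-6)
  }
})

test_that("printed-formula moments hold for the named examples", {
  expect_equal(prior_moments(prior_beta(2, 8)),
               list(mean = 0.2, variance = 0.2 * 0.8 / 11))
  expect_equal(prior_moments(prior_gamma(75, 10)),
               list(mean = 7.5, variance = 0.75))
  tn <- prior_moments(prior_truncnorm(0.1, 0.01))
  expect_equal(tn$mean, 0.1, tolerance = 1e-8)       # 10 sd from each bound
  expect_equal(sqrt(tn$variance), 0.01, tolerance = 1e-8)
})

test_that("quantile functions invert the CDF", {
  expect_equal(prior_quantile(prior_beta(1, 1), 0.25), 0.25)
  expect_equal(prior_quantile(prior_point(0.1), c(0, 0.3, 1)), rep(0.1, 3))
  expect_equal(prior_quantile(prior_truncnorm(0.1, 0.01), 0.5), 0.1,
               tolerance = 1e-10)
  v <- seq(0.001, 0.999, length.out = 41)
  for (p in list(prior_truncnorm(0.2, 0.15), prior_beta(0.8, 3),
                 prior_gamma(17.32, 40))) {
    expect_equal(prior_cdf(p, prior_quantile(p, v)), v, tolerance = 1e-8)
  }
})

test_that("sampling is seed-reproducible and consistent with the moments", {
  expect_equal(prior_sample(prior_point(0.2), 5), rep(0.2, 5))
  for (p in list(prior_beta(1, 1), prior_gamma(75, 10),
                 prior_truncnorm(0.3, 0.2))) {
    x1 <- prior_sample(p, 1e5, seed = 42)
    x2 <- prior_sample(p, 1e5, seed = 42)
    expect_identical(x1, x2)
    mom <- prior_moments(p)
    expect_lt(abs(mean(x1) - mom$mean),
              4 * sqrt(mom$variance) / sqrt(1e5))
  }
})

test_that("mode matching recovers known parametrizations", {
  g <- match_mode("gamma", mode = 7.4, sd = sqrt(75) / 10)
  expect_equal(g$k, 75, tolerance = 1e-8)
  expect_equal(g$theta, 10, tolerance = 1e-8)

  b <- match_mode("beta", mode = 0.5, sd = 0.1)
  expect_equal(b$a, b$b, tolerance = 1e-8)
  expect_gt(b$a, 1)
  expect_equal(prior_mode(b), 0.5)
  expect_equal(sqrt(prior_moments(b)$variance), 0.1, tolerance = 1e-8)

  tn <- match_mode("tn", mode = 0.1, sd = 0.01)
  expect_equal(tn$m, 0.1)
  expect_equal(tn$s, 0.01, tolerance = 1e-6)  # truncation negligible

  expect_error(match_mode("beta", 0.5, 0.4), "sd must be below")
})
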