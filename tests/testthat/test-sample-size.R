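test_that("frequentist cluster search reproduces the PG motivating design", {
  res <- min_clusters_freq("pg", n = 11, delta = 3, sigma = 7.5, rho = 0.1,
                           alpha = 0.025, power = 0.9)
  expect_equal(res$C, 48)
  expect_gte(res$achieved, 0.9)
  expect_equal(res$total_N, 48 * 11)
  # minimality: two clusters fewer miss the target
  expect_lt(power_pg(pg_design(46, 11), 3, 7.5, 0.1, 0.025)$power, 0.9)
  # the trial's actual 50 clusters comfortably pass
  expect_gte(power_pg(pg_design(50, 11), 3, 7.5, 0.1, 0.025)$power, 0.9)
})

test_that("no clustering recovers the textbook two-sample formula", {
  delta <- 0.4; sigma <- 1; alpha <- 0.025; pow <- 0.8
  res <- min_clusters_freq("pg", n = 1, delta = delta, sigma = sigma,
                           rho = 0, alpha = alpha, power = pow)
  C_formula <- 4 * sigma^2 * (qnorm(1 - alpha) + qnorm(pow))^2 / delta^2
  expect_equal(res$C, 2 * ceiling(C_formula / 2))
})

test_that("stepped-wedge search stays on equal wedges and is minimal", {
  res <- min_clusters_freq("sw", n = 132, T = 7, delta = 0.0278,
                           sigma = 0.426, rho = 0.2, alpha = 0.005,
                           power = 0.8)
  expect_lte(res$C, 30)           # the trial recruited 30 clinics
  expect_equal(res$C %% 6, 0)     # multiples of T - 1
  expect_gte(res$achieved, 0.8)
  if (res$C > 6) {
    below <- power_sw(sw_design(res$C - 6, 7, 132), 0.0278, 0.426, 0.2,
                      0.005)$power
    expect_lt(below, 0.8)
  }
})

test_that("hybrid search with point-mass priors equals the frequentist answer", {
  set.seed(51)
  for (i in 1:6) {
    cfg <- random_pg_config()
    delta <- cfg$sigma * runif(1, 0.2, 0.6)
    fr <- min_clusters_freq("pg", n = cfg$n, delta = delta,
                            sigma = cfg$sigma, rho = cfg$rho,
                            alpha = 0.025, power = 0.8)
    hy <- min_clusters_hybrid("pg", n = cfg$n, delta = delta,
                              icc_prior = prior_point(cfg$rho),
                              sd_prior = prior_point(cfg$sigma),
                              alpha = 0.025, ep_target = 0.8)
    expect_identical(hy$C, fr$C)
  }
})

test_that("prior uncertainty moves the required cluster count as expected", {
  fx <- crt_fixture("surr")
  fr <- min_clusters_freq("pg", n = 11, delta = 3, sigma = 7.5, rho = 0.1,
                          alpha = 0.025, power = 0.9)
  icc_only <- min_clusters_hybrid("pg", n = 11, delta = 3,
                                  icc_prior = fx$icc_prior, sigma = 7.5,
                                  alpha = 0.025, ep_target = 0.9)
  # small-variance ICC prior: hybrid needs no more clusters than frequentist
  expect_lte(icc_only$C, fr$C)
  both <- min_clusters_hybrid("pg", n = 11, delta = 3,
                              icc_prior = fx$icc_prior,
                              sd_prior = fx$sd_prior,
                              alpha = 0.025, ep_target = 0.9)
  # the SD prior weighs in low-power large-sigma scenarios
  expect_gte(both$C, icc_only$C)
})

test_that("cluster-size search solves the dual problem", {
  res <- min_cluster_size("pg", C = 50, delta = 3, sigma = 7.5, rho = 0.1,
                          alpha = 0.025, target = 0.9)
  expect_lte(res$n, 11)           # the trial used 11 per cluster
  expect_gte(power_pg(pg_design(50, res$n), 3, 7.5, 0.1, 0.025)$power, 0.9)
  expect_lt(power_pg(pg_design(50, res$n - 1), 3, 7.5, 0.1, 0.025)$power,
            0.9)
  # rho = 0: the unclustered per-arm size formula, split over clusters
  r0 <- min_cluster_size("pg", C = 10, delta = 1, sigma = 1, rho = 0,
                         alpha = 0.025, target = 0.8)
  n_formula <- 4 * (qnorm(0.975) + qnorm(0.8))^2 / (10 * 1^2)
  expect_equal(r0$n, ceiling(n_formula))
})

test_that("an unreachable power asymptote is reported, not searched past", {
  expect_error(
    min_cluster_size("pg", C = 4, delta = 0.1, sigma = 1, rho = 0.5,
                     alpha = 0.05, target = 0.9),
    "power approaches")
})

test_that("raising the target never lowers the returned cluster count", {
  Cs <- sapply(c(0.7, 0.8, 0.9, 0.95), function(t)
    min_clusters_hybrid("pg", n = 11, delta = 3,
                        icc_prior = prior_truncnorm(0.1, 0.05),
                        sigma = 7.5, alpha = 0.025, ep_target = t,
                        nodes = 65)$C)
  expect_true(all(diff(Cs) >= 0))
})
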