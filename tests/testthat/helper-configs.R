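# Random small design configurations for property-style tests.
# Draw from the current RNG stream; callers set the seed.

random_pg_config <- function() {
  list(C = 2L * sample(2:25, 1),          # even, 4..50
       n = sample(1:40, 1),
       rho = stats::runif(1, 0, 0.9),
       sigma = stats::runif(1, 0.2, 8))
}

random_sw_config <- function() {
  T <- sample(3:6, 1)
  list(C = (T - 1L) * sample(1:5, 1),     # equal wedge
       T = T,
       n = sample(1:30, 1),
       rho = stats::runif(1, 0, 0.9),
       sigma = stats::runif(1, 0.2, 8))
}

random_icc_prior <- function() {
  switch(sample(3, 1),
         prior_truncnorm(stats::runif(1, 0.02, 0.4),
                         stats::runif(1, 0.01, 0.3)),
         prior_beta(stats::runif(1, 0.5, 6), stats::runif(1, 1, 12)),
         prior_point(stats::runif(1, 0.01, 0.5)))
}

random_sd_prior <- function(around) {
  # Gamma centred loosely on `around`
  k <- stats::runif(1, 4, 80)
  prior_gamma(k, k / around)
}
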