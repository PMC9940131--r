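# Monotone minimal search over multiples of `step`, starting at `from`.
# `eval_at` maps the integer to the achieved power/EP.  Geometric doubling
# locates a bracket, bisection (on the multiplier) refines it, and the
# returned value is confirmed minimal.
search_min_monotone <- function(eval_at, target, step, from, max_value,
                                what = "clusters") {
  step <- as.integer(step)
  k_lo <- as.integer(ceiling(from / step))  # multiplier of `step`
  if (eval_at(k_lo * step) >= target) {
    k_hi <- k_lo
  } else {
    k_hi <- k_lo
    repeat {
      k_hi <- max(k_hi * 2L, k_hi + 1L)
      if (k_hi * step > max_value) {
        sup <- eval_at((max_value %/% step) * step)
        stop("target ", target, " not reached below ", what, " = ",
             max_value, " (supremum over the search range: ",
             signif(sup, 6), ")")
      }
      if (eval_at(k_hi * step) >= target) break
      k_lo <- k_hi
    }
    while (k_hi - k_lo > 1L) {
      k_mid <- (k_lo + k_hi) %/% 2L
      if (eval_at(k_mid * step) >= target) k_hi <- k_mid else k_lo <- k_mid
    }
  }
  as.integer(k_hi * step)
}

make_design <- function(kind, C, n, T, allow_unequal = FALSE) {
  if (kind == "pg") {
    pg_design(C, n, allow_unequal = allow_unequal)
  } else {
    if (allow_unequal) suppressWarnings(sw_design(C, T, n))
    else sw_design(C, T, n)
  }
}

ss_result <- function(kind, C, n, T, achieved, framework, target) {
  structure(list(kind = kind, C = C, n = n, T = if (kind == "sw") T else NULL,
                 achieved = achieved, framework = framework, target = target,
                 total_N = if (kind == "pg") C * n else C * n * T),
            class = "sample_size_result")
}

#' Minimal number of clusters under frequentist power
#'
#' Smallest admissible cluster count achieving one-sided frequentist power
#' at least \code{power} for fixed per-cluster(-period) size.  The search
#' ascends in steps of 2 for parallel-group designs (exact 1:1 allocation)
#' and in steps of \eqn{T-1} for the standard stepped wedge (equal
#' clusters per step), unless \code{allow_unequal} permits step 1 with the
#' remainder-to-earliest-steps rule.  Power is increasing in the cluster
#' count, so a doubling bracket plus bisection suffices; minimality of the
#' returned count is confirmed directly.
#'
#' @param kind \code{"pg"} or \code{"sw"}.
#' @param n Measurements per cluster (PG) or per cluster-period (SW).
#' @param T Number of periods (SW only).
#' @param delta Target difference.
#' @param sigma Total outcome SD.
#' @param rho Intra-cluster correlation.
#' @param alpha One-sided type-I error rate.
#' @param power Target power \eqn{1-\beta}.
#' @param allow_unequal Allow unequal arms / unequal wedge steps.
#' @param C_max Search ceiling.
#' @return A \code{sample_size_result}: \code{C}, \code{n}, \code{achieved}
#'   power, \code{framework}, \code{total_N}.
#' @examples
#' min_clusters_freq("pg", n = 11, delta = 3, sigma = 7.5, rho = 0.1,
#'                   alpha = 0.025, power = 0.9)  # C = 48
#' @export
min_clusters_freq <- function(kind = c("pg", "sw"), n, T = NULL, delta,
                              sigma, rho, alpha = 0.025, power = 0.9,
                              allow_unequal = FALSE, C_max = 1e6) {
  kind <- match.arg(kind)
  stopifnot(delta > 0)
  if (kind == "sw" && is.null(T)) stop("'T' is required for a stepped wedge")
  step <- if (allow_unequal) 1L
          else if (kind == "pg") 2L else as.integer(T - 1)
  from <- if (kind == "pg") 2L else as.integer(T - 1)
  eval_at <- function(C) {
    d <- make_design(kind, C, n, T, allow_unequal)
    if (kind == "pg") power_pg(d, delta, sigma, rho, alpha)$power
    else power_sw(d, delta, sigma, rho, alpha)$power
  }
  C <- search_min_monotone(eval_at, power, step, from, C_max)
  ss_result(kind, C, n, T, eval_at(C), "frequentist", power)
}

#' Minimal number of clusters under expected power
#'
#' Hybrid analogue of \code{\link{min_clusters_freq}}: smallest admissible
#' cluster count whose expected power under the supplied priors reaches
#' \code{ep_target} (\eqn{1-\gamma}).  Expected power inherits the
#' monotonicity of power in the cluster count, so the same bracketing and
#' bisection strategy applies.  With heavy-tailed SD priors the expected
#' power can plateau below the target; the error then reports the supremum
#' observed over the search range.
#'
#' @inheritParams min_clusters_freq
#' @inheritParams expected_power
#' @param ep_target Target expected power \eqn{1-\gamma} (conventionally
#'   \eqn{\gamma = \beta}).
#' @return A \code{sample_size_result} with \code{framework = "hybrid"}.
#' @export
min_clusters_hybrid <- function(kind = c("pg", "sw"), n, T = NULL, delta,
                                icc_prior, sd_prior = NULL, sigma = NULL,
                                alpha = 0.025, ep_target = 0.9,
                                allow_unequal = FALSE, C_max = 1e6,
                                nodes = 129) {
  kind <- match.arg(kind)
  stopifnot(delta > 0)
  if (kind == "sw" && is.null(T)) stop("'T' is required for a stepped wedge")
  step <- if (allow_unequal) 1L
          else if (kind == "pg") 2L else as.integer(T - 1)
  from <- if (kind == "pg") 2L else as.integer(T - 1)
  eval_at <- function(C) {
    d <- make_design(kind, C, n, T, allow_unequal)
    expected_power(d, delta, icc_prior, sd_prior, sigma, alpha,
                   nodes = nodes)$ep
  }
  C <- search_min_monotone(eval_at, ep_target, step, from, C_max)
  ss_result(kind, C, n, T, eval_at(C), "hybrid", ep_target)
}

#' Minimal cluster(-period) size at a fixed number of clusters
#'
#' Smallest integer per-cluster (PG) or per-cluster-period (SW) size
#' meeting a frequentist power or expected-power target with the cluster
#' count held fixed.  For a parallel-group design with \eqn{\rho > 0} the
#' power is bounded as \eqn{n \to \infty}
#' (\eqn{\Phi(\delta\sqrt{C/(4\rho\sigma^2)} - z_{1-\alpha})} at fixed
#' SD); when the target exceeds that asymptote the search fails with an
#' error reporting the attainable supremum.
#'
#' @inheritParams min_clusters_freq
#' @inheritParams expected_power
#' @param C Fixed cluster count.
#' @param framework \code{"frequentist"} (uses \code{sigma}, \code{rho}) or
#'   \code{"hybrid"} (uses the priors).
#' @param target Target power or expected power.
#' @param n_max Search ceiling on the size.
#' @return A \code{sample_size_result}.
#' @examples
#' min_cluster_size("pg", C = 50, delta = 3, sigma = 7.5, rho = 0.1,
#'                  alpha = 0.025, target = 0.9)  # n = 11
#' @export
min_cluster_size <- function(kind = c("pg", "sw"), C, T = NULL, delta,
                             alpha = 0.025, target = 0.9,
                             framework = c("frequentist", "hybrid"),
                             sigma = NULL, rho = NULL, icc_prior = NULL,
                             sd_prior = NULL, allow_unequal = FALSE,
                             n_max = 1e6, nodes = 129) {
  kind <- match.arg(kind)
  framework <- match.arg(framework)
  stopifnot(delta > 0)
  if (kind == "sw" && is.null(T)) stop("'T' is required for a stepped wedge")
  eval_at <- function(n) {
    d <- make_design(kind, C, n, T, allow_unequal)
    if (framework == "frequentist") {
      if (kind == "pg") power_pg(d, delta, sigma, rho, alpha)$power
      else power_sw(d, delta, sigma, rho, alpha)$power
    } else {
      expected_power(d, delta, icc_prior, sd_prior, sigma, alpha,
                     nodes = nodes)$ep
    }
  }
  n <- tryCatch(
    search_min_monotone(eval_at, target, 1L, 1L, n_max, what = "size"),
    error = function(e) {
      if (framework == "frequentist" && kind == "pg" && rho > 0) {
        asym <- stats::pnorm(delta * sqrt(C / (4 * rho * sigma^2)) -
                               stats::qnorm(1 - alpha))
        stop("target ", target, " unattainable at C = ", C,
             ": power approaches ", signif(asym, 6),
             " as the cluster size grows", call. = FALSE)
      }
      stop(e)
    })
  ss_result(kind, C, n, T, eval_at(n), framework, target)
}

#' @export
print.sample_size_result <- function(x, ...) {
  lab <- if (x$framework == "frequentist") "power" else "expected power"
  cat(sprintf("%s-CRT sample size (%s framework)\n", toupper(x$kind),
              x$framework))
  cat(sprintf("  clusters C = %d, size n = %g%s\n", x$C, x$n,
              if (!is.null(x$T)) sprintf(", periods T = %d", x$T) else ""))
  cat(sprintf("  achieved %s = %.4f (target %.3f)\n", lab, x$achieved,
              x$target))
  cat(sprintf("  total measurements = %g\n", x$total_N))
  invisible(x)
}
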