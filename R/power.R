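#' Treatment-effect variance for a parallel-group CRT
#'
#' Closed-form variance of the treatment-effect estimator in a two-arm
#' parallel-group cluster-randomized trial with 1:1 cluster allocation,
#' a random cluster intercept and a continuous outcome:
#' \deqn{Var(\hat\mu) = \frac{4\{1 + (n-1)\rho\}\sigma^2}{Cn}}
#' where \eqn{\rho} is the intra-cluster correlation and \eqn{\sigma} the
#' total outcome standard deviation.
#'
#' @param design A \code{\link{pg_design}}.
#' @param sigma Total outcome SD \eqn{\sigma > 0}.
#' @param rho Intra-cluster correlation \eqn{\rho \in [0, 1]}.
#' @return The variance (outcome units squared).
#' @examples
#' var_pg(pg_design(50, 11), sigma = 7.5, rho = 0.1)  # 450/550
#' @export
var_pg <- function(design, sigma, rho) {
  stopifnot(inherits(design, "pg_design"))
  check_var_components(sigma, rho)
  if (design$C %% 2L == 1L && !design$allow_unequal)
    stop("the closed-form PG variance assumes equal arms; odd cluster ",
         "counts require pg_design(..., allow_unequal = TRUE)")
  4 * (1 + (design$n - 1) * rho) * sigma^2 / (design$C * design$n)
}

#' Treatment-effect variance for a stepped-wedge CRT
#'
#' Closed-form variance of the treatment-effect estimator in a
#' cross-sectional stepped-wedge cluster-randomized trial under the
#' Hussey-Hughes model (fixed period effects, random cluster intercept):
#' \deqn{Var(\hat\mu) = \frac{C\sigma^2(1-\rho)\{1+\rho(nT-1)\}}{
#'   n[\{1+\rho(nT-1)\}(CU - W) + n\rho(U^2 - CV)]}}
#' with \eqn{U, W, V} the scalar summaries of the treatment-indicator
#' matrix (\code{\link{design_summaries}}).  At \eqn{\rho = 1} the variance
#' is 0 by continuity (the numerator factor \eqn{1-\rho} vanishes).
#'
#' @param design An \code{\link{sw_design}}.
#' @inheritParams var_pg
#' @return The variance (outcome units squared).
#' @examples
#' var_sw(sw_design(30, 7, 132), sigma = 0.426, rho = 0.2)
#' @export
var_sw <- function(design, sigma, rho) {
  stopifnot(inherits(design, "sw_design"))
  check_var_components(sigma, rho)
  s <- design_summaries(design$X)
  v <- sw_var_vec(design$C, design$T, design$n, s$U, s$W, s$V, sigma, rho)
  if (is.na(v))
    stop("degenerate stepped-wedge design (non-positive variance ",
         "denominator): C = ", design$C, ", T = ", design$T,
         "; the treatment effect is not estimable")
  v
}

check_var_components <- function(sigma, rho) {
  if (!is.numeric(sigma) || any(sigma <= 0)) stop("'sigma' must be positive")
  if (!is.numeric(rho) || any(rho < 0) || any(rho > 1))
    stop("'rho' must lie in [0, 1]")
  invisible(TRUE)
}

# Vectorized over rho and sigma; returns NA where the denominator is not
# positive (degenerate design), 0 at rho == 1 by continuity.
sw_var_vec <- function(C, T, n, U, W, V, sigma, rho) {
  f <- 1 + rho * (n * T - 1)
  den <- n * (f * (C * U - W) + n * rho * (U^2 - C * V))
  num <- C * sigma^2 * (1 - rho) * f
  v <- ifelse(den > 0, num / den, NA_real_)
  v[rho == 1 & !is.na(den) & den > 0] <- 0
  # rho == 1 with a zero denominator is still the continuity limit 0
  v[rho == 1] <- 0
  v
}

pg_power_vec <- function(C, n, delta, alpha, sigma, rho) {
  v <- 4 * (1 + (n - 1) * rho) * sigma^2 / (C * n)
  stats::pnorm(delta / sqrt(v) - stats::qnorm(1 - alpha))
}

sw_power_vec <- function(C, T, n, U, W, V, delta, alpha, sigma, rho) {
  v <- sw_var_vec(C, T, n, U, W, V, sigma, rho)
  p <- ifelse(v > 0,
              stats::pnorm(delta / sqrt(v) - stats::qnorm(1 - alpha)),
              1)
  p[is.na(v)] <- NA_real_
  p
}

#' One-sided frequentist power of a cluster-randomized design
#'
#' Power of the one-sided level-\eqn{\alpha} z-test of no positive treatment
#' effect (\eqn{H_0: \mu \le 0}, rejected when
#' \eqn{Z = \hat\mu/\sqrt{Var(\hat\mu)} > z_{1-\alpha}}) at target
#' difference \eqn{\delta}:
#' \deqn{\Phi\!\left(\delta/\sqrt{Var(\hat\mu)} - z_{1-\alpha}\right)}
#' with the design-specific closed-form variance (\code{\link{var_pg}},
#' \code{\link{var_sw}}).  The normal reference is used throughout; no
#' small-sample degrees-of-freedom correction is applied.  A two-sided test
#' at level \eqn{2\alpha} is obtained by passing \eqn{\alpha} directly.
#'
#' @param design A \code{\link{pg_design}} (for \code{power_pg}) or
#'   \code{\link{sw_design}} (for \code{power_sw}).
#' @param delta Target difference \eqn{\delta} (outcome units).
#' @param sigma Total outcome SD.
#' @param rho Intra-cluster correlation.
#' @param alpha One-sided type-I error rate.
#' @return An object of class \code{crt_power}: list with \code{variance},
#'   \code{power} and \code{design_kind}.
#' @examples
#' power_pg(pg_design(50, 11), delta = 3, sigma = 7.5, rho = 0.1,
#'          alpha = 0.025)  # ~0.913
#' @export
power_pg <- function(design, delta, sigma, rho, alpha = 0.025) {
  v <- var_pg(design, sigma, rho)
  p <- stats::pnorm(delta / sqrt(v) - stats::qnorm(1 - alpha))
  structure(list(variance = v, power = p, design_kind = "pg"),
            class = "crt_power")
}

#' @rdname power_pg
#' @examples
#' power_sw(sw_design(30, 7, 132), delta = 0.0278, sigma = 0.426,
#'          rho = 0.2, alpha = 0.005)  # ~0.803
#' @export
power_sw <- function(design, delta, sigma, rho, alpha = 0.025) {
  v <- var_sw(design, sigma, rho)
  p <- if (v > 0) stats::pnorm(delta / sqrt(v) - stats::qnorm(1 - alpha))
       else 1  # rho = 1 limit: zero variance, certain rejection for delta > 0
  structure(list(variance = v, power = p, design_kind = "sw"),
            class = "crt_power")
}

#' @export
print.crt_power <- function(x, ...) {
  cat(sprintf("%s-CRT: Var(mu_hat) = %.6g, one-sided power = %.4f\n",
              toupper(x$design_kind), x$variance, x$power))
  invisible(x)
}

#' Generalized-least-squares variance oracle
#'
#' Re-derives the treatment-effect variance from first principles for
#' verification of the closed-form expressions.  The cluster(-period) means
#' are modelled linearly -- intercept and treatment indicator for a
#' parallel-group design; intercept, \eqn{T-1} period indicators and
#' treatment indicator for a stepped wedge -- with covariance
#' \eqn{\sigma_e^2/n} on the diagonal plus \eqn{\sigma_c^2 = \rho\sigma^2}
#' shared within each cluster.  The returned value is the
#' treatment-coefficient entry of the inverse information matrix and must
#' agree with \code{\link{var_pg}} / \code{\link{var_sw}} to high relative
#' precision.  Intended for small designs (a few hundred cluster-period
#' cells); requires \eqn{\rho < 1}.
#'
#' @param design A \code{\link{pg_design}} or \code{\link{sw_design}}.
#' @inheritParams var_pg
#' @return The GLS variance of the treatment-effect estimator.
#' @examples
#' gls_variance(pg_design(4, 5), sigma = 2, rho = 0.3)
#' @export
gls_variance <- function(design, sigma, rho) {
  check_var_components(sigma, rho)
  if (rho >= 1) stop("the GLS oracle requires rho < 1")
  sc2 <- rho * sigma^2
  se2 <- (1 - rho) * sigma^2
  if (inherits(design, "pg_design")) {
    D <- cbind(1, design$allocation)
    # one mean per cluster; clusters independent
    w <- 1 / (se2 / design$n + sc2)
    info <- crossprod(D * sqrt(w))
  } else if (inherits(design, "sw_design")) {
    T <- design$T
    Sinv <- solve(diag(se2 / design$n, T) + matrix(sc2, T, T))
    info <- matrix(0, T + 1, T + 1)
    periods <- cbind(1, stats::model.matrix(~ factor(seq_len(T)))[, -1,
                                                                  drop = FALSE])
    for (j in seq_len(design$C)) {
      Dj <- cbind(periods, design$X[j, ])
      info <- info + t(Dj) %*% Sinv %*% Dj
    }
  } else stop("'design' must be a pg_design or sw_design")
  if (rcond(info) < 1e-14)
    stop("singular information matrix: degenerate design")
  vcov <- solve(info)
  vcov[nrow(vcov), ncol(vcov)]
}
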