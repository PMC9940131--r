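# Vectorized power evaluator P(sigma, rho) for a fixed design/effect/alpha.
power_closure <- function(design, delta, alpha) {
  if (inherits(design, "pg_design")) {
    if (design$C %% 2L == 1L && !design$allow_unequal)
      stop("odd cluster count: see ?pg_design")
    C <- design$C; n <- design$n
    function(sigma, rho) pg_power_vec(C, n, delta, alpha, sigma, rho)
  } else if (inherits(design, "sw_design")) {
    s <- design_summaries(design$X)
    C <- design$C; T <- design$T; n <- design$n
    function(sigma, rho)
      sw_power_vec(C, T, n, s$U, s$W, s$V, delta, alpha, sigma, rho)
  } else stop("'design' must be a pg_design or sw_design")
}

# Gauss-Legendre nodes/weights on [0, 1]; weights sum to 1.
gl_rule <- function(nodes) {
  r <- pracma::gaussLegendre(nodes, 0, 1)
  list(x = r$x, w = r$w)
}

resolve_sd_prior <- function(sd_prior, sigma) {
  if (is.null(sd_prior)) {
    if (is.null(sigma))
      stop("supply either 'sd_prior' or a fixed 'sigma'")
    sd_prior <- prior_point(sigma)
  }
  sd_prior
}

#' Expected power of a cluster-randomized design
#'
#' The prior-weighted average of the one-sided frequentist power,
#' \deqn{EP = \int_0^\infty\!\!\int_0^1 P(\delta, n, X, \alpha, \sigma, \rho)
#'   \,\psi_{SD}(\sigma)\,\psi_{ICC}(\rho)\,d\rho\,d\sigma,}
#' reducing to a single integral over \eqn{\rho} when the SD is held fixed
#' (point-mass SD prior).  The integral is evaluated on the priors'
#' probability scale: Gauss-Legendre nodes \eqn{v \in [0,1]} are mapped
#' through the prior quantile function, which handles Beta endpoint
#' singularities and the Gamma's unbounded support without domain cutoffs.
#' Convergence is verified by recomputing with roughly double the nodes;
#' the node count is doubled until the two estimates agree to \code{tol}.
#'
#' ICC nodes mapping to \eqn{\rho = 1} contribute power 1 (the
#' zero-variance limit).  With point-mass priors on both parameters the
#' result equals the frequentist power.
#'
#' @param design A \code{\link{pg_design}} or \code{\link{sw_design}}.
#' @param delta Target difference \eqn{\delta > 0}.
#' @param icc_prior A \code{\link{priors}} object on the ICC (support in
#'   \eqn{[0, 1]}).
#' @param sd_prior Optional prior on the SD; omit and pass \code{sigma} to
#'   hold the SD fixed.
#' @param sigma Fixed SD used when \code{sd_prior} is absent.
#' @param alpha One-sided type-I error rate.
#' @param nodes Initial Gauss-Legendre node count per dimension.
#' @param tol Convergence tolerance on the doubling check.
#' @return An object of class \code{ep_result}: \code{ep},
#'   \code{nodes_rho}, \code{nodes_sigma}, \code{est_error},
#'   \code{method = "quadrature"}.
#' @examples
#' d <- pg_design(50, 11)
#' expected_power(d, delta = 3, icc_prior = prior_truncnorm(0.1, 0.01),
#'                sigma = 7.5, alpha = 0.025)
#' @seealso \code{\link{ep_monte_carlo}} for the stochastic cross-check.
#' @export
expected_power <- function(design, delta, icc_prior, sd_prior = NULL,
                           sigma = NULL, alpha = 0.025, nodes = 129,
                           tol = 1e-6) {
  stopifnot(inherits(icc_prior, "crt_prior"))
  sd_prior <- resolve_sd_prior(sd_prior, sigma)
  P <- power_closure(design, delta, alpha)
  icc_only <- inherits(sd_prior, "point_prior")

  eval_ep <- function(nn) {
    g <- gl_rule(nn)
    rho <- prior_quantile(icc_prior, g$x)
    if (icc_only) {
      sum(g$w * P(sd_prior$value, rho))
    } else {
      sig <- prior_quantile(sd_prior, g$x)
      # tensor product over the unit square
      grid_p <- P(rep(sig, each = nn), rep(rho, times = nn))
      as.numeric(g$w %*% matrix(grid_p, nrow = nn) %*% g$w)
    }
  }

  nn <- nodes
  ep1 <- eval_ep(nn)
  err <- Inf
  for (i in 1:4) {
    nn2 <- 2L * nn + 1L
    ep2 <- eval_ep(nn2)
    err <- abs(ep2 - ep1)
    if (err < tol) break
    nn <- nn2; ep1 <- ep2
  }
  if (err >= tol)
    stop("expected-power quadrature did not converge: last change ",
         signif(err, 3), " at ", nn2, " nodes (tolerance ", tol, ")")
  structure(list(ep = min(max(ep2, 0), 1),
                 nodes_rho = nn2,
                 nodes_sigma = if (icc_only) 1L else nn2,
                 est_error = err,
                 method = "quadrature"),
            class = "ep_result")
}

#' Monte-Carlo expected power
#'
#' Estimates the expected power by averaging the frequentist power over
#' joint prior draws.  Serves as a stochastic oracle for the deterministic
#' quadrature of \code{\link{expected_power}}; the reported standard error
#' quantifies the Monte-Carlo noise.
#'
#' @inheritParams expected_power
#' @param draws Number of prior draws (at least 1000).
#' @param seed Integer seed for reproducibility.
#' @return An \code{ep_result} with \code{ep}, \code{mc_se}, \code{draws},
#'   \code{method = "monte_carlo"}.
#' @export
ep_monte_carlo <- function(design, delta, icc_prior, sd_prior = NULL,
                           sigma = NULL, alpha = 0.025, draws = 1e5,
                           seed = 1) {
  stopifnot(draws >= 1000, inherits(icc_prior, "crt_prior"))
  sd_prior <- resolve_sd_prior(sd_prior, sigma)
  P <- power_closure(design, delta, alpha)
  rho <- prior_sample(icc_prior, draws, seed = seed)
  sig <- prior_sample(sd_prior, draws, seed = seed + 1L)
  p <- P(sig, rho)
  structure(list(ep = mean(p),
                 mc_se = stats::sd(p) / sqrt(draws),
                 draws = draws,
                 method = "monte_carlo"),
            class = "ep_result")
}

#' @export
print.ep_result <- function(x, ...) {
  if (x$method == "quadrature")
    cat(sprintf(paste0("Expected power: %.6f  (quadrature, %d rho nodes",
                       ", %d sigma nodes, est. error %.2e)\n"),
                x$ep, x$nodes_rho, x$nodes_sigma, x$est_error))
  else
    cat(sprintf("Expected power: %.6f  (Monte Carlo, %d draws, se %.2e)\n",
                x$ep, x$draws, x$mc_se))
  invisible(x)
}
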