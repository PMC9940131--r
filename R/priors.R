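#' Design-stage priors for the ICC and outcome SD
#'
#' Constructors for the prior families used to express design-stage
#' uncertainty about the intra-cluster correlation (ICC) and the outcome
#' standard deviation (SD).  These priors weight the frequentist power when
#' computing expected power; they are not updated to posteriors.
#'
#' \itemize{
#'   \item \code{prior_truncnorm(m, s)}: normal with location \code{m} and
#'     scale \code{s}, truncated to \eqn{[0, 1]} -- the recommended ICC
#'     prior.  \code{m} need not lie in \eqn{[0, 1]}.
#'   \item \code{prior_beta(a, b)}: Beta on \eqn{[0, 1]}; shapes below 1
#'     (density unbounded at an endpoint) are allowed -- integration is
#'     performed on the probability scale so the singularity is never
#'     evaluated.
#'   \item \code{prior_gamma(shape, rate)}: Gamma on \eqn{(0, \infty)} in
#'     the \emph{rate} parametrization, density
#'     \eqn{\theta^k \sigma^{k-1} e^{-\theta\sigma}/\Gamma(k)} -- the usual
#'     SD prior.
#'   \item \code{prior_point(value)}: a point mass, recovering the
#'     conventional frequentist calculation as a degenerate prior.
#' }
#'
#' @param m,s Location and scale (\code{s > 0}) of the untruncated normal.
#' @param a,b Positive Beta shape parameters.
#' @param shape,rate Positive Gamma shape \eqn{k} and rate \eqn{\theta}.
#' @param value The fixed parameter value of a point mass.
#' @return An object of class \code{crt_prior} (subclasses
#'   \code{tn_prior}, \code{beta_prior}, \code{gamma_prior},
#'   \code{point_prior}).
#' @examples
#' prior_truncnorm(0.1, 0.01)   # ICC prior with mode 0.1
#' prior_gamma(75, 10)          # SD prior with mean 7.5
#' @name priors
NULL

#' @rdname priors
#' @export
prior_truncnorm <- function(m, s) {
  stopifnot(is.numeric(m), is.numeric(s), length(m) == 1, length(s) == 1)
  if (s <= 0) stop("'s' must be positive")
  l <- (0 - m) / s
  u <- (1 - m) / s
  structure(list(m = m, s = s, lo = 0, hi = 1, l = l, u = u,
                 Z = stats::pnorm(u) - stats::pnorm(l)),
            class = c("tn_prior", "crt_prior"))
}

#' @rdname priors
#' @export
prior_beta <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1, length(b) == 1)
  if (a <= 0 || b <= 0) stop("Beta shapes 'a' and 'b' must be positive")
  structure(list(a = a, b = b), class = c("beta_prior", "crt_prior"))
}

#' @rdname priors
#' @export
prior_gamma <- function(shape, rate) {
  stopifnot(is.numeric(shape), is.numeric(rate),
            length(shape) == 1, length(rate) == 1)
  if (shape <= 0 || rate <= 0) stop("'shape' and 'rate' must be positive")
  structure(list(k = shape, theta = rate),
            class = c("gamma_prior", "crt_prior"))
}

#' @rdname priors
#' @export
prior_point <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1)
  structure(list(value = value), class = c("point_prior", "crt_prior"))
}

#' Prior density
#'
#' Density of a design-stage prior at \code{x}.  Points outside the support
#' return 0 (not an error), so quadrature rules may probe the boundary.
#'
#' @param prior A \code{crt_prior}.
#' @param x Numeric vector of evaluation points.
#' @return Non-negative densities, same length as \code{x}.
#' @export
prior_pdf <- function(prior, x) UseMethod("prior_pdf")

#' @export
prior_pdf.tn_prior <- function(prior, x) {
  d <- stats::dnorm((x - prior$m) / prior$s) / (prior$s * prior$Z)
  ifelse(x >= 0 & x <= 1, d, 0)
}

#' @export
prior_pdf.beta_prior <- function(prior, x)
  ifelse(x >= 0 & x <= 1, stats::dbeta(x, prior$a, prior$b), 0)

#' @export
prior_pdf.gamma_prior <- function(prior, x)
  ifelse(x > 0, stats::dgamma(x, shape = prior$k, rate = prior$theta), 0)

#' @export
prior_pdf.point_prior <- function(prior, x)
  ifelse(x == prior$value, Inf, 0)

#' Prior cumulative distribution function
#' @inheritParams prior_pdf
#' @return Probabilities in \eqn{[0, 1]}.
#' @export
prior_cdf <- function(prior, x) UseMethod("prior_cdf")

#' @export
prior_cdf.tn_prior <- function(prior, x) {
  p <- (stats::pnorm((x - prior$m) / prior$s) - stats::pnorm(prior$l)) /
    prior$Z
  pmin(pmax(ifelse(x < 0, 0, ifelse(x > 1, 1, p)), 0), 1)
}

#' @export
prior_cdf.beta_prior <- function(prior, x)
  stats::pbeta(pmin(pmax(x, 0), 1), prior$a, prior$b)

#' @export
prior_cdf.gamma_prior <- function(prior, x)
  stats::pgamma(pmax(x, 0), shape = prior$k, rate = prior$theta)

#' @export
prior_cdf.point_prior <- function(prior, x)
  as.numeric(x >= prior$value)

#' Prior quantile function
#'
#' Inverse CDF within the prior's support; the backbone of
#' quantile-transform quadrature for expected power.
#'
#' @param prior A \code{crt_prior}.
#' @param v Probabilities in \eqn{[0, 1]}.
#' @return Quantiles, same length as \code{v}.
#' @export
prior_quantile <- function(prior, v) UseMethod("prior_quantile")

#' @export
prior_quantile.tn_prior <- function(prior, v) {
  q <- prior$m + prior$s *
    stats::qnorm(stats::pnorm(prior$l) + v * prior$Z)
  pmin(pmax(q, 0), 1)
}

#' @export
prior_quantile.beta_prior <- function(prior, v)
  stats::qbeta(v, prior$a, prior$b)

#' @export
prior_quantile.gamma_prior <- function(prior, v)
  stats::qgamma(v, shape = prior$k, rate = prior$theta)

#' @export
prior_quantile.point_prior <- function(prior, v)
  rep(prior$value, length(v))

#' Closed-form prior moments
#'
#' Mean and variance of a design-stage prior.  For the truncated normal the
#' standard truncated-moment formulas are used (with
#' \eqn{l = -m/s}, \eqn{u = (1-m)/s}, \eqn{Z = \Phi(u)-\Phi(l)}):
#' mean \eqn{m + s\{\phi(l)-\phi(u)\}/Z} and variance
#' \eqn{s^2[1 + \{l\phi(l)-u\phi(u)\}/Z - (\{\phi(l)-\phi(u)\}/Z)^2]}.
#'
#' @param prior A \code{crt_prior}.
#' @return A list with components \code{mean} and \code{variance}.
#' @examples
#' prior_moments(prior_gamma(75, 10))  # mean 7.5, variance 0.75
#' @export
prior_moments <- function(prior) UseMethod("prior_moments")

#' @export
prior_moments.tn_prior <- function(prior) {
  l <- prior$l; u <- prior$u; Z <- prior$Z
  dl <- stats::dnorm(l); du <- stats::dnorm(u)
  mean <- prior$m + prior$s * (dl - du) / Z
  variance <- prior$s^2 *
    (1 + (l * dl - u * du) / Z - ((dl - du) / Z)^2)
  list(mean = mean, variance = variance)
}

#' @export
prior_moments.beta_prior <- function(prior) {
  a <- prior$a; b <- prior$b
  list(mean = a / (a + b),
       variance = a * b / ((a + b)^2 * (a + b + 1)))
}

#' @export
prior_moments.gamma_prior <- function(prior)
  list(mean = prior$k / prior$theta, variance = prior$k / prior$theta^2)

#' @export
prior_moments.point_prior <- function(prior)
  list(mean = prior$value, variance = 0)

#' Prior mode
#' @param prior A \code{crt_prior}.
#' @return The mode of the prior within its support.
#' @export
prior_mode <- function(prior) UseMethod("prior_mode")

#' @export
prior_mode.tn_prior <- function(prior) min(max(prior$m, 0), 1)

#' @export
prior_mode.beta_prior <- function(prior) {
  a <- prior$a; b <- prior$b
  if (a > 1 && b > 1) return((a - 1) / (a + b - 2))
  if (a <= 1 && b > 1) return(0)
  if (a > 1 && b <= 1) return(1)
  stop("Beta(", a, ", ", b, ") has no unique interior mode")
}

#' @export
prior_mode.gamma_prior <- function(prior) {
  if (prior$k <= 1) return(0)
  (prior$k - 1) / prior$theta
}

#' @export
prior_mode.point_prior <- function(prior) prior$value

#' Draw from a prior
#'
#' Random sample from a design-stage prior, reproducible by seed.
#'
#' @param prior A \code{crt_prior}.
#' @param count Number of draws.
#' @param seed Optional integer seed; when supplied, draws are made in a
#'   local RNG scope so the caller's random stream is untouched.
#' @return Numeric vector of length \code{count}.
#' @export
prior_sample <- function(prior, count, seed = NULL) {
  stopifnot(count >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  prior_sample_impl(prior, count)
}

prior_sample_impl <- function(prior, count) UseMethod("prior_sample_impl")

#' @export
prior_sample_impl.tn_prior <- function(prior, count)
  prior_quantile(prior, stats::runif(count))

#' @export
prior_sample_impl.beta_prior <- function(prior, count)
  stats::rbeta(count, prior$a, prior$b)

#' @export
prior_sample_impl.gamma_prior <- function(prior, count)
  stats::rgamma(count, shape = prior$k, rate = prior$theta)

#' @export
prior_sample_impl.point_prior <- function(prior, count)
  rep(prior$value, count)

#' @export
print.crt_prior <- function(x, ...) {
  lab <- switch(class(x)[1],
    tn_prior = sprintf("Truncated-normal prior on [0, 1]: m = %g, s = %g",
                       x$m, x$s),
    beta_prior = sprintf("Beta prior: a = %g, b = %g", x$a, x$b),
    gamma_prior = sprintf("Gamma prior (rate parametrization): k = %g, rate = %g",
                          x$k, x$theta),
    point_prior = sprintf("Point mass at %g", x$value))
  mom <- prior_moments(x)
  cat(lab, "\n", sprintf("  mean = %.6g, sd = %.6g", mom$mean,
                         sqrt(mom$variance)), "\n", sep = "")
  invisible(x)
}

#' Construct a prior from its mode and standard deviation
#'
#' Solves for the parameters of a truncated-normal, Beta or Gamma prior so
#' that the prior's \emph{mode} equals a design point estimate and its SD
#' equals a stated uncertainty -- the "correctly specified prior"
#' construction, under which the prior mode matches the value a frequentist
#' calculation would assume.
#'
#' @param family One of \code{"tn"}, \code{"beta"}, \code{"gamma"}.
#' @param mode Target mode, interior to the family's support
#'   (\eqn{(0,1)} for tn/beta, \eqn{(0,\infty)} for gamma).
#' @param sd Target standard deviation (> 0).
#' @return A \code{crt_prior} of the requested family.
#' @examples
#' match_mode("gamma", mode = 7.4, sd = sqrt(75) / 10)  # Gamma(75, 10)
#' @export
match_mode <- function(family = c("tn", "beta", "gamma"), mode, sd) {
  family <- match.arg(family)
  stopifnot(is.numeric(mode), is.numeric(sd), length(mode) == 1,
            length(sd) == 1)
  if (sd <= 0) stop("'sd' must be positive")
  switch(family,
    gamma = {
      if (mode <= 0) stop("a Gamma mode must be positive")
      # mode = (k-1)/theta, sd = sqrt(k)/theta  =>  quadratic in k
      B <- 2 * sd^2 + mode^2
      disc <- B^2 - 4 * sd^4
      k <- (B + sqrt(disc)) / (2 * sd^2)   # root with k > 1
      prior_gamma(shape = k, rate = (k - 1) / mode)
    },
    beta = {
      if (mode <= 0 || mode >= 1)
        stop("a Beta mode must lie strictly inside (0, 1)")
      # a = 1 + mode (t-2), b = 1 + (1-mode)(t-2); variance decreasing in t
      vfun <- function(t) {
        a <- 1 + mode * (t - 2); b <- 1 + (1 - mode) * (t - 2)
        a * b / ((a + b)^2 * (a + b + 1)) - sd^2
      }
      sd_max <- sqrt(1 / 12)  # t -> 2 limit: Beta(1, 1)
      if (sd^2 >= 1 / 12 - 1e-12)
        stop("infeasible Beta mode/sd combination: with an interior mode ",
             "the sd must be below ", signif(sd_max, 4))
      t <- stats::uniroot(vfun, c(2 + 1e-9, 1e9), tol = 1e-12)$root
      prior_beta(1 + mode * (t - 2), 1 + (1 - mode) * (t - 2))
    },
    tn = {
      if (mode <= 0 || mode >= 1)
        stop("a truncated-normal mode must lie strictly inside (0, 1)")
      # interior mode equals the untruncated location m; solve s for the sd
      sdfun <- function(s)
        sqrt(prior_moments(prior_truncnorm(mode, s))$variance) - sd
      sd_sup <- sqrt(prior_moments(prior_truncnorm(mode, 1e6))$variance)
      if (sd >= sd_sup)
        stop("infeasible truncated-normal mode/sd combination: sd must be ",
             "below ", signif(sd_sup, 4), " for mode ", mode)
      s <- stats::uniroot(sdfun, c(1e-8, 1e6), tol = 1e-12)$root
      prior_truncnorm(mode, s)
    })
}
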