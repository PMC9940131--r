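#' Expected-power comparison of PG and SW designs over an ICC-prior grid
#'
#' Computes the expected power of a parallel-group and a stepped-wedge
#' design on a common measurement budget -- each cluster contributes
#' \eqn{N} measurements, so \eqn{n = N} for the PG arm and \eqn{n = N/T}
#' (fractional allowed) for the SW arm -- under a truncated-normal ICC
#' prior \eqn{TN(0, 1, m, s^2)}, for every combination of the prior
#' location \code{m_values} and scale \code{s_values}.  The SD is held
#' fixed; since with a point-mass SD the expected power depends on
#' \eqn{(\delta, \sigma)} only through \eqn{\delta/\sigma}, the SD is set
#' to 1 and \code{effect} is the standardized effect size.
#'
#' @param effect Standardized effect size \eqn{\delta/\sigma > 0}.
#' @param C Number of clusters (both designs).
#' @param N Measurements per cluster (both designs); must satisfy
#'   \eqn{N \ge T}.
#' @param T Stepped-wedge periods.
#' @param alpha One-sided type-I error rate.
#' @param m_values,s_values Grid axes for the truncated-normal prior
#'   location and scale (\code{s_values} must be positive).
#' @param nodes Gauss-Legendre nodes for each expected-power integral.
#' @return An object of class \code{ep_comparison_grid}: the axes, EP
#'   matrices \code{ep_pg} and \code{ep_sw} (rows index \code{m_values},
#'   columns \code{s_values}), their difference \code{diff}, and the
#'   settings.
#' @examples
#' g <- ep_comparison_grid(0.2, C = 50, N = 30, T = 3,
#'                         m_values = seq(0, 0.2, 0.05),
#'                         s_values = seq(0.05, 0.2, 0.05))
#' pg_region_summary(g)
#' @export
ep_comparison_grid <- function(effect, C = 50, N, T, alpha = 0.025,
                               m_values = seq(0, 0.5, by = 0.005),
                               s_values = seq(0.005, 0.5, by = 0.005),
                               nodes = 129) {
  stopifnot(effect > 0, N >= T, all(s_values > 0))
  pg <- pg_design(C, N)
  sw <- suppressWarnings(sw_design(C, T, N / T))
  P_pg <- power_closure(pg, effect, alpha)
  P_sw <- power_closure(sw, effect, alpha)
  g <- gl_rule(nodes)
  nm <- length(m_values); ns <- length(s_values)
  ep_pg <- ep_sw <- matrix(NA_real_, nm, ns,
                           dimnames = list(m_values, s_values))
  for (i in seq_len(nm)) {
    for (j in seq_len(ns)) {
      rho <- prior_quantile(prior_truncnorm(m_values[i], s_values[j]), g$x)
      ep_pg[i, j] <- sum(g$w * P_pg(1, rho))
      ep_sw[i, j] <- sum(g$w * P_sw(1, rho))
    }
  }
  structure(list(m_values = m_values, s_values = s_values,
                 ep_pg = ep_pg, ep_sw = ep_sw, diff = ep_pg - ep_sw,
                 settings = list(C = C, N = N, T = T, effect = effect,
                                 alpha = alpha, nodes = nodes)),
            class = "ep_comparison_grid")
}

#' Equal-expected-power contour of a comparison grid
#'
#' Zero-level set of the PG-minus-SW expected-power difference, extracted
#' by linear interpolation on grid cells.  An empty list is returned when
#' the difference has a single sign over the whole grid (no equal-EP
#' curve).
#'
#' @param grid An \code{\link{ep_comparison_grid}}.
#' @return A list of data frames, each a polyline with columns \code{m}
#'   and \code{s}.
#' @export
extract_contour <- function(grid) {
  stopifnot(inherits(grid, "ep_comparison_grid"))
  if (all(grid$diff > 0) || all(grid$diff < 0)) return(list())
  cl <- grDevices::contourLines(x = grid$m_values, y = grid$s_values,
                                z = grid$diff, levels = 0)
  lapply(cl, function(p) data.frame(m = p$x, s = p$y))
}

#' Extent of the PG-favourable region
#'
#' Maxima of the prior location \eqn{m} and scale \eqn{s} over grid cells
#' where the parallel-group design has strictly larger expected power than
#' the stepped wedge.  Resolution-limited: the true region boundary lies
#' within one grid step of the reported maxima.
#'
#' @param grid An \code{\link{ep_comparison_grid}}.
#' @return A list with \code{max_m}, \code{max_s} (both \code{NA} when the
#'   SW design dominates everywhere) and \code{n_cells}, the number of
#'   PG-favourable cells.
#' @export
pg_region_summary <- function(grid) {
  stopifnot(inherits(grid, "ep_comparison_grid"))
  pos <- which(grid$diff > 0, arr.ind = TRUE)
  if (nrow(pos) == 0)
    return(list(max_m = NA_real_, max_s = NA_real_, n_cells = 0L))
  list(max_m = max(grid$m_values[pos[, 1]]),
       max_s = max(grid$s_values[pos[, 2]]),
       n_cells = nrow(pos))
}

#' Long-format view of a comparison grid
#'
#' @param x An \code{\link{ep_comparison_grid}}.
#' @param ... Unused.
#' @return A data frame with columns \code{m}, \code{s}, \code{ep_pg},
#'   \code{ep_sw}, \code{diff}.
#' @export
as.data.frame.ep_comparison_grid <- function(x, ...) {
  data.frame(m = rep(x$m_values, times = length(x$s_values)),
             s = rep(x$s_values, each = length(x$m_values)),
             ep_pg = as.vector(x$ep_pg),
             ep_sw = as.vector(x$ep_sw),
             diff = as.vector(x$diff))
}

#' @export
print.ep_comparison_grid <- function(x, ...) {
  st <- x$settings
  cat(sprintf(paste0("PG vs SW expected-power grid: C = %d, N = %g, ",
                     "T = %d, effect = %g, alpha = %g\n"),
              st$C, st$N, st$T, st$effect, st$alpha))
  cat(sprintf("  %d x %d (m, s) cells; PG favourable in %d\n",
              length(x$m_values), length(x$s_values),
              sum(x$diff > 0)))
  invisible(x)
}
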