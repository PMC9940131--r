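#' Construct a parallel-group cluster-randomized design
#'
#' Builds the geometry of a two-arm parallel-group cluster-randomized trial
#' (PG-CRT) with 1:1 allocation of clusters: the first \code{ceiling(C/2)}
#' clusters are control, the rest intervention.  Cluster labels are
#' exchangeable; only the arm counts enter the variance formula, which
#' assumes an exact equal split.
#'
#' @param clusters Integer number of clusters \eqn{C \ge 2}.
#' @param size Measurements per cluster \eqn{n > 0}.  Non-integer values are
#'   permitted so that designs on a common measurement budget can be compared
#'   (the variance is a continuous function of \eqn{n}).
#' @param allow_unequal If \code{TRUE}, an odd \code{clusters} is accepted for
#'   variance computation even though the closed-form variance assumes equal
#'   arms; the equal-split value is then an approximation.  With the default
#'   \code{FALSE} an odd count is constructed (with a warning) but rejected
#'   by \code{\link{var_pg}}.
#' @return An object of class \code{pg_design} with elements \code{C},
#'   \code{n}, \code{allocation} (length-\eqn{C} 0/1 vector) and
#'   \code{allow_unequal}.
#' @examples
#' d <- pg_design(50, 11)
#' sum(d$allocation)  # 25 intervention clusters
#' @seealso \code{\link{sw_design}}, \code{\link{var_pg}}
#' @export
pg_design <- function(clusters, size, allow_unequal = FALSE) {
  C <- clusters
  stopifnot(length(C) == 1, length(size) == 1)
  if (!is.numeric(C) || C != round(C) || C < 2)
    stop("'clusters' must be an integer >= 2")
  if (!is.numeric(size) || size <= 0)
    stop("'size' must be a positive number")
  C <- as.integer(C)
  if (C %% 2L == 1L && !allow_unequal)
    warning("odd cluster count: 1:1 allocation is approximate and the ",
            "closed-form variance will be rejected; construct with ",
            "allow_unequal = TRUE to force the equal-split approximation")
  allocation <- c(rep(0L, ceiling(C / 2)), rep(1L, floor(C / 2)))
  structure(list(C = C, n = size, allocation = allocation,
                 allow_unequal = isTRUE(allow_unequal)),
            class = "pg_design")
}

#' Construct a standard stepped-wedge design
#'
#' Builds the treatment-indicator matrix of a standard cross-sectional
#' stepped-wedge cluster-randomized trial (SW-CRT): all clusters start in
#' control (period 1), clusters cross to the intervention in \eqn{T-1} steps
#' at periods \eqn{2,\dots,T}, and all are treated in the final period.
#' Clusters are divided as evenly as possible across steps; when
#' \eqn{(T-1)} does not divide \eqn{C} the remainder clusters are assigned
#' one per step starting from the earliest step, and a warning notes that
#' the wedge is unequal.
#'
#' @param clusters Integer number of clusters \eqn{C \ge T-1}.
#' @param periods Integer number of periods \eqn{T \ge 2}.
#' @param size Measurements per cluster-period \eqn{n > 0} (non-integer
#'   allowed; see \code{\link{pg_design}}).
#' @return An object of class \code{sw_design} with elements \code{C},
#'   \code{T}, \code{n}, \code{N} (\eqn{= nT}, measurements per cluster),
#'   \code{X} (\eqn{C \times T} binary indicator matrix, rows
#'   non-decreasing) and \code{steps} (clusters per step).
#' @examples
#' d <- sw_design(30, 7, 132)
#' colSums(d$X)  # 0, 5, 10, ..., 30
#' @export
sw_design <- function(clusters, periods, size) {
  C <- clusters; T <- periods
  stopifnot(length(C) == 1, length(T) == 1, length(size) == 1)
  if (!is.numeric(T) || T != round(T) || T < 2)
    stop("'periods' must be an integer >= 2")
  if (!is.numeric(C) || C != round(C) || C < 2)
    stop("'clusters' must be an integer >= 2")
  if (!is.numeric(size) || size <= 0)
    stop("'size' must be a positive number")
  C <- as.integer(C); T <- as.integer(T)
  g <- T - 1L
  if (C < g)
    stop("'clusters' (", C, ") must be at least periods - 1 (", g,
         "): some step would be empty")
  steps <- rep(C %/% g, g)
  rem <- C %% g
  if (rem > 0L) {
    steps[seq_len(rem)] <- steps[seq_len(rem)] + 1L
    warning("clusters (", C, ") not divisible by steps (", g, "): ",
            "remainder assigned to the earliest steps; the wedge is unequal")
  }
  X <- matrix(0L, nrow = C, ncol = T)
  row <- 1L
  for (s in seq_len(g)) {
    for (j in seq_len(steps[s])) {
      X[row, (s + 1L):T] <- 1L
      row <- row + 1L
    }
  }
  structure(list(C = C, T = T, n = size, N = size * T, X = X, steps = steps),
            class = "sw_design")
}

#' Scalar summaries of a stepped-wedge treatment matrix
#'
#' Computes the three design summaries entering the closed-form
#' stepped-wedge variance: \eqn{U = \sum_{jk} X_{jk}} (treated cells),
#' \eqn{W = \sum_k (\sum_j X_{jk})^2} (sum of squared column sums) and
#' \eqn{V = \sum_j (\sum_k X_{jk})^2} (sum of squared row sums).
#'
#' @param X A binary matrix of treatment indicators (rows = clusters,
#'   columns = periods), or an \code{sw_design}.
#' @return A list with integer components \code{U}, \code{W}, \code{V}.
#' @examples
#' design_summaries(sw_design(30, 7, 132))  # U = 105, W = 2275, V = 455
#' @export
design_summaries <- function(X) {
  if (inherits(X, "sw_design")) X <- X$X
  if (!is.matrix(X) || !all(X %in% c(0, 1)))
    stop("'X' must be a binary (0/1) matrix")
  list(U = sum(X), W = sum(colSums(X)^2), V = sum(rowSums(X)^2))
}

#' @export
print.pg_design <- function(x, ...) {
  cat("Parallel-group CRT design\n")
  cat("  clusters:            ", x$C, " (", sum(x$allocation == 0),
      " control / ", sum(x$allocation == 1), " intervention)\n", sep = "")
  cat("  size per cluster:    ", x$n, "\n", sep = "")
  cat("  total measurements:  ", x$C * x$n, "\n", sep = "")
  invisible(x)
}

#' @export
print.sw_design <- function(x, ...) {
  cat("Stepped-wedge CRT design (standard wedge)\n")
  cat("  clusters:              ", x$C, "\n", sep = "")
  cat("  periods:               ", x$T, "\n", sep = "")
  cat("  clusters per step:     ", paste(x$steps, collapse = ", "), "\n",
      sep = "")
  cat("  size per cluster-period:", x$n, "\n")
  cat("  total measurements:    ", x$C * x$N, "\n", sep = "")
  invisible(x)
}

# 1-based rows/columns rendered as CSV for the CLI `design` subcommand
design_matrix_csv <- function(design) {
  X <- if (inherits(design, "sw_design")) design$X
       else matrix(design$allocation, ncol = 1)
  header <- paste(c("cluster", paste0("period", seq_len(ncol(X)))),
                  collapse = ",")
  rows <- vapply(seq_len(nrow(X)), function(j)
    paste(c(j, X[j, ]), collapse = ","), character(1))
  c(header, rows)
}
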