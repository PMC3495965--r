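#' Offset and halfwidth of a coefficient's feasible interval
#'
#' Given the hypersphere factor rows fixed so far, coefficient c\[i, j\]
#' equals A_ij + S_ij * cos(theta\[i, j\]) with
#' A_ij = sum_(k<j) b\[i,k\] b\[j,k\] (the inner-product offset) and
#' S_ij = prod_(k<j) sin(theta\[i,k\]) * prod_(k<j) sin(theta\[j,k\]) >= 0
#' (the halfwidth).  Setting the cosine to +/-1 therefore gives the exact
#' bounds without optimization.  The sine products are recovered from the
#' factor itself through the unit-row-norm identity
#' prod_(k<j) sin(theta\[i,k\]) = sqrt(1 - sum_(k<j) b\[i,k\]^2), exact
#' because all sines are non-negative on \[0, pi\].
#'
#' The computation is conditional-sequential: it is exact for the
#' generation order (first column, then row by row), where rows 1..j of the
#' factor are fully determined and row i is determined through column
#' j - 1.  Undetermined entries are represented as `NA` in a partial
#' factor; requesting (i, j) before its prerequisites raises an ordering
#' error.
#'
#' @param factor n x n lower triangular factor, possibly partial with `NA`
#'   for not-yet-determined entries (a full [triangular_factor()] works).
#' @param i,j 1-based indices with i > j.
#' @return list with components `offset` (A_ij) and `halfwidth` (S_ij >= 0);
#'   for j = 1 this is offset 0, halfwidth 1, i.e. bounds \[-1, 1\].
#' @export
bound_components <- function(factor, i, j) {
  b <- unclass(as.matrix(factor))
  n <- nrow(b)
  i <- as.integer(i); j <- as.integer(j)
  if (i <= j || j < 1L || i > n) {
    stop(sprintf("need row > column within dimension; got (i, j) = (%d, %d)", i, j),
         call. = FALSE)
  }
  if (j == 1L) {
    return(list(offset = 0, halfwidth = 1))
  }
  pre_j <- b[j, 1:j]            # row j through its diagonal
  pre_i <- b[i, 1:(j - 1L)]     # row i through column j - 1
  if (anyNA(pre_j) || anyNA(pre_i)) {
    stop(sprintf(
      "ordering error: bounds for (%d,%d) require factor rows 1..%d and row %d through column %d",
      i, j, j, i, j - 1L), call. = FALSE)
  }
  offset <- sum(pre_i * b[j, 1:(j - 1L)])
  sin_i <- sqrt(max(0, 1 - sum(pre_i^2)))
  sin_j <- b[j, j]              # prod of sines of row j
  list(offset = offset, halfwidth = sin_i * sin_j)
}

#' Exact bounds of the next correlation coefficient
#'
#' Lower and upper bound of c\[i, j\] given all previously generated
#' coefficients: (offset - halfwidth, offset + halfwidth), clamped into
#' \[-1, 1\] as a floating-point guard (mathematically the interval is
#' already inside).  First-column coefficients are unconstrained: (-1, 1).
#'
#' @inheritParams bound_components
#' @return numeric vector `c(lower, upper)` with lower <= upper.
#' @examples
#' th <- matrix(0, 3, 3); th[2, 1] <- th[3, 1] <- pi / 3
#' B <- factor_from_angles(th)  # theta[3, 2] still free
#' coefficient_bounds(B, 3, 2)  # c(-0.5, 1)
#' @export
coefficient_bounds <- function(factor, i, j) {
  comps <- bound_components(factor, i, j)
  lower <- max(-1, comps$offset - comps$halfwidth)
  upper <- min(1, comps$offset + comps$halfwidth)
  c(lower = lower, upper = upper)
}

#' Correlative angle realizing a coefficient inside its bounds
#'
#' Inverts c = offset + halfwidth * cos(theta):
#' theta = acos((c - offset) / halfwidth), with the argument clamped when
#' within 1e-9 of \[-1, 1\].  A degenerate interval (halfwidth < 1e-12)
#' leaves the angle unidentifiable; the symmetric choice pi/2 is returned.
#'
#' @param c coefficient value, required within
#'   \[offset - halfwidth - 1e-9, offset + halfwidth + 1e-9\].
#' @param comps output of [bound_components()].
#' @return angle in radians in \[0, pi\]; `c` at the upper bound gives 0,
#'   at the lower bound pi, at the offset pi/2.
#' @export
angle_from_coefficient <- function(c, comps) {
  offset <- comps$offset
  hw <- comps$halfwidth
  if (hw < .sine_eps) {
    return(pi / 2)
  }
  lower <- offset - hw
  upper <- offset + hw
  if (c < lower - .acos_slack || c > upper + .acos_slack) {
    stop(sprintf("coefficient %.10g outside its bounds [%.10g, %.10g]",
                 c, max(-1, lower), min(1, upper)), call. = FALSE)
  }
  acos(.clamp_acos((c - offset) / hw, context = "angle_from_coefficient"))
}

#' Bounds-and-matrix bundle from a unit-interval draw matrix
#'
#' Runs the boundary-sequential construction on a supplied strictly lower
#' triangular matrix of unit-interval draws and returns the per-coefficient
#' lower-bound matrix L, upper-bound matrix U and the correlation matrix C
#' (before any reordering), optionally writing them as three delimited-text
#' matrices.
#'
#' @param draws n x n matrix; only the strictly lower triangle is read and
#'   must lie in \[0, 1\].
#' @param threshold_k boundary-gap threshold K (see [generate_na()]).
#' @param path optional directory; when given, writes `L.txt`, `U.txt`,
#'   `C.txt` there via [write_matrix()].
#' @return list with strictly lower triangular `L` and `U`, the
#'   [correlation_matrix()] `C`, the [angle_matrix()] `theta`, and C's
#'   minimum eigenvalue `min_eigenvalue`.
#' @export
bounds_matrices <- function(draws, threshold_k = 0.01, path = NULL) {
  u <- .check_unit_draws(draws)
  built <- .na_build(nrow(u), threshold_k, u)
  chk <- is_valid_corr(built$C, tol = 1e-12)
  out <- list(L = built$L, U = built$U,
              C = correlation_matrix(built$C, min_eigenvalue = chk$min_eigenvalue),
              theta = angle_matrix(built$theta),
              min_eigenvalue = chk$min_eigenvalue)
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    write_matrix(out$L, file.path(path, "L.txt"))
    write_matrix(out$U, file.path(path, "U.txt"))
    write_matrix(out$C, file.path(path, "C.txt"))
  }
  out
}

.check_unit_draws <- function(draws) {
  u <- unclass(as.matrix(draws))
  n <- nrow(u)
  if (ncol(u) != n || n < 2L) {
    stop("draw matrix must be square with dimension >= 2", call. = FALSE)
  }
  low <- u[lower.tri(u)]
  if (anyNA(low) || any(low < 0) || any(low > 1)) {
    stop("draws must lie in [0, 1] on the strictly lower triangle", call. = FALSE)
  }
  keep <- matrix(0, n, n)
  keep[lower.tri(keep)] <- low
  keep
}
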