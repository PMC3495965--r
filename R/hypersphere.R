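#' Strictly lower triangular matrix of correlative angles
#'
#' Constructs an `angle_matrix`: an n x n numeric matrix whose strictly
#' lower triangular entries theta\[i, j\] (row i > column j, 1-based) are
#' correlative angles in \[0, pi\]; all entries on or above the diagonal are
#' structurally zero.  Row i of the associated triangular factor is the
#' point on the unit (i-1)-sphere with spherical coordinates
#' theta\[i, 1\], ..., theta\[i, i-1\].
#'
#' @param theta numeric n x n matrix (n >= 2); only the strictly lower
#'   triangle is read, and it must lie in \[0, pi\].
#' @return an object of class `angle_matrix`.
#' @examples
#' th <- matrix(0, 3, 3)
#' th[lower.tri(th)] <- pi / 3
#' angle_matrix(th)
#' @export
angle_matrix <- function(theta) {
  theta <- as.matrix(theta)
  n <- nrow(theta)
  if (n < 2L || ncol(theta) != n) {
    stop("angle matrix must be square with dimension >= 2", call. = FALSE)
  }
  th <- matrix(0, n, n)
  low <- lower.tri(th)
  th[low] <- theta[low]
  .check_angle_range(th)
  structure(th, class = c("angle_matrix", "matrix"))
}

.check_angle_range <- function(th) {
  n <- nrow(th)
  for (j in seq_len(n - 1L)) {
    for (i in seq.int(j + 1L, n)) {
      v <- th[i, j]
      if (is.na(v) || v < 0 || v > pi) {
        stop(sprintf("correlative angle theta[%d,%d] = %g outside [0, pi]",
                     i, j, v), call. = FALSE)
      }
    }
  }
  invisible(th)
}

#' Lower triangular factor with unit-norm rows
#'
#' Wraps an n x n lower triangular matrix B satisfying B\[1,1\] = 1, zero
#' above the diagonal, non-negative diagonal and unit Euclidean row norms,
#' so that B B' is a correlation matrix.
#'
#' @param b numeric lower triangular matrix.
#' @param tol row-norm tolerance (default 1e-8).
#' @return an object of class `triangular_factor`.
#' @export
triangular_factor <- function(b, tol = 1e-8) {
  b <- as.matrix(b)
  n <- nrow(b)
  if (ncol(b) != n) stop("factor must be square", call. = FALSE)
  if (any(abs(b[upper.tri(b)]) > 0)) {
    stop("factor must be lower triangular", call. = FALSE)
  }
  norms <- sqrt(rowSums(b^2))
  if (any(abs(norms - 1) > tol)) {
    bad <- which.max(abs(norms - 1))
    stop(sprintf("invalid factor: row %d has norm %.12g (must be 1)",
                 bad, norms[bad]), call. = FALSE)
  }
  structure(b, class = c("triangular_factor", "matrix"))
}

#' Correlation matrix container
#'
#' Wraps a symmetric unit-diagonal matrix with off-diagonal entries in
#' \[-1, 1\].  Validity (positive semi-definiteness) is checked separately
#' with [is_valid_corr()]; the minimum eigenvalue, once computed, is cached
#' in the `"min_eigenvalue"` attribute.
#'
#' @param c numeric square matrix; symmetry is required within 1e-9 and the
#'   stored matrix is exactly symmetrized with a unit diagonal.
#' @param min_eigenvalue optional cached minimum eigenvalue.
#' @return an object of class `correlation_matrix`.
#' @export
correlation_matrix <- function(c, min_eigenvalue = NULL) {
  c <- as.matrix(c)
  n <- nrow(c)
  if (ncol(c) != n) stop("correlation matrix must be square", call. = FALSE)
  if (max(abs(c - t(c))) > 1e-9) {
    stop("correlation matrix must be symmetric (tolerance 1e-9)", call. = FALSE)
  }
  if (max(abs(diag(c) - 1)) > 1e-9) {
    stop("all diagonal entries must be equal to one", call. = FALSE)
  }
  if (max(abs(c)) > 1 + 1e-9) {
    stop("off-diagonal entries must lie in [-1, 1]", call. = FALSE)
  }
  c <- (c + t(c)) / 2
  diag(c) <- 1
  c[c > 1] <- 1
  c[c < -1] <- -1
  out <- structure(c, class = c("correlation_matrix", "matrix"))
  attr(out, "min_eigenvalue") <- min_eigenvalue
  out
}

#' @export
print.correlation_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("correlation_matrix %d x %d", nrow(x), nrow(x)))
  me <- attr(x, "min_eigenvalue")
  if (!is.null(me)) cat(sprintf(" (min eigenvalue %.5f)", me))
  cat("\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Triangular factor from correlative angles
#'
#' Maps a strictly lower triangular matrix of correlative angles to the
#' lower triangular factor B whose rows are the corresponding points on
#' unit hyperspheres:
#' b\[i,1\] = cos(theta\[i,1\]),
#' b\[i,j\] = cos(theta\[i,j\]) * prod_(k<j) sin(theta\[i,k\]) for 1 < j < i,
#' b\[i,i\] = prod_(k<i) sin(theta\[i,k\]), and b\[1,1\] = 1.
#' Unit row norms hold by construction (trigonometric identity), which is
#' what forces the unit diagonal of C = B B'.
#'
#' @param angles an [angle_matrix()] (or plain matrix coercible to one).
#' @return a [triangular_factor()].
#' @examples
#' th <- matrix(0, 3, 3); th[lower.tri(th)] <- pi / 2
#' factor_from_angles(th)   # identity
#' @export
factor_from_angles <- function(angles) {
  if (!inherits(angles, "angle_matrix")) angles <- angle_matrix(angles)
  n <- nrow(angles)
  b <- matrix(0, n, n)
  b[1, 1] <- 1
  for (i in 2:n) {
    sinprod <- 1
    for (j in seq_len(i - 1L)) {
      b[i, j] <- cos(angles[i, j]) * sinprod
      sinprod <- sinprod * sin(angles[i, j])
    }
    b[i, i] <- sinprod
  }
  triangular_factor(b, tol = 1e-12)
}

#' Correlation matrix from a triangular factor
#'
#' Computes the Gram matrix C = B B'.  Because the rows of B have unit
#' norm, C has a unit diagonal and is positive semi-definite by
#' construction.
#'
#' @param factor a [triangular_factor()] (row norms checked within `tol`).
#' @param tol row-norm tolerance.
#' @return a [correlation_matrix()].
#' @export
corr_from_factor <- function(factor, tol = 1e-8) {
  if (!inherits(factor, "triangular_factor")) {
    factor <- triangular_factor(factor, tol = tol)
  }
  b <- unclass(factor)
  correlation_matrix(tcrossprod(b))
}

#' Correlation matrix from correlative angles
#'
#' Composition of [factor_from_angles()] and [corr_from_factor()]: the
#' correlation matrix as a closed-form trigonometric function of the
#' correlative angles.  For example, at n = 3,
#' c\[3,2\] = cos(t21) cos(t31) + sin(t21) sin(t31) cos(t32).
#'
#' @inheritParams factor_from_angles
#' @return a [correlation_matrix()]; always passes the eigenvalue check.
#' @examples
#' th <- matrix(0, 3, 3); th[lower.tri(th)] <- pi / 3
#' corr_from_angles(th)   # off-diagonals 0.5, 0.5, 0.625
#' @export
corr_from_angles <- function(angles) {
  corr_from_factor(factor_from_angles(angles))
}

#' Correlative angles from a valid correlation matrix
#'
#' Inverts the hypersphere decomposition by sequential extraction:
#' theta\[i,1\] = acos(c\[i,1\]) and, for j >= 2,
#' theta\[i,j\] = acos((c\[i,j\] - A_ij) / S_ij) with
#' A_ij = sum_(k<j) b\[i,k\] b\[j,k\] and
#' S_ij = prod_(k<j) sin(theta\[i,k\]) * prod_(k<j) sin(theta\[j,k\]),
#' rebuilding the factor row as it goes.  When S_ij vanishes the
#' coefficient is fully determined by the earlier ones; if it is consistent
#' the unidentifiable angle is set to pi/2, otherwise an error names the
#' inconsistency.
#'
#' @param corr a valid [correlation_matrix()] (minimum eigenvalue >= -tol);
#'   rank-deficient matrices are accepted.
#' @param tol validity tolerance on the minimum eigenvalue (default 1e-8).
#' @return an [angle_matrix()]; `corr_from_angles()` of the result
#'   reproduces `corr` within 1e-8.
#' @export
angles_from_corr <- function(corr, tol = 1e-8) {
  if (!inherits(corr, "correlation_matrix")) corr <- correlation_matrix(corr)
  chk <- is_valid_corr(corr, tol = tol)
  if (!chk$valid) {
    stop(sprintf("not a valid correlation matrix: min eigenvalue %.6g < -%g",
                 chk$min_eigenvalue, tol), call. = FALSE)
  }
  n <- nrow(corr)
  th <- matrix(0, n, n)
  b <- matrix(0, n, n)
  b[1, 1] <- 1
  for (i in 2:n) {
    sinprod <- 1   # running prod of sin(theta[i, k]), k < current j
    for (j in seq_len(i - 1L)) {
      if (j == 1L) {
        a_ij <- 0
        s_ij <- 1
      } else {
        a_ij <- sum(b[i, 1:(j - 1L)] * b[j, 1:(j - 1L)])
        s_ij <- sinprod * b[j, j]   # b[j, j] = prod of sines of row j
      }
      if (s_ij < .sine_eps) {
        if (abs(corr[i, j] - a_ij) > 1e-9) {
          stop(sprintf(
            "inconsistent matrix: c[%d,%d] = %.10g but earlier coefficients force %.10g",
            i, j, corr[i, j], a_ij), call. = FALSE)
        }
        ang <- pi / 2
      } else {
        ang <- acos(.clamp_acos((corr[i, j] - a_ij) / s_ij,
                                context = sprintf("angle extraction at (%d,%d)", i, j)))
      }
      th[i, j] <- ang
      b[i, j] <- cos(ang) * sinprod
      sinprod <- sinprod * sin(ang)
    }
    b[i, i] <- sinprod
  }
  angle_matrix(th)
}
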