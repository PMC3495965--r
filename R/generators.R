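#' Configuration for the correlation-matrix generators
#'
#' @param n matrix dimension (>= 2).
#' @param threshold_k boundary-gap threshold K in \[0, 2\] (default 0.01).
#'   When the feasible interval of a coefficient is narrower than K the
#'   coefficient is centered within its bounds instead of drawn; larger K
#'   is more numerically stable but less random.
#' @param seed optional integer seed; when non-NULL, `set.seed(seed)` is
#'   called once at the start of a generation run so runs are replayable.
#' @param sampler bounded-variable source: `function(m)` returning `m`
#'   values in \[0, 1\] (default `runif`); draws are mapped affinely onto
#'   each coefficient's interval \[L, U\].
#' @param validity_tol tolerance on the minimum eigenvalue in the Step 4
#'   check (default 0: valid iff min(eig(C)) >= 0, mirroring the standard
#'   check; configurable because symmetric-eigensolver jitter differs
#'   across platforms).
#' @param max_attempts rejection budget before a generation-failure error
#'   (default 100; use `Inf` for validity-rate studies where rejection is
#'   itself the object of study).
#' @param rs_rounding logical; the rejection-sampling dialect that rounds
#'   each uniform draw to 8 decimal places before mapping to \[-1, 1\]
#'   (default TRUE; statistically irrelevant, kept for bit-exact replay of
#'   the reference construction).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n, threshold_k = 0.01, seed = NULL,
                             sampler = stats::runif, validity_tol = 0,
                             max_attempts = 100L, rs_rounding = TRUE) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("dimension n must be an integer >= 2", call. = FALSE)
  if (threshold_k < 0 || threshold_k > 2) {
    stop("threshold_k must lie in [0, 2]", call. = FALSE)
  }
  if (max_attempts < 1) stop("max_attempts must be >= 1", call. = FALSE)
  stopifnot(is.function(sampler))
  structure(list(n = n, threshold_k = threshold_k, seed = seed,
                 sampler = sampler, validity_tol = validity_tol,
                 max_attempts = max_attempts, rs_rounding = isTRUE(rs_rounding)),
            class = "generator_config")
}

.apply_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  invisible(NULL)
}

#' Step 4 eigenvalue validity check
#'
#' A correlation matrix is valid iff it is symmetric with a unit diagonal,
#' all coefficients lie in \[-1, 1\], and the minimum eigenvalue is
#' non-negative (within `tol`).
#'
#' @param corr square symmetric matrix (symmetry required within 1e-9).
#' @param tol eigenvalue tolerance: valid iff min eigenvalue >= -tol.
#' @return list with `valid` (logical) and `min_eigenvalue`.
#' @examples
#' is_valid_corr(diag(3))                       # valid, min eigenvalue 1
#' eq <- matrix(-0.6, 3, 3); diag(eq) <- 1
#' is_valid_corr(eq)                            # invalid: 1 + 2 rho = -0.2
#' @export
is_valid_corr <- function(corr, tol = 0) {
  m <- unclass(as.matrix(corr))
  n <- nrow(m)
  if (ncol(m) != n) stop("validity check requires a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-9) {
    stop("validity check requires a symmetric matrix (tolerance 1e-9)", call. = FALSE)
  }
  min_ev <- min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  structural <- max(abs(diag(m) - 1)) <= 1e-9 && max(abs(m)) <= 1 + 1e-9
  list(valid = structural && min_ev >= -tol, min_eigenvalue = min_ev)
}

# Core of the boundary-sequential construction (Steps 1-2): given a
# strictly lower triangular matrix of unit-interval draws, build the
# correlation matrix, its per-coefficient bound matrices and the angles.
# Returns plain matrices; callers wrap/validate.
.na_build <- function(n, threshold_k, u) {
  theta <- matrix(0, n, n)
  b <- matrix(0, n, n)
  b[1, 1] <- 1
  C <- diag(n)
  L <- matrix(0, n, n)
  U <- matrix(0, n, n)

  # Step 1: first column, bounds [-1, 1]
  for (i in 2:n) {
    cij <- -1 + 2 * u[i, 1]
    C[i, 1] <- C[1, i] <- cij
    L[i, 1] <- -1
    U[i, 1] <- 1
    ang <- acos(.clamp_acos(cij, context = "first-column angle"))
    theta[i, 1] <- ang
    b[i, 1] <- cos(ang)
  }
  b[2, 2] <- sin(theta[2, 1])

  # Step 2: rows 3..n, columns 2..i-1, left to right
  if (n >= 3L) {
    for (i in 3:n) {
      sinprod <- sin(theta[i, 1])
      for (j in 2:(i - 1L)) {
        offset <- sum(b[i, 1:(j - 1L)] * b[j, 1:(j - 1L)])
        hw <- sinprod * b[j, j]
        lo <- max(-1, offset - hw)
        up <- min(1, offset + hw)
        cij <- if (up - lo < threshold_k) (lo + up) / 2 else lo + u[i, j] * (up - lo)
        ang <- if (hw < .sine_eps) pi / 2 else {
          acos(.clamp_acos((cij - offset) / hw, context = "sequential angle"))
        }
        theta[i, j] <- ang
        b[i, j] <- cos(ang) * sinprod
        sinprod <- sinprod * sin(ang)
        C[i, j] <- C[j, i] <- cij
        L[i, j] <- lo
        U[i, j] <- up
      }
      b[i, i] <- sinprod
    }
  }
  list(C = C, L = L, U = U, theta = theta, B = b)
}

# Draw the full strictly lower triangular unit matrix in the documented
# order: first column top-down, then rows 3..n left-to-right.
.draw_unit_matrix <- function(n, sampler) {
  u <- matrix(0, n, n)
  u[2:n, 1] <- sampler(n - 1L)
  if (n >= 3L) {
    for (i in 3:n) u[i, 2:(i - 1L)] <- sampler(i - 2L)
  }
  bad <- u[lower.tri(u)]
  if (anyNA(bad) || any(bad < 0) || any(bad > 1)) {
    stop("sampler must return values in [0, 1]", call. = FALSE)
  }
  u
}

#' Boundary-sequential random correlation matrix (the four-step algorithm)
#'
#' Generates a valid random correlation matrix of dimension n:
#' \enumerate{
#'   \item First-column coefficients c\[i,1\] = -1 + 2 u\[i,1\] (their exact
#'     bounds are \[-1, 1\]); the corresponding angles are extracted.
#'   \item Remaining coefficients row by row (i = 3..n, j = 2..i-1): the
#'     exact bounds (L, U) are computed from the partial factor; if
#'     U - L >= K the coefficient is drawn as L + u (U - L), otherwise it is
#'     centered at (L + U) / 2 to avoid numerical instability in narrow
#'     intervals; the angle is extracted and the factor row extended.
#'   \item The matrix is randomly reordered (one simultaneous row/column
#'     permutation) so that all coefficient positions share the same
#'     marginal distribution.
#'   \item The minimum eigenvalue is checked; an invalid matrix is rejected
#'     and regeneration restarts from Step 1 (up to `max_attempts`).
#' }
#' RNG values are consumed in a fixed documented order (first column
#' top-down, then rows 3..n left-to-right, then the permutation), so a
#' seeded run is reproducible.
#'
#' @param config a [generator_config()].
#' @param draws optional strictly lower triangular matrix of unit-interval
#'   values to use instead of drawing from `config$sampler` (the role of
#'   the pre-drawn uniform matrix in the sequential construction).  Supplied
#'   draws are used for a single attempt; an invalid result is an error.
#' @param reorder logical; apply Step 3 (default TRUE).
#' @param on_reject optional `function(attempt, min_eigenvalue)` called on
#'   every rejected attempt (logging hook).
#' @return a [correlation_matrix()] that passes [is_valid_corr()], with
#'   attributes `min_eigenvalue` and `attempts`.
#' @examples
#' cfg <- generator_config(5, seed = 42)
#' C <- generate_na(cfg)
#' attr(C, "min_eigenvalue")
#' @export
generate_na <- function(config, draws = NULL, reorder = TRUE, on_reject = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  .apply_seed(config)
  if (!is.null(draws)) {
    u <- .check_unit_draws(draws)
    if (nrow(u) != n) stop("draw matrix dimension does not match config$n", call. = FALSE)
  }
  last_ev <- NA_real_
  max_att <- config$max_attempts
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    if (attempt > max_att) {
      stop(sprintf(
        "generation failed after %d attempts (last min eigenvalue %.6g)",
        max_att, last_ev), call. = FALSE)
    }
    u_att <- if (is.null(draws)) .draw_unit_matrix(n, config$sampler) else u
    built <- .na_build(n, config$threshold_k, u_att)
    C <- built$C
    if (reorder) C <- .permute_corr(C, sample.int(n))
    chk <- is_valid_corr(C, tol = config$validity_tol)
    last_ev <- chk$min_eigenvalue
    if (chk$valid) {
      out <- correlation_matrix(C, min_eigenvalue = chk$min_eigenvalue)
      attr(out, "attempts") <- attempt
      return(out)
    }
    if (!is.null(on_reject)) on_reject(attempt, last_ev)
    if (!is.null(draws)) {
      stop(sprintf(
        "supplied draws produce an invalid matrix (min eigenvalue %.6g); cannot regenerate fixed draws",
        last_ev), call. = FALSE)
    }
  }
}

.permute_corr <- function(C, perm) C[perm, perm, drop = FALSE]

#' Random simultaneous row/column reordering
#'
#' Applies one uniform random permutation P to both rows and columns
#' (P C P'), which preserves the eigenvalue multiset and the unit diagonal
#' while making all off-diagonal positions exchangeable.
#'
#' @param corr square symmetric matrix.
#' @param perm optional permutation of 1..n; drawn uniformly from the
#'   current RNG stream when NULL.
#' @return the reordered matrix, same class handling as the input.
#' @export
random_reorder <- function(corr, perm = NULL) {
  m <- as.matrix(corr)
  n <- nrow(m)
  if (ncol(m) != n || max(abs(m - t(m))) > 1e-9) {
    stop("random_reorder requires a square symmetric matrix", call. = FALSE)
  }
  if (is.null(perm)) perm <- sample.int(n)
  out <- .permute_corr(m, perm)
  if (inherits(corr, "correlation_matrix")) {
    out <- correlation_matrix(out, min_eigenvalue = attr(corr, "min_eigenvalue"))
  }
  out
}

#' Direct correlative-angle sampling
#'
#' Draws every correlative angle independently and maps through
#' [corr_from_angles()]; the result is a Gram matrix and therefore always
#' passes the eigenvalue check.  The default angle law is
#' theta = acos(1 - 2u) with u uniform, i.e. cos(theta) uniform on
#' \[-1, 1\]; any `function(m)` returning m angles in \[0, pi\] can be
#' substituted.  Provided for comparison: its coefficient marginals differ
#' markedly from the boundary-sequential generator's, which is why the
#' sequential construction is preferred.
#'
#' @param config a [generator_config()].
#' @param angle_sampler `function(m)` returning m angles in \[0, pi\].
#' @return a [correlation_matrix()] with attribute `min_eigenvalue`.
#' @export
generate_direct_angles <- function(config,
                                   angle_sampler = function(m) acos(1 - 2 * stats::runif(m))) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  .apply_seed(config)
  th <- matrix(0, n, n)
  th[2:n, 1] <- angle_sampler(n - 1L)
  if (n >= 3L) {
    for (i in 3:n) th[i, 2:(i - 1L)] <- angle_sampler(i - 2L)
  }
  C <- corr_from_angles(angle_matrix(th))
  chk <- is_valid_corr(C, tol = max(config$validity_tol, 1e-10))
  correlation_matrix(C, min_eigenvalue = chk$min_eigenvalue)
}

#' Rejection sampling (accept-reject) baseline
#'
#' Draws every strictly-lower coefficient independently uniform on
#' \[-1, 1\] (with the 8-decimal rounding dialect when
#' `config$rs_rounding`), symmetrizes with a unit diagonal, and keeps the
#' matrix only if its minimum eigenvalue is non-negative.  The per-attempt
#' success probability collapses with dimension (about 61.7% at n = 3,
#' 2.2% at n = 5, essentially zero for n >= 8), so the method is only
#' practical for small n.
#'
#' @param config a [generator_config()]; `max_attempts` bounds the number
#'   of rejections (use `Inf` with care for n <= 7).
#' @param warn_every emit a progress warning after this many rejected
#'   attempts when `max_attempts` is infinite (default 1e5).
#' @param on_reject optional `function(attempt, min_eigenvalue)` called on
#'   every rejected attempt (logging hook).
#' @return a [correlation_matrix()] with attributes `min_eigenvalue` and
#'   `attempts` (the number of draws consumed, accepted one included).
#' @export
generate_rs <- function(config, warn_every = 1e5, on_reject = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  if (n >= 8L) {
    warning("rejection sampling is practically infeasible for n >= 8 (per-attempt validity ~0)")
  }
  .apply_seed(config)
  m <- n * (n - 1L) / 2L
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    if (attempt > config$max_attempts) {
      stop(sprintf("rejection sampling failed after %d attempts", config$max_attempts),
           call. = FALSE)
    }
    e <- stats::runif(m)
    if (config$rs_rounding) e <- round(e * 1e8) / 1e8
    C <- diag(n)
    C[lower.tri(C)] <- -1 + 2 * e
    C <- C + t(C) - diag(n)
    chk <- is_valid_corr(C, tol = config$validity_tol)
    if (chk$valid) {
      out <- correlation_matrix(C, min_eigenvalue = chk$min_eigenvalue)
      attr(out, "attempts") <- attempt
      return(out)
    }
    if (!is.null(on_reject)) on_reject(attempt, chk$min_eigenvalue)
    if (is.infinite(config$max_attempts) && attempt %% warn_every == 0) {
      warning(sprintf("rejection sampling: %d attempts without success at n = %d",
                      attempt, n), immediate. = TRUE)
    }
  }
}

#' Spectrum-based baseline (Bendel-Davies lineage)
#'
#' Builds a correlation matrix with a prescribed eigenvalue spectrum: a
#' random orthogonal similarity transform of diag(eigenvalues) followed by
#' Givens plane rotations that drive each diagonal entry to exactly 1
#' while preserving the spectrum.  When no eigenvalues are supplied they
#' are drawn uniformly from the simplex scaled to sum to n.
#'
#' @param config a [generator_config()].
#' @param eigenvalues optional non-negative values summing to n (within
#'   1e-9).
#' @return a [correlation_matrix()] with attribute `min_eigenvalue`; its
#'   sorted eigenvalues equal the requested spectrum within 1e-8.
#' @export
generate_spectrum_baseline <- function(config, eigenvalues = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  .apply_seed(config)
  if (is.null(eigenvalues)) {
    g <- stats::rexp(n)
    eigenvalues <- n * g / sum(g)
  } else {
    if (length(eigenvalues) != n || any(eigenvalues < 0)) {
      stop("eigenvalues must be n non-negative values", call. = FALSE)
    }
    if (abs(sum(eigenvalues) - n) > 1e-9) {
      stop(sprintf("eigenvalue sum %.12g must equal n = %d", sum(eigenvalues), n),
           call. = FALSE)
    }
  }
  q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  A <- q %*% diag(eigenvalues, n) %*% t(q)
  A <- (A + t(A)) / 2

  # Givens sweep: while some diagonal entry differs from 1, pick a pair
  # straddling 1 (one below, one above; such a pair exists since the trace
  # is n) and rotate in that plane so one of them becomes exactly 1.
  for (iter in seq_len(4L * n)) {
    d <- diag(A)
    if (max(abs(d - 1)) <= 1e-12) break
    i <- which.min(d)
    j <- which.max(d)
    aii <- A[i, i]; ajj <- A[j, j]; aij <- A[i, j]
    # solve t^2 (ajj - 1) - 2 t aij + (aii - 1) = 0 for t = tan(theta)
    if (abs(ajj - 1) < 1e-14) {
      tt <- if (abs(aij) < 1e-14) 0 else (aii - 1) / (2 * aij)
    } else {
      disc <- sqrt(max(0, aij^2 - (aii - 1) * (ajj - 1)))
      t1 <- (aij + disc) / (ajj - 1)
      t2 <- (aij - disc) / (ajj - 1)
      tt <- if (abs(t1) <= abs(t2)) t1 else t2
    }
    cs <- 1 / sqrt(1 + tt^2)
    sn <- tt * cs
    rows <- A[c(i, j), , drop = FALSE]
    A[i, ] <- cs * rows[1, ] - sn * rows[2, ]
    A[j, ] <- sn * rows[1, ] + cs * rows[2, ]
    cols <- A[, c(i, j), drop = FALSE]
    A[, i] <- cs * cols[, 1] - sn * cols[, 2]
    A[, j] <- sn * cols[, 1] + cs * cols[, 2]
    A <- (A + t(A)) / 2
    A[i, i] <- 1
  }
  diag(A) <- 1
  A[A > 1] <- 1
  A[A < -1] <- -1
  chk <- is_valid_corr(A, tol = max(config$validity_tol, 1e-8))
  correlation_matrix(A, min_eigenvalue = chk$min_eigenvalue)
}
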