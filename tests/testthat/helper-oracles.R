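# Independent oracles used across test files.  Each is written directly
# from the mathematical definition, not by calling the code it checks.

# Closed-form 4x4 correlation matrix from correlative angles, expanded
# term by term (spherical-coordinate inner products written out by hand).
oracle_corr4 <- function(th) {
  t21 <- th[2, 1]; t31 <- th[3, 1]; t41 <- th[4, 1]
  t32 <- th[3, 2]; t42 <- th[4, 2]; t43 <- th[4, 3]
  C <- diag(4)
  C[2, 1] <- cos(t21)
  C[3, 1] <- cos(t31)
  C[4, 1] <- cos(t41)
  C[3, 2] <- cos(t21) * cos(t31) + sin(t21) * sin(t31) * cos(t32)
  C[4, 2] <- cos(t21) * cos(t41) + sin(t21) * sin(t41) * cos(t42)
  C[4, 3] <- cos(t31) * cos(t41) +
    sin(t31) * sin(t41) * (cos(t32) * cos(t42) + sin(t32) * sin(t42) * cos(t43))
  C[upper.tri(C)] <- t(C)[upper.tri(C)]
  C
}

# Strictly lower triangular angle matrix with entries drawn uniformly on
# an interior sub-interval of [0, pi].
random_interior_angles <- function(n, eps = 1e-2) {
  th <- matrix(0, n, n)
  m <- n * (n - 1) / 2
  th[lower.tri(th)] <- runif(m, eps, pi - eps)
  th
}

# Brute-force PSD-completability interval of entry (i, j) by grid search:
# fix the principal submatrix indexed {1..j, i} except its (j+1, j) entry,
# sweep that entry over a grid and keep values whose minimum eigenvalue is
# >= -1e-9.  Returns c(lower, upper) of the passing set.
grid_completability_interval <- function(C, i, j, step = 1e-3) {
  idx <- c(seq_len(j), i)
  S <- C[idx, idx, drop = FALSE]
  free <- length(idx)
  # the current entry is completable by construction; adding it to the grid
  # keeps the passing set non-empty when the feasible interval is narrower
  # than the step
  grid <- sort(c(seq(-1, 1, by = step), C[i, j]))
  ok <- vapply(grid, function(v) {
    S[free, j] <- v
    S[j, free] <- v
    min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) >= -1e-9
  }, logical(1))
  if (!any(ok)) stop("oracle found no completable value")
  range(grid[ok])
}

# Direct-definition moment summary: explicit sums, no shared code with
# summarize_coefficients().
oracle_moments <- function(x) {
  m <- length(x)
  mu <- sum(x) / m
  d <- x - mu
  m2 <- sum(d^2) / m
  list(mean = mu,
       sd = sqrt(sum(d^2) / (m - 1)),
       skewness = (sum(d^3) / m) / m2^(3 / 2),
       kurtosis = (sum(d^4) / m) / m2^2)
}

# Pool the coefficient at one strictly-lower position from repeated
# boundary-sequential generations, with or without the reordering step.
pool_na_coefficient <- function(count, n, position, reorder, k = 0.01) {
  cfg <- generator_config(n, threshold_k = k)
  vapply(seq_len(count), function(r) {
    C <- generate_na(cfg, reorder = reorder)
    C[position[1], position[2]]
  }, numeric(1))
}
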