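#' Per-attempt validity probability of a generator
#'
#' Monte-Carlo estimate of the probability that a single construction
#' attempt (no retries) passes the minimum-eigenvalue check.  For
#' rejection sampling this is the acceptance probability — geometrically,
#' the volume of the elliptope of valid correlation matrices relative to
#' the cube of symmetric unit-diagonal matrices — which collapses rapidly
#' with dimension.  For the boundary-sequential and spectrum generators it
#' is the pre-rejection stability rate (essentially 100%).
#'
#' @param method one of `"rs"`, `"na"`, `"spectrum"`.
#' @param n matrix dimension.
#' @param reps number of independent attempts (>= 1).
#' @param seed optional integer seed.
#' @param threshold_k boundary-gap threshold for `"na"`.
#' @param validity_tol eigenvalue tolerance of the check (default 0).
#' @param rs_rounding rejection-sampling rounding dialect (default TRUE).
#' @return list with `method`, `n`, `reps`, `valid_fraction`, and `ci95`
#'   (95% Wilson score interval).
#' @examples
#' estimate_pvalid("rs", n = 3, reps = 2000, seed = 1)$valid_fraction # ~0.617
#' @export
estimate_pvalid <- function(method, n, reps, seed = NULL, threshold_k = 0.01,
                            validity_tol = 0, rs_rounding = TRUE) {
  method <- match.arg(method, c("rs", "na", "spectrum"))
  n <- as.integer(n)
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ok <- switch(method,
    rs = {
      min_ev <- cpp_rs_mineig(n, reps, rs_rounding)
      sum(min_ev >= -validity_tol)
    },
    na = {
      valid <- 0L
      for (r in seq_len(reps)) {
        u <- .draw_unit_matrix(n, stats::runif)
        built <- .na_build(n, threshold_k, u)
        chk <- is_valid_corr(built$C, tol = validity_tol)
        if (chk$valid) valid <- valid + 1L
      }
      valid
    },
    spectrum = {
      cfg <- generator_config(n, validity_tol = validity_tol)
      valid <- 0L
      for (r in seq_len(reps)) {
        C <- generate_spectrum_baseline(cfg)
        if (attr(C, "min_eigenvalue") >= -max(validity_tol, 1e-8)) valid <- valid + 1L
      }
      valid
    })
  frac <- ok / reps
  list(method = method, n = n, reps = reps,
       valid_fraction = frac, ci95 = .wilson_ci(ok, reps))
}

.wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Pooled coefficient sample from repeated generation
#'
#' Generates `count` valid matrices with the requested method and collects
#' the coefficients at the given strictly-lower positions, in generation
#' order (so a seeded run can be replayed).  With random reordering on,
#' all positions share one marginal distribution (exchangeability), so the
#' choice of position is immaterial.
#'
#' @param method one of `"na"`, `"rs"`, `"angles"`, `"spectrum"`.
#' @param n matrix dimension; rejection sampling is refused for n >= 8,
#'   where its per-attempt validity is numerically zero.
#' @param count number of valid matrices to generate.
#' @param positions list of `c(i, j)` pairs with i > j (default `(2, 1)`).
#' @param seed optional integer seed.
#' @param threshold_k boundary-gap threshold for `"na"`.
#' @param reorder apply the random-reordering step for `"na"` (default
#'   TRUE).
#' @param rs_rounding rejection-sampling rounding dialect.
#' @return named list of numeric vectors of length `count`, one per
#'   position (names `"i.j"`).
#' @export
coefficient_sample <- function(method, n, count, positions = list(c(2L, 1L)),
                               seed = NULL, threshold_k = 0.01, reorder = TRUE,
                               rs_rounding = TRUE) {
  method <- match.arg(method, c("na", "rs", "angles", "spectrum"))
  n <- as.integer(n)
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1", call. = FALSE)
  if (!is.list(positions)) positions <- list(positions)
  for (p in positions) {
    if (length(p) != 2L || p[1] <= p[2] || p[2] < 1L || p[1] > n) {
      stop("positions must be strictly-lower index pairs c(i, j) with i > j",
           call. = FALSE)
    }
  }
  if (method == "rs" && n >= 8L) {
    stop("rejection sampling at n >= 8 is refused: per-attempt validity is numerically zero",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- lapply(positions, function(p) numeric(count))
  names(out) <- vapply(positions, function(p) paste(p[1], p[2], sep = "."), "")

  if (method == "rs") {
    mats <- cpp_rs_collect(n, count, rs_rounding)
    for (k in seq_along(positions)) {
      p <- positions[[k]]
      out[[k]] <- mats$matrices[, (p[2] - 1L) * n + p[1]]
    }
    attr(out, "total_attempts") <- mats$total_attempts
    return(out)
  }

  cfg <- generator_config(n, threshold_k = threshold_k, max_attempts = 1000L)
  for (r in seq_len(count)) {
    C <- switch(method,
      na = generate_na(cfg, reorder = reorder),
      angles = generate_direct_angles(cfg),
      spectrum = generate_spectrum_baseline(cfg))
    for (k in seq_along(positions)) {
      p <- positions[[k]]
      out[[k]][r] <- C[p[1], p[2]]
    }
  }
  out
}

#' Marginal summary of a coefficient sample
#'
#' Moments and percentiles of a pooled coefficient sample: mean, median,
#' standard deviation (n - 1 denominator), 10th/90th percentiles (linear
#' interpolation between closest order statistics), skewness, and
#' non-excess kurtosis (fourth standardized moment; normal = 3).  A
#' constant sample is flagged degenerate (sd 0, shape moments NA).
#'
#' @param sample numeric vector, length >= 2.
#' @return list with `n`, `mean`, `median`, `sd`, `p10`, `p90`,
#'   `skewness`, `kurtosis`, `degenerate`.
#' @export
summarize_coefficients <- function(sample) {
  x <- as.numeric(sample)
  if (length(x) < 2L || anyNA(x)) {
    stop("need at least 2 non-missing values to summarize", call. = FALSE)
  }
  m <- mean(x)
  s <- stats::sd(x)
  qs <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  if (s < 1e-14) {
    return(list(n = length(x), mean = m, median = qs[2], sd = 0,
                p10 = qs[1], p90 = qs[3],
                skewness = NA_real_, kurtosis = NA_real_, degenerate = TRUE))
  }
  z <- x - m
  m2 <- mean(z^2)
  list(n = length(x), mean = m, median = qs[2], sd = s,
       p10 = qs[1], p90 = qs[3],
       skewness = mean(z^3) / m2^1.5,
       kurtosis = mean(z^4) / m2^2,
       degenerate = FALSE)
}

#' Empirical CDF and histogram-PDF tables
#'
#' Distribution curves of a coefficient sample in plottable delimited
#' form: the empirical CDF evaluated at the sorted sample points
#' (F(x_(k)) = k / m) and a fixed-bin density histogram (default 61 bins
#' spanning \[-1, 1\]).
#'
#' @param sample numeric vector, length >= 100.
#' @param bins number of histogram bins (default 61).
#' @param range histogram support (default `c(-1, 1)`).
#' @return list of two data frames: `cdf` with columns `x`, `F`;
#'   `pdf` with columns `mid`, `density` (integrates to 1).
#' @export
empirical_curves <- function(sample, bins = 61L, range = c(-1, 1)) {
  x <- sort(as.numeric(sample))
  m <- length(x)
  if (m < 100L) stop("need at least 100 values for distribution curves", call. = FALSE)
  breaks <- seq(range[1], range[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  width <- diff(breaks)[1]
  list(
    cdf = data.frame(x = x, F = seq_len(m) / m),
    pdf = data.frame(mid = (breaks[-1] + breaks[-(bins + 1L)]) / 2,
                     density = counts / (m * width))
  )
}

#' Batched standard error of a sample statistic
#'
#' Splits the sample into consecutive batches, applies the statistic to
#' each, and returns the standard error of the overall statistic estimated
#' as sd(batch values) / sqrt(batches).  Used to attach Monte-Carlo
#' uncertainty to simulation summaries whose sampling variance has no
#' convenient closed form (sd, kurtosis, percentiles).
#'
#' @param sample numeric vector.
#' @param stat function mapping a numeric vector to a scalar.
#' @param batches number of consecutive batches (default 20).
#' @return list with `value` (statistic on the full sample) and `se`.
#' @export
batch_se <- function(sample, stat, batches = 20L) {
  x <- as.numeric(sample)
  m <- length(x)
  if (m < 2L * batches) stop("sample too small for the requested batching", call. = FALSE)
  idx <- cut(seq_len(m), batches, labels = FALSE)
  vals <- vapply(split(x, idx), stat, numeric(1))
  list(value = stat(x), se = stats::sd(vals) / sqrt(batches))
}
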