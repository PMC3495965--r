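test_that("step 1 maps a unit draw affinely onto [-1, 1]", {
  cfg <- generator_config(2)
  u <- matrix(0, 2, 2)
  u[2, 1] <- 0.75
  C <- generate_na(cfg, draws = u, reorder = FALSE)
  expect_equal(C[2, 1], 0.5)
  expect_true(is_valid_corr(C)$valid)
})

test_that("a midpoint sampler yields the identity at n = 3", {
  cfg <- generator_config(3, sampler = function(m) rep(0.5, m))
  C <- generate_na(cfg, reorder = FALSE)
  expect_equal(unclass(C), diag(3), ignore_attr = TRUE)
})

test_that("generated coefficients respect their post-hoc recomputed bounds", {
  cfg <- generator_config(5, threshold_k = 0.01, seed = 601)
  C <- generate_na(cfg, reorder = FALSE)
  expect_gte(attr(C, "min_eigenvalue"), 0)
  # reconstruct the factor by the inverse transform and recheck every bound
  B <- unclass(factor_from_angles(angles_from_corr(C)))
  for (i in 3:5) {
    for (j in 2:(i - 1)) {
      bd <- coefficient_bounds(B, i, j)
      gap <- bd["upper"] - bd["lower"]
      if (gap < cfg$threshold_k) {
        expect_equal(C[i, j], unname((bd["lower"] + bd["upper"]) / 2),
                     tolerance = 1e-8)
      } else {
        expect_gte(C[i, j], bd["lower"] - 1e-9)
        expect_lte(C[i, j], bd["upper"] + 1e-9)
      }
    }
  }
})

test_that("first-column coefficients are uniform on [-1, 1] before reordering", {
  set.seed(602)
  cfg <- generator_config(5)
  draws <- vapply(1:3000, function(r) generate_na(cfg, reorder = FALSE)[2, 1],
                  numeric(1))
  ks <- suppressWarnings(ks.test(draws, "punif", -1, 1))
  expect_gt(ks$p.value, 0.001)
})

test_that("reordering preserves the eigenvalue multiset and unit diagonal", {
  set.seed(603)
  C <- generate_na(generator_config(6))
  expect_equal(unclass(random_reorder(C, perm = 1:6)), unclass(C),
               ignore_attr = TRUE)
  P <- random_reorder(C, perm = sample.int(6))
  expect_identical(diag(unclass(P)), rep(1, 6))
  expect_equal(sort(eigen(unclass(P), symmetric = TRUE)$values),
               sort(eigen(unclass(C), symmetric = TRUE)$values),
               tolerance = 1e-12)
})

test_that("the validity check matches closed-form spectra", {
  expect_equal(is_valid_corr(diag(3)), list(valid = TRUE, min_eigenvalue = 1))
  eq <- matrix(-0.6, 3, 3); diag(eq) <- 1
  chk <- is_valid_corr(eq)
  expect_false(chk$valid)
  expect_equal(chk$min_eigenvalue, 1 + 2 * (-0.6), tolerance = 1e-12)
  edge <- is_valid_corr(matrix(1, 2, 2))
  expect_true(edge$valid)
  expect_equal(edge$min_eigenvalue, 0, tolerance = 1e-12)
  expect_error(is_valid_corr(matrix(1:6, 2, 3)), "square")
  expect_error(is_valid_corr(rbind(c(1, 0.5), c(0.2, 1))), "symmetric")
})

test_that("direct angle sampling is Gram-valid and has a degenerate limit", {
  cfg <- generator_config(4)
  Cdeg <- generate_direct_angles(cfg, angle_sampler = function(m) rep(pi / 2, m))
  expect_equal(unclass(Cdeg), diag(4), ignore_attr = TRUE)
  C <- generate_direct_angles(generator_config(10, seed = 604))
  expect_true(is_valid_corr(C, tol = 1e-10)$valid)
})

test_that("rejection sampling succeeds immediately at n = 2", {
  for (s in 1:5) {
    C <- generate_rs(generator_config(2, seed = s))
    expect_identical(attr(C, "attempts"), 1L)
    expect_true(is_valid_corr(C)$valid)
  }
})

test_that("the R and compiled rejection-sampling paths draw identically", {
  cfg <- generator_config(5, seed = 605, max_attempts = Inf)
  C <- generate_rs(cfg)
  set.seed(605)
  min_ev <- corrbound:::cpp_rs_mineig(5L, attr(C, "attempts"), TRUE)
  # every attempt before the last was rejected; the last matches the output
  expect_true(all(min_ev[-length(min_ev)] < 0))
  expect_equal(min_ev[length(min_ev)], attr(C, "min_eigenvalue"), tolerance = 1e-12)
})

test_that("the rounding dialect changes draws only in the 8th decimal", {
  C1 <- generate_rs(generator_config(3, seed = 606, rs_rounding = TRUE))
  C2 <- generate_rs(generator_config(3, seed = 606, rs_rounding = FALSE))
  expect_lt(max(abs(unclass(C1) - unclass(C2))), 1e-7)
})

test_that("the spectrum baseline hits the requested eigenvalues", {
  cfg3 <- generator_config(3)
  expect_equal(unclass(generate_spectrum_baseline(cfg3, eigenvalues = c(1, 1, 1))),
               diag(3), ignore_attr = TRUE)
  Csing <- generate_spectrum_baseline(generator_config(3, seed = 607),
                                      eigenvalues = c(2, 1, 0))
  ev <- sort(eigen(unclass(Csing), symmetric = TRUE)$values)
  expect_equal(ev, c(0, 1, 2), tolerance = 1e-8)
  expect_gte(attr(Csing, "min_eigenvalue"), -1e-8)
  set.seed(608)
  target <- rexp(5); target <- 5 * target / sum(target)
  C5 <- generate_spectrum_baseline(generator_config(5, seed = 609),
                                   eigenvalues = target)
  expect_equal(sort(eigen(unclass(C5), symmetric = TRUE)$values), sort(target),
               tolerance = 1e-8)
  expect_error(generate_spectrum_baseline(cfg3, eigenvalues = c(2, 2, 2)),
               "sum")
})

test_that("identical seed and config reproduce matrices exactly", {
  for (gen in list(generate_na, generate_rs, generate_direct_angles,
                   generate_spectrum_baseline)) {
    cfg <- generator_config(5, seed = 610)
    expect_identical(unclass(gen(cfg)), unclass(gen(cfg)))
  }
})

test_that("invalid supplied draws and exhausted budgets raise errors", {
  u <- matrix(0, 3, 3)
  u[lower.tri(u)] <- 1.5
  expect_error(generate_na(generator_config(3), draws = u), "\\[0, 1\\]")
  bad_sampler <- function(m) rep(2, m)
  expect_error(generate_na(generator_config(3, sampler = bad_sampler)),
               "\\[0, 1\\]")
  cfg <- generator_config(6, seed = 611, max_attempts = 2)
  expect_error(generate_rs(cfg), "after 2 attempts")
})
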