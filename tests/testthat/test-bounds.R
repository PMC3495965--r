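test_that("first-column bounds are always [-1, 1]", {
  set.seed(501)
  B <- factor_from_angles(random_interior_angles(5))
  for (i in 2:5) {
    comps <- bound_components(B, i, 1)
    expect_equal(comps$offset, 0)
    expect_equal(comps$halfwidth, 1)
    expect_equal(unname(coefficient_bounds(B, i, 1)), c(-1, 1))
  }
})

test_that("a perfect first-column correlation forces the next coefficient", {
  # theta[2,1] = 0: variable 2 duplicates variable 1, so c[3,2] must equal c[3,1]
  th <- matrix(0, 3, 3)
  th[3, 1] <- acos(0.3)
  B <- factor_from_angles(th)   # theta[2,1] = 0
  comps <- bound_components(B, 3, 2)
  expect_equal(comps$halfwidth, 0)
  expect_equal(comps$offset, 0.3)
  expect_equal(angle_from_coefficient(0.3, comps), pi / 2)
})

test_that("the n=3 closed-form bounds match cos(t21 +/- t31)", {
  th <- matrix(0, 3, 3)
  th[2, 1] <- th[3, 1] <- pi / 3
  B <- factor_from_angles(th)
  comps <- bound_components(B, 3, 2)
  expect_equal(comps$offset, 0.25)
  expect_equal(comps$halfwidth, 0.75)
  bd <- coefficient_bounds(B, 3, 2)
  expect_equal(unname(bd), c(cos(2 * pi / 3), cos(0)))
})

test_that("orthogonal priors leave every coefficient unconstrained", {
  th <- matrix(0, 5, 5)
  th[lower.tri(th)] <- pi / 2
  B <- factor_from_angles(th)
  for (i in 3:5) {
    for (j in 2:(i - 1)) {
      expect_equal(unname(coefficient_bounds(B, i, j)), c(-1, 1))
    }
  }
})

test_that("premature bound requests raise an ordering error", {
  B <- matrix(NA_real_, 4, 4)
  B[1, 1] <- 1
  B[2, 1:2] <- c(0.5, sqrt(0.75))
  # row 3 not yet determined: bounds for (4, 3) need rows 1..3
  expect_error(bound_components(B, 4, 3), "ordering")
  expect_error(bound_components(B, 2, 2), "row > column")
})

test_that("angle_from_coefficient maps the interval ends correctly", {
  comps <- list(offset = 0.2, halfwidth = 0.5)
  expect_equal(angle_from_coefficient(0.7, comps), 0, tolerance = 1e-6)
  expect_equal(angle_from_coefficient(-0.3, comps), pi, tolerance = 1e-6)
  expect_equal(angle_from_coefficient(0.2, comps), pi / 2)
  expect_error(angle_from_coefficient(0.9, comps), "outside its bounds")
})

test_that("bounds equal the brute-force completability interval", {
  set.seed(502)
  for (rep in 1:50) {
    n <- sample(4:6, 1)
    th <- random_interior_angles(n)
    B <- factor_from_angles(th)
    C <- unclass(corr_from_factor(B))
    i <- sample(3:n, 1)
    j <- sample(2:(i - 1), 1)
    oracle <- grid_completability_interval(C, i, j)
    bd <- coefficient_bounds(B, i, j)
    expect_lt(abs(bd["lower"] - oracle[1]), 2e-3)
    expect_lt(abs(bd["upper"] - oracle[2]), 2e-3)
  }
})

test_that("any coefficient drawn inside its bounds is reproduced exactly", {
  set.seed(503)
  for (rep in 1:20) {
    n <- 5
    th <- random_interior_angles(n)
    B <- unclass(factor_from_angles(th))
    i <- sample(3:n, 1)
    j <- sample(2:(i - 1), 1)
    comps <- bound_components(B, i, j)
    bd <- coefficient_bounds(B, i, j)
    cij <- runif(1, bd["lower"], bd["upper"])
    ang <- angle_from_coefficient(cij, comps)
    th2 <- th
    th2[i, j] <- ang
    C2 <- corr_from_angles(th2)
    expect_lt(abs(C2[i, j] - cij), 1e-10)
  }
})

test_that("halfwidth collapses when any prior angle hits 0 or pi", {
  th <- matrix(0, 4, 4)
  th[lower.tri(th)] <- pi / 4
  th[3, 1] <- pi   # anti-correlated with variable 1
  B <- factor_from_angles(th)
  expect_equal(bound_components(B, 3, 2)$halfwidth, 0)
  expect_equal(bound_components(B, 4, 3)$halfwidth, 0)
})

test_that("bounds_matrices reproduces the draws-to-L/U/C pipeline", {
  set.seed(504)
  u <- matrix(0, 5, 5)
  u[lower.tri(u)] <- runif(10)
  out <- bounds_matrices(u)
  # every generated coefficient inside its own interval
  low <- lower.tri(u)
  expect_true(all(out$L[low] <= unclass(out$C)[low] + 1e-12))
  expect_true(all(unclass(out$C)[low] <= out$U[low] + 1e-12))
  expect_true(all(out$L[low] <= out$U[low]))
  expect_equal(out$L[2, 1], -1)
  expect_equal(out$U[2, 1], 1)
  expect_true(is_valid_corr(out$C, tol = 1e-10)$valid)
  # degenerate midpoint draws give the identity (first column zero)
  mid <- bounds_matrices(matrix(0.5, 4, 4))
  expect_equal(unclass(mid$C), diag(4), ignore_attr = TRUE)
})
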