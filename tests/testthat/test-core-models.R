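test_that("parameter count matches the closed form and subset enumeration", {
  expect_identical(parameter_count(2), 9L)
  expect_identical(parameter_count(3), 21L)
  expect_identical(parameter_count(4), 45L)
  for (n in 2:6) {
    # brute force: 3 perturbations per compound + 3 per subset of size >= 2
    n_subsets <- sum(vapply(2:n, function(k) ncol(utils::combn(n, k)), 0))
    expect_identical(parameter_count(n), as.integer(3 * n + 3 * n_subsets))
  }
  expect_error(parameter_count(1), "integer >= 2")
})

test_that("scaled doses divide by EC50 and the d_m50 shift", {
  a <- hill_curve("a", ec50 = 0.144, slope = 4.8)
  b <- hill_curve("b", ec50 = 0.5, slope = 2)
  m <- ricc_model(list(a, b), perturbations = list(d_m50 = c(1, 2)))
  expect_equal(scaled_doses(m, c(0.144, 0))[1, ], c(1, 0))
  expect_equal(scaled_doses(m, c(0, 2))[1, 2], 2)        # 2 / (0.5 * 2)
  expect_equal(scaled_doses(m, c(0, 2), shifted = FALSE)[1, 2], 4)
})

test_that("null surface is sham-compliant for identical compounds", {
  same <- function(nm) hill_curve(nm, ec50 = 0.7, slope = 3.2, emax = 0.9)
  a <- same("a")
  m2 <- ricc_model(list(same("a"), same("b")))
  m3 <- ricc_model(list(same("a"), same("b"), same("c")))
  set.seed(42)
  for (i in 1:25) {
    D <- exp(stats::runif(1, -2, 2))
    p <- stats::runif(1)
    expect_equal(u_null(m2, c(p * D, (1 - p) * D)), hill_effect(a, D),
                 tolerance = 1e-10)
    w <- stats::runif(3); w <- w / sum(w)
    expect_equal(u_null(m3, w * D), hill_effect(a, D), tolerance = 1e-10)
  }
})

test_that("single-compound limits reduce to the (perturbed) Hill curves", {
  set.seed(7)
  for (seed in 1:5) {
    m <- random_model(3, seed)
    for (i in 1:3) {
      d <- numeric(3); d[i] <- exp(stats::runif(1, -2, 2))
      expect_equal(u_null(m, d), hill_effect(m$curves[[i]], d[i]),
                   tolerance = 1e-10)
      # full surface: interaction terms vanish, perturbations remain
      cv <- m$curves[[i]]
      pm <- d[i] / (cv$ec50 * m$pert$d_m50[i])
      pert_curve <- cv$e0 + (cv$emax + m$pert$d_emax[i] - cv$e0) /
        (1 + pm^(-(cv$slope + m$pert$d_slope[i])))
      expect_equal(u_ricc(m, d), pert_curve, tolerance = 1e-10)
    }
  }
})

test_that("perturbed saturation limit approaches emax + d_emax", {
  a <- hill_curve("a", ec50 = 1, slope = 3, emax = 0.8)
  b <- hill_curve("b", ec50 = 2, slope = 2)
  m <- ricc_model(list(a, b), perturbations = list(d_emax = c(0.15, 0)))
  expect_equal(u_ricc(m, c(1e12, 1)), 0.95, tolerance = 1e-5)
})

test_that("full surface reduces continuously to the null surface", {
  m0 <- random_model(2, 11, with_pert = FALSE, with_inter = FALSE)
  expect_equal(u_ricc(m0, c(0.5, 1.2)), u_null(m0, c(0.5, 1.2)))
  # shrink active parameters toward the inactive values
  d <- c(0.8, 0.6)
  vals <- vapply(c(1, 0.1, 0.01, 1e-4, 1e-8), function(eps) {
    set.seed(12)
    curves <- random_curves(2)
    m <- ricc_model(curves,
                    perturbations = list(d_emax = c(-0.05, -0.08) * eps,
                                         d_slope = c(0.3, -0.2) * eps,
                                         d_m50 = exp(c(0.2, -0.1) * eps)),
                    interactions = list("1,2" = c(0.5, 0.1, -0.5) * eps))
    u_ricc(m, d) - u_null(m, d)
  }, 0)
  expect_true(all(abs(vals) >= abs(vals[c(2:5, 5)]) - 1e-12))
  expect_lt(abs(vals[5]), 1e-8)
})

test_that("zero dose returns the baseline and monotonicity holds", {
  m <- random_model(3, 21)
  expect_equal(u_null(m, c(0, 0, 0)), m$umin_value)
  expect_equal(u_ricc(m, c(0, 0, 0)), m$umin_value)
  # equal maxima, positive slopes: nondecreasing in each dose
  cv <- list(hill_curve("a", 0.5, 2.5), hill_curve("b", 2, 6))
  mm <- ricc_model(cv)
  for (i in 1:2) {
    d <- matrix(0.7, 40, 2)
    d[, i] <- exp(seq(-4, 4, length.out = 40))
    expect_true(all(diff(u_null(mm, d)) >= -1e-12))
  }
})

test_that("a too-negative position interaction raises a named error", {
  cv <- random_curves(3)
  m <- ricc_model(cv, interactions = list("1,2" = c(-1.9, 0, 0),
                                          "1,3" = c(-1.9, 0, 0),
                                          "2,3" = c(-1.9, 0, 0)))
  ec50 <- vapply(cv, `[[`, 0, "ec50")
  expect_error(u_ricc(m, ec50), "too negative")
  expect_error(u_ricc(m, ec50), "\\{1,2\\}|\\{1,3\\}|\\{2,3\\}")
})

test_that("null and full surfaces satisfy the Riccati PDE", {
  set.seed(5)
  for (seed in 1:4) {
    for (n in 2:3) {
      m <- random_model(n, seed + 30 * n)
      for (rep in 1:5) {
        x <- stats::runif(n, -1.5, 1.5)
        expect_lt(abs(pde_residual(m, x, step = 1e-5, type = "null")), 1e-6)
        expect_lt(abs(pde_residual(m, x, step = 1e-5, type = "full")), 1e-6)
      }
    }
  }
})

test_that("a surface with inflated slope function violates the PDE", {
  # independent check: central differences of u_null against the analytic
  # right-hand side, correct vs corrupted gamma (identical curves so the
  # slope function is exactly the common Hill coefficient)
  a <- hill_curve("a", ec50 = 1, slope = 3)
  b <- hill_curve("b", ec50 = 1, slope = 3)
  m <- ricc_model(list(a, b))
  x <- c(-0.3, 0.4); h <- 1e-5
  f <- function(xx) u_null(m, exp(xx))
  lhs <- (f(x + c(h, 0)) - f(x - c(h, 0))) / (2 * h) +
    (f(x + c(0, h)) - f(x - c(0, h))) / (2 * h)
  u <- f(x)
  expect_lt(abs(lhs - 3 * u * (1 - u)), 1e-6)
  expect_gt(abs(lhs - 1.1 * 3 * u * (1 - u)), 1e-3)
})
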