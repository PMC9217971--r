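test_that("a null model has an identically zero synergy surface", {
  curves <- list(hill_curve("a", ec50 = 0.5, slope = 2),
                 hill_curve("b", ec50 = 2, slope = 3))
  m <- ricc_model(curves)
  axes <- list(a = c(0, 0.5 * 2^seq(-3, 3, length.out = 31)),
               b = c(0, 2 * 2^seq(-3, 3, length.out = 31)))
  sf <- synergy_surface(m, axes = axes)
  expect_true(all(sf$values == 0))
  ex <- find_extrema(sf, refine = FALSE)
  expect_equal(ex$maximum$value, 0)
  expect_equal(ex$minimum$value, 0)
})

test_that("interaction-only synergy vanishes along the single-drug axes", {
  curves <- list(hill_curve("a", ec50 = 0.5, slope = 2),
                 hill_curve("b", ec50 = 2, slope = 3))
  m <- ricc_model(curves, interactions = list("1,2" = c(0.8, 0.2, 1)))
  axes <- list(a = c(0, 0.5 * 2^seq(-3, 3, length.out = 21)),
               b = c(0, 2 * 2^seq(-3, 3, length.out = 21)))
  sf <- synergy_surface(m, axes = axes)
  expect_true(all(abs(sf$values[, 1]) < 1e-12))  # b = 0 line
  expect_true(all(abs(sf$values[1, ]) < 1e-12))  # a = 0 line
  expect_gt(max(sf$values), 0.01)
})

test_that("refined extrema are grid-resolution invariant", {
  curves <- list(hill_curve("a", ec50 = 0.5, slope = 2),
                 hill_curve("b", ec50 = 2, slope = 3))
  m <- ricc_model(curves, interactions = list("1,2" = c(0.8, 0.2, 1)))
  mk_axes <- function(np) list(a = c(0, 0.5 * 2^seq(-3, 3, length.out = np)),
                               b = c(0, 2 * 2^seq(-3, 3, length.out = np)))
  e1 <- find_extrema(synergy_surface(m, axes = mk_axes(101)))
  e2 <- find_extrema(synergy_surface(m, axes = mk_axes(201)))
  expect_equal(e1$maximum$value, e2$maximum$value, tolerance = 1e-6)
  # refined value is at least the dense-grid value
  dense <- synergy_surface(m, axes = mk_axes(801))
  expect_gte(e1$maximum$value + 1e-9, max(dense$values))
  # located within one coarse grid cell of the dense-grid argmax
  idx <- which(dense$values == max(dense$values), arr.ind = TRUE)[1, ]
  amax <- c(dense$axes[[1]][idx[1]], dense$axes[[2]][idx[2]])
  step <- diff(log(mk_axes(101)[[1]][-1]))[1]
  expect_true(all(abs(log(e1$maximum$doses) - log(amax)) < 2 * step))
})

test_that("mismatched null and full models are rejected", {
  curves <- list(hill_curve("a", ec50 = 0.5, slope = 2),
                 hill_curve("b", ec50 = 2, slope = 3))
  m <- ricc_model(curves, interactions = list("1,2" = c(0.8, 0.2, 1)))
  other <- ricc_model(list(hill_curve("a", ec50 = 0.7, slope = 2),
                           hill_curve("b", ec50 = 2, slope = 3)))
  axes <- list(a = c(0, 1), b = c(0, 1))
  expect_error(synergy_surface(m, null_model = other, axes = axes),
               "share compound order")
})

test_that("null-model isoboles are straight lines at the 50% level", {
  curves <- list(hill_curve("a", ec50 = 0.5, slope = 3),
                 hill_curve("b", ec50 = 2, slope = 3))
  m <- ricc_model(curves)
  axes <- list(a = c(0, 0.5 * 2^seq(-4, 2, length.out = 101)),
               b = c(0, 2 * 2^seq(-4, 2, length.out = 101)))
  iso <- iso_levels(m, 0.5, axes = axes, what = "null")
  pts <- do.call(rbind, iso[[1]])
  expect_gt(nrow(pts), 10)
  msum <- pts$a / 0.5 + pts$b / 2
  expect_true(all(abs(msum - 1) < 0.02))
})

test_that("ternary null iso-effect surface at 50% is planar in scaled doses", {
  curves <- anesthetic_curves()
  m <- ricc_model(curves)
  ec50 <- vapply(curves, `[[`, 0, "ec50")
  axes <- lapply(ec50, function(e) c(0, e * 2^seq(-4, 1.5, length.out = 41)))
  names(axes) <- vapply(curves, `[[`, "", "name")
  iso <- iso_levels(m, 0.5, axes = axes, what = "null")
  tri <- iso[[1]]
  expect_gt(nrow(tri), 100)
  msum <- as.matrix(tri[, 2:4]) %*% (1 / ec50)
  expect_lt(max(abs(msum - 1)), 0.05)
})

test_that("levels outside the surface range give an empty set with a warning", {
  curves <- list(hill_curve("a", ec50 = 0.5, slope = 2),
                 hill_curve("b", ec50 = 2, slope = 3))
  m <- ricc_model(curves)
  axes <- list(a = c(0, 0.5 * 2^seq(-2, 2, length.out = 21)),
               b = c(0, 2 * 2^seq(-2, 2, length.out = 21)))
  expect_warning(iso <- iso_levels(m, 1.5, axes = axes, what = "null"),
                 "outside")
  expect_length(iso[[1]], 0)
})

test_that("the ternary synergy field peaks at low midazolam/alfentanil and
           mid-range propofol", {
  curves <- anesthetic_curves()
  # published ternary interaction parameters
  m <- ricc_model(curves, interactions = list(
    "1,2" = c(1.11, 0.13, -12.84),
    "1,3" = c(1.69, -0.09, 1.56),
    "2,3" = c(0.40, 0.23, -11.78),
    "1,2,3" = c(-1.16, 0.00, 2.46)))
  axes <- list(midazolam = c(0, 0.2 * 2^seq(-6, 0, length.out = 41)),
               propofol = c(0, 2.5 * 2^seq(-6, 0, length.out = 41)),
               alfentanil = c(0, 0.15 * 2^seq(-6, 0, length.out = 41)))
  sf <- synergy_surface(m, axes = axes)
  ex <- find_extrema(sf)
  expect_gt(ex$maximum$value, 0.5)
  expect_lt(ex$maximum$doses[["midazolam"]], 0.06)
  expect_lt(ex$maximum$doses[["alfentanil"]], 0.02)
  expect_gt(ex$maximum$doses[["propofol"]], 0.2)
  expect_lt(ex$maximum$doses[["propofol"]], 0.8)
})
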