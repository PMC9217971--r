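test_that("pure-compound fit recovers noiseless Hill parameters", {
  d <- 0.5 * 2^seq(-2, 2, length.out = 8)
  truth <- hill_curve("x", ec50 = 0.5, slope = 2)
  tab <- dose_table(data.frame(x = d, effect = hill_effect(truth, d)),
                    compounds = "x")
  # an exact fit legitimately warns that the AIC degenerates
  f <- suppressWarnings(fit_pure(tab, "x"))
  expect_equal(f$curve$ec50, 0.5, tolerance = 1e-6)
  expect_equal(f$curve$slope, 2, tolerance = 1e-6)
  expect_lt(f$rmse, 1e-8)
})

test_that("midazolam rows give the published pure-curve parameters", {
  tab <- load_anesthetics()
  f <- fit_pure(tab, "midazolam")
  expect_equal(f$curve$ec50, 0.144, tolerance = 0.005)
  expect_equal(f$curve$slope, 4.8, tolerance = 0.02)
  expect_equal(f$rmse, 0.054, tolerance = 0.05)
  expect_error(fit_pure(tab, "caffeine"), "unknown compound")
  flat <- dose_table(data.frame(x = 1:5, effect = rep(0.5, 5)), compounds = "x")
  expect_error(fit_pure(flat, "x"), "degenerate")
})

test_that("EC50 estimation is nearly unbiased under moderate noise", {
  d <- 0.5 * 2^seq(-2.5, 2.5, length.out = 8)
  truth <- hill_curve("x", ec50 = 0.5, slope = 2)
  mu <- hill_effect(truth, d)
  set.seed(101)
  rel_err <- replicate(100, {
    tab <- dose_table(data.frame(x = d, effect = mu + stats::rnorm(8, sd = 0.05)),
                      compounds = "x", validate_effect = FALSE)
    fit_pure(tab, "x")$curve$ec50 / 0.5 - 1
  })
  expect_lt(abs(stats::median(rel_err)), 0.05)
})

test_that("an all-off mask returns null-model statistics without fitting", {
  tab <- load_anesthetics()
  curves <- anesthetic_curves()
  f <- fit_mixture(tab, curves, empty_mask(curves))
  expect_identical(f$n_params, 0L)
  m <- ricc_model(curves)
  expect_equal(f$rmse, sqrt(mean((tab$effect -
    u_null(m, as.matrix(tab[, 1:3])))^2)), tolerance = 1e-12)
})

test_that("the three-interaction fit reproduces the published mixture model", {
  tab <- load_anesthetics()
  curves <- anesthetic_curves()
  pt <- subset_compounds(tab, c("midazolam", "propofol"))
  cv <- curves[1:2]
  f <- fit_mixture(pt, cv, interaction_mask(cv), seed = 1)
  expect_equal(unname(f$par["d_m.midazolam:propofol"]), 1.11, tolerance = 0.05)
  expect_equal(unname(f$par["d_emax.midazolam:propofol"]), 0.14, tolerance = 0.05)
  expect_equal(unname(f$par["d_slope.midazolam:propofol"]), -12.9,
               tolerance = 0.05)
  expect_equal(f$rmse, 0.043, tolerance = 0.03)
  expect_gt(f$mw_p, 0.05)
})

test_that("known interaction parameters are recovered within 3 standard errors", {
  curves <- list(hill_curve("a", ec50 = 0.5, slope = 2),
                 hill_curve("b", ec50 = 2, slope = 3))
  truth <- c(0.5, 0.3, 1.0)  # d_m, d_emax, d_slope
  gt <- ricc_model(curves, interactions = list("1,2" = truth))
  spec <- synthetic_spec(gt, noise_sd = 0.02, seed = 77)
  tab <- generate_table(spec)
  f <- fit_mixture(tab, curves, interaction_mask(curves), seed = 3)
  expect_true(all(abs(f$par - truth) <= 3 * f$se))
})

test_that("fits are invariant to compound ordering", {
  tab <- load_anesthetics()
  curves <- anesthetic_curves()
  pt <- subset_compounds(tab, c("midazolam", "propofol"))
  qt <- subset_compounds(tab, c("propofol", "midazolam"))
  cv <- curves[1:2]
  f1 <- fit_mixture(pt, cv, interaction_mask(cv), seed = 1)
  cv2 <- curves[2:1]
  f2 <- fit_mixture(qt, cv2, interaction_mask(cv2), seed = 1)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-8)
  expect_equal(unname(f1$par), unname(f2$par), tolerance = 1e-5)
})

test_that("2-SE intervals cover the truth in at least 80% of seeded fits", {
  curves <- list(hill_curve("a", ec50 = 0.5, slope = 2),
                 hill_curve("b", ec50 = 2, slope = 3))
  triples <- list(c(0.5, 0.3, 1.0), c(1.0, -0.1, -2.0), c(0.2, 0.1, 0.5))
  covered <- total <- 0
  for (ti in seq_along(triples)) for (sd in c(0.01, 0.05)) {
    gt <- ricc_model(curves, interactions = list("1,2" = triples[[ti]]))
    tab <- generate_table(synthetic_spec(gt, noise_sd = sd,
                                         seed = 1000 + 10 * ti + round(100 * sd)))
    f <- fit_mixture(tab, curves, interaction_mask(curves), seed = 5)
    hit <- abs(f$par - triples[[ti]]) <= 2 * f$se
    covered <- covered + sum(hit); total <- total + length(hit)
  }
  expect_gte(covered / total, 0.8)
})
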