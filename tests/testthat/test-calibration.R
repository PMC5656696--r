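test_that("fit_ols matches closed-form least squares", {
  # hand arithmetic: Sxx = 5, Sxy = 1 -> slope 0.2, intercept 0.2, R^2 0.2
  d <- data.frame(x = 0:3, y = c(0, 1, 0, 1))
  fit <- fit_ols(d, x, y)
  expect_equal(fit$map$m, 0.2, tolerance = 1e-12)
  expect_equal(fit$map$b, 0.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 0.2, tolerance = 1e-12)
  expect_identical(fit$n, 4L)
  # residual_sd with n-2 denominator: residuals (-0.2, 0.6, -0.6, 0.2)
  expect_equal(fit$residual_sd, sqrt((0.04 + 0.36 + 0.36 + 0.04) / 2),
               tolerance = 1e-12)
})

test_that("fit_ols recovers collinear relations exactly", {
  pib <- c(1.0, 1.3, 1.7, 2.1)
  d <- data.frame(pib = pib, fbb = 0.61 * pib + 0.39)
  fit <- fit_ols(d, pib, fbb, from = "SUVR_PiB", to = "SUVR_FBB")
  expect_equal(fit$map$m, 0.61, tolerance = 1e-12)
  expect_equal(fit$map$b, 0.39, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  ident <- fit_ols(data.frame(x = 1:5, y = 1:5), x, y)
  expect_equal(ident$map$m, 1, tolerance = 1e-12)
  expect_equal(ident$map$b, 0, tolerance = 1e-12)

  # Deming agrees with OLS on noise-free collinear data
  dem <- fit_ols(d, pib, fbb, method = "deming")
  expect_equal(dem$map$m, 0.61, tolerance = 1e-12)
  expect_equal(dem$map$b, 0.39, tolerance = 1e-12)
})

test_that("fit_ols rejects degenerate inputs", {
  expect_error(fit_ols(data.frame(x = 1:2, y = 1:2), x, y),
               "insufficient pairs")
  expect_error(fit_ols(data.frame(x = c(1, 1, 1), y = 1:3), x, y),
               "zero variance")
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- data.frame(x = 0:3, y = c(0, 1, 0, 1))
  fit <- fit_ols(d, x, y)
  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(0.2, 0.2), tolerance = 1e-12)
  gl <- glance(fit)
  expect_identical(names(gl),
                   c("slope", "intercept", "r_squared", "residual_sd",
                     "n", "method"))
})

test_that("level-1 validation applies the published criteria", {
  ref <- c(-10, 0, 20, 50, 100)
  near <- validate_level1(data.frame(r = ref, c = ref - 0.07), c, r)
  expect_equal(near$fit$map$m, 1, tolerance = 1e-12)
  expect_equal(near$fit$map$b, -0.07, tolerance = 1e-10)
  expect_true(near$pass_overall)

  ident <- validate_level1(data.frame(r = ref, c = ref), c, r)
  expect_true(ident$pass_overall)

  shrunk <- validate_level1(data.frame(r = ref, c = 0.95 * ref), c, r)
  expect_false(shrunk$pass_slope)
  expect_false(shrunk$pass_overall)
  expect_true(shrunk$pass_r2) # still perfectly correlated

  off <- validate_level1(data.frame(r = ref, c = ref - 3), c, r)
  expect_false(off$pass_intercept)
  expect_false(off$pass_overall)
})

test_that("level-1 slope bound is sharp at 0.98", {
  ref <- c(-10, 0, 20, 50, 100)
  at_bound <- validate_level1(data.frame(r = ref, c = 0.98 * ref), c, r)
  expect_true(at_bound$pass_slope)
  below <- validate_level1(data.frame(r = ref, c = 0.9799 * ref), c, r)
  expect_false(below$pass_slope)
  # intercept bounds are inclusive too
  at_int <- validate_level1(data.frame(r = ref, c = ref + 2), c, r)
  expect_true(at_int$pass_intercept)
})

test_that("level-2 calibration composes the direct CL map at full precision", {
  pib <- seq(1.0, 2.2, length.out = 10)
  d <- data.frame(subject_id = paste0("S", 1:10),
                  suvr_pib = pib, suvr_tracer = 0.61 * pib + 0.39)
  rep2 <- calibrate_level2(d)
  expect_true(rep2$pass_gate)
  expect_equal(rep2$fit$map$m, 0.61, tolerance = 1e-12)
  expect_equal(rep2$to_pib$m, 1 / 0.61, tolerance = 1e-12)
  expect_equal(rep2$direct_cl$m, 93.7 / 0.61, tolerance = 1e-9)
  expect_equal(rep2$direct_cl$b, -93.7 * 0.39 / 0.61 - 94.6,
               tolerance = 1e-9)
  # the printed coefficients are a rounded view of this map
  expect_equal(round(rep2$direct_cl$m, 1), 153.6)
  expect_equal(round(rep2$direct_cl$b, 1), -154.5)
})

test_that("an identity inter-tracer relation leaves the standard map unchanged", {
  pib <- seq(1.0, 2.2, length.out = 8)
  d <- data.frame(suvr_pib = pib, suvr_tracer = pib)
  rep2 <- calibrate_level2(d, tracer = "PiB2")
  expect_equal(rep2$direct_cl$m, 93.7, tolerance = 1e-9)
  expect_equal(rep2$direct_cl$b, -94.6, tolerance = 1e-9)
})

test_that("the R^2 > 0.70 gate fails on uncorrelated pairs but still reports", {
  set.seed(9)
  d <- data.frame(suvr_pib = stats::rnorm(30, 1.5, 0.3),
                  suvr_tracer = stats::rnorm(30, 1.3, 0.3))
  rep2 <- calibrate_level2(d)
  expect_false(rep2$pass_gate)
  expect_s3_class(rep2$direct_cl, "linear_map") # report still emitted
  expect_lt(rep2$fit$r_squared, 0.70)
})

test_that("the direct CL map sends the fitted young-normal anchor to zero", {
  coh <- simulate_paired_cohort(seed = 31)
  rep2 <- calibrate_level2(coh)
  anchor_fbb <- apply_map(rep2$fit$map, 94.6 / 93.7)
  expect_equal(apply_map(rep2$direct_cl, anchor_fbb), 0, tolerance = 1e-9)
})
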