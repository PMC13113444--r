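test_that("sternum-head regression evaluates the height branch correctly", {
  p <- anthro_profile(1642.63, 65.07)
  # direct evaluation oracle: 0.3674 * 1642.63 - 297.0699
  expect_equal(estimate_sternum_head(p), 0.3674 * 1642.63 - 297.0699,
               tolerance = 1e-12)
  expect_equal(estimate_sternum_head(p), 306.4323, tolerance = 1e-4)
  # root of the line: y crosses zero at intercept/slope
  root <- 297.0699 / 0.3674
  expect_equal(estimate_sternum_head(anthro_profile(root, 65)), 0,
               tolerance = 1e-9)
  # positive slope: taller subject, longer sternum-head distance
  expect_gt(estimate_sternum_head(anthro_profile(1700, 65)),
            estimate_sternum_head(anthro_profile(1600, 65)))
  # profile derives the distance on construction
  expect_equal(p$sternum_head_mm, estimate_sternum_head(p))
})

test_that("sternum-head branches validate their inputs", {
  p <- anthro_profile(1700, 70)
  expect_error(estimate_sternum_head(p, branch = "sitting"), "sitting_height")
  expect_error(anthro_profile(-1, 70), "height_mm")
  expect_error(anthro_profile(1700, 0), "mass_kg")
  p2 <- anthro_profile(1700, 70, sitting_height_mm = 900)
  expect_equal(estimate_sternum_head(p2, "sitting"),
               0.7111 * 900 - 310.3478)
  expect_equal(estimate_sternum_head(p2, "weight"),
               2.1135 * 70 - 188.2610)
})

test_that("sternum-head regression is affine in its input", {
  y <- function(x) estimate_sternum_head(anthro_profile(x, 65))
  y0 <- sternum_head_fit("height")$coefficients[["intercept"]]
  for (a in c(0.5, 1.3, 2.7))
    expect_equal(y(a * 1600) - y0, a * (y(1600) - y0), tolerance = 1e-9)
})

test_that("ordinary least squares on noiseless points recovers the height line", {
  xs <- seq(1500, 1830, length.out = 12)
  ys <- vapply(xs, function(x)
    estimate_sternum_head(anthro_profile(x, 65)), numeric(1))
  fit <- stats::lm(ys ~ xs)   # independent refit
  expect_equal(unname(coef(fit)[2]), 0.3674, tolerance = 1e-7)
  expect_equal(unname(coef(fit)[1]), -297.0699, tolerance = 1e-7)
})

test_that("branch diagnostics expose the regression quality", {
  fits <- lapply(c("height", "weight", "sitting"), sternum_head_fit)
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  expect_equal(r2, c(0.97, 0.52, 0.94))
  expect_true(all(r2 >= 0 & r2 <= 1))
  # the default branch is the best-fitting one
  expect_identical(which.max(r2), 1L)
})

test_that("scale factors are subject/generic ratios with validation", {
  expect_equal(unclass(compute_scale_factors(c(femur = 450), c(femur = 400))),
               c(femur = 1.125))
  same <- c(femur = 400, tibia = 380)
  expect_equal(as.numeric(compute_scale_factors(same, same)), c(1, 1))
  # linearity: inflating every subject length scales every factor
  f1 <- compute_scale_factors(c(femur = 430, tibia = 390), same)
  f2 <- compute_scale_factors(2 * c(femur = 430, tibia = 390), same)
  expect_equal(as.numeric(f2), 2 * as.numeric(f1))
  expect_error(compute_scale_factors(c(femur = 450), c(tibia = 380)),
               "femur")
  expect_error(compute_scale_factors(c(femur = -1), c(femur = 400)),
               "femur")
})

test_that("optimal fiber length scales by the segment factor", {
  expect_equal(scale_optimal_fiber_length(0.10, 1.0), 0.10)
  expect_equal(scale_optimal_fiber_length(0.10, 1.2), 0.12)
  f <- compute_scale_factors(c(femur = 450), c(femur = 400))[["femur"]]
  expect_equal(scale_optimal_fiber_length(0.08, f), 0.09)
  expect_error(scale_optimal_fiber_length(0, 1), "positive")
  expect_error(scale_optimal_fiber_length(0.1, -2), "positive")
})

test_that("segment masses come from the packaged proportional table", {
  tab <- segment_mass_fractions()
  expect_true(all(c("segment", "fraction") %in% names(tab)))
  expect_true(all(tab$fraction > 0 & tab$fraction < 1))
  # single-side fractions sum to less than the whole body
  expect_lte(sum(tab$fraction), 1)
  thigh <- tab$fraction[tab$segment == "thigh"]
  expect_equal(segment_mass(65.07, "thigh"), 65.07 * thigh)
  expect_error(segment_mass(65.07, "antenna"), "antenna")
  expect_error(segment_mass(-3, "thigh"), "positive")
  # the full bilateral decomposition accounts for the whole body mass
  bilateral <- c("thigh", "shank", "foot", "upper_arm", "forearm", "hand")
  total <- sum(ifelse(tab$segment %in% bilateral, 2, 1) * tab$fraction)
  expect_equal(total, 1, tolerance = 0.01)
})
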