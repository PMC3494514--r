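test_that("internal-standard normalization is a guarded ratio", {
  expect_equal(normalize_is(1000, 500), 2.0)
  expect_equal(normalize_is(0, 500), 0.0)
  expect_error(normalize_is(1000, 0), "positive")
  expect_error(normalize_is(1000, 0, run_id = "s3"), "s3")
})

test_that("each family enforces its minimum number of standards", {
  mins <- c(linear = 2L, logarithmic = 2L, power = 2L, exponential = 2L,
            quadratic = 3L, cubic = 4L)
  for (fam in names(mins)) {
    std <- family_standards(fam)
    too_few <- std[seq_len(mins[[fam]] - 1L), ]
    expect_error(suppressWarnings(fit_calibration(fam, too_few)),
                 "at least", label = fam)
    just_enough <- std[seq_len(mins[[fam]]), ]
    cv <- suppressWarnings(fit_calibration(fam, just_enough))
    expect_s3_class(cv, "calibration_curve")
    expect_identical(cv$n_standards, mins[[fam]])
  }
})

test_that("an exact line is fitted with zero intercept and unit R-squared", {
  cv <- suppressWarnings(
    fit_calibration("linear", data.frame(concentration = 1:3,
                                         area = c(10, 20, 30))))
  expect_equal(cv$a0, 0, tolerance = 1e-9)
  expect_equal(cv$a1, 10, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
})

test_that("a power law is recovered from its own curve", {
  std <- data.frame(concentration = c(1, 2, 4, 8),
                    area = 2 * c(1, 2, 4, 8)^1.5)
  cv <- suppressWarnings(fit_calibration("power", std))
  expect_equal(cv$a0, 2, tolerance = 1e-6)
  expect_equal(cv$a1, 1.5, tolerance = 1e-6)
  expect_equal(cv$r_squared, 1, tolerance = 1e-9)
})

test_that("all six families recover their generating coefficients exactly", {
  for (fam in lcquant:::CURVE_FAMILIES) {
    co <- family_truth_coef(fam)
    cv <- suppressWarnings(fit_calibration(fam, family_standards(fam)))
    got <- c(cv$a0, cv$a1, cv$a2, cv$a3)[seq_along(co)]
    expect_equal(got, co, tolerance = 1e-6, label = fam)
    expect_gt(cv$r_squared, 1 - 1e-9)
  }
})

test_that("calibrations survive 2% multiplicative noise within 10%", {
  # median recovery error over replicate fits at n = 6; weighting matched
  # to the multiplicative noise; polynomial families judged on the curve
  for (fam in lcquant:::CURVE_FAMILIES)
    expect_lt(noisy_recovery_error(fam), 0.10, label = fam)
})

test_that("inverting the fitted curve undoes prediction for every family", {
  for (fam in lcquant:::CURVE_FAMILIES) {
    cv <- suppressWarnings(fit_calibration(fam, family_standards(fam)))
    grid <- seq(cv$c_min, cv$c_max, length.out = 20)
    back <- vapply(grid, function(C)
      invert_concentration(cv, predict(cv, C))$concentration, numeric(1))
    expect_equal(back, grid, tolerance = 1e-6, label = fam)
  }
})

test_that("zero-concentration standards are dropped from log-family fits", {
  std <- rbind(data.frame(concentration = 0, area = 3),
               family_standards("power"))
  expect_warning(cv <- fit_calibration("power", std), "zero-concentration")
  expect_identical(cv$n_standards, 6L)
})

test_that("the best-fit suggestion ranks by R-squared with parsimony ties", {
  lin_std <- family_standards("linear")
  fits <- suppressWarnings(fit_all_families(lin_std))$fits
  # a line nests inside the polynomials: equal R-squared, linear must win
  expect_identical(suggest_best_fit(fits), "linear")

  exp_std <- data.frame(concentration = c(5, 10, 25, 50, 100, 140),
                        area = 3 * 1.04^c(5, 10, 25, 50, 100, 140))
  efits <- suppressWarnings(fit_all_families(exp_std))$fits
  expect_identical(suggest_best_fit(efits), "exponential")
  r2 <- vapply(efits, `[[`, numeric(1), "r_squared")
  expect_true(all(r2[["exponential"]] >= r2[names(r2) != "exponential"]))

  single <- fits["cubic"]
  expect_identical(suggest_best_fit(single), "cubic")
  expect_error(suggest_best_fit(list()), "no successfully fitted")
})

test_that("quadratic inversion selects the in-range root", {
  cv <- structure(list(family = "quadratic", a0 = 0, a1 = 0, a2 = 1,
                       a3 = NA_real_, r_squared = 1, c_min = 1, c_max = 10,
                       n_standards = 6L, is_normalized = FALSE),
                  class = "calibration_curve")
  out <- invert_concentration(cv, 25)
  expect_equal(out$concentration, 5)   # the root -5 is out of range
  expect_false(out$extrapolated)
  out2 <- invert_concentration(cv, 400)
  expect_equal(out2$concentration, 20) # nearest-to-range real root
  expect_true(out2$extrapolated)
})

test_that("degenerate curves refuse inversion", {
  flat <- structure(list(family = "linear", a0 = 5, a1 = 0, a2 = NA_real_,
                         a3 = NA_real_, r_squared = 0, c_min = 1,
                         c_max = 10, n_standards = 2L,
                         is_normalized = FALSE),
                    class = "calibration_curve")
  expect_error(invert_concentration(flat, 7), "flat")
  pw <- structure(list(family = "power", a0 = 2, a1 = 1.5, a2 = NA_real_,
                       a3 = NA_real_, r_squared = 1, c_min = 1, c_max = 10,
                       n_standards = 4L, is_normalized = FALSE),
                  class = "calibration_curve")
  expect_error(invert_concentration(pw, -3), "invertible")
})

test_that("R-squared drops below one as soon as points leave the curve", {
  std <- family_standards("linear")
  std$area[3] <- std$area[3] * 1.2
  cv <- suppressWarnings(fit_calibration("linear", std))
  expect_lt(cv$r_squared, 1 - 1e-6)
})

test_that("fitting IS-normalized areas rescales the line consistently", {
  std <- family_standards("linear")
  is_area <- 5000
  raw <- suppressWarnings(fit_calibration("linear", std))
  norm_std <- data.frame(concentration = std$concentration,
                         area = normalize_is(std$area, is_area))
  norm <- suppressWarnings(fit_calibration("linear", norm_std,
                                           is_normalized = TRUE))
  expect_true(norm$is_normalized)
  expect_equal(norm$a0, raw$a0 / is_area, tolerance = 1e-9)
  expect_equal(norm$a1, raw$a1 / is_area, tolerance = 1e-9)
  expect_equal(norm$r_squared, raw$r_squared, tolerance = 1e-12)
})
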