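ref_df <- function(rt, mz = seq(100, by = 10, length.out = length(rt))) {
  data.frame(target_mz = mz, rt = rt)
}

peaks_df <- function(rt, mz, height = 1000) {
  data.frame(apex_rt = rt, rt_start = rt - 0.2, rt_end = rt + 0.2,
             height = height, area = height * 0.1, target_mz = mz,
             run_id = "s", manual = FALSE)
}

test_that("identical retention times give an identity-equivalent warp", {
  rt <- seq(2, 18, length.out = 10)
  ref <- ref_df(rt)
  w <- fit_rt_warp(ref, peaks_df(rt, ref$target_mz), seed = 1)
  expect_lt(w$rmse, 1e-9)
  expect_equal(warp_rt(w, rt), rt, tolerance = 1e-6)
  expect_identical(nrow(w$inlier_pairs), 10L)
})

test_that("a uniform shift is recovered as slope one, intercept the shift", {
  rt <- seq(2, 18, length.out = 10)
  ref <- ref_df(rt)
  w <- fit_rt_warp(ref, peaks_df(rt + 0.5, ref$target_mz), seed = 1)
  # least-squares oracle on clean pairs: exact affine recovery
  expect_equal(unname(w$coefficients[1]), 0.5, tolerance = 1e-6)
  expect_equal(unname(w$coefficients[2]), 1.0, tolerance = 1e-6)
  if (length(w$coefficients) == 3L)
    expect_equal(unname(w$coefficients[3]), 0, tolerance = 1e-8)
})

test_that("RANSAC recovers a quadratic drift and rejects gross outliers", {
  rt <- seq(1, 19, length.out = 20)
  ref <- ref_df(rt)
  warped <- rt + 0.002 * rt^2
  warped[c(3, 8, 13, 18)] <- warped[c(3, 8, 13, 18)] + 0.6  # 20% gross
  w <- fit_rt_warp(ref, peaks_df(warped, ref$target_mz), seed = 11)
  expect_identical(w$model, "quadratic")
  expect_identical(nrow(w$inlier_pairs), 16L)
  expect_false(any(w$inlier_pairs$rt_sample %in% warped[c(3, 8, 13, 18)]))
  expect_lt(abs(w$coefficients[3] - 0.002) / 0.002, 0.10)
})

test_that("RANSAC reduces to least squares when every pair is clean", {
  rt <- seq(1, 19, length.out = 15)
  samp <- 0.1 + 1.01 * rt + 0.0015 * rt^2
  w <- fit_rt_warp(ref_df(rt), peaks_df(samp, ref_df(rt)$target_mz),
                   seed = 5)
  ls <- lm(samp ~ rt + I(rt^2))
  expect_equal(unname(w$coefficients), unname(coef(ls)), tolerance = 1e-6)
  expect_identical(nrow(w$inlier_pairs), 15L)
})

test_that("too few pairs degrade the model family with a warning", {
  ref <- ref_df(c(5, 10))
  expect_warning(w <- fit_rt_warp(ref, peaks_df(c(5.1, 10.1),
                                                ref$target_mz), seed = 1),
                 "linear")
  expect_identical(w$model, "linear")
  expect_warning(w0 <- fit_rt_warp(ref_df(5), peaks_df(20, 999), seed = 1),
                 "identity")
  expect_identical(w0$model, "identity")
  expect_equal(warp_rt(w0, 7), 7)
})

test_that("peak suggestion picks the nearest apex and flags taller rivals", {
  id <- lcquant:::new_rt_warp("identity", numeric(0), NULL, 0, 0L)
  pk <- peaks_df(c(4.0, 4.1), c(100, 100), height = c(200, 900))
  s <- suggest_peak(4.0, id, pk, rt_window = 0.2)
  expect_equal(s$peak$apex_rt, 4.0)
  expect_true(s$flag_not_highest)       # the taller peak 0.1 min away
  expect_false(s$flag_out_of_window)

  lone <- suggest_peak(4.0, id, peaks_df(4.0, 100), rt_window = 0.2)
  expect_false(lone$flag_not_highest)
  expect_equal(lone$peak$apex_rt, 4.0)

  none <- suggest_peak(10, id, pk, rt_window = 0.2)
  expect_null(none$peak)
  expect_true(none$flag_out_of_window)
})

test_that("peak suggestion is invariant to peak-list order", {
  id <- lcquant:::new_rt_warp("identity", numeric(0), NULL, 0, 0L)
  pk <- peaks_df(c(3.9, 4.05, 4.2, 4.5), rep(100, 4),
                 height = c(100, 400, 900, 50))
  s1 <- suggest_peak(4.0, id, pk, rt_window = 0.3)
  s2 <- suggest_peak(4.0, id, pk[sample(4), ], rt_window = 0.3)
  expect_equal(s1$peak$apex_rt, s2$peak$apex_rt)
  expect_identical(s1$flag_not_highest, s2$flag_not_highest)
})

test_that("manual integration reproduces automatic areas and handles zeros", {
  rt <- seq(0, 10, by = 0.02)
  ch <- chrom_from(rt, gaussian_trace(rt, 5, 0.1, 100))
  pk <- deconvolve(ch, processing_config("fast", min_peak_height = 1))
  auto <- pk[which.max(pk$height), ]
  sug <- suggest_peak(5, lcquant:::new_rt_warp("identity", numeric(0),
                                               NULL, 0, 0L), pk, 0.5)
  manual <- override_selection(sug, c(auto$rt_start, auto$rt_end), ch)
  expect_true(manual$manual)
  expect_equal(manual$area, auto$area, tolerance = 1e-9)

  flatzone <- override_selection(sug, c(0.5, 1.5), ch)
  expect_equal(flatzone$area, 0, tolerance = 1e-6)
  expect_equal(flatzone$height, 0, tolerance = 1e-6)

  expect_error(override_selection(sug, c(2, 1), ch), "smaller")
})

test_that("manually splitting a merged doublet recovers both areas", {
  rt <- seq(0, 10, by = 0.02)
  a1 <- 120; a2 <- 90
  y <- gaussian_trace(rt, 4.8, 0.12, a1) + gaussian_trace(rt, 5.2, 0.12, a2)
  ch <- chrom_from(rt, y)
  sug <- suggest_peak(5, lcquant:::new_rt_warp("identity", numeric(0),
                                               NULL, 0, 0L),
                      lcquant:::empty_peaks(), 0.5)
  left <- override_selection(sug, c(4.0, 5.0), ch)
  right <- override_selection(sug, c(5.0, 6.0), ch)
  expect_lt(abs(left$area - a1) / a1, 0.10)
  expect_lt(abs(right$area - a2) / a2, 0.10)
})

test_that("saved selections round-trip through CSV", {
  sel <- data.frame(metabolite = c("a", "b"), run_id = "s1",
                    rt_start = c(1.1, 2.2), rt_end = c(1.5, 2.8),
                    manual = c(TRUE, FALSE))
  f <- file.path(tempdir(), "sel.csv")
  write_selections(sel, f)
  back <- read_selections(f)
  expect_equal(back, sel)
  writeLines("metabolite,run_id", f)
  expect_error(read_selections(f), "lacks")
})
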