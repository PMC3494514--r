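test_that("Savitzky-Golay reproduces polynomials up to its order", {
  expect_equal(smooth_sg(rep(5, 21), 5, 2), rep(5, 21))
  x <- 0:20
  y <- x^2
  sm <- smooth_sg(y, 7, 2)
  interior <- 4:18
  expect_equal(sm[interior], y[interior], tolerance = 1e-9)
  expect_error(smooth_sg(y, 6, 2), "odd")
  expect_error(smooth_sg(y, 7, 7), "order")
  expect_error(smooth_sg(y[1:5], 7, 2), "window")
})

test_that("Savitzky-Golay weights agree with the signal package's design", {
  co <- lcquant:::sg_coefficients(9, 3)
  ref <- signal::sgolay(p = 3, n = 9)[5, ]  # central row of the projector
  expect_equal(unname(co), unname(as.numeric(ref)), tolerance = 1e-10)
})

test_that("smoothing noisy data reduces the RMSE against the clean signal", {
  set.seed(42)
  x <- seq(0, 4 * pi, length.out = 200)
  clean <- sin(x)
  noisy <- clean + rnorm(200, 0, 0.3)
  sm <- smooth_sg(noisy, 11, 3)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(sm, clean), rmse(noisy, clean))
})

test_that("centroiding finds weighted-mean sticks above the noise level", {
  # triangular bump peaking at m/z 100.00, summit 1000
  mz <- seq(99.96, 100.04, by = 0.01)
  inten <- 1000 - 25000 * abs(mz - 100)
  sp <- new_spectrum(1, mz, pmax(inten, 0), mode = "profile")
  cs <- centroid(sp, 50)
  expect_length(cs$mz, 1L)
  # oracle: intensity-weighted mean over the above-noise region
  above <- inten > 50
  expect_equal(cs$mz, sum(mz[above] * inten[above]) / sum(inten[above]),
               tolerance = 1e-9)
  expect_equal(cs$intensity, 1000)
  expect_identical(cs$mode, "centroid")

  # everything below the noise level: empty output
  low <- new_spectrum(1, mz, rep(10, length(mz)), mode = "profile")
  expect_length(centroid(low, 50)$mz, 0L)
})

test_that("bumps separated by a quiet valley become distinct centroids", {
  mz <- seq(100, 101, by = 0.005)
  inten <- 800 * exp(-(mz - 100.2)^2 / (2 * 0.01^2)) +
    600 * exp(-(mz - 100.8)^2 / (2 * 0.01^2))
  sp <- new_spectrum(1, mz, inten, mode = "profile")
  cs <- centroid(sp, 50)
  # brute-force oracle: count strict local maxima above the threshold
  y <- inten
  n_max <- sum(vapply(2:(length(y) - 1), function(i)
    y[i] > y[i - 1] && y[i] >= y[i + 1] && y[i] > 50, logical(1)))
  expect_identical(length(cs$mz), n_max)
  expect_identical(length(cs$mz), 2L)
  expect_equal(cs$mz, c(100.2, 100.8), tolerance = 1e-3)
})

test_that("EICs trace only their own target on a uniform RT grid", {
  mets <- data.frame(name = c("a", "b"),
                     quant_mz = c(181.071, 147.076),
                     true_rt = c(2, 4), peak_sigma = 0.05,
                     response_factor = 25, curve_family = "linear",
                     is_internal_standard = FALSE)
  spec <- sim_spec(mets, rt_span = 6, sample_truth = NULL)
  sim <- simulate_run(spec, list(a = 100, b = 50), run_id = "r1", seed = 3)
  cfg <- processing_config(mz_tolerance = 0.05)
  eics <- build_eics(sim$run, mets$quant_mz, cfg)
  expect_length(eics, 2L)
  n_scans <- length(sim$run$spectra)
  for (e in eics) expect_length(e$intensity, n_scans)
  # apex of each trace sits at the simulated RT
  expect_equal(eics[[1]]$rt[which.max(eics[[1]]$intensity)], 2,
               tolerance = 0.03)
  expect_equal(eics[[2]]$rt[which.max(eics[[2]]$intensity)], 4,
               tolerance = 0.03)
  # cross-talk check: each trace is blind to the other's peak
  expect_equal(sum(eics[[1]]$intensity[abs(eics[[1]]$rt - 4) < 0.3]), 0)
  expect_equal(sum(eics[[2]]$intensity[abs(eics[[2]]$rt - 2) < 0.3]), 0)
  # a target with no signal anywhere: all-zero EIC of full length
  none <- build_eics(sim$run, 500.0, cfg)[[1]]
  expect_length(none$intensity, n_scans)
  expect_true(all(none$intensity == 0))
})

test_that("deconvolution recovers single and double Gaussian peaks", {
  rt <- seq(0, 10, by = 0.02)
  cfg <- processing_config("fast", min_peak_height = 10)
  one <- chrom_from(rt, gaussian_trace(rt, 5, 0.06, 120))
  pk <- deconvolve(one, cfg)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$apex_rt - 5), 0.02 + 1e-9)   # within one scan

  two <- chrom_from(rt, gaussian_trace(rt, 4, 0.05, 100) +
                      gaussian_trace(rt, 5, 0.05, 80))
  pk2 <- deconvolve(two, cfg)
  expect_identical(nrow(pk2), 2L)
  # border sits at the brute-force global minimum between the apexes
  between <- rt > 4 & rt < 5
  valley_rt <- rt[between][which.min(two$intensity[between])]
  expect_equal(pk2$rt_end[1], valley_rt)
  expect_equal(pk2$rt_start[2], valley_rt)

  flat <- chrom_from(rt, rep(0, length(rt)))
  expect_identical(nrow(deconvolve(flat, cfg)), 0L)
})

test_that("deconvolution borders equal a brute-force local-minimum scan", {
  rt <- seq(0, 8, length.out = 161)  # a small EIC, brute-force friendly
  y <- gaussian_trace(rt, 2, 0.5, 60) + gaussian_trace(rt, 4, 0.6, 90) +
    gaussian_trace(rt, 6.2, 0.45, 45)
  cfg <- processing_config("fast", min_peak_height = 1e-9,
                           min_valley_ratio = 1)
  pk <- deconvolve(chrom_from(rt, y), cfg)
  brute <- which(vapply(2:(length(y) - 1), function(i)
    y[i] <= y[i - 1] && y[i] <= y[i + 1], logical(1))) + 1L
  expect_equal(sort(unique(c(pk$rt_start, pk$rt_end))),
               sort(unique(rt[c(1L, brute, length(y))])))
})

test_that("deconvolution is symmetric under trace reversal", {
  rt <- seq(0, 10, by = 0.05)
  y <- gaussian_trace(rt, 3, 0.1, 50) + gaussian_trace(rt, 6.5, 0.2, 120) +
    gaussian_trace(rt, 8, 0.08, 30)
  cfg <- processing_config("fast", min_peak_height = 1)
  fwd <- deconvolve(chrom_from(rt, y), cfg)
  rev_pk <- deconvolve(chrom_from(rt, rev(y)), cfg)
  expect_identical(nrow(fwd), nrow(rev_pk))
  expect_equal(sort(10 - rev_pk$apex_rt), sort(fwd$apex_rt),
               tolerance = 1e-9)
})

test_that("peak areas never exceed the total trace area", {
  set.seed(7)
  rt <- seq(0, 10, by = 0.02)
  y <- gaussian_trace(rt, 3, 0.1, 100) + gaussian_trace(rt, 6, 0.15, 200) +
    pmax(rnorm(length(rt), 2, 1), 0)
  ch <- chrom_from(rt, y)
  pk <- deconvolve(ch, processing_config())
  expect_lte(sum(pk$area), pracma::trapz(rt, y) + 1e-9)
})

test_that("recovered area stays within 10% of truth at moderate SNR", {
  rt <- seq(0, 4, by = 0.02)
  true_area <- 150
  height <- true_area / (0.06 * sqrt(2 * pi))
  for (snr in c(10, 50)) {
    set.seed(100 + snr)
    y <- pmax(gaussian_trace(rt, 2, 0.06, true_area) +
                rnorm(length(rt), 0, height / snr), 0)
    cfg <- processing_config(noise_level = height / snr,
                             min_peak_height = 3 * height / snr)
    pk <- deconvolve(chrom_from(rt, y), cfg)
    main <- pk[which.max(pk$height), ]
    expect_lt(abs(main$area - true_area) / true_area, 0.10)
  }
})

test_that("trapezoidal integration matches geometry and is additive", {
  rt <- seq(0, 3, by = 0.001)
  rect <- chrom_from(rt, as.numeric(rt >= 1 & rt <= 2))
  expect_equal(integrate_area(rect, 0.5, 2.5), 1.0, tolerance = 5e-3)

  tri_y <- pmax(100 * (1 - abs(rt - 1.5) / 0.25), 0)
  tri <- chrom_from(rt, tri_y)
  expect_equal(integrate_area(tri, 1, 2), 25, tolerance = 0.1)

  a <- integrate_area(tri, 1.1, 1.43)
  b <- integrate_area(tri, 1.43, 1.9)
  expect_equal(a + b, integrate_area(tri, 1.1, 1.9), tolerance = 1e-9)

  expect_error(integrate_area(tri, 2, 1), "smaller")
  expect_error(integrate_area(tri, -1, 2), "span")
})

test_that("presets are pure functions of their name with ordered sensitivity", {
  f <- processing_config("fast")
  d <- processing_config("default")
  t <- processing_config("thorough")
  expect_identical(f, processing_config("fast"))
  expect_true(f$noise_level > d$noise_level &&
                d$noise_level > t$noise_level)
  expect_true(f$min_valley_ratio < d$min_valley_ratio &&
                d$min_valley_ratio < t$min_valley_ratio)
  expect_error(processing_config("default", bogus = 1), "unknown")
})
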