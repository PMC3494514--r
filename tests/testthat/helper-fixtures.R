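# Shared fixture builders: everything is generated in code at test time.

# a three-scan run with two sticks per spectrum, RTs 0.1/0.2/0.3 min
tiny_run <- function() {
  new_run(list(new_spectrum(0.1, c(100, 200), c(1, 2)),
               new_spectrum(0.2, c(100, 200), c(2, 4)),
               new_spectrum(0.3, c(100, 200), c(3, 6))),
          run_id = "tiny")
}

# a chromatogram object on a uniform grid
chrom_from <- function(rt, intensity, target_mz = 100, tol = 0.1,
                       run_id = "fix") {
  structure(list(target_mz = target_mz, mz_tolerance = tol, rt = rt,
                 intensity = intensity, run_id = run_id),
            class = "chromatogram")
}

# Gaussian trace with the given total area
gaussian_trace <- function(rt, apex, sigma, area) {
  area / (sigma * sqrt(2 * pi)) * exp(-(rt - apex)^2 / (2 * sigma^2))
}

# standards generated exactly on a family's curve
family_standards <- function(family, conc = c(5, 10, 25, 50, 100, 200)) {
  co <- family_truth_coef(family)
  A <- switch(family,
              linear = co[1] + co[2] * conc,
              logarithmic = co[1] + co[2] * log(conc),
              power = co[1] * conc^co[2],
              exponential = co[1] * co[2]^conc,
              quadratic = co[1] + co[2] * conc + co[3] * conc^2,
              cubic = co[1] + co[2] * conc + co[3] * conc^2 +
                co[4] * conc^3)
  data.frame(concentration = conc, area = A)
}

# generating coefficients per family (invertible, positive over 5..200)
family_truth_coef <- function(family) {
  switch(family,
         linear = c(2000, 30),
         logarithmic = c(5000, 1000),
         power = c(2, 1.5),
         exponential = c(500, 1.015),
         quadratic = c(2000, 25, 0.06),
         cubic = c(2000, 20, 0.05, 2e-4))
}

# weighting matched to multiplicative noise where the family needs it
family_weighting <- function(family) {
  switch(family, power = "1/C2", quadratic = "1/C2", cubic = "1/C2",
         "none")
}

# median max-relative recovery error across seeded replicate fits at n = 6
# with multiplicative noise; the polynomial families are judged on the
# fitted curve because their raw coefficients are collinear at this n
noisy_recovery_error <- function(family, n_rep = 11L, noise_cv = 0.02,
                                 base_seed = 2024L) {
  co <- family_truth_coef(family)
  clean <- family_standards(family)
  grid <- seq(min(clean$concentration), max(clean$concentration),
              length.out = 20)
  errs <- vapply(seq_len(n_rep), function(r) {
    set.seed(base_seed + r)
    std <- clean
    std$area <- std$area * (1 + rnorm(nrow(std), 0, noise_cv))
    cv <- suppressWarnings(
      fit_calibration(family, std, weighting = family_weighting(family)))
    if (family %in% c("quadratic", "cubic")) {
      truth <- family_standards(family, grid)$area
      max(abs(predict(cv, grid) - truth) / truth)
    } else {
      got <- c(cv$a0, cv$a1, cv$a2, cv$a3)[seq_along(co)]
      max(abs(got - co) / abs(co))
    }
  }, numeric(1))
  median(errs)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
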