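#' Simulation specification
#'
#' Describes a synthetic LC-MS project: the chromatographic grid, the
#' metabolite panel (quantifier m/z, true RT, peak width, response), the
#' per-run retention-time drift, the noise model and the concentration
#' design. All downstream modules are validated against the ground truth
#' this specification implies.
#'
#' @param metabolites Data frame with columns `name`, `quant_mz`,
#'   `true_rt` (minutes), `peak_sigma` (minutes), `response_factor`
#'   (area units per micromol/L), `curve_family` (truth response family),
#'   `is_internal_standard`.
#' @param rt_span Run length in minutes.
#' @param scan_interval Scan spacing in minutes; `peak_sigma` must exceed
#'   twice this so peaks are resolvable.
#' @param drift Function `(run_index) -> c(b0, b1, b2)` giving the
#'   quadratic warp `rt' = b0 + b1*rt + b2*rt^2` of each run, or a fixed
#'   coefficient vector; must be monotone over the span.
#' @param noise List with `baseline` (constant offset), `sd` (white-noise
#'   standard deviation) and `spurious_rate` (expected spurious peaks per
#'   minute per run).
#' @param standard_concentrations Numeric vector of standard levels
#'   (micromol/L), one standard run per level.
#' @param sample_truth Matrix (samples x metabolites) of true sample
#'   concentrations; column names must match metabolite names.
#' @param is_concentration Internal-standard amount added to every run.
#' @param injection_cv Run-to-run multiplicative injection/ionisation
#'   variability (log-normal coefficient of variation; 0 disables it).
#' @param seed Base seed; each run derives its own stream from it.
#' @return A list of class `"sim_spec"`.
#' @export
sim_spec <- function(metabolites, rt_span = 20, scan_interval = 0.02,
                     drift = c(0, 1, 0),
                     noise = list(baseline = 0, sd = 0, spurious_rate = 0),
                     standard_concentrations = c(5, 10, 25, 50, 100, 200),
                     sample_truth = NULL, is_concentration = 100,
                     injection_cv = 0, seed = 1L) {
  stopifnot(scan_interval > 0,
            all(metabolites$peak_sigma > 2 * scan_interval))
  drift_fun <- if (is.function(drift)) drift else function(i) drift
  spec <- list(metabolites = metabolites, rt_span = rt_span,
               scan_interval = scan_interval, drift = drift_fun,
               noise = noise,
               standard_concentrations = standard_concentrations,
               sample_truth = sample_truth,
               is_concentration = is_concentration,
               injection_cv = injection_cv, seed = as.integer(seed))
  class(spec) <- "sim_spec"
  spec
}

# true area response of one metabolite at concentration C
truth_area <- function(met, C) {
  rf <- met$response_factor
  switch(met$curve_family,
         linear = rf * C,
         logarithmic = rf * 40 * log(C) + rf,
         power = rf * C^1.3,
         exponential = rf * 30 * 1.02^C,
         quadratic = rf * C + rf / 400 * C^2,
         cubic = rf * C + rf / 500 * C^2 + rf / 60000 * C^3,
         stop("unknown curve_family: ", met$curve_family))
}

#' Simulate one LC-MS run with ground truth
#'
#' Each metabolite contributes a Gaussian chromatographic peak at its
#' warped retention time, with total area set by its truth response at the
#' given concentration. Spurious baseline peaks are Poisson-placed at
#' random target channels with log-uniform heights below the 25th
#' percentile of the true peak heights (mimicking small near-baseline
#' distractors); baseline and white noise are added to every target
#' channel, clamped at zero.
#'
#' @param spec A [sim_spec()].
#' @param concentrations Named vector of concentrations (micromol/L) for
#'   this run (internal standard included if defined).
#' @param drift_coef Quadratic warp coefficients `c(b0, b1, b2)` for this
#'   run.
#' @param run_id Run identifier.
#' @param seed Integer seed for this run's noise stream.
#' @param mode `"centroid"` (one stick per channel per scan) or
#'   `"profile"` (3-point m/z support per stick).
#' @return List with `run` (a [new_run()]) and `truth` (data frame of true
#'   peaks: metabolite, m/z, warped apex RT, area, height, concentration).
#' @export
simulate_run <- function(spec, concentrations, drift_coef = c(0, 1, 0),
                         run_id = "run", seed = 1L,
                         mode = c("centroid", "profile")) {
  mode <- match.arg(mode)
  rt <- seq(0, spec$rt_span, by = spec$scan_interval)
  warp <- function(t) drift_coef[1] + drift_coef[2] * t +
    drift_coef[3] * t^2
  dw <- diff(warp(range(rt)))
  if (dw <= 0) stop("non-monotone drift specification")
  mets <- spec$metabolites
  nt <- nrow(mets)
  signal <- matrix(0, nrow = length(rt), ncol = nt)
  truth <- NULL
  with_local_seed(seed, {
    inj <- if (spec$injection_cv > 0)
      exp(rnorm(1, -spec$injection_cv^2 / 2, spec$injection_cv)) else 1
    t_met <- character(0); t_mz <- t_rt <- t_area <- t_h <- t_conc <-
      numeric(0)
    for (j in seq_len(nt)) {
      met <- mets[j, ]
      C <- concentrations[[met$name]]
      if (is.null(C) || is.na(C) || C <= 0) next
      area <- truth_area(met, C) * inj
      apex <- warp(met$true_rt)
      h <- area / (met$peak_sigma * sqrt(2 * pi))
      signal[, j] <- signal[, j] +
        h * exp(-(rt - apex)^2 / (2 * met$peak_sigma^2))
      t_met <- c(t_met, met$name); t_mz <- c(t_mz, met$quant_mz)
      t_rt <- c(t_rt, apex); t_area <- c(t_area, area)
      t_h <- c(t_h, h); t_conc <- c(t_conc, C)
    }
    truth <- if (length(t_met))
      data.frame(metabolite = t_met, target_mz = t_mz, true_rt = t_rt,
                 area = t_area, height = t_h, concentration = t_conc,
                 run_id = run_id) else NULL
    # spurious near-baseline peaks; optionally a fraction clusters around
    # the true elution regions (crowded-chromatogram clutter)
    n_spur <- if (spec$noise$spurious_rate > 0)
      rpois(1, spec$noise$spurious_rate * spec$rt_span) else 0L
    if (n_spur > 0 && !is.null(truth)) {
      q25 <- unname(stats::quantile(truth$height, 0.25))
      frac_local <- spec$noise$spurious_local_frac
      if (is.null(frac_local)) frac_local <- 0
      local_sd <- spec$noise$spurious_local_sd
      if (is.null(local_sd)) local_sd <- 0.4
      for (k in seq_len(n_spur)) {
        j <- sample.int(nt, 1)
        apex <- if (runif(1) < frac_local &&
                    mets$name[j] %in% t_met) {
          t_rt[match(mets$name[j], t_met)] + rnorm(1, 0, local_sd)
        } else {
          runif(1, 0, spec$rt_span)
        }
        if (apex < 0 || apex > spec$rt_span) next
        h <- exp(runif(1, log(0.1 * q25), log(q25)))
        sig <- mets$peak_sigma[j]
        signal[, j] <- signal[, j] +
          h * exp(-(rt - apex)^2 / (2 * sig^2))
      }
    }
    if (spec$noise$sd > 0 || spec$noise$baseline > 0)
      signal <- pmax(signal + spec$noise$baseline +
                       rnorm(length(signal), 0, spec$noise$sd), 0)
  })
  # isomers share a quantifier m/z: one channel per distinct m/z
  channel_mz <- sort(unique(mets$quant_mz))
  grp <- match(mets$quant_mz, channel_mz)
  agg <- signal %*% outer(grp, seq_along(channel_mz), `==`)
  spectra <- lapply(seq_along(rt), function(i) {
    inten <- agg[i, ]
    nz <- inten > 0
    mz <- channel_mz[nz]
    inten <- inten[nz]
    if (mode == "profile" && length(mz)) {
      dm <- 0.01
      mzp <- as.vector(rbind(mz - dm, mz, mz + dm))
      intp <- as.vector(rbind(0.5 * inten, inten, 0.5 * inten))
      ord2 <- order(mzp)
      new_spectrum(rt[i], mzp[ord2], intp[ord2], mode = "profile")
    } else {
      new_spectrum(rt[i], mz, inten, mode = "centroid")
    }
  })
  list(run = new_run(spectra, run_id = run_id), truth = truth)
}

scenario_names <- c("linear_small", "six_family", "crowded_baseline",
                    "is_normalized", "full_panel")

# deterministic sub-seed for run r of replicate seed s (kept below 2^31)
derive_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 7919 + r * 104729) %% 2147483647)
}

#' Build a named synthetic scenario in memory
#'
#' Scenarios are fixed study designs with known ground truth:
#' \describe{
#'   \item{linear_small}{3 metabolites, 3 standards, 2 samples, no drift or
#'     noise — the smoke-test design.}
#'   \item{six_family}{6 metabolites, one per calibration family, 6
#'     standards, 2 samples, noise-free.}
#'   \item{crowded_baseline}{8 metabolites, 2 standards, 3 samples,
#'     quadratic drift and a high spurious-peak rate — the adversarial
#'     alignment design.}
#'   \item{is_normalized}{4 metabolites (one internal standard), strong
#'     run-to-run injection variability cancelled by IS normalization.}
#'   \item{full_panel}{29 metabolites, 6 standards, 12 samples, quadratic
#'     drift, signal-to-noise 20 at the lowest standard level — the
#'     full-pipeline validation design.}
#' }
#'
#' @param scenario Scenario name.
#' @param seed Integer seed; the whole project is deterministic given it.
#' @return List with `spec`, `runs` (named list of runs), `truth`
#'   (combined truth table), `design` (long standards design),
#'   `ion_list`, `standard_run_ids`, `sample_run_ids` and `sample_truth`.
#' @export
make_scenario <- function(scenario = scenario_names, seed = 1L) {
  scenario <- match.arg(scenario)
  spec <- scenario_spec(scenario, seed)
  realize_project(spec, seed)
}

scenario_spec <- function(scenario, seed) {
  if (scenario == "linear_small") {
    mets <- data.frame(
      name = c("L-alanine", "L-serine", "L-valine"),
      quant_mz = c(90.05496, 106.04987, 118.08626),
      true_rt = c(3, 6, 9), peak_sigma = 0.05,
      response_factor = c(25, 40, 15), curve_family = "linear",
      is_internal_standard = FALSE)
    sample_truth <- matrix(c(20, 80, 150, 60, 40, 120), nrow = 2,
                           dimnames = list(NULL, mets$name))
    sim_spec(mets, rt_span = 12, standard_concentrations = c(10, 50, 200),
             sample_truth = sample_truth, seed = seed)
  } else if (scenario == "six_family") {
    mets <- data.frame(
      name = paste0("cmpd_", CURVE_FAMILIES),
      quant_mz = seq(120, 420, by = 60) + 0.05,
      true_rt = seq(2, 17, by = 3), peak_sigma = 0.05,
      response_factor = 20, curve_family = CURVE_FAMILIES,
      is_internal_standard = FALSE)
    sample_truth <- matrix(rep(c(30, 120), each = 6), nrow = 2,
                           byrow = TRUE, dimnames = list(NULL, mets$name))
    sim_spec(mets, sample_truth = sample_truth, seed = seed)
  } else if (scenario == "crowded_baseline") {
    n <- 8L
    rf <- with_local_seed(derive_seed(seed, 998),
                          exp(runif(n, log(10), log(60))))
    mets <- data.frame(
      name = sprintf("cmpd%02d", seq_len(n)),
      quant_mz = seq(100, 450, length.out = n) + 0.07,
      true_rt = seq(2, 18, length.out = n), peak_sigma = 0.05,
      response_factor = rf, curve_family = "linear",
      is_internal_standard = FALSE)
    # heterogeneous responses and a wide sample range leave some cells
    # close to the baseline, where small spurious peaks compete
    truth <- with_local_seed(derive_seed(seed, 999), {
      matrix(exp(runif(3 * n, log(8), log(180))), nrow = 3,
             dimnames = list(NULL, mets$name))
    })
    sim_spec(mets, standard_concentrations = c(20, 200),
             drift = random_drift_fun(seed, amplitude = 0.5, rt_span = 20),
             noise = list(baseline = 0, sd = NA, spurious_rate = 4),
             sample_truth = truth, seed = seed)
  } else if (scenario == "is_normalized") {
    mets <- data.frame(
      name = c("L-alanine", "L-glutamate", "succinate", "IS"),
      quant_mz = c(90.05496, 148.06044, 119.03389, 250.10000),
      true_rt = c(3, 7, 11, 15), peak_sigma = 0.05,
      response_factor = c(25, 35, 18, 30), curve_family = "linear",
      is_internal_standard = c(FALSE, FALSE, FALSE, TRUE))
    sample_truth <- matrix(c(25, 90, 160, 55, 140, 35), nrow = 2,
                           dimnames = list(NULL, mets$name[1:3]))
    sim_spec(mets, rt_span = 18, sample_truth = sample_truth,
             injection_cv = 0.3, seed = seed)
  } else { # full_panel
    panel <- default_id_table()
    n <- nrow(panel)  # 29 metabolites
    rts <- with_local_seed(derive_seed(seed, 777),
                           sort(runif(n, 1.2, 18.8)))
    # enforce a minimal RT spacing so true peaks stay resolvable
    for (i in 2:n) rts[i] <- max(rts[i], rts[i - 1] + 0.25)
    mz <- quant_ion_mz(panel$monoisotopic_mw, "positive")
    # isobaric channels share an EIC window; a real assay separates them
    # chromatographically, so force >= 0.6 min between near-isobars
    for (pass in 1:20) {
      moved <- FALSE
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (abs(mz[i] - mz[j]) <= 0.25 && abs(rts[i] - rts[j]) < 0.6) {
          k <- if (rts[i] >= rts[j]) i else j
          rts[k] <- min(rts[i], rts[j]) + 0.6
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    rf <- with_local_seed(derive_seed(seed, 778),
                          exp(runif(n, log(15), log(60))))
    mets <- data.frame(
      name = panel$name, quant_mz = mz,
      true_rt = rts, peak_sigma = 0.05, response_factor = rf,
      curve_family = "linear", is_internal_standard = FALSE)
    truth <- with_local_seed(derive_seed(seed, 779), {
      matrix(exp(runif(12 * n, log(10), log(180))), nrow = 12,
             dimnames = list(NULL, mets$name))
    })
    # benchmark conditions: drift + SNR 20; spurious clutter is exercised
    # separately by the crowded_baseline scenario
    sim_spec(mets, standard_concentrations = c(5, 10, 25, 50, 100, 200),
             drift = random_drift_fun(seed, amplitude = 0.5, rt_span = 20),
             noise = list(baseline = 0, sd = NA, spurious_rate = 0),
             sample_truth = truth, seed = seed)
  }
}

# random monotone quadratic drift, bounded displacement over the span
random_drift_fun <- function(seed, amplitude = 0.5, rt_span = 20) {
  function(run_index) {
    if (run_index == 1L) return(c(0, 1, 0))  # the reference run
    with_local_seed(derive_seed(seed, run_index), {
      b2 <- runif(1, -amplitude, amplitude) / rt_span^2
      b1 <- 1 + runif(1, -0.3, 0.3) * amplitude / rt_span
      b0 <- runif(1, -0.2, 0.2) * amplitude
      if (b1 + 2 * b2 * rt_span <= 0 || b1 <= 0) c(0.1, 1, 0)
      else c(b0, b1, b2)
    })
  }
}

# turn a sim_spec into concrete runs + truth + project tables.
# Noise sd given as NA means "SNR 20": the white-noise sd is set to 1/20 of
# the apex height of the weakest standard-level peak (LLOQ-anchored SNR).
realize_project <- function(spec, seed) {
  mets <- spec$metabolites
  analytes <- mets$name[!mets$is_internal_standard]
  n_std <- length(spec$standard_concentrations)
  n_samp <- if (is.null(spec$sample_truth)) 0L else nrow(spec$sample_truth)
  if (is.na(spec$noise$sd)) {
    low <- min(spec$standard_concentrations)
    h_low <- min(vapply(seq_len(nrow(mets)), function(j)
      truth_area(mets[j, ], low) / (mets$peak_sigma[j] * sqrt(2 * pi)),
      numeric(1)))
    spec$noise$sd <- h_low / 20
  }
  run_ids <- c(sprintf("std_%02d", seq_len(n_std)),
               if (n_samp) sprintf("sample_%02d", seq_len(n_samp)))
  runs <- list()
  truth <- list()
  design <- list()
  sample_truth_long <- list()
  for (r in seq_along(run_ids)) {
    rid <- run_ids[r]
    if (r <= n_std) {
      conc <- setNames(rep(spec$standard_concentrations[r],
                           length(analytes)), analytes)
      design[[r]] <- data.frame(run_id = rid, metabolite = analytes,
                                concentration = unname(conc))
    } else {
      conc <- spec$sample_truth[r - n_std, ]
      sample_truth_long[[r - n_std]] <-
        data.frame(run_id = rid, metabolite = names(conc),
                   concentration = unname(conc))
    }
    if (any(mets$is_internal_standard))
      conc <- c(conc, setNames(spec$is_concentration,
                               mets$name[mets$is_internal_standard]))
    sim <- simulate_run(spec, as.list(conc), spec$drift(r), run_id = rid,
                        seed = derive_seed(seed, r))
    runs[[rid]] <- sim$run
    truth[[rid]] <- sim$truth
  }
  ion_list <- as_ion_list(data.frame(
    name = mets$name, quant_mz = mets$quant_mz, expected_rt = mets$true_rt,
    is_internal_standard = mets$is_internal_standard))
  list(spec = spec, runs = runs, truth = do.call(rbind, truth),
       design = do.call(rbind, design), ion_list = ion_list,
       standard_run_ids = run_ids[seq_len(n_std)],
       sample_run_ids = if (n_samp) run_ids[(n_std + 1L):length(run_ids)]
                        else character(0),
       sample_truth = if (n_samp) do.call(rbind, sample_truth_long)
                      else NULL)
}

#' Write a synthetic project to disk
#'
#' Materializes a [make_scenario()] project as a directory of mzML runs
#' plus the tabular artifacts the pipeline consumes: `ion_list.csv`,
#' `standards.csv` (long design), `config.txt` (flat key=value) and the
#' ground-truth CSVs.
#'
#' @inheritParams make_scenario
#' @param dir Output directory (created if needed).
#' @return The in-memory project, invisibly.
#' @export
make_project <- function(scenario = scenario_names, dir, seed = 1L) {
  proj <- make_scenario(scenario, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rid in names(proj$runs))
    write_run(proj$runs[[rid]], file.path(dir, paste0(rid, ".mzML")))
  write_ion_list(proj$ion_list, file.path(dir, "ion_list.csv"))
  write.csv(proj$design, file.path(dir, "standards.csv"),
            row.names = FALSE)
  write.csv(proj$truth, file.path(dir, "truth_peaks.csv"),
            row.names = FALSE)
  if (!is.null(proj$sample_truth))
    write.csv(proj$sample_truth, file.path(dir, "truth_concentrations.csv"),
              row.names = FALSE)
  cfg <- c(scenario = scenario, seed = seed,
           noise_sd = proj$spec$noise$sd,
           standard_runs = paste(proj$standard_run_ids, collapse = ";"),
           sample_runs = paste(proj$sample_run_ids, collapse = ";"))
  writeLines(paste0(names(cfg), "=", cfg), file.path(dir, "config.txt"))
  invisible(proj)
}
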