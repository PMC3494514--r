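CURVE_FAMILIES <- c("linear", "logarithmic", "power", "exponential",
                    "quadratic", "cubic")

# minimum number of standard levels per family (equals the parameter count
# for the polynomial families; two suffices for the two-parameter families)
MIN_STANDARDS <- c(linear = 2L, logarithmic = 2L, power = 2L,
                   exponential = 2L, quadratic = 3L, cubic = 4L)

# parsimony rank used to break R-squared ties: the straight line wins over
# the two-parameter transforms, which win over the higher polynomials
FAMILY_RANK <- c(linear = 1L, logarithmic = 2L, power = 2L,
                 exponential = 2L, quadratic = 3L, cubic = 4L)

#' Internal-standard normalization
#'
#' Divides an analyte area by the internal-standard area of the same run,
#' cancelling injection-volume and ionisation-efficiency variability. When a
#' project defines an internal standard the normalization is applied
#' uniformly to standards and samples before any curve fitting.
#'
#' @param analyte_area Analyte peak area (intensity x minutes). Vectorized.
#' @param is_area Internal-standard peak area of the same run, `> 0`.
#' @param run_id Optional run label for error messages.
#' @return Dimensionless area ratio.
#' @export
normalize_is <- function(analyte_area, is_area, run_id = NULL) {
  if (any(!is.finite(is_area)) || any(is_area <= 0))
    stop("internal-standard area must be positive",
         if (!is.null(run_id)) paste0(" (run '", run_id, "')") else "")
  analyte_area / is_area
}

#' Fit one calibration-curve family
#'
#' Fits the relation between peak area A and concentration C (micromol/L)
#' for one of six families by least squares on the area scale:
#' linear `A = a0 + a1*C`, logarithmic `A = a0 + a1*ln(C)`, power
#' `A = a0*C^a1`, exponential `A = a0*a1^C`, quadratic and cubic
#' polynomials. The polynomial and logarithmic families use ordinary linear
#' least squares; power and exponential are initialized by
#' log-linearization and refined by Levenberg-Marquardt on the area scale
#' (the log-scale R-squared of the initialization is kept alongside).
#'
#' @param family One of `"linear"`, `"logarithmic"`, `"power"`,
#'   `"exponential"`, `"quadratic"`, `"cubic"`.
#' @param standards Data frame with columns `concentration` (micromol/L)
#'   and `area` (possibly IS-normalized). Replicate levels are pooled.
#' @param is_normalized Whether the areas are IS ratios (recorded, not used
#'   numerically).
#' @param weighting `"none"` (ordinary least squares), `"1/C"` or
#'   `"1/C2"` (weights 1/C or 1/C-squared, the usual bioanalytical remedy
#'   when the noise is proportional to the signal).
#' @param min_recommended Standards below this count trigger a warning
#'   (six non-zero levels covering the expected range are recommended).
#' @return An object of class `"calibration_curve"` with coefficients
#'   `a0..a3`, `r_squared`, the calibration range `c_min`/`c_max` and
#'   `n_standards`.
#' @export
fit_calibration <- function(family, standards, is_normalized = FALSE,
                            weighting = c("none", "1/C", "1/C2"),
                            min_recommended = 6L) {
  weighting <- match.arg(weighting)
  family <- match.arg(family, CURVE_FAMILIES)
  stopifnot(is.data.frame(standards),
            all(c("concentration", "area") %in% names(standards)))
  C <- as.numeric(standards$concentration)
  A <- as.numeric(standards$area)
  keep <- is.finite(C) & is.finite(A)
  C <- C[keep]; A <- A[keep]
  if (family %in% c("logarithmic", "power")) {
    if (any(C < 0)) stop("negative concentrations are not allowed")
    if (any(C == 0)) {
      warning("excluding ", sum(C == 0), " zero-concentration standard(s) ",
              "from the ", family, " fit")
      A <- A[C > 0]; C <- C[C > 0]
    }
  }
  n <- length(C)
  if (n < MIN_STANDARDS[[family]])
    stop("family '", family, "' needs at least ", MIN_STANDARDS[[family]],
         " standards, got ", n)
  if (n < min_recommended)
    warning("only ", n, " standards; at least ", min_recommended,
            " non-zero levels covering the expected range are recommended")
  w <- switch(weighting, none = rep(1, n), `1/C` = 1 / C,
              `1/C2` = 1 / C^2)
  co <- c(a0 = NA_real_, a1 = NA_real_, a2 = NA_real_, a3 = NA_real_)
  r2_log <- NA_real_
  fitted <- switch(
    family,
    linear = {
      f <- lm_poly(C, A, 1L, w); co[1:2] <- f$coef; f$fitted
    },
    quadratic = {
      f <- lm_poly(C, A, 2L, w); co[1:3] <- f$coef; f$fitted
    },
    cubic = {
      f <- lm_poly(C, A, 3L, w); co[1:4] <- f$coef; f$fitted
    },
    logarithmic = {
      f <- lm_poly(log(C), A, 1L, w); co[1:2] <- f$coef; f$fitted
    },
    power = {
      init <- loglin_init(C, A, log_x = TRUE)
      r2_log <- init$r2_log
      f <- refine_nls(A ~ a0 * C^a1, data.frame(C = C, A = A),
                      init$start, w)
      co[1:2] <- f$coef
      f$fitted
    },
    exponential = {
      init <- loglin_init(C, A, log_x = FALSE)
      r2_log <- init$r2_log
      f <- refine_nls(A ~ a0 * a1^C, data.frame(C = C, A = A),
                      init$start, w)
      co[1:2] <- f$coef
      f$fitted
    })
  ss_res <- sum((A - fitted)^2)
  ss_tot <- sum((A - mean(A))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res < 1e-12) 1
        else NA_real_
  structure(list(family = family, a0 = co[[1]], a1 = co[[2]],
                 a2 = co[[3]], a3 = co[[4]], r_squared = r2,
                 r_squared_log = r2_log,
                 c_min = min(C), c_max = max(C), n_standards = n,
                 is_normalized = is_normalized),
            class = "calibration_curve")
}

lm_poly <- function(x, y, degree, w = rep(1, length(x))) {
  X <- outer(x, 0:degree, `^`)
  sw <- sqrt(w)
  qr_x <- qr(X * sw)
  if (qr_x$rank < degree + 1L)
    stop("singular calibration design (duplicate or collinear ",
         "concentration levels)")
  co <- as.numeric(qr.coef(qr_x, y * sw))
  list(coef = co, fitted = drop(X %*% co))
}

# log-linearized start values for the power/exponential families
loglin_init <- function(C, A, log_x) {
  pos <- A > 0
  if (sum(pos) < 2L)
    stop("need at least two positive areas to initialize this family")
  x <- if (log_x) log(C[pos]) else C[pos]
  f <- lm_poly(x, log(A[pos]), 1L)
  resid <- log(A[pos]) - f$fitted
  tot <- log(A[pos]) - mean(log(A[pos]))
  r2_log <- if (sum(tot^2) > 0) 1 - sum(resid^2) / sum(tot^2) else 1
  start <- if (log_x) list(a0 = exp(f$coef[1]), a1 = f$coef[2])
           else list(a0 = exp(f$coef[1]), a1 = exp(f$coef[2]))
  list(start = start, r2_log = r2_log)
}

refine_nls <- function(formula, data, start, w = rep(1, nrow(data))) {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the log-linearized initialization
    co <- unlist(start)
    env <- list2env(c(data, as.list(co)))
    return(list(coef = as.numeric(co),
                fitted = eval(formula[[3L]], env)))
  }
  list(coef = as.numeric(coef(fit)), fitted = as.numeric(fitted(fit)))
}

#' Predict areas from a calibration curve
#' @param object A `"calibration_curve"`.
#' @param concentration Concentrations (micromol/L).
#' @param ... Unused.
#' @return Predicted areas.
#' @export
predict.calibration_curve <- function(object, concentration, ...) {
  C <- concentration
  with(object, switch(family,
    linear = a0 + a1 * C,
    logarithmic = a0 + a1 * log(C),
    power = a0 * C^a1,
    exponential = a0 * a1^C,
    quadratic = a0 + a1 * C + a2 * C^2,
    cubic = a0 + a1 * C + a2 * C^2 + a3 * C^3))
}

#' @export
print.calibration_curve <- function(x, ...) {
  co <- c(x$a0, x$a1, x$a2, x$a3)
  cat(sprintf("<calibration_curve %s> a = (%s), R2 = %.5f, range [%g, %g], n = %d%s\n",
              x$family,
              paste(signif(co[!is.na(co)], 6), collapse = ", "),
              x$r_squared, x$c_min, x$c_max, x$n_standards,
              if (x$is_normalized) ", IS-normalized" else ""))
  invisible(x)
}

#' Suggest the best-fitting calibration family
#'
#' Ranks successfully fitted curves by R-squared on the area scale. Curves
#' whose R-squared values agree within `tie_tolerance` are tied; ties go to
#' the more parsimonious family (linear, then the two-parameter transforms,
#' then quadratic, then cubic).
#'
#' @param curves List of `"calibration_curve"` objects.
#' @param tie_tolerance R-squared difference treated as a tie.
#' @return The name of the winning family.
#' @export
suggest_best_fit <- function(curves, tie_tolerance = 1e-4) {
  curves <- Filter(function(cv) inherits(cv, "calibration_curve") &&
                     is.finite(cv$r_squared), curves)
  if (length(curves) == 0L)
    stop("no successfully fitted calibration curves to rank")
  r2 <- vapply(curves, `[[`, numeric(1), "r_squared")
  fam <- vapply(curves, `[[`, character(1), "family")
  best_r2 <- max(r2)
  tied <- which(r2 >= best_r2 - tie_tolerance)
  ranks <- FAMILY_RANK[fam[tied]]
  # stable order within equal rank: the CURVE_FAMILIES order
  pick <- tied[order(ranks, match(fam[tied], CURVE_FAMILIES))][1L]
  unname(fam[pick])
}

#' Invert a calibration curve
#'
#' Maps a measured (possibly IS-normalized) peak area back to a
#' concentration using the closed-form inverse where one exists
#' (linear, logarithmic, power, exponential, quadratic) and a bracketed
#' root search on the monotone branch for the cubic. Concentrations outside
#' the calibration range `[c_min, c_max]` are flagged as extrapolated.
#'
#' @param curve A `"calibration_curve"`.
#' @param area Measured area (scalar).
#' @return List with `concentration` (micromol/L) and `extrapolated`
#'   (logical).
#' @export
invert_concentration <- function(curve, area) {
  stopifnot(length(area) == 1L, is.finite(area))
  fam <- curve$family
  a0 <- curve$a0; a1 <- curve$a1; a2 <- curve$a2; a3 <- curve$a3
  conc <- switch(fam,
    linear = {
      if (a1 == 0) stop("flat linear curve cannot be inverted")
      (area - a0) / a1
    },
    logarithmic = {
      if (a1 == 0) stop("flat logarithmic curve cannot be inverted")
      exp((area - a0) / a1)
    },
    power = {
      if (a0 <= 0 || area / a0 <= 0)
        stop("power curve not invertible at this area")
      if (a1 == 0) stop("flat power curve cannot be inverted")
      (area / a0)^(1 / a1)
    },
    exponential = {
      if (a0 <= 0 || area / a0 <= 0)
        stop("exponential curve not invertible at this area")
      if (a1 <= 0 || a1 == 1)
        stop("degenerate exponential base cannot be inverted")
      log(area / a0) / log(a1)
    },
    quadratic = invert_quadratic(a0, a1, a2, area, curve$c_min,
                                 curve$c_max),
    cubic = invert_cubic(a0, a1, a2, a3, area, curve$c_min, curve$c_max))
  list(concentration = conc,
       extrapolated = conc < curve$c_min || conc > curve$c_max)
}

invert_quadratic <- function(a0, a1, a2, area, c_min, c_max) {
  if (a2 == 0) {
    if (a1 == 0) stop("flat quadratic curve cannot be inverted")
    return((area - a0) / a1)
  }
  disc <- a1^2 - 4 * a2 * (a0 - area)
  if (disc < 0) stop("quadratic curve has no real root at this area")
  roots <- (-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2)
  inside <- roots[roots >= c_min & roots <= c_max]
  if (length(inside)) return(inside[1L])
  # no in-range root: take the real root nearest to the range
  dist <- pmin(abs(roots - c_min), abs(roots - c_max))
  roots[which.min(dist)]
}

invert_cubic <- function(a0, a1, a2, a3, area, c_min, c_max) {
  f <- function(C) a0 + a1 * C + a2 * C^2 + a3 * C^3 - area
  lo <- 0; hi <- 2 * c_max
  # restrict to the monotone branch covering the calibration range:
  # stationary points are roots of the derivative 3*a3*C^2 + 2*a2*C + a1
  if (a3 != 0) {
    disc <- (2 * a2)^2 - 4 * 3 * a3 * a1
    if (disc > 0) {
      st <- sort(((-2 * a2) + c(-1, 1) * sqrt(disc)) / (2 * 3 * a3))
      mid <- (c_min + c_max) / 2
      lo <- max(lo, st[st < mid], -Inf)
      hi <- min(hi, st[st > mid], Inf)
      lo <- max(lo, 0); hi <- min(hi, 2 * c_max)
    }
  }
  if (!is.finite(f(lo)) || !is.finite(f(hi)) || f(lo) * f(hi) > 0) {
    # fall back to a grid scan for a bracket on [0, 2*c_max]
    grid <- seq(0, 2 * c_max, length.out = 512L)
    fg <- vapply(grid, f, numeric(1))
    sgn <- which(fg[-1L] * fg[-length(fg)] <= 0)
    if (length(sgn) == 0L)
      stop("cubic curve has no real root in [0, 2*c_max] at this area")
    # bracket nearest to the calibration range midpoint
    mid <- (c_min + c_max) / 2
    k <- sgn[which.min(abs(grid[sgn] - mid))]
    lo <- grid[k]; hi <- grid[k + 1L]
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Fit all applicable calibration families
#'
#' Attempts the six families on the same standards, collecting successful
#' fits and recording each failure reason.
#'
#' @inheritParams fit_calibration
#' @param families Families to try (default: all six).
#' @return List with `fits` (named list of curves) and `errors` (named
#'   character vector of failure reasons).
#' @export
fit_all_families <- function(standards, families = CURVE_FAMILIES,
                             is_normalized = FALSE, weighting = "none") {
  fits <- list()
  errors <- character(0)
  for (fam in families) {
    res <- tryCatch(
      suppressWarnings(fit_calibration(fam, standards,
                                       is_normalized = is_normalized,
                                       weighting = weighting)),
      error = function(e) conditionMessage(e))
    if (inherits(res, "calibration_curve")) fits[[fam]] <- res
    else errors[[fam]] <- res
  }
  list(fits = fits, errors = errors)
}

#' Calibration report table
#'
#' Flattens a per-metabolite set of fitted curves into the report CSV
#' layout: one row per metabolite and family with coefficients, R-squared,
#' standards count, range and whether the fit is the suggested best.
#'
#' @param curveset Named list (per metabolite) of lists with elements
#'   `fits` and `best`, as produced by [run_calibration()].
#' @return Data frame.
#' @export
calibration_report <- function(curveset) {
  rows <- list()
  for (met in names(curveset)) {
    for (fam in names(curveset[[met]]$fits)) {
      cv <- curveset[[met]]$fits[[fam]]
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = met, family = fam, a0 = cv$a0, a1 = cv$a1,
        a2 = cv$a2, a3 = cv$a3, r_squared = cv$r_squared,
        r_squared_log = cv$r_squared_log, n_standards = cv$n_standards,
        c_min = cv$c_min, c_max = cv$c_max,
        is_normalized = cv$is_normalized,
        best = identical(fam, curveset[[met]]$best))
    }
  }
  do.call(rbind, rows)
}
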