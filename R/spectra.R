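#' Construct a mass spectrum
#'
#' A spectrum is one MS scan: a retention time (minutes) plus parallel,
#' strictly m/z-ascending vectors of m/z (Th) and non-negative intensity.
#'
#' @param rt Retention time in minutes (non-negative scalar).
#' @param mz Numeric vector of m/z values, strictly ascending.
#' @param intensity Numeric vector of intensities, same length as `mz`,
#'   all non-negative.
#' @param ms_level MS level; only level-1 spectra are used for quantification.
#' @param mode `"profile"` or `"centroid"`.
#' @return An object of class `"spectrum"`.
#' @export
new_spectrum <- function(rt, mz, intensity, ms_level = 1L,
                         mode = "centroid") {
  if (!(mode %in% c("centroid", "profile")))
    stop("mode must be 'centroid' or 'profile'")
  if (!is.numeric(rt) || length(rt) != 1L || rt < 0)
    stop("rt must be a non-negative scalar (minutes)")
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("spectrum m/z values must be strictly ascending")
  if (length(intensity) && any(intensity < 0))
    stop("spectrum intensities must be non-negative")
  structure(
    list(rt = as.numeric(rt), mz = as.numeric(mz),
         intensity = as.numeric(intensity),
         ms_level = as.integer(ms_level), mode = mode),
    class = "spectrum"
  )
}

#' Construct an LC-MS run
#'
#' A run is an RT-ordered sequence of MS1 spectra plus acquisition metadata.
#' Spectra with `ms_level != 1` are dropped (tandem spectra are out of scope);
#' spectra are sorted by retention time on construction.
#'
#' @param spectra List of [new_spectrum()] objects.
#' @param run_id Identifier for the run (used in peak tables and exports).
#' @param source_path Path the run was read from, or `""` for in-memory runs.
#' @param format One of `"mzml"`, `"mzxml"`, `"netcdf"`, `"memory"`.
#' @return An object of class `"run"`.
#' @export
new_run <- function(spectra, run_id, source_path = "", format = "memory") {
  if (!is.list(spectra)) stop("spectra must be a list")
  lev <- vapply(spectra, function(s) s$ms_level, integer(1))
  spectra <- spectra[lev == 1L]
  if (length(spectra) == 0L)
    stop("run '", run_id, "' contains no MS1 spectra")
  rts <- vapply(spectra, function(s) s$rt, numeric(1))
  if (is.unsorted(rts)) spectra <- spectra[order(rts)]
  structure(
    list(spectra = spectra, run_id = as.character(run_id),
         source_path = source_path, format = format),
    class = "run"
  )
}

#' @export
print.run <- function(x, ...) {
  rts <- run_rt(x)
  cat(sprintf("<run '%s'> %d MS1 spectra, RT %.3f-%.3f min (%s)\n",
              x$run_id, length(x$spectra),
              min(rts), max(rts), x$format))
  invisible(x)
}

#' Retention times of a run's spectra, in minutes
#' @param run A [new_run()] object.
#' @return Numeric vector, one element per MS1 spectrum.
#' @export
run_rt <- function(run) {
  vapply(run$spectra, function(s) s$rt, numeric(1))
}

# Heuristic profile/centroid call for files that do not store the mode:
# a spectrum is called centroid when fewer than 50% of consecutive m/z gaps
# fall below twice the median gap (profile data sample a near-uniform grid).
infer_mode <- function(mz) {
  if (length(mz) < 4L) return("centroid")
  gaps <- diff(mz)
  frac_small <- mean(gaps < 2 * median(gaps))
  if (frac_small < 0.5) "centroid" else "profile"
}
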