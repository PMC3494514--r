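# run a block with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

warp_model_df <- c(identity = 0L, linear = 2L, quadratic = 3L)

new_rt_warp <- function(model, coefficients, inlier_pairs, rmse,
                        n_candidates) {
  structure(list(model = model, coefficients = coefficients,
                 inlier_pairs = inlier_pairs, rmse = rmse,
                 n_candidates = n_candidates),
            class = "rt_warp")
}

#' Apply a retention-time warp
#' @param warp An [fit_rt_warp()] result.
#' @param rt Retention times (minutes) in the reference run's time scale.
#' @return Predicted retention times in the sample run's time scale.
#' @export
warp_rt <- function(warp, rt) {
  co <- warp$coefficients
  switch(warp$model,
         identity = rt,
         linear = co[1] + co[2] * rt,
         quadratic = co[1] + co[2] * rt + co[3] * rt^2)
}

#' @export
print.rt_warp <- function(x, ...) {
  cat(sprintf("<rt_warp %s> %d/%d inliers, rmse %.4f min\n", x$model,
              nrow(x$inlier_pairs), x$n_candidates, x$rmse))
  invisible(x)
}

# least-squares polynomial rt_sample ~ rt_ref of the given degree
fit_poly_warp <- function(ref, samp, degree) {
  X <- outer(ref, 0:degree, `^`)
  qr_x <- qr(X)
  if (qr_x$rank < degree + 1L) return(NULL)
  as.numeric(qr.coef(qr_x, samp))
}

warp_monotone <- function(co, span) {
  if (length(co) == 2L) return(co[2] > 0)
  d <- co[2] + 2 * co[3] * span   # derivative is linear: check the ends
  all(d > 0)
}

#' Fit a retention-time warp by RANSAC
#'
#' Models the non-linear RT drift of a sample run relative to the reference
#' run. Candidate (reference, sample) peak pairs are all pairs matching in
#' m/z within `mz_tolerance` and in RT within `rt_pre_tolerance`. RANSAC
#' repeatedly fits the minimal pair set, counts pairs within
#' `inlier_threshold` of the model, keeps the consensus-maximal model and
#' refits it on all inliers by least squares. The warp family degrades
#' quadratic -> linear -> identity when candidate pairs are scarce or the
#' fitted warp is not monotone over the observed span.
#'
#' @param reference_peaks Data frame with columns `target_mz` and `rt`: the
#'   assigned peak per metabolite in the reference run.
#' @param sample_peaks Peak table of the sample run (from [deconvolve()]).
#' @param rt_pre_tolerance Maximum |RT difference| for a candidate pair
#'   (minutes).
#' @param mz_tolerance Matching tolerance in Th.
#' @param iterations RANSAC iterations.
#' @param inlier_threshold Inlier band in minutes.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return An object of class `"rt_warp"`.
#' @export
fit_rt_warp <- function(reference_peaks, sample_peaks,
                        rt_pre_tolerance = 1.0, mz_tolerance = 0.1,
                        iterations = 1000L, inlier_threshold = 0.05,
                        seed = 1L) {
  pairs <- candidate_pairs(reference_peaks, sample_peaks,
                           rt_pre_tolerance, mz_tolerance)
  n <- nrow(pairs)
  if (n < 2L) {
    warning("fewer than 2 candidate pairs; using identity warp")
    return(new_rt_warp("identity", numeric(0), pairs, 0, n))
  }
  degree <- if (n >= 3L) 2L else 1L
  if (degree == 1L)
    warning("only ", n, " candidate pairs; degrading warp to linear")
  span <- range(pairs$rt_ref)
  best <- with_local_seed(seed, ransac_poly(pairs, degree, iterations,
                                            inlier_threshold, span))
  if (is.null(best)) {
    warning("RANSAC found no valid model; using identity warp")
    return(new_rt_warp("identity", numeric(0), pairs, 0, n))
  }
  finalize_warp(pairs, best$inliers, degree, span, n)
}

candidate_pairs <- function(reference_peaks, sample_peaks,
                            rt_pre_tolerance, mz_tolerance) {
  out <- list()
  for (i in seq_len(nrow(reference_peaks))) {
    dmz <- abs(sample_peaks$target_mz - reference_peaks$target_mz[i])
    drt <- abs(sample_peaks$apex_rt - reference_peaks$rt[i])
    hit <- which(dmz <= mz_tolerance & drt <= rt_pre_tolerance)
    if (length(hit))
      out[[length(out) + 1L]] <-
        data.frame(rt_ref = reference_peaks$rt[i],
                   rt_sample = sample_peaks$apex_rt[hit])
  }
  if (length(out) == 0L)
    return(data.frame(rt_ref = numeric(0), rt_sample = numeric(0)))
  do.call(rbind, out)
}

ransac_poly <- function(pairs, degree, iterations, inlier_threshold, span) {
  n <- nrow(pairs)
  m <- degree + 1L
  best <- NULL
  for (it in seq_len(iterations)) {
    sel <- sample.int(n, m)
    co <- fit_poly_warp(pairs$rt_ref[sel], pairs$rt_sample[sel], degree)
    if (is.null(co) || !warp_monotone(co, span)) next
    pred <- drop(outer(pairs$rt_ref, 0:degree, `^`) %*% co)
    resid <- pairs$rt_sample - pred
    inl <- which(abs(resid) <= inlier_threshold)
    if (length(inl) < m) next
    score <- length(inl)
    rmse <- sqrt(mean(resid[inl]^2))
    if (is.null(best) || score > best$score ||
        (score == best$score && rmse < best$rmse))
      best <- list(inliers = inl, score = score, rmse = rmse)
  }
  best
}

finalize_warp <- function(pairs, inliers, degree, span, n_candidates) {
  inl <- pairs[inliers, , drop = FALSE]
  co <- fit_poly_warp(inl$rt_ref, inl$rt_sample, degree)
  if (degree == 2L && (is.null(co) || !warp_monotone(co, span))) {
    degree <- 1L
    co <- fit_poly_warp(inl$rt_ref, inl$rt_sample, degree)
  }
  if (is.null(co)) {
    warning("degenerate inlier set; using identity warp")
    return(new_rt_warp("identity", numeric(0), inl, 0, n_candidates))
  }
  model <- if (degree == 2L) "quadratic" else "linear"
  pred <- drop(outer(inl$rt_ref, 0:degree, `^`) %*% co)
  new_rt_warp(model, co, inl, sqrt(mean((inl$rt_sample - pred)^2)),
              n_candidates)
}

#' Suggest the sample peak for a metabolite
#'
#' Warps the metabolite's expected retention time into the sample run and
#' suggests the peak whose apex is nearest to the predicted RT within
#' `+/- rt_window`. The suggestion is flagged `not_highest` when a taller
#' peak exists in the window (small baseline peaks near the predicted
#' position are a known alignment failure mode, so such cells deserve visual
#' confirmation); if no peak falls in the window the suggestion is empty and
#' flagged `out_of_window`.
#'
#' @param metabolite_rt Expected RT in the reference time scale (minutes).
#' @param warp An [fit_rt_warp()] result.
#' @param peaks Peak table of the sample run.
#' @param rt_window Half-width of the search window (minutes).
#' @return List of class `"peak_suggestion"`: `peak` (one-row data frame or
#'   `NULL`), `flag_not_highest`, `flag_out_of_window`, `predicted_rt`.
#' @export
suggest_peak <- function(metabolite_rt, warp, peaks, rt_window = 0.2) {
  stopifnot(rt_window > 0)
  predicted <- warp_rt(warp, metabolite_rt)
  res <- list(peak = NULL, flag_not_highest = FALSE,
              flag_out_of_window = FALSE, predicted_rt = predicted)
  inwin <- which(abs(peaks$apex_rt - predicted) <= rt_window)
  if (length(inwin) == 0L) {
    res$flag_out_of_window <- TRUE
  } else {
    d <- abs(peaks$apex_rt[inwin] - predicted)
    ord <- order(d, peaks$apex_rt[inwin])   # distance, then leftmost apex
    pick <- inwin[ord[1L]]
    res$peak <- peaks[pick, , drop = FALSE]
    res$flag_not_highest <-
      any(peaks$height[inwin] > peaks$height[pick] + 1e-12)
  }
  class(res) <- "peak_suggestion"
  res
}

#' Manually override a peak selection
#'
#' Replaces an automatic suggestion by a manually integrated peak over the
#' given retention-time bounds; the area comes from [integrate_area()] and
#' the height is the maximum trace intensity within the bounds.
#'
#' @param suggestion A [suggest_peak()] result (may be empty).
#' @param manual_bounds Numeric `c(rt_start, rt_end)` within the
#'   chromatogram span.
#' @param chrom The metabolite's chromatogram in that run.
#' @return A one-row peak data frame with `manual = TRUE`.
#' @export
override_selection <- function(suggestion, manual_bounds, chrom) {
  rt_start <- manual_bounds[1]; rt_end <- manual_bounds[2]
  area <- integrate_area(chrom, rt_start, rt_end)  # validates the bounds
  inside <- chrom$rt >= rt_start & chrom$rt <= rt_end
  ys <- c(chrom$intensity[inside],
          approx(chrom$rt, chrom$intensity, rt_start)$y,
          approx(chrom$rt, chrom$intensity, rt_end)$y)
  height <- max(ys)
  xs <- c(chrom$rt[inside], rt_start, rt_end)
  data.frame(apex_rt = xs[which.max(ys)], rt_start = rt_start,
             rt_end = rt_end, height = height, area = area,
             target_mz = chrom$target_mz, run_id = chrom$run_id,
             manual = TRUE)
}

#' Read / write saved peak selections
#'
#' Selections persist manual (and accepted automatic) integrations per run
#' as CSV with columns `metabolite`, `run_id`, `rt_start`, `rt_end`,
#' `manual`, so a project can be re-quantified after curation.
#'
#' @param path CSV path.
#' @return `read_selections`: data frame of selections.
#' @export
read_selections <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "run_id", "rt_start", "rt_end", "manual")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("selections file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df$manual <- as.logical(df$manual)
  df
}

#' @rdname read_selections
#' @param selections Data frame of selections.
#' @export
write_selections <- function(selections, path) {
  write.csv(selections, path, row.names = FALSE)
  invisible(path)
}
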