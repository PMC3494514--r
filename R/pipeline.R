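#' Project configuration
#'
#' Binds together everything a quantification project needs: the ion list,
#' the standards design, run identities, the processing configuration,
#' alignment parameters and the seed making the whole pipeline
#' deterministic.
#'
#' @param ion_list Ion-list data frame ([read_ion_list()]); expected RTs
#'   must be present for every metabolite.
#' @param standards_design Long data frame `run_id`, `metabolite`,
#'   `concentration` (micromol/L) for the standard runs.
#' @param standard_run_ids Character vector of standard run ids, in order;
#'   the first is the alignment reference.
#' @param sample_run_ids Character vector of sample run ids.
#' @param processing A [processing_config()].
#' @param alignment List of [fit_rt_warp()] parameters
#'   (`rt_pre_tolerance`, `iterations`, `inlier_threshold`, `rt_window`).
#' @param seed Integer seed for the RANSAC streams.
#' @param id_db Identifier namespace for export (`"name"`, `"pubchem"`,
#'   `"kegg"`, `"hmdb"`).
#' @return List of class `"project_config"`.
#' @export
project_config <- function(ion_list, standards_design, standard_run_ids,
                           sample_run_ids = character(0),
                           processing = processing_config(),
                           alignment = list(), seed = 1L,
                           id_db = "name") {
  miss <- setdiff(unique(standards_design$metabolite), ion_list$name)
  if (length(miss))
    stop("standards design names metabolite(s) absent from the ion list: ",
         paste(miss, collapse = ", "))
  if (any(is.na(ion_list$expected_rt)))
    stop("every metabolite needs an expected_rt before calibration")
  al <- list(rt_pre_tolerance = 1.0, iterations = 1000L,
             inlier_threshold = 0.05, rt_window = 0.2, mz_tolerance = 0.1)
  al[names(alignment)] <- alignment
  structure(list(ion_list = ion_list, standards_design = standards_design,
                 standard_run_ids = standard_run_ids,
                 sample_run_ids = sample_run_ids, processing = processing,
                 alignment = al, seed = as.integer(seed), id_db = id_db),
            class = "project_config")
}

# preprocess one run: EICs for every quantifier ion + pooled peak table
preprocess_run <- function(run, ion_list, processing) {
  eics <- build_eics(run, ion_list$quant_mz, processing)
  peaks <- do.call(rbind, lapply(eics, deconvolve, config = processing))
  if (is.null(peaks)) peaks <- empty_peaks()
  rownames(peaks) <- NULL
  list(eics = eics, peaks = peaks)
}

# assign a peak to every metabolite of one run, via warp + suggestion
assign_peaks <- function(pre, ion_list, warp, rt_window) {
  out <- vector("list", nrow(ion_list))
  for (i in seq_len(nrow(ion_list))) {
    met <- ion_list[i, ]
    # peaks were built per target EIC, so match on the exact target m/z
    cand <- pre$peaks[pre$peaks$target_mz == met$quant_mz, , drop = FALSE]
    sug <- suggest_peak(met$expected_rt, warp, cand, rt_window)
    out[[i]] <- sug
  }
  names(out) <- ion_list$name
  out
}

suggestion_area <- function(sug) {
  if (is.null(sug$peak)) NA_real_ else sug$peak$area
}

suggestion_flags <- function(sug) {
  flags <- character(0)
  if (sug$flag_out_of_window) flags <- c(flags, "out_of_window")
  if (sug$flag_not_highest) flags <- c(flags, "not_highest")
  if (!is.null(sug$peak) && isTRUE(sug$peak$manual))
    flags <- c(flags, "manual")
  flags
}

#' Run the calibration stage
#'
#' For every standard run: preprocess, warp its retention times onto the
#' reference (the first standard run, where the expected RTs were defined),
#' suggest a peak per metabolite, optionally normalize by the internal
#' standard, then per metabolite fit all six curve families on the
#' (concentration, area) points and record the suggested best fit.
#' Metabolites without enough usable standards are excluded with a warning.
#'
#' @param config A [project_config()].
#' @param runs Named list of [new_run()] objects covering
#'   `config$standard_run_ids`.
#' @return List of class `"calibration_result"`: `curves` (per metabolite:
#'   `fits`, `errors`, `best`), `warps`, `reference_peaks`,
#'   `standard_areas`, `is_name`.
#' @export
run_calibration <- function(config, runs) {
  ions <- config$ion_list
  al <- config$alignment
  is_name <- ions$name[ions$is_internal_standard]
  has_is <- length(is_name) == 1L
  ref_id <- config$standard_run_ids[1L]
  warps <- list()
  areas <- list()
  reference_peaks <- NULL
  for (r in seq_along(config$standard_run_ids)) {
    rid <- config$standard_run_ids[r]
    if (is.null(runs[[rid]])) stop("standard run '", rid, "' not supplied")
    pre <- preprocess_run(runs[[rid]], ions, config$processing)
    if (rid == ref_id) {
      warp <- new_rt_warp("identity", numeric(0),
                          data.frame(rt_ref = numeric(0),
                                     rt_sample = numeric(0)), 0, 0L)
    } else {
      warp <- fit_rt_warp(reference_peaks, pre$peaks,
                          rt_pre_tolerance = al$rt_pre_tolerance,
                          mz_tolerance = al$mz_tolerance,
                          iterations = al$iterations,
                          inlier_threshold = al$inlier_threshold,
                          seed = derive_seed(config$seed, r))
    }
    warps[[rid]] <- warp
    sugs <- assign_peaks(pre, ions, warp, al$rt_window)
    if (rid == ref_id) {
      ok <- !vapply(sugs, function(s) is.null(s$peak), logical(1))
      reference_peaks <- data.frame(
        target_mz = ions$quant_mz[ok],
        rt = vapply(sugs[ok], function(s) s$peak$apex_rt, numeric(1)))
    }
    a <- vapply(sugs, suggestion_area, numeric(1))
    if (has_is) {
      is_area <- a[[is_name]]
      a <- if (is.na(is_area) || is_area <= 0) {
        warning("internal-standard peak missing in standard run '", rid,
                "'; its areas are unusable")
        setNames(rep(NA_real_, length(a)), names(a))
      } else normalize_is(a, is_area, rid)
    }
    areas[[rid]] <- data.frame(run_id = rid, metabolite = names(a),
                               area = unname(a))
  }
  std_areas <- do.call(rbind, areas)
  rownames(std_areas) <- NULL
  curves <- list()
  for (met in setdiff(ions$name, is_name)) {
    des <- config$standards_design[config$standards_design$metabolite ==
                                     met, , drop = FALSE]
    pts <- merge(des, std_areas[std_areas$metabolite == met, ],
                 by = c("run_id", "metabolite"))
    pts <- pts[is.finite(pts$area), , drop = FALSE]
    if (nrow(pts) < 2L) {
      warning("metabolite '", met, "' has ", nrow(pts),
              " usable standard(s); excluded from calibration")
      next
    }
    res <- fit_all_families(pts[, c("concentration", "area")],
                            is_normalized = has_is)
    if (length(res$fits) == 0L) {
      warning("no calibration family could be fitted for '", met, "'")
      next
    }
    res$best <- suggest_best_fit(res$fits)
    curves[[met]] <- res
  }
  structure(list(curves = curves, warps = warps,
                 reference_peaks = reference_peaks,
                 standard_areas = std_areas, is_name = is_name),
            class = "calibration_result")
}

#' Run the quantification stage
#'
#' For every sample run: preprocess, fit the RANSAC warp against the
#' calibration reference, suggest (or take overridden) peaks, normalize by
#' the internal standard when one is defined, and invert each metabolite's
#' best-fit calibration curve to a concentration in micromol/L. Cells carry
#' quality flags (`not_highest`, `out_of_window`, `extrapolated`,
#' `manual`, `is_missing`).
#'
#' @param config A [project_config()].
#' @param calib A [run_calibration()] result.
#' @param runs Named list of runs covering `config$sample_run_ids`.
#' @param selections Optional data frame of saved manual selections
#'   ([read_selections()]) applied before quantification.
#' @return A `"concentration_table"`: long data frame `cells` plus the
#'   metabolite and sample indexes.
#' @export
run_quantification <- function(config, calib, runs, selections = NULL) {
  ions <- config$ion_list
  al <- config$alignment
  is_name <- calib$is_name
  has_is <- length(is_name) == 1L
  mets <- names(calib$curves)
  cells <- list()
  warps <- list()
  for (r in seq_along(config$sample_run_ids)) {
    rid <- config$sample_run_ids[r]
    if (is.null(runs[[rid]])) stop("sample run '", rid, "' not supplied")
    pre <- preprocess_run(runs[[rid]], ions, config$processing)
    warp <- fit_rt_warp(calib$reference_peaks, pre$peaks,
                        rt_pre_tolerance = al$rt_pre_tolerance,
                        mz_tolerance = al$mz_tolerance,
                        iterations = al$iterations,
                        inlier_threshold = al$inlier_threshold,
                        seed = derive_seed(config$seed, 1000L + r))
    warps[[rid]] <- warp
    sugs <- assign_peaks(pre, ions, warp, al$rt_window)
    if (!is.null(selections)) {
      sel <- selections[selections$run_id == rid, , drop = FALSE]
      for (k in seq_len(nrow(sel))) {
        met <- sel$metabolite[k]
        chrom <- pre$eics[[format_mz(ions$quant_mz[ions$name == met])]]
        sugs[[met]]$peak <- override_selection(
          sugs[[met]], c(sel$rt_start[k], sel$rt_end[k]), chrom)
        sugs[[met]]$flag_out_of_window <- FALSE
      }
    }
    a <- vapply(sugs, suggestion_area, numeric(1))
    is_failed <- FALSE
    if (has_is) {
      is_area <- a[[is_name]]
      if (is.na(is_area) || is_area <= 0) {
        warning("internal-standard peak missing in sample run '", rid,
                "'; all its cells are marked missing")
        is_failed <- TRUE
      } else {
        a <- normalize_is(a, is_area, rid)
      }
    }
    for (met in mets) {
      sug <- sugs[[met]]
      flags <- suggestion_flags(sug)
      conc <- NA_real_
      if (is_failed) {
        flags <- c(flags, "is_missing")
      } else if (!is.na(a[[met]])) {
        best <- calib$curves[[met]]$fits[[calib$curves[[met]]$best]]
        inv <- tryCatch(invert_concentration(best, a[[met]]),
                        error = function(e) NULL)
        if (!is.null(inv)) {
          conc <- inv$concentration
          if (inv$extrapolated) flags <- c(flags, "extrapolated")
          if (conc < 0) {  # clamp non-physical inversions at zero
            conc <- 0
            flags <- unique(c(flags, "extrapolated"))
          }
        }
      }
      cells[[length(cells) + 1L]] <- data.frame(
        metabolite = met, run_id = rid, concentration = conc,
        area = a[[met]],
        apex_rt = if (is.null(sug$peak)) NA_real_ else sug$peak$apex_rt,
        predicted_rt = sug$predicted_rt,
        flags = paste(flags, collapse = ";"))
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  structure(list(cells = cells, metabolites = mets,
                 sample_run_ids = config$sample_run_ids,
                 ion_list = ions, warps = warps),
            class = "concentration_table")
}

#' @export
print.concentration_table <- function(x, ...) {
  cat(sprintf("<concentration_table> %d metabolites x %d samples (%d cells)\n",
              length(x$metabolites), length(x$sample_run_ids),
              nrow(x$cells)))
  invisible(x)
}

#' Binned relative-error comparison of two concentration tables
#'
#' Compares a table against a reference table cell by cell:
#' `relative error = |c - c_ref| / c_ref * 100`. Errors are binned
#' (default edges 0/5/10/15/Inf percent); reference cells equal to zero are
#' excluded and counted separately. Percentages sum to 100.
#'
#' @param a Long data frame (or `"concentration_table"`) with columns
#'   `metabolite`, `run_id`, `concentration`.
#' @param b The reference, same metabolites and samples.
#' @param bin_edges Increasing percent edges; a final `Inf` is implied.
#' @return List with `table` (bin, count, percentage), `n_compared`,
#'   `n_excluded_zero_reference` and `errors` (per-cell values).
#' @export
relative_error_table <- function(a, b, bin_edges = c(0, 5, 10, 15)) {
  ca <- if (inherits(a, "concentration_table")) a$cells else a
  cb <- if (inherits(b, "concentration_table")) b$cells else b
  m <- merge(ca[, c("metabolite", "run_id", "concentration")],
             cb[, c("metabolite", "run_id", "concentration")],
             by = c("metabolite", "run_id"), suffixes = c("_a", "_b"))
  if (nrow(m) < max(nrow(ca), nrow(cb)))
    stop("tables do not share the same metabolite x sample cells")
  ok <- is.finite(m$concentration_a) & is.finite(m$concentration_b)
  m <- m[ok, , drop = FALSE]
  zero_ref <- m$concentration_b == 0
  n_excl <- sum(zero_ref)
  m <- m[!zero_ref, , drop = FALSE]
  err <- abs(m$concentration_a - m$concentration_b) /
    m$concentration_b * 100
  edges <- c(bin_edges, Inf)
  labels <- paste0(utils::head(edges, -1), "-", utils::tail(edges, -1), "%")
  labels[length(labels)] <- paste0(">", bin_edges[length(bin_edges)], "%")
  bins <- cut(err, breaks = edges, include.lowest = TRUE, right = TRUE,
              labels = labels)
  counts <- as.integer(table(bins))
  list(table = data.frame(bin = labels, count = counts,
                          percentage = if (length(err))
                            100 * counts / length(err) else counts * NA),
       n_compared = length(err),
       n_excluded_zero_reference = n_excl,
       errors = data.frame(metabolite = m$metabolite, run_id = m$run_id,
                           relative_error = err))
}

#' Export a concentration table as ID-keyed CSV
#'
#' Writes the metabolites x samples concentration matrix with the first
#' column holding compound identifiers in the chosen namespace (PubChem,
#' KEGG, HMDB or the compound name), the layout downstream metabolomics
#' tools expect. Rows lacking the requested identifier fall back to the
#' name with a warning. Cell flags go to a sibling `*_flags.csv`.
#'
#' @param table A `"concentration_table"`.
#' @param path Output CSV path.
#' @param id_db `"name"`, `"pubchem"`, `"kegg"` or `"hmdb"`.
#' @param id_table Offline ID table for the lookup
#'   ([default_id_table()]).
#' @return `path`, invisibly.
#' @export
export_csv <- function(table, path, id_db = c("name", "pubchem", "kegg",
                                              "hmdb"),
                       id_table = default_id_table()) {
  id_db <- match.arg(id_db)
  mets <- table$metabolites
  ids <- mets
  if (id_db != "name") {
    for (i in seq_along(mets)) {
      found <- tryCatch(suppressWarnings(lookup_compound(mets[i],
                                                         id_table)),
                        error = function(e) list())
      v <- found[[id_db]]
      if (is.null(v)) {
        warning("no ", id_db, " ID for '", mets[i],
                "'; falling back to the name")
      } else ids[i] <- as.character(v)
    }
  }
  wide <- matrix(NA_real_, nrow = length(mets),
                 ncol = length(table$sample_run_ids),
                 dimnames = list(mets, table$sample_run_ids))
  flags <- matrix("", nrow = length(mets),
                  ncol = length(table$sample_run_ids),
                  dimnames = list(mets, table$sample_run_ids))
  for (k in seq_len(nrow(table$cells))) {
    cl <- table$cells[k, ]
    wide[cl$metabolite, cl$run_id] <- cl$concentration
    flags[cl$metabolite, cl$run_id] <- cl$flags
  }
  out <- data.frame(ID = ids, wide, check.names = FALSE)
  write.csv(out, path, row.names = FALSE, na = "")
  fl <- data.frame(ID = ids, flags, check.names = FALSE)
  write.csv(fl, sub("\\.csv$", "_flags.csv", path), row.names = FALSE)
  invisible(path)
}

#' Read back an exported concentration CSV
#'
#' Inverse of [export_csv()] for round-tripping: returns the long cell
#' table keyed by the exported first column.
#'
#' @param path CSV written by [export_csv()].
#' @return Long data frame `metabolite` (the exported ID), `run_id`,
#'   `concentration`.
#' @export
read_concentration_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- setdiff(names(df), "ID")
  out <- do.call(rbind, lapply(samples, function(s)
    data.frame(metabolite = df$ID, run_id = s, concentration = df[[s]])))
  rownames(out) <- NULL
  out
}

# processing configuration matched to a synthetic scenario's noise level
scenario_processing <- function(spec) {
  sd <- spec$noise$sd
  if (is.null(sd) || is.na(sd) || sd <= 0)
    return(processing_config("default", noise_level = 1e-9,
                             min_peak_height = 1e-6))
  processing_config("default", noise_level = sd,
                    min_peak_height = 6 * sd)
}

#' Quantify a synthetic scenario end to end
#'
#' Convenience wrapper used by the validation suite: builds (or accepts) a
#' [make_scenario()] project, runs calibration and quantification, and
#' returns the results together with the ground truth.
#'
#' @param scenario Scenario name, or a project from [make_scenario()].
#' @param seed Integer seed.
#' @param processing Optional [processing_config()] override.
#' @return List with `project`, `config`, `calibration`, `table`.
#' @export
quantify_scenario <- function(scenario, seed = 1L, processing = NULL) {
  proj <- if (is.character(scenario)) make_scenario(scenario, seed)
          else scenario
  if (is.null(processing)) processing <- scenario_processing(proj$spec)
  config <- project_config(proj$ion_list, proj$design,
                           proj$standard_run_ids, proj$sample_run_ids,
                           processing = processing, seed = seed)
  calib <- suppressWarnings(run_calibration(config, proj$runs))
  table <- suppressWarnings(run_quantification(config, calib, proj$runs))
  list(project = proj, config = config, calibration = calib, table = table)
}
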