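#' Read a raw LC-MS run
#'
#' Reads mzML (1.0/1.1), mzXML (2.0/2.1/3.0) or ANDI-MS netCDF, optionally
#' inside a zip archive containing exactly one supported raw file. Retention
#' times are normalized to minutes on ingest regardless of the file's native
#' unit; only MS1 spectra are retained and they are returned sorted by RT.
#'
#' @param path Path to the raw file (or a `.zip` wrapping one raw file).
#' @param format_hint Optional `"mzml"`, `"mzxml"` or `"netcdf"`; by default
#'   the format is detected from the file extension.
#' @param run_id Run identifier; defaults to the file name without extension.
#' @return A [new_run()] object.
#' @export
read_run <- function(path, format_hint = NULL, run_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "zip") {
    members <- unzip(path, list = TRUE)$Name
    supported <- members[tolower(tools::file_ext(members)) %in%
                           c("mzml", "mzxml", "cdf", "nc")]
    if (length(supported) != 1L)
      stop("zip archive must contain exactly one supported raw file, found ",
           length(supported), " in ", path)
    exdir <- tempfile("lcquant_unzip")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
    unzip(path, files = supported, exdir = exdir)
    if (is.null(run_id))
      run_id <- tools::file_path_sans_ext(basename(path))
    return(read_run(file.path(exdir, supported), format_hint, run_id))
  }
  format <- if (!is.null(format_hint)) {
    match.arg(format_hint, c("mzml", "mzxml", "netcdf"))
  } else {
    switch(ext,
           mzml = "mzml", mzxml = "mzxml",
           cdf = "netcdf", nc = "netcdf",
           stop("unsupported raw-data format: extension '.", ext,
                "' (supported: mzML, mzXML, netCDF, zip)"))
  }
  if (is.null(run_id)) run_id <- tools::file_path_sans_ext(basename(path))
  if (format == "netcdf") {
    read_run_netcdf(path, run_id)
  } else {
    read_run_mzr(path, format, run_id)
  }
}

# mzML / mzXML through the proteowizard-backed parser; mzR reports RT in
# seconds whatever unit the file declares, so minutes = seconds / 60.
read_run_mzr <- function(path, format, run_id) {
  handle <- tryCatch(
    mzR::openMSfile(path, backend = "pwiz"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) stop("no spectra in ", path)
  lev <- hdr$msLevel
  if (anyNA(lev)) {
    message("ms_level missing for ", sum(is.na(lev)),
            " spectra in ", basename(path), "; assuming MS1")
    lev[is.na(lev)] <- 1L
  }
  keep <- which(lev == 1L)
  spectra <- lapply(keep, function(i) {
    pk <- mzR::peaks(handle, i)
    mode <- if (!is.null(hdr$centroided) && !is.na(hdr$centroided[i])) {
      if (hdr$centroided[i]) "centroid" else "profile"
    } else {
      m <- infer_mode(pk[, 1L])
      message("spectrum ", i, " of ", basename(path),
              ": mode not stored, inferred ", m)
      m
    }
    ord <- order(pk[, 1L])
    new_spectrum(rt = hdr$retentionTime[i] / 60,
                 mz = pk[ord, 1L], intensity = pmax(pk[ord, 2L], 0),
                 ms_level = 1L, mode = mode)
  })
  new_run(spectra, run_id = run_id, source_path = path, format = format)
}

# ANDI-MS netCDF: scan_acquisition_time + flat mass/intensity vectors indexed
# by scan_index (0-based offsets) / point_count.
read_run_netcdf <- function(path, run_id) {
  nc <- tryCatch(ncdf4::nc_open(path),
                 error = function(e) stop("failed to parse netCDF ", path,
                                          ": ", conditionMessage(e)))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  need <- c("scan_acquisition_time", "mass_values", "intensity_values",
            "scan_index")
  missing_var <- setdiff(need, names(nc$var))
  if (length(missing_var))
    stop("netCDF file ", path, " lacks required variable(s): ",
         paste(missing_var, collapse = ", "))
  rt_raw <- as.numeric(ncdf4::ncvar_get(nc, "scan_acquisition_time"))
  units <- tryCatch(ncdf4::ncatt_get(nc, "scan_acquisition_time",
                                     "units")$value,
                    error = function(e) NA_character_)
  rt_min <- if (is.character(units) && grepl("min", tolower(units))) {
    rt_raw
  } else {
    rt_raw / 60  # ANDI-MS convention stores seconds
  }
  mz_all <- as.numeric(ncdf4::ncvar_get(nc, "mass_values"))
  int_all <- as.numeric(ncdf4::ncvar_get(nc, "intensity_values"))
  idx0 <- as.integer(ncdf4::ncvar_get(nc, "scan_index"))
  n <- length(rt_raw)
  ends <- c(idx0[-1L], length(mz_all))
  spectra <- lapply(seq_len(n), function(i) {
    sel <- if (ends[i] > idx0[i]) (idx0[i] + 1L):ends[i] else integer(0)
    mz <- mz_all[sel]
    ord <- order(mz)
    new_spectrum(rt = rt_min[i], mz = mz[ord],
                 intensity = pmax(int_all[sel][ord], 0),
                 ms_level = 1L, mode = infer_mode(mz[ord]))
  })
  new_run(spectra, run_id = run_id, source_path = path, format = "netcdf")
}

#' Write a run to mzML or mzXML
#'
#' Serializes an in-memory run (RTs in minutes) to mzML or mzXML, choosing
#' the format from the file extension. Used by the synthetic-data generator
#' and for round-trip testing.
#'
#' @param run A [new_run()] object.
#' @param path Output path ending in `.mzML` or `.mzXML`.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  ext <- tolower(tools::file_ext(path))
  outformat <- switch(ext, mzml = "mzml", mzxml = "mzxml",
                      stop("write_run supports .mzML/.mzXML, got .", ext))
  n <- length(run$spectra)
  pks <- lapply(run$spectra, function(s) cbind(mz = s$mz,
                                               intensity = s$intensity))
  npk <- vapply(pks, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = npk,
    totIonCurrent = vapply(run$spectra, function(s) sum(s$intensity),
                           numeric(1)),
    retentionTime = run_rt(run) * 60,
    basePeakMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(run$spectra, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = vapply(run$spectra, function(s) s$mode == "centroid",
                        logical(1)),
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  suppressWarnings(mzR::writeMSData(pks, path, header = hdr,
                                    outformat = outformat))
  invisible(path)
}

#' Write a run as ANDI-MS netCDF
#'
#' Emits the classic ANDI-MS variable layout (`scan_acquisition_time` in
#' seconds, flat `mass_values`/`intensity_values` with `scan_index`
#' offsets). Mainly used to exercise the netCDF reader on synthetic data.
#'
#' @inheritParams write_run
#' @return `path`, invisibly.
#' @export
write_run_netcdf <- function(run, path) {
  n <- length(run$spectra)
  npk <- vapply(run$spectra, function(s) length(s$mz), integer(1))
  total <- sum(npk)
  dim_scan <- ncdf4::ncdim_def("scan_number", "", seq_len(n),
                               create_dimvar = FALSE)
  dim_pt <- ncdf4::ncdim_def("point_number", "", seq_len(max(total, 1L)),
                             create_dimvar = FALSE)
  vars <- list(
    ncdf4::ncvar_def("scan_acquisition_time", "seconds", dim_scan,
                     prec = "double"),
    ncdf4::ncvar_def("scan_index", "", dim_scan, prec = "integer"),
    ncdf4::ncvar_def("point_count", "", dim_scan, prec = "integer"),
    ncdf4::ncvar_def("total_intensity", "", dim_scan, prec = "double"),
    ncdf4::ncvar_def("mass_values", "Th", dim_pt, prec = "double"),
    ncdf4::ncvar_def("intensity_values", "", dim_pt, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, "scan_acquisition_time", run_rt(run) * 60)
  ncdf4::ncvar_put(nc, "scan_index", cumsum(c(0L, npk[-n])))
  ncdf4::ncvar_put(nc, "point_count", npk)
  ncdf4::ncvar_put(nc, "total_intensity",
                   vapply(run$spectra, function(s) sum(s$intensity),
                          numeric(1)))
  ncdf4::ncvar_put(nc, "mass_values",
                   unlist(lapply(run$spectra, `[[`, "mz")))
  ncdf4::ncvar_put(nc, "intensity_values",
                   unlist(lapply(run$spectra, `[[`, "intensity")))
  invisible(path)
}

ion_list_required_cols <- c("name", "quant_mz", "expected_rt",
                            "is_internal_standard")

#' Read a quantifier-ion list
#'
#' The ion list is a UTF-8 comma-separated table with one row per metabolite
#' and at least the columns `name`, `quant_mz`, `expected_rt`,
#' `is_internal_standard`. Optional columns (`molecular_weight`,
#' `ionisation_mode`, `pubchem`, `kegg`, `hmdb`, ...) are preserved. Rows
#' with a missing `quant_mz` are filled from `molecular_weight` and
#' `ionisation_mode` via [quant_ion_mz()]; at most one row may be flagged as
#' the internal standard.
#'
#' @param path CSV file path.
#' @return A data frame of metabolites (class `"ion_list"`).
#' @export
read_ion_list <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(ion_list_required_cols, names(df))
  if (length(missing_cols))
    stop("ion list ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("ion list ", path, " is empty (header only)")
    return(as_ion_list(df))
  }
  df$is_internal_standard <- as.logical(df$is_internal_standard)
  df$is_internal_standard[is.na(df$is_internal_standard)] <- FALSE
  validate_ion_list(df, path)
}

as_ion_list <- function(df) {
  class(df) <- c("ion_list", "data.frame")
  df
}

validate_ion_list <- function(df, label = "ion list") {
  if (sum(df$is_internal_standard) > 1L)
    stop(label, ": more than one internal standard flagged")
  df$quant_mz <- suppressWarnings(as.numeric(df$quant_mz))
  need_mz <- is.na(df$quant_mz)
  if (any(need_mz)) {
    mw <- if (is.null(df$molecular_weight)) rep(NA_real_, nrow(df))
          else suppressWarnings(as.numeric(df$molecular_weight))
    if (any(is.na(mw[need_mz])))
      stop(label, ": row(s) ", paste(which(need_mz & is.na(mw)),
                                     collapse = ", "),
           " have neither quant_mz nor molecular_weight")
    mode <- if (!is.null(df$ionisation_mode)) df$ionisation_mode[need_mz]
            else rep("positive", sum(need_mz))
    df$quant_mz[need_mz] <- mapply(quant_ion_mz, mw[need_mz], mode)
  }
  df$quant_mz <- as.numeric(df$quant_mz)
  if (any(df$quant_mz <= 0)) stop(label, ": quant_mz must be positive")
  as_ion_list(df)
}

#' Write a quantifier-ion list
#'
#' Inverse of [read_ion_list()]; the round trip is lossless, including
#' columns beyond the required set.
#'
#' @param ions Ion-list data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ion_list <- function(ions, path) {
  write.csv(as.data.frame(ions), path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

# --- minimal zip writer (stored entries, no compression) ---------------
# Used to package raw runs for upload-style workflows and to exercise the
# zip-transparent reader; readable by any unzip implementation.

crc32_table <- function() {
  if (is.null(the$crc_tab)) {
    tab <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L)) bitwXor(-306674912L, bitwShiftR(c, 1L))
             else bitwShiftR(c, 1L)
      tab[n + 1L] <- c
    }
    the$crc_tab <- tab
  }
  the$crc_tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  bitwXor(crc, -1L)
}

u16_raw <- function(v) as.raw(c(v %% 256, (v %/% 256) %% 256))
u32_raw <- function(v) {
  v <- as.numeric(v) %% 2^32
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

#' Create a zip archive with stored (uncompressed) entries
#'
#' A dependency-free writer for the zip container format, sufficient to
#' bundle raw runs; entries are stored without compression.
#'
#' @param files Files to archive (stored under their base names).
#' @param zipfile Output archive path.
#' @return `zipfile`, invisibly.
#' @export
write_zip_stored <- function(files, zipfile) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  centrals <- list()
  offset <- 0
  for (f in files) {
    data <- readBin(f, "raw", file.info(f)$size)
    name <- charToRaw(basename(f))
    crc <- crc32(data)
    local_hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), u16_raw(20),
                   u16_raw(0), u16_raw(0), u16_raw(0), u16_raw(0x21),
                   u32_raw(crc), u32_raw(length(data)),
                   u32_raw(length(data)), u16_raw(length(name)),
                   u16_raw(0), name)
    writeBin(local_hdr, con)
    writeBin(data, con)
    centrals[[length(centrals) + 1L]] <-
      c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16_raw(20), u16_raw(20),
        u16_raw(0), u16_raw(0), u16_raw(0), u16_raw(0x21), u32_raw(crc),
        u32_raw(length(data)), u32_raw(length(data)),
        u16_raw(length(name)), u16_raw(0), u16_raw(0), u16_raw(0),
        u16_raw(0), u32_raw(0), u32_raw(offset), name)
    offset <- offset + length(local_hdr) + length(data)
  }
  cd_start <- offset
  for (cd in centrals) writeBin(cd, con)
  cd_size <- sum(vapply(centrals, length, integer(1)))
  writeBin(c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16_raw(0), u16_raw(0),
             u16_raw(length(centrals)), u16_raw(length(centrals)),
             u32_raw(cd_size), u32_raw(cd_start), u16_raw(0)), con)
  invisible(zipfile)
}
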