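PROTON_MASS <- 1.00728  # Da, mass of H+ for [M+H]+ / [M-H]- adducts

#' Quantifier ion m/z from molecular weight
#'
#' Converts a (monoisotopic) molecular weight into the single quantifier m/z
#' traced for a metabolite, assuming the dominant electrospray adducts:
#' protonation `[M+H]+` in positive mode, deprotonation `[M-H]-` in negative
#' mode. Other adducts can be expressed through `adduct_shift`.
#'
#' @param molecular_weight Molecular weight in Da, `> 0`. Vectorized.
#' @param mode `"positive"` or `"negative"` ionisation.
#' @param adduct_shift Mass added (positive mode) or subtracted (negative
#'   mode); defaults to the proton mass 1.00728 Da.
#' @return Quantifier m/z in Th.
#' @export
#' @examples
#' quant_ion_mz(180.06339, "positive")  # 181.07067
#' quant_ion_mz(180.06339, "negative")  # 179.05611
quant_ion_mz <- function(molecular_weight, mode = c("positive", "negative"),
                         adduct_shift = PROTON_MASS) {
  mode <- match.arg(mode)
  if (any(molecular_weight <= 0))
    stop("molecular_weight must be positive")
  mz <- switch(mode,
               positive = molecular_weight + adduct_shift,
               negative = molecular_weight - adduct_shift)
  if (any(mz <= 0))
    stop("negative-mode quantifier ion would be non-positive ",
         "(molecular weight below the adduct mass)")
  mz
}

#' Inverse of [quant_ion_mz()]
#' @param mz Quantifier m/z in Th.
#' @inheritParams quant_ion_mz
#' @return Molecular weight in Da.
#' @export
quant_ion_mw <- function(mz, mode = c("positive", "negative"),
                         adduct_shift = PROTON_MASS) {
  mode <- match.arg(mode)
  switch(mode,
         positive = mz - adduct_shift,
         negative = mz + adduct_shift)
}

#' The packaged offline compound-ID table
#'
#' A curated table mapping common metabolite names to PubChem CID, KEGG and
#' HMDB identifiers plus monoisotopic molecular weight, so that annotation
#' works fully offline and deterministically.
#'
#' @return Data frame with columns `name`, `pubchem_cid`, `kegg_id`,
#'   `hmdb_id`, `monoisotopic_mw`.
#' @export
default_id_table <- function() {
  if (is.null(the$id_table)) {
    path <- system.file("extdata", "compound_ids.csv", package = "lcquant",
                        mustWork = TRUE)
    the$id_table <- read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(pubchem_cid = "character"))
  }
  the$id_table
}

normalize_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Look up database identifiers for a compound name
#'
#' Matching is case-insensitive exact first, then insensitive to
#' non-alphanumeric characters ("L-alanine" matches "Lalanine"). A miss
#' returns an empty map with a warning (identifiers are only needed at
#' export time); an ambiguous match is an error listing the candidates.
#'
#' @param name Compound name to look up.
#' @param table ID table; defaults to [default_id_table()].
#' @return Named list with any of `pubchem`, `kegg`, `hmdb`,
#'   `monoisotopic_mw` present in the matched row; empty list on a miss.
#' @export
lookup_compound <- function(name, table = default_id_table()) {
  hit <- which(tolower(table$name) == tolower(name))
  if (length(hit) == 0L)
    hit <- which(normalize_name(table$name) == normalize_name(name))
  if (length(hit) == 0L) {
    warning("no identifier match for compound '", name, "'")
    return(list())
  }
  if (length(hit) > 1L)
    stop("compound name '", name, "' matches multiple table rows: ",
         paste(table$name[hit], collapse = ", "))
  row <- table[hit, ]
  out <- list(pubchem = row$pubchem_cid, kegg = row$kegg_id,
              hmdb = row$hmdb_id, monoisotopic_mw = row$monoisotopic_mw)
  out[!vapply(out, function(v) is.na(v) || identical(v, ""), logical(1))]
}

#' Annotate an ion list with database IDs and molecular weights
#'
#' Fills `pubchem`/`kegg`/`hmdb` and `molecular_weight` columns by name
#' lookup against the offline table, leaving existing values untouched.
#' Unmatched names are kept with a warning.
#'
#' @param ions Ion-list data frame from [read_ion_list()].
#' @param table ID table; defaults to [default_id_table()].
#' @return The annotated ion list.
#' @export
annotate_ion_list <- function(ions, table = default_id_table()) {
  for (col in c("pubchem", "kegg", "hmdb", "molecular_weight"))
    if (is.null(ions[[col]]))
      ions[[col]] <- if (col == "molecular_weight") NA_real_
                     else NA_character_
  for (i in seq_len(nrow(ions))) {
    ids <- tryCatch(lookup_compound(ions$name[i], table),
                    warning = function(w) list())
    if (!is.null(ids$pubchem) && is.na(ions$pubchem[i]))
      ions$pubchem[i] <- as.character(ids$pubchem)
    if (!is.null(ids$kegg) && is.na(ions$kegg[i]))
      ions$kegg[i] <- ids$kegg
    if (!is.null(ids$hmdb) && is.na(ions$hmdb[i]))
      ions$hmdb[i] <- ids$hmdb
    if (!is.null(ids$monoisotopic_mw) && is.na(ions$molecular_weight[i]))
      ions$molecular_weight[i] <- ids$monoisotopic_mw
  }
  as_ion_list(ions)
}
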