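# Feature annotation by accurate mass (and retention time).
#
# Level 1 (confirmed): match against an authentic-standard library run on
# the same platform, within +/- 5 ppm and +/- 15 s. Level 4 (tentative):
# match against a formula library over the mode's full adduct list within
# 10 ppm, no RT constraint; a simple match-confidence score counts how many
# distinct adducts of the same metabolite have a supporting feature (a
# deliberately simplified stand-in for correlation-clustering annotation
# scores — not equivalent).

#' Level-1 annotation against an authentic-standard library
#'
#' All (feature, entry) pairs within both the ppm and RT tolerances are
#' returned; for each feature the nearest-ppm entry is flagged primary.
#'
#' @param features data.frame with `feature_id`, `mz`, `rt`, `mode`.
#' @param library_df Reference library (see [read_reference_library]).
#' @param tol_ppm m/z tolerance in ppm (default 5).
#' @param tol_rt_s RT tolerance in seconds (default 15).
#' @return data.frame of hits: `feature_id`, `metabolite`, `adduct`,
#'   `library_mz`, `ppm_error`, `rt_error_s`, `confidence`, `primary`.
#' @export
match_level1 <- function(features, library_df, tol_ppm = 5, tol_rt_s = 15) {
  hits <- list()
  for (i in seq_len(nrow(features))) {
    lib <- library_df[library_df$mode == features$mode[i], , drop = FALSE]
    if (!nrow(lib)) next
    perr <- ppm_error(features$mz[i], lib$mz)
    rerr <- features$rt[i] - lib$rt
    sel <- which(abs(perr) <= tol_ppm & abs(rerr) <= tol_rt_s)
    if (!length(sel)) next
    h <- data.frame(feature_id = features$feature_id[i],
                    metabolite = lib$name[sel], adduct = lib$adduct[sel],
                    library_mz = lib$mz[sel], ppm_error = perr[sel],
                    rt_error_s = rerr[sel], confidence = "level1",
                    primary = FALSE, stringsAsFactors = FALSE)
    h$primary[which.min(abs(h$ppm_error))] <- TRUE
    hits[[length(hits) + 1L]] <- h
  }
  if (!length(hits)) {
    return(data.frame(feature_id = character(), metabolite = character(),
                      adduct = character(), library_mz = numeric(),
                      ppm_error = numeric(), rt_error_s = numeric(),
                      confidence = character(), primary = logical()))
  }
  do.call(rbind, hits)
}

#' Level-4 annotation against a formula library
#'
#' Matches features to theoretical adduct m/z values of a formula library
#' over the feature's mode adduct list, within `tol_ppm` (default 10), with
#' no RT constraint. Every hit is reported, carrying an adduct-support
#' score: the number of distinct adducts of the metabolite for which at
#' least one feature matches.
#'
#' @param features data.frame with `feature_id`, `mz`, `mode`.
#' @param formula_lib data.frame with `name` and `formula` (or
#'   `neutral_mass`).
#' @param tol_ppm m/z tolerance in ppm.
#' @return data.frame of hits: `feature_id`, `metabolite`, `adduct`,
#'   `theoretical_mz`, `ppm_error`, `confidence`, `adduct_support`.
#' @export
match_level4 <- function(features, formula_lib, tol_ppm = 10) {
  if (is.null(formula_lib$neutral_mass)) {
    formula_lib$neutral_mass <- vapply(formula_lib$formula,
                                       monoisotopic_mass, 0)
  }
  hits <- list()
  for (mode in unique(features$mode)) {
    f <- features[features$mode == mode, , drop = FALSE]
    for (ad in mode_adducts(mode)) {
      theo <- adduct_mz(formula_lib$neutral_mass, ad, mode)
      for (i in seq_len(nrow(f))) {
        perr <- ppm_error(f$mz[i], theo)
        sel <- which(abs(perr) <= tol_ppm)
        if (!length(sel)) next
        hits[[length(hits) + 1L]] <- data.frame(
          feature_id = f$feature_id[i],
          metabolite = formula_lib$name[sel], adduct = ad,
          theoretical_mz = theo[sel], ppm_error = perr[sel],
          confidence = "level4", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(feature_id = character(), metabolite = character(),
                      adduct = character(), theoretical_mz = numeric(),
                      ppm_error = numeric(), confidence = character(),
                      adduct_support = integer()))
  }
  out <- do.call(rbind, hits)
  support <- tapply(out$adduct, out$metabolite,
                    function(a) length(unique(a)))
  out$adduct_support <- as.integer(support[out$metabolite])
  rownames(out) <- NULL
  out
}

#' Path to the packaged authentic-standard mini-library
#'
#' Seventeen metabolites confirmed in the study plus the two smoking
#' biomarkers (cotinine, hydroxycotinine), with formulas, adducts, printed
#' library m/z and retention times. Biomarker RTs are synthetic (no
#' published value) and marked as such in the file.
#'
#' @return File path of the JSON library.
#' @export
default_reference_library_path <- function() {
  system.file("extdata", "reference_library.json", package = "mwasdbs",
              mustWork = TRUE)
}
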