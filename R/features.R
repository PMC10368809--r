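## Cell-content (composition) features per compartment and assembly of the
## patient-level feature table.

#' Phenotype composition of a compartment
#'
#' Percentage of each phenotype class among the cells of one compartment
#' (%/sight). Because each panel images its own serial section, the
#' denominator for a class is the cell count of its panel within the
#' compartment.
#'
#' The unclassified `other` fraction, which exists on both panels, is pooled
#' over the two serial sections.
#'
#' @param cells Per-cell table (one section) with `panel`, `compartment`,
#'   `phenotype`.
#' @param compartment `"TN"` or `"TS"`.
#' @param classes Cell classes per panel.
#' @return Named percentages over all classes plus `other` (NA for a class
#'   whose panel has no cell in the compartment, with a warning).
#' @export
composition <- function(cells, compartment, classes = phenotypeClasses()) {
  out <- stats::setNames(
    rep(NA_real_, length(unlist(classes)) + 1L),
    c(unlist(classes), "other"))
  for (p in 1:2) {
    sub <- cells[cells$panel == p & cells$compartment == compartment, ,
                 drop = FALSE]
    if (!nrow(sub)) {
      warning(sprintf("no panel-%d cells in compartment %s", p, compartment))
      next
    }
    for (cl in classes[[p]])
      out[cl] <- 100 * sum(sub$phenotype == cl) / nrow(sub)
  }
  all <- cells[cells$compartment == compartment, , drop = FALSE]
  if (nrow(all))
    out["other"] <- 100 * sum(all$phenotype == "other") / nrow(all)
  out
}

#' Cell density of a compartment
#'
#' @param count Number of cells of interest in the compartment.
#' @param areaPx Compartment area in pixels (see [compartmentAreas()]).
#' @param pixelSizeUm Microns per pixel.
#' @return Cells per mm^2.
#' @export
#' @examples
#' cellDensity(10, 4e6, 0.5)  # 10 cells in 1 mm^2
cellDensity <- function(count, areaPx, pixelSizeUm) {
  if (areaPx <= 0) stop("compartment area must be > 0")
  count / (areaPx * pixelSizeUm^2 * 1e-6)
}

#' Compartment areas of a mask
#'
#' @param mask Compartment mask (0 non-tissue, 1 TN, 2 TS).
#' @return Named pixel counts for TN and TS.
#' @export
compartmentAreas <- function(mask) {
  c(TN = sum(mask == 1L), TS = sum(mask == 2L))
}

#' Ratio features between phenotype percentages
#'
#' @param comp Named percentage vector (e.g. from [composition()]).
#' @param pairs data.frame(num, den) of phenotype names; default the
#'   regulatory-to-helper T cell ratio Treg / CD4 T.
#' @return Named ratios (`<num>_over_<den>`); NA when the denominator is 0
#'   or missing.
#' @export
ratioFeatures <- function(comp,
                          pairs = data.frame(num = "Treg", den = "CD4_T")) {
  bad <- setdiff(c(pairs$num, pairs$den), names(comp))
  if (length(bad)) stop("unknown phenotype(s): ", paste(bad, collapse = ", "))
  vals <- mapply(function(n, d) {
    den <- comp[[d]]
    if (is.na(den) || den == 0) NA_real_ else comp[[n]] / den
  }, pairs$num, pairs$den)
  stats::setNames(as.numeric(vals),
                  paste0(pairs$num, "_over_", pairs$den))
}

#' Content features of one section
#'
#' The default content schema has 66 features: 11 classes x 2 compartments
#' x \{percentage, density\} (44), the 10 marker H-scores x 2 compartments
#' (20), and the Treg / CD4 T percentage ratio per compartment (2). The
#' published feature count is reproduced by this documented reconstruction;
#' the schema is configurable via `classes` and `ratios`.
#'
#' @param cells Per-cell table of one section (needs `fs_*` columns for the
#'   H-scores).
#' @param mask Compartment mask of the section.
#' @param pixelSizeUm Microns per pixel.
#' @param classes Cell classes per panel.
#' @param ratios Ratio pairs, see [ratioFeatures()].
#' @return Named numeric vector of content features.
#' @export
sectionContentFeatures <- function(cells, mask, pixelSizeUm,
                                   classes = phenotypeClasses(),
                                   ratios = data.frame(num = "Treg",
                                                       den = "CD4_T")) {
  areas <- compartmentAreas(mask)
  mk <- panelMarkers()
  out <- c()
  for (cmp in c("TN", "TS")) {
    pct <- suppressWarnings(composition(cells, cmp, classes))
    names(pct) <- paste0("pct_", names(pct), "_", cmp)
    cls <- c(unlist(classes), "other")
    dens <- sapply(cls, function(cl) {
      n <- sum(cells$phenotype == cl & cells$compartment == cmp)
      ## `other` occurs on both serial sections of the same geometry:
      ## average the two per-section densities
      if (cl == "other") n <- n / 2
      cellDensity(n, areas[[cmp]], pixelSizeUm)
    })
    names(dens) <- paste0("dens_", cls, "_", cmp)
    hs <- sapply(1:2, function(p) {
      sub <- cells[cells$panel == p & cells$compartment == cmp, ,
                   drop = FALSE]
      sapply(mk[[p]], function(m) hScoreFromLevels(sub[[paste0("fs_", m)]]))
    })
    hs <- unlist(hs)
    names(hs) <- paste0("hscore_", unlist(mk), "_", cmp)
    rat <- suppressWarnings(ratioFeatures(
      stats::setNames(pct, sub("_TN$|_TS$", "",
                               sub("^pct_", "", names(pct)))), ratios))
    names(rat) <- paste0("ratio_", names(rat), "_", cmp)
    out <- c(out, pct, dens, hs, rat)
  }
  out
}

#' Content features averaged over a patient's sections
#'
#' @param sections List of per-section named vectors from
#'   [sectionContentFeatures()].
#' @return Named vector; per feature, the mean over sections where defined.
#' @export
patientContentFeatures <- function(sections) {
  patientSpatialFeatures(sections)
}

#' Assemble the patient-level feature table
#'
#' Joins content features, spatial features and the clinical table by
#' patient id. Content and spatial feature counts are reported via a
#' message. Patients missing from the spatial table keep their row with
#' missing spatial cells; a clinical/content id mismatch is an error that
#' names the offenders.
#'
#' @param content data.frame of content features with `patient_id`.
#' @param spatial data.frame of spatial features with `patient_id` (or
#'   NULL).
#' @param clinical Clinical data.frame with `patient_id`.
#' @return Merged data.frame, one row per patient.
#' @export
assembleFeatureTable <- function(content, spatial, clinical) {
  mismatch <- c(setdiff(clinical$patient_id, content$patient_id),
                setdiff(content$patient_id, clinical$patient_id))
  if (length(mismatch))
    stop("patient id mismatch between clinical and content tables: ",
         paste(unique(mismatch), collapse = ", "))
  out <- merge(clinical, content, by = "patient_id", sort = TRUE)
  nSpat <- 0L
  if (!is.null(spatial)) {
    out <- merge(out, spatial, by = "patient_id", all.x = TRUE, sort = TRUE)
    nSpat <- ncol(spatial) - 1L
  }
  message(sprintf("feature table: %d content + %d spatial features, %d patients",
                  ncol(content) - 1L, nSpat, nrow(out)))
  out
}

#' Write / read a feature table
#'
#' CSV round-trip with the empty field as the missing-value sentinel (never
#' zero-imputed).
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return `readFeatureTable` returns the data.frame.
#' @export
writeFeatureTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = "", check.names = FALSE)
}
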