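## TIFF / CSV / JSON input-output for scenes, masks and cell tables.

#' Write / read a multi-channel TIFF
#'
#' Channels are stored as 32-bit pages, DAPI first then the five markers in
#' panel order. Intensities are divided by `fullScale` on write (TIFF pages
#' hold values in [0, 1]) and multiplied back on read; the same `fullScale`
#' must be used for both directions.
#'
#' @param channels Named list of numeric matrices.
#' @param path File path.
#' @param fullScale Full-scale intensity of the stored unit range; values
#'   above it are clamped with a warning.
#' @return `readChannelTiff` returns the named list (names from `names`
#'   when supplied).
#' @export
writeChannelTiff <- function(channels, path, fullScale = 16) {
  if (max(unlist(lapply(channels, max))) > fullScale)
    warning("intensities above fullScale are clamped")
  scaled <- lapply(channels, function(ch) pmin(ch / fullScale, 1))
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeChannelTiff
#' @param names Channel names to assign on read.
#' @export
readChannelTiff <- function(path, names = NULL, fullScale = 16) {
  pages <- lapply(tiff::readTIFF(path, all = TRUE), function(p) p * fullScale)
  if (!is.null(names)) names(pages) <- names
  pages
}

#' Write / read an integer label TIFF
#'
#' Label masks (nucleus ids or compartment codes) are stored as 16-bit
#' pages; ids must not exceed 65535.
#'
#' @param mask Integer matrix.
#' @param path File path.
#' @return `readLabelTiff` returns the integer matrix.
#' @export
writeLabelTiff <- function(mask, path) {
  if (max(mask) > 65535L) stop("label ids exceed the 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelTiff
#' @export
readLabelTiff <- function(path) {
  m <- tiff::readTIFF(path)
  out <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  out
}

#' Write a scene to disk
#'
#' Per panel: a multi-page channel TIFF (page 1 DAPI, pages 2-6 markers in
#' panel order) and a ground-truth label TIFF; plus the shared compartment
#' TIFF and a `truth_cells.csv` with both panels' cell records.
#'
#' @param scene A [MifScene-class] with rendered channels.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
writeScene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  cellRows <- list()
  for (p in 1:2) {
    ch <- panelChannels(scene, p)
    if (length(ch)) {
      f <- file.path(dir, sprintf("%s_panel%d.tif", prefix, p))
      writeChannelTiff(ch, f)
      paths[sprintf("panel%d", p)] <- f
    }
    f <- file.path(dir, sprintf("%s_nuclei%d.tif", prefix, p))
    writeLabelTiff(nucleusLabels(scene, p), f)
    paths[sprintf("nuclei%d", p)] <- f
    cellRows[[p]] <- truthCells(scene, p)
  }
  f <- file.path(dir, paste0(prefix, "_compartments.tif"))
  writeLabelTiff(compartmentMask(scene), f)
  paths["compartments"] <- f
  f <- file.path(dir, paste0(prefix, "_truth_cells.csv"))
  cells <- merge(cellRows[[1]], cellRows[[2]], all = TRUE, sort = FALSE,
                 by = intersect(names(cellRows[[1]]), names(cellRows[[2]])))
  utils::write.csv(cells[order(cells$panel, cells$cell_id), ], f,
                   row.names = FALSE, na = "")
  paths["truth_cells"] <- f
  invisible(paths)
}

#' Write a cohort's clinical table and scenes
#'
#' @param cohort Output of [generateCohort()].
#' @param dir Output directory.
#' @return Invisibly, the path of `clinical.csv`.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, "clinical.csv")
  utils::write.csv(cohort$clinical, f, row.names = FALSE, na = "")
  utils::write.csv(cohort$features, file.path(dir, "truth_features.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(cohort$scenes))
    for (pt in names(cohort$scenes))
      for (s in seq_along(cohort$scenes[[pt]]))
        writeScene(cohort$scenes[[pt]][[s]], file.path(dir, pt),
                   prefix = sprintf("section%d", s))
  invisible(f)
}

#' Read marker thresholds from JSON
#'
#' @param path JSON file mapping marker name to positive threshold Z.
#' @return Named numeric vector.
#' @export
readThresholds <- function(path) {
  z <- unlist(jsonlite::read_json(path))
  if (any(z <= 0)) stop("thresholds Z must be > 0")
  z
}
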