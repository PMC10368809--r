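## Per-cell marker quantification: fluorescence-field extraction, field /
## nucleus intersection, Z / 2Z / 3Z fluorescence-strength binning, H-score,
## phenotype and compartment assignment.

#' Extract the fluorescence field of a channel
#'
#' Returns the coordinates of pixels whose intensity exceeds the
#' `backgroundQuantile` of the channel (the CF, coordinates of fields with
#' fluorescence).
#'
#' @param channel Numeric matrix.
#' @param backgroundQuantile Background quantile in (0, 1]; `0` degenerately
#'   selects every pixel and warns.
#' @return Logical matrix marking field pixels.
#' @export
extractFluorescence <- function(channel, backgroundQuantile = 0.95) {
  if (backgroundQuantile < 0 || backgroundQuantile > 1)
    stop("backgroundQuantile must be in [0, 1]")
  if (backgroundQuantile == 0) {
    warning("backgroundQuantile 0: every pixel selected")
    return(matrix(TRUE, nrow(channel), ncol(channel)))
  }
  thr <- stats::quantile(channel, backgroundQuantile, names = FALSE)
  field <- channel > thr
  if (!any(field) && diff(range(channel)) == 0)
    warning("constant channel: empty fluorescence field")
  field
}

#' Intersect a fluorescence field with nucleus coordinates
#'
#' Attributes fluorescent pixels to cells: a field pixel belongs to a cell
#' iff it falls inside that nucleus dilated by `dilationPx` (dilated zones
#' are grown competitively, so a pixel reachable from two nuclei goes to the
#' nearer one). Unattributed field pixels are discarded as non-specific
#' signal. Returns the mean channel intensity of each cell's attributed
#' pixels (0 if a cell has none).
#'
#' @param channel Numeric matrix of marker intensities.
#' @param nuclei Integer label mask (the CCN).
#' @param field Logical matrix from [extractFluorescence()]; computed from
#'   `channel` when missing.
#' @param dilationPx Dilation radius in pixels (default 2, ~1 um at
#'   0.5 um/px, capturing membrane/cytoplasmic staining around the nucleus).
#' @return Named numeric vector of mean intensities, one entry per nucleus id.
#' @export
intersectCfCcn <- function(channel, nuclei,
                           field = extractFluorescence(channel),
                           dilationPx = 2L) {
  if (!identical(dim(channel), dim(nuclei)) ||
      !identical(dim(field), dim(nuclei)))
    stop("channel, field and nuclei must have the same shape")
  if (dilationPx < 0) stop("dilationPx must be >= 0")
  ids <- sort(unique(nuclei[nuclei > 0L]))
  out <- stats::setNames(numeric(length(ids)), ids)
  if (!length(ids)) return(out)
  zones <- if (dilationPx > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilationPx) + 1L, "disc")
    mask <- EBImage::dilate(EBImage::Image(nuclei > 0L), brush)
    as.matrix(EBImage::imageData(EBImage::propagate(
      EBImage::Image(channel), EBImage::Image(nuclei), mask)))
  } else nuclei
  idx <- which(field & zones > 0)
  if (length(idx)) {
    sums <- tapply(channel[idx], zones[idx], sum)
    cnts <- tapply(rep(1, length(idx)), zones[idx], sum)
    out[names(sums)] <- sums / cnts
  }
  out
}

#' Assign a fluorescence-strength level
#'
#' Bins a mean intensity against the marker's positive threshold Z:
#' below Z negative, [Z, 2Z) low, [2Z, 3Z) median, at or above 3Z high.
#' Boundary values belong to the upper bin.
#'
#' @param intensity Non-negative numeric vector of mean intensities.
#' @param Z Positive threshold.
#' @return Character vector with levels `neg`, `low`, `med`, `high`.
#' @export
#' @examples
#' assignFsLevel(c(0, 1, 2, 3.5), Z = 1)
assignFsLevel <- function(intensity, Z) {
  if (Z <= 0) stop("Z must be > 0")
  if (any(intensity < 0)) stop("negative intensity")
  .fsLevels[findInterval(intensity, c(Z, 2 * Z, 3 * Z)) + 1L]
}

#' Histochemistry score
#'
#' H-score = \%low x 1 + \%median x 2 + \%high x 3, on the 0-100 percentage
#' scale, giving a score in [0, 300].
#'
#' @param fracLow,fracMed,fracHigh Percentages of cells at each FS level
#'   (non-negative, summing to at most 100).
#' @return H-score in [0, 300].
#' @export
#' @examples
#' hScore(50, 30, 20)  # 170
hScore <- function(fracLow, fracMed, fracHigh) {
  if (any(c(fracLow, fracMed, fracHigh) < 0)) stop("fractions must be >= 0")
  if (fracLow + fracMed + fracHigh > 100 + 1e-9)
    stop("FS fractions sum to more than 100%")
  fracLow * 1 + fracMed * 2 + fracHigh * 3
}

#' H-score from per-cell FS levels
#'
#' @param fs Character vector of FS levels over the cells of interest.
#' @return H-score in [0, 300], or NA for an empty input.
#' @export
hScoreFromLevels <- function(fs) {
  if (!length(fs)) return(NA_real_)
  p <- 100 * c(mean(fs == "low"), mean(fs == "med"), mean(fs == "high"))
  hScore(p[1], p[2], p[3])
}

#' Default phenotype-calling rule tables
#'
#' Ordered rules; the first matching rule wins. Panel 1: CD4+FOXP3+ Treg,
#' then CD4+ T, CD38+ activated T, CD20+ B, CD66b+ neutrophil. Panel 2:
#' CD68+CD163+ M2 macrophage, then CD68+ macrophage, CD8+ T, CD133+ cancer
#' stem cell, and PD-L1+ for cells matching no other rule. Cells matching
#' nothing are `other`. "Positive" means FS level above negative.
#'
#' @param panel Panel index (1 or 2).
#' @return data.frame with columns `phenotype` and `requires` (list column
#'   of marker sets).
#' @export
phenotypeRules <- function(panel) {
  if (panel == 1L)
    data.frame(phenotype = c("Treg", "CD4_T", "activated_T", "B",
                             "neutrophil"),
               requires = I(list(c("CD4", "FOXP3"), "CD4", "CD38", "CD20",
                                 "CD66b")))
  else
    data.frame(phenotype = c("M2_macrophage", "macrophage", "CD8_T", "CSC",
                             "PDL1_pos"),
               requires = I(list(c("CD68", "CD163"), "CD68", "CD8", "CD133",
                                 "PDL1")))
}

#' Call cell phenotypes from FS levels
#'
#' @param fs data.frame or matrix of per-cell FS levels with one column per
#'   marker (values `neg`/`low`/`med`/`high`).
#' @param rules Ordered rule table from [phenotypeRules()].
#' @return Character vector of phenotype labels (`other` when no rule
#'   matches).
#' @export
callPhenotype <- function(fs, rules) {
  fs <- as.data.frame(fs, stringsAsFactors = FALSE)
  need <- unique(unlist(rules$requires))
  missing <- setdiff(need, colnames(fs))
  if (length(missing))
    stop("marker(s) missing from FS table: ", paste(missing, collapse = ", "))
  out <- rep("other", nrow(fs))
  undecided <- rep(TRUE, nrow(fs))
  for (r in seq_len(nrow(rules))) {
    req <- rules$requires[[r]]
    hit <- Reduce(`&`, lapply(req, function(m) fs[[m]] != "neg"))
    sel <- undecided & hit
    out[sel] <- rules$phenotype[r]
    undecided[sel] <- FALSE
  }
  out
}

#' Assign a cell to a tissue compartment
#'
#' @param x,y Centroid coordinates in pixels (1-based; rounded to the
#'   nearest pixel).
#' @param mask Compartment mask: 0 non-tissue, 1 TN, 2 TS.
#' @return Character vector: `TN`, `TS` or `excluded` (non-tissue; such
#'   cells are dropped downstream).
#' @export
assignCompartment <- function(x, y, mask) {
  xi <- round(x); yi <- round(y)
  if (any(xi < 1 | xi > ncol(mask) | yi < 1 | yi > nrow(mask)))
    stop("centroid out of raster bounds")
  c("excluded", "TN", "TS")[mask[cbind(yi, xi)] + 1L]
}

#' Otsu threshold of a numeric vector
#'
#' Maximizes between-class variance over a 256-bin histogram; used as the
#' default per-marker positive threshold Z when none is supplied (in the
#' study design Z is set by pathologists and is a required config input for
#' real data).
#'
#' @param x Numeric vector.
#' @return Threshold value.
#' @export
otsuThreshold <- function(x) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(findInterval(x, seq(rng[1], rng[2], length.out = 257),
                             rightmost.closed = TRUE), 256)
  mids <- seq(rng[1], rng[2], length.out = 257)[-257] + diff(rng) / 512
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  bc <- w1 * w2 * (m1 - m2)^2
  bc[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(bc)]
}

#' Quantify a scene into a per-cell record table
#'
#' Runs the full quantification chain for both panels of a scene: field
#' extraction, field/nucleus intersection, FS binning against the marker
#' thresholds, phenotype calling and compartment assignment.
#'
#' @param scene A [MifScene-class] with rendered channels.
#' @param thresholds Named positive thresholds Z per marker; when NULL, an
#'   Otsu threshold on each marker's per-cell mean intensity distribution is
#'   used and a message is emitted.
#' @param nuclei Optional list of two label masks overriding the scene's
#'   ground-truth masks (e.g. output of [detectNuclei()]).
#' @param backgroundQuantile Passed to [extractFluorescence()].
#' @param dilationPx Passed to [intersectCfCcn()].
#' @return data.frame with one row per cell: ids, centroid (px and um),
#'   compartment, per-marker mean intensity (`int_*`) and FS level (`fs_*`),
#'   phenotype and the independent PD-L1 positivity flag.
#' @export
quantifyScene <- function(scene, thresholds = NULL, nuclei = NULL,
                          backgroundQuantile = 0.95, dilationPx = 2L) {
  stopifnot(is(scene, "MifScene"))
  mk <- panelMarkers()
  res <- vector("list", 2L)
  for (p in 1:2) {
    chans <- panelChannels(scene, p)
    if (!length(chans)) stop("scene has no rendered channels (render = FALSE?)")
    lab <- if (is.null(nuclei)) nucleusLabels(scene, p) else nuclei[[p]]
    ids <- sort(unique(lab[lab > 0L]))
    markers <- mk[[p]]
    ints <- matrix(0, length(ids), length(markers),
                   dimnames = list(NULL, markers))
    for (m in markers)
      ints[, m] <- intersectCfCcn(chans[[m]], lab,
                                  extractFluorescence(chans[[m]],
                                                      backgroundQuantile),
                                  dilationPx)[as.character(ids)]
    fs <- matrix("neg", length(ids), length(markers),
                 dimnames = list(NULL, markers))
    for (m in markers) {
      Z <- if (is.null(thresholds)) {
        z <- otsuThreshold(ints[, m])
        message(sprintf("Otsu threshold for %s: %.3f", m, z))
        z
      } else thresholds[[m]]
      if (is.null(Z) || !is.finite(Z) || Z <= 0)
        stop("no positive threshold Z for marker ", m)
      fs[, m] <- assignFsLevel(ints[, m], Z)
    }
    cent <- .labelCentroids(lab, ids)
    df <- data.frame(cell_id = ids, panel = p,
                     x_px = cent[, 1], y_px = cent[, 2],
                     x_um = cent[, 1] * pixelSize(scene),
                     y_um = cent[, 2] * pixelSize(scene),
                     compartment = assignCompartment(cent[, 1], cent[, 2],
                                                     compartmentMask(scene)),
                     stringsAsFactors = FALSE)
    for (m in markers) df[[paste0("int_", m)]] <- ints[, m]
    for (m in markers) df[[paste0("fs_", m)]] <- fs[, m]
    df$phenotype <- callPhenotype(fs, phenotypeRules(p))
    df$pdl1 <- if ("PDL1" %in% markers) fs[, "PDL1"] != "neg" else NA
    res[[p]] <- df
  }
  out <- merge(res[[1]], res[[2]], all = TRUE, sort = FALSE,
               by = intersect(names(res[[1]]), names(res[[2]])))
  out[order(out$panel, out$cell_id), , drop = FALSE]
}

.labelCentroids <- function(lab, ids) {
  idx <- which(lab > 0L)
  v <- lab[idx]
  row <- (idx - 1L) %% nrow(lab) + 1L
  col <- (idx - 1L) %/% nrow(lab) + 1L
  cbind(tapply(col, v, mean)[as.character(ids)],
        tapply(row, v, mean)[as.character(ids)])
}
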