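## Synthetic mIF scene generation: compartment geometry, Gibbs cell
## placement, star-convex nuclei, channel rendering.

#' Default marker intensity model
#'
#' Per-marker positive threshold `Z` (arbitrary fluorescence units; 1 for
#' every marker by default), the representative intensity of each
#' fluorescence-strength level as a multiple of `Z` (placed at the centre of
#' the low/median bins and above the high threshold), the lognormal spread of
#' per-cell intensities (`sigma`, sd on the log scale), additive background
#' noise, Gaussian blur, the DAPI level of nucleus pixels, and the
#' distribution of true FS levels among marker-positive cells.
#'
#' Setting `sigma`, `backgroundSd` and `blurSigma` to 0 yields a noiseless
#' scene where every positive nucleus renders exactly its representative
#' intensity.
#'
#' @return Named list of intensity-model parameters.
#' @export
defaultIntensityModel <- function() {
  mk <- unlist(panelMarkers(), use.names = FALSE)
  list(Z = stats::setNames(rep(1, length(mk)), mk),
       levelMeans = c(low = 1.5, med = 2.5, high = 3.6),
       sigma = 0.08, backgroundSd = 0.01, blurSigma = 1,
       dapiLevel = 1, fsProbs = c(low = 0.35, med = 0.40, high = 0.25))
}

#' Specify a synthetic mIF scene
#'
#' Constructs a validated [SceneSpec-class]. The default scene is 1024 x 768
#' px at 0.5 um/px, a compromise that keeps whole-pipeline simulations fast;
#' `fullRes = TRUE` switches to the 4028 x 3012 px full-slide-resolution
#' geometry of a scanned whole-slide image.
#'
#' @param width,height Raster size, pixels.
#' @param pixelSize Microns per pixel.
#' @param nCells Cells per section.
#' @param nestCount Number of tumour-nest blobs.
#' @param nestRadiusRange Range of nest radii, microns.
#' @param marginFrac Non-tissue border, as a fraction of the shorter side.
#' @param mixture Named phenotype fractions summing to 1; see
#'   [defaultMixture()].
#' @param interactions data.frame with columns `a`, `b`, `strength`:
#'   pairwise attraction (> 0) / repulsion (< 0) between phenotype classes.
#' @param interactionRange Range of the pairwise potential, microns.
#' @param nucleusRadius Base nucleus radius, microns.
#' @param radiusJitter Relative jitter of the eight star-polygon ray radii.
#' @param hardCore Minimum distance between cell centres, microns; defaults
#'   to the mean nucleus diameter.
#' @param sweeps Metropolis sweeps of the Gibbs sampler.
#' @param intensity Intensity model, see [defaultIntensityModel()].
#' @param fullRes Use the 4028 x 3012 full-slide raster.
#' @param seed Integer seed (or NA to inherit the session RNG state).
#' @return A [SceneSpec-class] object.
#' @export
#' @examples
#' spec <- sceneSpec(nCells = 50, seed = 1)
#' spec
sceneSpec <- function(width = 1024L, height = 768L, pixelSize = 0.5,
                      nCells = 500L, nestCount = 5L,
                      nestRadiusRange = c(40, 90), marginFrac = 0.03,
                      mixture = defaultMixture(),
                      interactions = data.frame(a = character(0),
                                                b = character(0),
                                                strength = numeric(0)),
                      interactionRange = 30, nucleusRadius = 3.5,
                      radiusJitter = 0.3, hardCore = 2 * nucleusRadius,
                      sweeps = 2000L, intensity = defaultIntensityModel(),
                      fullRes = FALSE, seed = NA_integer_) {
  if (isTRUE(fullRes)) { width <- 4028L; height <- 3012L }
  new("SceneSpec", width = as.integer(width), height = as.integer(height),
      pixelSize = pixelSize, nCells = as.integer(nCells),
      nestCount = as.integer(nestCount),
      nestRadiusRange = as.numeric(nestRadiusRange),
      marginFrac = marginFrac, mixture = mixture,
      interactions = interactions, interactionRange = interactionRange,
      nucleusRadius = nucleusRadius, radiusJitter = radiusJitter,
      hardCore = hardCore, sweeps = as.integer(sweeps),
      intensity = intensity, seed = as.integer(seed))
}

## Tumour-nest blobs inside the tissue rectangle; 0 non-tissue, 1 TN, 2 TS.
.makeCompartmentMask <- function(spec) {
  h <- spec@height; w <- spec@width
  m <- ceiling(spec@marginFrac * min(h, w))
  mask <- matrix(0L, h, w)
  mask[(m + 1):(h - m), (m + 1):(w - m)] <- 2L
  rr <- spec@nestRadiusRange / spec@pixelSize
  ## nests must fit the tissue rectangle on small test scenes
  rr <- pmin(rr, (min(h, w) - 2 * m) / 3)
  xg <- matrix(seq_len(w), h, w, byrow = TRUE)
  yg <- matrix(seq_len(h), h, w)
  for (k in seq_len(spec@nestCount)) {
    r <- stats::runif(1, rr[1], rr[2])
    cx <- stats::runif(1, m + r, w - m - r)
    cy <- stats::runif(1, m + r, h - m - r)
    inside <- (xg - cx)^2 + (yg - cy)^2 <= r^2
    mask[inside & mask > 0L] <- 1L
  }
  mask
}

## Sequential hard-core darts on tissue pixels; errors if packing fails.
.initialPositions <- function(n, tissueXY, hardCore, pixelSize) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  hc2 <- hardCore^2
  px <- numeric(n); py <- numeric(n)
  placed <- 0L
  tries <- 0L; maxTries <- 400L * n
  m <- nrow(tissueXY)
  while (placed < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop(sprintf(
        "infeasible packing: placed %d of %d cells (density %.3g cells/um^2 with hard core %.1f um)",
        placed, n, n / (m * pixelSize^2), hardCore))
    idx <- sample.int(m, 1L)
    x <- tissueXY[idx, 1] + (stats::runif(1) - 0.5) * pixelSize
    y <- tissueXY[idx, 2] + (stats::runif(1) - 0.5) * pixelSize
    if (placed > 0L) {
      d2 <- (px[seq_len(placed)] - x)^2 + (py[seq_len(placed)] - y)^2
      if (min(d2) < hc2) next
    }
    placed <- placed + 1L
    px[placed] <- x; py[placed] <- y
  }
  cbind(px, py)
}

## Place one section's cells: darts, then Metropolis sweeps if any
## interaction term is non-zero.
.placeCells <- function(spec, phen, tissueXY) {
  xy <- .initialPositions(length(phen), tissueXY, spec@hardCore,
                          spec@pixelSize)
  it <- spec@interactions
  if (length(phen) && nrow(it) && any(it$strength != 0)) {
    classes <- sort(unique(c(names(spec@mixture), it$a, it$b)))
    bad <- setdiff(c(it$a, it$b), names(spec@mixture))
    if (length(bad))
      stop("interaction references unknown phenotype(s): ",
           paste(unique(bad), collapse = ", "))
    S <- matrix(0, length(classes), length(classes),
                dimnames = list(classes, classes))
    for (r in seq_len(nrow(it))) {
      S[it$a[r], it$b[r]] <- S[it$a[r], it$b[r]] + it$strength[r]
      S[it$b[r], it$a[r]] <- S[it$a[r], it$b[r]]
    }
    code <- match(phen, classes) - 1L
    xy <- .gibbsSweeps(xy, code, S, spec@interactionRange, spec@hardCore,
                       spec@sweeps, tissueXY, spec@pixelSize)
  }
  xy
}

## Rasterize star-convex 8-ray nuclei. Contested pixels go to the nearer
## centroid, keeping nuclei pairwise disjoint. Returns the label matrix.
.rasterizeNuclei <- function(spec, xyPx) {
  h <- spec@height; w <- spec@width
  labels <- matrix(0L, h, w)
  if (!nrow(xyPx)) return(labels)
  claim <- matrix(Inf, h, w)   # squared distance to the owning centroid
  rBase <- spec@nucleusRadius / spec@pixelSize
  jit <- spec@radiusJitter
  dAng <- pi / 4
  for (i in seq_len(nrow(xyPx))) {
    rot <- stats::runif(1, 0, dAng)
    radii <- rBase * (1 + stats::runif(8, -jit, jit))
    rMax <- max(radii)
    cx <- xyPx[i, 1]; cy <- xyPx[i, 2]
    x0 <- max(1L, floor(cx - rMax)); x1 <- min(w, ceiling(cx + rMax))
    y0 <- max(1L, floor(cy - rMax)); y1 <- min(h, ceiling(cy + rMax))
    xs <- x0:x1; ys <- y0:y1
    dx <- rep(xs - cx, each = length(ys))
    dy <- rep(ys - cy, times = length(xs))
    rho2 <- dx^2 + dy^2
    phi <- (atan2(dy, dx) - rot) %% (2 * pi)
    k <- pmin(floor(phi / dAng), 7)
    t <- phi - k * dAng
    r1 <- radii[k + 1]; r2 <- radii[(k + 1) %% 8 + 1]
    ## straight polygon edge between consecutive rays, in polar form
    rb <- r1 * r2 * sin(dAng) / (r1 * sin(t) + r2 * sin(dAng - t))
    inside <- rho2 <= rb^2
    if (!any(inside)) next
    rows <- rep(ys, times = length(xs))[inside]
    cols <- rep(xs, each = length(ys))[inside]
    idx <- cbind(rows, cols)
    take <- rho2[inside] < claim[idx]
    if (any(take)) {
      idx <- idx[take, , drop = FALSE]
      labels[idx] <- i
      claim[idx] <- rho2[inside][take]
    }
  }
  labels
}

## Sample true FS levels for one section's cells on one panel.
.sampleMarkerTruth <- function(phen, markers, fsProbs) {
  out <- matrix("neg", length(phen), length(markers),
                dimnames = list(NULL, markers))
  lv <- names(fsProbs)
  for (i in seq_along(phen)) {
    pos <- intersect(.phenotypePositiveMarkers[[phen[i]]], markers)
    if (length(pos))
      out[i, pos] <- sample(lv, length(pos), replace = TRUE, prob = fsProbs)
  }
  out
}

## Render DAPI + marker channels for one panel.
.renderChannels <- function(spec, labels, fsTruth, markers) {
  h <- spec@height; w <- spec@width
  im <- spec@intensity
  Z <- im$Z
  idxByCell <- split(seq_along(labels), labels)
  idxByCell[["0"]] <- NULL
  chans <- vector("list", length(markers) + 1L)
  names(chans) <- c("DAPI", markers)
  dapi <- matrix(0, h, w)
  for (nm in names(idxByCell)) dapi[idxByCell[[nm]]] <- im$dapiLevel
  chans[["DAPI"]] <- .finishChannel(dapi, im)
  for (mk in markers) {
    ch <- matrix(0, h, w)
    for (nm in names(idxByCell)) {
      cellI <- as.integer(nm)
      lev <- fsTruth[cellI, mk]
      if (lev == "neg") next
      mu <- im$levelMeans[[lev]] * Z[[mk]]
      val <- if (im$sigma > 0) stats::rlnorm(1, log(mu), im$sigma) else mu
      ch[idxByCell[[nm]]] <- val
    }
    chans[[mk]] <- .finishChannel(ch, im)
  }
  chans
}

.finishChannel <- function(ch, im) {
  if (im$blurSigma > 0)
    ch <- as.matrix(EBImage::gblur(EBImage::Image(ch), sigma = im$blurSigma))
  if (im$backgroundSd > 0)
    ch <- ch + matrix(stats::rnorm(length(ch), 0, im$backgroundSd),
                      nrow(ch), ncol(ch))
  pmax(ch, 0)
}

#' Generate a synthetic mIF scene
#'
#' Generates two serial-section panels that share the tumour-nest/stroma
#' compartment geometry but have independently placed cells (each panel is a
#' different 4-um physical slice, so cell coordinates cannot correspond
#' across panels). Cells are placed by a hard-core dart process followed by
#' Metropolis sweeps under the pairwise Gibbs potential of
#' `spec@interactions`; nuclei are star-convex eight-ray polygons; marker
#' channels render phenotype-conditioned lognormal intensities with optional
#' blur and background noise.
#'
#' @param spec A [SceneSpec-class].
#' @param render Render channel rasters? With `FALSE` only label masks and
#'   ground-truth cell tables are produced (fast path for spatial-statistics
#'   simulations).
#' @param seed Seed; defaults to `spec@seed`. Identical spec + seed give
#'   bit-identical output.
#' @return A [MifScene-class].
#' @export
#' @examples
#' sc <- generateScene(sceneSpec(nCells = 40, seed = 7), render = FALSE)
#' head(truthCells(sc, 1))
generateScene <- function(spec, render = TRUE, seed = spec@seed) {
  validObject(spec)
  if (!is.na(seed)) set.seed(seed)
  mask <- .makeCompartmentMask(spec)
  tissueIdx <- which(mask > 0L)
  tissueXY <- cbind(((tissueIdx - 1L) %/% spec@height) + 1L,   # x (col)
                    ((tissueIdx - 1L) %% spec@height) + 1L)    # y (row)
  tissueXY <- tissueXY * spec@pixelSize
  mk <- panelMarkers()
  panels <- vector("list", 2L)
  for (p in 1:2) {
    phen <- if (spec@nCells > 0L)
      sample(names(spec@mixture), spec@nCells, replace = TRUE,
             prob = spec@mixture) else character(0)
    xyUm <- .placeCells(spec, phen, tissueXY)
    xyPx <- xyUm / spec@pixelSize
    labels <- .rasterizeNuclei(spec, xyPx)
    markers <- mk[[p]]
    fsTruth <- .sampleMarkerTruth(phen, markers, spec@intensity$fsProbs)
    comp <- if (nrow(xyPx))
      mask[cbind(pmin(pmax(round(xyPx[, 2]), 1L), spec@height),
                 pmin(pmax(round(xyPx[, 1]), 1L), spec@width))] else integer(0)
    cells <- data.frame(
      cell_id = seq_along(phen), panel = rep(p, length(phen)),
      x_px = xyPx[, 1], y_px = xyPx[, 2],
      x_um = xyUm[, 1], y_um = xyUm[, 2],
      compartment = c("non-tissue", "TN", "TS")[comp + 1L],
      phenotype = phen, stringsAsFactors = FALSE)
    for (m in markers) cells[[paste0("fs_", m)]] <- fsTruth[, m]
    channels <- if (render) .renderChannels(spec, labels, fsTruth, markers)
                else list()
    panels[[p]] <- list(channels = channels, labels = labels, cells = cells)
  }
  new("MifScene", panels = panels, compartmentMask = mask,
      pixelSize = spec@pixelSize,
      seed = if (is.na(seed)) NA_integer_ else as.integer(seed))
}
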