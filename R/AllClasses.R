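## S4 classes for scenes, cohorts and result containers.

#' SceneSpec: parameters of a synthetic mIF scene
#'
#' Describes one synthetic multiplex-immunofluorescence scene: raster geometry,
#' tumour-nest/stroma compartments, the phenotype mixture, pairwise phenotype
#' interactions (Gibbs attraction/repulsion), and the marker intensity model.
#' Build with [sceneSpec()].
#'
#' @slot width,height Raster size in pixels.
#' @slot pixelSize Microns per pixel.
#' @slot nCells Number of cells per section.
#' @slot nestCount Number of tumour-nest blobs.
#' @slot nestRadiusRange Min/max nest radius in microns.
#' @slot marginFrac Non-tissue border as a fraction of the shorter side.
#' @slot mixture Named phenotype fractions summing to 1.
#' @slot interactions data.frame(a, b, strength): attraction (> 0) or
#'   repulsion (< 0) between two phenotype classes.
#' @slot interactionRange Range of the pairwise Gibbs potential, microns.
#' @slot nucleusRadius Base nucleus radius in microns.
#' @slot radiusJitter Relative jitter of the star-polygon ray radii.
#' @slot hardCore Hard-core distance between cell centres, microns.
#' @slot sweeps Metropolis sweeps of the Gibbs sampler.
#' @slot intensity Intensity model (see [sceneSpec()]).
#' @slot seed Integer seed or NA.
#' @export
setClass("SceneSpec", representation(
  width = "integer", height = "integer", pixelSize = "numeric",
  nCells = "integer", nestCount = "integer", nestRadiusRange = "numeric",
  marginFrac = "numeric", mixture = "numeric", interactions = "data.frame",
  interactionRange = "numeric", nucleusRadius = "numeric",
  radiusJitter = "numeric", hardCore = "numeric", sweeps = "integer",
  intensity = "list", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character(0)
  if (object@width < 1L || object@height < 1L)
    msg <- c(msg, "width and height must be positive")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (abs(sum(object@mixture) - 1) > 1e-9)
    msg <- c(msg, "phenotype mixture must sum to 1")
  if (any(object@mixture < 0)) msg <- c(msg, "mixture fractions must be >= 0")
  bad <- setdiff(names(object@mixture),
                 c(names(.phenotypePanel), "other"))
  if (length(bad))
    msg <- c(msg, paste("unknown phenotype(s) in mixture:",
                        paste(bad, collapse = ", ")))
  ## packing feasibility: total maximal nucleus area must fit in the scene
  maxRadPx <- object@nucleusRadius * (1 + object@radiusJitter) / object@pixelSize
  if (object@nCells * pi * maxRadPx^2 >= object@width * object@height)
    msg <- c(msg, sprintf(
      "packing infeasible: %d cells of max area %.0f px^2 exceed the %d x %d scene",
      object@nCells, pi * maxRadPx^2, object@width, object@height))
  if (length(msg)) msg else TRUE
})

#' MifScene: a synthetic scene with ground truth
#'
#' Two serial-section panels (shared compartment geometry, independently
#' placed cells) with rendered channel rasters, ground-truth nucleus label
#' masks and per-cell truth tables. Created by [generateScene()].
#'
#' @slot panels List of two lists with elements `channels` (named list of
#'   matrices; empty when the scene was generated with `render = FALSE`),
#'   `labels` (integer matrix) and `cells` (data.frame).
#' @slot compartmentMask Integer matrix: 0 non-tissue, 1 tumour nest (TN),
#'   2 tumour stroma (TS).
#' @slot pixelSize Microns per pixel.
#' @slot seed Seed used for generation.
#' @export
setClass("MifScene", representation(
  panels = "list", compartmentMask = "matrix",
  pixelSize = "numeric", seed = "integer"))

setValidity("MifScene", function(object) {
  msg <- character(0)
  if (length(object@panels) != 2L) msg <- c(msg, "a scene has exactly 2 panels")
  for (p in seq_along(object@panels)) {
    pl <- object@panels[[p]]
    if (!all(c("channels", "labels", "cells") %in% names(pl))) {
      msg <- c(msg, sprintf("panel %d lacks channels/labels/cells", p))
      next
    }
    ids <- sort(unique(as.vector(pl$labels)))
    ids <- ids[ids > 0]
    if (length(ids) && !all(ids %in% pl$cells$cell_id))
      msg <- c(msg, sprintf("panel %d: label ids missing from cell table", p))
  }
  if (length(msg)) msg else TRUE
})

#' CohortSpec: parameters of a synthetic patient cohort
#'
#' Build with [cohortSpec()]. Holds stage prevalences, stage-dependent
#' composition shifts, the proportional-hazards coefficient vector and
#' censoring model, plus the [SceneSpec-class] shared by all sections.
#'
#' @slot nPatients Number of patients.
#' @slot sectionsPerPatient Sections (panel pairs) per patient.
#' @slot stagePrevalence Named prevalences of `IA-IIA` and `IIB-IIIB`.
#' @slot compositionShift Named additive deltas applied to the phenotype
#'   mixture of `IIB-IIIB` patients (balanced against `other`).
#' @slot beta Named log-hazard coefficients over features/covariates.
#' @slot baselineShape,baselineScale Weibull baseline hazard parameters
#'   (time in days).
#' @slot censoringRate Probability that a subject is randomly censored.
#' @slot adminCap Administrative censoring time, days.
#' @slot sceneSpec The per-section [SceneSpec-class].
#' @slot seed Integer seed or NA.
#' @export
setClass("CohortSpec", representation(
  nPatients = "integer", sectionsPerPatient = "integer",
  stagePrevalence = "numeric", compositionShift = "numeric",
  beta = "numeric", baselineShape = "numeric", baselineScale = "numeric",
  censoringRate = "numeric", adminCap = "numeric",
  sceneSpec = "SceneSpec", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
  if (object@sectionsPerPatient < 1L)
    msg <- c(msg, "sectionsPerPatient must be >= 1")
  if (abs(sum(object@stagePrevalence) - 1) > 1e-9)
    msg <- c(msg, "stage prevalences must sum to 1")
  if (object@censoringRate < 0 || object@censoringRate > 1)
    msg <- c(msg, "censoringRate must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SpatialGraph: Delaunay adjacency of one section's cells
#'
#' Nodes are the cells of one section/panel; edges are the Delaunay
#' triangulation of their centroids with Euclidean lengths in microns.
#' Created by [buildDelaunay()].
#'
#' @slot nodes data.frame(id, x, y, phenotype) with coordinates in microns.
#' @slot edges data.frame(i, j, length) indexing rows of `nodes`.
#' @export
setClass("SpatialGraph",
         representation(nodes = "data.frame", edges = "data.frame"))

setValidity("SpatialGraph", function(object) {
  msg <- character(0)
  n <- nrow(object@nodes)
  if (nrow(object@edges)) {
    if (any(object@edges$i < 1 | object@edges$i > n |
            object@edges$j < 1 | object@edges$j > n))
      msg <- c(msg, "edge endpoints out of range")
    if (any(object@edges$length <= 0)) msg <- c(msg, "edge lengths must be > 0")
    if (n >= 3 && nrow(object@edges) > 3 * n - 6)
      msg <- c(msg, "edge count exceeds the planar bound 3n - 6")
  }
  if (length(msg)) msg else TRUE
})

#' SegMatch: one-to-one object matching between two label masks
#'
#' @slot pairs data.frame(pred, gt, iou) of matched object pairs.
#' @slot tp,fp,fn True positive, false positive and false negative counts.
#' @slot iouThreshold The (strict) IoU threshold used.
#' @export
setClass("SegMatch", representation(
  pairs = "data.frame", tp = "integer", fp = "integer", fn = "integer",
  iouThreshold = "numeric"))

setValidity("SegMatch", function(object) {
  msg <- character(0)
  if (object@tp != nrow(object@pairs)) msg <- c(msg, "tp must equal |pairs|")
  if (nrow(object@pairs)) {
    if (anyDuplicated(object@pairs$pred) || anyDuplicated(object@pairs$gt))
      msg <- c(msg, "matching must be one-to-one")
    if (any(object@pairs$iou <= object@iouThreshold))
      msg <- c(msg, "all matched pairs must exceed the IoU threshold")
  }
  if (length(msg)) msg else TRUE
})

#' SegMetrics: segmentation evaluation summary
#'
#' @slot precision,recall,f1,pixelAccuracy Reals in [0, 1].
#' @export
setClass("SegMetrics", representation(
  precision = "numeric", recall = "numeric", f1 = "numeric",
  pixelAccuracy = "numeric"))

setValidity("SegMetrics", function(object) {
  v <- c(object@precision, object@recall, object@f1, object@pixelAccuracy)
  if (any(v < -1e-12 | v > 1 + 1e-12)) "all metrics must lie in [0, 1]" else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d px @ %.2f um/px, %d cells, %d nests\n",
              object@width, object@height, object@pixelSize, object@nCells,
              object@nestCount))
  cat("  mixture:",
      paste(sprintf("%s=%.2f", names(object@mixture), object@mixture),
            collapse = " "), "\n")
  if (nrow(object@interactions))
    cat(sprintf("  %d interaction term(s), range %.1f um\n",
                nrow(object@interactions), object@interactionRange))
})

setMethod("show", "MifScene", function(object) {
  d <- dim(object@compartmentMask)
  cat(sprintf("MifScene: %d x %d px @ %.2f um/px\n", d[2], d[1],
              object@pixelSize))
  for (p in 1:2)
    cat(sprintf("  panel %d: %d cells, %d channel(s)\n", p,
                nrow(object@panels[[p]]$cells),
                length(object@panels[[p]]$channels)))
})

setMethod("show", "SpatialGraph", function(object) {
  cat(sprintf("SpatialGraph: %d nodes, %d Delaunay edges\n",
              nrow(object@nodes), nrow(object@edges)))
})

setMethod("show", "SegMatch", function(object) {
  cat(sprintf("SegMatch (IoU > %.2f): TP %d, FP %d, FN %d\n",
              object@iouThreshold, object@tp, object@fp, object@fn))
})

setMethod("show", "SegMetrics", function(object) {
  cat(sprintf(
    "SegMetrics: precision %.4f, recall %.4f, F1 %.4f, pixel accuracy %.6f\n",
    object@precision, object@recall, object@f1, object@pixelAccuracy))
})

## ---- accessors ----------------------------------------------------------

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "MifScene", function(x) x@pixelSize)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "SceneSpec", function(x) x@pixelSize)

#' @rdname compartmentMask
#' @export
setMethod("compartmentMask", "MifScene", function(x) x@compartmentMask)

#' @rdname panelChannels
#' @export
setMethod("panelChannels", "MifScene",
          function(x, panel = 1L) x@panels[[panel]]$channels)

#' @rdname nucleusLabels
#' @export
setMethod("nucleusLabels", "MifScene",
          function(x, panel = 1L) x@panels[[panel]]$labels)

#' @rdname truthCells
#' @export
setMethod("truthCells", "MifScene",
          function(x, panel = 1L) x@panels[[panel]]$cells)

#' Graph accessors
#' @param x A [SpatialGraph-class].
#' @return `graphNodes`: the node data.frame; `graphEdges`: the edge
#'   data.frame.
#' @export
graphNodes <- function(x) x@nodes

#' @rdname graphNodes
#' @export
graphEdges <- function(x) x@edges
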