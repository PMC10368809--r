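#' @importFrom methods new validObject is slot show setClass setGeneric setMethod setValidity
NULL

#' Pixel size accessor
#' @param x An object with a pixel-size slot.
#' @return Microns per pixel (numeric scalar).
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Compartment mask accessor
#' @param x A [MifScene-class] object.
#' @return Integer matrix: 0 = non-tissue, 1 = tumour nest, 2 = tumour stroma.
#' @export
setGeneric("compartmentMask", function(x) standardGeneric("compartmentMask"))

#' Panel channel accessor
#' @param x A [MifScene-class] object.
#' @param panel Panel index (1 or 2).
#' @return Named list of channel matrices (DAPI first, then the five markers).
#' @export
setGeneric("panelChannels", function(x, panel = 1L) standardGeneric("panelChannels"))

#' Ground-truth nucleus label accessor
#' @param x A [MifScene-class] object.
#' @param panel Panel index (1 or 2).
#' @return Integer label matrix (0 background, k > 0 nucleus k).
#' @export
setGeneric("nucleusLabels", function(x, panel = 1L) standardGeneric("nucleusLabels"))

#' Ground-truth cell table accessor
#' @param x A [MifScene-class] object.
#' @param panel Panel index (1 or 2).
#' @return data.frame with one row per nucleus: centroid, phenotype,
#'   compartment and true per-marker fluorescence-strength level.
#' @export
setGeneric("truthCells", function(x, panel = 1L) standardGeneric("truthCells"))
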