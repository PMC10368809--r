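## Marker panels and phenotype vocabulary used throughout the package.

#' Marker panels
#'
#' The two five-marker immunofluorescence panels quantified by the pipeline.
#' Each panel is stained on its own serial section and imaged together with a
#' DAPI counterstain.
#'
#' @return Named list with character vectors `p1` and `p2`.
#' @export
#' @examples
#' panelMarkers()
panelMarkers <- function() {
  list(p1 = c("FOXP3", "CD38", "CD4", "CD20", "CD66b"),
       p2 = c("CD8", "CD68", "PDL1", "CD163", "CD133"))
}

#' Phenotype classes per panel
#'
#' The five cell classes resolved on each panel (one per marker) in canonical
#' (alphabetical) order, used for the pairwise spatial feature schema and the
#' composition features. `other` denotes cells matching no rule.
#'
#' @return Named list with character vectors `p1` and `p2`.
#' @export
phenotypeClasses <- function() {
  list(p1 = sort(c("Treg", "CD4_T", "activated_T", "B", "neutrophil")),
       p2 = sort(c("CD8_T", "macrophage", "M2_macrophage", "CSC", "PDL1_pos")))
}

## Marker sets that are truly positive for each phenotype (generator truth and
## the basis of the default calling rules).
.phenotypePositiveMarkers <- list(
  Treg          = c("CD4", "FOXP3"),
  CD4_T         = "CD4",
  activated_T   = "CD38",
  B             = "CD20",
  neutrophil    = "CD66b",
  CD8_T         = "CD8",
  macrophage    = "CD68",
  M2_macrophage = c("CD68", "CD163"),
  CSC           = "CD133",
  PDL1_pos      = "PDL1",
  other         = character(0)
)

## Which panel a phenotype is visible on.
.phenotypePanel <- c(
  Treg = 1L, CD4_T = 1L, activated_T = 1L, B = 1L, neutrophil = 1L,
  CD8_T = 2L, macrophage = 2L, M2_macrophage = 2L, CSC = 2L, PDL1_pos = 2L
)

## Defining marker per phenotype (used for the H-score feature labels).
.phenotypeMarker <- c(
  Treg = "FOXP3", CD4_T = "CD4", activated_T = "CD38", B = "CD20",
  neutrophil = "CD66b", CD8_T = "CD8", macrophage = "CD68",
  M2_macrophage = "CD163", CSC = "CD133", PDL1_pos = "PDL1"
)

#' Default phenotype mixture
#'
#' Default phenotype fractions for the synthetic scene generator, chosen to
#' mimic an immune-infiltrated NSCLC microenvironment: T-cell subsets dominate
#' the lymphoid compartment, macrophages the myeloid one, and roughly a third
#' of nuclei carry none of the ten markers.
#'
#' @return Named numeric vector over the eleven phenotype classes, summing to 1.
#' @export
defaultMixture <- function() {
  c(Treg = 0.05, CD4_T = 0.13, activated_T = 0.05, B = 0.07,
    neutrophil = 0.09, CD8_T = 0.12, macrophage = 0.08,
    M2_macrophage = 0.05, CSC = 0.03, PDL1_pos = 0.05, other = 0.28)
}

.fsLevels <- c("neg", "low", "med", "high")
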