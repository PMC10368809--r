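## Delaunay spatial graph and the 30 within-panel pairwise distance features.

#' Build the Delaunay graph over one section's cells
#'
#' Edges are the Delaunay triangulation of the cell centroids; lengths are
#' Euclidean distances in microns. Duplicate centroids are deduplicated with
#' a warning; fewer than three (or collinear) points give a degenerate graph
#' with no edges, with a warning.
#'
#' @param cells data.frame with columns `x_um`, `y_um` (or `x_px`, `y_px`
#'   with `pixelSize` supplied) and `phenotype`.
#' @param pixelSize Microns per pixel, used only when micron columns are
#'   absent.
#' @return A [SpatialGraph-class].
#' @export
buildDelaunay <- function(cells, pixelSize = NULL) {
  if (!all(c("x_um", "y_um") %in% names(cells))) {
    if (is.null(pixelSize))
      stop("cells lack x_um/y_um and no pixelSize was given")
    cells$x_um <- cells$x_px * pixelSize
    cells$y_um <- cells$y_px * pixelSize
  }
  nodes <- data.frame(id = if ("cell_id" %in% names(cells)) cells$cell_id
                           else seq_len(nrow(cells)),
                      x = cells$x_um, y = cells$y_um,
                      phenotype = cells$phenotype,
                      stringsAsFactors = FALSE)
  dup <- duplicated(nodes[, c("x", "y")])
  if (any(dup)) {
    warning(sum(dup), " duplicate centroid(s) removed")
    nodes <- nodes[!dup, , drop = FALSE]
  }
  rownames(nodes) <- NULL
  emptyE <- data.frame(i = integer(0), j = integer(0), length = numeric(0))
  if (nrow(nodes) < 3) {
    warning("fewer than 3 points: degenerate graph with no edges")
    return(new("SpatialGraph", nodes = nodes, edges = emptyE))
  }
  if (.allCollinear(nodes$x, nodes$y)) {
    warning("all points collinear: degenerate graph with no edges")
    return(new("SpatialGraph", nodes = nodes, edges = emptyE))
  }
  dd <- deldir::deldir(nodes$x, nodes$y, suppressMsge = TRUE)
  e <- dd$delsgs
  edges <- data.frame(i = pmin(e$ind1, e$ind2), j = pmax(e$ind1, e$ind2))
  edges <- edges[!duplicated(edges), , drop = FALSE]
  edges$length <- sqrt((nodes$x[edges$i] - nodes$x[edges$j])^2 +
                       (nodes$y[edges$i] - nodes$y[edges$j])^2)
  rownames(edges) <- NULL
  new("SpatialGraph", nodes = nodes, edges = edges)
}

.allCollinear <- function(x, y) {
  if (length(x) < 3) return(TRUE)
  dx <- x - x[1]; dy <- y - y[1]
  span <- max(abs(c(dx, dy)))
  if (span == 0) return(TRUE)
  all(abs(dx * dy[2] - dy * dx[2]) < 1e-9 * span^2) &&
    (abs(dx[2]) + abs(dy[2]) > 0)
}

#' Mean Delaunay distance between two cell classes
#'
#' Mean Euclidean length over Delaunay edges whose endpoints carry the
#' unordered phenotype pair \{a, b\} (both endpoints `a` when `a == b`).
#' Returns NA ("missing") when the graph holds no such edge.
#'
#' @param graph A [SpatialGraph-class].
#' @param a,b Phenotype class names.
#' @param agg Aggregation of qualifying edge lengths: `mean` (default) or
#'   `median`.
#' @return Mean (or median) distance in microns, or NA.
#' @export
pairDistance <- function(graph, a, b, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  vocab <- c(unlist(phenotypeClasses(), use.names = FALSE), "other")
  if (!a %in% vocab || !b %in% vocab)
    stop("unknown phenotype name: ", paste(setdiff(c(a, b), vocab),
                                           collapse = ", "))
  nodes <- graphNodes(graph); edges <- graphEdges(graph)
  if (!nrow(edges)) return(NA_real_)
  pi_ <- nodes$phenotype[edges$i]; pj <- nodes$phenotype[edges$j]
  sel <- (pi_ == a & pj == b) | (pi_ == b & pj == a)
  if (!any(sel)) return(NA_real_)
  if (agg == "mean") mean(edges$length[sel]) else
    stats::median(edges$length[sel])
}

#' Enumerate the within-panel pair schema
#'
#' For each panel, all unordered distinct-class pairs plus the self-pairs;
#' panels are never mixed because each panel is stained on its own serial
#' section. Two five-class panels give C(5,2) + 5 = 15 keys each, 30 in
#' total. For other panel sizes the generalized count
#' 2 (C(k, 2) + k) is produced and reported.
#'
#' @param classes List of two character vectors of cell classes (default
#'   [phenotypeClasses()]).
#' @return Character vector of keys, panel 1 first, alphabetical within
#'   panel; key format `p<panel>.<A>.vs.<B>` with A <= B.
#' @export
#' @examples
#' length(enumeratePairSchema())  # 30
enumeratePairSchema <- function(classes = phenotypeClasses()) {
  stopifnot(length(classes) == 2)
  keys <- unlist(lapply(1:2, function(p) {
    cl <- sort(classes[[p]])
    k <- length(cl)
    pairs <- c(if (k >= 2) {
      cmb <- utils::combn(cl, 2)
      paste0(cmb[1, ], ".vs.", cmb[2, ])
    }, paste0(cl, ".vs.", cl))
    paste0("p", p, ".", sort(pairs))
  }))
  if (any(lengths(classes) != 5))
    message(sprintf("non-standard panel sizes (%s): %d pair keys",
                    paste(lengths(classes), collapse = ", "), length(keys)))
  keys
}

#' Spatial feature vector of one section
#'
#' @param cells Per-cell table of one section (both panels), as produced by
#'   [quantifyScene()] or [truthCells()]; non-tissue cells are excluded.
#' @param pixelSize Microns per pixel (used when micron coordinates are
#'   absent).
#' @param classes Cell classes per panel.
#' @param agg Edge-length aggregation, see [pairDistance()].
#' @return Named numeric vector over [enumeratePairSchema()] keys (NA where
#'   a pair has no Delaunay adjacency).
#' @export
sectionSpatialFeatures <- function(cells, pixelSize = NULL,
                                   classes = phenotypeClasses(),
                                   agg = "mean") {
  keys <- enumeratePairSchema(classes)
  out <- stats::setNames(rep(NA_real_, length(keys)), keys)
  if ("compartment" %in% names(cells))
    cells <- cells[cells$compartment %in% c("TN", "TS"), , drop = FALSE]
  for (p in 1:2) {
    sub <- cells[cells$panel == p, , drop = FALSE]
    if (nrow(sub) < 3) next
    g <- buildDelaunay(sub, pixelSize)
    cl <- sort(classes[[p]])
    for (a in cl) for (b in cl[cl >= a]) {
      key <- paste0("p", p, ".", a, ".vs.", b)
      out[key] <- suppressWarnings(pairDistance(g, a, b, agg))
    }
  }
  out
}

#' Average spatial features over a patient's sections
#'
#' Per key, the mean over sections where the feature is defined; missing
#' only when undefined in every section.
#'
#' @param sections List of named per-section vectors (identical key sets).
#' @return Named numeric vector.
#' @export
patientSpatialFeatures <- function(sections) {
  if (!length(sections)) stop("no sections supplied")
  m <- do.call(rbind, sections)
  out <- colMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Patient-level spatial feature table
#'
#' Computes the per-section 30-variable vectors and averages them per
#' patient.
#'
#' @param cells Per-cell table with `patient_id` and `section` columns (plus
#'   the columns required by [sectionSpatialFeatures()]).
#' @param pixelSize Microns per pixel.
#' @param classes Cell classes per panel.
#' @param agg Edge aggregation.
#' @return data.frame, one row per patient: `patient_id` + one column per
#'   pair key.
#' @export
spatialFeatures <- function(cells, pixelSize = NULL,
                            classes = phenotypeClasses(), agg = "mean") {
  stopifnot(all(c("patient_id", "section") %in% names(cells)))
  pats <- unique(cells$patient_id)
  rows <- lapply(pats, function(pt) {
    sub <- cells[cells$patient_id == pt, , drop = FALSE]
    secs <- lapply(split(sub, sub$section), sectionSpatialFeatures,
                   pixelSize = pixelSize, classes = classes, agg = agg)
    patientSpatialFeatures(secs)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(patient_id = pats, stringsAsFactors = FALSE), out)
}
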