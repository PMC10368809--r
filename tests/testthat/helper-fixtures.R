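## Shared fixtures and independent brute-force oracles.

## Draw a filled disk into a matrix (row = y, col = x).
drawDisk <- function(img, cx, cy, r, value = 1) {
  for (x in seq_len(ncol(img))) for (y in seq_len(nrow(img)))
    if ((x - cx)^2 + (y - cy)^2 <= r^2) img[y, x] <- value
  img
}

## Intensity model with all noise sources off: positive nuclei render
## exactly their representative level intensity.
noiselessModel <- function() {
  im <- defaultIntensityModel()
  im$sigma <- 0; im$backgroundSd <- 0; im$blurSigma <- 0
  im
}

trueZ <- function() stats::setNames(rep(1, 10), unlist(panelMarkers()))

noInteraction <- function()
  data.frame(a = character(0), b = character(0), strength = numeric(0))

## Brute-force optimal one-to-one matching: maximum number of matched pairs
## over all assignments among candidates with IoU above the threshold.
bruteForceMatchCount <- function(pred, gt, threshold = 0.6) {
  predIds <- sort(unique(pred[pred > 0]))
  gtIds <- sort(unique(gt[gt > 0]))
  cand <- list()
  for (p in predIds) for (g in gtIds) {
    ov <- iou(pred == p, gt == g)
    if (ov > threshold) cand[[length(cand) + 1L]] <- c(p, g)
  }
  if (!length(cand)) return(0L)
  best <- 0L
  recurse <- function(k, usedP, usedG, count) {
    if (count + (length(cand) - k + 1L) <= best) return()
    if (k > length(cand)) { best <<- max(best, count); return() }
    pg <- cand[[k]]
    if (!(pg[1] %in% usedP) && !(pg[2] %in% usedG))
      recurse(k + 1L, c(usedP, pg[1]), c(usedG, pg[2]), count + 1L)
    recurse(k + 1L, usedP, usedG, count)
  }
  recurse(1L, integer(0), integer(0), 0L)
  best
}

## Brute-force Delaunay edges via the empty-circumcircle test (general
## position); returns a sorted two-column matrix of point indices.
bruteForceDelaunayEdges <- function(x, y) {
  n <- length(x)
  edges <- matrix(integer(0), 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    if (all((x[others] - ux)^2 + (y[others] - uy)^2 > r2 * (1 + 1e-9)))
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}
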