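test_that("small configurations triangulate as hand-worked", {
  g <- buildDelaunay(data.frame(x_um = c(0, 10, 5), y_um = c(0, 0, 8),
                                phenotype = "B"))
  expect_equal(nrow(graphEdges(g)), 3L)

  sq <- buildDelaunay(data.frame(x_um = c(0, 1, 1, 0), y_um = c(0, 0, 1, 1),
                                 phenotype = "B"))
  expect_equal(nrow(graphEdges(sq)), 5L)  # 4 sides + 1 diagonal

  expect_warning(
    dup <- buildDelaunay(data.frame(x_um = c(0, 0, 1, 5), y_um = c(0, 0, 1, 3),
                                    phenotype = "B")), "duplicate")
  expect_equal(nrow(graphNodes(dup)), 3L)

  expect_warning(
    deg <- buildDelaunay(data.frame(x_um = c(0, 1, 2), y_um = c(0, 1, 2),
                                    phenotype = "B")), "collinear")
  expect_equal(nrow(graphEdges(deg)), 0L)
})

test_that("edges match the brute-force empty-circumcircle construction", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    x <- runif(n, 0, 100); y <- runif(n, 0, 100)
    g <- buildDelaunay(data.frame(x_um = x, y_um = y, phenotype = "B"))
    got <- as.matrix(graphEdges(g)[, c("i", "j")])
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    want <- bruteForceDelaunayEdges(x, y)
    expect_equal(unname(got), unname(want))
  }
})

test_that("pair distances aggregate qualifying Delaunay edges", {
  ## single a-b edge of known length
  g <- buildDelaunay(data.frame(x_um = c(0, 12.5, 6), y_um = c(0, 0, 20),
                                phenotype = c("CD4_T", "neutrophil", "B")))
  expect_equal(pairDistance(g, "CD4_T", "neutrophil"), 12.5)
  expect_equal(pairDistance(g, "neutrophil", "CD4_T"), 12.5)  # unordered
  expect_true(is.na(pairDistance(g, "Treg", "B")))            # absent pair
  expect_error(pairDistance(g, "CD4_T", "fibroblast"), "unknown phenotype")

  ## self-pair with two qualifying edges (10 and 20): collinear trio blocked
  ## by an off-axis witness, so the 30-um chord is not a Delaunay edge
  g2 <- buildDelaunay(data.frame(
    x_um = c(0, 10, 30, 15), y_um = c(0, 0, 0, 10),
    phenotype = c("B", "B", "B", "CD8_T")))
  expect_equal(pairDistance(g2, "B", "B"), 15)
})

test_that("the pair schema enumerates 30 within-panel keys", {
  keys <- enumeratePairSchema()
  expect_length(keys, 30L)
  expect_length(unique(keys), 30L)
  expect_equal(sum(startsWith(keys, "p1.")), 15L)
  expect_equal(sum(startsWith(keys, "p2.")), 15L)
  ## panels are never mixed
  expect_false(any(grepl("CD8_T", keys[startsWith(keys, "p1.")])))

  expect_message(k2 <- enumeratePairSchema(list(c("A", "B"), c("A", "B"))),
                 "6 pair keys")
  expect_length(k2, 6L)
  expect_message(k1 <- enumeratePairSchema(list("A", "B")), "2 pair keys")
  expect_length(k1, 2L)
})

test_that("per-patient averaging follows the missing-value rules", {
  s1 <- c(a = 10, b = NA, c = 5)
  s2 <- c(a = 30, b = NA, c = NA)
  avg <- patientSpatialFeatures(list(s1, s2))
  expect_equal(avg[["a"]], 20)
  expect_true(is.na(avg[["b"]]))
  expect_equal(avg[["c"]], 5)
  expect_equal(patientSpatialFeatures(list(s1)), s1)
  expect_error(patientSpatialFeatures(list()), "no sections")
})

test_that("pair distances are rigid-motion invariant and scale equivariant", {
  set.seed(17)
  n <- 40
  cells <- data.frame(x_um = runif(n, 0, 100), y_um = runif(n, 0, 100),
                      phenotype = sample(c("CD4_T", "neutrophil", "B"), n,
                                         replace = TRUE))
  d0 <- pairDistance(buildDelaunay(cells), "CD4_T", "neutrophil")
  th <- 0.7
  rot <- data.frame(
    x_um = 15 + cells$x_um * cos(th) - cells$y_um * sin(th),
    y_um = -8 + cells$x_um * sin(th) + cells$y_um * cos(th),
    phenotype = cells$phenotype)
  expect_equal(pairDistance(buildDelaunay(rot), "CD4_T", "neutrophil"), d0,
               tolerance = 1e-6)
  scl <- transform(cells, x_um = x_um * 3, y_um = y_um * 3)
  expect_equal(pairDistance(buildDelaunay(scl), "CD4_T", "neutrophil"),
               3 * d0, tolerance = 1e-9)
})

test_that("patient-level tables average sections and keep the schema", {
  sc <- generateScene(sceneSpec(width = 512L, height = 384L, nCells = 120L,
                                seed = 23L), render = FALSE)
  keep <- c("cell_id", "panel", "x_um", "y_um", "phenotype", "compartment")
  cells <- rbind(truthCells(sc, 1)[, keep], truthCells(sc, 2)[, keep])
  cells$section <- 1L
  cells$patient_id <- "P1"
  ft <- spatialFeatures(cells)
  expect_equal(nrow(ft), 1L)
  expect_equal(ncol(ft), 31L)  # patient_id + 30 keys
  vals <- unlist(ft[1, -1])
  expect_true(all(vals[!is.na(vals)] > 0))
})
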