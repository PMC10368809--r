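test_that("scene generation is deterministic and honours the empty case", {
  spec <- sceneSpec(width = 256L, height = 192L, nCells = 60L, seed = 42L)
  a <- generateScene(spec)
  b <- generateScene(spec)
  expect_identical(nucleusLabels(a, 1), nucleusLabels(b, 1))
  expect_identical(panelChannels(a, 2), panelChannels(b, 2))
  expect_identical(truthCells(a, 1), truthCells(b, 1))

  empty <- generateScene(sceneSpec(width = 128L, height = 96L, nCells = 0L,
                                   seed = 1L), render = FALSE)
  expect_identical(max(nucleusLabels(empty, 1)), 0L)
  expect_identical(nrow(truthCells(empty, 1)), 0L)
})

test_that("spec invariants are enforced", {
  mx <- defaultMixture(); mx[1] <- mx[1] + 0.1
  expect_error(sceneSpec(mixture = mx), "sum to 1")
  expect_error(sceneSpec(width = 64L, height = 64L, nCells = 500L),
               "packing infeasible")
  expect_error(generateScene(sceneSpec(
    nCells = 20L, seed = 1L,
    interactions = data.frame(a = "CD4_T", b = "dendritic", strength = 1)),
    render = FALSE), "unknown phenotype")
})

test_that("serial sections share compartments but not cell coordinates", {
  sc <- generateScene(sceneSpec(nCells = 80L, seed = 7L), render = FALSE)
  c1 <- truthCells(sc, 1); c2 <- truthCells(sc, 2)
  expect_equal(nrow(c1), nrow(c2))
  expect_false(isTRUE(all.equal(c1$x_px, c2$x_px)))
  expect_true(all(compartmentMask(sc) %in% 0:2))
})

test_that("nuclei rasters are disjoint star-convex objects inside the scene", {
  sc <- generateScene(sceneSpec(nCells = 100L, seed = 3L), render = FALSE)
  lab <- nucleusLabels(sc, 1)
  ids <- sort(unique(lab[lab > 0]))
  expect_identical(ids, seq_along(ids))  # contiguous ids, disjoint by raster
  sizes <- tabulate(lab[lab > 0])
  expect_true(all(sizes > 0))
  spec <- sceneSpec()
  maxArea <- pi * (spec@nucleusRadius * 1.3 / spec@pixelSize)^2
  expect_true(all(sizes <= maxArea * 1.3))
})

test_that("realized composition converges to the phenotype mixture", {
  spec <- sceneSpec(width = 2048L, height = 1536L, nCells = 5000L,
                    seed = 11L)
  sc <- generateScene(spec, render = FALSE)
  ph <- truthCells(sc, 1)$phenotype
  mx <- spec@mixture
  for (cl in names(mx)) {
    se <- sqrt(mx[[cl]] * (1 - mx[[cl]]) / 5000)
    expect_lt(abs(mean(ph == cl) - mx[[cl]]), 3 * se + 1e-12)
  }
})

test_that("zero interaction strength leaves cross-phenotype spacing at the
           random-labelling envelope", {
  sc <- generateScene(sceneSpec(nCells = 200L, seed = 5L), render = FALSE)
  cells <- truthCells(sc, 1)
  stat <- function(ph) {
    a <- cells[ph == "CD4_T", c("x_um", "y_um")]
    b <- cells[ph == "neutrophil", c("x_um", "y_um")]
    mean(apply(as.matrix(a), 1, function(p)
      min(sqrt((b$x_um - p[1])^2 + (b$y_um - p[2])^2))))
  }
  obs <- stat(cells$phenotype)
  set.seed(99)
  env <- replicate(200, stat(sample(cells$phenotype)))
  expect_gte(obs, quantile(env, 0.005))
  expect_lte(obs, quantile(env, 0.995))
})

test_that("attraction strictly shortens pair spacing across strengths", {
  pairMean <- function(strength, seed) {
    inter <- if (strength == 0) noInteraction() else
      data.frame(a = "CD4_T", b = "neutrophil", strength = strength)
    sc <- generateScene(sceneSpec(width = 512L, height = 384L, nCells = 150L,
                                  interactions = inter, seed = seed),
                        render = FALSE)
    v <- sectionSpatialFeatures(truthCells(sc, 1))
    v[["p1.CD4_T.vs.neutrophil"]]
  }
  seeds <- 1:4
  d0 <- vapply(seeds, function(s) pairMean(0, s), numeric(1))
  d1 <- vapply(seeds, function(s) pairMean(0.8, s), numeric(1))
  d2 <- vapply(seeds, function(s) pairMean(2, s), numeric(1))
  ## Jonckheere-style monotone trend over the three strengths
  expect_lt(mean(d1, na.rm = TRUE), mean(d0, na.rm = TRUE))
  expect_lt(mean(d2, na.rm = TRUE), mean(d1, na.rm = TRUE))
})
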