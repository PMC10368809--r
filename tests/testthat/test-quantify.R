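test_that("fluorescence-field extraction follows the background quantile", {
  ch <- matrix(0, 40, 40)
  expect_false(any(suppressWarnings(extractFluorescence(ch))))

  ch[5:7, 5:7] <- 10   # one bright 3 x 3 block (9 of 1600 px)
  f <- extractFluorescence(ch, 0.99)
  expect_equal(sum(f), 9)
  expect_true(all(which(f) == which(ch > 0)))

  expect_warning(f0 <- extractFluorescence(ch, 0), "every pixel")
  expect_true(all(f0))
})

test_that("field/nucleus intersection attributes pixels to the right cells", {
  lab <- matrix(0L, 30, 30)
  lab[5:9, 5:9] <- 1L
  lab[20:24, 20:24] <- 2L
  ch <- matrix(0, 30, 30)

  ## disjoint field: everyone zero
  ch[1:2, 15:16] <- 5
  v <- intersectCfCcn(ch, lab, dilationPx = 0L)
  expect_equal(unname(v), c(0, 0))

  ## field exactly nucleus 1 at intensity 7
  ch <- matrix(0, 30, 30); ch[5:9, 5:9] <- 7
  v <- intersectCfCcn(ch, lab, dilationPx = 0L)
  expect_equal(unname(v), c(7, 0))

  ## with dilation, a ring just outside the nucleus is captured
  ch <- matrix(0, 30, 30); ch[4:10, 4:10] <- 3   # 1-px halo around nucleus 1
  v <- intersectCfCcn(ch, lab, field = ch > 0, dilationPx = 2L)
  expect_equal(unname(v), c(3, 0))
  ## pixel bookkeeping: with ample dilation every field pixel is attributed
  expect_equal(sum(ch[ch > 0]) / sum(ch > 0), unname(v[1]))
})

test_that("FS binning respects the Z/2Z/3Z boundaries (closed below)", {
  expect_equal(assignFsLevel(c(0, 0.99, 1, 1.99, 2, 2.99, 3, 3.5), Z = 1),
               c("neg", "neg", "low", "low", "med", "med", "high", "high"))
  expect_equal(assignFsLevel(7, Z = 2), "high")
  expect_error(assignFsLevel(-1, Z = 1), "negative")
  expect_error(assignFsLevel(1, Z = 0), "Z must be")
})

test_that("the H-score reproduces the weighted-percentage formula", {
  expect_equal(hScore(100, 0, 0), 100)
  expect_equal(hScore(0, 0, 100), 300)
  expect_equal(hScore(50, 30, 20), 170)
  expect_error(hScore(60, 30, 20), "more than 100")
  expect_equal(hScoreFromLevels(c("low", "low", "med", "high", "neg")),
               40 * 1 + 20 * 2 + 20 * 3)
  ## monotone under transferring mass upward
  expect_lt(hScore(50, 30, 20), hScore(40, 40, 20))
  expect_lt(hScore(40, 40, 20), hScore(40, 30, 30))
})

test_that("phenotype calling follows the ordered rule tables", {
  p1 <- panelMarkers()$p1
  fs <- as.data.frame(matrix("neg", 4, 5, dimnames = list(NULL, p1)),
                      stringsAsFactors = FALSE)
  fs$CD4[2] <- "low"; fs$FOXP3[2] <- "med"   # Treg beats CD4 T
  fs$CD4[3] <- "high"                        # plain CD4 T
  fs$CD38[4] <- "low"; fs$CD4[4] <- "low"    # CD4 precedence over CD38
  expect_equal(callPhenotype(fs, phenotypeRules(1)),
               c("other", "Treg", "CD4_T", "CD4_T"))

  p2 <- panelMarkers()$p2
  fs2 <- as.data.frame(matrix("neg", 3, 5, dimnames = list(NULL, p2)),
                       stringsAsFactors = FALSE)
  fs2$CD68[1] <- "high"                      # macrophage, not M2
  fs2$CD68[2] <- "low"; fs2$CD163[2] <- "low"  # M2
  fs2$PDL1[3] <- "med"                       # PD-L1 only
  expect_equal(callPhenotype(fs2, phenotypeRules(2)),
               c("macrophage", "M2_macrophage", "PDL1_pos"))

  expect_error(callPhenotype(fs2[, 1:3], phenotypeRules(2)), "missing")
})

test_that("compartment assignment reads the mask and flags non-tissue", {
  mask <- matrix(0L, 10, 10)
  mask[3:8, 3:8] <- 2L; mask[4:6, 4:6] <- 1L
  expect_equal(assignCompartment(5, 5, mask), "TN")
  expect_equal(assignCompartment(3, 8, mask), "TS")
  expect_equal(assignCompartment(1, 1, mask), "excluded")
  expect_error(assignCompartment(11, 5, mask), "out of raster")
})

test_that("FS fractions sum to one over included cells", {
  sc <- generateScene(sceneSpec(width = 512L, height = 384L, nCells = 120L,
                                seed = 21L))
  cells <- quantifyScene(sc, thresholds = trueZ())
  sub <- cells[cells$panel == 1, ]
  for (m in panelMarkers()$p1) {
    fr <- table(factor(sub[[paste0("fs_", m)]],
                       levels = c("neg", "low", "med", "high"))) / nrow(sub)
    expect_equal(sum(fr), 1)
  }
})

test_that("noiseless scenes with oracle nuclei recover the true FS levels", {
  sc <- generateScene(sceneSpec(width = 512L, height = 384L, nCells = 150L,
                                intensity = noiselessModel(), seed = 13L))
  cells <- quantifyScene(sc, thresholds = trueZ())
  agree <- unlist(lapply(1:2, function(p) {
    tr <- truthCells(sc, p)
    q <- cells[cells$panel == p, ]
    q <- q[match(tr$cell_id, q$cell_id), ]
    vapply(panelMarkers()[[p]], function(m)
      mean(q[[paste0("fs_", m)]] == tr[[paste0("fs_", m)]]), numeric(1))
  }))
  expect_gte(mean(agree), 0.99)
})
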