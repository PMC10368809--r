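test_that("Cox fits recover planted coefficients and reject degenerate input", {
  set.seed(41)
  n <- 1000
  x <- rnorm(n)
  s <- generateSurvival(0.5 * x, censoringRate = 0.2)
  fit <- fitCox(cbind(s, x = x), "x")
  expect_lt(abs(fit$coef - 0.5), 0.1)
  expect_true(fit$ci_lower < fit$HR && fit$HR < fit$ci_upper)

  expect_error(fitCox(cbind(s, x = rep(1, n)), "x"), "constant covariate")
  few <- data.frame(time = 1:8, event = rep(0L, 8), x = rnorm(8))
  expect_error(fitCox(few, "x"), "events")
})

test_that("null features give nominal Cox confidence-interval coverage", {
  cover <- vapply(1:30, function(s) {
    set.seed(500 + s)
    x <- rnorm(300)
    sv <- generateSurvival(rep(0, 300), censoringRate = 0.2)
    fit <- fitCox(cbind(sv, x = x), "x")
    fit$ci_lower <= 1 && 1 <= fit$ci_upper
  }, logical(1))
  expect_gte(mean(cover), 25 / 30)
})

test_that("the log-rank test matches a hand-worked table and its identities", {
  ## groups {1,2,3} vs {4,5,6}, all events: O_A = 3, E_A = 1.15, V = 0.6775
  lr <- kmLogrank(1:6, rep(1L, 6), rep(c("A", "B"), each = 3))
  expect_equal(lr$chisq, (3 - 1.15)^2 / 0.6775, tolerance = 1e-6)
  ## label swap invariance
  lr2 <- kmLogrank(1:6, rep(1L, 6), rep(c("B", "A"), each = 3))
  expect_equal(lr2$chisq, lr$chisq)
  ## identical groups
  lr3 <- kmLogrank(rep(c(1, 2, 3), 2), rep(1L, 6), rep(c("A", "B"), 3))
  expect_equal(lr3$chisq, 0, tolerance = 1e-10)
  expect_equal(lr3$p, 1, tolerance = 1e-6)
  ## all censored
  lr4 <- kmLogrank(1:6, rep(0L, 6), rep(c("A", "B"), 3))
  expect_equal(lr4$chisq, 0)
  expect_error(kmLogrank(1:6, rep(1L, 6), rep("A", 6)), "2 non-empty")
})

test_that("the maximal-chi-square cutoff recovers a planted split exactly", {
  set.seed(43)
  ## near-indicator feature: three levels, hazard tripled above the gap
  x <- sample(c(0, 1, 10), 300, replace = TRUE, prob = c(0.3, 0.3, 0.4))
  high <- x > 5
  s <- generateSurvival(ifelse(high, log(3), 0), censoringRate = 0.1)
  ct <- xtileCutoff(x, s$time, s$event)
  expect_true(all((x > ct$cutoff) == high))
  expect_equal(ct$n_high, sum(high))
  expect_error(xtileCutoff(rep(1, 50), s$time[1:50], s$event[1:50]),
               "distinct")
})

test_that("cutoff ties break toward the lower value and bounds are enforced", {
  ## no events: every candidate has chi-square 0, so the smallest admissible
  ## cutoff must be returned
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  ct <- xtileCutoff(x, rep(10, 10), rep(0L, 10), minGroupFrac = 0.2)
  expect_equal(ct$cutoff, 2)  # lowest cutoff keeping both groups >= 2
  expect_gte(ct$n_low, 2); expect_gte(ct$n_high, 2)
  expect_error(xtileCutoff(x, rep(10, 10), rep(0L, 10), minGroupFrac = 0.6),
               "group-size")
})

test_that("permutation-adjusted p exceeds the naive p under the null", {
  set.seed(47)
  raw <- adj <- numeric(10)
  for (i in 1:10) {
    x <- rnorm(60)
    s <- generateSurvival(rep(0, 60), censoringRate = 0.1)
    ct <- xtileCutoff(x, s$time, s$event, nPerm = 30L)
    raw[i] <- ct$p; adj[i] <- ct$p_adjusted
  }
  expect_true(mean(adj > raw) >= 0.9)  # maximal selection inflates naive p
})

test_that("fixed-effects pooling matches hand arithmetic and metafor", {
  one <- fixedEffectsPool(0.3, 0.12)
  expect_equal(one$logHR, 0.3)
  expect_equal(one$se, 0.12)

  two <- fixedEffectsPool(c(0.2, 0.4), c(0.1, 0.1))
  expect_equal(two$logHR, 0.3, tolerance = 1e-12)
  expect_equal(two$se, 0.1 / sqrt(2), tolerance = 1e-12)

  lim <- fixedEffectsPool(c(0.25, 5), c(0.1, 1e6))
  expect_equal(lim$logHR, 0.25, tolerance = 1e-6)

  skip_if_not_installed("metafor")
  th <- c(0.11, -0.2, 0.35); se <- c(0.08, 0.2, 0.15)
  ours <- fixedEffectsPool(th, se)
  rma <- metafor::rma(yi = th, sei = se, method = "FE")
  expect_equal(ours$logHR, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(ours$se, rma$se, tolerance = 1e-10)
  ## pooled SE never exceeds the best stratum
  expect_lte(ours$se, min(se))
  expect_error(fixedEffectsPool(numeric(0), numeric(0)), "no strata")
  expect_error(fixedEffectsPool(0.2, 0), "positive SE")
})

test_that("cohort summaries reproduce the published proportions", {
  counts <- read.csv(system.file("extdata", "published_cohort_counts.csv",
                                 package = "mifspatial"),
                     check.names = FALSE)
  hist <- expandCohortCounts(counts, "histology")
  expect_equal(nrow(hist), 553L)
  clin <- data.frame(patient_id = seq_len(nrow(hist)),
                     stage_group = hist$stage_group,
                     histology = hist$value)
  sm <- cohortSummary(clin, vars = "histology")
  luad <- sm$by_group[sm$by_group$level == "LUAD", ]
  expect_equal(round(luad$pct_overall, 1), 69.1)

  rel <- expandCohortCounts(counts, "relapse")
  clin2 <- data.frame(patient_id = seq_len(nrow(rel)),
                      stage_group = rel$stage_group,
                      relapse = as.integer(rel$value == "yes"))
  sm2 <- cohortSummary(clin2, vars = "relapse")
  expect_equal(round(unname(sm2$relapse_pct["IA-IIA"]), 1), 32.9)
  expect_equal(round(unname(sm2$relapse_pct["IIB-IIIB"]), 1), 67.1)
  expect_error(cohortSummary(clin, vars = "missing_col"), "missing column")
})
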