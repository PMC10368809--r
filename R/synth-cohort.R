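## Synthetic cohorts: stage-dependent composition, clinical covariates and
## proportional-hazards outcomes.

#' Specify a synthetic cohort
#'
#' @param nPatients Number of patients.
#' @param sectionsPerPatient Sections (pairs of panel slides) per patient.
#' @param stagePrevalence Named prevalences of the stage groups `IA-IIA`
#'   and `IIB-IIIB`; the default reproduces a 383:170 early/mid-to-late
#'   split.
#' @param compositionShift Additive percentage-point deltas applied to the
#'   phenotype mixture of mid-to-late-stage patients (balanced against
#'   `other`). The default lowers neutrophil and cancer-stem-cell fractions
#'   and raises the M2-macrophage fraction with progression.
#' @param beta Named log-hazard coefficients over the feature/covariate
#'   names produced by [generateCohort()] (see its documentation).
#' @param baselineShape,baselineScale Weibull baseline hazard (days).
#' @param censoringRate Probability of random censoring per subject.
#' @param adminCap Administrative censoring time, days.
#' @param sceneSpec Per-section [SceneSpec-class].
#' @param seed Integer seed.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nPatients = 100L, sectionsPerPatient = 1L,
                       stagePrevalence = c("IA-IIA" = 383 / 553,
                                           "IIB-IIIB" = 170 / 553),
                       compositionShift = c(neutrophil = -0.03,
                                            M2_macrophage = 0.03,
                                            CSC = -0.015),
                       beta = numeric(0), baselineShape = 1.2,
                       baselineScale = 2000, censoringRate = 0.2,
                       adminCap = 3000,
                       sceneSpec = mifspatial::sceneSpec(),
                       seed = NA_integer_) {
  new("CohortSpec", nPatients = as.integer(nPatients),
      sectionsPerPatient = as.integer(sectionsPerPatient),
      stagePrevalence = stagePrevalence,
      compositionShift = compositionShift, beta = beta,
      baselineShape = baselineShape, baselineScale = baselineScale,
      censoringRate = censoringRate, adminCap = adminCap,
      sceneSpec = sceneSpec, seed = as.integer(seed))
}

#' Generate proportional-hazards survival times
#'
#' Weibull baseline hazard (default shape 1.2) with linear predictor `lp`
#' on the log-hazard scale; censoring is a mixture of uniform random
#' censoring (each subject independently censored with probability
#' `censoringRate`, at a uniform fraction of its event time) and
#' administrative censoring at `adminCap`.
#'
#' @param lp Linear predictor per subject.
#' @param shape,scale Weibull baseline parameters (time in days).
#' @param censoringRate Probability of random censoring.
#' @param adminCap Administrative cap, days (Inf to disable).
#' @return data.frame(time, event).
#' @export
generateSurvival <- function(lp, shape = 1.2, scale = 2000,
                             censoringRate = 0.2, adminCap = Inf) {
  n <- length(lp)
  u <- stats::runif(n)
  t <- scale * (-log(u) / exp(lp))^(1 / shape)
  event <- rep(1L, n)
  cens <- stats::runif(n) < censoringRate
  t[cens] <- t[cens] * stats::runif(sum(cens))
  event[cens] <- 0L
  over <- t > adminCap
  t[over] <- adminCap
  event[over] <- 0L
  data.frame(time = pmax(t, 1e-8), event = event)
}

## Stage-adjusted phenotype mixture; deltas are balanced against `other`.
.stageMixture <- function(mixture, shift, stage) {
  if (stage != "IIB-IIIB" || !length(shift)) return(mixture)
  bad <- setdiff(names(shift), names(mixture))
  if (length(bad))
    stop("composition shift references unknown phenotype(s): ",
         paste(bad, collapse = ", "))
  mixture[names(shift)] <- mixture[names(shift)] + shift
  mixture["other"] <- mixture["other"] - sum(shift)
  if (any(mixture < 0)) stop("composition shift drives a fraction below 0")
  mixture / sum(mixture)
}

#' Generate a synthetic patient cohort
#'
#' Draws each patient's stage group, clinical covariates and true phenotype
#' composition (a multinomial realization of the stage-adjusted mixture over
#' the patient's total cell count), then survival times from the
#' proportional-hazards model with coefficients `spec@beta`.
#'
#' Feature/covariate names `beta` may reference: `pct_<phenotype>` (realized
#' percentage), `pct_<phenotype>_z` (the percentage standardized by its
#' early-stage binomial mean and SD), `age_z`, `sex_male`, `t_stage`, `vte`
#' and `stage_midlate`. An unknown name is an error.
#'
#' @param spec A [CohortSpec-class].
#' @param makeScenes Render per-section [MifScene-class] objects? With
#'   FALSE (default) only the clinical table and true feature values are
#'   produced, which is what large simulation studies need.
#' @param seed Seed; defaults to `spec@seed`.
#' @return List: `clinical` (patient_id, covariates, stage_group, time,
#'   event, relapse), `features` (true per-patient composition features),
#'   `scenes` (list of per-patient lists of scenes, or NULL).
#' @export
generateCohort <- function(spec, makeScenes = FALSE, seed = spec@seed) {
  validObject(spec)
  if (!is.na(seed)) set.seed(seed)
  n <- spec@nPatients
  ss <- spec@sceneSpec
  stage <- sample(names(spec@stagePrevalence), n, replace = TRUE,
                  prob = spec@stagePrevalence)
  sex <- ifelse(stats::runif(n) < 0.59, "male", "female")
  age <- round(stats::rnorm(n, 60, 10))
  tStage <- sample(1:4, n, replace = TRUE, prob = c(0.25, 0.35, 0.25, 0.15))
  vpi <- sample(c("PL0", "PL1", "PL2"), n, replace = TRUE,
                prob = c(0.37, 0.56, 0.07))
  vte <- as.integer(stats::runif(n) < 0.47)
  nTot <- ss@nCells * spec@sectionsPerPatient
  if (nTot < 1L) stop("cohort generation needs nCells >= 1 per section")
  mixBase <- ss@mixture
  pct <- t(vapply(seq_len(n), function(i) {
    mx <- .stageMixture(mixBase, spec@compositionShift, stage[i])
    100 * as.vector(stats::rmultinom(1, nTot, mx)) / nTot
  }, numeric(length(mixBase))))
  colnames(pct) <- paste0("pct_", names(mixBase))
  pctZ <- sweep(sweep(pct, 2, 100 * mixBase), 2,
                100 * sqrt(mixBase * (1 - mixBase) / nTot), "/")
  colnames(pctZ) <- paste0(colnames(pct), "_z")
  feats <- data.frame(patient_id = sprintf("P%04d", seq_len(n)), pct, pctZ,
                      age_z = (age - 60) / 10,
                      sex_male = as.integer(sex == "male"),
                      t_stage = tStage, vte = vte,
                      stage_midlate = as.integer(stage == "IIB-IIIB"),
                      check.names = FALSE, stringsAsFactors = FALSE)
  lp <- rep(0, n)
  if (length(spec@beta)) {
    bad <- setdiff(names(spec@beta), names(feats))
    if (length(bad))
      stop("beta references feature(s) not produced by the generator: ",
           paste(bad, collapse = ", "))
    lp <- as.vector(as.matrix(feats[, names(spec@beta), drop = FALSE]) %*%
                      spec@beta)
  }
  surv <- generateSurvival(lp, spec@baselineShape, spec@baselineScale,
                           spec@censoringRate, spec@adminCap)
  clinical <- data.frame(patient_id = feats$patient_id, sex = sex, age = age,
                         t_stage = tStage, vpi = vpi, vte = vte,
                         stage_group = stage, time = surv$time,
                         event = surv$event, relapse = surv$event,
                         stringsAsFactors = FALSE)
  scenes <- NULL
  if (makeScenes) {
    sceneSeeds <- sample.int(.Machine$integer.max, n * spec@sectionsPerPatient)
    scenes <- lapply(seq_len(n), function(i) {
      mx <- .stageMixture(mixBase, spec@compositionShift, stage[i])
      ssp <- ss; ssp@mixture <- mx
      lapply(seq_len(spec@sectionsPerPatient), function(s) {
        generateScene(ssp,
                      seed = sceneSeeds[(i - 1L) * spec@sectionsPerPatient + s])
      })
    })
    names(scenes) <- feats$patient_id
  }
  list(clinical = clinical, features = feats, scenes = scenes)
}

#' Generate a synthetic six-gene expression cohort
#'
#' Lognormal expression for the six risk-score genes, with the hazard
#' log-linear in the standardized true risk score: the linear predictor is
#' `scoreEffect` times the z-scored [ndegsScore()] of the generated
#' expression.
#'
#' @param n Number of samples (>= 2).
#' @param scoreEffect Log-hazard coefficient of the standardized score.
#' @param seed Integer seed.
#' @param meanlog,sdlog Lognormal expression parameters (shared by the six
#'   genes).
#' @param shape,scale,censoringRate,adminCap Survival model, see
#'   [generateSurvival()].
#' @return data.frame: `sample_id`, the six gene columns, `time`, `event`.
#' @export
generateExpression <- function(n, scoreEffect = 0, seed = NA_integer_,
                               meanlog = 0, sdlog = 0.5, shape = 1.2,
                               scale = 1200, censoringRate = 0.25,
                               adminCap = 2500) {
  if (n < 2) stop("n must be >= 2")
  if (!is.na(seed)) set.seed(seed)
  genes <- names(ndegsCoefficients())
  expr <- matrix(stats::rlnorm(n * length(genes), meanlog, sdlog), n,
                 dimnames = list(NULL, genes))
  df <- as.data.frame(expr)
  score <- ndegsScore(df)
  z <- (score - mean(score)) / stats::sd(score)
  surv <- generateSurvival(scoreEffect * z, shape, scale, censoringRate,
                           adminCap)
  cbind(data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                   stringsAsFactors = FALSE),
        df, surv)
}
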