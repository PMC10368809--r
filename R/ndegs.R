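## The six-gene neutrophil differentiation expression gene score (NDEGS):
## frozen linear risk score, cutoff-based risk grouping, IPCW time-dependent
## AUC, and tumour mutational burden classification.

#' NDEGS coefficients
#'
#' The frozen coefficients of the six-gene neutrophil differentiation
#' expression gene score. The coefficients are bound to the expression scale
#' they were fitted on; callers must supply expression on a consistent,
#' documented normalization (see the methods vignette).
#'
#' @return Named numeric vector of the six gene coefficients.
#' @export
#' @examples
#' sum(ndegsCoefficients())  # 7.442
ndegsCoefficients <- function() {
  c(CTSZ = 0.706, PLAUR = 1.225, NME2 = 1.268, NPM1 = 1.339,
    EIF3E = 1.349, PPIA = 1.555)
}

#' Compute the NDEGS risk score
#'
#' NDEGS = 0.706 CTSZ + 1.225 PLAUR + 1.268 NME2 + 1.339 NPM1 +
#' 1.349 EIF3E + 1.555 PPIA. A missing gene or missing value is an error;
#' no imputation is performed.
#'
#' @param expr data.frame or matrix with the six gene columns
#'   (non-negative expression values).
#' @return Numeric score per row.
#' @export
#' @examples
#' ndegsScore(data.frame(CTSZ = 1, PLAUR = 1, NME2 = 1, NPM1 = 1,
#'                       EIF3E = 1, PPIA = 1))
ndegsScore <- function(expr) {
  cf <- ndegsCoefficients()
  missing <- setdiff(names(cf), colnames(expr))
  if (length(missing))
    stop("missing gene(s): ", paste(missing, collapse = ", "))
  m <- as.matrix(as.data.frame(expr)[, names(cf), drop = FALSE])
  if (anyNA(m)) stop("missing expression values (no imputation)")
  if (any(m < 0)) stop("expression must be non-negative")
  as.vector(m %*% cf)
}

#' Assign risk groups at a cutoff
#'
#' @param score Numeric scores.
#' @param cutoff Cutoff value; the high group is `score > cutoff`.
#' @return Character vector `low` / `high`.
#' @export
ndegsGroup <- function(score, cutoff) {
  ifelse(score > cutoff, "high", "low")
}

#' IPCW time-dependent AUC (cumulative/dynamic)
#'
#' Uno-style inverse-probability-of-censoring-weighted estimator of the
#' cumulative/dynamic AUC: at horizon t, cases are subjects with an observed
#' event by t (weighted by 1 / G(T_i), the Kaplan-Meier estimate of the
#' censoring survival), controls are subjects still at risk after t, and
#' score ties count one half.
#'
#' @param score Risk scores (higher = higher risk).
#' @param time,event Survival data.
#' @param times Evaluation horizons (same unit as `time`).
#' @return Named numeric AUC per horizon (NA where no case or no control
#'   exists).
#' @export
timeDependentAUC <- function(score, time, event, times) {
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(cfit$time, c(1, cfit$surv), right = FALSE)
  auc <- vapply(times, function(tt) {
    case <- time <= tt & event == 1
    ctrl <- time > tt
    if (!any(case) || !any(ctrl)) return(NA_real_)
    w <- 1 / pmax(G(time[case]), 1e-12)
    sc <- score[case]; sv <- score[ctrl]
    conc <- vapply(seq_along(sc), function(i)
      sum((sc[i] > sv) + 0.5 * (sc[i] == sv)), numeric(1))
    sum(w * conc) / (sum(w) * length(sv))
  }, numeric(1))
  stats::setNames(auc, paste0("t", times))
}

#' Train/validation evaluation of a risk score
#'
#' Splits the cohort (default 7:3), learns the outcome-based optimal cutoff
#' on the training split only ([xtileCutoff()]), applies it unchanged to the
#' validation split, and reports the validation Kaplan-Meier/log-rank
#' comparison of the risk groups, the Cox hazard ratio of high vs low, and
#' the IPCW time-dependent AUC of the continuous score at the requested
#' horizons (1, 3 and 5 years by default, with time in days).
#'
#' @param score Risk scores.
#' @param time,event Survival data (days).
#' @param trainFrac Training fraction in (0, 1); 7:3 by default.
#' @param seed Seed for the split.
#' @param aucTimes AUC horizons, days.
#' @param minEvents Minimum events required in each split.
#' @param minGroupFrac Passed to [xtileCutoff()].
#' @return List: `cutoff`, `train` (logical index), `group` (all subjects),
#'   `logrank` (validation chisq/p), `cox` (validation HR row), `auc`
#'   (validation AUCs).
#' @export
splitAndEvaluate <- function(score, time, event, trainFrac = 0.7,
                             seed = NA_integer_,
                             aucTimes = c(365, 1095, 1825),
                             minEvents = 10L, minGroupFrac = 0.1) {
  if (trainFrac <= 0 || trainFrac >= 1)
    stop("trainFrac must be strictly between 0 and 1 (both splits non-empty)")
  n <- length(score)
  stopifnot(length(time) == n, length(event) == n)
  if (!is.na(seed)) set.seed(seed)
  train <- rep(FALSE, n)
  train[sample.int(n, round(trainFrac * n))] <- TRUE
  if (sum(event[train]) < minEvents || sum(event[!train]) < minEvents)
    stop("too few events in a split (need >= ", minEvents, " in each)")
  ct <- xtileCutoff(score[train], time[train], event[train],
                    minGroupFrac = minGroupFrac)
  group <- ndegsGroup(score, ct$cutoff)
  val <- !train
  if (length(unique(group[val])) < 2L)
    stop("validation split has a single risk group at the learned cutoff")
  lr <- kmLogrank(time[val], event[val], group[val])
  cox <- fitCox(data.frame(time = time[val], event = event[val],
                           high = as.integer(group[val] == "high")),
                "high")
  auc <- timeDependentAUC(score[val], time[val], event[val], aucTimes)
  list(cutoff = ct$cutoff, train = train, group = group,
       logrank = list(chisq = lr$chisq, p = lr$p), cox = cox, auc = auc)
}

#' Tumour mutational burden
#'
#' Somatic mutations per megabase of interrogated genome; samples at or
#' above `cutoff` mut/Mb are TMB-high.
#'
#' @param mutations data.frame of somatic mutation rows (MAF-like; one row
#'   per mutation) with a sample id column.
#' @param samples Optional character vector of all sample ids (so samples
#'   without any mutation row are reported with TMB 0).
#' @param sampleCol Name of the sample id column.
#' @param interrogatedMb Megabases interrogated (> 0); default 38, a
#'   whole-exome convention.
#' @param cutoff TMB-high cutoff, mut/Mb (inclusive).
#' @return data.frame: `sample`, `n_mutations`, `tmb`, `group`
#'   (`TMB-H` / `TMB-L`).
#' @export
#' @examples
#' tmb(data.frame(sample = rep("s1", 760)))  # 20 mut/Mb, TMB-H
tmb <- function(mutations, samples = NULL, sampleCol = "sample",
                interrogatedMb = 38, cutoff = 20) {
  if (interrogatedMb <= 0) stop("interrogatedMb must be > 0")
  if (!sampleCol %in% names(mutations))
    stop("missing sample column: ", sampleCol)
  counts <- table(mutations[[sampleCol]])
  ids <- union(names(counts), samples)
  n <- stats::setNames(rep(0L, length(ids)), ids)
  n[names(counts)] <- as.integer(counts)
  val <- as.numeric(n) / interrogatedMb
  data.frame(sample = ids, n_mutations = as.integer(n), tmb = val,
             group = ifelse(val >= cutoff, "TMB-H", "TMB-L"),
             row.names = NULL, stringsAsFactors = FALSE)
}
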