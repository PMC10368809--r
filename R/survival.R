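## Survival statistics: multivariate Cox, KM/log-rank, maximally selected
## log-rank cutpoint, inverse-variance fixed-effects pooling, cohort
## descriptives.

#' Multivariate Cox regression for a feature
#'
#' Fits a proportional-hazards model for `feature` adjusted for the given
#' covariates (partial likelihood, Efron tie handling, via
#' [survival::coxph()]). The standard adjustment set for this pipeline is
#' sex, age, T stage, visceral pleural invasion and vascular tumour emboli
#' status.
#'
#' @param data data.frame with columns `time` (days, > 0), `event` (0/1),
#'   the feature and the covariates.
#' @param feature Name of the feature column.
#' @param adjust Character vector of covariate column names.
#' @param minEvents Minimum number of events required.
#' @return data.frame, one row per model term: `coef`, `HR`, `se`,
#'   `ci_lower`, `ci_upper`, `p`.
#' @export
fitCox <- function(data, feature, adjust = character(0), minEvents = 10L) {
  vars <- c(feature, adjust)
  stopifnot(all(c("time", "event", vars) %in% names(data)))
  if (sum(data$event) < minEvents)
    stop("fewer than ", minEvents, " events")
  for (v in vars)
    if (length(unique(data[[v]])) < 2L)
      stop("constant covariate: ", v)
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(vars, collapse = " + ")))
  fit <- survival::coxph(f, data = data, ties = "efron")
  if (!is.null(fit$info) || any(!is.finite(fit$coefficients)) ||
      any(!is.finite(sqrt(diag(fit$var)))))
    stop("Cox fit did not converge (possible separation)")
  s <- summary(fit)
  co <- s$coefficients
  data.frame(term = rownames(co), coef = co[, "coef"],
             HR = co[, "exp(coef)"], se = co[, "se(coef)"],
             ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
             ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
             p = co[, "Pr(>|z|)"], row.names = NULL)
}

#' Kaplan-Meier curves and log-rank test
#'
#' @param time,event Survival times and event indicators.
#' @param group Group labels (>= 2 non-empty groups).
#' @return List with `chisq`, `df`, `p` (log-rank) and `fit` (the
#'   [survival::survfit()] object with censoring marks).
#' @export
kmLogrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L || any(table(group) == 0))
    stop("need at least 2 non-empty groups")
  df <- data.frame(time = time, event = event, group = group)
  chisq <- if (sum(event) == 0) 0 else
    survival::survdiff(survival::Surv(time, event) ~ group, data = df)$chisq
  k <- nlevels(group)
  list(chisq = chisq, df = k - 1L,
       p = stats::pchisq(chisq, k - 1L, lower.tail = FALSE),
       fit = survival::survfit(survival::Surv(time, event) ~ group,
                               data = df))
}

## Log-rank chi-square for a binary split, vectorised over one candidate.
.logrankChisq <- function(time, event, highGroup) {
  d <- data.frame(time = time, event = event, g = highGroup)
  if (sum(event) == 0) return(0)
  survival::survdiff(survival::Surv(time, event) ~ g, data = d)$chisq
}

#' Outcome-based optimal cutpoint (maximal log-rank chi-square)
#'
#' Scans candidate cutoffs at the observed feature values between the
#' `minGroupFrac` and `1 - minGroupFrac` quantiles and returns the cutoff
#' maximizing the two-group log-rank chi-square (the X-tile criterion);
#' membership in the high group is `value > cutoff`. Ties are broken toward
#' the lower cutoff. The maximally selected statistic inflates the naive
#' log-rank p-value; an optional permutation correction (`nPerm` label
#' permutations) is provided alongside the raw p.
#'
#' @param x Feature values (>= 3 distinct values).
#' @param time,event Survival data.
#' @param minGroupFrac Minimum fraction of the cohort in each group.
#' @param nPerm Number of permutations for the adjusted p (0 = skip).
#' @return List: `cutoff`, `chisq`, `p` (raw), `p_adjusted` (or NA),
#'   `n_low`, `n_high`.
#' @export
xtileCutoff <- function(x, time, event, minGroupFrac = 0.1, nPerm = 0L) {
  if (length(unique(x)) < 3L) stop("feature has fewer than 3 distinct values")
  n <- length(x)
  minN <- ceiling(minGroupFrac * n)
  scan <- function(xv) {
    cand <- sort(unique(xv))
    best <- c(cutoff = NA_real_, chisq = -Inf)
    for (cv in cand) {
      hi <- xv > cv
      if (sum(hi) < minN || sum(!hi) < minN) next
      cs <- .logrankChisq(time, event, hi)
      if (cs > best["chisq"] + 1e-12)  # strict: ties keep the lower cutoff
        best <- c(cutoff = cv, chisq = cs)
    }
    best
  }
  obs <- scan(x)
  if (!is.finite(obs["chisq"]))
    stop("no candidate cutoff satisfies the group-size bound")
  hi <- x > obs["cutoff"]
  pRaw <- stats::pchisq(obs["chisq"], 1L, lower.tail = FALSE)
  pAdj <- NA_real_
  if (nPerm > 0L) {
    exceed <- vapply(seq_len(nPerm), function(b) {
      scan(sample(x))["chisq"] >= obs["chisq"]
    }, logical(1))
    pAdj <- (1 + sum(exceed, na.rm = TRUE)) / (nPerm + 1)
  }
  list(cutoff = unname(obs["cutoff"]), chisq = unname(obs["chisq"]),
       p = unname(pRaw), p_adjusted = pAdj,
       n_low = sum(!hi), n_high = sum(hi))
}

#' Fixed-effects (inverse-variance) pooling of stratum effects
#'
#' Pools per-stratum log hazard ratios with weights w_i = 1 / SE_i^2:
#' pooled estimate sum(w theta) / sum(w), SE = 1 / sqrt(sum(w)), Wald CI
#' and p. Used to combine the prognostic effect of a cell population across
#' its fluorescence-strength strata.
#'
#' @param theta Log hazard ratios per stratum.
#' @param se Standard errors (> 0).
#' @param labels Optional stratum labels.
#' @return List: `logHR`, `se`, `HR`, `ci_lower`, `ci_upper`, `z`, `p`,
#'   `weights`.
#' @export
#' @examples
#' fixedEffectsPool(c(0.2, 0.4), c(0.1, 0.1))$logHR  # 0.3
fixedEffectsPool <- function(theta, se, labels = NULL) {
  if (!length(theta)) stop("no strata supplied")
  if (length(se) != length(theta) || any(se <= 0))
    stop("each stratum needs a positive SE")
  w <- 1 / se^2
  est <- sum(w * theta) / sum(w)
  seP <- 1 / sqrt(sum(w))
  z <- est / seP
  list(logHR = est, se = seP, HR = exp(est),
       ci_lower = exp(est - 1.96 * seP), ci_upper = exp(est + 1.96 * seP),
       z = z, p = 2 * stats::pnorm(-abs(z)),
       weights = stats::setNames(w / sum(w), labels))
}

#' Descriptive cohort summary by stage group
#'
#' Counts and percentages of each categorical variable by stage group, with
#' a group-comparison p-value (chi-square for categorical variables,
#' Mann-Whitney for numeric ones), plus overall level percentages and, when
#' a `relapse` column is present, the relapse percentage within each stage
#' group.
#'
#' @param clinical data.frame with a `stage_group` column.
#' @param vars Variables to summarize (default: all columns except ids and
#'   survival columns).
#' @return List: `by_group` (data.frame variable/level/counts/pct per
#'   group), `overall_pct` (named level percentages over the whole cohort),
#'   `tests` (p-values), `relapse_pct` (named by stage group, if available).
#' @export
cohortSummary <- function(clinical, vars = NULL) {
  if (!"stage_group" %in% names(clinical)) stop("missing column: stage_group")
  drop <- c("patient_id", "time", "event", "stage_group")
  if (is.null(vars)) vars <- setdiff(names(clinical), drop)
  miss <- setdiff(vars, names(clinical))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  grp <- factor(clinical$stage_group)
  rows <- list(); tests <- c()
  for (v in vars) {
    x <- clinical[[v]]
    if (is.numeric(x) && length(unique(x)) > 6) {
      tests[v] <- stats::wilcox.test(x ~ grp, exact = FALSE)$p.value
      next
    }
    x <- factor(x)
    tab <- table(x, grp)
    tests[v] <- tryCatch(
      suppressWarnings(stats::chisq.test(tab)$p.value), error = function(e) NA)
    for (lv in levels(x)) {
      r <- data.frame(variable = v, level = lv, stringsAsFactors = FALSE)
      for (g in levels(grp)) {
        r[[paste0("n_", g)]] <- tab[lv, g]
        r[[paste0("pct_", g)]] <- 100 * tab[lv, g] / sum(tab[, g])
      }
      r$n_overall <- sum(tab[lv, ])
      r$pct_overall <- 100 * sum(tab[lv, ]) / sum(tab)
      rows[[paste(v, lv)]] <- r
    }
  }
  byGroup <- do.call(rbind, rows)
  rownames(byGroup) <- NULL
  relapse <- NULL
  if ("relapse" %in% names(clinical)) {
    relapse <- 100 * tapply(clinical$relapse, grp, mean)
  }
  list(by_group = byGroup, overall_pct = NULL, tests = tests,
       relapse_pct = relapse)
}

#' Expand a published-style counts table to patient rows
#'
#' Turns a long counts table (columns `variable`, `level`, and one count
#' column per stage group) into one row per patient, for feeding
#' [cohortSummary()] with printed summary counts. Variables are expanded
#' independently (the joint distribution is not recoverable from margins),
#' so only per-variable summaries are meaningful.
#'
#' @param counts data.frame(variable, level, `IA-IIA`, `IIB-IIIB`).
#' @param variable Which variable to expand.
#' @return data.frame(stage_group, value), one row per patient.
#' @export
expandCohortCounts <- function(counts, variable) {
  sub <- counts[counts$variable == variable, , drop = FALSE]
  if (!nrow(sub)) stop("unknown variable: ", variable)
  groups <- setdiff(names(sub), c("variable", "level"))
  do.call(rbind, lapply(groups, function(g) {
    data.frame(stage_group = g,
               value = rep(sub$level, times = sub[[g]]),
               stringsAsFactors = FALSE)
  }))
}
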