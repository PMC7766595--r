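# Classification metrics, correlations and survival analyses surrounding the
# marker. Kaplan-Meier, log-rank and Cox fits delegate to the survival
# package; the module fixes the contracts (Greenwood/log(-log) intervals,
# Efron ties, Wald tests at z = 1.96).

#' Dichotomise clinical outcome
#'
#' Ovarian carcinoma: poor outcome is recurrence or cancer-specific death
#' within ten years after surgery; patients who survived ten years without
#' recurring are good; patients censored before ten years are `unknown`
#' (excluded from classification training/testing but still used in survival
#' analyses, where no dichotomisation applies). Endometrial carcinoma: poor
#' outcome is cancer-specific death; all other patients are good.
#'
#' @param records data frame with `time_years` and `event` columns.
#' @param cancer_type `"ovarian"` or `"endometrial"`.
#' @param horizon_years dichotomisation horizon for ovarian (default 10).
#' @return Character vector `"good"`/`"poor"`/`"unknown"` per record.
#' @export
dichotomize_outcome <- function(records, cancer_type = c("ovarian", "endometrial"),
                                horizon_years = 10) {
  cancer_type <- match.arg(cancer_type)
  if (cancer_type == "ovarian") {
    ifelse(records$event == 1 & records$time_years < horizon_years, "poor",
      ifelse(records$time_years >= horizon_years, "good", "unknown"))
  } else {
    ifelse(records$event == 1, "poor", "good")
  }
}

#' Classification metrics of the marker calls
#'
#' DCC counts as a prediction of poor outcome. Sensitivity is the fraction
#' of poor-outcome patients called DCC, specificity the fraction of
#' good-outcome patients called SCC, BCCR (balanced correct classification
#' rate, i.e. balanced accuracy) their mean, and CCR the overall accuracy
#' weighted by the true class sizes.
#'
#' @param calls character vector of `"DCC"`/`"SCC"` calls.
#' @param truth character vector of `"poor"`/`"good"` outcomes; other values
#'   are excluded pairwise.
#' @return List with `sensitivity`, `specificity`, `bccr`, `ccr`, `n`. A
#'   truth class with no patients yields `NA` for the affected metrics, with
#'   a warning.
#' @export
confusion_metrics <- function(calls, truth) {
  keep <- truth %in% c("poor", "good")
  calls <- calls[keep]; truth <- truth[keep]
  npoor <- sum(truth == "poor"); ngood <- sum(truth == "good")
  if (npoor == 0 || ngood == 0)
    warning("a truth class is empty; sensitivity/specificity undefined")
  sens <- if (npoor > 0) mean(calls[truth == "poor"] == "DCC") else NA_real_
  spec <- if (ngood > 0) mean(calls[truth == "good"] == "SCC") else NA_real_
  correct <- (calls == "DCC") == (truth == "poor")
  list(sensitivity = sens, specificity = spec,
       bccr = (sens + spec) / 2, ccr = mean(correct),
       n = length(calls))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y paired continuous values (pairs with missing values dropped).
#' @param conf_z normal quantile of the interval (default 1.96 for 95%).
#' @return List with `r`, `ci` (length 2) and `n`.
#' @export
pearson_correlation <- function(x, y, conf_z = 1.96) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop_value("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_value("zero variance in correlation input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    ci <- c(r, r)
  } else {
    z <- atanh(r)
    ci <- tanh(z + c(-1, 1) * conf_z / sqrt(n - 3))
  }
  list(r = r, ci = ci, n = n)
}

#' Kaplan-Meier estimate with Greenwood log(-log) intervals
#'
#' Product-limit estimator per group with 95% confidence intervals on the
#' log(-log) scale, plus the estimated survival at requested horizons.
#'
#' @param records data frame with `time_years` and `event`.
#' @param group optional grouping vector (default: a single group).
#' @param horizons times (years) at which survival is reported
#'   (default `c(5, 10)`).
#' @return List with `curve` (data frame: group, time, n_risk, n_event,
#'   survival, lower, upper) and `at_horizons` (data frame: group, time,
#'   survival, lower, upper).
#' @export
km_estimate <- function(records, group = NULL, horizons = c(5, 10)) {
  if (nrow(records) < 1) stop_value("no records")
  g <- if (is.null(group)) rep("all", nrow(records)) else as.character(group)
  d <- data.frame(time = records$time_years, event = records$event, g = g)
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = d,
                           conf.type = "log-log")
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(d$g)[1], length(sm$time)) else
    sub("^g=", "", as.character(sm$strata))
  curve <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                      n_event = sm$n.event, survival = sm$surv,
                      lower = sm$lower, upper = sm$upper,
                      stringsAsFactors = FALSE)
  at <- do.call(rbind, lapply(horizons, function(h) {
    s <- summary(fit, times = h, extend = TRUE)
    gh <- if (is.null(s$strata)) rep(unique(d$g)[1], length(s$time)) else
      sub("^g=", "", as.character(s$strata))
    data.frame(group = gh, time = h, survival = s$surv,
               lower = s$lower, upper = s$upper, stringsAsFactors = FALSE)
  }))
  list(curve = curve, at_horizons = at)
}

#' Log-rank test between survival groups
#'
#' @param records data frame with `time_years` and `event`.
#' @param group grouping vector with at least two distinct values.
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(records, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) < 2) stop_value("log-rank requires >= 2 groups")
  d <- data.frame(time = records$time_years, event = records$event, g = g)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  df <- length(sd_$n) - 1
  list(chisq = sd_$chisq, df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit with Wald statistics
#'
#' Partial-likelihood maximisation with Efron tie handling via
#' [survival::coxph()]. Hazard ratios with 95% Wald intervals
#' (`exp(beta +- 1.96 se)`) and Wald chi-square p values per coefficient.
#' Constant covariates (rank deficiency) and non-convergence or monotone
#' likelihood (infinite estimates) are flagged as errors / diagnostics.
#'
#' @param records data frame with `time_years`, `event` and the covariate
#'   columns; rows with missing values in used variables are excluded.
#' @param covariates character vector of covariate column names.
#' @return Data frame with one row per fitted coefficient: `term`, `beta`,
#'   `se`, `hr`, `hr_lower`, `hr_upper`, `wald_chisq`, `p`; the fitted model
#'   and any diagnostic message are attached as attributes `fit` and
#'   `diagnostic`.
#' @export
cox_fit <- function(records, covariates) {
  use <- c("time_years", "event", covariates)
  d <- records[stats::complete.cases(records[, use, drop = FALSE]), use,
               drop = FALSE]
  if (sum(d$event) < 1) stop_value("no events among complete records")
  for (v in covariates) {
    if (length(unique(d[[v]])) < 2)
      stop_value(sprintf("covariate '%s' is constant (rank deficiency)", v))
  }
  fm <- stats::as.formula(paste("survival::Surv(time_years, event) ~",
                                paste(covariates, collapse = " + ")))
  diagnostic <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fm, data = d, ties = "efron"),
    warning = function(w) {
      diagnostic <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (anyNA(beta)) stop_numerical("Cox design matrix is rank deficient")
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(beta)) || any(abs(beta) > 50))
    diagnostic <- paste(c(diagnostic, "possible monotone likelihood"),
                        collapse = "; ")
  out <- data.frame(term = names(beta), beta = unname(beta), se = unname(se),
                    hr = exp(unname(beta)),
                    hr_lower = exp(unname(beta) - 1.96 * unname(se)),
                    hr_upper = exp(unname(beta) + 1.96 * unname(se)),
                    wald_chisq = unname(beta / se)^2,
                    p = stats::pchisq(unname(beta / se)^2, 1, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "diagnostic") <- diagnostic
  out
}

#' Named multivariable covariate presets
#'
#' The ovarian model adjusts the marker for FIGO substage (IB or IC vs. IA)
#' and histological grade (grade 3 or clear cell vs. grade 1 or 2); the
#' endometrial model for age (continuous) and pathological risk
#' classification (high vs. low risk).
#'
#' @param cancer_type `"ovarian"` or `"endometrial"`.
#' @return Character vector of covariate column names.
#' @export
covariate_preset <- function(cancer_type = c("ovarian", "endometrial")) {
  switch(match.arg(cancer_type),
         ovarian = c("figo_substage", "grade_class"),
         endometrial = c("age", "path_risk"))
}

#' Integrate the marker call with the pathological risk classification
#'
#' Low risk = SCC and LPR; high risk = DCC and HPR; medium risk when the two
#' markers indicate different prognoses. Missing inputs yield `NA`.
#'
#' @param call `"DCC"`/`"SCC"` vector.
#' @param path_risk `"HPR"`/`"LPR"` vector.
#' @return Character vector `"low"`/`"medium"`/`"high"` (or `NA`).
#' @export
integrate_risk <- function(call, path_risk) {
  out <- ifelse(call == "SCC" & path_risk == "LPR", "low",
         ifelse(call == "DCC" & path_risk == "HPR", "high", "medium"))
  out[!(call %in% c("DCC", "SCC")) | !(path_risk %in% c("HPR", "LPR"))] <- NA
  out
}
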