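# Five-year overall-survival analysis of amplification-defined patient
# groups, built on the survival package (product-limit estimator, log-rank
# test, Cox proportional hazards with Efron tie handling).

.check_surv <- function(records) {
  need <- c("time", "event")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("survival records lack columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(records$time)) || any(records$time <= 0)) {
    stop("survival times must be positive")
  }
  invisible(records)
}

#' Censor survival records at a follow-up horizon
#'
#' Events beyond the horizon become censored observations at the horizon;
#' all times are truncated to it. The default emulates a five-year
#' overall-survival endpoint.
#'
#' @param records data.frame with `time` (years, positive) and `event`
#'   (0/1 or logical).
#' @param horizon Follow-up horizon in years; default 5.
#' @return The records with `time` and `event` adjusted.
#' @export
censor_at_horizon <- function(records, horizon = 5) {
  .check_surv(records)
  over <- records$time > horizon
  records$event[over] <- 0L
  records$time <- pmin(records$time, horizon)
  records$event <- as.integer(records$event)
  records
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator per group, with the survival probability read off
#' at a landmark time.
#'
#' @param records data.frame with `time`, `event` and a `group` column.
#' @param group Name of the grouping column; default `"group"`.
#' @param at Landmark time for the reported survival probability; default 5.
#' @return A list with `fit` (a [survival::survfit] object) and `surv_at`,
#'   a data.frame of per-group survival at `at`.
#' @export
km_estimate <- function(records, group = "group", at = 5) {
  .check_surv(records)
  if (!group %in% names(records)) stop("grouping column '", group, "' missing")
  g <- factor(records[[group]])
  if (any(table(g) == 0L)) stop("empty group")
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ g
  )
  sm <- summary(fit, times = at, extend = TRUE)
  strata <- if (is.null(sm$strata)) levels(g) else sub("^g=", "", as.character(sm$strata))
  list(
    fit = fit,
    surv_at = data.frame(group = strata, time = at, surv = sm$surv,
                         n_risk = sm$n.risk, stringsAsFactors = FALSE)
  )
}

#' Log-rank test between survival groups
#'
#' @inheritParams km_estimate
#' @return A list with `statistic` (chi-square), `df`, `p_value`,
#'   `method_tag`.
#' @export
logrank_test <- function(records, group = "group") {
  .check_surv(records)
  g <- factor(records[[group]])
  if (nlevels(droplevels(g)) < 2L) stop("log-rank test needs at least 2 groups")
  sd <- survival::survdiff(survival::Surv(records$time, records$event) ~ g)
  df <- length(sd$n) - 1L
  list(statistic = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       method_tag = "logrank")
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron handling of tied event times, returning
#' Wald confidence intervals and p-values per coefficient. With a single
#' covariate this is the univariable model; with several, the multivariable
#' model.
#'
#' @param records data.frame with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param conf_level Confidence level of the Wald interval; default 0.95.
#' @return data.frame with one row per fitted coefficient: `term`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`, `model` (`"univariable"` or
#'   `"multivariable"`), plus attribute `fit` with the
#'   [survival::coxph] object.
#' @export
cox_fit <- function(records, covariates, conf_level = 0.95) {
  .check_surv(records)
  miss <- setdiff(covariates, names(records))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  for (cv in covariates) {
    if (length(unique(records[[cv]][!is.na(records[[cv]])])) < 2L) {
      stop("covariate '", cv, "' is constant")
    }
  }
  if (sum(records$event) < 1L) stop("no events in the data")
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~", paste(covariates, collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = records, ties = "efron")
  if (!is.null(fit$info) || any(!is.finite(stats::coef(fit)))) {
    stop("Cox fit did not converge (possible separation); inspect the data")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  out <- data.frame(
    term = names(beta),
    hr = exp(beta),
    ci_lower = exp(beta - z * se),
    ci_upper = exp(beta + z * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    model = if (length(covariates) == 1L) "univariable" else "multivariable",
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "fit") <- fit
  out
}

#' Build the survival analysis table from cohort metadata
#'
#' Restricts to stage I-III microsatellite-stable tumors, censors at the
#' horizon, dichotomizes age at the analysis cohort's median, and attaches
#' the amplification exposure group.
#'
#' @param metadata Cohort metadata with columns `sample`, `msi`, `stage`,
#'   `age`, `gender`, `localization`, `os_time`, `os_event`.
#' @param carriers Character vector of sample ids carrying a qualifying
#'   amplification.
#' @param horizon Follow-up horizon in years; default 5.
#' @return data.frame ready for [km_estimate()], [logrank_test()] and
#'   [cox_fit()], with columns `time`, `event`, `amplified`, `age_high`,
#'   `gender`, `localization`, `stage`.
#' @export
build_survival_records <- function(metadata, carriers, horizon = 5) {
  keep <- metadata$msi == "MSS" & metadata$stage %in% c("I", "II", "III")
  md <- metadata[keep, , drop = FALSE]
  rec <- data.frame(
    sample = md$sample,
    time = md$os_time,
    event = as.integer(md$os_event),
    amplified = as.integer(md$sample %in% carriers),
    age_high = as.integer(md$age > stats::median(md$age)),
    gender = factor(md$gender),
    localization = factor(md$localization),
    stage = factor(md$stage, levels = c("I", "II", "III")),
    stringsAsFactors = FALSE
  )
  censor_at_horizon(rec, horizon)
}
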