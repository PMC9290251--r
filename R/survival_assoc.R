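#' Kaplan-Meier product-limit estimate for one group
#'
#' Ties between events and censorings at the same time are resolved
#' events-first (the product-limit convention). Computed via
#' [survival::survfit()].
#'
#' @param time Follow-up times (months), `>= 0`.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return `data.frame` with `time` (distinct event/censoring times),
#'   `n_risk`, `n_event`, `surv` (non-increasing, `S(0) = 1`).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("empty survival input")
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Computes the log-rank statistic (sum of observed-minus-expected event
#' counts over distinct event times, squared, over its variance) and its
#' p-value from a chi-square with 1 df, via [survival::survdiff()].
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level group labels.
#' @return List with `statistic`, `p_value`, `n` (per-group sizes),
#'   `observed` and `expected` event counts per group.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2L) stop("exactly two non-empty groups required")
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(statistic = unname(sd0$chisq),
       p_value = unname(pchisq(sd0$chisq, df = 1, lower.tail = FALSE)),
       n = as.vector(sd0$n), observed = as.vector(sd0$obs),
       expected = as.vector(sd0$exp))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Efron approximation for tied
#' event times, via [survival::coxph()]; Wald 95% confidence intervals.
#'
#' @param time,event As in [km_estimate()].
#' @param covariates `data.frame` of numeric or binary-encoded covariates
#'   (one column per term).
#' @param ties Tie handling: `"efron"` (default) or `"breslow"`.
#' @return `data.frame` with one row per covariate: `term`, `loghr`, `hr`,
#'   `ci_lo`, `ci_hi`, `p`; convergence flag in attribute `"converged"`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (sum(event) < 1) stop("no events in survival input")
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  s <- summary(fit)
  z <- stats::qnorm(0.975)
  beta <- s$coefficients[, "coef"]
  se <- s$coefficients[, "se(coef)"]
  out <- data.frame(term = rownames(s$coefficients), loghr = unname(beta),
                    hr = unname(exp(beta)),
                    ci_lo = unname(exp(beta - z * se)),
                    ci_hi = unname(exp(beta + z * se)),
                    p = unname(s$coefficients[, "Pr(>|z|)"]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "converged") <- is.null(fit$fail)
  out
}

#' Administrative truncation of follow-up
#'
#' Caps follow-up at `months`: subjects followed beyond the cap are
#' censored at the cap. Applied before cohort-specific survival analyses
#' when follow-up horizons differ across cohorts.
#'
#' @param time,event As in [km_estimate()].
#' @param months Truncation horizon.
#' @return List with truncated `time` and `event`.
#' @export
truncate_followup <- function(time, event, months) {
  over <- time > months
  list(time = pmin(time, months), event = ifelse(over, 0, event))
}

#' Survival association of epi-cluster labels
#'
#' Convenience recipe joining a clinical table with subtype assignments:
#' Kaplan-Meier per subtype, a two-group log-rank test, and a Cox model.
#' Covariates are screened univariately first; those with univariate Wald
#' p below `screen_alpha` enter the multivariate fit together with the
#' subtype indicator.
#'
#' @param clinical Clinical `data.frame` from [read_clinical()].
#' @param assignments Assignment `data.frame` (`sample`, `label`).
#' @param endpoint `"os"` or `"pfs"`.
#' @param truncate_months Optional administrative censoring horizon.
#' @param covariates Optional character vector of clinical covariate
#'   columns to screen.
#' @param screen_alpha Univariate inclusion threshold.
#' @return List with `km` (per-label estimates), `logrank`, `cox`
#'   (multivariate fit), and `univariate` screen results.
#' @export
subtype_survival <- function(clinical, assignments,
                             endpoint = c("os", "pfs"),
                             truncate_months = NULL, covariates = NULL,
                             screen_alpha = 0.05) {
  endpoint <- match.arg(endpoint)
  dat <- merge(clinical, assignments, by.x = "sample", by.y = "sample")
  time <- dat[[paste0(endpoint, "_time")]]
  event <- dat[[paste0(endpoint, "_event")]]
  if (!is.null(truncate_months)) {
    tr <- truncate_followup(time, event, truncate_months)
    time <- tr$time; event <- tr$event
  }
  subtype <- as.integer(dat$label == "Methy-High")
  km <- lapply(split(seq_along(time), dat$label),
               function(i) km_estimate(time[i], event[i]))
  lr <- logrank_test(time, event, dat$label)
  uni <- NULL
  keep_cov <- character()
  for (cv in covariates) {
    u <- cox_fit(time, event, dat[, cv, drop = FALSE])
    uni <- rbind(uni, u)
    if (!is.na(u$p[1L]) && u$p[1L] < screen_alpha) keep_cov <- c(keep_cov, cv)
  }
  cov_df <- cbind(data.frame(subtype_high = subtype),
                  dat[, keep_cov, drop = FALSE])
  cox <- cox_fit(time, event, cov_df)
  list(km = km, logrank = lr, cox = cox, univariate = uni)
}
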