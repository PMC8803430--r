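#' Kaplan-Meier product-limit estimate
#'
#' @param time positive event/censoring times (months).
#' @param event 1 = event observed, 0 = censored.
#' @return data.frame with one row per observed time: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (nonincreasing, S(0) = 1 implicitly).
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop_ts("need >= 1 subject")
  if (any(time <= 0)) stop_ts("times must be positive")
  if (!is_binary01(as.numeric(event))) stop_ts("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the pooled event times,
#' 1 df, two-sided.
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level grouping vector.
#' @return List with `chi2`, `p`, and the per-group observed/expected
#'   event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop_ts("log-rank needs exactly 2 non-empty groups")
  if (sum(event) < 1L) stop_ts("log-rank needs >= 1 event")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- sd_$chisq
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = sd_$obs, expected = sd_$exp)
}

#' Cox proportional-hazards regression (Breslow ties)
#'
#' Wraps the partial-likelihood Newton fit; reports the hazard ratio,
#' 95% Wald confidence interval and two-sided p per covariate. With
#' `univariate = TRUE` each covariate is fitted in its own model (the
#' usual screening table before a multivariate fit).
#'
#' @param table data.frame with columns `time`, `event`, plus covariates.
#' @param covariates character vector of covariate column names.
#' @param univariate fit one model per covariate instead of a joint one.
#' @return data.frame: `covariate`, `coef`, `hr`, `ci_low`, `ci_high`, `p`.
#' @export
cox_fit <- function(table, covariates, univariate = FALSE) {
  stopifnot(all(c("time", "event") %in% names(table)))
  missing_cov <- setdiff(covariates, names(table))
  if (length(missing_cov))
    stop_ts("covariates absent from table: ", paste(missing_cov, collapse = ", "))
  if (sum(table$event) < 5 * length(covariates) && !univariate)
    warning("fewer than 5 events per covariate; estimates may be unstable")
  fit_one <- function(covs) {
    f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covs, collapse = " + ")))
    fit <- survival::coxph(f, data = table, ties = "breslow")
    s <- summary(fit)
    data.frame(covariate = rownames(s$coefficients),
               coef = s$coefficients[, "coef"],
               hr = s$coefficients[, "exp(coef)"],
               ci_low = s$conf.int[, "lower .95"],
               ci_high = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  if (univariate) {
    out <- do.call(rbind, lapply(covariates, fit_one))
  } else {
    out <- fit_one(covariates)
  }
  rownames(out) <- NULL
  out
}

#' Time-dependent ROC AUC with censoring weights
#'
#' Cumulative-cases / dynamic-controls AUC at each horizon: cases have an
#' observed event by the horizon, controls are still under observation
#' beyond it. Pairs are weighted by inverse-probability-of-censoring
#' weights from the Kaplan-Meier estimate of the censoring distribution
#' (cases at their event time's left limit, controls at the horizon), so
#' with no censoring the estimate reduces to the plain binary AUC of
#' `T <= horizon` against the score.
#'
#' @param score risk score (higher = higher event risk).
#' @param time,event as in [km_estimate()].
#' @param horizons evaluation horizons in the time unit of `time`
#'   (default `c(12, 36, 60)` months, i.e. 1/3/5 years).
#' @return data.frame: `horizon`, `auc` (NA when a horizon has no case or
#'   no control), `n_case`, `n_control`.
#' @export
time_dependent_roc <- function(score, time, event, horizons = c(12, 36, 60)) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  # KM of the censoring distribution (event indicator flipped)
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(t) {
    # left-continuous censoring survival G(t-)
    vapply(t, function(ti) {
      s <- c(1, cfit$surv)[findInterval(ti, cfit$time, left.open = TRUE) + 1L]
      max(s, 1e-12)
    }, numeric(1))
  }
  out <- lapply(horizons, function(h) {
    case <- which(time <= h & event == 1)
    ctrl <- which(time > h)
    if (length(case) == 0L || length(ctrl) == 0L)
      return(data.frame(horizon = h, auc = NA_real_,
                        n_case = length(case), n_control = length(ctrl)))
    w_case <- 1 / G(time[case])
    w_ctrl <- rep(1 / G(h), length(ctrl))
    conc <- outer(score[case], score[ctrl],
                  function(a, b) (a > b) + 0.5 * (a == b))
    wmat <- outer(w_case, w_ctrl)
    data.frame(horizon = h, auc = sum(conc * wmat) / sum(wmat),
               n_case = length(case), n_control = length(ctrl))
  })
  do.call(rbind, out)
}
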