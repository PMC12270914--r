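# Mortality analyses: Cox proportional hazards for age-acceleration
# predictors (HR per s.d., adjusted for age and sex), Kaplan-Meier curves
# for the extreme DNAm IC quintiles, log-rank tests and restricted-mean
# survival contrasts. The partial-likelihood machinery is delegated to the
# survival package (Efron tie handling), wrapped behind this module's
# contracts.

#' Cox proportional-hazards fit for an acceleration predictor
#'
#' Fits `Surv(time, event) ~ focal + covariates` with Efron tie handling.
#' The focal predictor is standardized to unit variance (unless
#' `standardize = FALSE`) so the hazard ratio is per one s.d.
#'
#' @param time follow-up times (> 0).
#' @param event 0/1 event indicator.
#' @param focal numeric focal predictor (e.g. age acceleration).
#' @param covariates optional data.frame of adjustment covariates
#'   (typically age and sex).
#' @param standardize scale `focal` to sd 1 before fitting.
#' @return a `cox_fit` list: coef (log HR), hr, ci (95%), p (two-sided
#'   Wald), n, n_events, and the underlying `survival::coxph` fit.
#' @export
cox_fit <- function(time, event, focal, covariates = NULL,
                    standardize = TRUE) {
  check_aligned(length(time), length(event), "time", "event")
  check_aligned(length(time), length(focal), "time", "focal")
  if (sum(event) < 2L) {
    stop_ic("need at least 2 events", class = "icclock_contract_error")
  }
  if (stats::sd(focal) == 0) {
    stop_ic("constant focal predictor", class = "icclock_identifiability_error")
  }
  if (standardize) focal <- as.numeric(scale(focal))
  df <- data.frame(time = time, event = event, focal = focal)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    check_aligned(length(time), nrow(covariates), "time", "covariate rows")
    df <- cbind(df, covariates)
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df,
                         ties = "efron")
  sm <- summary(fit)
  i <- which(rownames(sm$coefficients) == "focal")
  co <- sm$coefficients[i, ]
  ci <- sm$conf.int[i, c("lower .95", "upper .95")]
  structure(list(
    coef = unname(co["coef"]),
    hr = unname(exp(co["coef"])),
    ci = unname(ci),
    se = unname(co["se(coef)"]),
    p = unname(co["Pr(>|z|)"]),
    n = length(time),
    n_events = sum(event),
    fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH: HR %.3f per s.d. (95%% CI %.3f-%.3f), Wald p %.3g, %d events / %d\n",
              x$hr, x$ci[1], x$ci[2], x$p, x$n_events, x$n))
  invisible(x)
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator with the standard convention that censoring at an
#' event time occurs after the event. Each curve starts at (0, 1) and is a
#' nonincreasing right-continuous step function.
#'
#' @param time,event follow-up times and 0/1 indicators.
#' @param group group labels.
#' @return named list of `km_curve` data.frames (time, n_risk, n_event,
#'   surv), one per group.
#' @export
kaplan_meier <- function(time, event, group) {
  check_aligned(length(time), length(group), "time", "group")
  group <- as.factor(droplevels(as.factor(group)))
  if (any(table(group) == 0L)) {
    stop_ic("empty group", class = "icclock_contract_error")
  }
  out <- lapply(levels(group), function(g) {
    sel <- group == g
    sf <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    cur <- data.frame(time = c(0, sf$time),
                      n_risk = c(sum(sel), sf$n.risk),
                      n_event = c(0, sf$n.event),
                      surv = c(1, sf$surv))
    class(cur) <- c("km_curve", "data.frame")
    cur
  })
  names(out) <- levels(group)
  out
}

#' Two-group log-rank test
#'
#' @param time,event follow-up data.
#' @param group two-level grouping.
#' @return list with `chisq` (1 df) and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) {
    stop_ic("log-rank test requires exactly two nonempty groups",
            class = "icclock_contract_error")
  }
  if (sum(event) < 1L) {
    stop_ic("need at least one event", class = "icclock_contract_error")
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = unname(sd_$chisq),
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

# Area under a KM step curve on [0, tau] by exact rectangle sums.
km_auc <- function(curve, tau) {
  t <- curve$time; s <- curve$surv
  if (tau > max(t)) {
    # constant extrapolation beyond the last observed time is not allowed
    stop_ic("tau ", tau, " exceeds the curve's last observed time ",
            max(t), class = "icclock_truncation_error")
  }
  keep <- t <= tau
  tt <- c(t[keep], tau)
  ss <- c(s[keep], s[sum(keep)])
  sum(diff(tt) * ss[-length(ss)])
}

#' Restricted-mean survival difference between two KM curves
#'
#' Difference of the areas under the two Kaplan-Meier step functions on
#' `[0, tau]`: the expected extra years lived within the horizon by the
#' first group. This is the estimator behind "lives on average X years
#' longer" statements derived from survival curves.
#'
#' @param km_high,km_low `km_curve` data.frames (see [kaplan_meier()]).
#' @param tau horizon in years (must not exceed either curve's last
#'   observed time).
#' @return difference in years (high minus low).
#' @export
rmst_difference <- function(km_high, km_low, tau) {
  km_auc(km_high, tau) - km_auc(km_low, tau)
}
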