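#' Calibration experiments: parameter recovery on synthetic arms
#'
#' Small self-contained simulation studies that check each estimator against
#' the parameters that generated its data. Event times are exponential,
#' calibrated through the 5-year survival (`rate = -log(S5) / 5` per year);
#' administrative censoring is uniform; the death process is Bernoulli from
#' a logistic model. Each experiment returns the fitted quantity together
#' with its standard error so callers can judge recovery on the
#' estimator's own scale.
#'
#' @name calibration
NULL

#' Kaplan-Meier readout of a synthetic exponential arm
#'
#' Draws `n` exponential event times with the rate implied by the 5-year
#' survival `s5`, censors administratively at a uniform 5-8 years, and
#' reads the product-limit estimate at the 5-year point (1826 days).
#'
#' @param n arm size.
#' @param s5 true 5-year event-free survival in (0, 1).
#' @param seed RNG seed.
#' @param censor_years length-2 numeric; administrative censoring drawn
#'   uniformly over this range (years).
#' @return list: `estimate` (survival at 5 years), `std_err` (Greenwood),
#'   `n`, `s5_true`.
#' @export
sim_km_readout <- function(n, s5, seed, censor_years = c(5, 8)) {
  stopifnot(n >= 2, s5 > 0, s5 < 1)
  set.seed(seed)
  rate <- -log(s5) / 5                        # per year
  t_event <- stats::rexp(n, rate) * 365.25
  t_cens <- stats::runif(n, censor_years[1], censor_years[2]) * 365.25
  tte <- data.frame(time = pmin(t_event, t_cens),
                    event = as.integer(t_event <= t_cens))
  curve <- km_estimate(tte, by_group = FALSE)
  list(estimate = surv_at(curve, .DAYS_5Y),
       std_err = surv_at(curve, .DAYS_5Y, what = "std_err"),
       n = n, s5_true = s5)
}

#' Cox recovery of a two-group hazard ratio
#'
#' Simulates exponential event times whose elderly-onset : non-elderly
#' hazard ratio is `hr`, with administrative censoring tuned (by root
#' finding) to the requested censored fraction, and fits the
#' proportional-hazards model with elderly onset as the only covariate.
#'
#' @param n subjects.
#' @param hr true hazard ratio (elderly vs non-elderly onset).
#' @param eo_frac fraction of elderly-onset subjects.
#' @param seed RNG seed.
#' @param censor_frac target fraction of administratively censored subjects.
#' @return list: `estimate` (fitted HR), `se_log`, `hr_true`, `n`,
#'   `n_events`.
#' @export
sim_cox_recovery <- function(n, hr, eo_frac, seed, censor_frac = 0.4) {
  stopifnot(hr > 0, eo_frac > 0, eo_frac < 1, censor_frac > 0,
            censor_frac < 1)
  set.seed(seed)
  eo <- stats::runif(n) < eo_frac
  rate <- ifelse(eo, hr, 1)                   # baseline rate 1 per unit time
  # expected censored fraction under Exp(r) events and U(0, cmax) censoring:
  # P(T > C) = E[(1 - exp(-r * cmax)) / (r * cmax)] mixed over groups
  pcens <- function(cmax)
    eo_frac * (1 - exp(-hr * cmax)) / (hr * cmax) +
    (1 - eo_frac) * (1 - exp(-cmax)) / cmax - censor_frac
  cmax <- stats::uniroot(pcens, c(1e-6, 1e3))$root
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, cmax)
  d <- data.frame(time_steroid = pmin(t_event, t_cens),
                  event_steroid = as.integer(t_event <= t_cens),
                  elderly_onset = eo)
  fit <- fit_outcome_model(d, "steroid", covariates = "elderly_onset")
  list(estimate = fit$estimate[1], se_log = fit$se_log[1], hr_true = hr,
       n = n, n_events = fit$n_events[1])
}

#' Logistic recovery of death odds ratios
#'
#' Simulates Bernoulli deaths from a logistic model with intercept
#' `qlogis(p_base)`, an elderly-onset coefficient `log(or_eo)` and (when
#' `or_steroid` is given) an independent steroid-use indicator with
#' coefficient `log(or_steroid)`, then fits the logistic death model.
#'
#' @param n subjects.
#' @param or_eo true elderly-onset odds ratio.
#' @param p_base baseline death probability (non-elderly, no steroid).
#' @param seed RNG seed.
#' @param eo_frac fraction of elderly-onset subjects.
#' @param or_steroid optional true steroid-use odds ratio.
#' @param p_steroid steroid-use prevalence when `or_steroid` is given.
#' @return list: `fit` (the `model_result`), `estimate_eo`, `se_log_eo`,
#'   and when applicable `estimate_steroid`, `se_log_steroid`.
#' @export
sim_logistic_recovery <- function(n, or_eo, p_base, seed, eo_frac = 0.5,
                                  or_steroid = NULL, p_steroid = 0.34) {
  stopifnot(or_eo > 0, p_base > 0, p_base < 1)
  set.seed(seed)
  eo <- stats::runif(n) < eo_frac
  lin <- stats::qlogis(p_base) + log(or_eo) * eo
  covs <- "elderly_onset"
  d <- data.frame(elderly_onset = eo)
  if (!is.null(or_steroid)) {
    ster <- stats::runif(n) < p_steroid
    lin <- lin + log(or_steroid) * ster
    d$steroid_use <- ster
    covs <- c(covs, "steroid_use")
  }
  d$death <- stats::runif(n) < stats::plogis(lin)
  fit <- fit_outcome_model(d, "death", covariates = covs)
  out <- list(fit = fit,
              estimate_eo = fit$estimate[fit$term == "elderly_onset"],
              se_log_eo = fit$se_log[fit$term == "elderly_onset"])
  if (!is.null(or_steroid)) {
    out$estimate_steroid <- fit$estimate[fit$term == "steroid_use"]
    out$se_log_steroid <- fit$se_log[fit$term == "steroid_use"]
  }
  out
}
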