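#' Multivariable outcome models and group comparisons
#'
#' Three time-to-event outcomes (systemic steroid administration, MTD use,
#' surgery) are modelled with Cox proportional hazards (partial likelihood,
#' Efron tie handling — claims dates are day-granular with many ties) and
#' reported as hazard ratios; death is modelled with multivariable logistic
#' regression and reported as odds ratios. Categorical group comparisons use
#' the Pearson chi-square test without continuity correction (Fisher's exact
#' test is available as an alternative for sparse tables).
#'
#' @name outcome-models
NULL

# default covariate sets per outcome (reference levels: male, non-elderly
# onset, non-academic, no steroid, no MTD)
.MODEL_COVARIATES <- list(
  steroid = c("female", "elderly_onset", "academic"),
  mtd     = c("female", "elderly_onset", "academic", "steroid_use"),
  surgery = c("female", "elderly_onset", "academic", "steroid_use",
              "mtd_use"),
  death   = c("female", "elderly_onset", "academic", "steroid_use",
              "mtd_use"))

#' One-row-per-patient analysis dataset from a cohort
#'
#' Derives the model covariates (`female`, `elderly_onset`, `academic`,
#' `steroid_use`, `mtd_use`) and per-outcome time/event columns
#' (`time_steroid`/`event_steroid`, ..., plus the `death` indicator).
#'
#' @param cohort_obj a `uc_cohort`.
#' @return data.frame, one row per patient.
#' @export
build_analysis_dataset <- function(cohort_obj) {
  co <- if (inherits(cohort_obj, "uc_cohort")) cohort_obj$cohort
  else cohort_obj
  out <- data.frame(patient_id = co$patient_id,
                    female = co$sex == "female",
                    elderly_onset = co$onset_group == "EO",
                    academic = co$academic,
                    steroid_use = co$steroid_use,
                    mtd_use = co$mtd_use,
                    death = co$death,
                    stringsAsFactors = FALSE)
  for (oc in c("steroid", "mtd", "surgery")) {
    tte <- extract_time_to_event(co, oc)
    out[[paste0("time_", oc)]] <- tte$time
    out[[paste0("event_", oc)]] <- tte$event
  }
  out
}

#' Fit a multivariable outcome model
#'
#' For `steroid`, `mtd` and `surgery`: Cox proportional-hazards on the
#' time-to-event columns (`ties = "efron"`), hazard ratios. For `death`:
#' logistic regression, odds ratios. Wald 95% confidence intervals and
#' p-values throughout.
#'
#' @param data analysis dataset from [build_analysis_dataset()] (or any
#'   data.frame with the needed `time_*`/`event_*`/indicator columns).
#' @param outcome one of `"steroid"`, `"mtd"`, `"surgery"`, `"death"`.
#' @param covariates character vector of covariate column names; defaults to
#'   the study's covariate set for that outcome.
#' @return a `model_result` data.frame: `outcome`, `family`, `term`,
#'   `estimate` (HR or OR), `ci_low`, `ci_high`, `p_value`, `n`, `n_events`.
#' @export
fit_outcome_model <- function(data,
                              outcome = c("steroid", "mtd", "surgery",
                                          "death"),
                              covariates = NULL) {
  outcome <- match.arg(outcome)
  if (is.null(covariates)) covariates <- .MODEL_COVARIATES[[outcome]]
  covariates <- intersect(covariates, names(data))
  if (length(covariates) == 0L)
    stop("no covariate columns found in `data`", call. = FALSE)
  rhs <- paste(covariates, collapse = " + ")

  if (outcome == "death") {
    if (!"death" %in% names(data)) stop("no `death` column", call. = FALSE)
    n_ev <- sum(data$death)
    if (n_ev == 0L) stop("degenerate fit: zero death events", call. = FALSE)
    fit <- stats::glm(stats::as.formula(paste("death ~", rhs)),
                      data = data, family = stats::binomial())
    co <- summary(fit)$coefficients
    co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
    term <- rownames(co)
    est <- unname(co[, "Estimate"]); se <- unname(co[, "Std. Error"])
    p <- unname(co[, "Pr(>|z|)"])
    fam <- "logistic"
    n_used <- stats::nobs(fit)
  } else {
    tcol <- paste0("time_", outcome); ecol <- paste0("event_", outcome)
    if (!all(c(tcol, ecol) %in% names(data)))
      stop("missing ", tcol, "/", ecol, " columns", call. = FALSE)
    n_ev <- sum(data[[ecol]])
    if (n_ev == 0L)
      stop("degenerate fit: zero ", outcome, " events", call. = FALSE)
    fml <- stats::as.formula(paste0("survival::Surv(", tcol, ", ", ecol,
                                    ") ~ ", rhs))
    fit <- survival::coxph(fml, data = data, ties = "efron")
    co <- summary(fit)$coefficients
    term <- rownames(co)
    est <- unname(co[, "coef"]); se <- unname(co[, "se(coef)"])
    p <- unname(co[, "Pr(>|z|)"])
    fam <- "proportional_hazards"
    n_used <- fit$n
  }
  if (any(!is.finite(se)) || any(se > 50))
    stop("degenerate fit for outcome '", outcome, "': covariate ",
         paste(term[!is.finite(se) | se > 50], collapse = ", "),
         " is separated or unestimable", call. = FALSE)
  structure(data.frame(outcome = outcome, family = fam,
                       term = sub("TRUE$", "", term),
                       estimate = exp(est),
                       se_log = se,
                       ci_low = exp(est - 1.959964 * se),
                       ci_high = exp(est + 1.959964 * se),
                       p_value = p, n = n_used, n_events = n_ev,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("model_result", "data.frame"))
}

#' Pearson chi-square comparison of a 2 x k contingency table
#'
#' Pearson chi-square without continuity correction (the default group
#' comparison); `method = "fisher"` switches to Fisher's exact test for
#' sparse tables.
#'
#' @param table a 2 x k matrix of non-negative counts (k >= 2).
#' @param method `"pearson"` (default) or `"fisher"`.
#' @param correct apply the Yates continuity correction (Pearson only).
#' @return list with `statistic` (NA for Fisher), `df`, `p_value`.
#' @export
chi_square_compare <- function(table, method = c("pearson", "fisher"),
                               correct = FALSE) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < 2L)
    stop("need a 2 x k table with k >= 2", call. = FALSE)
  if (any(table < 0) || sum(table) == 0)
    stop("counts must be non-negative with a positive total", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero-margin row or column", call. = FALSE)
  if (method == "fisher") {
    ft <- stats::fisher.test(table)
    return(list(statistic = NA_real_, df = NA_integer_,
                p_value = ft$p.value))
  }
  ct <- stats::chisq.test(table, correct = correct)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (type-7 quantiles).
#'
#' @param values numeric vector (non-empty; NAs dropped).
#' @return named numeric: `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2L], q1 = q[1L], q3 = q[3L])
}
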