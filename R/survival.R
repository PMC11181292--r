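#' Time-to-event analyses: event-free and treatment-persistence curves
#'
#' Event-free curves (steroid-free, MTD-free, surgery-free) run from the
#' onset date; treatment-persistence curves run from the first prescription
#' of the first molecular targeting drug. Estimation is product-limit
#' (Kaplan-Meier) with censoring at the earlier of observation end and
#' death; death is treated as right-censoring, not a competing risk. Group
#' curves are compared with the log-rank test.
#'
#' @name survival-analyses
NULL

#' Extract time-to-event records from a cohort
#'
#' @param cohort_obj a `uc_cohort` from [build_cohort()], or its `cohort`
#'   data.frame.
#' @param outcome one of `"steroid"`, `"mtd"`, `"surgery"`.
#' @return data.frame `patient_id`, `time` (days from onset), `event`
#'   (0/1), `group` (onset group). Time runs to the first qualifying event,
#'   censored at the earlier of observation end and death.
#' @export
extract_time_to_event <- function(cohort_obj, outcome = c("steroid", "mtd",
                                                          "surgery")) {
  outcome <- match.arg(outcome)
  co <- if (inherits(cohort_obj, "uc_cohort")) cohort_obj$cohort
  else cohort_obj
  event_date <- switch(outcome,
                       steroid = co$steroid_date,
                       mtd = co$mtd_date,
                       surgery = co$surgery_date)
  # obs_end is already truncated at death for deceased patients
  censor_time <- as.integer(co$obs_end - co$onset_date)
  event <- !is.na(event_date)
  time <- ifelse(event, as.integer(event_date - co$onset_date), censor_time)
  data.frame(patient_id = co$patient_id, time = as.integer(time),
             event = as.integer(event), group = co$onset_group,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()]; censored subjects at an event time are
#' counted at risk for that time (the standard convention). The returned
#' step function starts at 1 and is evaluated with [surv_at()].
#'
#' @param tte data.frame with `time`, `event`, and optionally `group`.
#' @param by_group estimate one curve per `group` level (default when a
#'   `group` column is present).
#' @return a `surv_curve` data.frame: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `std_err` (Greenwood standard error of the
#'   survival estimate).
#' @export
km_estimate <- function(tte, by_group = "group" %in% names(tte)) {
  stopifnot(nrow(tte) >= 1L, all(c("time", "event") %in% names(tte)))
  if (by_group) {
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = tte)
    grp <- if (is.null(fit$strata)) unique(tte$group)
    else sub("^group=", "", names(fit$strata))
    glab <- if (is.null(fit$strata)) rep.int(grp, length(fit$time))
    else rep(grp, fit$strata)
  } else {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = tte)
    glab <- rep.int("all", length(fit$time))
  }
  structure(data.frame(group = glab, time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       surv = fit$surv,
                       std_err = fit$std.err * fit$surv,
                       stringsAsFactors = FALSE),
            class = c("surv_curve", "data.frame"))
}

#' Read a survival curve at given times
#'
#' Step-function evaluation: the estimate at `t` is the value after the last
#' event time `<= t` (1 before the first event time).
#'
#' @param curve a `surv_curve` (single group, or use `group`).
#' @param times numeric vector of times (days).
#' @param group group label to select when the curve holds several.
#' @param what column to read, `"surv"` (default) or `"std_err"`.
#' @return numeric vector, one value per requested time.
#' @export
surv_at <- function(curve, times, group = NULL, what = "surv") {
  if (!is.null(group)) curve <- curve[curve$group == group, , drop = FALSE]
  if (length(unique(curve$group)) > 1L)
    stop("curve holds several groups; pass `group`", call. = FALSE)
  cv <- curve[order(curve$time), , drop = FALSE]
  vapply(times, function(t) {
    i <- which(cv$time <= t)
    if (!length(i)) return(if (what == "surv") 1 else 0)
    cv[[what]][max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Wraps [survival::survdiff()] (rho = 0); 1 degree of freedom.
#'
#' @param tte data.frame with `time`, `event`, `group` (exactly two
#'   non-empty groups).
#' @return list with `statistic` (chi-square), `df`, `p_value`, and the
#'   per-group observed/expected event counts.
#' @export
logrank_test <- function(tte) {
  stopifnot(all(c("time", "event", "group") %in% names(tte)))
  groups <- unique(tte$group)
  if (length(groups) != 2L)
    stop("log-rank comparison needs exactly 2 groups, got ",
         length(groups), call. = FALSE)
  if (any(table(tte$group) == 0L))
    stop("empty group", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = tte)
  list(statistic = unname(sd$chisq), df = 1L,
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Treatment-persistence curves for the first molecular targeting drug
#'
#' Persistence time runs from the first MTD episode start to its
#' discontinuation (event) or to censoring for episodes still ongoing at the
#' patient's observation end. Curves can be stratified by onset group, by
#' drug, or by the azathioprine combination flag (for infliximab).
#'
#' @param cohort_obj a `uc_cohort` (episodes included).
#' @param catalog a `drug_catalog`.
#' @param stratify_by `"group"`, `"drug"`, or `"combo"`.
#' @param drug restrict to one drug id (e.g. `"infliximab"`, required for
#'   `stratify_by = "combo"`).
#' @return list with `tte` (persistence time-to-event records) and `curve`
#'   (a `surv_curve`).
#' @export
persistence_curve <- function(cohort_obj, catalog = default_drug_catalog(),
                              stratify_by = c("group", "drug", "combo"),
                              drug = NULL) {
  stratify_by <- match.arg(stratify_by)
  stopifnot(inherits(cohort_obj, "uc_cohort"))
  co <- cohort_obj$cohort
  eps <- cohort_obj$episodes
  fm <- first_mtd(eps, catalog)
  fm <- fm[fm$patient_id %in% co$patient_id, , drop = FALSE]
  if (!is.null(drug)) fm <- fm[fm$drug_id == drug, , drop = FALSE]
  if (nrow(fm) == 0L) stop("no first-MTD episodes to analyse", call. = FALSE)

  time <- as.integer(fm$end_date - fm$start_date)
  event <- as.integer(fm$status == "discontinued")
  group <- switch(stratify_by,
    group = co$onset_group[match(fm$patient_id, co$patient_id)],
    drug = fm$drug_id,
    combo = {
      if (is.null(drug) || drug != "infliximab")
        stop("combination stratification applies to infliximab; pass drug = ",
             '"infliximab"', call. = FALSE)
      vapply(seq_len(nrow(fm)), function(i) {
        aza <- eps[eps$patient_id == fm$patient_id[i] &
                     eps$drug_id == "azathioprine", , drop = FALSE]
        if (combination_flag(fm$start_date[i], aza)) "combo" else "mono"
      }, character(1))
    })
  tte <- data.frame(patient_id = fm$patient_id, time = time, event = event,
                    group = group, stringsAsFactors = FALSE)
  list(tte = tte, curve = km_estimate(tte))
}

#' Write a survival curve as a delimited step-function table
#'
#' @param curve a `surv_curve`.
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_surv_curve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
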