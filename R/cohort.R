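#' Cohort construction: UC case identification and onset-group classification
#'
#' Implements the extraction flow: identify ulcerative colitis cases from
#' ICD-10 codes (K51, excluding suspicious-only records and Crohn's
#' co-diagnoses), estimate the UC onset date as the earliest qualifying new
#' prescription, keep patients aged >= 65 at the end of observation, and
#' split them into the elderly-onset (EO, onset at >= 65) and
#' non-elderly-onset (NEO, onset < 65 but reaching 65 during observation)
#' groups.
#'
#' @name cohort-builder
NULL

#' Completed years of age at a date, from a year-month birth record
#'
#' Birth records carry year and month only; the day is treated as the 1st
#' and age is the calendar year difference, minus one when the evaluation
#' month precedes the birth month.
#'
#' @param birth_year_month character `"YYYY-MM"`.
#' @param date `Date` (or string) at which to evaluate age.
#' @return integer completed years.
#' @export
age_completed_years <- function(birth_year_month, date) {
  date <- as.Date(date)
  by <- as.integer(substr(birth_year_month, 1L, 4L))
  bm <- as.integer(substr(birth_year_month, 6L, 7L))
  if (anyNA(by) || anyNA(bm) || any(bm < 1L) || any(bm > 12L))
    stop("birth_year_month must be 'YYYY-MM'", call. = FALSE)
  dy <- as.integer(format(date, "%Y"))
  dm <- as.integer(format(date, "%m"))
  age <- dy - by - as.integer(dm < bm)
  if (any(age < 0L, na.rm = TRUE))
    stop("evaluation date precedes birth", call. = FALSE)
  age
}

#' Identify ulcerative colitis cases from a diagnosis table
#'
#' A patient is a UC case when they carry at least one non-suspicious K51
#' diagnosis and no Crohn's (K50) diagnosis at any time. Rows whose ICD-10
#' code is malformed (not letter-digit shaped) are skipped with a single
#' warning reporting the skipped count.
#'
#' @param diagnoses data.frame with `patient_id`, `icd10`, `suspicious`.
#' @return character vector of UC patient ids, with attribute `n_malformed`.
#' @export
identify_uc_cases <- function(diagnoses) {
  stopifnot(all(c("patient_id", "icd10", "suspicious") %in% names(diagnoses)))
  code <- toupper(trimws(diagnoses$icd10))
  ok <- grepl("^[A-Z][0-9]{2}", code)
  n_bad <- sum(!ok)
  if (n_bad > 0L)
    warning("skipped ", n_bad, " diagnosis rows with malformed ICD-10 codes",
            call. = FALSE)
  d <- diagnoses[ok, , drop = FALSE]
  code <- code[ok]
  is_k51 <- startsWith(code, "K51")
  is_k50 <- startsWith(code, "K50")
  uc <- unique(d$patient_id[is_k51 & !d$suspicious])
  crohns <- unique(d$patient_id[is_k50])
  structure(setdiff(uc, crohns), n_malformed = n_bad)
}

#' Estimate the UC onset date for one patient
#'
#' The onset proxy is the earliest new prescription of a qualifying class
#' (5-ASA, systemic steroid, or topical steroid). Novelty is assessed at
#' treatment-course level: the patient's qualifying prescriptions are first
#' assembled into exposure episodes ([build_episodes()]), and every episode
#' start is tested with the 26-week washout
#' ([classify_prescription_novelty()]) against the full same-drug history.
#' Refills inside a continuous episode belong to the course that opened it
#' and are not classified separately. A patient with any "old" episode start
#' is dropped as not new-onset (prevalent or irregular use); a patient with
#' no qualifying prescription has no estimable onset.
#'
#' @param prescriptions prescription rows for one patient (`drug_id`,
#'   `rx_date`, `dispensed`).
#' @param catalog a `drug_catalog`.
#' @param censor_date the patient's observation end.
#' @return list with `onset` (`Date` or `NA`) and `reason` (`"ok"`,
#'   `"no_qualifying_rx"`, or `"old_prescription"`).
#' @export
estimate_onset <- function(prescriptions, catalog, censor_date) {
  qual_ids <- onset_class_ids(catalog)
  p <- prescriptions[prescriptions$drug_id %in% qual_ids, , drop = FALSE]
  if (nrow(p) == 0L)
    return(list(onset = as.Date(NA), reason = "no_qualifying_rx"))
  p <- p[order(p$drug_id, p$rx_date), , drop = FALSE]
  starts <- as.Date(character(0))
  for (did in unique(p$drug_id)) {
    rows <- p[p$drug_id == did, , drop = FALSE]
    eps <- build_episodes(rows$rx_date, rows$dispensed,
                          catalog_get(catalog, did), as.Date(censor_date))
    for (s in seq_len(nrow(eps))) {
      st <- eps$start_date[s]
      hist <- rows$rx_date[rows$rx_date < st]
      if (classify_prescription_novelty(hist, st) == "old")
        return(list(onset = as.Date(NA), reason = "old_prescription"))
    }
    starts <- c(starts, eps$start_date[1L])
  }
  list(onset = min(starts), reason = "ok")
}

#' Classify a patient into the elderly- / non-elderly-onset group
#'
#' @param onset_date `Date` of UC onset.
#' @param birth_year_month `"YYYY-MM"`.
#' @param observation_end `Date`; end of the patient's observation (death
#'   date when the patient died).
#' @return `"EO"` (onset at age >= 65), `"NEO"` (onset < 65, aged >= 65 at
#'   observation end), or `"ineligible"`.
#' @export
classify_group <- function(onset_date, birth_year_month, observation_end) {
  age_onset <- age_completed_years(birth_year_month, onset_date)
  if (age_onset >= 65L) return("EO")
  age_end <- age_completed_years(birth_year_month, observation_end)
  if (age_end >= 65L) "NEO" else "ineligible"
}

#' Build the eligible cohort from a claims bundle
#'
#' Chains UC case identification, onset estimation, and onset-group
#' classification, then attaches outcome indicators and dates derived from
#' exposure episodes and the event table. Exclusion counts are tallied per
#' step; retained + excluded always equals the input patient count.
#'
#' @param bundle a `claims_bundle`.
#' @param catalog a `drug_catalog`; defaults to the packaged catalog.
#' @return a `uc_cohort` list: `cohort` (one row per eligible patient),
#'   `exclusions` (named integer tally: `no_uc_diagnosis`, `suspicious`,
#'   `crohns`, `not_new_onset`, `under_65`), and `episodes` (exposure
#'   episodes of retained patients).
#' @export
build_cohort <- function(bundle, catalog = default_drug_catalog()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  pat <- bundle$patients
  uc_ids <- identify_uc_cases(bundle$diagnoses)

  # disaggregate the non-UC exclusions for the tally
  code <- toupper(trimws(bundle$diagnoses$icd10))
  valid <- grepl("^[A-Z][0-9]{2}", code)
  k51_any <- unique(bundle$diagnoses$patient_id[valid & startsWith(code, "K51")])
  k51_real <- unique(bundle$diagnoses$patient_id[
    valid & startsWith(code, "K51") & !bundle$diagnoses$suspicious])
  k50 <- unique(bundle$diagnoses$patient_id[valid & startsWith(code, "K50")])
  excl <- c(no_uc_diagnosis = sum(!pat$patient_id %in% k51_any),
            suspicious = sum(pat$patient_id %in% setdiff(k51_any, k51_real)),
            crohns = sum(pat$patient_id %in% intersect(k51_real, k50)),
            not_new_onset = 0L, under_65 = 0L)

  keep <- pat$patient_id %in% uc_ids
  rx_by_pat <- split(bundle$prescriptions,
                     factor(bundle$prescriptions$patient_id,
                            levels = pat$patient_id))

  rows <- vector("list", nrow(pat))
  for (i in which(keep)) {
    pid <- pat$patient_id[i]
    obs_end_i <- pat$obs_end[i]
    est <- estimate_onset(rx_by_pat[[pid]], catalog, obs_end_i)
    if (is.na(est$onset)) {
      excl[["not_new_onset"]] <- excl[["not_new_onset"]] + 1L
      next
    }
    grp <- classify_group(est$onset, pat$birth_year_month[i], obs_end_i)
    if (grp == "ineligible") {
      excl[["under_65"]] <- excl[["under_65"]] + 1L
      next
    }
    rows[[i]] <- data.frame(
      patient_id = pid, sex = pat$sex[i],
      birth_year_month = pat$birth_year_month[i],
      onset_date = est$onset,
      age_at_onset = age_completed_years(pat$birth_year_month[i], est$onset),
      age_at_end = age_completed_years(pat$birth_year_month[i], obs_end_i),
      onset_group = grp,
      obs_start = pat$obs_start[i], obs_end = obs_end_i,
      academic = pat$academic[i],
      death = !is.na(pat$death_date[i]), death_date = pat$death_date[i],
      lookback_short =
        as.integer(est$onset - pat$obs_start[i]) < 182L,
      stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(cohort)) cohort <- .empty_cohort()
  rownames(cohort) <- NULL

  # exposure episodes for retained patients, censored at observation end
  rx_keep <- bundle$prescriptions[
    bundle$prescriptions$patient_id %in% cohort$patient_id, , drop = FALSE]
  censor <- as.Date(stats::setNames(cohort$obs_end, cohort$patient_id))
  episodes <- if (nrow(rx_keep))
    build_all_episodes(rx_keep, catalog, censor)
  else NULL

  cohort <- .attach_outcomes(cohort, episodes, bundle$events, catalog)
  structure(list(cohort = cohort, exclusions = excl, episodes = episodes),
            class = "uc_cohort")
}

.empty_cohort <- function() {
  data.frame(patient_id = character(0), sex = character(0),
             birth_year_month = character(0),
             onset_date = as.Date(character(0)),
             age_at_onset = integer(0), age_at_end = integer(0),
             onset_group = character(0),
             obs_start = as.Date(character(0)),
             obs_end = as.Date(character(0)), academic = logical(0),
             death = logical(0), death_date = as.Date(character(0)),
             lookback_short = logical(0), stringsAsFactors = FALSE)
}

# first episode start of the given drug ids at or after onset, per patient
.first_start <- function(episodes, drug_ids, onset_by_pat) {
  out <- rep(as.Date(NA), length(onset_by_pat))
  names(out) <- names(onset_by_pat)
  if (is.null(episodes)) return(out)
  e <- episodes[episodes$drug_id %in% drug_ids, , drop = FALSE]
  e <- e[e$patient_id %in% names(onset_by_pat), , drop = FALSE]
  if (nrow(e) == 0L) return(out)
  e <- e[e$start_date >= onset_by_pat[e$patient_id], , drop = FALSE]
  if (nrow(e) == 0L) return(out)
  agg <- tapply(as.integer(e$start_date), e$patient_id, min)
  out[names(agg)] <- as.Date(as.integer(agg), origin = "1970-01-01")
  out
}

.attach_outcomes <- function(cohort, episodes, events, catalog) {
  n <- nrow(cohort)
  onset_by_pat <- as.Date(stats::setNames(cohort$onset_date,
                                          cohort$patient_id))
  ster_ids <- catalog_class_ids(catalog, "systemic_steroid")
  ster_date <- .first_start(episodes, ster_ids, onset_by_pat)
  cohort$steroid_use <- !is.na(ster_date)
  cohort$steroid_date <- unname(ster_date)

  fm <- if (is.null(episodes))
    data.frame(patient_id = character(0), drug_id = character(0),
               start_date = as.Date(character(0)), stringsAsFactors = FALSE)
  else first_mtd(episodes, catalog)
  if (nrow(fm))  # guard against MTD exposure predating the onset proxy
    fm <- fm[fm$start_date >= onset_by_pat[fm$patient_id], , drop = FALSE]
  idx <- match(cohort$patient_id, fm$patient_id)
  cohort$mtd_use <- !is.na(idx)
  cohort$mtd_first_drug <- ifelse(is.na(idx), NA_character_,
                                  fm$drug_id[idx])
  cohort$mtd_date <- as.Date(ifelse(is.na(idx), NA, fm$start_date[idx]),
                             origin = "1970-01-01")

  lines <- if (is.null(episodes)) integer(0)
  else count_mtd_lines(episodes, catalog)
  cohort$mtd_lines <- ifelse(cohort$patient_id %in% names(lines),
                             unname(lines[cohort$patient_id]), 0L)

  # covered steroid days by route
  po <- .covered_by_drug(episodes, "prednisolone_po", cohort$patient_id)
  iv <- .covered_by_drug(episodes, "prednisolone_iv", cohort$patient_id)
  cohort$steroid_po_days <- po
  cohort$steroid_iv_days <- iv

  # first surgery at or after onset
  surg_date <- rep(as.Date(NA), n)
  if (!is.null(events) && nrow(events)) {
    ev <- events[events$event_type == "surgery" &
                   events$patient_id %in% cohort$patient_id, , drop = FALSE]
    if (nrow(ev)) {
      ev <- ev[ev$event_date >= onset_by_pat[ev$patient_id], , drop = FALSE]
      if (nrow(ev)) {
        agg <- tapply(as.integer(ev$event_date), ev$patient_id, min)
        m <- match(cohort$patient_id, names(agg))
        surg_date <- as.Date(ifelse(is.na(m), NA, agg[m]),
                             origin = "1970-01-01")
      }
    }
  }
  cohort$surgery <- !is.na(surg_date)
  cohort$surgery_date <- surg_date
  cohort
}

.covered_by_drug <- function(episodes, drug_id, patient_ids) {
  out <- rep.int(0L, length(patient_ids))
  if (is.null(episodes)) return(out)
  e <- episodes[episodes$drug_id == drug_id, , drop = FALSE]
  if (nrow(e) == 0L) return(out)
  agg <- tapply(e$covered_days, e$patient_id, sum)
  m <- match(patient_ids, names(agg))
  ifelse(is.na(m), 0L, as.integer(agg[m]))
}

#' @export
print.uc_cohort <- function(x, ...) {
  tab <- table(factor(x$cohort$onset_group, levels = c("EO", "NEO")))
  cat("<uc_cohort> ", nrow(x$cohort), " patients (EO ", tab[["EO"]],
      ", NEO ", tab[["NEO"]], ")\n", sep = "")
  cat("  exclusions:",
      paste(names(x$exclusions), x$exclusions, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
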