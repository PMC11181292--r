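#' Synthetic administrative-claims generator
#'
#' Emulates the statistical structure of a nationwide prescription-claims
#' database for ulcerative colitis so the whole cohort/episode/outcome
#' pipeline can be exercised without proprietary data: a bimodal onset-age
#' distribution (young adults and the elderly), month-granular birth dates,
#' maintenance 5-ASA refill trains from onset, group-specific exponential
#' hazards for steroid initiation, molecular-targeting-drug (MTD) initiation
#' and surgery, and a logistic death process with configurable odds ratios
#' for elderly onset and steroid use. Contamination paths (suspicious-only
#' diagnoses, Crohn's co-diagnosis, never-elderly patients) exercise the
#' cohort exclusion flow.
#'
#' @name synthetic-claims
NULL

.DAYS_5Y <- 1826L  # 5-year readout, 365.25 * 5 rounded

#' Configuration for the synthetic claims generator
#'
#' Defaults reproduce the study conditions: observation window April 2014 to
#' February 2022, elderly-onset share 0.906 among eligible patients, male
#' fraction 0.565, 5-year steroid-free survival 0.576 (EO) / 0.686 (NEO),
#' MTD-free 0.888 / 0.929, surgery-free 0.975 / 0.985, and a logistic death
#' model with baseline (non-elderly, no steroid) probability 0.0072, odds
#' ratio 6.18 for elderly onset and 1.65 for steroid use.
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer RNG seed; a fixed seed gives byte-identical bundles.
#' @param eo_share probability that an eligible patient is elderly-onset
#'   (onset at age >= 65) rather than non-elderly-onset (onset 57-65,
#'   reaching 65 in the window).
#' @param p_young probability of a young-onset patient (onset around age 25)
#'   who never reaches 65 and is excluded by the cohort filter.
#' @param p_male probability of male sex.
#' @param obs_start,obs_end observation window (`Date` or string).
#' @param s5_steroid,s5_mtd,s5_surgery named numeric `c(EO=, NEO=)` 5-year
#'   event-free survival probabilities; converted to exponential hazards
#'   `-log(s5)/1826` per day.
#' @param p_death_base baseline death probability (non-elderly-onset, no
#'   steroid) over the observation period.
#' @param or_death_eo,or_death_steroid odds ratios applied to the death
#'   model for elderly onset and for steroid use.
#' @param refill_days nominal 5-ASA maintenance script length in days.
#' @param refill_noise_days refill-date jitter, uniform on
#'   `[-refill_noise_days, refill_noise_days]`; the default stays well inside
#'   the 13-week discontinuation grace so maintenance episodes stay
#'   continuous.
#' @param steroid_po_meanlog,steroid_po_sdlog log-normal parameters of total
#'   oral prednisolone covered days (median `exp(meanlog)` = 61 days).
#' @param p_steroid_iv probability a steroid user also receives an
#'   intravenous course.
#' @param steroid_iv_meanlog,steroid_iv_sdlog log-normal parameters of
#'   intravenous covered days (median 10 days).
#' @param mtd_persistence_mean_days mean of the exponential treatment
#'   persistence time of an MTD course.
#' @param p_second_mtd probability an MTD user starts a second, different
#'   MTD after discontinuing the first.
#' @param p_combo_aza probability an infliximab starter has azathioprine
#'   active at infliximab initiation (combination therapy).
#' @param p_suspicious probability a patient's UC diagnoses are all flagged
#'   "suspicious" (excluded by the cohort filter).
#' @param p_crohns probability of a Crohn's (K50) co-diagnosis (excluded).
#' @param p_academic probability of the academic-hospital flag.
#' @return a validated `claims_config` list.
#' @export
claims_config <- function(n_patients = 1000L,
                          seed = 1L,
                          eo_share = 0.906,
                          p_young = 0.05,
                          p_male = 0.565,
                          obs_start = "2014-04-01",
                          obs_end = "2022-02-28",
                          s5_steroid = c(EO = 0.576, NEO = 0.686),
                          s5_mtd = c(EO = 0.888, NEO = 0.929),
                          s5_surgery = c(EO = 0.975, NEO = 0.985),
                          p_death_base = 0.0072,
                          or_death_eo = 6.18,
                          or_death_steroid = 1.65,
                          refill_days = 30L,
                          refill_noise_days = 7L,
                          steroid_po_meanlog = log(61),
                          steroid_po_sdlog = 1.3,
                          p_steroid_iv = 0.25,
                          steroid_iv_meanlog = log(10),
                          steroid_iv_sdlog = 0.8,
                          mtd_persistence_mean_days = 540,
                          p_second_mtd = 0.24,
                          p_combo_aza = 0.3,
                          p_suspicious = 0.05,
                          p_crohns = 0.02,
                          p_academic = 0.0054) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              eo_share = eo_share, p_young = p_young, p_male = p_male,
              obs_start = as.Date(obs_start), obs_end = as.Date(obs_end),
              s5_steroid = s5_steroid, s5_mtd = s5_mtd,
              s5_surgery = s5_surgery,
              p_death_base = p_death_base, or_death_eo = or_death_eo,
              or_death_steroid = or_death_steroid,
              refill_days = as.integer(refill_days),
              refill_noise_days = as.integer(refill_noise_days),
              steroid_po_meanlog = steroid_po_meanlog,
              steroid_po_sdlog = steroid_po_sdlog,
              p_steroid_iv = p_steroid_iv,
              steroid_iv_meanlog = steroid_iv_meanlog,
              steroid_iv_sdlog = steroid_iv_sdlog,
              mtd_persistence_mean_days = mtd_persistence_mean_days,
              p_second_mtd = p_second_mtd, p_combo_aza = p_combo_aza,
              p_suspicious = p_suspicious, p_crohns = p_crohns,
              p_academic = p_academic)
  validate_claims_config(cfg)
  structure(cfg, class = "claims_config")
}

#' Validate a generator configuration
#' @param cfg a `claims_config` (or plain list with the same fields).
#' @return the config, invisibly; stops with a message on invalid fields.
#' @export
validate_claims_config <- function(cfg) {
  probs <- c("eo_share", "p_young", "p_male", "p_death_base", "p_steroid_iv",
             "p_second_mtd", "p_combo_aza", "p_suspicious", "p_crohns",
             "p_academic")
  for (p in probs)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("config field '", p, "' must be a probability in [0, 1]",
           call. = FALSE)
  for (s in c("s5_steroid", "s5_mtd", "s5_surgery")) {
    v <- cfg[[s]]
    if (!all(c("EO", "NEO") %in% names(v)) || any(v <= 0) || any(v >= 1))
      stop("config field '", s,
           "' must be named c(EO=, NEO=) survival probabilities in (0, 1)",
           call. = FALSE)
  }
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (cfg$obs_end <= cfg$obs_start)
    stop("obs_end must follow obs_start", call. = FALSE)
  if (cfg$or_death_eo <= 0 || cfg$or_death_steroid <= 0)
    stop("death odds ratios must be positive", call. = FALSE)
  if (cfg$refill_noise_days >= cfg$refill_days)
    stop("refill_noise_days must be smaller than refill_days", call. = FALSE)
  invisible(cfg)
}

# first-MTD choice probabilities by onset group (counts of first MTDs
# observed per group in the reference cohort)
.MTD_FIRST_COUNTS <- list(
  EO  = c(infliximab = 58, adalimumab = 14, golimumab = 11, ustekinumab = 13,
          vedolizumab = 36, tofacitinib = 3, tacrolimus = 36,
          cyclosporine_po = 13, cyclosporine_iv = 1),
  NEO = c(infliximab = 10, adalimumab = 3, golimumab = 1, ustekinumab = 0,
          vedolizumab = 1, tofacitinib = 1, tacrolimus = 4,
          cyclosporine_po = 0, cyclosporine_iv = 0))

# exponential rate per day from a 5-year survival probability
.rate_from_s5 <- function(s5) -log(s5) / .DAYS_5Y

# birth year-month string from an onset date and an exact age in years
.birth_ym <- function(onset, age_years) {
  b <- onset - round(age_years * 365.25)
  format(b, "%Y-%m")
}

# refill train: dates and dispensed amounts covering [from, until] under a
# prescription_days-style rule with jittered refill gaps
.refill_train <- function(from, until, script_days, noise) {
  total <- as.integer(until - from)
  if (total < 0L) return(list(dates = as.Date(character(0)),
                              dispensed = integer(0)))
  n_max <- ceiling((total + 1) / max(1L, script_days - noise)) + 1L
  gaps <- script_days + sample.int(2L * noise + 1L, n_max, replace = TRUE) -
    noise - 1L
  offs <- cumsum(c(0L, gaps))
  offs <- offs[offs <= total]
  list(dates = from + offs, dispensed = rep.int(script_days, length(offs)))
}

# fixed-interval train (fixed_weeks / count_times_14 drugs)
.interval_train <- function(from, until, interval, dispensed_each, noise) {
  total <- as.integer(until - from)
  if (total < 0L) return(list(dates = as.Date(character(0)),
                              dispensed = integer(0)))
  n_max <- ceiling((total + 1) / max(1L, interval - noise)) + 1L
  gaps <- interval + sample.int(2L * noise + 1L, n_max, replace = TRUE) -
    noise - 1L
  offs <- cumsum(c(0L, gaps))
  offs <- offs[offs <= total]
  list(dates = from + offs,
       dispensed = rep.int(dispensed_each, length(offs)))
}

#' Generate a synthetic claims bundle
#'
#' Draws patients under the configured study conditions and emits the four
#' claims tables. Onset dates anchor a maintenance 5-ASA refill process;
#' steroid initiation, MTD initiation and surgery times are exponential with
#' group-specific hazards calibrated to the configured 5-year event-free
#' survival; death is Bernoulli from a logistic model in elderly onset and
#' steroid use, and closes the patient's observation window.
#'
#' @param config a [claims_config()].
#' @param catalog a `drug_catalog`; defaults to [default_drug_catalog()].
#' @return a `claims_bundle`: list with data.frames `patients` (patient_id,
#'   sex, birth_year_month, obs_start, obs_end, academic, death_date),
#'   `diagnoses` (patient_id, icd10, suspicious, diag_date), `prescriptions`
#'   (patient_id, drug_id, rx_date, dispensed), `events` (patient_id,
#'   event_type, event_date), plus `truth` (generator ground truth per
#'   patient, for calibration checks) and `meta` (config and seed).
#' @export
generate_claims <- function(config, catalog = default_drug_catalog()) {
  validate_claims_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  win_start <- config$obs_start
  win_end <- config$obs_end
  win_days <- as.integer(win_end - win_start)
  noise <- config$refill_noise_days

  # --- patient-level draws -------------------------------------------------
  u_kind <- stats::runif(n)
  kind <- ifelse(u_kind < config$p_young, "young",
                 ifelse(u_kind < config$p_young +
                          (1 - config$p_young) * config$eo_share,
                        "EO", "NEO"))
  age_onset <- numeric(n)
  age_onset[kind == "young"] <- stats::rnorm(sum(kind == "young"), 25, 6)
  # keep drawn ages clear of the 65-year boundary so month-granular birth
  # dates cannot flip the intended onset group
  age_onset[kind == "EO"] <- 65.2 + stats::rexp(sum(kind == "EO"), rate = 1 / 7)
  age_onset[kind == "NEO"] <- stats::runif(sum(kind == "NEO"), 57.5, 64.6)
  age_onset <- pmax(18, pmin(94, age_onset))

  # onset date uniform in the window, constrained so NEO patients reach 65
  # before the window closes and every patient has >= 30 days of follow-up
  latest <- rep(win_days - 30L, n)
  is_neo <- kind == "NEO"
  latest[is_neo] <- pmin(latest[is_neo],
                         win_days - as.integer(ceiling((65 - age_onset[is_neo]) *
                                                         365.25)))
  latest <- pmax(latest, 1L)
  onset <- win_start + floor(stats::runif(n) * latest)

  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  academic <- stats::runif(n) < config$p_academic
  suspicious_only <- stats::runif(n) < config$p_suspicious
  has_crohns <- stats::runif(n) < config$p_crohns
  birth_ym <- .birth_ym(onset, age_onset)

  grp <- ifelse(kind == "EO", "EO", "NEO")  # hazard group (young use NEO)
  rate_ster <- .rate_from_s5(config$s5_steroid)[grp]
  rate_mtd <- .rate_from_s5(config$s5_mtd)[grp]
  rate_surg <- .rate_from_s5(config$s5_surgery)[grp]

  t_ster <- stats::rexp(n, rate_ster)
  t_mtd <- stats::rexp(n, rate_mtd)
  t_surg <- stats::rexp(n, rate_surg)
  fu_admin <- as.numeric(win_end - onset)

  steroid_user <- t_ster < fu_admin
  lin <- stats::qlogis(config$p_death_base) +
    log(config$or_death_eo) * (kind == "EO") +
    log(config$or_death_steroid) * steroid_user
  dies <- stats::runif(n) < stats::plogis(lin)

  # death date: after steroid initiation when the steroid indicator is set,
  # so the realized indicator matches the logistic draw
  death_date <- rep(as.Date(NA), n)
  if (any(dies)) {
    lo <- ifelse(steroid_user, pmin(t_ster + 30, fu_admin - 1), 1)
    dd <- lo + stats::runif(n) * pmax(0, fu_admin - lo)
    death_date[dies] <- onset[dies] + round(dd[dies])
  }
  obs_end_pat <- as.Date(ifelse(dies, pmin(death_date, win_end), win_end),
                         origin = "1970-01-01")
  fu <- as.numeric(obs_end_pat - onset)

  mtd_user <- t_mtd < fu
  surgery_flag <- t_surg < fu

  # --- per-patient claim rows ---------------------------------------------
  ids <- sprintf("P%06d", seq_len(n))
  rx_pid <- list(); rx_drug <- list(); rx_date <- list(); rx_disp <- list()
  ev_pid <- character(0); ev_date <- as.Date(character(0))
  truth_first_mtd <- rep(NA_character_, n)
  combo <- rep(NA, n)
  mtd_p <- lapply(.MTD_FIRST_COUNTS, function(x) x / sum(x))
  mtd_drugs_all <- names(.MTD_FIRST_COUNTS$EO)
  j <- 0L
  add_rx <- function(pid, drug, tr) {
    if (length(tr$dates) == 0L) return(invisible(NULL))
    j <<- j + 1L
    rx_pid[[j]] <<- rep.int(pid, length(tr$dates))
    rx_drug[[j]] <<- rep.int(drug, length(tr$dates))
    rx_date[[j]] <<- tr$dates
    rx_disp[[j]] <<- tr$dispensed
    invisible(NULL)
  }

  for (i in seq_len(n)) {
    pid <- ids[i]
    end_i <- obs_end_pat[i]
    # maintenance 5-ASA from onset to censoring
    add_rx(pid, "mesalazine",
           .refill_train(onset[i], end_i, config$refill_days, noise))

    if (steroid_user[i] && t_ster[i] < fu[i]) {
      s0 <- onset[i] + round(t_ster[i])
      po_days <- max(5, round(stats::rlnorm(1, config$steroid_po_meanlog,
                                            config$steroid_po_sdlog)))
      po_end <- min(end_i, s0 + po_days)
      add_rx(pid, "prednisolone_po",
             .refill_train(s0, po_end, min(30L, po_days), 0L))
      if (stats::runif(1) < config$p_steroid_iv) {
        iv_days <- max(2, round(stats::rlnorm(1, config$steroid_iv_meanlog,
                                              config$steroid_iv_sdlog)))
        iv_end <- min(end_i, s0 + iv_days)
        add_rx(pid, "prednisolone_iv",
               .refill_train(s0, iv_end, min(7L, iv_days), 0L))
      }
    }

    if (mtd_user[i]) {
      m0 <- onset[i] + round(t_mtd[i])
      drug1 <- sample(mtd_drugs_all, 1L, prob = mtd_p[[grp[i]]])
      truth_first_mtd[i] <- drug1
      d1_end <- .emit_mtd_course(add_rx, pid, drug1, m0, end_i, config,
                                 catalog)
      if (drug1 == "infliximab") {
        combo[i] <- stats::runif(1) < config$p_combo_aza
        if (isTRUE(combo[i])) {
          a0 <- max(onset[i], m0 - round(stats::runif(1, 0, 180)))
          a_end <- min(end_i, m0 + round(stats::runif(1, 90, 540)))
          add_rx(pid, "azathioprine",
                 .refill_train(a0, a_end, config$refill_days, noise))
        }
      }
      if (stats::runif(1) < config$p_second_mtd &&
          as.integer(end_i - d1_end) > 150L) {
        drug2 <- sample(setdiff(mtd_drugs_all, drug1), 1L)
        m2 <- d1_end + round(stats::runif(1, 30, 120))
        if (m2 < end_i) .emit_mtd_course(add_rx, pid, drug2, m2, end_i,
                                         config, catalog)
      }
    }

    if (surgery_flag[i]) {
      ev_pid <- c(ev_pid, pid)
      ev_date <- c(ev_date, onset[i] + round(t_surg[i]))
    }
  }

  prescriptions <- data.frame(
    patient_id = unlist(rx_pid, use.names = FALSE),
    drug_id = unlist(rx_drug, use.names = FALSE),
    rx_date = as.Date(unlist(rx_date, use.names = FALSE),
                      origin = "1970-01-01"),
    dispensed = unlist(rx_disp, use.names = FALSE),
    stringsAsFactors = FALSE)

  diagnoses <- data.frame(
    patient_id = ids, icd10 = "K51.9", suspicious = suspicious_only,
    diag_date = onset, stringsAsFactors = FALSE)
  if (any(has_crohns))
    diagnoses <- rbind(diagnoses, data.frame(
      patient_id = ids[has_crohns], icd10 = "K50.1", suspicious = FALSE,
      diag_date = onset[has_crohns], stringsAsFactors = FALSE))

  patients <- data.frame(
    patient_id = ids, sex = sex, birth_year_month = birth_ym,
    obs_start = rep(win_start, n), obs_end = obs_end_pat,
    academic = academic, death_date = death_date, stringsAsFactors = FALSE)

  events <- data.frame(patient_id = ev_pid, event_type = "surgery",
                       event_date = ev_date, stringsAsFactors = FALSE)

  truth <- data.frame(
    patient_id = ids, kind = kind, onset_date = onset,
    age_at_onset = age_onset, steroid_user = steroid_user,
    mtd_user = mtd_user, first_mtd = truth_first_mtd,
    surgery = surgery_flag, death = dies, combo_aza = combo,
    suspicious_only = suspicious_only, has_crohns = has_crohns,
    stringsAsFactors = FALSE)

  structure(list(patients = patients, diagnoses = diagnoses,
                 prescriptions = prescriptions, events = events,
                 truth = truth,
                 meta = list(config = config, seed = config$seed)),
            class = "claims_bundle")
}

# one MTD course from m0: refill train per the drug's rule for an
# exponential persistence duration; returns the last covered date
.emit_mtd_course <- function(add_rx, pid, drug_id, m0, censor, config,
                             catalog) {
  spec <- catalog_get(catalog, drug_id)
  dur <- stats::rexp(1, 1 / config$mtd_persistence_mean_days)
  until <- min(censor, m0 + round(dur))
  noise <- min(config$refill_noise_days, 7L)
  tr <- switch(spec$rule,
    fixed_weeks = .interval_train(m0, until, 7L * spec$rule_param, 1L, noise),
    count_times_14 = .interval_train(m0, until, 28L, 2L, noise),
    prescription_days = .refill_train(m0, until, config$refill_days, noise))
  add_rx(pid, drug_id, tr)
  if (length(tr$dates)) max(tr$dates) else m0
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle> ", nrow(x$patients), " patients, ",
      nrow(x$prescriptions), " prescriptions, ", nrow(x$diagnoses),
      " diagnoses, ", nrow(x$events), " events (seed ",
      x$meta$seed, ")\n", sep = "")
  invisible(x)
}

#' Hand-built edge-case claims bundles
#'
#' Tiny deterministic bundles that exercise single pipeline edge cases:
#' \describe{
#'   \item{washout_boundary}{one patient, two 5-ASA prescriptions exactly
#'     182 days apart (the second is still "new").}
#'   \item{crohns_overlap}{one patient with both K51 and K50 codes
#'     (excluded as Crohn's).}
#'   \item{gap_13_weeks}{one patient whose 5-ASA refill arrives exactly 91
#'     days after the scheduled date (episode stays continuous).}
#'   \item{suspicious_only}{one patient whose only K51 diagnosis is flagged
#'     suspicious (excluded).}
#'   \item{death_before_rx}{one patient who dies before any prescription.}
#' }
#'
#' @param case_name one of the fixture names above.
#' @return a `claims_bundle` (without a `truth` table).
#' @export
make_fixture <- function(case_name) {
  d <- function(x) as.Date(x)
  base_patient <- function(pid, birth = "1950-01", death = as.Date(NA),
                           obs_end = d("2022-02-28"))
    data.frame(patient_id = pid, sex = "male", birth_year_month = birth,
               obs_start = d("2014-04-01"), obs_end = obs_end,
               academic = FALSE, death_date = death,
               stringsAsFactors = FALSE)
  base_diag <- function(pid, icd = "K51.9", susp = FALSE,
                        date = d("2016-01-01"))
    data.frame(patient_id = pid, icd10 = icd, suspicious = susp,
               diag_date = date, stringsAsFactors = FALSE)
  rx <- function(pid, drug, dates, disp)
    data.frame(patient_id = pid, drug_id = drug, rx_date = d(dates),
               dispensed = disp, stringsAsFactors = FALSE)
  no_events <- data.frame(patient_id = character(0), event_type = character(0),
                          event_date = d(character(0)),
                          stringsAsFactors = FALSE)
  bundle <- function(p, dg, pr)
    structure(list(patients = p, diagnoses = dg, prescriptions = pr,
                   events = no_events, truth = NULL,
                   meta = list(config = NULL, seed = NA_integer_,
                               fixture = case_name)),
              class = "claims_bundle")

  switch(case_name,
    washout_boundary = bundle(
      base_patient("F1"), base_diag("F1"),
      rx("F1", "mesalazine", c("2016-01-01", "2016-07-01"), c(30L, 30L))),
    crohns_overlap = bundle(
      base_patient("F2"),
      rbind(base_diag("F2"), base_diag("F2", icd = "K50.0")),
      rx("F2", "mesalazine", "2016-01-01", 30L)),
    gap_13_weeks = bundle(
      base_patient("F3"), base_diag("F3"),
      # 30-day script on day 0: scheduled refill day 30; next on day 121 is
      # exactly 91 days late, then steady refills
      rx("F3", "mesalazine",
         d("2016-01-01") + c(0L, 121L, 151L), rep(30L, 3))),
    suspicious_only = bundle(
      base_patient("F4"), base_diag("F4", susp = TRUE),
      rx("F4", "mesalazine", "2016-01-01", 30L)),
    death_before_rx = bundle(
      base_patient("F5", death = d("2015-06-01"), obs_end = d("2015-06-01")),
      base_diag("F5", date = d("2015-01-01")),
      data.frame(patient_id = character(0), drug_id = character(0),
                 rx_date = d(character(0)), dispensed = integer(0),
                 stringsAsFactors = FALSE)),
    stop("unknown fixture '", case_name, "'", call. = FALSE))
}

#' Write a claims bundle as delimited text files
#'
#' Writes `patients.tsv`, `diagnoses.tsv`, `prescriptions.tsv`, `events.tsv`
#' and a `manifest.txt` recording the seed and configuration.
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claims <- function(bundle, dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in c("patients", "diagnoses", "prescriptions", "events"))
    utils::write.table(bundle[[tab]], file.path(dir, paste0(tab, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- c(paste0("seed: ", bundle$meta$seed),
                paste0("generated: ucclaims ",
                       as.character(utils::packageVersion("ucclaims"))),
                "config:",
                utils::capture.output(utils::str(bundle$meta$config)))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a claims bundle from delimited text files
#'
#' @param dir directory produced by [write_claims()] (or any directory with
#'   the four tables in the documented schema).
#' @return a `claims_bundle` (without generator truth).
#' @export
read_claims <- function(dir) {
  rd <- function(name, datecols) {
    df <- utils::read.delim(file.path(dir, paste0(name, ".tsv")),
                            stringsAsFactors = FALSE)
    for (dc in intersect(datecols, names(df))) df[[dc]] <- as.Date(df[[dc]])
    df
  }
  structure(list(
    patients = rd("patients", c("obs_start", "obs_end", "death_date")),
    diagnoses = rd("diagnoses", "diag_date"),
    prescriptions = rd("prescriptions", "rx_date"),
    events = rd("events", "event_date"),
    truth = NULL, meta = list(config = NULL, seed = NA_integer_)),
    class = "claims_bundle")
}
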