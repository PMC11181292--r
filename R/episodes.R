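#' Exposure episodes: new/old prescriptions and refill-gap discontinuation
#'
#' The analysis treats drug exposure as a sequence of *episodes*: continuous
#' treatment intervals assembled from prescription claims. Two definitions
#' drive everything here.
#'
#' *Washout / novelty.* A prescription is "new" when no same-drug
#' prescription falls within the 26 weeks (182 days) immediately before it;
#' otherwise it is "old". The window is half-open: a prior prescription at
#' exactly 182 days is outside it, so the prescription is still new.
#'
#' *Discontinuation.* An episode is discontinued when no refill arrives for
#' more than 13 weeks (91 days) after the next scheduled prescription date
#' (see [next_scheduled_date()]); a refill at exactly scheduled + 91 days
#' still continues the episode. A discontinued episode ends on its last
#' scheduled date — uncovered waiting time is not credited to persistence.
#'
#' @name exposure-episodes
NULL

.WASHOUT_DAYS <- 182L  # 26 weeks
.GRACE_DAYS <- 91L     # 13 weeks past the scheduled refill date

#' Classify one prescription as new or old
#'
#' @param history `Date` vector of prior same-drug prescription dates
#'   (all strictly before `rx_date`); may be empty.
#' @param rx_date `Date` of the prescription being classified.
#' @return `"new"` or `"old"`.
#' @export
classify_prescription_novelty <- function(history, rx_date) {
  rx_date <- as.Date(rx_date)
  stopifnot(length(rx_date) == 1L, !is.na(rx_date))
  if (length(history) == 0L) return("new")
  history <- as.Date(history)
  if (any(history >= rx_date))
    stop("history must be strictly before rx_date", call. = FALSE)
  gap <- as.integer(rx_date - max(history))
  if (gap < .WASHOUT_DAYS) "old" else "new"
}

#' Merge same-day duplicate claim lines for one patient-drug
#'
#' Duplicate lines on one date are merged before episode construction:
#' dispensed amounts are summed (covered days pool; dispensed counts pool
#' within the merged line, but counts never pool across dates).
#' @noRd
merge_same_day <- function(dates, dispensed) {
  if (anyDuplicated(dates)) {
    agg <- rowsum(as.numeric(dispensed), group = as.integer(dates))
    dates <- as.Date(as.integer(rownames(agg)), origin = "1970-01-01")
    dispensed <- as.integer(agg[, 1L])
  }
  list(dates = dates, dispensed = as.integer(dispensed))
}

#' Build exposure episodes for one patient-drug prescription history
#'
#' Scans date-sorted prescriptions once. A prescription on or before
#' `scheduled_next + 91` days extends the running episode and advances
#' `scheduled_next` via [next_scheduled_date()]; a later prescription closes
#' the episode as discontinued (ending on `scheduled_next`) and opens a new
#' one. After the last prescription the episode is discontinued when the
#' censoring date lies more than 91 days past `scheduled_next`, and is
#' otherwise ongoing at censoring (ending at the censoring date).
#'
#' @param rx_dates `Date` vector of prescription dates, sorted ascending.
#' @param dispensed integer vector, same length: covered days
#'   (`prescription_days` drugs), dispensed count (`count_times_14`), or
#'   ignored (`fixed_weeks`).
#' @param spec the drug's [drug_spec()].
#' @param censor_date `Date`; end of the patient's observation
#'   (>= last prescription).
#' @return data.frame with one row per episode: `drug_id`, `start_date`,
#'   `last_rx_date`, `scheduled_next`, `end_date`, `status`
#'   (`"discontinued"` or `"ongoing_at_censor"`), `covered_days`,
#'   `n_prescriptions`.
#' @examples
#' cat <- default_drug_catalog()
#' build_episodes(as.Date("2020-01-01") + c(0, 56), c(1, 1),
#'                catalog_get(cat, "infliximab"), as.Date("2020-05-30"))
#' @export
build_episodes <- function(rx_dates, dispensed, spec, censor_date) {
  stopifnot(inherits(spec, "drug_spec"))
  rx_dates <- as.Date(rx_dates)
  censor_date <- as.Date(censor_date)
  stopifnot(length(censor_date) == 1L, !is.na(censor_date))
  if (length(rx_dates) == 0L) return(.empty_episodes(spec))
  if (is.unsorted(rx_dates)) stop("rx_dates must be sorted", call. = FALSE)
  if (censor_date < max(rx_dates))
    stop("censor_date precedes the last prescription", call. = FALSE)
  m <- merge_same_day(rx_dates, dispensed)
  rx_dates <- m$dates; dispensed <- m$dispensed

  n <- length(rx_dates)
  eps <- list(); k <- 0L
  start <- rx_dates[1L]
  last_rx <- rx_dates[1L]
  sched <- next_scheduled_date(spec, last_rx, dispensed[1L])
  cover_end <- sched
  covered <- as.integer(sched - last_rx)
  n_rx <- 1L
  i <- 2L
  while (i <= n) {
    d <- rx_dates[i]
    if (as.integer(d - sched) <= .GRACE_DAYS) {
      last_rx <- d
      sched <- next_scheduled_date(spec, d, dispensed[i])
      # coverage is the union of [rx, scheduled) intervals: an early refill
      # only adds days beyond the end of the running coverage
      covered <- covered + max(0L, as.integer(sched - max(d, cover_end)))
      cover_end <- max(cover_end, sched)
      n_rx <- n_rx + 1L
    } else {
      k <- k + 1L
      eps[[k]] <- list(start, last_rx, sched, sched, "discontinued",
                       covered, n_rx)
      start <- d; last_rx <- d
      sched <- next_scheduled_date(spec, d, dispensed[i])
      cover_end <- sched
      covered <- as.integer(sched - d)
      n_rx <- 1L
    }
    i <- i + 1L
  }
  k <- k + 1L
  if (as.integer(censor_date - sched) > .GRACE_DAYS) {
    eps[[k]] <- list(start, last_rx, sched, sched, "discontinued",
                     covered, n_rx)
  } else {
    eps[[k]] <- list(start, last_rx, sched, censor_date, "ongoing_at_censor",
                     covered, n_rx)
  }
  out <- .empty_episodes(spec, k)
  for (j in seq_len(k)) {
    e <- eps[[j]]
    out$start_date[j] <- e[[1L]]; out$last_rx_date[j] <- e[[2L]]
    out$scheduled_next[j] <- e[[3L]]; out$end_date[j] <- e[[4L]]
    out$status[j] <- e[[5L]]; out$covered_days[j] <- e[[6L]]
    out$n_prescriptions[j] <- e[[7L]]
  }
  out
}

.empty_episodes <- function(spec, n = 0L) {
  data.frame(drug_id = rep.int(spec$drug_id, n),
             start_date = rep(as.Date(NA), n),
             last_rx_date = rep(as.Date(NA), n),
             scheduled_next = rep(as.Date(NA), n),
             end_date = rep(as.Date(NA), n),
             status = rep.int(NA_character_, n),
             covered_days = rep.int(NA_integer_, n),
             n_prescriptions = rep.int(NA_integer_, n),
             stringsAsFactors = FALSE)
}

#' Build episodes for every patient-drug pair in a prescription table
#'
#' @param prescriptions data.frame with columns `patient_id`, `drug_id`,
#'   `rx_date` (`Date`), `dispensed`.
#' @param catalog a `drug_catalog`.
#' @param censor_dates named `Date` vector: per-patient censoring date
#'   (observation end, already truncated at death).
#' @return data.frame of episodes with a leading `patient_id` column.
#' @export
build_all_episodes <- function(prescriptions, catalog, censor_dates) {
  stopifnot(inherits(catalog, "drug_catalog"))
  need <- c("patient_id", "drug_id", "rx_date", "dispensed")
  stopifnot(all(need %in% names(prescriptions)))
  unknown <- setdiff(unique(prescriptions$drug_id), names(catalog$entries))
  if (length(unknown))
    stop("prescription drug_id not in catalog: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  prescriptions <- prescriptions[order(prescriptions$patient_id,
                                       prescriptions$drug_id,
                                       prescriptions$rx_date), , drop = FALSE]
  key <- interaction(prescriptions$patient_id, prescriptions$drug_id,
                     drop = TRUE)
  pieces <- lapply(split(seq_len(nrow(prescriptions)), key), function(idx) {
    pid <- prescriptions$patient_id[idx[1L]]
    did <- prescriptions$drug_id[idx[1L]]
    cens <- censor_dates[[as.character(pid)]]
    if (is.null(cens) || is.na(cens))
      stop("no censor date for patient ", pid, call. = FALSE)
    ep <- build_episodes(prescriptions$rx_date[idx],
                         prescriptions$dispensed[idx],
                         catalog_get(catalog, did), as.Date(cens))
    cbind(patient_id = rep.int(pid, nrow(ep)), ep)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' First molecular targeting drug for each patient
#'
#' Returns, per patient with at least one MTD episode, the MTD episode with
#' the earliest start. Ties on the start date are broken by lexicographic
#' `drug_id` and reported via the `tie` column.
#'
#' @param episodes episode table from [build_all_episodes()].
#' @param catalog a `drug_catalog`.
#' @return data.frame: `patient_id`, `drug_id`, `start_date`, `end_date`,
#'   `status`, `tie` (logical).
#' @export
first_mtd <- function(episodes, catalog) {
  mtd <- episodes[episodes$drug_id %in% mtd_ids(catalog), , drop = FALSE]
  if (nrow(mtd) == 0L)
    return(data.frame(patient_id = character(0), drug_id = character(0),
                      start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      status = character(0), tie = logical(0)))
  mtd <- mtd[order(mtd$patient_id, mtd$start_date, mtd$drug_id), ,
             drop = FALSE]
  first <- !duplicated(mtd$patient_id)
  out <- mtd[first, c("patient_id", "drug_id", "start_date", "end_date",
                      "status")]
  # a tie: more than one distinct MTD starting on the patient's first date
  nd <- tapply(mtd$drug_id, paste(mtd$patient_id, mtd$start_date),
               function(x) length(unique(x)))
  out$tie <- nd[paste(out$patient_id, out$start_date)] > 1L
  rownames(out) <- NULL
  out
}

#' Azathioprine combination flag at infliximab initiation
#'
#' Combination therapy is azathioprine exposure active on the infliximab
#' start date: an azathioprine episode with `start_date <= ifx_start <=
#' end_date` (an ongoing episode extends to the censoring date via its
#' `end_date`).
#'
#' @param ifx_start `Date`; infliximab episode start.
#' @param aza_episodes episode rows for the same patient's azathioprine.
#' @return logical.
#' @export
combination_flag <- function(ifx_start, aza_episodes) {
  ifx_start <- as.Date(ifx_start)
  stopifnot(length(ifx_start) == 1L, !is.na(ifx_start))
  if (is.null(aza_episodes) || nrow(aza_episodes) == 0L) return(FALSE)
  any(aza_episodes$start_date <= ifx_start &
        ifx_start <= aza_episodes$end_date)
}

#' Number of distinct molecular targeting drugs used by a patient
#'
#' Counts distinct MTD drugs with at least one episode (lines of therapy),
#' not episodes: two episodes of one drug count once.
#'
#' @param episodes episode rows for one patient (or a full episode table
#'   with `patient_id`, in which case a named vector is returned).
#' @param catalog a `drug_catalog`.
#' @return integer count (or named integer vector per patient).
#' @export
count_mtd_lines <- function(episodes, catalog) {
  mtd <- episodes[episodes$drug_id %in% mtd_ids(catalog), , drop = FALSE]
  if (!"patient_id" %in% names(episodes))
    return(length(unique(mtd$drug_id)))
  if (nrow(mtd) == 0L) return(integer(0))
  vapply(split(mtd$drug_id, mtd$patient_id),
         function(x) length(unique(x)), integer(1))
}
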