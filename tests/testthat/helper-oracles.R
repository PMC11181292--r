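# Independent brute-force oracles. Each re-derives its quantity directly
# from the defining formulas, by a different route than the package code.

# --- day-scan episode oracle ------------------------------------------------
# Walks calendar days one at a time, re-deriving episode boundaries, status
# and covered days from the two definition sentences: refills due at the
# drug's next scheduled date, discontinuation after a >13-week (91-day) gap
# past it, episode end at the last scheduled date. Coverage is counted from
# an explicit per-day boolean vector (union of [rx, scheduled) intervals).
oracle_episodes <- function(rx_dates, dispensed, spec, censor_date) {
  sched_of <- function(date, disp) {
    switch(spec$rule,
           fixed_weeks = date + 7L * spec$rule_param,
           count_times_14 = date + 14L * as.integer(disp),
           prescription_days = date + as.integer(disp))
  }
  # merge same-day duplicate lines by summing dispensed
  o <- order(rx_dates)
  rx_dates <- rx_dates[o]; dispensed <- dispensed[o]
  if (anyDuplicated(rx_dates)) {
    agg <- tapply(as.numeric(dispensed), as.integer(rx_dates), sum)
    rx_dates <- as.Date(as.integer(names(agg)), origin = "1970-01-01")
    dispensed <- as.integer(agg)
  }
  n <- length(rx_dates)
  out <- list()
  i <- 1L
  while (i <= n) {
    start <- rx_dates[i]
    last_rx <- start
    sched <- sched_of(start, dispensed[i])
    day0 <- as.integer(start)
    dayN <- as.integer(censor_date)
    covered <- rep(FALSE, dayN - day0 + 200L)
    mark <- function(cov, from, to) {  # [from, to)
      a <- as.integer(from) - day0 + 1L; b <- as.integer(to) - day0
      if (b >= a) cov[a:b] <- TRUE
      cov
    }
    covered <- mark(covered, start, sched)
    n_rx <- 1L
    j <- i + 1L
    status <- NULL; end <- NULL
    day <- as.integer(start)
    repeat {
      day <- day + 1L
      if (day > dayN) {
        if (dayN - as.integer(sched) > 91L) {
          status <- "discontinued"; end <- sched
        } else {
          status <- "ongoing_at_censor"; end <- censor_date
        }
        break
      }
      if (day - as.integer(sched) > 91L) {
        status <- "discontinued"; end <- sched
        break
      }
      if (j <= n && as.integer(rx_dates[j]) == day) {
        last_rx <- rx_dates[j]
        sched <- sched_of(last_rx, dispensed[j])
        covered <- mark(covered, last_rx, sched)
        n_rx <- n_rx + 1L
        j <- j + 1L
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      drug_id = spec$drug_id, start_date = start, last_rx_date = last_rx,
      scheduled_next = sched, end_date = end, status = status,
      covered_days = sum(covered), n_prescriptions = n_rx,
      stringsAsFactors = FALSE)
    i <- j
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# --- hypergeometric-moment log-rank oracle ----------------------------------
# Direct evaluation of the log-rank statistic: at each distinct event time,
# observed minus expected deaths in group 1 with the hypergeometric variance.
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n_t <- sum(at_risk); n1_t <- sum(at_risk & g1)
    d_t <- sum(time == t & event == 1)
    d1_t <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1_t
    E1 <- E1 + d_t * n1_t / n_t
    if (n_t > 1)
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
  }
  stat <- (O1 - E1)^2 / V
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# --- expected-count chi-square oracle ---------------------------------------
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expd)^2 / expd)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

# --- product-limit oracle ----------------------------------------------------
# Hand-rolled Kaplan-Meier: product over distinct event times <= t.
oracle_km_at <- function(time, event, t) {
  times <- sort(unique(time[event == 1 & time <= t]))
  s <- 1
  for (tt in times) {
    n_t <- sum(time >= tt)
    d_t <- sum(time == tt & event == 1)
    s <- s * (1 - d_t / n_t)
  }
  s
}

# random small time-to-event tables with ties, for the statistical oracles
random_tte <- function(n, seed) {
  set.seed(seed)
  data.frame(time = sample.int(8L, n, replace = TRUE),
             event = rbinom(n, 1L, 0.7),
             group = sample(c("A", "B"), n, replace = TRUE))
}

# small generator bundle shared across tests (memoised per session)
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_claims(claims_config(n_patients = 600, seed = 11))
    cache
  }
})

shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_cohort(shared_bundle())
    cache
  }
})
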