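cat_ <- default_drug_catalog()
d_ <- function(x) as.Date(x)

test_that("UC case identification keeps non-suspicious K51 without K50", {
  dg <- data.frame(
    patient_id = c("a", "b", "b", "c", "c", "d"),
    icd10 = c("K51.3", "K51", "K51", "K51.9", "K50.1", "K51"),
    suspicious = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  ids <- identify_uc_cases(dg)
  expect_setequal(as.character(ids), c("a", "d"))
  # malformed codes are skipped with a warning, not an error
  dg_bad <- rbind(dg, data.frame(patient_id = "e", icd10 = "???",
                                 suspicious = FALSE))
  expect_warning(ids2 <- identify_uc_cases(dg_bad), "malformed")
  expect_setequal(as.character(ids2), c("a", "d"))
  expect_equal(attr(ids2, "n_malformed"), 1L)
})

test_that("onset estimation returns the earliest qualifying course start", {
  # first-ever 5-ASA on day 200 of observation
  rx <- data.frame(drug_id = "mesalazine", rx_date = d_("2014-10-18"),
                   dispensed = 30L)
  est <- estimate_onset(rx, cat_, d_("2022-02-28"))
  expect_equal(est$onset, d_("2014-10-18"))
  expect_equal(est$reason, "ok")
  # steroid course earlier than the 5-ASA start moves the onset back
  rx2 <- rbind(rx, data.frame(drug_id = "prednisolone_po",
                              rx_date = d_("2014-08-01"), dispensed = 14L))
  expect_equal(estimate_onset(rx2, cat_, d_("2022-02-28"))$onset,
               d_("2014-08-01"))
  # immunomodulator-only history has no estimable onset
  rx3 <- data.frame(drug_id = "azathioprine", rx_date = d_("2015-01-01"),
                    dispensed = 30L)
  expect_true(is.na(estimate_onset(rx3, cat_, d_("2022-02-28"))$onset))
  expect_equal(estimate_onset(rx3, cat_, d_("2022-02-28"))$reason,
               "no_qualifying_rx")
})

test_that("a qualifying restart inside the washout window drops the patient", {
  # 7-day script, then a restart 130 days later: past the 91-day grace
  # (episode split) but inside the 26-week washout -> "old" start
  rx <- data.frame(drug_id = "prednisolone_po",
                   rx_date = d_("2015-01-01") + c(0, 130),
                   dispensed = c(7L, 7L))
  est <- estimate_onset(rx, cat_, d_("2022-02-28"))
  expect_true(is.na(est$onset))
  expect_equal(est$reason, "old_prescription")
  # the same restart 200 days later passes the washout: two clean courses
  rx2 <- transform(rx, rx_date = d_("2015-01-01") + c(0, 200))
  est2 <- estimate_onset(rx2, cat_, d_("2022-02-28"))
  expect_equal(est2$onset, d_("2015-01-01"))
})

test_that("maintenance refill trains are one continuous course, not old prescriptions", {
  rx <- data.frame(drug_id = "mesalazine",
                   rx_date = d_("2015-01-01") + seq(0, 360, by = 30),
                   dispensed = 30L)
  est <- estimate_onset(rx, cat_, d_("2022-02-28"))
  expect_equal(est$reason, "ok")
  expect_equal(est$onset, d_("2015-01-01"))
})

test_that("age computation and onset-group classification follow the 65-year rule", {
  expect_equal(age_completed_years("1950-03", d_("2018-06-15")), 68L)
  expect_equal(age_completed_years("1950-03", d_("2018-02-15")), 67L)
  expect_equal(age_completed_years("1950-03", d_("2018-03-01")), 68L)
  expect_equal(classify_group(d_("2018-06-01"), "1950-03", d_("2022-02-28")),
               "EO")
  # onset at 61, aged 67 by observation end
  expect_equal(classify_group(d_("2016-01-15"), "1954-03", d_("2022-02-28")),
               "NEO")
  # never reaches 65
  expect_equal(classify_group(d_("2018-01-01"), "1980-01", d_("2022-02-28")),
               "ineligible")
  expect_error(age_completed_years("2030-01", d_("2020-01-01")), "precedes")
})

test_that("fixtures route through the expected exclusion paths", {
  co <- build_cohort(make_fixture("crohns_overlap"), cat_)
  expect_equal(nrow(co$cohort), 0L)
  expect_equal(unname(co$exclusions[["crohns"]]), 1L)
  co2 <- build_cohort(make_fixture("suspicious_only"), cat_)
  expect_equal(nrow(co2$cohort), 0L)
  expect_equal(unname(co2$exclusions[["suspicious"]]), 1L)
  co3 <- build_cohort(make_fixture("death_before_rx"), cat_)
  expect_equal(nrow(co3$cohort), 0L)
  expect_equal(unname(co3$exclusions[["not_new_onset"]]), 1L)
  # the 182-day washout boundary keeps the patient (both scripts new)
  co4 <- build_cohort(make_fixture("washout_boundary"), cat_)
  expect_equal(nrow(co4$cohort), 1L)
  expect_equal(co4$cohort$onset_date, d_("2016-01-01"))
  # a refill exactly 13 weeks late keeps one continuous course
  co5 <- build_cohort(make_fixture("gap_13_weeks"), cat_)
  expect_equal(nrow(co5$cohort), 1L)
  expect_equal(nrow(co5$episodes), 1L)
})

test_that("the exclusion tally partitions the input patients", {
  co <- shared_cohort()
  b <- shared_bundle()
  expect_equal(nrow(co$cohort) + sum(co$exclusions), nrow(b$patients))
  expect_setequal(unique(co$cohort$onset_group), c("EO", "NEO"))
  expect_true(all(co$cohort$age_at_end >= 65L))
  eo <- co$cohort$onset_group == "EO"
  expect_true(all(co$cohort$age_at_onset[eo] >= 65L))
  expect_true(all(co$cohort$age_at_onset[!eo] < 65L))
  # outcome dates never precede onset
  for (col in c("steroid_date", "mtd_date", "surgery_date"))
    expect_true(all(co$cohort[[col]] >= co$cohort$onset_date, na.rm = TRUE))
})

test_that("rebuilding the cohort from its own retained patients is a no-op", {
  b <- shared_bundle()
  co <- shared_cohort()
  keep <- b$patients$patient_id %in% co$cohort$patient_id
  b2 <- b
  b2$patients <- b$patients[keep, ]
  b2$diagnoses <- b$diagnoses[b$diagnoses$patient_id %in%
                                co$cohort$patient_id, ]
  b2$prescriptions <- b$prescriptions[b$prescriptions$patient_id %in%
                                        co$cohort$patient_id, ]
  b2$events <- b$events[b$events$patient_id %in% co$cohort$patient_id, ]
  co2 <- build_cohort(b2, cat_)
  expect_equal(sum(co2$exclusions), 0L)
  expect_equal(co2$cohort$patient_id, co$cohort$patient_id)
  expect_equal(co2$cohort$onset_group, co$cohort$onset_group)
})

test_that("the elderly-onset share converges to the configured value", {
  cfg <- claims_config(n_patients = 4000, seed = 31, eo_share = 0.9,
                       p_young = 0, p_suspicious = 0, p_crohns = 0)
  b <- generate_claims(cfg)
  co <- build_cohort(b, cat_)
  share <- mean(co$cohort$onset_group == "EO")
  expect_lt(abs(share - 0.9), 3 * sqrt(0.9 * 0.1 / nrow(co$cohort)))
})

test_that("generator cohorts carry the washout-consistency property", {
  co <- shared_cohort()
  eps <- co$episodes
  rx <- shared_bundle()$prescriptions
  # sample a slice of episodes; every start must pass the washout test
  set.seed(1)
  take <- sample(nrow(eps), min(300, nrow(eps)))
  for (i in take) {
    h <- rx$rx_date[rx$patient_id == eps$patient_id[i] &
                      rx$drug_id == eps$drug_id[i] &
                      rx$rx_date < eps$start_date[i]]
    expect_equal(classify_prescription_novelty(h, eps$start_date[i]), "new")
  }
})
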