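test_that("the product-limit estimate matches hand computation and the no-censoring identity", {
  # 3 subjects, events at 1, 2, 3: S(1) = 2/3, S(2) = 1/3, S(3) = 0
  tte <- data.frame(time = c(1, 2, 3), event = 1L)
  cv <- km_estimate(tte, by_group = FALSE)
  expect_equal(surv_at(cv, 1), 2 / 3)
  expect_equal(surv_at(cv, 2), 1 / 3)
  expect_equal(surv_at(cv, 2.9), 1 / 3)
  expect_equal(surv_at(cv, 3), 0)
  expect_equal(surv_at(cv, 0.5), 1)
  # all censored: flat at 1
  flat <- km_estimate(data.frame(time = c(5, 7), event = 0L),
                      by_group = FALSE)
  expect_equal(surv_at(flat, 10), 1)
  # single subject with an event at t: S drops to 0 at t
  one <- km_estimate(data.frame(time = 4, event = 1L), by_group = FALSE)
  expect_equal(surv_at(one, 3.9), 1)
  expect_equal(surv_at(one, 4), 0)
  # with no censoring the estimate equals the empirical survival function
  set.seed(42)
  t <- sample.int(20L, 60L, replace = TRUE)
  cv2 <- km_estimate(data.frame(time = t, event = 1L), by_group = FALSE)
  for (q in c(1, 5, 10, 19))
    expect_equal(surv_at(cv2, q), mean(t > q))
})

test_that("the estimate agrees with the product-limit oracle under censoring", {
  for (seed in 1:10) {
    tte <- random_tte(40, seed)
    cv <- km_estimate(tte, by_group = FALSE)
    for (q in c(2, 5, 8))
      expect_equal(surv_at(cv, q), oracle_km_at(tte$time, tte$event, q),
                   tolerance = 1e-12)
  }
})

test_that("survival estimates are monotone with decreasing risk sets", {
  tte <- random_tte(80, 99)
  cv <- km_estimate(tte)
  for (g in unique(cv$group)) {
    s <- cv[cv$group == g, ]
    s <- s[order(s$time), ]
    expect_true(all(diff(s$surv) <= 1e-12))
    expect_true(all(diff(s$n_risk) < 0))
    expect_true(all(s$surv <= 1))
  }
})

test_that("the log-rank test matches the hypergeometric-moment oracle", {
  # 6-subject worked example with a tie
  tte6 <- data.frame(time = c(1, 2, 2, 4, 5, 6),
                     event = c(1, 1, 1, 0, 1, 1),
                     group = c("A", "B", "A", "B", "A", "B"))
  got <- logrank_test(tte6)
  want <- oracle_logrank(tte6$time, tte6$event, tte6$group)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  for (seed in 1:25) {
    tte <- random_tte(30, seed + 500)
    if (length(unique(tte$group[tte$event == 1])) < 2) next
    got <- logrank_test(tte)
    want <- oracle_logrank(tte$time, tte$event, tte$group)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  }
})

test_that("log-rank is symmetric in group labels and degenerate cases error", {
  tte <- random_tte(50, 7)
  sw <- tte
  sw$group <- ifelse(tte$group == "A", "B", "A")
  expect_equal(logrank_test(tte)$statistic, logrank_test(sw)$statistic)
  # identical samples in both groups: statistic 0, p = 1
  same <- data.frame(time = rep(c(1, 3, 5), 2), event = 1L,
                     group = rep(c("A", "B"), each = 3))
  z <- logrank_test(same)
  expect_equal(z$statistic, 0, tolerance = 1e-12)
  expect_equal(z$p_value, 1, tolerance = 1e-12)
  expect_error(logrank_test(data.frame(time = 1, event = 1L, group = "A")),
               "2 groups")
})

test_that("null log-rank p-values are approximately uniform over seeds", {
  ps <- vapply(1:60, function(s) {
    set.seed(s + 9000)
    tte <- data.frame(time = rexp(120), event = rbinom(120, 1, 0.8),
                      group = rep(c("A", "B"), each = 60))
    logrank_test(tte)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.005)
  expect_gt(mean(ps < 0.5), 0.3)
})

test_that("time-to-event extraction censors at death and observation end", {
  co <- data.frame(
    patient_id = c("a", "b", "c"),
    onset_date = as.Date("2016-01-01"),
    obs_end = as.Date(c("2018-01-01", "2016-10-27", "2021-06-24")),
    onset_group = c("EO", "EO", "NEO"),
    steroid_date = as.Date(c("2017-02-04", NA, NA)),
    mtd_date = as.Date(NA), surgery_date = as.Date(NA),
    stringsAsFactors = FALSE)
  tte <- extract_time_to_event(co, "steroid")
  expect_equal(tte$time, c(400L, 300L, 2001L))
  expect_equal(tte$event, c(1L, 0L, 0L))
  expect_equal(tte$group, co$onset_group)
})

test_that("persistence curves follow episode status, and combination strata partition infliximab users", {
  co <- shared_cohort()
  pc <- persistence_curve(co)
  # persistence events are discontinuations; censoring only at observation end
  expect_true(all(pc$tte$event %in% c(0L, 1L)))
  expect_true(all(pc$tte$time >= 0))
  expect_setequal(unique(pc$tte$group),
                  intersect(c("EO", "NEO"), co$cohort$onset_group[co$cohort$mtd_use]))
  # single discontinued ustekinumab episode: step to 0 at day 84
  cat_ <- default_drug_catalog()
  rx <- data.frame(patient_id = "p1", drug_id = "ustekinumab",
                   rx_date = as.Date("2020-01-01"), dispensed = 1L)
  mini <- list(cohort = data.frame(patient_id = "p1", onset_group = "EO",
                                   stringsAsFactors = FALSE),
               episodes = build_all_episodes(rx, cat_,
                                             c(p1 = as.Date("2021-02-04"))))
  class(mini) <- "uc_cohort"
  pc1 <- persistence_curve(mini)
  expect_equal(pc1$tte$time, 84L)
  expect_equal(pc1$tte$event, 1L)
  expect_equal(surv_at(pc1$curve, 84, group = "EO"), 0)
  # combination stratification partitions the infliximab users
  ifx <- first_mtd(co$episodes, default_drug_catalog())
  ifx <- ifx[ifx$drug_id == "infliximab" &
               ifx$patient_id %in% co$cohort$patient_id, ]
  if (nrow(ifx) >= 2) {
    pcc <- persistence_curve(co, stratify_by = "combo", drug = "infliximab")
    expect_equal(nrow(pcc$tte), nrow(ifx))
    expect_true(all(pcc$tte$group %in% c("combo", "mono")))
  }
})
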