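#' Summary tables and the end-to-end pipeline
#'
#' Cohort background and outcome tables stratified by onset group, with
#' count / denominator / percentage rows, plus a single driver that runs the
#' whole pipeline (cohort -> episodes -> survival -> models -> summaries)
#' and writes every artifact as delimited text.
#'
#' @name reporting
NULL

#' Percentage rounded half-up to one decimal
#'
#' Matches the conventional table formatting (half-up, not banker's
#' rounding): `pct(1008, 2946)` is `34.2`.
#'
#' @param count numerator.
#' @param denominator denominator (> 0).
#' @return numeric percentage with one decimal.
#' @export
pct <- function(count, denominator) {
  stopifnot(all(denominator > 0), all(count >= 0),
            all(count <= denominator))
  floor(1000 * count / denominator + 0.5) / 10
}

.count_row <- function(label, count, denom)
  data.frame(label = label, count = count, denominator = denom,
             percent = pct(count, denom), stringsAsFactors = FALSE)

#' Cohort summary tables
#'
#' Emits the background/outcome summaries: group sizes, sex split, academic
#' flag, steroid use, MTD use, breakdown of the first MTD (denominator: MTD
#' users in the stratum), number of distinct MTDs used, surgery and death
#' rates, and median (IQR) covered steroid days by route — overall and per
#' onset group.
#'
#' @param cohort_obj a `uc_cohort`.
#' @param catalog a `drug_catalog`.
#' @return list of data.frames: `counts` (label, stratum, count,
#'   denominator, percent) and `steroid_days` (stratum, route, n, median,
#'   q1, q3).
#' @export
summarize_cohort <- function(cohort_obj, catalog = default_drug_catalog()) {
  stopifnot(inherits(cohort_obj, "uc_cohort"))
  co <- cohort_obj$cohort
  if (nrow(co) == 0L) stop("empty cohort", call. = FALSE)
  strata <- list(overall = co,
                 EO = co[co$onset_group == "EO", , drop = FALSE],
                 NEO = co[co$onset_group == "NEO", , drop = FALSE])
  counts <- list()
  for (s in names(strata)) {
    d <- strata[[s]]
    n <- nrow(d)
    if (n == 0L) next
    rows <- rbind(
      .count_row("patients", n, nrow(co)),
      .count_row("male", sum(d$sex == "male"), n),
      .count_row("female", sum(d$sex == "female"), n),
      .count_row("academic_hospital", sum(d$academic), n),
      .count_row("steroid_use", sum(d$steroid_use), n),
      .count_row("mtd_use", sum(d$mtd_use), n),
      .count_row("surgery", sum(d$surgery), n),
      .count_row("death", sum(d$death), n))
    n_mtd <- sum(d$mtd_use)
    if (n_mtd > 0L) {
      for (did in sort(unique(d$mtd_first_drug[d$mtd_use])))
        rows <- rbind(rows, .count_row(paste0("first_mtd_", did),
                                       sum(d$mtd_first_drug == did,
                                           na.rm = TRUE), n_mtd))
      lines <- pmin(d$mtd_lines, 2L)
      for (k in 0:2)
        rows <- rbind(rows, .count_row(
          paste0("mtd_lines_", if (k == 2L) "2plus" else k),
          sum(lines == k), n))
    }
    rows$stratum <- s
    counts[[s]] <- rows
  }
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL

  sd_rows <- list()
  for (s in names(strata)) {
    d <- strata[[s]]
    for (route in c("po", "iv")) {
      v <- d[[paste0("steroid_", route, "_days")]]
      v <- v[v > 0]
      if (length(v) == 0L) next
      m <- median_iqr(v)
      sd_rows[[paste(s, route)]] <- data.frame(
        stratum = s, route = route, n = length(v),
        median = m[["median"]], q1 = m[["q1"]], q3 = m[["q3"]],
        stringsAsFactors = FALSE)
    }
  }
  steroid_days <- do.call(rbind, sd_rows)
  rownames(steroid_days) <- NULL
  list(counts = counts, steroid_days = steroid_days)
}

#' Chi-square group comparisons for the standard outcome set
#'
#' EO-vs-NEO 2 x 2 (or 2 x k) comparisons of sex, academic flag, steroid
#' use, MTD use, MTD line counts, surgery and death.
#'
#' @param cohort_obj a `uc_cohort`.
#' @return data.frame: `comparison`, `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(cohort_obj) {
  co <- cohort_obj$cohort
  eo <- co$onset_group == "EO"
  cmp <- function(name, x) {
    tab <- table(factor(eo, levels = c(FALSE, TRUE)), x)
    res <- tryCatch(chi_square_compare(tab),
                    error = function(e) list(statistic = NA_real_,
                                             df = NA_integer_,
                                             p_value = NA_real_))
    data.frame(comparison = name, statistic = res$statistic, df = res$df,
               p_value = res$p_value, stringsAsFactors = FALSE)
  }
  out <- rbind(cmp("sex", co$sex),
               cmp("academic", co$academic),
               cmp("steroid_use", co$steroid_use),
               cmp("mtd_use", co$mtd_use),
               cmp("mtd_lines", pmin(co$mtd_lines, 2L)),
               cmp("surgery", co$surgery),
               cmp("death", co$death))
  rownames(out) <- NULL
  out
}

#' Run the full pipeline and write all artifacts
#'
#' Executes cohort construction, episode assembly, the three event-free
#' survival comparisons, MTD persistence, the four outcome models, group
#' comparisons and summary tables, writing each result as a tab-separated
#' file under `out_dir` plus a run log (seed, package version, exclusion
#' tally).
#'
#' @param bundle a `claims_bundle` (generated or read from disk).
#' @param out_dir output directory.
#' @param catalog a `drug_catalog`.
#' @return (invisibly) a list with every in-memory result.
#' @export
run_pipeline <- function(bundle, out_dir,
                         catalog = default_drug_catalog()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  cohort_obj <- build_cohort(bundle, catalog)
  wt(cohort_obj$cohort, "cohort")
  wt(cohort_obj$episodes, "episodes")

  ads <- build_analysis_dataset(cohort_obj)
  wt(ads, "analysis_dataset")

  km <- list(); lr <- list()
  for (oc in c("steroid", "mtd", "surgery")) {
    tte <- extract_time_to_event(cohort_obj, oc)
    km[[oc]] <- km_estimate(tte)
    wt(km[[oc]], paste0("km_", oc))
    lr[[oc]] <- tryCatch(logrank_test(tte), error = function(e) NULL)
  }
  lr_df <- do.call(rbind, lapply(names(lr), function(oc)
    if (!is.null(lr[[oc]]))
      data.frame(outcome = oc, statistic = lr[[oc]]$statistic,
                 p_value = lr[[oc]]$p_value, stringsAsFactors = FALSE)))
  if (!is.null(lr_df)) wt(lr_df, "logrank")

  persist <- tryCatch(persistence_curve(cohort_obj, catalog, "group"),
                      error = function(e) NULL)
  if (!is.null(persist)) wt(persist$curve, "km_persistence")

  models <- list()
  for (oc in c("steroid", "mtd", "surgery", "death"))
    models[[oc]] <- tryCatch(fit_outcome_model(ads, oc),
                             error = function(e) NULL)
  mod_df <- do.call(rbind, models[!vapply(models, is.null, logical(1))])
  if (!is.null(mod_df)) wt(mod_df, "models")

  summaries <- summarize_cohort(cohort_obj, catalog)
  wt(summaries$counts, "summary_counts")
  if (!is.null(summaries$steroid_days))
    wt(summaries$steroid_days, "summary_steroid_days")
  comparisons <- compare_groups(cohort_obj)
  wt(comparisons, "group_comparisons")

  writeLines(c(
    paste0("ucclaims ", as.character(utils::packageVersion("ucclaims"))),
    paste0("seed: ", bundle$meta$seed),
    paste0("patients in: ", nrow(bundle$patients)),
    paste0("cohort: ", nrow(cohort_obj$cohort)),
    paste0("exclusions: ",
           paste(names(cohort_obj$exclusions), cohort_obj$exclusions,
                 sep = "=", collapse = ", "))),
    file.path(out_dir, "run_log.txt"))

  invisible(list(cohort = cohort_obj, analysis = ads, km = km,
                 logrank = lr, persistence = persist, models = models,
                 summaries = summaries, comparisons = comparisons))
}
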