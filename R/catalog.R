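#' Drug catalog: study drugs and their scheduled-refill rules
#'
#' Exposure-episode construction hinges on the *next scheduled prescription
#' date*: the date a refill is expected, after which a >13-week gap counts as
#' discontinuation. The expected-refill interval differs by drug:
#' ustekinumab is redosed every 12 weeks, infliximab and vedolizumab every
#' 8 weeks, adalimumab and golimumab cover `dispensed count x 14` days per
#' claim line, and all remaining drugs cover the dispensed prescription days.
#' The catalog encodes one such rule per drug together with its class and
#' route, and is the single source the episode engine consults.
#'
#' @name drug-catalog
NULL

.DRUG_CLASSES <- c("5-ASA", "systemic_steroid", "topical_steroid",
                   "immunomodulator", "biologic", "small_molecule")
.ROUTES <- c("po", "iv", "sc")
.RULES <- c("fixed_weeks", "count_times_14", "prescription_days")

# drug classes whose first new prescription anchors the UC onset date
.ONSET_CLASSES <- c("5-ASA", "systemic_steroid", "topical_steroid")
# molecular targeting drugs = biologics + small molecules
.MTD_CLASSES <- c("biologic", "small_molecule")

#' Create a single drug specification
#'
#' @param drug_id unique token identifying the drug (and route, where the
#'   same molecule is tabulated separately by route).
#' @param display_name human-readable name.
#' @param drug_class one of `"5-ASA"`, `"systemic_steroid"`,
#'   `"topical_steroid"`, `"immunomodulator"`, `"biologic"`,
#'   `"small_molecule"`.
#' @param route one of `"po"`, `"iv"`, `"sc"`.
#' @param rule refill rule: `"fixed_weeks"` (next refill due `rule_param`
#'   weeks after the last prescription), `"count_times_14"` (dispensed count
#'   times 14 days), or `"prescription_days"` (dispensed covered days).
#' @param rule_param integer number of weeks; required for `fixed_weeks`,
#'   ignored otherwise.
#' @return a `drug_spec` list.
#' @export
drug_spec <- function(drug_id, display_name, drug_class, route, rule,
                      rule_param = NA_integer_) {
  stopifnot(is.character(drug_id), length(drug_id) == 1L, nzchar(drug_id))
  drug_class <- match.arg(drug_class, .DRUG_CLASSES)
  route <- match.arg(route, .ROUTES)
  rule <- match.arg(rule, .RULES)
  if (rule == "fixed_weeks") {
    rule_param <- as.integer(rule_param)
    if (is.na(rule_param) || rule_param <= 0L)
      stop("fixed_weeks rule requires a positive integer number of weeks for '",
           drug_id, "'", call. = FALSE)
  } else {
    rule_param <- NA_integer_
  }
  structure(list(drug_id = drug_id, display_name = display_name,
                 drug_class = drug_class, route = route, rule = rule,
                 rule_param = rule_param),
            class = "drug_spec")
}

#' Assemble a drug catalog from drug specifications
#'
#' @param specs list of [drug_spec()] objects.
#' @return a `drug_catalog` object: named list of specs plus a class index.
#' @export
drug_catalog <- function(specs) {
  stopifnot(is.list(specs), length(specs) > 0L)
  ids <- vapply(specs, function(s) s$drug_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate drug_id in catalog: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(specs) <- ids
  classes <- vapply(specs, function(s) s$drug_class, character(1))
  class_index <- split(ids, factor(classes, levels = .DRUG_CLASSES))
  structure(list(entries = specs, class_index = class_index),
            class = "drug_catalog")
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat("<drug_catalog> ", length(x$entries), " drugs\n", sep = "")
  for (cl in names(x$class_index)) {
    ids <- x$class_index[[cl]]
    if (length(ids))
      cat("  ", format(cl, width = 16), paste(ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Look up one drug in a catalog
#'
#' @param catalog a `drug_catalog`.
#' @param drug_id drug token.
#' @return the `drug_spec`.
#' @export
catalog_get <- function(catalog, drug_id) {
  stopifnot(inherits(catalog, "drug_catalog"))
  spec <- catalog$entries[[drug_id]]
  if (is.null(spec))
    stop("unknown drug_id '", drug_id, "' not in catalog", call. = FALSE)
  spec
}

#' Drug ids belonging to given classes
#'
#' @param catalog a `drug_catalog`.
#' @param classes character vector of drug classes.
#' @return character vector of drug ids.
#' @export
catalog_class_ids <- function(catalog, classes) {
  stopifnot(inherits(catalog, "drug_catalog"))
  unlist(catalog$class_index[classes], use.names = FALSE)
}

#' Drug ids of the onset-qualifying classes (5-ASA, systemic and topical steroid)
#' @param catalog a `drug_catalog`.
#' @return character vector of drug ids.
#' @export
onset_class_ids <- function(catalog) catalog_class_ids(catalog, .ONSET_CLASSES)

#' Drug ids of the molecular targeting drugs (biologics and small molecules)
#' @param catalog a `drug_catalog`.
#' @return character vector of drug ids.
#' @export
mtd_ids <- function(catalog) catalog_class_ids(catalog, .MTD_CLASSES)

#' Next scheduled prescription date
#'
#' Advances the last prescription date by the drug's expected-refill interval:
#' `fixed_weeks` drugs by `7 * k` days regardless of the dispensed amount,
#' `count_times_14` drugs by `14 * dispensed` days, and `prescription_days`
#' drugs by the dispensed covered days. Weeks are exactly 7 calendar days;
#' no month arithmetic is used.
#'
#' @param spec a `drug_spec`.
#' @param last_rx_date `Date` of the most recent prescription.
#' @param dispensed dispensed count (for `count_times_14`) or covered days
#'   (for `prescription_days`); must be >= 1. Ignored for `fixed_weeks`.
#' @return `Date` on which the next refill is expected.
#' @examples
#' cat <- default_drug_catalog()
#' next_scheduled_date(catalog_get(cat, "ustekinumab"), as.Date("2020-01-01"))
#' @export
next_scheduled_date <- function(spec, last_rx_date, dispensed = 1L) {
  stopifnot(inherits(spec, "drug_spec"))
  last_rx_date <- as.Date(last_rx_date)
  if (anyNA(last_rx_date)) stop("invalid last_rx_date", call. = FALSE)
  offset <- switch(spec$rule,
    fixed_weeks = rep.int(7L * spec$rule_param, length(last_rx_date)),
    count_times_14 = {
      .check_dispensed(dispensed, spec)
      14L * as.integer(dispensed)
    },
    prescription_days = {
      .check_dispensed(dispensed, spec)
      as.integer(dispensed)
    })
  last_rx_date + offset
}

.check_dispensed <- function(dispensed, spec) {
  if (anyNA(dispensed) || any(dispensed < 1))
    stop("dispensed must be >= 1 for rule '", spec$rule, "' (drug '",
         spec$drug_id, "')", call. = FALSE)
  invisible(TRUE)
}

#' The default study drug catalog
#'
#' Reads the packaged catalog config (`inst/extdata/drug_catalog.tsv`), which
#' encodes the study drug set: 5-ASA, prednisolone (po and iv), a topical
#' steroid, azathioprine, 6-mercaptopurine, the biologics infliximab,
#' adalimumab, golimumab, ustekinumab and vedolizumab, and the small molecules
#' tofacitinib, tacrolimus and cyclosporine (po and iv tabulated separately).
#'
#' @return a `drug_catalog`.
#' @export
default_drug_catalog <- function() {
  path <- system.file("extdata", "drug_catalog.tsv", package = "ucclaims",
                      mustWork = TRUE)
  read_drug_catalog(path)
}

#' Read a drug catalog from a delimited config file
#'
#' The config is a tab-separated file with header
#' `drug_id  display_name  drug_class  route  rule  rule_param`; `rule_param`
#' is the week count for `fixed_weeks` drugs and empty otherwise. The drug
#' list can be extended without code change.
#'
#' @param path path to the config file.
#' @return a `drug_catalog`.
#' @export
read_drug_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(rule_param = "integer"))
  need <- c("drug_id", "display_name", "drug_class", "route", "rule",
            "rule_param")
  if (!all(need %in% names(df)))
    stop("catalog config missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  specs <- lapply(seq_len(nrow(df)), function(i)
    drug_spec(df$drug_id[i], df$display_name[i], df$drug_class[i],
              df$route[i], df$rule[i], df$rule_param[i]))
  drug_catalog(specs)
}
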