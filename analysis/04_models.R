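#!/usr/bin/env Rscript
# Multivariable outcome models: Cox proportional hazards for steroid / MTD /
# surgery (hazard ratios), logistic regression for death (odds ratios).
# Covariates follow the study design: sex, onset group, academic hospital,
# plus prior steroid / MTD use for the later outcomes.

library(ucclaims)

bundle <- read_claims("results/claims")
cohort <- build_cohort(bundle)
ads <- build_analysis_dataset(cohort)
dir.create("results/models", showWarnings = FALSE, recursive = TRUE)

# Rare covariates (the ~0.5% academic flag; the onset group when no
# non-elderly death occurs in a replicate) can be completely separated at
# this cohort scale. Fit the full covariate set first and drop the
# offending covariate when the fit is degenerate, reporting what was kept.
default_covs <- list(
  steroid = c("female", "elderly_onset", "academic"),
  mtd     = c("female", "elderly_onset", "academic", "steroid_use"),
  surgery = c("female", "elderly_onset", "academic", "steroid_use",
              "mtd_use"),
  death   = c("female", "elderly_onset", "academic", "steroid_use",
              "mtd_use"))

fit_with_fallback <- function(ads, oc) {
  covs <- default_covs[[oc]]
  while (length(covs) > 0L) {
    res <- tryCatch(suppressWarnings(fit_outcome_model(ads, oc, covs)),
                    error = function(e) e)
    if (!inherits(res, "error")) return(res)
    msg <- conditionMessage(res)
    bad <- regmatches(msg, regexpr("[a-z_]+(?=TRUE)", msg, perl = TRUE))
    if (length(bad) == 0L || !bad %in% covs) {
      cat("model", oc, "not estimable:", msg, "\n")
      return(NULL)
    }
    cat("model ", oc, ": dropping separated covariate '", bad, "'\n",
        sep = "")
    covs <- setdiff(covs, bad)
  }
  NULL
}

fits <- list()
for (oc in c("steroid", "mtd", "surgery", "death"))
  fits[[oc]] <- fit_with_fallback(ads, oc)
out <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
write.table(out, "results/models/outcome_models.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

for (i in seq_len(nrow(out)))
  cat(sprintf("%-8s %-22s %s = %.2f (%.2f-%.2f)  p = %.3g\n",
              out$outcome[i], out$term[i],
              if (out$family[i] == "logistic") "OR" else "HR",
              out$estimate[i], out$ci_low[i], out$ci_high[i],
              out$p_value[i]))
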