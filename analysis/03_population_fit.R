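#!/usr/bin/env Rscript
## Fit the dissemination-and-growth model to the synthetic cohort,
## replicating the two-stage calibration: (1) preliminary fit of the
## primary tumour with the inoculum signal free, giving the one-cell
## signal by proportionality with the 1e5 injected cells; (2) joint fit of
## primary tumour and total metastatic burden, pooled and mixed-effects.
## Recovery is judged against the generator's sidecar truth.

library(metaburden)
stopifnot(file.exists("results/cohort.csv"))

cohort <- read.csv("results/cohort.csv")
truth <- read_sidecar_truth("results/cohort_truth.json")
cohort <- preprocess_cohort(cohort)
cat(sprintf("cohort after preprocessing: %d rows\n", nrow(cohort)))

## stage 1: primary tumour, v_inj free
prim <- fit_primary_vinj(cohort[cohort$organ == "kidney", ])
cat(sprintf("primary fit: v_inj = %.3g, alpha = %.3g, beta = %.3g, v0 = %.3g\n",
            prim$v_inj, prim$alpha, prim$beta, prim$v0))

## stage 2: joint fits
pooled <- fit_joint(cohort, v0 = prim$v0, mode = "pooled")
print(pooled)
mixed <- fit_joint(cohort, v0 = prim$v0, mode = "mixed")
print(mixed)

recovery <- merge(
  data.frame(parameter = names(truth$medians),
             truth_median = unlist(truth$medians),
             truth_cv = unlist(truth$cv_pct)),
  mixed$estimates, by = "parameter")
recovery$rel_err_median <- recovery$median / recovery$truth_median - 1
print(recovery, row.names = FALSE)

out <- list(primary = prim[c("v_inj", "alpha", "beta", "v0", "sigma_log")],
            pooled = pooled$estimates, mixed = mixed$estimates,
            mixed_converged = mixed$converged,
            recovery = recovery)
jsonlite::write_json(out, "results/population_fit.json", auto_unbox = TRUE,
                     digits = NA, dataframe = "rows")
cat("wrote results/population_fit.json\n")
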