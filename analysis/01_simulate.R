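#!/usr/bin/env Rscript
# Generate the two synthetic plasma cohorts (training 47 cases / 46 controls,
# validation 20/20) under the default chronic-fatigue scenario and write the
# peak tables, sample metadata and calibration standards as TSV.

suppressPackageStartupMessages(library(ratiodx))

seed <- 20161011L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scenario <- default_cfs_scenario()
write_scenario(scenario, file.path(out, "scenario.yaml"))

for (cohort in c("training", "validation")) {
  g <- generate_cohort(scenario, cohort,
                       seed = seed + match(cohort, c("training", "validation")))
  write_tsv(g$peaks, file.path(out, paste0("peaks_", cohort, ".tsv")))
  write_tsv(g$samples, file.path(out, paste0("samples_", cohort, ".tsv")))
  write_tsv(g$standards, file.path(out, paste0("standards_", cohort, ".tsv")))
  message(sprintf("%s cohort: %d samples, %d peak records (%.1f%% censored)",
                  cohort, nrow(g$samples), nrow(g$peaks),
                  100 * (1 - nrow(g$peaks) /
                           (nrow(g$samples) * nrow(scenario$metabolites)))))
}
message("inputs written under ", out)
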