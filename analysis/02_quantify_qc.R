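#!/usr/bin/env Rscript
# Quantify both cohorts through the internal-standard calibration, apply the
# S/N >= 10 and per-group missingness retention rules, intersect the cohorts'
# surviving metabolites, and impute missing cells by half the per-metabolite
# minimum. Writes the imputed matrices and the QC report.

suppressPackageStartupMessages(library(ratiodx))

inp <- "results/data"
out <- "results/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config(rng_seed = 20161011L)

prep <- function(cohort) {
  peaks <- read_peak_table(file.path(inp, paste0("peaks_", cohort, ".tsv")))
  samples <- read_sample_metadata(file.path(inp, paste0("samples_", cohort, ".tsv")))
  standards <- read_calibration(file.path(inp, paste0("standards_", cohort, ".tsv")))
  mat <- quantify(peaks, standards, samples)
  snr <- filter_snr(mat, peaks, cfg$snr_threshold)
  msn <- filter_missingness(snr$matrix, samples, cfg$max_missing_fraction)
  message(sprintf("%s: %d quantified -> %d pass S/N -> %d pass missingness",
                  cohort, ncol(mat$values), ncol(snr$matrix$values),
                  ncol(msn$matrix$values)))
  list(samples = samples, snr = snr, msn = msn)
}

tr <- prep("training")
va <- prep("validation")

shared <- intersect_cohorts(metabolite_ids(tr$msn$matrix),
                            metabolite_ids(va$msn$matrix))
message(length(shared), " metabolites consistently observed in both cohorts")

write_tsv(combine_qc(tr$snr$report, tr$msn$report, shared),
          file.path(out, "qc_training.tsv"))
write_tsv(combine_qc(va$snr$report, va$msn$report, shared),
          file.path(out, "qc_validation.tsv"))

for (x in list(list(tag = "training", p = tr), list(tag = "validation", p = va))) {
  imp <- impute_half_min(subset_matrix(x$p$msn$matrix, metabolites = shared))
  write_matrix(imp, file.path(out, paste0("matrix_", x$tag, ".tsv")))
  message(sprintf("%s matrix imputed: %d x %d, written", x$tag,
                  nrow(imp$values), ncol(imp$values)))
}
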