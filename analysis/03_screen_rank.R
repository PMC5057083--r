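#!/usr/bin/env Rscript
# Univariate Mann-Whitney screening of the training cohort, linear SVM-RFE
# multivariate ranking, and pathway-guided enumeration of substrate/product
# ratio-index candidates among the top-ranked metabolites.

suppressPackageStartupMessages(library(ratiodx))

out <- "results/screening"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config(rng_seed = 20161011L)

mat <- read_matrix("results/qc/matrix_training.tsv")
samples <- read_sample_metadata("results/data/samples_training.tsv")

scr <- mannwhitney_all(mat, samples)
scr <- scr[order(scr$p_value), ]
write_tsv(scr, file.path(out, "mannwhitney.tsv"))
message("metabolites at p < 0.05: ",
        paste(scr$metabolite_id[scr$p_value < 0.05], collapse = ", "))

rk <- rank_svm_fs(mat, samples, seed = 20161011L + 100L, cost = cfg$svm_cost)
write_tsv(data.frame(rank = seq_along(rk$metabolite_ids),
                     metabolite_id = rk$metabolite_ids,
                     score = unname(rk$score)),
          file.path(out, "svm_ranking.tsv"))
message("SVM-RFE top five: ",
        paste(rk$metabolite_ids[1:5], collapse = ", "))

cand <- enumerate_ratio_indexes(rk, default_pathway_graph(),
                                top_k = cfg$top_k_features,
                                max_path_length = cfg$max_path_length)
write_tsv(cand, file.path(out, "ratio_candidates.tsv"))
sel <- select_ratio_indexes(cand, cfg$n_indexes)
write_tsv(sel[, c("numerator", "denominator", "path_length", "pathway")],
          file.path(out, "ratio_indexes.tsv"))
message("selected ratio indexes: ", paste(sel$label, collapse = ", "))
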