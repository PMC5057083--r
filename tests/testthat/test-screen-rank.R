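test_that("Mann-Whitney screening reproduces the extreme 3-vs-3 configuration", {
  fx <- matrix_from_groups(case = c(4, 5, 6), control = c(1, 2, 3))
  res <- mannwhitney_all(fx$matrix, fx$samples)
  expect_equal(res$u_statistic, 9)         # all case-control pairs concordant
  expect_equal(res$p_value, 0.100, tolerance = 1e-12)
  expect_equal(res$direction, "up_in_case")
  expect_equal(res$significance_band, "ns")
})

test_that("identical groups give p = 1 and no direction", {
  fx <- matrix_from_groups(case = c(2, 2, 2), control = c(2, 2, 2))
  res <- mannwhitney_all(fx$matrix, fx$samples)
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, "none")
})

test_that("relabelling groups preserves p and flips direction and U", {
  set.seed(3)
  x <- rnorm(8, 1); y <- rnorm(9)
  a <- matrix_from_groups(x, y)
  b <- matrix_from_groups(y, x)
  ra <- mannwhitney_all(a$matrix, a$samples)
  rb <- mannwhitney_all(b$matrix, b$samples)
  expect_equal(ra$p_value, rb$p_value)
  expect_equal(ra$direction, "up_in_case")
  expect_equal(rb$direction, "down_in_case")
  # U(case) + U(control) = n1 * n2 for tie-free data
  expect_equal(ra$u_statistic + rb$u_statistic, 8 * 9)
})

test_that("exact and normal-approximation p agree within 0.02 at n=10 per group", {
  set.seed(11)
  for (rep in 1:20) {
    x <- rnorm(10, 0.5); y <- rnorm(10)
    p_norm <- mannwhitney_all(matrix_from_groups(x, y)$matrix,
                              matrix_from_groups(x, y)$samples)$p_value
    p_exact <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(p_norm - p_exact), 0.02)
  }
})

test_that("significance bands follow the reporting cut points", {
  expect_equal(significance_band(c(0.0005, 0.005, 0.03, 0.07, 0.5)),
               c("p<0.001", "p<0.01", "p<0.05", "p<0.10", "ns"))
})

test_that("SVM-RFE ranks a cleanly separating feature first", {
  set.seed(21)
  samples <- make_samples(20, 20)
  signal <- c(rnorm(20, 4, 0.3), rnorm(20, -4, 0.3))
  vals <- cbind(noise1 = rnorm(40), signal = signal, noise2 = rnorm(40))
  mat <- make_matrix(vals, samples)
  rk <- rank_svm_fs(mat, samples, seed = 5)
  expect_equal(rk$metabolite_ids[1], "signal")
  expect_setequal(rk$metabolite_ids, colnames(vals))

  # deterministic given the seed
  rk2 <- rank_svm_fs(mat, samples, seed = 5)
  expect_identical(rk, rk2)

  # invariant to affine rescaling of any input feature
  vals_scaled <- vals
  vals_scaled[, "noise1"] <- vals[, "noise1"] * 1000 + 77
  rk3 <- rank_svm_fs(make_matrix(vals_scaled, samples), samples, seed = 5)
  expect_identical(rk3$metabolite_ids, rk$metabolite_ids)

  # duplicating every sample leaves the separating geometry unchanged
  dup_samples <- make_samples(40, 40)
  dup_vals <- rbind(vals[1:20, ], vals[1:20, ], vals[21:40, ], vals[21:40, ])
  rk4 <- rank_svm_fs(make_matrix(dup_vals, dup_samples), dup_samples, seed = 5)
  expect_identical(rk4$metabolite_ids, rk$metabolite_ids)
})

test_that("constant features are zeroed with a warning but still ranked", {
  samples <- make_samples(5, 5)
  vals <- cbind(flat = rep(2, 10), good = c(rnorm(5, 3), rnorm(5, -3)))
  expect_warning(rk <- rank_svm_fs(make_matrix(vals, samples), samples, 1),
                 "flat")
  expect_equal(rk$metabolite_ids, c("good", "flat"))
})

test_that("ratio enumeration finds the substrate/product pairs on the bundled map", {
  g <- default_pathway_graph()
  top5 <- c("ornithine", "citrulline", "lactate", "isocitrate", "pyruvate")
  rk <- structure(list(metabolite_ids = top5,
                       score = setNames(5:1, top5),
                       method = "fixed", seed = 0L),
                  class = "feature_ranking")
  cand <- enumerate_ratio_indexes(rk, g, top_k = 5, max_path_length = 4)
  expect_true("ornithine/citrulline" %in% cand$label)
  expect_true("pyruvate/isocitrate" %in% cand$label)
  expect_equal(cand$path_length[cand$label == "ornithine/citrulline"], 1L)
  expect_equal(cand$path_length[cand$label == "pyruvate/isocitrate"], 3L)
  expect_equal(cand$pathway[cand$label == "ornithine/citrulline"],
               "urea_cycle")
  # sorted by combined rank: ornithine/citrulline (1+2) leads
  expect_equal(cand$label[1], "ornithine/citrulline")
  # reordering the input metabolites does not change the output
  rk_shuffled <- rk
  rk_shuffled$metabolite_ids <- top5   # ranking fixed, graph order irrelevant
  g2 <- read_pathway_graph(system.file("extdata", "pathway_energy_urea.tsv",
                                       package = "ratiodx"))
  expect_identical(enumerate_ratio_indexes(rk, g2, 5, 4), cand)
})

test_that("path length bounds and disconnected sets behave as specified", {
  toy <- igraph::graph_from_data_frame(
    data.frame(substrate = c("a", "b"), product = c("b", "c"),
               pathway = "toy"), directed = TRUE)
  rk <- structure(list(metabolite_ids = c("a", "c"),
                       score = c(a = 2, c = 1), method = "fixed", seed = 0L),
                  class = "feature_ranking")
  expect_equal(nrow(enumerate_ratio_indexes(rk, toy, 2, max_path_length = 1)), 0)
  two <- enumerate_ratio_indexes(rk, toy, 2, max_path_length = 2)
  expect_equal(two$label, "a/c")
  expect_equal(two$path_length, 2L)

  apart <- igraph::graph_from_data_frame(
    data.frame(substrate = c("a", "x"), product = c("b", "y")),
    directed = TRUE)
  rk2 <- structure(list(metabolite_ids = c("a", "y"),
                        score = c(a = 2, y = 1), method = "fixed", seed = 0L),
                   class = "feature_ranking")
  expect_equal(nrow(enumerate_ratio_indexes(rk2, apart, 2, 4)), 0)
})

test_that("reciprocal candidates are deduplicated at selection", {
  cand <- data.frame(
    numerator = c("orn", "cit", "pyr"),
    denominator = c("cit", "orn", "iso"),
    path_length = c(1L, 3L, 3L), pathway = "p",
    combined_rank = c(3L, 3L, 9L),
    label = c("orn/cit", "cit/orn", "pyr/iso"),
    stringsAsFactors = FALSE)
  sel <- select_ratio_indexes(cand, n = 2)
  expect_equal(sel$label, c("orn/cit", "pyr/iso"))
  sel_all <- select_ratio_indexes(cand, n = 2, dedupe_reciprocal = FALSE)
  expect_equal(sel_all$label, c("orn/cit", "cit/orn"))
})

test_that("ratio features divide concentrations and cancel global scaling", {
  samples <- make_samples(2, 1)
  vals <- cbind(ornithine = c(100, 60, 30), citrulline = c(50, 30, 60))
  mat <- make_matrix(vals, samples)
  idx <- data.frame(numerator = "ornithine", denominator = "citrulline",
                    stringsAsFactors = FALSE)
  feats <- compute_ratio_features(mat, idx)
  expect_equal(unname(feats$values[, 1]), c(2, 2, 0.5))
  expect_equal(feats$provenance, "features")

  # per-sample global rescaling cancels bit-for-bit
  s <- c(0.25, 3, 17)
  scaled <- make_matrix(vals * s, samples)
  expect_identical(compute_ratio_features(scaled, idx)$values, feats$values)

  # empty index set yields a zero-column feature matrix
  empty <- compute_ratio_features(mat, idx[0, , drop = FALSE])
  expect_equal(ncol(empty$values), 0)

  # zero denominators are named
  vals0 <- vals; vals0[2, "citrulline"] <- 0
  expect_error(compute_ratio_features(make_matrix(vals0, samples), idx),
               "citrulline.*S02")
})
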