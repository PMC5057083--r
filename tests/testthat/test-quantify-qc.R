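peak_row <- function(sample, met, area, isa, mode = "cation", sn = 20) {
  data.frame(sample_id = sample, metabolite_id = met, mode = mode,
             peak_area = area, sn_ratio = sn, is_area = isa,
             stringsAsFactors = FALSE)
}

std_row <- function(met, conc, rel = 1, mode = "cation") {
  data.frame(metabolite_id = met, mode = mode,
             standard_concentration = conc, standard_relative_area = rel,
             stringsAsFactors = FALSE)
}

test_that("internal-standard quantification applies the calibration formula", {
  peaks <- peak_row("S01", "ornithine", area = 1000, isa = 500)
  std <- std_row("ornithine", conc = 50, rel = 1)
  mat <- quantify(peaks, std)
  expect_equal(mat$values["S01", "ornithine"], 100)  # (1000/500)/1 * 50
  expect_equal(mat$provenance, "quantified")

  # sample relative area equal to the standard's recovers the standard conc
  mat2 <- quantify(peak_row("S01", "m", 750, 500), std_row("m", 80, rel = 1.5))
  expect_equal(mat2$values["S01", "m"], 80)
})

test_that("quantification is invariant to common detector rescaling", {
  std <- std_row("m", 40, rel = 0.8)
  for (s in c(0.01, 1, 250)) {
    mat <- quantify(peak_row("S01", "m", 600 * s, 300 * s), std)
    expect_equal(mat$values["S01", "m"], (600 / 300) / 0.8 * 40)
  }
})

test_that("quantification errors name missing standards and bad IS areas", {
  expect_error(quantify(peak_row("S01", "mystery", 10, 5), std_row("m", 1)),
               "mystery")
  bad <- peak_row("S01", "m", 10, isa = 0)
  expect_error(quantify(bad, std_row("m", 1)), "is_area")
})

test_that("S/N retention uses an inclusive per-metabolite median threshold", {
  samples <- make_samples(2, 1)
  peaks <- rbind(
    peak_row(c("S01", "S02", "S03"), "at_limit", 10, 5, sn = c(9, 10, 11)),
    peak_row(c("S01", "S02", "S03"), "below", 10, 5, sn = c(9.99, 9.99, 9.99)),
    peak_row(c("S01", "S02", "S03"), "strong", 10, 5, sn = c(100, 120, 90)))
  mat <- to_matrix(peaks, samples)
  res <- filter_snr(mat, peaks, threshold = 10)
  expect_setequal(metabolite_ids(res$matrix), c("at_limit", "strong"))
  rep_below <- res$report[res$report$metabolite_id == "below", ]
  expect_false(rep_below$retained)
  expect_equal(rep_below$rejection_reason, "low_snr")
  # all above threshold leaves the matrix untouched
  res2 <- filter_snr(mat, peaks, threshold = 5)
  expect_identical(res2$matrix$values, mat$values)
})

test_that("metabolites without any S/N data are retained with a warning", {
  samples <- make_samples(1, 1)
  peaks <- peak_row(c("S01", "S02"), "m", 10, 5, sn = NA)
  mat <- to_matrix(peaks, samples)
  expect_warning(res <- filter_snr(mat, peaks, 10), "m")
  expect_true(res$report$retained)
  expect_false(res$report$sn_checked)
})

test_that("missingness filtering is per group with an inclusive cap", {
  samples <- make_samples(10, 10)
  vals <- matrix(1, 20, 2, dimnames = list(samples$sample_id, c("ok", "gappy")))
  vals[11:13, 2] <- NA   # 3/10 controls missing
  mat <- metabolite_matrix(vals, provenance = "quantified")
  res <- filter_missingness(mat, samples, max_fraction = 0.2)
  expect_equal(metabolite_ids(res$matrix), "ok")
  expect_equal(res$report$rejection_reason[res$report$metabolite_id == "gappy"],
               "too_missing")
  expect_equal(res$report$missing_fraction_control[
    res$report$metabolite_id == "gappy"], 0.3)
  # vacuous threshold drops nothing; complete data always retained
  expect_equal(ncol(filter_missingness(mat, samples, 1)$matrix$values), 2)
  expect_true(all(filter_missingness(
    metabolite_matrix(matrix(1, 20, 2,
                             dimnames = dimnames(vals)),
                      provenance = "quantified"),
    samples, 0)$report$retained))
})

test_that("filters are monotone in their thresholds", {
  set.seed(7)
  samples <- make_samples(8, 8)
  peaks <- do.call(rbind, lapply(paste0("m", 1:6), function(m)
    peak_row(samples$sample_id, m, 10, 5, sn = runif(16, 5, 20))))
  vals <- matrix(rexp(16 * 6), 16, 6,
                 dimnames = list(samples$sample_id, paste0("m", 1:6)))
  vals[runif(96) < 0.2] <- NA
  mat <- metabolite_matrix(vals, provenance = "quantified")
  snr_sets <- lapply(c(5, 8, 11, 14),
                     function(t) metabolite_ids(filter_snr(mat, peaks, t)$matrix))
  for (i in seq_len(length(snr_sets) - 1))
    expect_true(all(snr_sets[[i + 1]] %in% snr_sets[[i]]))
  miss_sets <- lapply(c(0.4, 0.25, 0.1, 0),
                      function(f) metabolite_ids(
                        filter_missingness(mat, samples, f)$matrix))
  for (i in seq_len(length(miss_sets) - 1))
    expect_true(all(miss_sets[[i + 1]] %in% miss_sets[[i]]))
})

test_that("cohort intersection preserves training order and rejects emptiness", {
  expect_equal(intersect_cohorts(c("A", "B", "C"), c("C", "B", "D")),
               c("B", "C"))
  expect_equal(intersect_cohorts(c("A", "B"), c("A", "B")), c("A", "B"))
  expect_error(intersect_cohorts("A", "B"), "cannot proceed")
  # sizes mirroring a 53-vs-33 retention with 31 shared
  tr <- paste0("t", 1:53)
  va <- c(tr[1:31], paste0("v", 1:2))
  expect_length(intersect_cohorts(tr, va), 31)
})

test_that("half-minimum imputation fills each metabolite from its own minimum", {
  samples <- make_samples(2, 1)
  vals <- matrix(c(4, 8, NA, 10, 20, 30), 3, 2,
                 dimnames = list(samples$sample_id, c("gap", "full")))
  mat <- metabolite_matrix(vals, provenance = "quantified")
  imp <- impute_half_min(mat)
  expect_equal(unname(imp$values[, "gap"]), c(4, 8, 2))
  expect_equal(unname(imp$values[, "full"]), c(10, 20, 30))
  expect_equal(imp$provenance, "imputed")
  expect_false(any(imp$missing))
  # minimum after imputation is exactly half the observed minimum
  expect_equal(min(imp$values[, "gap"]), min(vals[, "gap"], na.rm = TRUE) / 2)
  # idempotent
  expect_identical(impute_half_min(imp)$values, imp$values)
  # no-missing input is returned unchanged
  expect_identical(impute_half_min(metabolite_matrix(
    vals[, "full", drop = FALSE], provenance = "quantified"))$values,
    vals[, "full", drop = FALSE])
})

test_that("a fully missing metabolite cannot be imputed", {
  samples <- make_samples(1, 1)
  vals <- matrix(NA_real_, 2, 1,
                 dimnames = list(samples$sample_id, "void"))
  expect_error(impute_half_min(metabolite_matrix(vals, provenance = "raw")),
               "void")
})

test_that("combined QC accounts for every metabolite exactly once", {
  samples <- make_samples(5, 5)
  peaks <- do.call(rbind, lapply(paste0("m", 1:4), function(m)
    peak_row(samples$sample_id, m, 10, 5,
             sn = if (m == "m1") 3 else 50)))
  vals <- matrix(1, 10, 4,
                 dimnames = list(samples$sample_id, paste0("m", 1:4)))
  vals[6:9, 2] <- NA
  mat <- metabolite_matrix(vals, provenance = "quantified")
  snr <- filter_snr(mat, peaks, 10)
  msn <- filter_missingness(snr$matrix, samples, 0.2)
  qc <- combine_qc(snr$report, msn$report, shared_ids = c("m3"))
  expect_equal(nrow(qc), 4)
  expect_equal(sum(qc$retained) + sum(!qc$retained), 4)
  expect_equal(qc$rejection_reason[match(paste0("m", 1:4), qc$metabolite_id)],
               c("low_snr", "too_missing", "none", "not_shared"))
  expect_true(all(qc$retained == (qc$rejection_reason == "none")))
})
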