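#' Convert peak areas to absolute concentrations via internal standards
#'
#' Each peak area is first divided by the internal-standard peak area of the
#' same run (cancelling detector-sensitivity fluctuation), then scaled
#' through the standard-mixture calibration:
#' `conc = (peak_area / is_area) / standard_relative_area * standard_concentration`.
#'
#' @param peaks Validated peak records; must carry `is_area > 0`.
#' @param standards Calibration table (see [read_calibration()]), one entry
#'   per (metabolite, mode).
#' @param samples Optional sample metadata defining row order; derived from
#'   the peaks when omitted.
#' @return A `metabolite_matrix` with provenance `"quantified"` (micromolar).
#' @export
quantify <- function(peaks, standards, samples = NULL) {
  peaks <- validate_peaks(peaks)
  standards <- validate_standards(standards)
  if (!"is_area" %in% names(peaks) || any(is.na(peaks$is_area)))
    stop("quantification requires an is_area value on every peak record")
  if (any(peaks$is_area <= 0))
    stop("internal-standard peak area (is_area) must be > 0")
  key_p <- paste(peaks$metabolite_id, peaks$mode, sep = "/")
  key_s <- paste(standards$metabolite_id, standards$mode, sep = "/")
  unmatched <- setdiff(unique(key_p), key_s)
  if (length(unmatched))
    stop("no calibration standard for: ", fmt_tokens(unmatched))
  idx <- match(key_p, key_s)
  rel <- peaks$peak_area / peaks$is_area
  peaks$concentration <- rel / standards$standard_relative_area[idx] *
    standards$standard_concentration[idx]
  if (is.null(samples))
    samples <- data.frame(sample_id = unique(peaks$sample_id),
                          cohort = "training", group = "case",
                          stringsAsFactors = FALSE)
  to_matrix(peaks, samples, value_col = "concentration",
            provenance = "quantified")
}

qc_report_row <- function(metabolite, median_sn = NA_real_,
                          miss_case = NA_real_, miss_control = NA_real_,
                          retained = TRUE, reason = "none") {
  data.frame(metabolite_id = metabolite, median_sn = median_sn,
             missing_fraction_case = miss_case,
             missing_fraction_control = miss_control,
             retained = retained, rejection_reason = reason,
             stringsAsFactors = FALSE)
}

#' Retain metabolites by median signal-to-noise ratio
#'
#' A metabolite is kept iff the median S/N over its detected records is at
#' least `threshold` (inclusive, so a median of exactly 10 passes the
#' default rule). Metabolites with no S/N data at all are retained with a
#' warning and flagged in the report.
#'
#' @param matrix A `metabolite_matrix`.
#' @param peaks Peak records carrying `sn_ratio` for the same metabolites.
#' @param threshold Minimum median S/N, > 0.
#' @return `list(matrix =, report =)`; the report is one row per metabolite.
#' @export
filter_snr <- function(matrix, peaks, threshold = 10) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  if (threshold <= 0) stop("threshold must be > 0")
  peaks <- validate_peaks(peaks)
  mets <- metabolite_ids(matrix)
  sn_col <- if ("sn_ratio" %in% names(peaks)) peaks$sn_ratio else
    rep(NA_real_, nrow(peaks))
  med <- vapply(mets, function(m) {
    v <- sn_col[peaks$metabolite_id == m]
    v <- v[!is.na(v)]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))
  no_sn <- is.na(med)
  if (any(no_sn))
    warning("no S/N data for metabolite(s), retained unchecked: ",
            fmt_tokens(mets[no_sn]))
  keep <- no_sn | med >= threshold
  report <- qc_report_row(mets, median_sn = med,
                          retained = keep,
                          reason = ifelse(keep, "none", "low_snr"))
  report$sn_checked <- !no_sn
  list(matrix = subset_matrix(matrix, metabolites = mets[keep],
                              provenance = "filtered"),
       report = report)
}

#' Retain metabolites by per-group missingness
#'
#' A metabolite is kept iff its missing fraction is at most `max_fraction`
#' within the case group and within the control group separately.
#'
#' @param matrix A `metabolite_matrix`.
#' @param samples Sample metadata for the matrix rows.
#' @param max_fraction Proportion in `[0, 1]`.
#' @return `list(matrix =, report =)`.
#' @export
filter_missingness <- function(matrix, samples, max_fraction = 0.2) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  if (max_fraction < 0 || max_fraction > 1)
    stop("max_fraction must be in [0, 1]")
  samples <- validate_samples(samples)
  ids <- sample_ids(matrix)
  grp <- samples$group[match(ids, samples$sample_id)]
  if (any(is.na(grp))) stop("matrix sample(s) absent from metadata")
  frac <- function(g) colMeans(matrix$missing[grp == g, , drop = FALSE])
  f_case <- frac("case"); f_ctrl <- frac("control")
  keep <- f_case <= max_fraction & f_ctrl <= max_fraction
  mets <- metabolite_ids(matrix)
  report <- qc_report_row(mets, miss_case = f_case, miss_control = f_ctrl,
                          retained = keep,
                          reason = ifelse(keep, "none", "too_missing"))
  list(matrix = subset_matrix(matrix, metabolites = mets[keep],
                              provenance = "filtered"),
       report = report)
}

#' Metabolites consistently observed in both cohorts
#'
#' Set intersection preserving the training-cohort order; an empty result
#' aborts the pipeline.
#'
#' @param training_ids,validation_ids Character vectors of metabolite ids
#'   retained in each cohort.
#' @export
intersect_cohorts <- function(training_ids, validation_ids) {
  shared <- training_ids[training_ids %in% validation_ids]
  if (length(shared) == 0)
    stop("no metabolite passes retention in both cohorts; cannot proceed")
  shared
}

#' Half-minimum imputation of missing concentrations
#'
#' Every missing cell of a metabolite becomes half the minimum of its
#' observed values in this dataset. Apply per cohort dataset independently.
#' Idempotent: imputed values (half the old minimum) can never fall below
#' half the new minimum.
#'
#' @param matrix A `metabolite_matrix`.
#' @return The completed matrix, provenance `"imputed"`.
#' @export
impute_half_min <- function(matrix) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  vals <- matrix$values
  all_missing <- colSums(!matrix$missing) == 0
  if (any(all_missing))
    stop("metabolite(s) fully missing, cannot impute: ",
         fmt_tokens(metabolite_ids(matrix)[all_missing]))
  for (j in seq_len(ncol(vals))) {
    miss <- matrix$missing[, j]
    if (any(miss)) vals[miss, j] <- min(vals[!miss, j]) / 2
  }
  metabolite_matrix(vals, missing = matrix(FALSE, nrow(vals), ncol(vals),
                                           dimnames = dimnames(vals)),
                    provenance = "imputed")
}

#' Merge QC reports from successive filters
#'
#' One row per metabolite of the first report; metabolites rejected earlier
#' keep their first rejection reason, later columns are filled where known.
#'
#' @param snr_report,missing_report Reports from [filter_snr()] /
#'   [filter_missingness()].
#' @param shared_ids Optional metabolite ids surviving cohort intersection;
#'   survivors of both filters absent from this set are marked `not_shared`.
#' @export
combine_qc <- function(snr_report, missing_report, shared_ids = NULL) {
  rep_all <- snr_report[, c("metabolite_id", "median_sn", "retained",
                            "rejection_reason")]
  m <- match(rep_all$metabolite_id, missing_report$metabolite_id)
  rep_all$missing_fraction_case <- missing_report$missing_fraction_case[m]
  rep_all$missing_fraction_control <- missing_report$missing_fraction_control[m]
  later_drop <- !is.na(m) & !missing_report$retained[m] & rep_all$retained
  rep_all$retained[later_drop] <- FALSE
  rep_all$rejection_reason[later_drop] <- "too_missing"
  if (!is.null(shared_ids)) {
    unshared <- rep_all$retained & !(rep_all$metabolite_id %in% shared_ids)
    rep_all$retained[unshared] <- FALSE
    rep_all$rejection_reason[unshared] <- "not_shared"
  }
  rep_all[, c("metabolite_id", "median_sn", "missing_fraction_case",
              "missing_fraction_control", "retained", "rejection_reason")]
}
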