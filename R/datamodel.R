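#' Construct a samples-by-metabolites concentration matrix
#'
#' The central exchange object of the pipeline: a numeric matrix of
#' concentrations (micromolar after quantification) with an explicit
#' missingness mask and a provenance tag recording which stage produced it.
#' Missing cells hold `NA` in `values` and `TRUE` in `missing`.
#'
#' @param values Numeric matrix, samples as rows (rownames = sample ids),
#'   metabolites as columns (colnames = metabolite ids).
#' @param missing Logical matrix of the same dimensions; defaults to
#'   `is.na(values)`.
#' @param provenance One of `"raw"`, `"quantified"`, `"filtered"`,
#'   `"imputed"`, `"features"`.
#' @return A `metabolite_matrix` object.
#' @export
metabolite_matrix <- function(values,
                              missing = is.na(values),
                              provenance = c("raw", "quantified", "filtered",
                                             "imputed", "features")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must carry sample ids as rownames and metabolite ids as colnames")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample ids in matrix rownames")
  if (anyDuplicated(colnames(values)))
    stop("duplicated metabolite ids in matrix colnames")
  if (!identical(dim(missing), dim(values)))
    stop("`missing` mask and `values` must have identical dimensions")
  storage.mode(missing) <- "logical"
  if (any(is.na(values) & !missing))
    stop("NA value present in a cell not flagged missing")
  # concentrations are non-negative; derived feature values are unrestricted
  if (provenance != "features" && any(values[!missing] < 0, na.rm = TRUE))
    stop("non-missing concentrations must be >= 0")
  values[missing] <- NA_real_
  structure(list(values = values, missing = missing, provenance = provenance),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("<metabolite_matrix> %d samples x %d metabolites (%s), %d missing cells\n",
              nrow(x$values), ncol(x$values), x$provenance, sum(x$missing)))
  invisible(x)
}

#' @rdname metabolite_matrix
#' @param x A `metabolite_matrix`.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname metabolite_matrix
#' @export
metabolite_ids <- function(x) colnames(x$values)

#' Subset a metabolite matrix
#'
#' @param x A `metabolite_matrix`.
#' @param metabolites,samples Character vectors of ids to keep (order kept as
#'   given). `NULL` keeps everything.
#' @param provenance Provenance tag for the result; defaults to the input's.
#' @export
subset_matrix <- function(x, metabolites = NULL, samples = NULL,
                          provenance = x$provenance) {
  stopifnot(inherits(x, "metabolite_matrix"))
  mets <- if (is.null(metabolites)) metabolite_ids(x) else metabolites
  smps <- if (is.null(samples)) sample_ids(x) else samples
  miss_m <- setdiff(mets, metabolite_ids(x))
  if (length(miss_m)) stop("unknown metabolite id(s): ", paste(miss_m, collapse = ", "))
  miss_s <- setdiff(smps, sample_ids(x))
  if (length(miss_s)) stop("unknown sample id(s): ", paste(miss_s, collapse = ", "))
  metabolite_matrix(x$values[smps, mets, drop = FALSE],
                    x$missing[smps, mets, drop = FALSE],
                    provenance = provenance)
}

fmt_tokens <- function(x) paste(sQuote(unique(x)), collapse = ", ")

check_enum <- function(x, levels, what) {
  bad <- setdiff(unique(as.character(x[!is.na(x)])), levels)
  if (length(bad))
    stop(sprintf("unknown %s value(s) %s; allowed: %s",
                 what, fmt_tokens(bad), paste(levels, collapse = ", ")))
  invisible(x)
}

#' Validate a sample metadata table
#'
#' Checks the closed cohort/group (and optional sex) vocabularies and
#' uniqueness of sample ids. Returns the table with enum columns as character.
#'
#' @param samples Data frame with columns `sample_id`, `cohort`, `group` and
#'   optionally `age`, `sex`, `fasting`.
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "cohort", "group")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols))
    stop("sample metadata lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup)) stop("duplicated sample_id: ", fmt_tokens(dup))
  check_enum(samples$cohort, COHORT_LEVELS, "cohort")
  check_enum(samples$group, GROUP_LEVELS, "group")
  if ("sex" %in% names(samples)) check_enum(samples$sex, SEX_LEVELS, "sex")
  samples$cohort <- as.character(samples$cohort)
  samples$group <- as.character(samples$group)
  samples
}

#' Validate a peak record table
#'
#' @param peaks Data frame with columns `sample_id`, `metabolite_id`, `mode`,
#'   `peak_area` and optionally `sn_ratio`, `is_area`.
#' @export
validate_peaks <- function(peaks) {
  need <- c("sample_id", "metabolite_id", "mode", "peak_area")
  missing_cols <- setdiff(need, names(peaks))
  if (length(missing_cols))
    stop("peak table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  peaks$sample_id <- as.character(peaks$sample_id)
  peaks$metabolite_id <- as.character(peaks$metabolite_id)
  check_enum(peaks$mode, MODE_LEVELS, "mode")
  peaks$mode <- as.character(peaks$mode)
  if (!is.numeric(peaks$peak_area)) stop("peak_area must be numeric")
  if (any(is.na(peaks$peak_area))) stop("unparseable/missing peak_area value")
  if (any(peaks$peak_area < 0)) stop("peak_area must be >= 0")
  key <- paste(peaks$sample_id, peaks$metabolite_id, peaks$mode, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample_id, metabolite_id, mode) record(s): ",
         fmt_tokens(sub("\r", "/", key[duplicated(key)])))
  peaks
}

#' Validate a calibration standard table
#'
#' One entry per (metabolite, ionization mode): the known concentration of the
#' standard mixture and its peak area relative to the internal standard.
#'
#' @param standards Data frame with columns `metabolite_id`, `mode`,
#'   `standard_concentration`, `standard_relative_area`.
#' @export
validate_standards <- function(standards) {
  need <- c("metabolite_id", "mode", "standard_concentration",
            "standard_relative_area")
  missing_cols <- setdiff(need, names(standards))
  if (length(missing_cols))
    stop("calibration table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  check_enum(standards$mode, MODE_LEVELS, "mode")
  key <- paste(standards$metabolite_id, standards$mode, sep = "/")
  if (anyDuplicated(key))
    stop("duplicated calibration entry: ", fmt_tokens(key[duplicated(key)]))
  if (any(standards$standard_concentration <= 0))
    stop("standard_concentration must be > 0")
  if (any(standards$standard_relative_area <= 0))
    stop("standard_relative_area must be > 0")
  standards
}
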