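read_cohort_inputs <- function(x) {
  if (is.list(x) && !is.null(x$peaks) && is.data.frame(x$peaks)) return(x)
  if (is.list(x) && is.character(x$peaks))
    return(list(peaks = read_peak_table(x$peaks),
                samples = read_sample_metadata(x$samples),
                standards = read_calibration(x$standards)))
  stop("cohort input must be a list(peaks, samples, standards) of data ",
       "frames or of file paths")
}

#' Run the full discrimination pipeline
#'
#' Orchestrates quantification, S/N and missingness retention, cohort
#' intersection, half-minimum imputation, Mann-Whitney screening, SVM-RFE
#' ranking, pathway-guided ratio-index construction, logistic model fitting
#' on the training cohort, ROC on both cohorts, repeated cross-validation
#' and bootstrap resampling, and the report bundle. Any stage failure aborts
#' with the stage name; everything already computed is persisted when
#' `out_dir` is given. Idempotent given the configuration seed.
#'
#' @param training `list(peaks, samples, standards)` — data frames or file
#'   paths.
#' @param validation Like `training`, or `NULL` for a CV-only run (the
#'   bootstrap then evaluates on the training set only).
#' @param config A [pipeline_config()].
#' @param pathway_graph Directed pathway graph (default: bundled map).
#' @param indexes Optional data frame with `numerator`/`denominator` columns
#'   to skip feature selection and fit exactly these ratio indexes.
#' @param out_dir Output directory for the report bundle and stage TSVs;
#'   `NULL` for in-memory results only.
#' @return A list: `manifest`, `report`, `model`, `roc_train`, `roc_valid`,
#'   `cv`, `bootstrap`, `screening`, `ranking`, `indexes`, `qc`,
#'   `features_train`, `features_valid`.
#' @export
run_pipeline <- function(training, validation = NULL,
                         config = pipeline_config(),
                         pathway_graph = default_pathway_graph(),
                         indexes = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  outputs <- character(0)
  stage <- local({
    last <- t0
    function(name, expr) {
      res <- tryCatch(force(expr),
                      error = function(e) stop("stage '", name, "': ",
                                               conditionMessage(e),
                                               call. = FALSE))
      now <- proc.time()[["elapsed"]]
      timings[[name]] <<- now - last
      last <<- now
      res
    }
  })
  persist <- function(obj, file) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(out_dir, file)
    if (inherits(obj, "metabolite_matrix")) write_matrix(obj, path)
    else write_tsv(obj, path)
    outputs <<- c(outputs, path)
  }

  tr_in <- stage("read_training", read_cohort_inputs(training))
  va_in <- if (!is.null(validation))
    stage("read_validation", read_cohort_inputs(validation))
  has_valid <- !is.null(va_in)

  prep_cohort <- function(inp, tag) {
    quantified <- stage(paste0("quantify_", tag),
                        quantify(inp$peaks, inp$standards, inp$samples))
    snr <- stage(paste0("filter_snr_", tag),
                 filter_snr(quantified, inp$peaks, config$snr_threshold))
    msn <- stage(paste0("filter_missingness_", tag),
                 filter_missingness(snr$matrix, inp$samples,
                                    config$max_missing_fraction))
    list(inp = inp, quantified = quantified, snr = snr, missing = msn)
  }
  tr <- prep_cohort(tr_in, "train")
  va <- if (has_valid) prep_cohort(va_in, "valid")

  shared <- if (has_valid)
    stage("intersect_cohorts",
          intersect_cohorts(metabolite_ids(tr$missing$matrix),
                            metabolite_ids(va$missing$matrix)))
  else metabolite_ids(tr$missing$matrix)
  qc_train <- combine_qc(tr$snr$report, tr$missing$report, shared)
  persist(qc_train, "qc_train.tsv")
  if (has_valid)
    persist(combine_qc(va$snr$report, va$missing$report, shared),
            "qc_valid.tsv")

  imp_train <- stage("impute_train",
                     impute_half_min(subset_matrix(tr$missing$matrix,
                                                   metabolites = shared)))
  imp_valid <- if (has_valid)
    stage("impute_valid",
          impute_half_min(subset_matrix(va$missing$matrix,
                                        metabolites = shared)))
  persist(imp_train, "matrix_train.tsv")
  if (has_valid) persist(imp_valid, "matrix_valid.tsv")

  screening <- stage("mannwhitney",
                     mannwhitney_all(imp_train, tr$inp$samples))
  persist(screening, "screening.tsv")

  ranking <- stage("svm_fs",
                   rank_svm_fs(imp_train, tr$inp$samples,
                               seed = stage_seed(config, "svm"),
                               cost = config$svm_cost))
  persist(data.frame(rank = seq_along(ranking$metabolite_ids),
                     metabolite_id = ranking$metabolite_ids,
                     score = unname(ranking$score)),
          "ranking.tsv")

  if (is.null(indexes)) {
    candidates <- stage("ratio_indexes",
                        enumerate_ratio_indexes(ranking, pathway_graph,
                                                config$top_k_features,
                                                config$max_path_length))
    if (nrow(candidates) == 0)
      stop("stage 'ratio_indexes': no pathway-connected pair among the top ",
           config$top_k_features, " metabolites", call. = FALSE)
    indexes <- select_ratio_indexes(candidates, config$n_indexes)
  } else {
    candidates <- indexes
  }
  persist(indexes[, intersect(c("numerator", "denominator", "path_length",
                                "pathway"), names(indexes))],
          "indexes.tsv")

  features_train <- stage("features_train",
                          compute_ratio_features(imp_train, indexes))
  features_valid <- if (has_valid)
    stage("features_valid", compute_ratio_features(imp_valid, indexes))

  model <- stage("fit_mlr",
                 fit_mlr(features_train, tr$inp$samples,
                         ci_method = config$mlr_ci_method,
                         ridge = config$ridge,
                         ridge_lambda = config$ridge_lambda))

  grp_of <- function(feat, smp)
    smp$group[match(sample_ids(feat), smp$sample_id)]
  roc_train <- stage("roc_train",
                     roc_with_ci(predict_proba(model, features_train),
                                 grp_of(features_train, tr$inp$samples),
                                 method = config$auc_ci_method))
  roc_valid <- if (has_valid)
    stage("roc_valid",
          roc_with_ci(predict_proba(model, features_valid),
                      grp_of(features_valid, va$inp$samples),
                      method = config$auc_ci_method))

  cv <- stage("repeated_cv",
              repeated_cv(features_train, tr$inp$samples,
                          folds = config$cv_folds, trials = config$cv_trials,
                          seed = stage_seed(config, "cv"),
                          ridge = TRUE, ridge_lambda = config$ridge_lambda))
  bs <- stage("bootstrap",
              bootstrap_validate(features_train, tr$inp$samples,
                                 features_valid,
                                 if (has_valid) va$inp$samples,
                                 trials = config$bootstrap_trials,
                                 seed = stage_seed(config, "bootstrap"),
                                 ridge = TRUE,
                                 ridge_lambda = config$ridge_lambda))

  report <- stage("report",
                  build_report(model, roc_train, roc_valid, cv, bs, config,
                               out_dir = out_dir))
  if (!is.null(out_dir))
    outputs <- c(outputs, file.path(out_dir, "report.json"))

  input_paths <- unlist(lapply(list(training, validation), function(x)
    if (is.list(x) && is.character(x$peaks)) unlist(x)), use.names = FALSE)
  manifest <- list(
    config = unclass(config),
    root_seed = config$rng_seed,
    stage_seconds = as.list(timings),
    total_seconds = proc.time()[["elapsed"]] - t0,
    version = as.character(packageVersion("ratiodx")),
    input_digests = if (length(input_paths))
      as.list(tools::md5sum(input_paths)),
    output_files = outputs,
    output_digests = if (length(outputs)) as.list(tools::md5sum(outputs)))
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(manifest = manifest, report = report, model = model,
       roc_train = roc_train, roc_valid = roc_valid, cv = cv, bootstrap = bs,
       screening = screening, ranking = ranking, indexes = indexes,
       candidates = candidates, qc = qc_train,
       features_train = features_train, features_valid = features_valid)
}
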