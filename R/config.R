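#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one validated object. Defaults
#' follow the study protocol where it states a value (S/N threshold 10,
#' 10-fold cross-validation repeated 200 times, 200 bootstrap trials) and
#' conservative common practice elsewhere (missingness cap 0.2 per group,
#' top five SVM-ranked metabolites, ratio paths of at most 4 pathway edges).
#'
#' @param snr_threshold Minimum per-metabolite median signal-to-noise ratio
#'   (inclusive) for retention.
#' @param max_missing_fraction Maximum fraction of missing cells tolerated
#'   within each group (case and control separately).
#' @param top_k_features Number of top SVM-ranked metabolites searched for
#'   pathway-consistent ratio pairs.
#' @param max_path_length Maximum directed pathway distance (edges) between
#'   the numerator and denominator of a ratio index.
#' @param n_indexes Number of ratio indexes kept for the regression model.
#' @param cv_folds,cv_trials Stratified k-fold cross-validation geometry.
#' @param bootstrap_trials Number of with-replacement resampling refits.
#' @param rng_seed Root seed; stage seeds are derived by fixed offsets
#'   (+100 feature ranking, +200 cross-validation, +300 bootstrap).
#' @param auc_ci_method `"hanley_mcneil"` (closed form, default) or `"delong"`.
#' @param mlr_ci_method `"wald"` (default) or `"profile"`.
#' @param svm_cost Soft-margin cost of the linear SVM used for feature
#'   elimination.
#' @param ridge Logical; enable ridge stabilisation (lambda `ridge_lambda`)
#'   of logistic fits that would otherwise fail on perfect separation.
#' @param ridge_lambda Penalty used when `ridge = TRUE`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(snr_threshold = 10,
                            max_missing_fraction = 0.2,
                            top_k_features = 5,
                            max_path_length = 4,
                            n_indexes = 2,
                            cv_folds = 10,
                            cv_trials = 200,
                            bootstrap_trials = 200,
                            rng_seed = 1L,
                            auc_ci_method = c("hanley_mcneil", "delong"),
                            mlr_ci_method = c("wald", "profile"),
                            svm_cost = 1,
                            ridge = FALSE,
                            ridge_lambda = 1e-6) {
  cfg <- list(
    snr_threshold = snr_threshold,
    max_missing_fraction = max_missing_fraction,
    top_k_features = as.integer(top_k_features),
    max_path_length = as.integer(max_path_length),
    n_indexes = as.integer(n_indexes),
    cv_folds = as.integer(cv_folds),
    cv_trials = as.integer(cv_trials),
    bootstrap_trials = as.integer(bootstrap_trials),
    rng_seed = as.integer(rng_seed),
    auc_ci_method = match.arg(auc_ci_method),
    mlr_ci_method = match.arg(mlr_ci_method),
    svm_cost = svm_cost,
    ridge = isTRUE(ridge),
    ridge_lambda = ridge_lambda
  )
  if (cfg$snr_threshold <= 0) stop("snr_threshold must be > 0")
  if (cfg$max_missing_fraction < 0 || cfg$max_missing_fraction > 1)
    stop("max_missing_fraction must be in [0, 1]")
  counts <- c("top_k_features", "max_path_length", "n_indexes", "cv_folds",
              "cv_trials", "bootstrap_trials")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1) stop(nm, " must be a count >= 1")
  if (cfg$cv_folds < 2) stop("cv_folds must be >= 2")
  if (is.na(cfg$rng_seed)) stop("rng_seed is mandatory")
  if (cfg$svm_cost <= 0) stop("svm_cost must be > 0")
  if (cfg$ridge_lambda <= 0) stop("ridge_lambda must be > 0")
  class(cfg) <- "pipeline_config"
  cfg
}

# Fixed per-stage seed offsets so one root seed reproduces the whole run.
stage_seed <- function(cfg, stage = c("svm", "cv", "bootstrap")) {
  offset <- c(svm = 100L, cv = 200L, bootstrap = 300L)[[match.arg(stage)]]
  (cfg$rng_seed + offset) %% .Machine$integer.max
}

#' Read or write a pipeline configuration as YAML
#'
#' CLI-free counterpart of a config file: field names match the arguments of
#' [pipeline_config()]; unknown fields are rejected.
#'
#' @param path File path.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown configuration field(s): ", fmt_tokens(bad))
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
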