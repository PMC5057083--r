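#' Assemble the discrimination report bundle
#'
#' Collects the fitted model (parameter/odds-ratio table), ROC results for
#' the training and (optionally) validation sets, the repeated-CV and
#' bootstrap summaries, the configuration echo and the software version into
#' one report object; optionally writes it as `report.json` plus TSVs
#' (`parameters.tsv`, `roc_points_{train,valid}.tsv`, `cv_auc.tsv`,
#' `bootstrap_auc.tsv`).
#'
#' @param model A `logistic_model`.
#' @param roc_train,roc_valid `roc_result`s (`roc_valid` may be `NULL`).
#' @param cv_summary A `validation_summary` or `NULL`.
#' @param bootstrap_summaries Output of [bootstrap_validate()] or `NULL`.
#' @param config A `pipeline_config`.
#' @param out_dir Directory to write the bundle to; `NULL` keeps it in
#'   memory only.
#' @return The report list, invisibly when written.
#' @export
build_report <- function(model, roc_train, roc_valid = NULL,
                         cv_summary = NULL, bootstrap_summaries = NULL,
                         config, out_dir = NULL) {
  stopifnot(inherits(model, "logistic_model"),
            inherits(roc_train, "roc_result"),
            inherits(config, "pipeline_config"))
  roc_block <- function(r) if (is.null(r)) NULL else
    list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
         ci_method = r$ci_method, p_value = r$p_value,
         n_case = r$n_case, n_control = r$n_control)
  vs_block <- function(v) if (is.null(v)) NULL else
    list(scheme = v$scheme, n_trials = v$n_trials,
         median_auc = v$median_auc, ci_low = v$ci_low, ci_high = v$ci_high,
         seed = v$seed, per_trial_auc = v$per_trial_auc)
  report <- list(
    software = list(package = "ratiodx",
                    version = as.character(packageVersion("ratiodx"))),
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    seed = config$rng_seed,
    model = list(outcome_coding = model$outcome_coding,
                 method = model$method,
                 n = model$n,
                 parameters = odds_ratio_table(model)),
    roc = list(training = roc_block(roc_train),
               validation = roc_block(roc_valid)),
    cross_validation = vs_block(cv_summary),
    bootstrap = if (!is.null(bootstrap_summaries))
      list(training = vs_block(bootstrap_summaries$training),
           validation = vs_block(bootstrap_summaries$validation)))
  check_report_structure(report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    write_tsv(report$model$parameters, file.path(out_dir, "parameters.tsv"))
    write_tsv(roc_train$curve_points, file.path(out_dir, "roc_points_train.tsv"))
    if (!is.null(roc_valid))
      write_tsv(roc_valid$curve_points, file.path(out_dir, "roc_points_valid.tsv"))
    if (!is.null(cv_summary))
      write_tsv(data.frame(trial = seq_along(cv_summary$per_trial_auc),
                           auc = cv_summary$per_trial_auc),
                file.path(out_dir, "cv_auc.tsv"))
    if (!is.null(bootstrap_summaries)) {
      bs <- data.frame(trial = seq_along(bootstrap_summaries$training$per_trial_auc),
                       auc_training = bootstrap_summaries$training$per_trial_auc)
      if (!is.null(bootstrap_summaries$validation))
        bs$auc_validation <- bootstrap_summaries$validation$per_trial_auc
      write_tsv(bs, file.path(out_dir, "bootstrap_auc.tsv"))
    }
    return(invisible(report))
  }
  report
}

#' Structural validation of a report
#'
#' Checks the presence and types of every mandatory block (the machine
#' contract shipped as `extdata/report_schema.json`).
#'
#' @param report A report list from [build_report()].
#' @export
check_report_structure <- function(report) {
  need <- c("software", "generated_at", "config", "seed", "model", "roc")
  absent <- setdiff(need, names(report))
  if (length(absent))
    stop("report lacks block(s): ", paste(absent, collapse = ", "))
  if (!is.data.frame(report$model$parameters))
    stop("report model parameters must be a table")
  if (is.null(report$roc$training$auc))
    stop("report lacks training ROC block")
  with_num <- c("auc", "ci_low", "ci_high", "p_value")
  for (nm in with_num)
    if (!is.numeric(report$roc$training[[nm]]))
      stop("training ROC field not numeric: ", nm)
  invisible(TRUE)
}
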