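validation_summary <- function(scheme, aucs, seed, extra = list()) {
  structure(c(list(scheme = scheme, n_trials = length(aucs),
                   per_trial_auc = aucs,
                   median_auc = median(aucs),
                   ci_low = unname(quantile(aucs, 0.025)),
                   ci_high = unname(quantile(aucs, 0.975)),
                   seed = as.integer(seed)), extra),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("<validation_summary> %s: %d trials, median AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$scheme, x$n_trials, x$median_auc, x$ci_low, x$ci_high))
  invisible(x)
}

# Stratified fold labels: within each class, shuffle a balanced 1..k vector.
stratified_folds <- function(grp, k) {
  fold <- integer(length(grp))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the ratio-index model
#'
#' Per trial: samples are assigned to k stratified folds; the model is
#' refitted on each 9/10 and scores the held-out 1/10; all out-of-fold
#' scores of the trial are pooled into a single AUC. The summary is the
#' median and 2.5/97.5 percentiles over per-trial AUCs. Fully deterministic
#' given the seed. Refits are ridge-stabilised by default because a small
#' training fold can transiently separate.
#'
#' @param features Complete `metabolite_matrix` of model features.
#' @param samples Sample metadata.
#' @param folds Folds per trial (>= 2; each class must have >= `folds`
#'   samples).
#' @param trials Number of independent repetitions.
#' @param seed Integer seed.
#' @param outcome_coding Passed to [fit_mlr()].
#' @param ridge,ridge_lambda Stabilisation of refits (default on).
#' @return A `validation_summary` (scheme `"repeated_cv"`).
#' @export
repeated_cv <- function(features, samples, folds = 10, trials = 200,
                        seed = 1L, outcome_coding = "case",
                        ridge = TRUE, ridge_lambda = 1e-6) {
  stopifnot(inherits(features, "metabolite_matrix"))
  samples <- validate_samples(samples)
  grp <- samples$group[match(sample_ids(features), samples$sample_id)]
  if (any(is.na(grp))) stop("feature sample(s) absent from metadata")
  if (folds < 2) stop("folds must be >= 2")
  if (trials < 1) stop("trials must be >= 1")
  if (min(table(grp)) < folds)
    stop("each class needs at least `folds` samples")
  set.seed(seed)
  n <- nrow(features$values)
  aucs <- vapply(seq_len(trials), function(tr) {
    fold <- NULL
    for (attempt in seq_len(10)) {
      cand <- stratified_folds(grp, folds)
      ok <- all(vapply(seq_len(folds), function(f)
        length(unique(grp[cand != f])) == 2, logical(1)))
      if (ok) { fold <- cand; break }
      message("refolding trial ", tr, " (class absent from a training fold)")
    }
    if (is.null(fold)) stop("could not stratify folds after 10 attempts")
    scores <- numeric(n)
    for (f in seq_len(folds)) {
      hold <- fold == f
      m <- fit_mlr(subset_matrix(features, samples = sample_ids(features)[!hold]),
                   samples, outcome_coding = outcome_coding,
                   ridge = ridge, ridge_lambda = ridge_lambda)
      scores[hold] <- predict_proba(
        m, subset_matrix(features, samples = sample_ids(features)[hold]))
    }
    auc_mw(scores, grp, positive = outcome_coding)
  }, numeric(1))
  validation_summary("repeated_cv", aucs, seed,
                     extra = list(folds = as.integer(folds)))
}

#' Bootstrap resampling validation
#'
#' Per trial: the training individuals are resampled with replacement
#' (stratified by class, preserving the class sizes), the model is refitted
#' on the resample, and the refit scores (a) the original full training set
#' and (b) the untouched independent validation set. Validation samples
#' never enter any resample. Returns one `validation_summary` per evaluation
#' set; the training summary records the resampled ids of every trial.
#'
#' @param train_features,train_samples Training features and metadata.
#' @param valid_features,valid_samples Optional independent validation set.
#' @param trials Number of resampling refits.
#' @param seed Integer seed.
#' @inheritParams repeated_cv
#' @return `list(training =, validation = or NULL)`.
#' @export
bootstrap_validate <- function(train_features, train_samples,
                               valid_features = NULL, valid_samples = NULL,
                               trials = 200, seed = 1L,
                               outcome_coding = "case",
                               ridge = TRUE, ridge_lambda = 1e-6) {
  stopifnot(inherits(train_features, "metabolite_matrix"))
  train_samples <- validate_samples(train_samples)
  ids <- sample_ids(train_features)
  grp <- train_samples$group[match(ids, train_samples$sample_id)]
  if (any(is.na(grp))) stop("feature sample(s) absent from metadata")
  if (trials < 1) stop("trials must be >= 1")
  has_valid <- !is.null(valid_features)
  if (has_valid) {
    valid_samples <- validate_samples(valid_samples)
    vgrp <- valid_samples$group[match(sample_ids(valid_features),
                                      valid_samples$sample_id)]
    if (any(is.na(vgrp))) stop("validation sample(s) absent from metadata")
  }
  set.seed(seed)
  auc_tr <- numeric(trials)
  auc_va <- if (has_valid) numeric(trials) else NULL
  resampled <- vector("list", trials)
  for (tr in seq_len(trials)) {
    boot_ids <- NULL
    for (attempt in seq_len(10)) {
      cand <- unlist(lapply(unique(grp), function(g) {
        pool <- ids[grp == g]
        sample(pool, length(pool), replace = TRUE)
      }), use.names = FALSE)
      if (length(unique(grp[match(cand, ids)])) == 2) { boot_ids <- cand; break }
      message("redrawing degenerate resample in trial ", tr)
    }
    if (is.null(boot_ids)) stop("could not draw a two-class resample")
    resampled[[tr]] <- boot_ids
    boot_vals <- train_features$values[boot_ids, , drop = FALSE]
    rownames(boot_vals) <- sprintf("b%04d", seq_along(boot_ids))
    boot_samples <- train_samples[match(boot_ids, train_samples$sample_id), ]
    boot_samples$sample_id <- rownames(boot_vals)
    m <- fit_mlr(metabolite_matrix(boot_vals, provenance = "features"),
                 boot_samples, outcome_coding = outcome_coding,
                 ridge = ridge, ridge_lambda = ridge_lambda)
    auc_tr[tr] <- auc_mw(predict_proba(m, train_features), grp,
                         positive = outcome_coding)
    if (has_valid)
      auc_va[tr] <- auc_mw(predict_proba(m, valid_features), vgrp,
                           positive = outcome_coding)
  }
  list(training = validation_summary("bootstrap", auc_tr, seed,
                                     extra = list(evaluated_on = "training",
                                                  resampled_ids = resampled)),
       validation = if (has_valid)
         validation_summary("bootstrap", auc_va, seed,
                            extra = list(evaluated_on = "validation")))
}
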