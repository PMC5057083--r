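#' Fit the multiple logistic regression discrimination model
#'
#' Maximum-likelihood fit by iteratively reweighted least squares (via
#' [stats::glm()]), outcome coded 1 for the chosen class (case by default).
#' Wald confidence intervals by default; profile likelihood optionally.
#' Perfect separation aborts with advice to enable the ridge-stabilised
#' fallback (`ridge = TRUE`, penalty `ridge_lambda` on the non-intercept
#' coefficients), which is numerically indistinguishable from the MLE
#' whenever the MLE exists.
#'
#' @param features A `metabolite_matrix` of model features (complete).
#' @param samples Sample metadata for the feature rows.
#' @param outcome_coding `"case"` or `"control"`: which group is coded 1.
#' @param ci_method `"wald"` (beta +/- 1.96 SE) or `"profile"`.
#' @param ridge Enable the penalised fallback on separation.
#' @param ridge_lambda Ridge penalty (default 1e-6).
#' @param level Confidence level (default 0.95).
#' @return A `logistic_model` with coefficients, intercept, standard errors,
#'   covariance, odds ratios and per-parameter CIs on the log-odds scale.
#' @export
fit_mlr <- function(features, samples,
                    outcome_coding = c("case", "control"),
                    ci_method = c("wald", "profile"),
                    ridge = FALSE, ridge_lambda = 1e-6, level = 0.95) {
  outcome_coding <- match.arg(outcome_coding)
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(features, "metabolite_matrix"))
  if (any(features$missing)) stop("features must be complete")
  samples <- validate_samples(samples)
  grp <- samples$group[match(sample_ids(features), samples$sample_id)]
  if (any(is.na(grp))) stop("feature sample(s) absent from metadata")
  y <- as.integer(grp == outcome_coding)
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- features$values
  p <- ncol(X)
  if (nrow(X) <= p + 1) stop("need n > number of parameters + 1")

  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ X, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged && !ridge)
    stop("IRLS did not converge in ", fit$iter,
         " iterations (deviance ", format(fit$deviance), ")")
  if (separated || !fit$converged) {
    if (!ridge)
      stop("(quasi-)perfect separation detected; enable the penalized ",
           "fallback with ridge = TRUE (lambda = ", ridge_lambda, ")")
    r <- irls_ridge(X, y, lambda = ridge_lambda)
    beta <- r$beta; cov <- r$cov
    converged <- r$converged; method <- "irls_ridge"
  } else {
    beta <- coef(fit); cov <- vcov(fit)
    names(beta)[1] <- "(Intercept)"
    converged <- TRUE; method <- "irls_mle"
  }
  term_names <- c("(Intercept)", colnames(X))
  names(beta) <- term_names
  dimnames(cov) <- list(term_names, term_names)
  se <- sqrt(diag(cov))
  z <- qnorm(1 - (1 - level) / 2)
  if (ci_method == "profile" && method == "irls_mle") {
    ci <- suppressMessages(suppressWarnings(confint(fit, level = level)))
    rownames(ci) <- term_names
    ci_low <- ci[, 1]; ci_high <- ci[, 2]
  } else {
    ci_low <- beta - z * se
    ci_high <- beta + z * se
  }
  p_values <- 2 * pnorm(-abs(beta / se))
  structure(list(
    feature_ids = colnames(X),
    intercept = beta[["(Intercept)"]],
    coefficients = beta[-1],
    all_coefficients = beta,
    standard_errors = se,
    covariance = cov,
    odds_ratios = exp(beta[-1]),
    ci_low = ci_low, ci_high = ci_high,
    p_values = p_values,
    outcome_coding = outcome_coding,
    ci_method = ci_method, level = level,
    converged = converged, method = method,
    n = nrow(X)), class = "logistic_model")
}

# Ridge-penalised IRLS (intercept unpenalised). Converges when the largest
# absolute penalised score drops below 1e-8, capped at 100 iterations.
irls_ridge <- function(X, y, lambda, tol = 1e-8, maxit = 100) {
  Xd <- cbind("(Intercept)" = 1, X)
  k <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, k - 1)), k)
  beta <- numeric(k)
  trace <- numeric(maxit)
  converged <- FALSE
  H <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    score <- drop(crossprod(Xd, y - mu)) - drop(pen %*% beta)
    trace[it] <- max(abs(score))
    H <- crossprod(Xd * w, Xd) + pen
    if (trace[it] < tol) { converged <- TRUE; break }
    beta <- beta + drop(solve(H, score))
  }
  if (!converged)
    stop("penalized IRLS did not converge; max|score| trace: ",
         paste(format(trace[seq_len(it)], digits = 3), collapse = " "))
  list(beta = setNames(beta, colnames(Xd)), cov = solve(H),
       converged = TRUE, iters = it)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> %s, outcome %s=1, n=%d\n",
              x$method, x$outcome_coding, x$n))
  print(odds_ratio_table(x), digits = 4)
  invisible(x)
}

#' Parameter and odds-ratio table of a fitted model
#'
#' One row per parameter: coefficient (log-odds), its CI, the odds ratio
#' `exp(beta)` with exponentiated CI bounds, and the Wald p-value. The
#' intercept row carries no odds ratio.
#'
#' @param model A `logistic_model`.
#' @export
odds_ratio_table <- function(model) {
  stopifnot(inherits(model, "logistic_model"))
  terms <- names(model$all_coefficients)
  is_int <- terms == "(Intercept)"
  data.frame(
    term = terms,
    estimate = unname(model$all_coefficients),
    ci_low = unname(model$ci_low),
    ci_high = unname(model$ci_high),
    odds_ratio = ifelse(is_int, NA_real_, exp(unname(model$all_coefficients))),
    or_ci_low = ifelse(is_int, NA_real_, exp(unname(model$ci_low))),
    or_ci_high = ifelse(is_int, NA_real_, exp(unname(model$ci_high))),
    p_value = unname(model$p_values),
    stringsAsFactors = FALSE)
}

#' Predicted class probability
#'
#' `plogis(intercept + sum(beta * x))` per sample, strictly inside (0, 1).
#'
#' @param model A `logistic_model`.
#' @param features A `metabolite_matrix` carrying every model feature.
#' @return Named numeric vector of probabilities.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "logistic_model"),
            inherits(features, "metabolite_matrix"))
  absent <- setdiff(model$feature_ids, metabolite_ids(features))
  if (length(absent))
    stop("feature column(s) missing: ", fmt_tokens(absent))
  X <- features$values[, model$feature_ids, drop = FALSE]
  eta <- model$intercept + drop(X %*% model$coefficients)
  setNames(plogis(eta), sample_ids(features))
}

#' AUC by the concordant-pair (Mann-Whitney) rule
#'
#' Identical to the trapezoidal area under the empirical ROC curve; ties get
#' half credit on both sides via midranks.
#'
#' @param scores Numeric score vector (higher = more case-like).
#' @param labels Group labels (`"case"`/`"control"` or a 2-level factor).
#' @param positive Label counted as positive.
#' @export
auc_mw <- function(scores, labels, positive = "case") {
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stop("both classes must be present")
  u <- sum(rank(scores)[pos]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Closed-form Hanley-McNeil standard error of an AUC
#'
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`;
#' `SE^2 = (A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)) / (n1 n2)`.
#'
#' @param auc Observed AUC.
#' @param n_case,n_control Group sizes.
#' @export
hanley_mcneil_se <- function(auc, n_case, n_control) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_case - 1) * (q1 - auc^2) +
          (n_control - 1) * (q2 - auc^2)) / (n_case * n_control))
}

delong_se <- function(scores, labels, positive = "case") {
  x <- scores[labels == positive]
  y <- scores[labels != positive]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yi) mean((x > yi) + 0.5 * (x == yi)), numeric(1))
  sqrt(stats::var(v10) / length(x) + stats::var(v01) / length(y))
}

#' ROC curve, AUC, confidence interval and null p-value
#'
#' AUC by the concordant-pair rule (equal to the trapezoidal area). The CI
#' is closed-form Hanley-McNeil by default or DeLong; both truncated to
#' `[0, 1]`. The two-sided p-value against AUC = 0.5 comes from the
#' Mann-Whitney normal approximation on the scores.
#'
#' @inheritParams auc_mw
#' @param method `"hanley_mcneil"` or `"delong"`.
#' @param level Confidence level.
#' @return A `roc_result`: `auc`, `ci_low`, `ci_high`, `ci_method`,
#'   `p_value`, `curve_points` (FPR/TPR data frame from (0,0) to (1,1)),
#'   `n_case`, `n_control`.
#' @export
roc_with_ci <- function(scores, labels, method = c("hanley_mcneil", "delong"),
                        positive = "case", level = 0.95) {
  method <- match.arg(method)
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stop("both classes must be present")
  a <- auc_mw(scores, labels, positive)
  se <- if (method == "hanley_mcneil") hanley_mcneil_se(a, n1, n2)
        else delong_se(scores, labels, positive)
  z <- qnorm(1 - (1 - level) / 2)
  p <- suppressWarnings(
    wilcox.test(scores[pos], scores[!pos], exact = FALSE,
                correct = TRUE)$p.value)
  if (is.na(p)) p <- 1
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)))
  structure(list(auc = a,
                 ci_low = max(0, a - z * se),
                 ci_high = min(1, a + z * se),
                 ci_method = method, se = se, p_value = p,
                 curve_points = curve, n_case = n1, n_control = n2,
                 level = level),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d%% CI %.3f-%.3f, %s), p = %.3g\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high,
              x$ci_method, x$p_value))
  invisible(x)
}
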