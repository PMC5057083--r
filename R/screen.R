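#' Mann-Whitney comparison of every metabolite between groups
#'
#' Two-sided test per metabolite. The exact null distribution is used for
#' small tie-free comparisons (total n of 12 or fewer); otherwise the normal
#' approximation with tie and continuity correction. The reported U counts
#' case-over-control concordant pairs (half credit for ties), so
#' `U / (n_case * n_control)` is the AUC of that metabolite as a score.
#'
#' @param matrix Imputed (complete) `metabolite_matrix`.
#' @param samples Sample metadata for the matrix rows.
#' @return Data frame with `metabolite_id`, `u_statistic`, `p_value`,
#'   `direction` (`up_in_case`/`down_in_case`/`none`), `significance_band`.
#' @export
mannwhitney_all <- function(matrix, samples) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  if (any(matrix$missing))
    stop("matrix contains missing cells; impute before testing")
  samples <- validate_samples(samples)
  grp <- samples$group[match(sample_ids(matrix), samples$sample_id)]
  if (any(is.na(grp))) stop("matrix sample(s) absent from metadata")
  n_case <- sum(grp == "case"); n_ctrl <- sum(grp == "control")
  if (n_case < 2 || n_ctrl < 2)
    stop("each group needs at least 2 samples (case=", n_case,
         ", control=", n_ctrl, ")")
  res <- lapply(metabolite_ids(matrix), function(m) {
    x <- matrix$values[grp == "case", m]
    y <- matrix$values[grp == "control", m]
    mw <- mann_whitney(x, y)
    dir <- if (median(x) > median(y)) "up_in_case"
           else if (median(x) < median(y)) "down_in_case" else "none"
    data.frame(metabolite_id = m, u_statistic = mw$u, p_value = mw$p,
               direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significance_band <- significance_band(out$p_value)
  out
}

# Two-sided Mann-Whitney with the exact distribution for small tie-free
# samples and the corrected normal approximation otherwise. All-equal input
# degenerates to p = 1 (zero-variance null).
mann_whitney <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  u <- sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (length(unique(c(x, y))) == 1L)
    return(list(u = u, p = 1))
  exact <- (length(x) + length(y)) <= 12 && !ties
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  if (is.na(p)) p <- 1
  list(u = u, p = min(p, 1))
}

significance_band <- function(p) {
  cut(p, breaks = c(0, 0.001, 0.01, 0.05, 0.10, 1),
      labels = c("p<0.001", "p<0.01", "p<0.05", "p<0.10", "ns"),
      include.lowest = TRUE, right = FALSE) |> as.character()
}

#' Rank metabolites by linear SVM recursive feature elimination
#'
#' Features are z-scored (constant columns map to all-zeros with a warning),
#' then a linear soft-margin SVM is fitted repeatedly, each round discarding
#' the feature with the smallest absolute weight; the rank is the reverse of
#' the elimination order, so the last survivor ranks first. Deterministic
#' given the seed.
#'
#' @param matrix Imputed `metabolite_matrix` (2+ metabolites).
#' @param samples Sample metadata.
#' @param seed Integer seed (recorded in the result).
#' @param cost Soft-margin cost `C` of the SVM.
#' @return A `feature_ranking`: `metabolite_ids` (best first), `score`
#'   (absolute weight at elimination), `method`, `seed`.
#' @export
rank_svm_fs <- function(matrix, samples, seed = 1L, cost = 1) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  if (any(matrix$missing))
    stop("matrix contains missing cells; impute before ranking")
  if (ncol(matrix$values) < 2) stop("need at least 2 metabolites to rank")
  samples <- validate_samples(samples)
  grp <- samples$group[match(sample_ids(matrix), samples$sample_id)]
  if (any(is.na(grp))) stop("matrix sample(s) absent from metadata")
  y <- factor(grp, levels = GROUP_LEVELS)
  X <- zscore_columns(matrix$values)
  set.seed(seed)
  remaining <- colnames(X)
  eliminated <- character(0)
  elim_score <- numeric(0)
  while (length(remaining) > 1) {
    fit <- e1071::svm(x = X[, remaining, drop = FALSE], y = y,
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    names(w) <- remaining
    drop_id <- remaining[which.min(abs(w))]
    eliminated <- c(eliminated, drop_id)
    elim_score <- c(elim_score, abs(w[[drop_id]]))
    if (length(remaining) == 2) {
      last <- setdiff(remaining, drop_id)
      eliminated <- c(eliminated, last)
      elim_score <- c(elim_score, abs(w[[last]]))
    }
    remaining <- setdiff(remaining, drop_id)
  }
  ord <- rev(eliminated)
  structure(list(metabolite_ids = ord,
                 score = setNames(rev(elim_score), ord),
                 method = "linear_svm_rfe", seed = as.integer(seed)),
            class = "feature_ranking")
}

zscore_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  const <- sdv == 0 | is.na(sdv)
  if (any(const)) {
    warning("constant feature(s) mapped to zero: ",
            fmt_tokens(colnames(X)[const]))
    sdv[const] <- 1
    mu[const] <- X[1, const]
  }
  sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %s (seed %d)\n", x$method, x$seed))
  cat(paste(sprintf("%2d. %s (%.3g)", seq_along(x$metabolite_ids),
                    x$metabolite_ids, x$score), collapse = "\n"), "\n")
  invisible(x)
}

#' Enumerate pathway-consistent metabolite-ratio candidates
#'
#' For every ordered pair of distinct top-k metabolites with a directed
#' pathway path numerator -> denominator of at most `max_path_length` edges,
#' emits a ratio index (substrate over product). Candidates are sorted by
#' combined rank (sum of the two ranks, best first), then by path length,
#' then lexically, so the output is reproducible and independent of the
#' metabolite input order.
#'
#' @param ranking A `feature_ranking`.
#' @param graph Directed pathway [igraph::igraph] graph.
#' @param top_k Number of top-ranked metabolites considered.
#' @param max_path_length Maximum path length in edges.
#' @return Data frame with `numerator`, `denominator`, `path_length`,
#'   `pathway`, `combined_rank`, `label`; zero rows when no pair connects.
#' @export
enumerate_ratio_indexes <- function(ranking, graph, top_k = 5,
                                    max_path_length = 4) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (top_k > length(ranking$metabolite_ids))
    stop("top_k exceeds ranking length")
  top <- ranking$metabolite_ids[seq_len(top_k)]
  in_graph <- top[top %in% igraph::V(graph)$name]
  empty <- data.frame(numerator = character(0), denominator = character(0),
                      path_length = integer(0), pathway = character(0),
                      combined_rank = integer(0), label = character(0),
                      stringsAsFactors = FALSE)
  if (length(in_graph) < 2) return(empty)
  d <- igraph::distances(graph, v = in_graph, to = in_graph, mode = "out")
  rows <- list()
  for (u in in_graph) for (v in in_graph) {
    if (u == v) next
    len <- d[u, v]
    if (!is.finite(len) || len > max_path_length) next
    sp <- igraph::shortest_paths(graph, from = u, to = v, mode = "out",
                                 output = "epath")$epath[[1]]
    pw <- igraph::edge_attr(graph, "pathway", sp[1])
    if (is.null(pw) || is.na(pw)) pw <- ""
    rows[[length(rows) + 1L]] <- data.frame(
      numerator = u, denominator = v, path_length = as.integer(len),
      pathway = pw,
      combined_rank = match(u, ranking$metabolite_ids) +
        match(v, ranking$metabolite_ids),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$combined_rank, out$path_length, out$numerator,
                   out$denominator), , drop = FALSE]
  out$label <- paste(out$numerator, out$denominator, sep = "/")
  rownames(out) <- NULL
  out
}

#' Select the ratio indexes used by the model stage
#'
#' Takes the top `n` candidates in enumeration order, skipping a candidate
#' whose reciprocal (same unordered pair, swapped orientation) was already
#' kept — a ratio and its inverse are rank-equivalent features.
#'
#' @param candidates Output of [enumerate_ratio_indexes()].
#' @param n Number of indexes to keep.
#' @param dedupe_reciprocal Drop reversed duplicates (default `TRUE`).
#' @export
select_ratio_indexes <- function(candidates, n = 2, dedupe_reciprocal = TRUE) {
  if (nrow(candidates) == 0) return(candidates)
  keep <- integer(0)
  seen <- character(0)
  for (i in seq_len(nrow(candidates))) {
    pair <- paste(sort(c(candidates$numerator[i], candidates$denominator[i])),
                  collapse = "\r")
    if (dedupe_reciprocal && pair %in% seen) next
    keep <- c(keep, i)
    seen <- c(seen, pair)
    if (length(keep) >= n) break
  }
  candidates[keep, , drop = FALSE]
}

#' Compute ratio-index feature values
#'
#' One feature per index: numerator concentration over denominator
#' concentration, per sample. Because a per-sample global concentration
#' factor (e.g. diurnal variation) multiplies numerator and denominator
#' alike, it cancels exactly in every feature.
#'
#' @param matrix Imputed `metabolite_matrix` containing all index
#'   metabolites with strictly positive denominators.
#' @param indexes Data frame with `numerator`, `denominator` (and optionally
#'   `label`) columns.
#' @return A `metabolite_matrix` of features, provenance `"features"`; zero
#'   columns when `indexes` is empty.
#' @export
compute_ratio_features <- function(matrix, indexes) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  if (any(matrix$missing))
    stop("matrix contains missing cells; impute before computing ratios")
  labels <- if ("label" %in% names(indexes)) indexes$label else
    paste(indexes$numerator, indexes$denominator, sep = "/")
  vals <- matrix(NA_real_, nrow = nrow(matrix$values), ncol = nrow(indexes),
                 dimnames = list(sample_ids(matrix), labels))
  for (i in seq_len(nrow(indexes))) {
    num <- indexes$numerator[i]; den <- indexes$denominator[i]
    for (id in c(num, den))
      if (!id %in% metabolite_ids(matrix))
        stop("index metabolite absent from matrix: ", id)
    d <- matrix$values[, den]
    zero <- d == 0
    if (any(zero))
      stop(sprintf("zero denominator %s in sample(s) %s", den,
                   fmt_tokens(sample_ids(matrix)[zero])))
    vals[, i] <- matrix$values[, num] / d
  }
  metabolite_matrix(vals, provenance = "features")
}
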