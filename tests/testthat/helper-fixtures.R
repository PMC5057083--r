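# Shared fixture builders; everything is generated in code at test time.

make_samples <- function(n_case = 3, n_control = 3, cohort = "training",
                         prefix = "S") {
  data.frame(
    sample_id = sprintf("%s%02d", prefix, seq_len(n_case + n_control)),
    cohort = cohort,
    group = rep(c("case", "control"), c(n_case, n_control)),
    stringsAsFactors = FALSE)
}

make_matrix <- function(values, samples, provenance = "features") {
  rownames(values) <- samples$sample_id
  metabolite_matrix(values, provenance = provenance)
}

# One-feature matrix from per-group value vectors.
matrix_from_groups <- function(case, control, metabolite = "m1",
                               provenance = "features") {
  samples <- make_samples(length(case), length(control))
  vals <- matrix(c(case, control), ncol = 1,
                 dimnames = list(samples$sample_id, metabolite))
  list(matrix = metabolite_matrix(vals, provenance = provenance),
       samples = samples)
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Labelled logistic-regression data with known truth.
logistic_fixture <- function(n_per = 50, beta = c(1.5), intercept = 0,
                             seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  X <- matrix(rnorm(n * length(beta)), n,
              dimnames = list(sprintf("S%03d", 1:n),
                              paste0("f", seq_along(beta))))
  p <- plogis(intercept + drop(X %*% beta))
  y <- rbinom(n, 1, p)
  samples <- data.frame(sample_id = rownames(X), cohort = "training",
                        group = ifelse(y == 1, "case", "control"),
                        stringsAsFactors = FALSE)
  list(features = metabolite_matrix(X, provenance = "features"),
       samples = samples, beta = beta, intercept = intercept)
}

# Independent brute-force two-sided Mann-Whitney p: enumerate every
# assignment of the pooled values into the two groups and fold the exact U
# distribution into 2 * min(P(U <= u), P(U >= u)), capped at 1.
enumerate_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force AUC by explicit concordant-pair counting.
pairwise_auc <- function(case, control) {
  conc <- outer(case, control, ">") + 0.5 * outer(case, control, "==")
  mean(conc)
}
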