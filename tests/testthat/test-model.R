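test_that("a class-independent feature gets a near-zero coefficient", {
  fx <- logistic_fixture(n_per = 60, beta = 0, seed = 4)
  # force balanced-ish labels independent of the feature
  m <- fit_mlr(fx$features, fx$samples)
  expect_lt(abs(m$coefficients[1]),
            3 * m$standard_errors["f1"])
  expect_true(m$converged)
  expect_equal(m$method, "irls_mle")
})

test_that("odds ratios are exp(coefficients) and beta=0 maps to OR=1", {
  fx <- logistic_fixture(n_per = 40, beta = c(0.8, -0.5), seed = 9)
  m <- fit_mlr(fx$features, fx$samples)
  tab <- odds_ratio_table(m)
  expect_equal(tab$odds_ratio[-1], exp(tab$estimate[-1]))
  expect_equal(tab$or_ci_low[-1], exp(tab$ci_low[-1]))
  expect_true(is.na(tab$odds_ratio[tab$term == "(Intercept)"]))
  fake <- m
  fake$all_coefficients["f1"] <- 0
  expect_equal(odds_ratio_table(fake)$odds_ratio[2], 1)
})

test_that("predicted probabilities follow the logistic closed form", {
  fx <- logistic_fixture(n_per = 30, beta = c(-0.128, -0.705), seed = 2)
  m <- fit_mlr(fx$features, fx$samples)
  # identity model: probability one half everywhere
  m0 <- m
  m0$intercept <- 0
  m0$coefficients[] <- 0
  expect_equal(unname(predict_proba(m0, fx$features)),
               rep(0.5, nrow(fx$features$values)))
  # closed-form evaluation at the origin with the published-style parameters
  m1 <- m
  m1$intercept <- 4.41
  m1$coefficients[] <- c(-0.128, -0.705)
  origin <- metabolite_matrix(
    matrix(0, 1, 2, dimnames = list("S0", c("f1", "f2"))),
    provenance = "features")
  expect_equal(unname(predict_proba(m1, origin)), plogis(4.41))
  expect_equal(unname(predict_proba(m1, origin)), 0.9880, tolerance = 1e-4)
  # raising a negative-beta feature strictly lowers the probability
  up <- metabolite_matrix(
    matrix(c(0, 1), 2, 2, dimnames = list(c("a", "b"), c("f1", "f2"))),
    provenance = "features")
  pr <- predict_proba(m1, up)
  expect_lt(pr[["b"]], pr[["a"]])
})

test_that("perfect separation errors unless the ridge fallback is enabled", {
  samples <- make_samples(6, 6)
  vals <- matrix(c(rnorm(6, 5, 0.1), rnorm(6, -5, 0.1)), ncol = 1,
                 dimnames = list(samples$sample_id, "f1"))
  feats <- metabolite_matrix(vals, provenance = "features")
  expect_error(fit_mlr(feats, samples), "ridge")
  m <- fit_mlr(feats, samples, ridge = TRUE)
  expect_true(m$converged)
  expect_equal(m$method, "irls_ridge")
  expect_gt(m$coefficients[["f1"]], 0)
  # covariance symmetric positive semidefinite
  expect_equal(m$covariance, t(m$covariance))
  expect_true(all(eigen(m$covariance, only.values = TRUE)$values > -1e-10))
})

test_that("ridge at lambda 1e-6 matches the MLE when the MLE exists", {
  fx <- logistic_fixture(n_per = 80, beta = c(1), seed = 6)
  mle <- fit_mlr(fx$features, fx$samples)
  # route the same data through the penalised path
  r <- ratiodx:::irls_ridge(fx$features$values,
                            as.integer(fx$samples$group == "case"),
                            lambda = 1e-6)
  expect_equal(unname(r$beta), unname(mle$all_coefficients), tolerance = 1e-5)
})

test_that("AUC equals the Mann-Whitney identity and the pairwise count", {
  # the 2-vs-2 example: 3 of 4 pairs concordant
  expect_equal(auc_mw(c(0.4, 0.8, 0.2, 0.6),
                      c("case", "case", "control", "control")), 0.75)
  # perfectly separated scores
  expect_equal(auc_mw(c(5, 6, 1, 2), c("case", "case", "control", "control")),
               1.0)
  set.seed(31)
  for (rep in 1:25) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    sc <- round(c(rnorm(n1, 0.3), rnorm(n2)), sample(c(1, 8), 1))  # some ties
    lab <- rep(c("case", "control"), c(n1, n2))
    expect_equal(auc_mw(sc, lab), pairwise_auc(sc[1:n1], sc[-(1:n1)]))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  sc <- c(rnorm(30, 0.8), rnorm(25))
  lab <- rep(c("case", "control"), c(30, 25))
  expect_equal(auc_mw(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("control", "case"),
                                              direction = "<", quiet = TRUE))))
  ours <- roc_with_ci(sc, lab, method = "delong")
  ref <- pROC::ci.auc(pROC::roc(lab, sc, levels = c("control", "case"),
                                direction = "<", quiet = TRUE),
                      method = "delong")
  expect_equal(ours$ci_low, as.numeric(ref[1]), tolerance = 1e-8)
  expect_equal(ours$ci_high, as.numeric(ref[3]), tolerance = 1e-8)
})

test_that("ROC curves run monotonically from (0,0) to (1,1)", {
  set.seed(23)
  sc <- c(rnorm(15, 1), rnorm(12))
  lab <- rep(c("case", "control"), c(15, 12))
  r <- roc_with_ci(sc, lab)
  cp <- r$curve_points
  expect_equal(cp$fpr[1], 0); expect_equal(cp$tpr[1], 0)
  expect_equal(cp$fpr[nrow(cp)], 1); expect_equal(cp$tpr[nrow(cp)], 1)
  expect_true(all(diff(cp$fpr) >= 0))
  expect_true(all(diff(cp$tpr) >= 0))
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_error(roc_with_ci(sc[lab == "case"], lab[lab == "case"]),
               "both classes")
})
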