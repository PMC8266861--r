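# ROC/AUC, Youden thresholding, confusion metrics, SVM evaluation.

test_that("AUC equals the concordant-pair fraction (Mann-Whitney identity)", {
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  # perfect separation and all-tied scores
  expect_equal(roc_auc(c(5, 4, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(2, 6), rep(c(1, 0), 3))$auc, 0.5)

  set.seed(99)
  for (case in 1:200) {
    n <- sample(6:25, 1)
    labels <- c(1, 0, stats::rbinom(n - 2, 1, 0.4))
    scores <- round(stats::rnorm(n), sample(c(0, 1, 3), 1))  # induce ties
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_pair_oracle(scores, labels))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(7)
  scores <- stats::rnorm(40)
  labels <- stats::rbinom(40, 1, 0.4)
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<",
                                              quiet = TRUE))))
})

test_that("ROC points trace monotone (fpr, tpr) steps", {
  set.seed(3)
  r <- roc_auc(stats::rnorm(30), stats::rbinom(30, 1, 0.5))
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
  expect_equal(r$roc$tpr[1], 0)
  expect_equal(utils::tail(r$roc$tpr, 1), 1)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("Youden threshold maximizes J with ties broken toward specificity", {
  scores <- c(0.9, 0.4, 0.6, 0.1)
  labels <- c(1, 1, 0, 0)
  thr <- youden_threshold(scores, labels)
  expect_equal(attr(thr, "J"), 0.5)
  # two candidates reach J = 0.5; the higher-specificity one lies in (0.6, 0.9)
  expect_gt(as.numeric(thr), 0.6)
  expect_lt(as.numeric(thr), 0.9)

  # separable scores: gap midpoint, J = 1
  thr2 <- youden_threshold(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_equal(as.numeric(thr2), 2.5)
  expect_equal(attr(thr2, "J"), 1)

  # uninformative scores: J = 0
  expect_equal(attr(youden_threshold(rep(1, 6), rep(c(1, 0), 3)), "J"), 0)
})

test_that("Youden maximality verified by threshold enumeration", {
  set.seed(21)
  for (case in 1:50) {
    n <- sample(6:30, 1)
    labels <- c(1, 0, stats::rbinom(n - 2, 1, 0.5))
    scores <- round(stats::rnorm(n), sample(c(1, 2), 1))
    thr <- youden_threshold(scores, labels)
    expect_equal(youden_at(scores, labels, as.numeric(thr)),
                 youden_max_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("confusion metrics: arithmetic and extreme thresholds", {
  # TP=2, FP=1, TN=3, FN=0
  scores <- c(2, 3, 2.5, 0.5, 0.2, 0.1)
  labels <- c(1, 1, 0, 0, 0, 0)
  m <- confusion_metrics(scores, labels, threshold = 1)
  expect_equal(m$accuracy, 83.3)
  expect_equal(m$sensitivity, 100.0)
  expect_equal(m$specificity, 75.0)
  low <- confusion_metrics(scores, labels, min(scores) - 1)
  expect_equal(c(low$sensitivity, low$specificity), c(100, 0))
  high <- confusion_metrics(scores, labels, max(scores) + 1)
  expect_equal(c(high$sensitivity, high$specificity), c(0, 100))
})

test_that("metrics are threshold-monotone", {
  set.seed(5)
  scores <- stats::rnorm(40)
  labels <- stats::rbinom(40, 1, 0.4)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) confusion_metrics(scores, labels, t)$sensitivity,
                 numeric(1))
  spec <- vapply(thr, function(t) confusion_metrics(scores, labels, t)$specificity,
                 numeric(1))
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("LOO scores separate a separable cohort and are deterministic", {
  coh <- tiny_cohort(seed = 14, n_pcr = 8, n_nonpcr = 10, n_features = 30,
                     informative_idx = 0:4, effect_size = 4)
  X <- coh$features[, coh$truth]
  s1 <- loo_scores(X, coh$labels)
  expect_equal(roc_auc(s1, coh$labels)$auc, 1.0)
  expect_identical(s1, loo_scores(X, coh$labels))
  expect_error(loo_scores(X[1:9, ], rep("pCR", 9)), "two classes")
})

test_that("LOO scores are invariant to patient ordering", {
  coh <- tiny_cohort(seed = 15, n_pcr = 6, n_nonpcr = 8, n_features = 20,
                     informative_idx = 0:2, effect_size = 2)
  X <- coh$features[, coh$truth]
  s <- loo_scores(X, coh$labels)
  perm <- sample(nrow(X))
  s_perm <- loo_scores(X[perm, ], coh$labels[perm])
  # the libsvm solver is working-set-order dependent at its optimization
  # tolerance, so equality holds to solver precision, not bit-for-bit
  expect_equal(s_perm[names(s)], s, tolerance = 0.02)
})

test_that("clinical encoding widths match the model grid", {
  tab <- gen_clinical_table(10, 14, 1, seed = 8)
  osf20 <- matrix(stats::rnorm(24 * 20), 24,
                  dimnames = list(tab$patient_id, paste0("f", 0:19)))
  aug <- append_clinical(osf20, tab)
  expect_equal(ncol(aug), 24)  # 20 image features + ER, PgR, HER2, subtype
  clin_only <- append_clinical(matrix(numeric(0), 24, 0), tab)
  expect_equal(ncol(clin_only), 4)
  expect_true(all(aug[, "er"] %in% 0:1))
  expect_true(all(aug[, "subtype"] %in% 0:2))

  tab_bad <- tab; levels(tab_bad$her2) <- c("neg", "weird")
  expect_error(append_clinical(osf20, tab_bad), "unknown category")
})

test_that("missing clinical values are imputed to the training-fold mode and flagged", {
  tab <- gen_clinical_table(10, 14, 1, seed = 9)
  tab$her2[3] <- NA
  aug <- append_clinical(matrix(numeric(0), 24, 0), tab)
  expect_false(anyNA(aug))
  expect_equal(attr(aug, "imputed")$her2, 3)
  mode_val <- if (sum(tab$her2 == "pos", na.rm = TRUE) >
                  sum(tab$her2 == "neg", na.rm = TRUE)) 1 else 0
  expect_equal(unname(aug[3, "her2"]), mode_val)
})

test_that("independent evaluation: resubstitution on separable data is perfect", {
  coh <- tiny_cohort(seed = 17, n_pcr = 8, n_nonpcr = 12, n_features = 30,
                     informative_idx = 0:4, effect_size = 4)
  X <- coh$features
  rep <- independent_eval(X, coh$labels, X, coh$labels, osf = coh$truth)
  expect_equal(rep$accuracy, 100.0)
  expect_equal(rep$auc, 1.0)
  expect_error(independent_eval(X, coh$labels, X, coh$labels,
                                osf = character(0)),
               "OSF is empty")
  expect_error(independent_eval(X, coh$labels, X, coh$labels,
                                osf = "not-a-column"),
               "missing")
})

test_that("independent evaluation reports both threshold choices", {
  train <- tiny_cohort(seed = 18, n_pcr = 12, n_nonpcr = 18, n_features = 40,
                       informative_idx = 0:5, effect_size = 2)
  test <- tiny_cohort(seed = 19, n_pcr = 5, n_nonpcr = 8, n_features = 40,
                      informative_idx = 0:5, effect_size = 2)
  r <- independent_eval(train$features, train$labels, test$features,
                        test$labels, osf = train$truth)
  expect_true(is.finite(r$threshold_train))
  expect_true(is.finite(r$threshold_test))
  expect_equal(r$youden_threshold, r$threshold_test)
  r2 <- independent_eval(train$features, train$labels, test$features,
                         test$labels, osf = train$truth,
                         threshold_from = "train")
  expect_equal(r2$youden_threshold, r2$threshold_train)
  expect_equal(r$auc, r2$auc)  # threshold choice never changes the AUC
})

test_that("subtype-stratified metrics respect missing subtypes and degenerate strata", {
  scores <- c(2, 3, -1, -2, 4, -3, 1, -1.5)
  labels <- c(1, 1, 0, 0, 1, 0, 1, 0)
  subtype <- c("Luminal", "Luminal", "Luminal", "Luminal",
               "HER2+", "HER2+", NA, NA)
  out <- subtype_stratified_eval(scores, labels, subtype, threshold = 0)
  expect_equal(out$n_excluded_missing, 2)
  expect_equal(sum(out$per_subtype$n), length(scores) - 2)
  lum <- out$per_subtype[out$per_subtype$subtype == "Luminal", ]
  expect_equal(lum$accuracy, 100)
  # a one-class stratum reports NA for the undefined metric
  one_class <- subtype_stratified_eval(c(1, 2), c(1, 1), c("TN", "TN"), 0)
  expect_true(is.na(one_class$per_subtype$specificity))
})
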