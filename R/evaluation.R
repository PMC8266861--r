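# SVM classification on selected features, LOO and independent-test
# evaluation, ROC/AUC, Youden thresholding, clinical augmentation.

# z-score scaling fit on the training fold only; zero-variance columns pass
# through unscaled
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$mu, "-"), 2, sc$sd, "/")
}

# train a libsvm C-classifier and return a scoring closure oriented so that
# larger scores mean more pCR-like
train_svm_scorer <- function(X, labels, kernel = "linear", cost = 1) {
  labels <- factor(labels, levels = c("non-pCR", "pCR"))
  sc <- fit_scaler(X)
  Xs <- apply_scaler(X, sc)
  fit <- e1071::svm(Xs, labels, kernel = kernel, cost = cost, scale = FALSE)
  dv_train <- attr(stats::predict(fit, Xs, decision.values = TRUE),
                   "decision.values")[, 1]
  flip <- mean(dv_train[labels == "pCR"]) < mean(dv_train[labels == "non-pCR"])
  function(Xnew) {
    d <- attr(stats::predict(fit, apply_scaler(Xnew, sc),
                             decision.values = TRUE),
              "decision.values")[, 1]
    if (flip) -d else d
  }
}

#' Encode and append clinical variables to an image-feature matrix
#'
#' ER/PgR/HER2 are encoded 0/1 (`pos` = 1) and molecular subtype as a single
#' 3-level integer code (Luminal = 0, HER2+ = 1, Triple Negative = 2),
#' appended after the image-feature columns. Missing values are imputed to
#' the mode of the training fold (by default the table itself); the imputed
#' cells are recorded in the `imputed` attribute.
#'
#' @param features numeric matrix (possibly 0 columns) with one row per
#'   patient.
#' @param clinical data.frame aligned to `features` rows with the requested
#'   variables.
#' @param variables clinical columns to append, default
#'   `c("er", "pgr", "her2", "subtype")`.
#' @param impute_from optional data.frame used to compute imputation modes
#'   (the training fold); defaults to `clinical`.
#' @return numeric matrix of width `ncol(features) + length(variables)`.
#' @export
append_clinical <- function(features, clinical,
                            variables = c("er", "pgr", "her2", "subtype"),
                            impute_from = NULL) {
  features <- as.matrix(features)
  if (nrow(features) == 0) features <- matrix(0, nrow(clinical), 0)
  if (nrow(features) != nrow(clinical)) {
    stop("features and clinical table must have matching rows", call. = FALSE)
  }
  missing_vars <- setdiff(variables, names(clinical))
  if (length(missing_vars)) {
    stop("clinical table lacks variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  if (is.null(impute_from)) impute_from <- clinical
  encode_one <- function(v, tab) {
    x <- as.character(tab[[v]])
    if (v == "subtype") {
      lev <- c("Luminal", "HER2+", "Triple Negative")
    } else {
      lev <- c("neg", "pos")
    }
    bad <- !is.na(x) & !(x %in% lev)
    if (any(bad)) {
      stop("unknown category in '", v, "': ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
    as.numeric(factor(x, levels = lev)) - 1
  }
  imputed <- list()
  cols <- sapply(variables, function(v) {
    x <- encode_one(v, clinical)
    if (anyNA(x)) {
      train_x <- encode_one(v, impute_from)
      mode_val <- as.numeric(names(which.max(table(train_x))))
      imputed[[v]] <<- which(is.na(x))
      x[is.na(x)] <- mode_val
    }
    x
  })
  cols <- matrix(cols, nrow = nrow(clinical),
                 dimnames = list(rownames(features), variables))
  out <- cbind(features, cols)
  attr(out, "imputed") <- imputed
  out
}

#' Leave-one-patient-out SVM decision scores
#'
#' For every patient an SVM is trained on the remaining patients (z-score
#' scaling and any clinical-value imputation fit on that training fold only)
#' and the held-out patient is scored. Scores are oriented so larger = more
#' pCR-like. Deterministic; invariant to patient ordering.
#'
#' @param X numeric matrix of selected features (may have 0 columns when a
#'   clinical-only model is requested).
#' @param labels two-level labels (`non-pCR`/`pCR`), >= 2 patients per class.
#' @param clinical optional clinical data.frame; when given, the variables in
#'   `clinical_vars` are encoded and appended per fold.
#' @param clinical_vars clinical columns to append.
#' @param kernel,cost SVM settings (linear kernel, unit cost by default:
#'   sensible for very-high-dimension / low-n problems).
#' @return named numeric vector of per-patient decision scores.
#' @export
loo_scores <- function(X, labels, clinical = NULL,
                       clinical_vars = c("er", "pgr", "her2", "subtype"),
                       kernel = "linear", cost = 1) {
  X <- as.matrix(X)
  labels <- check_two_class(labels)
  labels <- factor(as.character(labels), levels = c("non-pCR", "pCR"))
  n <- nrow(X)
  if (!is.null(clinical) && nrow(clinical) != n) {
    stop("clinical table must align with the feature matrix", call. = FALSE)
  }
  if (ncol(X) == 0 && is.null(clinical)) {
    stop("model resolves to zero columns", call. = FALSE)
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- labels[-i]
    if (nlevels(droplevels(ytr)) < 2) {
      stop("degenerate LOO fold: training set has a single class",
           call. = FALSE)
    }
    if (is.null(clinical)) {
      Xtr <- X[-i, , drop = FALSE]
      Xte <- X[i, , drop = FALSE]
    } else {
      Xtr <- append_clinical(X[-i, , drop = FALSE], clinical[-i, , drop = FALSE],
                             clinical_vars, impute_from = clinical[-i, , drop = FALSE])
      Xte <- append_clinical(X[i, , drop = FALSE], clinical[i, , drop = FALSE],
                             clinical_vars, impute_from = clinical[-i, , drop = FALSE])
    }
    scorer <- train_svm_scorer(Xtr, ytr, kernel, cost)
    scores[i] <- scorer(Xte)
  }
  names(scores) <- rownames(X) %||% paste0("patient", seq_len(n))
  scores
}

#' ROC curve and AUC by the Mann-Whitney identity
#'
#' The AUC equals the fraction of (positive, negative) score pairs in which
#' the positive scores higher, with half credit for ties — computed through
#' the rank identity `AUC = (R1 - n1(n1+1)/2) / (n1 n0)`. ROC points are
#' produced at every distinct score threshold.
#'
#' @param scores numeric decision scores (larger = more pCR-like).
#' @param labels two-level labels; the positive class is `"pCR"` when
#'   present, otherwise the second factor level.
#' @return list of class `roc_curve`: `roc` (data.frame `threshold`, `fpr`,
#'   `tpr`), `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive_indicator(labels)
  if (!any(pos) || all(pos)) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
               data.frame(threshold = thr, fpr = fpr, tpr = tpr))
  structure(list(roc = roc, auc = auc, n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

as_positive_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if ("pCR" %in% levels(f)) f == "pCR" else f == levels(f)[nlevels(f)]
}

#' Operating threshold by Youden's index
#'
#' Enumerates every candidate threshold (each distinct score, plus one above
#' the maximum for the predict-nobody rule) under the decision rule
#' `positive when score >= threshold`, and maximizes
#' `J = sensitivity + specificity - 1`. Ties are broken toward higher
#' specificity (the higher threshold). The returned cut-off is the midpoint
#' between the winning score and the next distinct score below it, so on
#' separable data it is the midpoint of the class gap.
#'
#' @param scores,labels as in [roc_auc()].
#' @return numeric threshold with attribute `J` (the maximal Youden index).
#' @export
youden_threshold <- function(scores, labels) {
  pos <- as_positive_indicator(labels)
  u <- sort(unique(scores))
  cand <- c(u, max(u) + 1)
  J <- vapply(cand, function(t) {
    mean(scores[pos] >= t) + mean(scores[!pos] < t) - 1
  }, numeric(1))
  best <- max(J)
  # ties toward higher specificity = larger threshold
  t_star <- max(cand[J >= best - 1e-12])
  below <- u[u < t_star]
  thr <- if (length(below)) (t_star + max(below)) / 2 else t_star
  attr(thr, "J") <- best
  thr
}

#' Confusion-matrix metrics at a threshold
#'
#' Predicts pCR when `score >= threshold` and reports accuracy, sensitivity
#' (pCR recall) and specificity as percentages rounded to one decimal. A
#' stratum with no positives (or no negatives) yields `NA` sensitivity
#' (specificity).
#'
#' @param scores,labels as in [roc_auc()].
#' @param threshold decision cut-off (finite).
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent),
#'   and the counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  stopifnot(is.finite(threshold))
  pos <- as_positive_indicator(labels)
  pred <- scores >= threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  pct <- function(x) round(100 * x, 1)
  list(accuracy = pct((tp + tn) / length(scores)),
       sensitivity = if (tp + fn > 0) pct(tp / (tp + fn)) else NA_real_,
       specificity = if (tn + fp > 0) pct(tn / (tn + fp)) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

new_eval_report <- function(scores, labels, threshold, roc, extra = list()) {
  m <- confusion_metrics(scores, labels, threshold)
  pos <- as_positive_indicator(labels)
  structure(c(list(auc = roc$auc,
                   youden_threshold = as.numeric(threshold),
                   youden_J = attr(threshold, "J"),
                   accuracy = m$accuracy, sensitivity = m$sensitivity,
                   specificity = m$specificity,
                   roc = roc$roc,
                   scores = scores,
                   predictions = ifelse(scores >= as.numeric(threshold),
                                        "pCR", "non-pCR"),
                   n_pos = sum(pos), n_neg = sum(!pos),
                   note = paste("The OSF was derived using every fine-tuning",
                                "patient, so fine-tuning LOO metrics are",
                                "optimistically biased; the independent test",
                                "is the unbiased surface.")),
              extra),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> AUC %.3f | thr %.4g (J = %.3f) | acc %.1f%% sens %.1f%% spec %.1f%% | n+ %d n- %d\n",
    x$auc, x$youden_threshold, x$youden_J, x$accuracy, x$sensitivity,
    x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Evaluate pooled LOO scores
#'
#' Computes the ROC/AUC of leave-one-out scores, places the operating
#' threshold by Youden's index on the pooled-score ROC, and reports the
#' confusion metrics at that threshold.
#'
#' @param scores LOO decision scores (see [loo_scores()]).
#' @param labels two-level labels.
#' @return An `eval_report`.
#' @export
evaluate_loo <- function(scores, labels) {
  roc <- roc_auc(scores, labels)
  thr <- youden_threshold(scores, labels)
  new_eval_report(scores, labels, thr, roc)
}

#' Train on the full cohort and evaluate on an independent test set
#'
#' Fits a single SVM on every training patient (restricted to the OSF
#' columns, optionally augmented with clinical variables whose encoding and
#' imputation are fit on the training set), scores the test patients, and
#' reports ROC/AUC plus Youden-thresholded metrics. The threshold is placed
#' on the test-set ROC by default; `threshold_from = "train"` reuses the
#' training-score threshold instead, and both thresholds are recorded in the
#' report either way.
#'
#' @param train_x,train_labels fine-tuning feature matrix (OSF columns) and
#'   labels.
#' @param test_x,test_labels independent-test feature matrix (same columns)
#'   and labels.
#' @param osf character vector of OSF column names; must be non-empty and
#'   present in both matrices.
#' @param train_clinical,test_clinical optional clinical data.frames.
#' @param clinical_vars clinical columns to append.
#' @param threshold_from `"test"` (default) or `"train"`.
#' @param kernel,cost SVM settings.
#' @return An `eval_report` with extra fields `threshold_train`,
#'   `threshold_test`, `threshold_from`.
#' @export
independent_eval <- function(train_x, train_labels, test_x, test_labels,
                             osf = colnames(train_x),
                             train_clinical = NULL, test_clinical = NULL,
                             clinical_vars = c("er", "pgr", "her2", "subtype"),
                             threshold_from = c("test", "train"),
                             kernel = "linear", cost = 1) {
  threshold_from <- match.arg(threshold_from)
  use_clinical <- !is.null(train_clinical)
  if (length(osf) == 0 && !use_clinical) {
    stop("OSF is empty: rerun the feature selection (larger alpha or ",
         "stronger effect) before fitting a classifier", call. = FALSE)
  }
  missing_cols <- setdiff(osf, colnames(train_x))
  if (length(osf) && (length(missing_cols) ||
                      length(setdiff(osf, colnames(test_x))))) {
    stop("OSF columns missing from the train or test matrix", call. = FALSE)
  }
  Xtr <- as.matrix(train_x)[, osf, drop = FALSE]
  Xte <- as.matrix(test_x)[, osf, drop = FALSE]
  if (use_clinical) {
    Xtr <- append_clinical(Xtr, train_clinical, clinical_vars,
                           impute_from = train_clinical)
    Xte <- append_clinical(Xte, test_clinical, clinical_vars,
                           impute_from = train_clinical)
  }
  train_labels <- check_two_class(train_labels)
  scorer <- train_svm_scorer(Xtr, train_labels, kernel, cost)
  test_scores <- scorer(Xte)
  names(test_scores) <- rownames(test_x)
  train_scores <- scorer(Xtr)
  thr_test <- youden_threshold(test_scores, test_labels)
  thr_train <- youden_threshold(train_scores, train_labels)
  thr <- if (threshold_from == "test") thr_test else thr_train
  roc <- roc_auc(test_scores, test_labels)
  new_eval_report(test_scores, test_labels, thr, roc,
                  extra = list(threshold_train = as.numeric(thr_train),
                               threshold_test = as.numeric(thr_test),
                               threshold_from = threshold_from))
}

#' Per-molecular-subtype confusion metrics at a global threshold
#'
#' Splits the cohort by molecular subtype and reports the confusion metrics
#' of the already-computed scores within each stratum, using the single
#' global threshold. Patients with missing subtype are excluded and counted.
#' A stratum containing a single class reports `NA` for the undefined metric.
#'
#' @param scores per-patient decision scores.
#' @param labels two-level labels.
#' @param subtype factor/character of molecular subtypes (NA allowed).
#' @param threshold global decision threshold.
#' @return list with `per_subtype` (data.frame: subtype, n, n_pos, n_neg,
#'   accuracy, sensitivity, specificity) and `n_excluded_missing`.
#' @export
subtype_stratified_eval <- function(scores, labels, subtype, threshold) {
  stopifnot(length(scores) == length(subtype))
  keep <- !is.na(subtype)
  excluded <- sum(!keep)
  sc <- scores[keep]
  lab <- labels[keep]
  st <- droplevels(as.factor(subtype[keep]))
  rows <- lapply(levels(st), function(s) {
    sel <- st == s
    m <- confusion_metrics(sc[sel], lab[sel], threshold)
    pos <- as_positive_indicator(lab[sel])
    data.frame(subtype = s, n = sum(sel), n_pos = sum(pos),
               n_neg = sum(!pos), accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               stringsAsFactors = FALSE)
  })
  list(per_subtype = do.call(rbind, rows), n_excluded_missing = excluded)
}
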