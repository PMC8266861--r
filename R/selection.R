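#' Configuration of the stability feature-selection procedure
#'
#' Defaults follow the study design this package implements: at every
#' leave-one-patient-out step, 20 iterations are run; each iteration draws 10
#' random subsets of 90% of the training patients, Wilcoxon-filters every
#' subset at p < 0.001, takes the union of the 10 filtered sets, and the 20
#' iteration sets are intersected. Features surviving the intersection are
#' the "stable" ones — those selected regardless of which training patients
#' happened to be drawn.
#'
#' @param n_iterations iterations per LOO step (default 20).
#' @param n_subsets random subsets per iteration (default 10).
#' @param subset_fraction fraction of training patients per subset
#'   (default 0.90; subset size is `floor(fraction * n_train)`).
#' @param alpha rank-sum p-value cut-off, strict (default 0.001).
#' @param seed master seed; every (patient, iteration, subset) draw uses its
#'   own substream so results are independent of evaluation order.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_iterations = 20, n_subsets = 10,
                             subset_fraction = 0.90, alpha = 0.001,
                             seed = 1) {
  if (subset_fraction <= 0 || subset_fraction > 1) {
    stop("subset_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (n_iterations < 1 || n_subsets < 1) {
    stop("counts must be at least 1", call. = FALSE)
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets),
                 subset_fraction = subset_fraction,
                 alpha = alpha, seed = as.integer(seed)),
            class = "selection_config")
}

# coerce labels to a two-level factor and check both classes have >= 2 rows
check_two_class <- function(labels, min_per_class = 2) {
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2) {
    stop("labels must contain exactly two classes", call. = FALSE)
  }
  if (any(table(labels) < min_per_class)) {
    stop("each class needs at least ", min_per_class, " samples",
         call. = FALSE)
  }
  labels
}

ensure_feature_names <- function(X) {
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)) - 1L)
  X
}

#' Two-sided Wilcoxon-Mann-Whitney rank-sum p-values per feature column
#'
#' Compares the two class distributions of every column. Ties receive
#' midranks. When the combined sample size is at most 25 and a column has no
#' ties the exact rank-sum distribution is used; otherwise the normal
#' approximation with tie and continuity correction. A column whose values
#' are all equal carries p = 1.
#'
#' @param X numeric matrix, rows = patients, columns = features.
#' @param labels two-level class labels aligned to rows (both classes must
#'   have at least 2 samples).
#' @return named numeric vector of two-sided p-values, one per column.
#' @examples
#' X <- cbind(a = c(1, 2, 3, 4, 5, 6))
#' rank_sum_pvalues(X, rep(c("g1", "g2"), each = 3))  # exact p = 0.1
#' @export
rank_sum_pvalues <- function(X, labels) {
  X <- ensure_feature_names(as.matrix(X))
  labels <- check_two_class(labels)
  ranksum_p_fast(X, labels == levels(labels)[1])
}

# hot-path variant: X a named matrix, g1 a logical group indicator with both
# groups of size >= 2
ranksum_p_fast <- function(X, g1) {
  n1 <- sum(g1)
  n2 <- length(g1) - n1
  n <- n1 + n2
  cr <- col_ranks_mid(X)
  W <- colSums(cr$ranks[g1, , drop = FALSE])
  U <- W - n1 * (n1 + 1) / 2
  p <- rep(NA_real_, ncol(X))
  constant <- cr$tie >= n^3 - n  # all values equal -> one tie group of size n
  exact_ok <- (n <= 25) & (cr$tie == 0)
  if (any(exact_ok)) {
    u <- U[exact_ok]
    p_lo <- stats::pwilcox(u, n1, n2)
    p_hi <- 1 - stats::pwilcox(u - 1, n1, n2)
    p[exact_ok] <- pmin(1, 2 * pmin(p_lo, p_hi))
  }
  approx_cols <- !exact_ok & !constant
  if (any(approx_cols)) {
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - cr$tie[approx_cols] / (n * (n - 1)))
    z <- U[approx_cols] - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p[approx_cols] <- pmin(1, 2 * stats::pnorm(-abs(z)))
  }
  p[constant] <- 1
  names(p) <- colnames(X)
  p
}

#' Features passing the rank-sum filter
#'
#' @param X,labels as in [rank_sum_pvalues()].
#' @param alpha strict p-value cut-off: a feature is kept when `p < alpha`.
#' @return character vector of feature names (possibly empty).
#' @export
filter_features <- function(X, labels, alpha = 0.001) {
  p <- rank_sum_pvalues(X, labels)
  names(p)[p < alpha]
}

# deterministic two-class subset draw for (patient_key, iteration, subset);
# redraws (logged via attribute) if a draw loses a class. g1 is the logical
# class indicator.
draw_subset <- function(n_train, g1, size, seed, patient_key, iteration,
                        subset) {
  for (attempt in 0:100) {
    rows <- with_seed(mix_seed(seed, patient_key, iteration, subset, attempt),
                      sample.int(n_train, size))
    gs <- g1[rows]
    if (any(gs) && !all(gs)) {
      attr(rows, "redraws") <- attempt
      return(rows)
    }
  }
  stop("could not draw a two-class subset after 100 attempts", call. = FALSE)
}

# hot-path iteration: X already restricted to candidate columns, g1 logical
iteration_select_fast <- function(X, g1, config, patient_key, iteration) {
  n_train <- nrow(X)
  size <- max(2L, floor(config$subset_fraction * n_train))
  out <- character(0)
  redraws <- 0L
  for (s in seq_len(config$n_subsets)) {
    rows <- draw_subset(n_train, g1, size, config$seed, patient_key,
                        iteration, s)
    redraws <- redraws + attr(rows, "redraws")
    p <- ranksum_p_fast(X[rows, , drop = FALSE], g1[rows])
    out <- union(out, names(p)[p < config$alpha])
  }
  attr(out, "redraws") <- redraws
  out
}

#' One iteration of the dynamic feature selection
#'
#' Draws `n_subsets` random subsets of `floor(subset_fraction * n_train)`
#' training patients (without replacement; a draw that loses a class is
#' redrawn and logged), applies the rank-sum filter to each subset, and
#' returns the UNION of the per-subset feature sets — the candidate set of
#' this iteration.
#'
#' @param X,labels training feature matrix and labels.
#' @param config a [selection_config()].
#' @param patient_key integer key of the held-out patient (seeds the
#'   substreams; use 0 when not inside a LOO loop).
#' @param iteration iteration number (seeds the substreams).
#' @param columns optional character vector restricting the filter to these
#'   feature columns (results for those columns are unchanged; used to skip
#'   work for features that can no longer survive the running intersection).
#' @return character vector of feature names with attribute `redraws`
#'   (total redraw count across subsets).
#' @export
iteration_select <- function(X, labels, config, patient_key = 0L,
                             iteration = 1L, columns = NULL) {
  stopifnot(inherits(config, "selection_config"))
  X <- ensure_feature_names(as.matrix(X))
  labels <- check_two_class(labels)
  Xf <- if (is.null(columns)) X else X[, columns, drop = FALSE]
  iteration_select_fast(Xf, labels == levels(labels)[1], config,
                        patient_key, iteration)
}

#' Per-patient stable feature sets by leave-one-patient-out resampling
#'
#' For every held-out patient, runs `n_iterations` calls of
#' [iteration_select()] on the remaining patients and intersects the
#' iteration sets, yielding that patient's stable feature set. Empty
#' intersections are legal and logged. Fully deterministic given
#' `config$seed`; the draw log allows bit-exact replay.
#'
#' Features eliminated from the running intersection can never re-enter, so
#' later iterations only test the surviving columns and the loop stops early
#' once the intersection is empty — the result is identical to the
#' unrestricted computation.
#'
#' @param X feature matrix (patients x features).
#' @param labels two-level labels (>= 3 patients, both classes present).
#' @param config a [selection_config()].
#' @return An object of class `selection_result`: `per_patient_sets` (named
#'   list of character vectors), `osf` (their intersection, see
#'   [compute_osf()]), `config`, and `draw_log` (data.frame with per-patient
#'   iteration counts and redraws).
#' @export
loo_dynamic_select <- function(X, labels, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  X <- ensure_feature_names(as.matrix(X))
  labels <- check_two_class(labels)
  if (nrow(X) < 3) stop("need at least 3 patients for LOO", call. = FALSE)
  ids <- rownames(X) %||% paste0("patient", seq_len(nrow(X)))
  g1_all <- labels == levels(labels)[1]
  sets <- vector("list", nrow(X))
  log_rows <- vector("list", nrow(X))
  for (i in seq_len(nrow(X))) {
    Xi <- X[-i, , drop = FALSE]
    gi <- g1_all[-i]
    if (!any(gi) || all(gi)) {
      stop("leaving out patient ", ids[i], " removes a class", call. = FALSE)
    }
    S <- NULL
    Xi_S <- Xi
    redraws <- 0L
    it_run <- 0L
    for (it in seq_len(config$n_iterations)) {
      if (!is.null(S) && length(S) == 0) break  # intersection can only stay empty
      sel <- iteration_select_fast(Xi_S, gi, config, patient_key = i,
                                   iteration = it)
      redraws <- redraws + attr(sel, "redraws")
      S_new <- if (is.null(S)) sel else intersect(S, sel)
      if (is.null(S) || length(S_new) < length(S)) {
        Xi_S <- Xi[, S_new, drop = FALSE]
      }
      S <- S_new
      it_run <- it
    }
    sets[[i]] <- as.character(S)
    log_rows[[i]] <- data.frame(patient = ids[i], iterations_run = it_run,
                                redraws = redraws,
                                set_size = length(S),
                                stringsAsFactors = FALSE)
  }
  names(sets) <- ids
  structure(list(per_patient_sets = sets,
                 osf = compute_osf(sets),
                 config = config,
                 draw_log = do.call(rbind, log_rows)),
            class = "selection_result")
}

#' Optimal Subset of Features: intersection across all patients
#'
#' Intersects every held-out patient's stable feature set; the surviving
#' features are those selected no matter which patient was left out — the
#' OSF used by the downstream classifiers. An empty OSF is a legal outcome
#' (warned about, with guidance), not an error.
#'
#' @param per_patient_sets named list of character vectors, or a
#'   `selection_result`.
#' @return character vector of feature names.
#' @export
compute_osf <- function(per_patient_sets) {
  if (inherits(per_patient_sets, "selection_result")) {
    per_patient_sets <- per_patient_sets$per_patient_sets
  }
  if (length(per_patient_sets) == 0) {
    stop("per_patient_sets is empty", call. = FALSE)
  }
  osf <- Reduce(intersect, per_patient_sets)
  if (length(osf) == 0) {
    warning("OSF is empty: no feature is stable across all patients. ",
            "Consider a larger alpha or a stronger class effect.",
            call. = FALSE)
  }
  as.character(osf)
}

#' @export
print.selection_result <- function(x, ...) {
  sizes <- lengths(x$per_patient_sets)
  cat("<selection_result> ", length(sizes), " LOO patients; per-patient set ",
      "sizes ", min(sizes), "-", max(sizes), " (median ",
      stats::median(sizes), "); OSF size ", length(x$osf), "\n", sep = "")
  if (length(x$osf)) cat("OSF:", paste(x$osf, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param result a `selection_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  obj <- list(
    osf = result$osf,
    per_patient_sets = result$per_patient_sets,
    config = unclass(result$config),
    draw_log = result$draw_log
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
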