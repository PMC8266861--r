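#' Association screening between clinical variables and pCR
#'
#' For each clinical variable, tests its association with the two-level pCR
#' label: Mann-Whitney (two-sided rank-sum) for `age`, Pearson chi-square
#' without continuity correction for the categorical variables. Rows with a
#' missing value are dropped per variable and counted. A variable observed
#' at a single level is reported as not testable (`NA` p-value). Expected
#' cell counts below 5 are flagged in the `low_expected` column.
#'
#' @param clinical data.frame with (a subset of) columns `age`, `race`,
#'   `er`, `pgr`, `her2`, `subtype`.
#' @param labels two-level pCR labels aligned to rows; defaults to
#'   `clinical$pcr`.
#' @param variables variables to test, default every recognised column
#'   present.
#' @return An object of class `association_report`: a data.frame with
#'   columns `variable`, `test`, `statistic`, `p_value`, `selected`
#'   (p < 0.05), `n_used`, `n_missing`, `low_expected`; the contingency
#'   tables are attached as the `tables` attribute.
#' @examples
#' tab <- gen_clinical_table(30, 78, assoc_strength = 1, seed = 3)
#' associate(tab)
#' @export
associate <- function(clinical, labels = clinical$pcr,
                      variables = intersect(
                        c("age", "race", "er", "pgr", "her2", "subtype"),
                        names(clinical))) {
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  if (length(labels) != nrow(clinical)) {
    stop("labels must align with the clinical table", call. = FALSE)
  }
  labels <- check_two_class(labels, min_per_class = 1)
  tables <- list()
  rows <- lapply(variables, function(v) {
    x <- clinical[[v]]
    keep <- !is.na(x) & !is.na(labels)
    xk <- x[keep]
    yk <- droplevels(labels[keep])
    n_missing <- sum(!keep)
    if (v == "age") {
      if (nlevels(yk) < 2) {
        return(data.frame(variable = v, test = "Mann-Whitney",
                          statistic = NA_real_, p_value = NA_real_,
                          selected = NA, n_used = sum(keep),
                          n_missing = n_missing, low_expected = FALSE))
      }
      ht <- stats::wilcox.test(xk ~ yk, exact = FALSE, correct = TRUE)
      data.frame(variable = v, test = "Mann-Whitney",
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 selected = ht$p.value < 0.05, n_used = sum(keep),
                 n_missing = n_missing, low_expected = FALSE)
    } else {
      xk <- droplevels(as.factor(xk))
      if (nlevels(xk) < 2 || nlevels(yk) < 2) {
        return(data.frame(variable = v, test = "Chi-square",
                          statistic = NA_real_, p_value = NA_real_,
                          selected = NA, n_used = sum(keep),
                          n_missing = n_missing, low_expected = FALSE))
      }
      tab <- table(xk, yk)
      tables[[v]] <<- tab
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable = v, test = "Chi-square",
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 selected = ht$p.value < 0.05, n_used = sum(keep),
                 n_missing = n_missing,
                 low_expected = any(ht$expected < 5))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "tables") <- tables
  class(out) <- c("association_report", class(out))
  out
}

#' Clinical variables significantly associated with pCR
#'
#' @param report an [associate()] result.
#' @param alpha significance level (default 0.05; strict `p < alpha`).
#' @return character vector of variable names, input order preserved;
#'   untestable variables are never selected.
#' @export
select_associated <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "association_report"))
  ok <- !is.na(report$p_value) & report$p_value < alpha
  report$variable[ok]
}

#' @export
print.association_report <- function(x, ...) {
  df <- as.data.frame(unclass(x))
  df$p_value <- signif(df$p_value, 3)
  df$statistic <- signif(df$statistic, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
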