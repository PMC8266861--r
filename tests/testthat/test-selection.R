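# Rank-sum filtering and the layered stability-selection set operations.

test_that("rank-sum p-values match exact enumeration on small groups", {
  # canonical fully-separated 3 vs 3: extreme rank sum, exact p = 2/20
  X <- cbind(a = c(1, 2, 3, 4, 5, 6))
  expect_equal(unname(rank_sum_pvalues(X, rep(c("g1", "g2"), each = 3))),
               0.1)

  set.seed(42)
  for (case in 1:15) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- sample(seq_len(50), n1); y <- sample(setdiff(seq_len(50), x), n2)
    p_pkg <- unname(rank_sum_pvalues(cbind(c(x, y)),
                                     rep(c("a", "b"), c(n1, n2))))
    expect_equal(p_pkg, rank_sum_enum_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("rank-sum handles ties, constants and sign symmetry", {
  lab <- rep(c("a", "b"), each = 6)
  X <- cbind(const = rep(3, 12),
             v = c(1, 5, 2, 8, 9, 4, 7, 3, 10, 6, 11, 12))
  p <- rank_sum_pvalues(X, lab)
  expect_equal(unname(p["const"]), 1)
  # a column and its negation have identical p-values (rank symmetry)
  expect_equal(unname(rank_sum_pvalues(cbind(X[, "v"]), lab)),
               unname(rank_sum_pvalues(cbind(-X[, "v"]), lab)))
  # midranks + tie correction agree with wilcox.test on tied data
  tied <- c(1, 1, 2, 2, 2, 3, 3, 4, 4, 5, 5, 5)
  p_pkg <- unname(rank_sum_pvalues(cbind(tied), lab))
  p_ref <- stats::wilcox.test(tied[1:6], tied[7:12], exact = FALSE,
                              correct = TRUE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  expect_error(rank_sum_pvalues(cbind(1:5), rep("a", 5)), "two classes")
})

test_that("large-sample approximation agrees with wilcox.test columnwise", {
  coh <- tiny_cohort(seed = 8, n_pcr = 20, n_nonpcr = 30, n_features = 25)
  p <- rank_sum_pvalues(coh$features, coh$labels)
  ref <- apply(coh$features, 2, function(v) {
    stats::wilcox.test(v[coh$labels == "non-pCR"], v[coh$labels == "pCR"],
                       exact = FALSE, correct = TRUE)$p.value
  })
  expect_equal(unname(p), unname(ref), tolerance = 1e-12)
})

test_that("the 0.001 filter is an impossible bar for 3 vs 3 but not a permissive one", {
  X <- cbind(a = c(1, 2, 3, 10, 11, 12), b = c(5, 1, 9, 2, 7, 3))
  lab <- rep(c("g1", "g2"), each = 3)
  expect_length(filter_features(X, lab, alpha = 0.001), 0)
  expect_true("a" %in% filter_features(X, lab, alpha = 1.0))
})

test_that("planted-effect recall of the plain filter", {
  coh <- tiny_cohort(seed = 3, n_pcr = 40, n_nonpcr = 40, n_features = 500,
                     informative_idx = 0:9)
  sel <- filter_features(coh$features, coh$labels, 0.001)
  recall <- length(intersect(sel, coh$truth)) / length(coh$truth)
  expect_gte(recall, 0.8)
})

test_that("iteration_select degenerates to the plain filter and is deterministic", {
  coh <- tiny_cohort(seed = 4)
  cfg1 <- selection_config(n_subsets = 1, subset_fraction = 1, alpha = 0.01,
                           seed = 1)
  got <- iteration_select(coh$features, coh$labels, cfg1)
  expect_setequal(got, filter_features(coh$features, coh$labels, 0.01))
  # two full-sample subsets: union of identical sets is the same set
  cfg2 <- selection_config(n_subsets = 2, subset_fraction = 1, alpha = 0.01,
                           seed = 1)
  expect_setequal(iteration_select(coh$features, coh$labels, cfg2), got)
  # keyed substreams: same (patient, iteration) draws reproduce exactly
  cfg3 <- selection_config(seed = 7)
  a <- iteration_select(coh$features, coh$labels, cfg3, patient_key = 3,
                        iteration = 5)
  b <- iteration_select(coh$features, coh$labels, cfg3, patient_key = 3,
                        iteration = 5)
  expect_identical(sort(a), sort(b))
})

test_that("set algebra of the intersection layers", {
  sets <- list(p1 = c("f1", "f2", "f3"), p2 = c("f2", "f3"),
               p3 = c("f2", "f3", "f4"))
  expect_setequal(compute_osf(sets), c("f2", "f3"))
  expect_length(suppressWarnings(
    compute_osf(c(sets, list(p4 = character(0))))), 0)
  expect_setequal(compute_osf(sets["p1"]), c("f1", "f2", "f3"))
  expect_error(compute_osf(list()), "empty")
})

test_that("LOO selection: layered subset relations hold (monotonicity)", {
  coh <- tiny_cohort(seed = 6, n_pcr = 10, n_nonpcr = 14, n_features = 120)
  cfg <- selection_config(n_iterations = 4, n_subsets = 5, seed = 11,
                          alpha = 0.01)
  res <- loo_dynamic_select(coh$features, coh$labels, cfg)
  expect_s3_class(res, "selection_result")
  for (i in seq_along(res$per_patient_sets)) {
    s <- res$per_patient_sets[[i]]
    # OSF within every per-patient set
    expect_true(all(res$osf %in% s))
    # per-patient set within every iteration set (replayed via keyed draws)
    for (it in seq_len(cfg$n_iterations)) {
      it_set <- iteration_select(coh$features[-i, ], coh$labels[-i], cfg,
                                 patient_key = i, iteration = it)
      expect_true(all(s %in% it_set))
    }
  }
  # full determinism under a fixed config seed
  res2 <- loo_dynamic_select(coh$features, coh$labels, cfg)
  expect_identical(res$per_patient_sets, res2$per_patient_sets)
  expect_identical(res$osf, res2$osf)
})

test_that("n_iterations = 1 reduces each per-patient set to one iteration set", {
  coh <- tiny_cohort(seed = 9, n_pcr = 8, n_nonpcr = 10, n_features = 80)
  cfg <- selection_config(n_iterations = 1, n_subsets = 3, alpha = 0.05,
                          seed = 2)
  res <- loo_dynamic_select(coh$features, coh$labels, cfg)
  for (i in seq_along(res$per_patient_sets)) {
    expect_setequal(res$per_patient_sets[[i]],
                    iteration_select(coh$features[-i, ], coh$labels[-i], cfg,
                                     patient_key = i, iteration = 1))
  }
})

test_that("raising alpha never shrinks selected sets under fixed draws", {
  coh <- tiny_cohort(seed = 10, n_pcr = 10, n_nonpcr = 12, n_features = 100)
  lo <- selection_config(n_iterations = 3, n_subsets = 4, alpha = 0.005,
                         seed = 5)
  hi <- selection_config(n_iterations = 3, n_subsets = 4, alpha = 0.05,
                         seed = 5)
  res_lo <- loo_dynamic_select(coh$features, coh$labels, lo)
  res_hi <- loo_dynamic_select(coh$features, coh$labels, hi)
  for (i in seq_along(res_lo$per_patient_sets)) {
    expect_true(all(res_lo$per_patient_sets[[i]] %in%
                      res_hi$per_patient_sets[[i]]))
  }
  expect_true(all(res_lo$osf %in% res_hi$osf))
})

test_that("selection results serialize to JSON and replay from the log", {
  coh <- tiny_cohort(seed = 2)
  cfg <- selection_config(n_iterations = 2, n_subsets = 3, alpha = 0.01,
                          seed = 3)
  res <- loo_dynamic_select(coh$features, coh$labels, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_json(res, path)
  loaded <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(unlist(loaded$osf), res$osf)
  expect_equal(loaded$config$alpha, 0.01)
  expect_equal(nrow(res$draw_log), nrow(coh$features))
})
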