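# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force enumeration and direct pair counting.

# exact two-sided rank-sum p-value by enumerating all assignments of the
# pooled values to group 1 (tail-doubling definition, tie-free inputs)
rank_sum_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2, function(ix) sum(r[ix]))
  p_lo <- mean(ws <= w_obs)
  p_hi <- mean(ws >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# AUC as the concordant-pair fraction, 0.5 credit for ties
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels == "pCR" | labels == 1 | labels == TRUE)]
  neg <- scores[!(labels == "pCR" | labels == 1 | labels == TRUE)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# maximal Youden index over every possible real threshold (attained on the
# set of observed scores plus a predict-nobody threshold)
youden_max_oracle <- function(scores, labels) {
  pos <- as.logical(labels == "pCR" | labels == 1 | labels == TRUE)
  cand <- c(sort(unique(scores)), max(scores) + 1)
  max(vapply(cand, function(t) {
    mean(scores[pos] >= t) + mean(scores[!pos] < t) - 1
  }, numeric(1)))
}

# J achieved by a given threshold under the package's decision rule
youden_at <- function(scores, labels, thr) {
  pos <- as.logical(labels == "pCR" | labels == 1 | labels == TRUE)
  mean(scores[pos] >= thr) + mean(scores[!pos] < thr) - 1
}

# Pearson chi-square statistic by the closed form sum((O - E)^2 / E)
chisq_closed_form <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# small phantom config used throughout the imaging tests
tiny_phantom <- function(seed = 5, ...) {
  synthetic_phantom_config(seed = seed, ...)
}

# small planted cohort for selection/evaluation tests
tiny_cohort <- function(seed = 2, n_pcr = 15, n_nonpcr = 25,
                        n_features = 200, informative_idx = 0:4,
                        effect_size = 3) {
  gen_feature_cohort(synthetic_cohort_config(
    n_pcr = n_pcr, n_nonpcr = n_nonpcr, n_features = n_features,
    informative_idx = informative_idx, effect_size = effect_size,
    seed = seed))
}
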