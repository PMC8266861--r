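# Internal numeric helpers shared across modules.

#' Derive a reproducible substream seed from a master seed and integer keys
#'
#' Mixes the master seed with a sequence of integer keys through a small
#' modular linear recurrence, giving every (patient, iteration, subset, ...)
#' combination its own RNG substream. Results are invariant to evaluation
#' order because the seed depends only on the keys, never on call order.
#' All arithmetic stays below 2^53 so it is exact in doubles; the result is
#' a valid 32-bit seed.
#'
#' @param seed master seed (integer).
#' @param ... integer keys identifying the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
mix_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (k in c(...)) {
    h <- (h * 69621 + (as.double(k) %% m) * 10007 + 12345) %% m
  }
  # one extra scrambling pass so nearby keys decorrelate
  h <- (h * 69621 + 12345) %% m
  as.integer(h)
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Columnwise midranks and tie corrections
#'
#' Ranks every column of a matrix in a single radix sort keyed by
#' (column id, value), averaging ties to midranks. Returns the per-column
#' tie-correction term sum(t^3 - t) needed by the rank-sum normal
#' approximation.
#'
#' @param X numeric matrix (observations x features).
#' @return list with `ranks` (same shape as `X`) and `tie` (length `ncol(X)`).
#' @keywords internal
col_ranks_mid <- function(X) {
  n <- nrow(X)
  p <- ncol(X)
  cid <- rep.int(seq_len(p), rep.int(n, p))
  o <- order(cid, as.vector(X), method = "radix")
  xs <- X[o]
  len <- length(xs)
  new <- c(TRUE, xs[-1L] != xs[-len] | cid[-1L] != cid[-len])
  g <- cumsum(new)
  pos <- rep.int(seq_len(n), p)
  s <- tabulate(g)
  mid <- (pos[new] + (s - 1) / 2)[g]
  r <- numeric(len)
  r[o] <- mid
  dim(r) <- c(n, p)
  tie <- rep(0, p)
  tc <- rowsum(s^3 - s, cid[new], reorder = FALSE)
  tie[unique(cid[new])] <- tc[, 1L]
  list(ranks = r, tie = tie)
}

#' Corner-aligned bilinear resize of a 2-D image
#'
#' Output pixel i samples source coordinate `1 + (i-1)*(n-1)/(m-1)`, so the
#' four corners map exactly onto the source corners: constant images stay
#' constant and linear ramps keep their extremes (to floating-point
#' precision), which the ROI contract relies on.
#'
#' @param img numeric matrix.
#' @param out_rows,out_cols output dimensions.
#' @return numeric matrix `out_rows x out_cols`.
#' @keywords internal
bilinear_resize <- function(img, out_rows, out_cols) {
  src_coord <- function(m_out, n_in) {
    if (n_in == 1L || m_out == 1L) {
      rep(1, m_out)
    } else {
      1 + (seq_len(m_out) - 1) * (n_in - 1) / (m_out - 1)
    }
  }
  interp_axis <- function(coord, n_in) {
    lo <- pmin(floor(coord), n_in - ifelse(n_in > 1, 1, 0))
    lo <- pmax(lo, 1)
    hi <- pmin(lo + 1, n_in)
    frac <- coord - lo
    list(lo = as.integer(lo), hi = as.integer(hi), frac = frac)
  }
  rc <- interp_axis(src_coord(out_rows, nrow(img)), nrow(img))
  cc <- interp_axis(src_coord(out_cols, ncol(img)), ncol(img))
  # rows first: frac recycles down columns
  A <- img[rc$lo, , drop = FALSE] * (1 - rc$frac) + img[rc$hi, , drop = FALSE] * rc$frac
  wc <- matrix(cc$frac, out_rows, out_cols, byrow = TRUE)
  A[, cc$lo, drop = FALSE] * (1 - wc) + A[, cc$hi, drop = FALSE] * wc
}

# evaluate expr under a temporary RNG seed, restoring global RNG state
# (hand-rolled: this sits on the resampling hot path, where the generic
# state-capture machinery costs more than the draw itself)
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  res <- expr
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  res
}
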