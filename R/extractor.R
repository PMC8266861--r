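#' Convolutional feature extractors honouring the pool2 contract
#'
#' The pipeline consumes low-level convolutional features: the output of the
#' second pooling stage of an AlexNet-shaped network, a 13 x 13 x 256 block
#' per 227 x 227 input that flattens to 43,264 values. Any backend satisfying
#' that contract can be plugged in; the package ships `"filterbank"`, a fully
#' deterministic bank of seeded Gaussian random convolutions with the exact
#' AlexNet geometry (227 -> conv 11x11/4 -> 55 -> pool 3x3/2 -> 27 ->
#' conv 5x5/1 pad 2 -> 27 -> pool 3x3/2 -> 13, 256 channels), bias-free and
#' weight-download-free. Random convolutions retain the locality and
#' edge/dot/curve sensitivity of trained low-level filters, which is all the
#' downstream selection machinery requires of them.
#'
#' @param backend `"filterbank"`, or a function `f(tensor)` mapping a
#'   227 x 227 x 3 array to a 13 x 13 x 256 array for a custom (e.g.
#'   pretrained) backend.
#' @param seed seed for the filter-bank weights; part of the extractor's
#'   identity.
#' @param name identifier recorded in provenance (defaults to the backend
#'   name).
#' @return An object of class `pool2_extractor`.
#' @examples
#' ex <- make_extractor("filterbank", seed = 909)
#' ex$output_shape
#' @export
make_extractor <- function(backend = "filterbank", seed = 909, name = NULL) {
  if (is.function(backend)) {
    ext <- structure(
      list(name = name %||% "custom", fun = backend,
           input_shape = c(227L, 227L, 3L), output_shape = c(13L, 13L, 256L),
           flatten_order = "index = (row*13 + col)*256 + channel (zero-based)",
           seed = NA_integer_),
      class = "pool2_extractor")
    return(validate_extractor(ext))
  }
  backend <- match.arg(backend, "filterbank")
  fb <- filterbank_weights(seed)
  fun <- function(x) filterbank_forward(x, fb)
  ext <- structure(
    list(name = name %||% sprintf("filterbank-%d", seed), fun = fun,
         input_shape = c(227L, 227L, 3L), output_shape = c(13L, 13L, 256L),
         flatten_order = "index = (row*13 + col)*256 + channel (zero-based)",
         seed = as.integer(seed)),
    class = "pool2_extractor")
  validate_extractor(ext)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Verify that an extractor satisfies the pool2 contract
#'
#' Pushes a fixed probe tensor through the backend and checks that the output
#' shape is 13 x 13 x 256 (43,264 values when flattened) and that a repeat
#' call reproduces it bit-for-bit (determinism).
#'
#' @param extractor a `pool2_extractor`.
#' @return The extractor, invisibly-checked; errors on contract violation.
#' @export
validate_extractor <- function(extractor) {
  stopifnot(inherits(extractor, "pool2_extractor"))
  probe <- array(with_seed(20231L, stats::runif(227 * 227 * 3)),
                 c(227L, 227L, 3L))
  out <- extractor$fun(probe)
  if (!identical(dim(out), c(13L, 13L, 256L))) {
    stop("extractor contract violation: backend output is not 13 x 13 x 256",
         call. = FALSE)
  }
  if (length(out) != 43264L) {
    stop("extractor contract violation: flattened length != 43264",
         call. = FALSE)
  }
  if (!identical(out, extractor$fun(probe))) {
    stop("extractor contract violation: backend is not deterministic",
         call. = FALSE)
  }
  extractor
}

#' @export
print.pool2_extractor <- function(x, ...) {
  cat("<pool2_extractor> ", x$name, ": 227x227x3 -> 13x13x256 (43,264), ",
      x$flatten_order, "\n", sep = "")
  invisible(x)
}

# ---- filter-bank internals ---------------------------------------------

# linear indices of im2col patches for an (h, w, d) input, kernel kh x kw,
# given stride and output side; rows = output positions (row index fastest,
# matching R's column-major array() reshape), cols = patch elements
im2col_indices <- function(h, w, d, kh, kw, stride, out) {
  pos <- expand.grid(r = seq_len(out), c = seq_len(out))
  off <- expand.grid(i = 0:(kh - 1), j = 0:(kw - 1), k = 0:(d - 1))
  base_r <- (pos$r - 1) * stride + 1
  base_c <- (pos$c - 1) * stride + 1
  R <- outer(base_r, off$i, "+")
  C <- outer(base_c, off$j, "+")
  K <- matrix(off$k, nrow(pos), nrow(off), byrow = TRUE)
  matrix(as.integer(R + (C - 1) * h + K * h * w), nrow(pos), nrow(off))
}

max_pool <- function(A, out, k = 3L, stride = 2L) {
  ch <- dim(A)[3]
  base <- (seq_len(out) - 1L) * stride + 1L
  O <- array(-Inf, c(out, out, ch))
  for (i in 0:(k - 1)) {
    for (j in 0:(k - 1)) {
      O <- pmax(O, A[base + i, base + j, , drop = FALSE])
    }
  }
  O
}

filterbank_weights <- function(seed) {
  w1 <- with_seed(mix_seed(seed, 1L),
                  stats::rnorm(11 * 11 * 3 * 96, 0, 1 / sqrt(11 * 11 * 3)))
  w2 <- with_seed(mix_seed(seed, 2L),
                  stats::rnorm(5 * 5 * 96 * 256, 0, 1 / sqrt(5 * 5 * 96)))
  list(
    W1 = matrix(w1, 363, 96),
    W2 = matrix(w2, 2400, 256),
    idx1 = im2col_indices(227, 227, 3, 11, 11, 4, 55),
    idx2 = im2col_indices(31, 31, 96, 5, 5, 1, 27)
  )
}

# two conv(+ReLU)+maxpool stages; bias-free, so a zero input maps to zero
filterbank_forward <- function(x, fb) {
  P1 <- matrix(x[fb$idx1], 3025, 363)
  A1 <- array(pmax(P1 %*% fb$W1, 0), c(55, 55, 96))
  M1 <- max_pool(A1, 27L)
  PAD <- array(0, c(31, 31, 96))
  PAD[3:29, 3:29, ] <- M1
  P2 <- matrix(PAD[fb$idx2], 729, 2400)
  A2 <- array(pmax(P2 %*% fb$W2, 0), c(27, 27, 256))
  max_pool(A2, 13L)
}

# ---- input preparation and flattening ----------------------------------

#' Prepare a ROI patch as a 3-channel network input
#'
#' Linearly rescales the patch to `[0, 1]` (min to 0, max to 1; a constant
#' patch maps to all zeros) and replicates the grayscale plane into three
#' identical channels. The rescaling parameters are recorded as attributes
#' for provenance.
#'
#' @param patch a [extract_roi()] result or a bare 227 x 227 matrix.
#' @return 227 x 227 x 3 array with attributes `rescale_min`, `rescale_max`.
#' @export
prepare_input <- function(patch) {
  img <- if (inherits(patch, "roi_patch")) patch$image else patch
  if (!is.matrix(img) || !all(dim(img) == c(227L, 227L))) {
    stop("patch image must be a 227 x 227 matrix", call. = FALSE)
  }
  if (any(!is.finite(img))) {
    stop("patch contains non-finite pixels", call. = FALSE)
  }
  lo <- min(img)
  hi <- max(img)
  scaled <- if (hi > lo) (img - lo) / (hi - lo) else array(0, dim(img))
  out <- array(scaled, c(227L, 227L, 3L))
  attr(out, "rescale_min") <- lo
  attr(out, "rescale_max") <- hi
  out
}

#' Extract the 43,264-length pool2 feature vector of one ROI patch
#'
#' Runs the prepared patch through the extractor backend and flattens the
#' 13 x 13 x 256 output with the documented order
#' `index = (row*13 + col)*256 + channel` (all zero-based), i.e. channel
#' fastest, then activation-map column, then row. Feature identifiers are the
#' zero-based names `f0` ... `f43263` for a single timepoint.
#'
#' @param patch a [extract_roi()] result or 227 x 227 matrix.
#' @param extractor a [make_extractor()] object.
#' @param patient_id optional provenance.
#' @return An object of class `feature_vector`: `values` (named numeric,
#'   length 43,264), `patient_id`, `timepoints`.
#' @export
extract_features <- function(patch, extractor, patient_id = NA_character_) {
  stopifnot(inherits(extractor, "pool2_extractor"))
  x <- prepare_input(patch)
  out <- extractor$fun(x)
  if (!identical(dim(out), c(13L, 13L, 256L))) {
    stop("extractor contract violation: output is not 13 x 13 x 256",
         call. = FALSE)
  }
  # channel fastest, then col, then row: permute to (channel, col, row)
  values <- as.vector(aperm(out, c(3, 2, 1)))
  names(values) <- paste0("f", seq_along(values) - 1L)
  tp <- if (inherits(patch, "roi_patch")) patch$timepoint else NA_character_
  structure(list(values = values, patient_id = patient_id, timepoints = tp),
            class = "feature_vector")
}

#' Concatenate the T1 and T2 feature vectors of one patient
#'
#' The pre-treatment (T1) block occupies indices 0-43,263 and the
#' early-treatment (T2) block indices 43,264-86,527, giving 86,528 features
#' per patient. Passing `v2 = NULL` returns the single-timepoint vector
#' unchanged.
#'
#' @param v1 `feature_vector` at T1 (length 43,264).
#' @param v2 `feature_vector` at T2, or `NULL`.
#' @return A `feature_vector` of length 86,528 (names `f0` ... `f86527`) or
#'   the length-43,264 passthrough.
#' @export
concat_timepoints <- function(v1, v2 = NULL) {
  stopifnot(inherits(v1, "feature_vector"))
  if (is.null(v2)) return(v1)
  stopifnot(inherits(v2, "feature_vector"))
  if (length(v1$values) != 43264L || length(v2$values) != 43264L) {
    stop("each timepoint vector must have length 43264", call. = FALSE)
  }
  if (!is.na(v1$patient_id) && !is.na(v2$patient_id) &&
      v1$patient_id != v2$patient_id) {
    stop("cannot concatenate feature vectors of different patients",
         call. = FALSE)
  }
  values <- c(v1$values, v2$values)
  names(values) <- paste0("f", seq_along(values) - 1L)
  structure(list(values = values,
                 patient_id = v1$patient_id %|na|% v2$patient_id,
                 timepoints = c("T1", "T2")),
            class = "feature_vector")
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' Map a flat feature index back to its activation-map cell
#'
#' Inverts the flattening order: for a zero-based feature index (or a name
#' like `"f43264"`) returns the activation-map cell (row, col), the channel
#' (which 13 x 13 map) and the timepoint block — the information needed to
#' localize a selected feature on the ROI, since each activation-map cell
#' corresponds to a patch neighbourhood of the 227 x 227 input.
#'
#' @param index zero-based integer index in `[0, 86528)`, or feature name.
#' @return data.frame with zero-based `row`, `col`, `channel` and
#'   `timepoint` (`"T1"` or `"T2"`), one row per input index.
#' @examples
#' locate_feature(0)        # row 0, col 0, channel 0, T1
#' locate_feature("f43264") # the first T2 feature
#' @export
locate_feature <- function(index) {
  if (is.character(index)) index <- as.integer(sub("^f", "", index))
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 0) || any(index >= 86528L)) {
    stop("feature index out of range [0, 86528)", call. = FALSE)
  }
  tp <- ifelse(index < 43264L, "T1", "T2")
  within <- index %% 43264L
  row <- within %/% (13L * 256L)
  rem <- within %% (13L * 256L)
  data.frame(row = row, col = rem %/% 256L, channel = rem %% 256L,
             timepoint = tp, stringsAsFactors = FALSE)
}

#' Flat feature index of an activation-map cell
#'
#' The forward flattening map, inverse of [locate_feature()].
#'
#' @param row,col,channel zero-based cell coordinates (`0-12`, `0-12`,
#'   `0-255`).
#' @param timepoint `"T1"` or `"T2"`.
#' @return zero-based integer index.
#' @export
flatten_index <- function(row, col, channel, timepoint = "T1") {
  stopifnot(all(row >= 0 & row < 13), all(col >= 0 & col < 13),
            all(channel >= 0 & channel < 256),
            all(timepoint %in% c("T1", "T2")))
  (row * 13L + col) * 256L + channel + ifelse(timepoint == "T2", 43264L, 0L)
}
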