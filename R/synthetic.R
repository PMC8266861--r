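#' Configuration for a synthetic feature cohort
#'
#' Describes a two-class cohort of patients represented by a feature matrix in
#' which a known subset of columns carries a class signal. The informative
#' columns receive a Gaussian mean shift of `effect_size * noise_sd` in the
#' pCR class; all other columns are exchangeable between classes. This is the
#' ground-truth stand-in for the output of convolutional feature extraction,
#' used to calibrate and validate the stability feature selection downstream.
#'
#' @param n_pcr,n_nonpcr patients per class (each at least 2).
#' @param n_features number of feature columns.
#' @param informative_idx zero-based indices of the informative columns
#'   (must lie in `[0, n_features)`); they become columns named
#'   `f<informative_idx>`.
#' @param effect_size standardized mean shift (unitless, non-negative).
#' @param noise_sd standard deviation of the Gaussian feature noise.
#' @param seed master seed; one seed governs one cohort, and each patient row
#'   is drawn from its own substream so patient k's features do not depend on
#'   cohort size.
#' @return An object of class `synthetic_cohort_config`.
#' @seealso [gen_feature_cohort()]
#' @export
synthetic_cohort_config <- function(n_pcr = 30, n_nonpcr = 78,
                                    n_features = 1000,
                                    informative_idx = 0:9,
                                    effect_size = 3,
                                    noise_sd = 1,
                                    seed = 1) {
  if (n_pcr < 2 || n_nonpcr < 2) {
    stop("synthetic cohort needs at least 2 patients per class", call. = FALSE)
  }
  if (n_features < 1) stop("n_features must be positive", call. = FALSE)
  informative_idx <- sort(unique(as.integer(informative_idx)))
  if (length(informative_idx) &&
      (min(informative_idx) < 0 || max(informative_idx) >= n_features)) {
    stop("informative_idx must be a subset of [0, n_features)", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be non-negative", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  structure(
    list(n_pcr = as.integer(n_pcr), n_nonpcr = as.integer(n_nonpcr),
         n_features = as.integer(n_features),
         informative_idx = informative_idx,
         effect_size = effect_size, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_cohort_config"
  )
}

#' Generate a two-class feature cohort with planted discriminative columns
#'
#' Draws a `patients x n_features` Gaussian matrix and shifts the informative
#' columns of the pCR class by `effect_size * noise_sd`, so the class-mean
#' difference of every informative column equals the configured effect while
#' all remaining columns are class-exchangeable. Deterministic given the
#' config (including seed); patient rows come from counter-based substreams.
#'
#' @param config a [synthetic_cohort_config()].
#' @return list with `features` (matrix with rownames `P...` and zero-based
#'   column names `f0`, `f1`, ...), `labels` (factor, levels
#'   `c("non-pCR", "pCR")`), and `truth` (the informative column names).
#' @examples
#' cfg <- synthetic_cohort_config(n_pcr = 5, n_nonpcr = 5, n_features = 20,
#'                                informative_idx = 0:1, seed = 7)
#' cohort <- gen_feature_cohort(cfg)
#' dim(cohort$features)
#' @export
gen_feature_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  n <- config$n_pcr + config$n_nonpcr
  labels <- factor(rep(c("pCR", "non-pCR"), c(config$n_pcr, config$n_nonpcr)),
                   levels = c("non-pCR", "pCR"))
  X <- matrix(NA_real_, n, config$n_features)
  for (k in seq_len(n)) {
    X[k, ] <- with_seed(mix_seed(config$seed, 1L, k),
                        stats::rnorm(config$n_features, 0, config$noise_sd))
  }
  shift_cols <- config$informative_idx + 1L
  if (length(shift_cols)) {
    X[labels == "pCR", shift_cols] <-
      X[labels == "pCR", shift_cols] + config$effect_size * config$noise_sd
  }
  colnames(X) <- paste0("f", seq_len(config$n_features) - 1L)
  rownames(X) <- sprintf("P%03d", seq_len(n))
  names(labels) <- rownames(X)
  list(features = X, labels = labels,
       truth = paste0("f", config$informative_idx))
}

#' Configuration for a DCE-MRI phantom patient
#'
#' An ellipsoidal tumor inside a uniform-background volume, imaged as one
#' pre-contrast and two post-contrast acquisitions (nominally ~2.5 and ~7.5
#' minutes after injection). Contrast uptake is modelled as a multiplicative
#' gain applied to tumor voxels at each post-contrast acquisition, with the
#' gain pair depending on response class; tissue texture is additive Gaussian
#' noise. No MR physics (coil profiles, bias fields, pharmacokinetics) is
#' modelled — the phantom exists to exercise enhancement-map segmentation and
#' ROI geometry against a known mask.
#'
#' @param volume_shape integer vector (slices, rows, cols).
#' @param pixel_spacing in-plane spacing in mm/pixel.
#' @param tumor_center voxel coordinates (slice, row, col), 1-based.
#' @param tumor_radii ellipsoid semi-axes in voxels (slice, row, col).
#' @param enhancement_pcr,enhancement_nonpcr length-2 positive gains applied
#'   to tumor voxels at the two post-contrast acquisitions for each class.
#' @param texture_sd additive noise standard deviation as a fraction of the
#'   background intensity.
#' @param base_intensity pre-contrast background signal level.
#' @param seed master seed for this patient's noise streams.
#' @return An object of class `synthetic_phantom_config`.
#' @export
synthetic_phantom_config <- function(volume_shape = c(24, 64, 64),
                                     pixel_spacing = 1,
                                     tumor_center = NULL,
                                     tumor_radii = c(5, 10, 10),
                                     enhancement_pcr = c(1.9, 1.6),
                                     enhancement_nonpcr = c(2.6, 2.2),
                                     texture_sd = 0.02,
                                     base_intensity = 100,
                                     seed = 1) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape < 1)) {
    stop("volume_shape must be three positive integers", call. = FALSE)
  }
  if (is.null(tumor_center)) tumor_center <- ceiling(volume_shape / 2)
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive", call. = FALSE)
  if (any(enhancement_pcr <= 0) || any(enhancement_nonpcr <= 0)) {
    stop("enhancement gains must be positive", call. = FALSE)
  }
  if (length(enhancement_pcr) != 2 || length(enhancement_nonpcr) != 2) {
    stop("each class needs two post-contrast gains", call. = FALSE)
  }
  if (any(tumor_center - tumor_radii < 1) ||
      any(tumor_center + tumor_radii > volume_shape)) {
    stop("tumor does not fit inside the volume", call. = FALSE)
  }
  structure(
    list(volume_shape = volume_shape, pixel_spacing = pixel_spacing,
         tumor_center = tumor_center, tumor_radii = tumor_radii,
         enhancement_pcr = enhancement_pcr,
         enhancement_nonpcr = enhancement_nonpcr,
         texture_sd = texture_sd, base_intensity = base_intensity,
         seed = as.integer(seed)),
    class = "synthetic_phantom_config"
  )
}

#' Generate one phantom DCE patient
#'
#' Builds the pre-contrast volume (background plus texture noise), applies the
#' class's multiplicative gains to tumor voxels for the two post-contrast
#' volumes (each with its own acquisition noise), and returns the ground-truth
#' ellipsoid mask together with the clinical-report largest diameter:
#' `LD = max in-plane pairwise extent of the mask x pixel_spacing`.
#'
#' @param config a [synthetic_phantom_config()].
#' @param label `"pCR"` or `"non-pCR"` — selects the gain pair.
#' @return list with `series` (a [dce_series()]), `mask` (logical array) and
#'   `ld_mm` (numeric).
#' @export
gen_dce_patient <- function(config, label = c("pCR", "non-pCR")) {
  stopifnot(inherits(config, "synthetic_phantom_config"))
  label <- match.arg(label)
  gains <- if (label == "pCR") config$enhancement_pcr else config$enhancement_nonpcr
  shp <- config$volume_shape
  ctr <- config$tumor_center
  rad <- config$tumor_radii
  z <- slice.index(array(0, shp), 1)
  r <- slice.index(array(0, shp), 2)
  cc <- slice.index(array(0, shp), 3)
  mask <- ((z - ctr[1]) / rad[1])^2 + ((r - ctr[2]) / rad[2])^2 +
    ((cc - ctr[3]) / rad[3])^2 <= 1
  nvox <- prod(shp)
  sd_abs <- config$texture_sd * config$base_intensity
  pre <- config$base_intensity +
    with_seed(mix_seed(config$seed, 11L), stats::rnorm(nvox, 0, sd_abs))
  pre <- array(pmax(pre, 0), shp)
  post <- lapply(1:2, function(j) {
    v <- pre * (1 + (gains[j] - 1) * mask) +
      with_seed(mix_seed(config$seed, 12L, j), stats::rnorm(nvox, 0, sd_abs))
    array(pmax(v, 0), shp)
  })
  list(series = dce_series(pre, post[[1]], post[[2]], config$pixel_spacing),
       mask = mask,
       ld_mm = mask_largest_diameter(mask, config$pixel_spacing))
}

#' Largest in-plane diameter of a tumor mask
#'
#' For every slice the maximal pairwise Euclidean distance between in-slice
#' mask voxel centres is computed (via the convex hull); the largest such
#' extent across slices, scaled by the pixel spacing, is the phantom's
#' clinical-report LD.
#'
#' @param mask logical 3-D array (slices, rows, cols).
#' @param pixel_spacing in-plane mm/pixel.
#' @return LD in mm (0 for an empty mask).
#' @export
mask_largest_diameter <- function(mask, pixel_spacing = 1) {
  stopifnot(length(dim(mask)) == 3)
  best <- 0
  for (s in seq_len(dim(mask)[1])) {
    sl <- mask[s, , ]
    pts <- which(sl, arr.ind = TRUE)
    if (nrow(pts) == 0) next
    if (nrow(pts) > 2) pts <- pts[grDevices::chull(pts), , drop = FALSE]
    d <- max(stats::dist(pts), 0)
    if (d > best) best <- d
  }
  best * pixel_spacing
}

#' Generate a synthetic clinical table with a known class association
#'
#' Emulates the clinical covariates of a neoadjuvant-chemotherapy cohort:
#' `age` (continuous) and `race` are class-independent; hormone-receptor and
#' HER2 status are drawn with class-dependent probabilities interpolated by
#' `assoc_strength` (0 = identical distributions, 1 = full planted effect),
#' and `subtype` (Luminal / HER2+ / Triple Negative) is derived from
#' ER/PgR/HER2 so its class association flows from theirs — mirroring the
#' clinical fact that pCR rates are higher in Triple Negative and HER2+
#' tumors than in luminal ones.
#'
#' @param n_pcr,n_nonpcr patients per class (at least 1 each).
#' @param assoc_strength in `[0, 1]`; 0 removes every class effect.
#' @param seed master seed.
#' @return data.frame with columns `patient_id`, `pcr` (factor
#'   `non-pCR`/`pCR`), `age`, `race`, `er`, `pgr`, `her2` (factors
#'   `neg`/`pos`) and `subtype`.
#' @export
gen_clinical_table <- function(n_pcr, n_nonpcr, assoc_strength = 1, seed = 1) {
  if (n_pcr < 1 || n_nonpcr < 1) {
    stop("both classes need at least one patient", call. = FALSE)
  }
  if (assoc_strength < 0 || assoc_strength > 1) {
    stop("assoc_strength must lie in [0, 1]", call. = FALSE)
  }
  n <- n_pcr + n_nonpcr
  pcr <- factor(rep(c("pCR", "non-pCR"), c(n_pcr, n_nonpcr)),
                levels = c("non-pCR", "pCR"))
  # receptor-positivity probabilities; the pCR column interpolates toward the
  # planted effect with assoc_strength
  p_non <- c(er = 0.62, pgr = 0.52, her2 = 0.23)
  p_pcr_full <- c(er = 0.25, pgr = 0.20, her2 = 0.50)
  p_pcr <- (1 - assoc_strength) * p_non + assoc_strength * p_pcr_full
  draw <- function(k, var) {
    pr <- if (pcr[k] == "pCR") p_pcr[[var]] else p_non[[var]]
    stats::rbinom(1, 1, pr)
  }
  rows <- lapply(seq_len(n), function(k) {
    with_seed(mix_seed(seed, 21L, k), {
      age <- stats::rnorm(1, 48.5, 9)
      race <- sample(c("Caucasian", "African American", "Asian", "Other"),
                     1, prob = c(0.76, 0.16, 0.05, 0.03))
      er <- draw(k, "er"); pgr <- draw(k, "pgr"); her2 <- draw(k, "her2")
      data.frame(age = age, race = race, er = er, pgr = pgr, her2 = her2,
                 stringsAsFactors = FALSE)
    })
  })
  tab <- do.call(rbind, rows)
  subtype <- ifelse(tab$her2 == 1, "HER2+",
                    ifelse(tab$er == 1 | tab$pgr == 1,
                           "Luminal", "Triple Negative"))
  out <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    pcr = pcr,
    age = tab$age,
    race = factor(tab$race,
                  levels = c("Caucasian", "African American", "Asian", "Other")),
    er = factor(ifelse(tab$er == 1, "pos", "neg"), levels = c("neg", "pos")),
    pgr = factor(ifelse(tab$pgr == 1, "pos", "neg"), levels = c("neg", "pos")),
    her2 = factor(ifelse(tab$her2 == 1, "pos", "neg"), levels = c("neg", "pos")),
    subtype = factor(subtype,
                     levels = c("Luminal", "HER2+", "Triple Negative")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$patient_id
  out
}
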