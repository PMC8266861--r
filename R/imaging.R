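#' A single patient-timepoint DCE acquisition
#'
#' Bundles the pre-contrast volume with the two post-contrast volumes
#' (nominally ~2.5 and ~7.5 minutes after contrast injection) and the
#' in-plane pixel spacing. Volumes are 3-D arrays indexed (slice, row, col)
#' and must share a shape; intensities are non-negative.
#'
#' @param pre,post1,post2 numeric 3-D arrays of identical shape.
#' @param pixel_spacing in-plane spacing, mm/pixel (> 0).
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(pre, post1, post2, pixel_spacing) {
  dims <- dim(pre)
  if (length(dims) != 3) stop("volumes must be 3-D arrays", call. = FALSE)
  if (!identical(dims, dim(post1)) || !identical(dims, dim(post2))) {
    stop("pre/post volumes must share a shape", call. = FALSE)
  }
  if (min(pre, post1, post2) < 0) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1 ||
      pixel_spacing <= 0) {
    stop("pixel_spacing must be a positive scalar", call. = FALSE)
  }
  structure(list(pre = pre, post1 = post1, post2 = post2,
                 pixel_spacing = pixel_spacing),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  cat("<dce_series> ", paste(dim(x$pre), collapse = " x "),
      " voxels, ", x$pixel_spacing, " mm/pixel in-plane\n", sep = "")
  invisible(x)
}

#' Semi-quantitative enhancement maps (PE and SER)
#'
#' Peak enhancement `PE = (post1 - pre) / pre` and signal enhancement ratio
#' `SER = (post1 - pre) / (post2 - pre)`, the two pharmacokinetic surrogates
#' thresholded during tumor segmentation. Voxels whose denominator is
#' non-positive carry `NA` in the corresponding map and `FALSE` in the
#' validity masks, and are excluded from any thresholding.
#'
#' @param series a [dce_series()].
#' @return list of class `enhancement_maps` with `pe`, `ser` (numeric arrays,
#'   `NA` where invalid) and `pe_valid`, `ser_valid` (logical arrays).
#' @examples
#' v <- function(x) array(x, c(1, 2, 2))
#' m <- compute_enhancement_maps(dce_series(v(100), v(200), v(150), 1))
#' m$pe[1, 1, 1]   # 1.0
#' m$ser[1, 1, 1]  # 2.0
#' @export
compute_enhancement_maps <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  pe_valid <- series$pre > 0
  ser_valid <- pe_valid & (series$post2 - series$pre) > 0
  pe <- (series$post1 - series$pre) / series$pre
  pe[!pe_valid] <- NA_real_
  ser <- (series$post1 - series$pre) / (series$post2 - series$pre)
  ser[!ser_valid] <- NA_real_
  structure(list(pe = pe, ser = ser,
                 pe_valid = pe_valid, ser_valid = ser_valid),
            class = "enhancement_maps")
}

# largest 6-connected component of a logical 3-D array (igraph components
# over the voxel adjacency graph; ties broken by lowest voxel index)
largest_component_3d <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  if (length(idx) <= 1) return(mask)
  edges <- NULL
  strides <- c(1L, dims[1], dims[1] * dims[2])
  pos <- arrayInd(idx, dims)
  inmask <- logical(prod(dims))
  inmask[idx] <- TRUE
  for (ax in 1:3) {
    ok <- pos[, ax] < dims[ax]
    nb <- idx[ok] + strides[ax]
    keep <- inmask[nb]
    if (any(keep)) edges <- rbind(edges, cbind(idx[ok][keep], nb[keep]))
  }
  vid <- as.character(idx)
  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) data.frame(from = character(), to = character())
        else data.frame(from = as.character(edges[, 1]),
                        to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = vid)
  )
  comp <- igraph::components(g)
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1) {
    # tie: keep the component containing the lowest voxel index
    first_members <- vapply(biggest, function(b) {
      min(as.numeric(names(comp$membership)[comp$membership == b]))
    }, numeric(1))
    biggest <- biggest[which.min(first_members)]
  }
  keep_idx <- as.numeric(names(comp$membership)[comp$membership == biggest])
  out <- array(FALSE, dims)
  out[keep_idx] <- TRUE
  out
}

#' Segment the tumor by thresholding enhancement maps
#'
#' Inside a seed region (a radiologist-style box or coarse mask), voxels with
#' `PE > pe_threshold` and `SER` inside `ser_range` are retained and the
#' largest 6-connected component becomes the tumor mask. The thresholds are
#' configuration parameters: they stand in for the enhancement-threshold
#' segmentation used on clinical DCE data, whose exact cut-offs are
#' protocol-specific.
#'
#' @param series a [dce_series()].
#' @param seed_region logical array aligned to the series, or a list
#'   `list(lo = c(slice, row, col), hi = c(slice, row, col))` describing an
#'   inclusive box.
#' @param pe_threshold retain voxels with peak enhancement strictly above
#'   this value (default 0.7; arbitrary desk-scale default).
#' @param ser_range inclusive SER interval, default `c(0.9, Inf)`.
#' @return A logical tumor mask (class `tumor_mask` attribute-free array).
#' @export
segment_tumor <- function(series, seed_region, pe_threshold = 0.7,
                          ser_range = c(0.9, Inf)) {
  stopifnot(inherits(series, "dce_series"))
  dims <- dim(series$pre)
  if (is.list(seed_region) && !is.array(seed_region)) {
    lo <- pmax(as.integer(seed_region$lo), 1L)
    hi <- pmin(as.integer(seed_region$hi), dims)
    box <- array(FALSE, dims)
    box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    seed_region <- box
  }
  if (!identical(dim(seed_region), dims)) {
    stop("seed_region must align with the series volumes", call. = FALSE)
  }
  if (!any(seed_region)) stop("seed_region is empty", call. = FALSE)
  maps <- compute_enhancement_maps(series)
  cand <- seed_region & maps$pe_valid & maps$ser_valid &
    !is.na(maps$pe) & maps$pe > pe_threshold &
    !is.na(maps$ser) & maps$ser >= ser_range[1] & maps$ser <= ser_range[2]
  cand[is.na(cand)] <- FALSE
  if (!any(cand)) {
    stop("segmentation failure: no voxel passed the enhancement thresholds ",
         "(pe_threshold = ", pe_threshold, ", ser_range = [",
         ser_range[1], ", ", ser_range[2], "])", call. = FALSE)
  }
  largest_component_3d(cand)
}

#' Extract the LD-sized ROI patch and resize it to 227 x 227
#'
#' Picks the slice with the largest in-slice tumor area (ties to the lowest
#' slice index), centres a square window of side
#' `ld_px = round(ld_mm / pixel_spacing)` (minimum 8 px, rounding half-up) on
#' the rounded mask centroid in that slice, crops the FIRST post-contrast
#' volume with zero padding past the borders, and bilinearly resizes the crop
#' to 227 x 227. The window is half-open: it spans
#' `[centre - floor(ld_px/2), centre - floor(ld_px/2) + ld_px)` in each axis.
#'
#' @param series a [dce_series()].
#' @param mask logical tumor mask aligned to the series.
#' @param ld_mm clinical-report largest diameter in mm.
#' @param timepoint `"T1"` (pre-treatment) or `"T2"` (early-treatment);
#'   provenance only.
#' @return An object of class `roi_patch`: `image` (227 x 227 matrix),
#'   `source_slice`, `center` (row, col), `ld_mm`, `ld_px`, `timepoint`.
#' @export
extract_roi <- function(series, mask, ld_mm, timepoint = c("T1", "T2")) {
  stopifnot(inherits(series, "dce_series"))
  timepoint <- match.arg(timepoint)
  if (!identical(dim(mask), dim(series$pre))) {
    stop("mask must align with the series volumes", call. = FALSE)
  }
  if (!any(mask)) stop("tumor mask is empty", call. = FALSE)
  areas <- apply(mask, 1, sum)
  s <- which.max(areas)  # ties -> lowest index
  sl_mask <- mask[s, , ]
  pts <- which(sl_mask, arr.ind = TRUE)
  center <- round_half_up(colMeans(pts))
  ld_px <- max(8L, as.integer(round_half_up(ld_mm / series$pixel_spacing)))
  half <- floor(ld_px / 2)
  r0 <- center[1] - half
  c0 <- center[2] - half
  src <- series$post1[s, , ]
  crop <- matrix(0, ld_px, ld_px)
  rr <- r0:(r0 + ld_px - 1)
  cc <- c0:(c0 + ld_px - 1)
  rok <- rr >= 1 & rr <= nrow(src)
  cok <- cc >= 1 & cc <= ncol(src)
  crop[rok, cok] <- src[rr[rok], cc[cok]]
  structure(
    list(image = bilinear_resize(crop, 227L, 227L),
         source_slice = s,
         center = as.integer(center),
         ld_mm = ld_mm,
         ld_px = ld_px,
         timepoint = timepoint),
    class = "roi_patch"
  )
}

#' @export
print.roi_patch <- function(x, ...) {
  cat("<roi_patch> ", x$timepoint, ", slice ", x$source_slice,
      ", center (", x$center[1], ", ", x$center[2], "), LD ",
      x$ld_mm, " mm (", x$ld_px, " px)\n", sep = "")
  invisible(x)
}

#' Dice overlap between two masks
#'
#' @param a,b logical arrays of identical shape.
#' @return `2|A∩B| / (|A|+|B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
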