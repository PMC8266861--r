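# Enhancement maps, segmentation and ROI geometry.

vol <- function(x, shp = c(1, 2, 2)) array(x, shp)

test_that("PE and SER follow the enhancement arithmetic", {
  m <- compute_enhancement_maps(dce_series(vol(100), vol(200), vol(150), 1))
  expect_equal(m$pe[1, 1, 1], 1.0)
  expect_equal(m$ser[1, 1, 1], 2.0)

  s <- dce_series(vol(100), vol(100), vol(150), 1)
  expect_true(all(compute_enhancement_maps(s)$pe == 0))
})

test_that("non-positive denominators are flagged invalid and excluded", {
  pre <- vol(c(0, 100, 100, 100))
  post2 <- vol(c(150, 90, 150, 150))  # voxel 2: post2 - pre < 0
  m <- compute_enhancement_maps(dce_series(pre, vol(200), post2, 1))
  expect_false(m$pe_valid[1, 1, 1])
  expect_true(is.na(m$pe[1, 1, 1]))
  expect_false(m$ser_valid[1, 2, 1])
  expect_true(is.na(m$ser[1, 2, 1]))
  expect_true(m$pe_valid[1, 2, 1])  # PE only needs pre > 0
})

test_that("segmentation recovers the planted phantom mask", {
  pat <- gen_dce_patient(tiny_phantom(seed = 5), "non-pCR")
  seg <- segment_tumor(pat$series,
                       list(lo = c(1, 1, 1), hi = dim(pat$series$pre)))
  expect_gte(dice_coefficient(seg, pat$mask), 0.9)

  pat2 <- gen_dce_patient(tiny_phantom(seed = 6), "pCR")
  seg2 <- segment_tumor(pat2$series,
                        list(lo = c(1, 1, 1), hi = dim(pat2$series$pre)))
  expect_gte(dice_coefficient(seg2, pat2$mask), 0.9)
})

test_that("impossible thresholds raise a segmentation-failure error", {
  pat <- gen_dce_patient(tiny_phantom(seed = 5), "non-pCR")
  maps <- compute_enhancement_maps(pat$series)
  too_high <- max(maps$pe, na.rm = TRUE) + 1
  expect_error(
    segment_tumor(pat$series, list(lo = c(1, 1, 1), hi = dim(pat$series$pre)),
                  pe_threshold = too_high),
    "segmentation failure")
  expect_error(
    segment_tumor(pat$series, array(FALSE, dim(pat$series$pre))),
    "empty")
})

test_that("segmentation keeps only the largest connected component", {
  shp <- c(3, 20, 20)
  pre <- array(100, shp)
  post1 <- array(100, shp)
  post2 <- array(100, shp)
  big <- array(FALSE, shp); big[2, 3:8, 3:8] <- TRUE
  small <- array(FALSE, shp); small[2, 15:16, 15:16] <- TRUE
  enh <- big | small
  post1[enh] <- 300
  post2[enh] <- 200
  seg <- segment_tumor(dce_series(pre, post1, post2, 1),
                       list(lo = c(1, 1, 1), hi = shp))
  expect_true(all(seg[big]))
  expect_false(any(seg[small]))
})

# a series whose first post-contrast slice holds distinct linear-ramp values
ramp_series <- function(nr = 128, nc = 128) {
  sl <- outer(seq_len(nr), seq_len(nc), function(r, c) r * 1000 + c)
  pre <- array(1, c(1, nr, nc))
  post1 <- array(sl, c(1, nr, nc))
  post2 <- array(3, c(1, nr, nc))
  dce_series(pre, post1, post2, 1)
}

square_mask <- function(nr, nc, rows, cols) {
  m <- array(FALSE, c(1, nr, nc))
  m[1, rows, cols] <- TRUE
  m
}

test_that("ROI crop is the centered half-open window of the first post-contrast", {
  s <- ramp_series()
  mask <- square_mask(128, 128, 61:69, 61:69)  # centroid (65, 65)
  roi <- extract_roi(s, mask, ld_mm = 32, timepoint = "T1")
  expect_equal(roi$ld_px, 32L)
  expect_equal(roi$center, c(65L, 65L))
  expect_identical(dim(roi$image), c(227L, 227L))
  # corner-aligned resize maps patch corners onto crop corners exactly:
  # window = [center - 16, center + 16) = rows/cols 49..80
  src <- s$post1[1, , ]
  expect_equal(roi$image[1, 1], src[49, 49])
  expect_equal(roi$image[227, 227], src[80, 80])
  expect_equal(roi$image[1, 227], src[49, 80])
})

test_that("crops past the border are zero-padded", {
  s <- ramp_series(64, 64)
  mask <- square_mask(64, 64, 2:4, 2:4)  # centroid (3, 3)
  roi <- extract_roi(s, mask, ld_mm = 16, timepoint = "T2")
  # window rows/cols [-5, 11): the top-left of the patch is padding
  expect_equal(roi$image[1, 1], 0)
  expect_equal(roi$image[227, 227], s$post1[1, 10, 10])
  expect_equal(roi$timepoint, "T2")
})

test_that("resize preserves constants and ramp extremes", {
  s <- dce_series(array(1, c(1, 40, 40)), array(7.5, c(1, 40, 40)),
                  array(9, c(1, 40, 40)), 1)
  mask <- square_mask(40, 40, 15:25, 15:25)
  roi <- extract_roi(s, mask, ld_mm = 10, timepoint = "T1")
  expect_true(all(roi$image == 7.5))

  r <- ramp_series(64, 64)
  mask2 <- square_mask(64, 64, 25:39, 25:39)
  roi2 <- extract_roi(r, mask2, ld_mm = 15, timepoint = "T1")
  crop <- r$post1[1, 25:39, 25:39]
  expect_lt(abs(max(roi2$image) - max(crop)), 1e-6)
  expect_lt(abs(min(roi2$image) - min(crop)), 1e-6)
})

test_that("ROI extraction is translation-covariant", {
  s <- ramp_series(96, 96)
  mask <- square_mask(96, 96, 41:49, 41:49)
  roi_a <- extract_roi(s, mask, ld_mm = 20, timepoint = "T1")
  # shift image content and mask together by (+4, +7) voxels
  sl <- s$post1[1, , ]
  shifted <- array(0, c(1, 96, 96))
  shifted[1, 5:96, 8:96] <- sl[1:92, 1:89]
  s2 <- dce_series(s$pre, shifted, s$post2, 1)
  mask2 <- square_mask(96, 96, 45:53, 48:56)
  roi_b <- extract_roi(s2, mask2, ld_mm = 20, timepoint = "T1")
  expect_equal(roi_b$image, roi_a$image)
})

test_that("slice choice, LD floor and empty-mask handling", {
  shp <- c(4, 40, 40)
  m <- array(FALSE, shp)
  m[2, 10:20, 10:20] <- TRUE   # area 121
  m[3, 5:25, 5:15] <- TRUE     # area 231 -> chosen
  s <- dce_series(array(1, shp), array(outer(1:40, 1:40), c(4, 40, 40)),
                  array(3, shp), 1)
  roi <- extract_roi(s, m, ld_mm = 12, timepoint = "T1")
  expect_equal(roi$source_slice, 3L)

  # tie in area -> lowest slice index
  m2 <- array(FALSE, shp)
  m2[2, 10:20, 10:20] <- TRUE
  m2[4, 10:20, 10:20] <- TRUE
  expect_equal(extract_roi(s, m2, 12, "T1")$source_slice, 2L)

  # LD below 8 px is floored
  expect_equal(extract_roi(s, m, ld_mm = 2, timepoint = "T1")$ld_px, 8L)
  expect_error(extract_roi(s, array(FALSE, shp), 12, "T1"), "empty")
})
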