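# RPU quantification: disk regions, the normalization equation,
# representative-frame averaging, reference validation.

test_that("the default region is exactly 317 pixels inside the map", {
  m <- matrix(runif(100 * 100), 100, 100)
  rs <- extract_region(m, c(50, 50))
  expect_identical(nrow(rs$pixels), 317L)
  expect_identical(rs$area_px, 317L)
  # all pixels unique and within bounds
  expect_identical(nrow(unique(as.data.frame(rs$pixels))), 317L)
  expect_true(all(rs$pixels >= 1 & rs$pixels <= 100))
  # the region is a disk: max radius just over the area-equivalent radius
  rad <- sqrt((rs$pixels[, 1] - 50)^2 + (rs$pixels[, 2] - 50)^2)
  expect_lt(max(rad), sqrt(317 / pi) + 1.5)
})

test_that("region means are exact on uniform maps and match a brute-force pick", {
  expect_equal(extract_region(matrix(3.7, 50, 50), c(25, 25))$mean_raw, 3.7)
  # 5-pixel region on a 5x5 map with values 1..25 laid out left-to-right:
  # nearest five pixels to the center are the center and its 4-neighbours
  m <- matrix(1:25, 5, 5, byrow = TRUE)
  rs <- extract_region(m, c(3, 3), area_px = 5)
  nearest <- c(m[3, 3], m[2, 3], m[4, 3], m[3, 2], m[3, 4])
  expect_equal(rs$mean_raw, mean(nearest))
})

test_that("regions clipping the border fail and name the offending center", {
  m <- matrix(1, 30, 30)
  expect_error(extract_region(m, c(5, 15)), "\\(5, 15\\)")
  expect_silent(extract_region(m, c(15, 15)))
})

test_that("the RPU equation anchors Hot at 100 and Cold at 0", {
  refs <- reference_pair(8.4, 1.2)
  expect_identical(compute_rpu(8.4, refs), 100)
  expect_identical(compute_rpu(1.2, refs), 0)
  expect_equal(compute_rpu((8.4 + 1.2) / 2, refs), 50)
  # no clipping: brighter than Hot exceeds 100, darker than Cold is negative
  expect_gt(compute_rpu(9, refs), 100)
  expect_lt(compute_rpu(1, refs), 0)
})

test_that("swapped or equal references raise a degenerate-reference error", {
  expect_error(reference_pair(1.2, 8.4), "degenerate")
  expect_error(reference_pair(5, 5), "degenerate")
})

test_that("RPU is invariant to affine rescaling of the raw scale", {
  set.seed(31)
  for (i in 1:25) {
    cold <- runif(1, 0.5, 2); hot <- cold + runif(1, 0.5, 120)
    roi <- runif(1, cold - 1, hot + 1)
    a <- runif(1, -5, 5); b <- runif(1, 0.1, 10)
    r0 <- compute_rpu(roi, reference_pair(hot, cold))
    r1 <- compute_rpu(a + b * roi, reference_pair(a + b * hot, a + b * cold))
    expect_equal(r1, r0, tolerance = 1e-9)
  }
})

test_that("frame averaging over representative frames is plain arithmetic", {
  # maps engineered so the ROI raw value differs per frame while references
  # stay fixed: per-frame RPUs 40, 50, 60, 50, 50 must average to 50
  mk <- function(roi_val) {
    m <- matrix(1, 60, 90)
    m[, 61:90] <- 10                    # hot block
    m[11:31, 35:55] <- roi_val          # roi block
    m
  }
  rpus <- c(40, 50, 60, 50, 50)
  maps <- lapply(1 + 9 * rpus / 100, mk)  # roi raw = cold + rpu% of span
  refs <- list(hot = c(30, 75), cold = c(45, 11))
  res <- rpu_over_frames(maps, refs, roi_center = c(21, 45), n = 5,
                         selector = function(n_avail, n) seq_len(n))
  expect_equal(res$per_frame$rpu, rpus, tolerance = 1e-9)
  expect_equal(res$mean_rpu, 50, tolerance = 1e-9)
})

test_that("constant sequences and n = 1 reduce to single-frame RPU", {
  m <- matrix(1, 60, 90); m[, 61:90] <- 10; m[11:31, 35:55] <- 5.5
  refs <- list(hot = c(30, 75), cold = c(45, 11))
  single <- compute_rpu(extract_region(m, c(21, 45)),
                        reference_pair(extract_region(m, c(30, 75)),
                                       extract_region(m, c(45, 11))))
  res5 <- rpu_over_frames(rep(list(m), 6), refs, c(21, 45), n = 5)
  expect_equal(res5$mean_rpu, single)
  res1 <- rpu_over_frames(rep(list(m), 2), refs, c(21, 45), n = 1)
  expect_equal(res1$mean_rpu, single)
  expect_error(rpu_over_frames(list(m), refs, c(21, 45), n = 5), "frames")
})

test_that("the uniform frame selector spreads n frames over the window", {
  sel <- frame_selector_uniform(60)
  expect_identical(sel(120, 5), as.integer(round(seq(1, 60, length.out = 5))))
  expect_identical(sel(10, 5), as.integer(round(seq(1, 10, length.out = 5))))
  expect_identical(sel(5, 5), 1:5)
})

test_that("reference validation reports separation and warns when weak", {
  m <- matrix(runif(80 * 80, 1, 2), 80, 80)
  m[30:50, 30:50] <- 90
  hot <- extract_region(m, c(40, 40))
  cold <- extract_region(m, c(15, 15))
  expect_silent(rep_ok <- validate_references(reference_pair(hot, cold), m))
  expect_length(rep_ok$warnings, 0)
  expect_gt(rep_ok$hot_percentile, 90)
  # a barely-warmer reference: separation far below half the map range
  m[5:25, 50:70] <- 3
  weak <- reference_pair(extract_region(m, c(15, 60)), cold)
  expect_warning(rep_weak <- validate_references(weak, m), "separation")
  expect_gt(length(rep_weak$warnings), 0)
})
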