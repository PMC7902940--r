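# IHC quantification: 8-bit conversion, whole-image histogram statistics,
# mode - k*SD thresholding, percent-positive area, object counting.

test_that("RGB to 8-bit gray is the unweighted channel mean, rounded half up", {
  # channel-equal identity across the full range
  v <- 0:255
  rgb <- array(rep(v, 3), c(length(v), 1, 3))
  expect_equal(as.vector(rgb_to_gray8(rgb)), v)
  # pure red pixel: (255 + 0 + 0) / 3 = 85
  expect_equal(rgb_to_gray8(array(c(255, 0, 0), c(1, 1, 3)))[1, 1], 85L)
  # random fixture vs a scalar per-pixel loop
  set.seed(11)
  rgb <- array(sample(0:255, 4 * 4 * 3, TRUE), c(4, 4, 3))
  got <- rgb_to_gray8(rgb)
  for (i in 1:4) for (j in 1:4) {
    expect_identical(got[i, j],
                     as.integer(floor(mean(rgb[i, j, ]) + 0.5)))
  }
  expect_error(rgb_to_gray8(array(0, c(2, 2, 4))), "3")
})

test_that("whole-image statistics match a direct-summation oracle", {
  # degenerate constant image
  st <- image_stats(matrix(200L, 5, 5))
  expect_equal(st$mean, 200); expect_equal(st$median, 200)
  expect_equal(st$mode, 200); expect_equal(st$sd, 0)
  # small arithmetic case: eight pixels at 200, two at 100
  st <- image_stats(matrix(c(rep(200L, 8), rep(100L, 2)), 2, 5))
  expect_equal(st$mode, 200)
  expect_equal(st$mean, 180)
  # random fixture vs brute force (population SD)
  set.seed(3)
  px <- matrix(sample(0:255, 400, TRUE), 20, 20)
  st <- image_stats(px)
  v <- as.vector(px)
  expect_equal(st$mean, sum(v) / length(v), tolerance = 1e-9)
  expect_equal(st$median, stats::median(v), tolerance = 1e-9)
  expect_equal(st$sd, sqrt(sum((v - mean(v))^2) / length(v)), tolerance = 1e-9)
  counts <- table(v)
  expect_equal(max(counts[as.character(st$mode)]), max(counts))
})

test_that("mode ties break toward the brighter (background) level", {
  px <- matrix(c(rep(50L, 4), rep(220L, 4), 130L), 3, 3)
  expect_equal(image_stats(px)$mode, 220)
})

test_that("threshold is mode - k*SD, clamped to the gray range", {
  st <- structure(list(mean = 195, median = 200, mode = 200, sd = 10),
                  class = "histogram_stats")
  expect_equal(compute_threshold(st, 2)$threshold, 180)
  low <- structure(list(mean = 25, median = 20, mode = 20, sd = 10),
                   class = "histogram_stats")
  expect_equal(compute_threshold(low, 3)$threshold, 0)
  # fixed per-antibody multipliers used across a staining series
  expect_equal(compute_threshold(st, "MBP")$k, 2.0)
  expect_equal(compute_threshold(st, "GFAP")$k, 2.5)
  expect_equal(compute_threshold(st, "Iba1")$k, 3.0)
  expect_error(compute_threshold(st, 0), "> 0")
  expect_error(compute_threshold(st, "DAPI"), "antibody")
})

test_that("percent positive area counts pixels at or below the threshold", {
  img <- matrix(50L, 8, 8)
  roi <- matrix(TRUE, 8, 8)
  expect_equal(positive_area_fraction(img, roi, 180), 100)
  expect_equal(positive_area_fraction(matrix(200L, 8, 8), roi, 180), 0)
  # inclusive at the threshold
  expect_equal(positive_area_fraction(matrix(180L, 8, 8), roi, 180), 100)
  expect_error(positive_area_fraction(img, matrix(FALSE, 8, 8), 180), "empty")
  expect_error(positive_area_fraction(img, matrix(TRUE, 4, 4), 180), "shape")
})

test_that("recovered area fraction matches the planted ground truth", {
  for (seed in 1:3) {
    sim <- simulate_ihc_image(ihc_sim_params(image_shape = c(256, 256),
                                             seed = seed))
    thr <- compute_threshold(image_stats(sim$image), "GFAP")
    rec <- positive_area_fraction(sim$image, matrix(TRUE, 256, 256),
                                  thr$threshold)
    expect_lt(abs(rec - 100 * sim$planted_fraction), 1)
  }
})

test_that("object counting applies the strict size filter", {
  expect_equal(count_objects(matrix(FALSE, 10, 10)), 0)
  # 16x16 = 256 px counts; 15x15 = 225 px does not (both vs the 250 filter)
  m <- matrix(FALSE, 40, 40)
  m[2:17, 2:17] <- TRUE
  m[22:36, 22:36] <- TRUE
  expect_equal(count_objects(m, 250), 1)
  # exactly 250 px is not "above 250"
  sq <- matrix(FALSE, 30, 30)
  sq[3:27, 3:12] <- TRUE  # 25 x 10 = 250 px
  expect_equal(count_objects(sq, 250), 0)
  expect_equal(count_objects(sq, 249), 1)
})

test_that("component counts agree with the flood-fill oracle", {
  for (seed in 1:6) {
    mask <- if (seed %% 2) random_blob_mask(64, 64, seed) else
      random_noise_mask(64, 64, seed)
    for (conn in c(8, 4)) {
      expect_equal(
        count_objects(mask, min_area = 20, connectivity = conn),
        flood_fill_count(mask, 20, conn),
        info = sprintf("seed %d conn %d", seed, conn)
      )
      expect_equal(
        count_objects(mask, min_area = 0, connectivity = conn),
        flood_fill_count(mask, 0, conn)
      )
    }
  }
  # diagonal adjacency distinguishes the two connectivities
  diag_mask <- matrix(FALSE, 4, 4); diag_mask[1, 1] <- diag_mask[2, 2] <- TRUE
  expect_equal(count_objects(diag_mask, 0, connectivity = 8), 1)
  expect_equal(count_objects(diag_mask, 0, connectivity = 4), 2)
})

test_that("quantify_section measures every ROI with one shared threshold", {
  sim <- simulate_ihc_image(ihc_sim_params(image_shape = c(96, 96), seed = 2),
                            antibody = "GFAP", subject_id = "M_WT_1",
                            sex = "M", genotype = "WT", level = "anterior")
  rois <- synthetic_roi_grid(c(96, 96), 1, 3,
                             names = c("Cg1", "Cg2", "S2"))
  res <- quantify_section(sim$image, rois)
  expect_equal(nrow(res), 3)
  expect_equal(res$region, c("Cg1", "Cg2", "S2"))
  expect_equal(length(unique(res$threshold_used)), 1)
  expect_true(all(res$percent_positive_area >= 0 &
                    res$percent_positive_area <= 100))
  expect_true(all(res$object_count >= 0))  # GFAP: counts reported
  # MBP (myelin, not somata): no object counts
  mbp <- sim$image; mbp$metadata$antibody <- "MBP"
  expect_true(all(is.na(quantify_section(mbp, rois)$object_count)))
})

test_that("a no-signal section yields only the Gaussian-tail positive area", {
  sim <- simulate_ihc_image(ihc_sim_params(signal_fraction = 0, noise_sd = 10,
                                           image_shape = c(256, 256), seed = 4),
                            antibody = "Iba1")
  rois <- synthetic_roi_grid(c(256, 256), 2, 2)
  res <- quantify_section(sim$image, rois)
  # expected tail mass P(X <= mode - 3 sd) ~ pnorm(-3) ~ 0.13%
  expect_true(all(res$percent_positive_area <= 2))
})

test_that("a cohort batch produces one tidy row per subject and ROI", {
  d <- cohort_design(6)
  cohort <- simulate_ihc_cohort(
    d, ihc_sim_params(image_shape = c(64, 64), seed = 3), antibody = "Iba1")
  rois <- synthetic_roi_grid(c(64, 64), 2, 2)
  tab <- quantify_batch(cohort$sections, rois)
  expect_equal(nrow(tab), 24 * 4)
  expect_setequal(unique(tab$subject_id), d$subject_id)
  expect_equal(as.vector(table(tab$sex, tab$genotype)), rep(24L, 4))
})

test_that("positive area is monotone in the threshold", {
  sim <- simulate_ihc_image(ihc_sim_params(image_shape = c(64, 64), seed = 8))
  roi <- matrix(TRUE, 64, 64)
  fracs <- vapply(seq(0, 255, by = 5), function(thr) {
    positive_area_fraction(sim$image, roi, thr)
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("adding a constant shifts mode and threshold but not the area", {
  sim <- simulate_ihc_image(ihc_sim_params(background_level = 150,
                                           signal_offset = 80,
                                           image_shape = c(128, 128), seed = 6))
  px <- sim$image$pixels
  shifted <- px + 30L
  expect_true(max(shifted) <= 255)  # stays in range, no clamping involved
  st0 <- image_stats(px); st1 <- image_stats(shifted)
  expect_equal(st1$mode, st0$mode + 30)
  expect_equal(st1$sd, st0$sd, tolerance = 1e-12)
  roi <- matrix(TRUE, 128, 128)
  thr0 <- compute_threshold(st0, 2.5)$threshold
  thr1 <- compute_threshold(st1, 2.5)$threshold
  expect_equal(thr1, thr0 + 30)
  expect_equal(positive_area_fraction(shifted, roi, thr1),
               positive_area_fraction(px, roi, thr0))
})
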