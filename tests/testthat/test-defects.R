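test_that("thresholds use the linear-interpolation quantile convention", {
  expect_equal(as.numeric(leakage_threshold(rep(5, 100))), 5)
  # medians 1..100 at q = 0.98 -> 98.02 (order-statistics oracle)
  expect_equal(as.numeric(leakage_threshold(1:100)), 98.02)
  # pooled pixels 1..1000 at q = 0.997 -> 997.003
  lab <- matrix(0L, 40, 25)
  lab[1:1000] <- rep(1:50, each = 20) # 50 cells of 20 px each
  img <- matrix(0, 40, 25)
  img[1:1000] <- 1:1000
  cells <- suppressWarnings(cells_from_labels(lab))
  expect_equal(as.numeric(brightness_reference(cells, img)), 997.003)
})

test_that("threshold calibration demands enough reference cells", {
  expect_error(leakage_threshold(1:49), class = "rodmapr_calibration_error")
  lab <- rect_labels()
  cells <- cells_from_labels(lab)
  expect_error(brightness_reference(cells, matrix(1, 60, 80)),
               class = "rodmapr_calibration_error")
})

test_that("quantile thresholds are invariant under reference duplication", {
  x <- c(10, 30, 22, 7, 90, 15, 44, 61, 28, 33)
  x <- rep(x, 6) # 60 cells
  expect_equal(as.numeric(leakage_threshold(x)),
               as.numeric(leakage_threshold(rep(x, 2))))
  # monotone under adding brighter references
  expect_gte(as.numeric(leakage_threshold(c(x, rep(100, 10)))),
             as.numeric(leakage_threshold(x)))
})

test_that("leakage calls use a strict inequality", {
  tr <- tibble::tibble(cell_id = 1:3, median_value = c(1, 2, 3))
  calls <- classify_leakage(tr, threshold = 2)
  expect_equal(calls$is_leaky, c(TRUE, FALSE, FALSE)) # median == threshold: intact
  expect_equal(calls$threshold_used, rep(2, 3))
})

test_that("leakage decisions are invariant under affine rescaling", {
  set.seed(61)
  ref <- runif(200, 10, 30)
  test_m <- runif(100, 5, 60)
  thr <- leakage_threshold(ref)
  calls1 <- classify_leakage(tibble::tibble(cell_id = 1:100, median_value = test_m), thr)
  resc <- function(v) 3.7 * v + 11
  thr2 <- leakage_threshold(resc(ref))
  calls2 <- classify_leakage(tibble::tibble(cell_id = 1:100, median_value = resc(test_m)), thr2)
  expect_identical(calls1$is_leaky, calls2$is_leaky)
})

test_that("mixed population leakage classification recovers ground truth", {
  gm <- growth_model()
  ch <- list(channel_model("periplasmic", 200, noise_sd = 10)) # 5% of amplitude
  ref <- render_scene(sample_population(500, gm, seed = 62), ch,
                      defects = defect_model(leak_fraction = 1, leak_attenuation = 0.2),
                      phase_noise_sd = 20, seed = 63)
  rc <- segment_cells(ref$images$phase)
  thr <- leakage_threshold(contour_fluorescence(rc, ref$images$periplasmic))
  # ~98% of the reference itself is called leaky, by construction
  frac_ref <- mean(classify_leakage(contour_fluorescence(rc, ref$images$periplasmic),
                                    thr)$is_leaky)
  expect_equal(frac_ref, 0.98, tolerance = 0.02 / 0.98)
  mix <- render_scene(sample_population(400, gm, seed = 64), ch,
                      defects = defect_model(leak_fraction = 0.3, leak_attenuation = 0.2),
                      phase_noise_sd = 20, seed = 65)
  mc <- segment_cells(mix$images$phase)
  calls <- classify_leakage(contour_fluorescence(mc, mix$images$periplasmic), thr)
  m <- match_truth(mc, mix)
  truth <- mix$cells$is_leaky[m]
  pred <- calls$is_leaky
  expect_gte(sum(pred & truth) / sum(truth), 0.95) # sensitivity
  expect_gte(sum(!pred & !truth) / sum(!truth), 0.95) # specificity
})

test_that("bleb boundary rules reject oversized and distant puncta", {
  # one rod plus two synthetic puncta drawn directly into the image
  lab <- matrix(0L, 120, 160)
  lab[10:19, 10:49] <- 1L
  cells <- cells_from_labels(lab)
  img <- matrix(0, 120, 160)
  img[lab > 0] <- 100
  # punctum A: 5 um^2 (1221 px) block touching the cell -> rejected by area
  img[21:57, 20:52] <- 1000 # 37x33 px = 1221 px = 5.002 um^2
  # punctum B: small but 0.5 um away from the cell -> rejected by distance
  img[40:42, 100:102] <- 1000 # nearest cell pixel is >> 0.3 um away
  calls <- detect_blebs(img, cells, brightness_threshold = 500)
  expect_equal(nrow(calls), 0)
  # shrink punctum A below 4 um^2 and move B within 0.3 um: both accepted
  img2 <- matrix(0, 120, 160)
  img2[lab > 0] <- 100
  img2[22:31, 20:29] <- 1000 # 100 px = 0.41 um^2, 2 px (0.128 um) from cell
  calls2 <- detect_blebs(img2, cells, brightness_threshold = 500)
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$cell_id, 1L)
  expect_lte(calls2$distance_um, 0.3)
})

test_that("every reported bleb satisfies all three printed rules", {
  gm <- growth_model()
  pop <- sample_population(120, gm, seed = 66)
  sc <- render_scene(pop, list(channel_model("periplasmic", 200, noise_sd = 10)),
                     defects = defect_model(bleb_rate = 0.2, bleb_amplitude = 1000,
                                            bleb_radius = 0.15, bleb_max_offset = 0.2),
                     phase_noise_sd = 20, seed = 67)
  cells <- segment_cells(sc$images$phase)
  thr <- brightness_reference(cells, sc$images$periplasmic)
  calls <- detect_blebs(sc$images$periplasmic, cells, thr)
  expect_gt(nrow(calls), 0)
  expect_true(all(calls$mean_brightness > thr))
  expect_true(all(calls$area_um2 < 4))
  expect_true(all(calls$distance_um <= 0.3))
  expect_true(all(calls$cell_id %in% cells$cell_id))
  # detection quality against ground truth
  d <- sqrt(outer(calls$x_um, sc$blebs$x_um, "-")^2 +
            outer(calls$y_um, sc$blebs$y_um, "-")^2)
  expect_gte(mean(apply(d, 1, min) <= 0.3), 0.9) # precision
  expect_gte(mean(apply(d, 2, min) <= 0.3), 0.9) # recall
})

test_that("defect summaries count calls", {
  lk <- tibble::tibble(cell_id = 1:10, median_contour_fluorescence = 1:10,
                       threshold_used = 5, is_leaky = c(rep(TRUE, 4), rep(FALSE, 6)))
  bb <- tibble::tibble(bleb_id = 1:3)
  s <- defect_summary(lk, bb)
  expect_equal(s$fraction_leaky, 0.4)
  expect_equal(s$blebs_per_100_cells, 30)
})
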