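test_that("population sampling follows the steady-state age distribution", {
  pop <- sample_population(10000, growth_model(), seed = 42)
  # mean of p(a) = 2 ln2 2^-a is 1/ln2 - 1 = 0.4427; 3 SE ~ 0.009
  expect_equal(mean(pop$true_age), 1 / log(2) - 1, tolerance = 0.01 / 0.44)
  # closed-form CDF as the oracle for the whole distribution
  ks <- suppressWarnings(stats::ks.test(pop$true_age, age_cdf))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("population sampling edge cases and determinism", {
  expect_equal(nrow(sample_population(0, growth_model(), seed = 1)), 0)
  expect_error(sample_population(-1, growth_model()), "non-negative")
  gm <- growth_model(birth_length = 2, length_cv = 0)
  expect_equal(growth_length(gm, 1), 4) # L(1) = 2 L0
  expect_equal(growth_length(gm, 0), 2)
  p1 <- sample_population(100, gm, seed = 7)
  p2 <- sample_population(100, gm, seed = 7)
  expect_identical(p1, p2)
  # lengths follow the growth law exactly when length_cv = 0
  expect_equal(p1$length_um, 2 * 2^p1$true_age)
})

test_that("sampling under a seed does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(sample_population(10, growth_model(), seed = 5))
  expect_identical(runif(1), a)
})

test_that("rendered cytoplasmic fluorescence is conserved over the true mask", {
  sc <- one_cell_scene(channels = list(channel_model("cytoplasmic", 100)))
  expect_equal(nrow(sc$cells), 1)
  in_mask <- sc$labels > 0
  total <- sum(sc$images$cytoplasmic[in_mask])
  expect_equal(total, 100 * sum(in_mask), tolerance = 0.01)
  # nothing rendered outside the mask in a noiseless scene
  expect_equal(sum(sc$images$cytoplasmic[!in_mask]), 0)
})

test_that("septal band is gated by onset age", {
  ch <- list(channel_model("septal", amplitude = 50, septal_onset_age = 0.4))
  young <- one_cell_scene(age = 0.3, channels = ch)
  old <- one_cell_scene(age = 0.5, channels = ch)
  expect_equal(sum(young$images$septal), 0)
  expect_gt(sum(old$images$septal), 0)
  expect_false(young$cells$septal_present)
  expect_true(old$cells$septal_present)
})

test_that("rendering is bit-identical under a fixed seed", {
  pop <- sample_population(12, growth_model(), seed = 3)
  ch <- list(channel_model("contour", 150, noise_sd = 8))
  df <- defect_model(leak_fraction = 0.5, bleb_rate = 0.3)
  s1 <- render_scene(pop, ch, defects = df, phase_noise_sd = 10, seed = 9)
  s2 <- render_scene(pop, ch, defects = df, phase_noise_sd = 10, seed = 9)
  expect_identical(s1$images, s2$images)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$blebs, s2$blebs)
})

test_that("leaky cells have attenuated contour signal", {
  ch <- list(channel_model("periplasmic", 200))
  gm <- growth_model(length_cv = 0)
  pop <- as_rod_population(c(2.5, 2.5), true_age = c(0.3, 0.3), growth = gm)
  intact <- render_scene(pop, ch, defects = defect_model(leak_fraction = 0),
                         field_px = c(256, 256), seed = 4)
  leaky <- render_scene(pop, ch, defects = defect_model(leak_fraction = 1,
                                                        leak_attenuation = 0.2),
                        field_px = c(256, 256), seed = 4)
  expect_equal(sum(leaky$images$periplasmic), 0.2 * sum(intact$images$periplasmic),
               tolerance = 1e-10)
})

test_that("bleb ground truth is complete and consistent", {
  pop <- sample_population(40, growth_model(), seed = 5)
  sc <- render_scene(pop, list(channel_model("periplasmic", 200)),
                     defects = defect_model(bleb_rate = 0.5), seed = 6)
  expect_gt(nrow(sc$blebs), 0)
  # every bleb's parent cell exists in the population
  expect_true(all(sc$blebs$cell_id %in% sc$cells$cell_id))
  # bleb centres lie near their parent's contour: within max_offset + w/2 of
  # the parent's spine by construction
  expect_true(all(sc$blebs$radius_um == 0.15))
})

test_that("placement failure names the achieved cell count", {
  pop <- sample_population(80, growth_model(), seed = 8)
  expect_error(
    render_scene(pop, list(channel_model("cytoplasmic", 10)),
                 field_px = c(220, 220), seed = 8, max_attempts = 50),
    "placed \\d+ of 80 cells")
})

test_that("analytic profiles integrate the generative model exactly", {
  gm <- growth_model(length_cv = 0)
  pop <- as_rod_population(c(3, 4), true_age = c(0.6, 0.9), growth = gm)
  chs <- list(channel_model("cytoplasmic", 80),
              channel_model("septal", amplitude = 60, septal_onset_age = 0.5))
  pr <- simulate_profiles(pop, chs, n_bins = 50, noise_sd = 0)
  tr <- profile_truth(pr)
  # per-cell total = uniform base + septal excess (both analytic)
  tot <- tapply(pr$value, pr$cell_id, sum)
  expect_equal(as.numeric(tot), tr$baseline_density * tr$length_um + tr$septal_excess,
               tolerance = 1e-8)
  # septal excess present in both cells (ages past onset)
  expect_true(all(tr$septal_excess > 0))
})

test_that("analytic profile noise scales with bin area", {
  gm <- growth_model(length_cv = 0)
  pop <- as_rod_population(rep(4, 400), true_age = rep(0.5, 400), growth = gm)
  ch <- channel_model("cytoplasmic", 0, noise_sd = 10)
  pr <- simulate_profiles(pop, ch, n_bins = 50, noise_sd = 10, seed = 77)
  # empirical bin sd vs the per-pixel model: sd = 10 * sqrt(bw * w) * px
  expected <- 10 * sqrt((4 / 50) * gm$width) * 0.064
  expect_equal(sd(pr$value), expected, tolerance = 0.05)
})
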