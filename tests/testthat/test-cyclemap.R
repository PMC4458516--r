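test_that("age assignment inverts the steady-state CDF", {
  tab <- assign_ages(seq(2, 4, length.out = 1001))
  # mid-rank F = 0.5 -> a = -log2(0.75)
  expect_equal(tab$age[tab$rank_fraction == 0.5], -log2(0.75), tolerance = 1e-12)
  # endpoints approach 0 and 1 as n grows
  expect_lt(tab$age[1], 0.001)
  expect_gt(tab$age[1001], 0.999)
  expect_true(all(diff(tab$age) > 0)) # strictly increasing with rank
})

test_that("age assignment edge cases and stable ties", {
  expect_equal(nrow(assign_ages(numeric(0))), 0)
  expect_error(assign_ages(c(2, -1)), "positive")
  tab <- assign_ages(tibble::tibble(cell_id = c(7L, 3L), length_um = c(3, 3)))
  expect_equal(tab$cell_id, c(3L, 7L)) # equal lengths tie-broken by id
})

test_that("assigned ages track true ages on synthetic populations", {
  pop <- sample_population(1000, growth_model(length_cv = 0.05), seed = 50)
  tab <- assign_ages(pop)
  expect_gte(cor(tab$true_age, tab$age), 0.95)
  # the assigned-age histogram matches the sampling density 2 ln2 2^-a
  ks <- suppressWarnings(stats::ks.test(tab$age, age_cdf))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("profile maps are sorted by length with stable tie-breaks", {
  prof <- tibble::tibble(
    cell_id = rep(c(7L, 3L, 5L), each = 4), channel = "x",
    bin = rep(1:4, 3), position = rep((1:4 - 0.5) / 4, 3),
    value = rep(c(1, 2, 3), each = 4)
  )
  tab <- assign_ages(tibble::tibble(cell_id = c(7L, 3L, 5L),
                                    length_um = c(3, 3, 2)))
  pm <- build_profile_map(prof, tab, n_cols = 4)
  expect_equal(pm$cells$cell_id, c(5L, 3L, 7L)) # ascending length, then id
  expect_equal(pm$map[1, ], rep(3, 4)) # rows carry the right profiles
  expect_error(build_profile_map(dplyr::mutate(prof, cell_id = cell_id + 100L), tab),
               "absent")
})

test_that("profile map rows conserve per-cell totals under resampling", {
  pop <- sample_population(200, growth_model(), seed = 51)
  pr <- simulate_profiles(pop, channel_model("cytoplasmic", 80), n_bins = 50)
  tab <- assign_ages(profile_truth(pr))
  pm <- build_profile_map(pr, tab, n_cols = 30)
  tot_map <- rowSums(pm$map)
  tot_prof <- tapply(pr$value, pr$cell_id, sum)[as.character(pm$cells$cell_id)]
  expect_equal(as.numeric(tot_map), as.numeric(tot_prof), tolerance = 0.01)
})

test_that("ring fraction matches analytic oracles", {
  expect_equal(ring_fraction(rep(1, 50), length_um = 4), 0.2) # 0.8/4
  expect_equal(ring_fraction(rep(5, 40), length_um = 2), 0.4) # scale-invariant
  v <- gaussian_profile(50, 2, sigma = 0.05, total = 9)
  expect_equal(ring_fraction(v, 2), 1, tolerance = 1e-6) # fully inside window
  expect_identical(ring_fraction(rep(0, 50), 4), NA_real_) # zero total flagged
  # mid-cell Gaussian sigma 0.2, L = 3: numerical-integration oracle; with
  # window edges on bin boundaries the pro-rata sum is exact
  oracle <- (pnorm(0.4, 0, 0.2) - pnorm(-0.4, 0, 0.2)) /
    (pnorm(1.5, 0, 0.2) - pnorm(-1.5, 0, 0.2))
  v300 <- gaussian_profile(300, 3, sigma = 0.2)
  expect_equal(ring_fraction(v300, 3), oracle, tolerance = 1e-6)
  v50 <- gaussian_profile(50, 3, sigma = 0.2)
  expect_equal(ring_fraction(v50, 3), oracle, tolerance = 1e-2)
})

test_that("FCplus is zero on uniform profiles and recovers injected excess", {
  expect_equal(fc_plus(rep(2, 50), length_um = 4), 0)
  v <- rep(2, 50) + gaussian_profile(50, 4, sigma = 0.15, total = 7)
  expect_equal(fc_plus(v, 4), 7, tolerance = 0.02)
  # linear in amplitude
  v3 <- rep(2, 50) + gaussian_profile(50, 4, sigma = 0.15, total = 21)
  expect_equal(fc_plus(v3, 4) / fc_plus(v, 4), 3, tolerance = 1e-6)
  # too short for window + flanks: undefined, flagged
  expect_identical(fc_plus(rep(1, 50), length_um = 2), NA_real_)
})

test_that("FCplus separates septal from pre-onset cells by ground truth", {
  pop <- sample_population(800, growth_model(), seed = 52)
  chs <- list(channel_model("cytoplasmic", 80),
              channel_model("septal", amplitude = 60, septal_onset_age = 0.5))
  pr <- simulate_profiles(pop, chs, noise_sd = 3, seed = 53)
  tr <- profile_truth(pr)
  tab <- assign_ages(tr)
  st <- midcell_stats(pr, tab)
  st <- st[st$fc_defined, ]
  septal <- tr$septal_excess[match(st$cell_id, tr$cell_id)] > 1
  expect_gt(mean(st$fc_plus[septal]), 5 * mean(st$fc_plus[!septal]))
})

test_that("age-class averages partition cells and normalize peaks", {
  pop <- sample_population(500, growth_model(), seed = 54)
  pr <- simulate_profiles(pop, channel_model("cytoplasmic", 80))
  tab <- assign_ages(profile_truth(pr))
  s <- age_class_averages(pr, tab) # default 10 classes
  expect_equal(nrow(s), 10)
  expect_equal(sum(s$n), 500)
  expect_true(all(abs(s$age_hi - s$age_lo - 0.1) < 1e-12))
  # peak-normalized profiles reach exactly 1 where defined
  for (k in which(s$defined)) expect_equal(max(s$peak_profile[[k]]), 1)
  # uniform-signal population: class means flat (interior bins)
  mp <- s$mean_profile[[5]][10:40]
  expect_lt(diff(range(mp)) / mean(mp), 0.1)
})

test_that("empty age classes are retained and flagged", {
  pop <- sample_population(120, growth_model(), seed = 61)
  pr <- simulate_profiles(pop, channel_model("cytoplasmic", 10))
  tab <- assign_ages(profile_truth(pr))
  # drop every cell of one age class: rank ages cover [0,1], so carve a hole
  keep <- tab$cell_id[tab$age < 0.4 | tab$age >= 0.5]
  pr <- pr[pr$cell_id %in% keep, ]
  tab <- tab[tab$cell_id %in% keep, ]
  s <- age_class_averages(pr, tab)
  expect_equal(nrow(s), 10)
  expect_true(any(s$n == 0))
  expect_true(all(!s$defined[s$n == 0]))
  expect_true(all(is.na(s$mid_excess_mean[s$n == 0])))
})

test_that("initiation is undefined without mid-cell signal", {
  pop <- sample_population(600, growth_model(), seed = 55)
  pr <- simulate_profiles(pop, channel_model("cytoplasmic", 80), noise_sd = 3,
                          seed = 56)
  tab <- assign_ages(profile_truth(pr))
  expect_identical(detect_initiation(age_class_averages(pr, tab)), NA_real_)
})

test_that("initiation and moment recover the generative timings", {
  for (onset in c(0.3, 0.4)) {
    pop <- sample_population(3000, growth_model(), seed = 57)
    chs <- list(channel_model("cytoplasmic", 80),
                channel_model("septal", amplitude = 60, septal_onset_age = onset,
                              septal_peak_age = 0.65))
    pr <- simulate_profiles(pop, chs, noise_sd = 3, seed = 58)
    tab <- assign_ages(profile_truth(pr))
    init <- detect_initiation(age_class_averages(pr, tab))
    expect_equal(init, onset, tolerance = 0.1 / onset) # within one age class
    mom <- detect_moment(midcell_stats(pr, tab))
    expect_lte(abs(mom - 0.65), 0.1)
  }
})

test_that("moment handles degenerate inputs", {
  st <- tibble::tibble(age = runif(50), fc_plus = rep(0, 50))
  expect_identical(detect_moment(st), NA_real_) # all-zero FCplus
  expect_identical(detect_moment(st[1:5, ]), NA_real_) # too few cells
  # strictly increasing FCplus: moment = midpoint of the last class
  st2 <- tibble::tibble(age = seq(0.01, 0.99, length.out = 100),
                        fc_plus = seq(1, 100))
  expect_equal(detect_moment(st2), 0.95)
})

test_that("tidiers expose class summaries and per-cell stats", {
  pop <- sample_population(300, growth_model(), seed = 59)
  chs <- list(channel_model("cytoplasmic", 80),
              channel_model("septal", amplitude = 60, septal_onset_age = 0.4))
  pr <- simulate_profiles(pop, chs, noise_sd = 3, seed = 60)
  tab <- assign_ages(profile_truth(pr))
  s <- age_class_averages(pr, tab)
  td <- generics::tidy(s)
  expect_equal(nrow(td), 10)
  expect_false(any(vapply(td, is.list, TRUE)))
  st <- midcell_stats(pr, tab)
  g <- generics::glance(st)
  expect_equal(g$n_cells, 300)
  expect_true(g$mean_ring_fraction > 0 && g$mean_ring_fraction < 1)
})
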