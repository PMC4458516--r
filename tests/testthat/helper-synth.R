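# shared fixtures, all generated in code

# axis-aligned rectangular label image (rod proxy of exact geometry)
rect_labels <- function(nrow_px = 60, ncol_px = 80, rows = 25:34, cols = 20:59,
                        id = 1L) {
  lab <- matrix(0L, nrow_px, ncol_px)
  lab[rows, cols] <- id
  lab
}

# one-cell noiseless scene with a fixed length/width, default orientation free
one_cell_scene <- function(length_um = 2.56, width_um = 0.64, age = 0,
                           channels = list(channel_model("cytoplasmic", 100)),
                           seed = 1, ...) {
  gm <- growth_model(birth_length = length_um, width = width_um, length_cv = 0,
                     constriction_onset_age = 1)
  pop <- as_rod_population(length_um, true_age = age, growth = gm)
  render_scene(pop, channels, field_px = c(128, 128), seed = seed, ...)
}

# greedy nearest-centroid matching of detected cells to scene ground truth;
# returns the truth row index for each detected cell
match_truth <- function(cells, scene, max_dist_px = 8) {
  d2 <- outer(scene$cells$x_px, cells$centroid_x, "-")^2 +
    outer(scene$cells$y_px, cells$centroid_y, "-")^2
  m <- apply(d2, 2, which.min)
  d <- sqrt(d2[cbind(m, seq_along(m))])
  m[d > max_dist_px] <- NA_integer_
  m
}

# analytic per-bin integrals of a Gaussian band (+ optional uniform base)
gaussian_profile <- function(n_bins, length_um, sigma, total = 1, base = 0,
                             center = length_um / 2) {
  e <- seq(0, length_um, length.out = n_bins + 1)
  total * (pnorm(e[-1], center, sigma) - pnorm(e[-(n_bins + 1)], center, sigma)) +
    base / n_bins
}
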