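#' @importFrom rlang %||% .data
#' @importFrom stats rnorm runif rpois median quantile sd pnorm approx setNames
#' @importFrom utils head tail
NULL

# run expr under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL means "use the current stream"
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Deterministic growth-law length
#'
#' Length of a cell at cell-cycle age `a` under the exponential growth law
#' \eqn{L(a) = L_0 \cdot 2^a}.
#'
#' @param growth A [growth_model()].
#' @param age Cell-cycle age(s) in `[0, 1]`.
#' @return Length(s) in micrometres.
#' @export
growth_length <- function(growth, age) {
  stopifnot(inherits(growth, "growth_model"))
  growth$birth_length * 2^age
}

#' Steady-state cell-cycle age distribution
#'
#' In a steady-state exponentially growing population the density of
#' cell-cycle ages is \eqn{p(a) = 2 \ln 2 \cdot 2^{-a}} on `[0, 1]`, with
#' CDF \eqn{F(a) = 2 (1 - 2^{-a})}: young cells are over-represented
#' because every division produces two newborns.
#'
#' @param a Ages in `[0, 1]`.
#' @return Density or cumulative probability values.
#' @name steady_state_age
NULL

#' @rdname steady_state_age
#' @export
age_density <- function(a) ifelse(a >= 0 & a <= 1, 2 * log(2) * 2^(-a), 0)

#' @rdname steady_state_age
#' @export
age_cdf <- function(a) pmin(1, pmax(0, 2 * (1 - 2^(-a))))

# inverse CDF: u in [0,1] -> age
age_quantile <- function(u) -log2(1 - u / 2)

#' Sample a steady-state population of rod-shaped cells
#'
#' Draws `n` cells with cell-cycle ages from the steady-state density
#' \eqn{p(a) = 2\ln 2 \cdot 2^{-a}} (inverse-CDF sampling) and lengths from
#' the growth law \eqn{L_0 2^a} with multiplicative log-normal noise of
#' coefficient of variation `growth$length_cv`.
#'
#' @param n Number of cells (`n >= 0`).
#' @param growth A [growth_model()].
#' @param seed Optional integer seed; identical `(seed, growth, n)` give an
#'   identical population.
#' @return A tibble of class `rod_population` with columns `cell_id`,
#'   `true_age`, `length_um`, and the growth model stored as attribute
#'   `growth`.
#' @examples
#' pop <- sample_population(1000, growth_model(), seed = 1)
#' mean(pop$true_age) # close to 1/log(2) - 1 = 0.4427
#' @export
sample_population <- function(n, growth = growth_model(), seed = NULL) {
  stopifnot(inherits(growth, "growth_model"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0) {
    stop("`n` must be a single non-negative number", call. = FALSE)
  }
  n <- as.integer(n)
  pop <- with_seed(seed, {
    age <- age_quantile(runif(n))
    len <- growth_length(growth, age)
    if (growth$length_cv > 0 && n > 0) {
      len <- len * exp(rnorm(n, 0, growth$length_cv))
    }
    tibble::tibble(cell_id = seq_len(n), true_age = age, length_um = len)
  })
  attr(pop, "growth") <- growth
  class(pop) <- c("rod_population", class(pop))
  pop
}

#' Construct a population from given lengths and ages
#'
#' Builds a `rod_population` from explicit per-cell values instead of
#' sampling, for controlled experiments. When `true_age` is omitted it is
#' inferred from the growth law, `a = log2(L / L0)`, clipped to `[0, 1]`.
#'
#' @param length_um Cell lengths, micrometres.
#' @param true_age Optional ages in `[0, 1]`.
#' @param growth A [growth_model()].
#' @return A `rod_population` tibble.
#' @export
as_rod_population <- function(length_um, true_age = NULL,
                              growth = growth_model()) {
  stopifnot(inherits(growth, "growth_model"), all(length_um > 0))
  if (is.null(true_age)) {
    true_age <- pmin(1, pmax(0, log2(length_um / growth$birth_length)))
  }
  stopifnot(length(true_age) == length(length_um),
            all(true_age >= 0), all(true_age <= 1))
  pop <- tibble::tibble(cell_id = seq_along(length_um),
                        true_age = true_age, length_um = length_um)
  attr(pop, "growth") <- growth
  class(pop) <- c("rod_population", class(pop))
  pop
}

# per-unit-length signal density (fluorescence units per um) of the uniform
# (non-septal) part of a channel, used by the analytic profile path
baseline_density <- function(channel, growth) {
  switch(channel$kind,
    cytoplasmic = channel$amplitude * growth$width,
    contour = ,
    periplasmic = channel$amplitude * 2 * channel$shell_thickness,
    septal = 0
  )
}

# analytic integrated septal excess over [0, L] for one cell; the band spans
# the full cell cross-section, hence the width factor
septal_excess_analytic <- function(channel, age, length, width) {
  if (channel$kind != "septal") return(rep(0, length(age)))
  amp <- septal_amplitude_at(channel, age)
  s <- channel$septal_sigma
  amp * width * sqrt(2 * pi) * s *
    (pnorm(length / 2, 0, s) - pnorm(-length / 2, 0, s))
}

#' Simulate per-cell axial fluorescence profiles analytically
#'
#' Computes the integrated axial fluorescence profile of every cell in a
#' population directly from the generative channel model, without rendering
#' an image: each bin holds the exact integral of the channel's axial signal
#' density over that bin, plus optional Gaussian noise. This is the fast
#' path for population-scale cell-cycle statistics; [render_scene()] plus
#' segmentation exercises the same quantities through pixels.
#'
#' @param population A `rod_population` from [sample_population()].
#' @param channels A [channel_model()] or list of channel models; their
#'   signals are summed into one profile per cell.
#' @param n_bins Number of axial bins per cell (profiles are
#'   length-normalized downstream, so the bin count is fixed per cell).
#' @param noise_sd Per-pixel additive Gaussian noise, in the same units as
#'   [render_scene()]: the noise of a bin's integrated value scales with
#'   the square root of the bin's pixel area. Defaults to the first
#'   channel's `noise_sd`.
#' @param pixel_size Pixel size in micrometres, used only to convert the
#'   per-pixel noise into integrated units.
#' @param seed Optional seed for the noise.
#' @return A long tibble of class `axial_profiles` with columns `cell_id`,
#'   `channel`, `bin`, `position` (normalized bin centre in `[0, 1]`) and
#'   `value`. Per-cell generative truth (analytic septal excess and
#'   baseline density) is attached as attribute `"truth"`; see
#'   [profile_truth()].
#' @export
simulate_profiles <- function(population, channels, n_bins = 50,
                              noise_sd = NULL, pixel_size = 0.064, seed = NULL) {
  stopifnot(inherits(population, "rod_population"), n_bins >= 2)
  if (inherits(channels, "channel_model")) channels <- list(channels)
  stopifnot(all(vapply(channels, inherits, TRUE, "channel_model")))
  growth <- attr(population, "growth")
  noise_sd <- noise_sd %||% channels[[1]]$noise_sd
  chan_name <- paste(vapply(channels, function(ch) ch$name, ""), collapse = "+")

  n <- nrow(population)
  ages <- population$true_age
  lens <- population$length_um

  # bin integrals: rows = cells, cols = bins
  mat <- matrix(0, n, n_bins)
  base <- rep(0, n)
  excess <- rep(0, n)
  edges_frac <- seq(0, 1, length.out = n_bins + 1)
  for (ch in channels) {
    dens <- baseline_density(ch, growth)
    base <- base + dens
    if (dens > 0) mat <- mat + outer(lens, diff(edges_frac)) * dens
    if (ch$kind == "septal") {
      amp <- septal_amplitude_at(ch, ages)
      s <- ch$septal_sigma
      # per-bin integral of the mid-cell Gaussian band (full cross-section)
      lo <- outer(lens, edges_frac[-(n_bins + 1)]) - lens / 2
      hi <- outer(lens, edges_frac[-1]) - lens / 2
      mat <- mat + amp * growth$width * sqrt(2 * pi) * s *
        (pnorm(hi, 0, s) - pnorm(lo, 0, s))
      excess <- excess + septal_excess_analytic(ch, ages, lens, growth$width)
    }
  }
  if (noise_sd > 0) {
    # per-pixel white noise integrated over a bin of area (L/n_bins) x width:
    # sd of the bin value (in these integrated units) is
    # noise_sd * sqrt(bin_area_um2) * pixel_size
    bin_sd <- noise_sd * sqrt((lens / n_bins) * growth$width) * pixel_size
    mat <- mat + with_seed(seed,
      matrix(rnorm(n * n_bins, 0, rep(bin_sd, n_bins)), n, n_bins))
  }

  out <- tibble::tibble(
    cell_id = rep(population$cell_id, each = n_bins),
    channel = chan_name,
    bin = rep(seq_len(n_bins), n),
    position = rep((seq_len(n_bins) - 0.5) / n_bins, n),
    value = as.vector(t(mat))
  )
  attr(out, "truth") <- tibble::tibble(
    cell_id = population$cell_id,
    length_um = lens,
    true_age = ages,
    septal_excess = excess,
    baseline_density = base
  )
  attr(out, "n_bins") <- n_bins
  class(out) <- c("axial_profiles", class(out))
  out
}

#' Generative ground truth attached to simulated profiles
#'
#' @param profiles An `axial_profiles` tibble from [simulate_profiles()].
#' @return A tibble with one row per cell: `cell_id`, `length_um`,
#'   `true_age`, `septal_excess` (analytic integrated mid-cell excess) and
#'   `baseline_density`.
#' @export
profile_truth <- function(profiles) {
  truth <- attr(profiles, "truth")
  if (is.null(truth)) stop("profiles carry no generative truth", call. = FALSE)
  truth
}

# minimum distance between segment (p1,p2) and segments given as matrices
# a1, a2 (k x 2); vectorized over the k placed segments
seg_seg_dist <- function(p1, p2, a1, a2) {
  if (nrow(a1) == 0) return(numeric(0))
  pt_seg <- function(px, py, sx1, sy1, sx2, sy2) {
    dx <- sx2 - sx1; dy <- sy2 - sy1
    l2 <- dx^2 + dy^2
    t <- ifelse(l2 > 0, ((px - sx1) * dx + (py - sy1) * dy) / l2, 0)
    t <- pmin(1, pmax(0, t))
    sqrt((px - (sx1 + t * dx))^2 + (py - (sy1 + t * dy))^2)
  }
  # sample points along the new segment; exact enough for clearance testing
  ts <- seq(0, 1, length.out = 9)
  px <- p1[1] + ts * (p2[1] - p1[1]); py <- p1[2] + ts * (p2[2] - p1[2])
  d <- Inf
  for (i in seq_along(ts)) {
    d <- pmin(d, pt_seg(px[i], py[i], a1[, 1], a1[, 2], a2[, 1], a2[, 2]))
  }
  # and endpoints of placed segments against the new one
  for (j in c(1, 2)) {
    m <- if (j == 1) a1 else a2
    d <- pmin(d, pt_seg(m[, 1], m[, 2], p1[1], p1[2], p2[1], p2[2]))
  }
  d
}

#' Render a synthetic microscopy scene
#'
#' Places the cells of a population in a 2D field (rejection sampling with a
#' minimum clearance, so cells never touch) and renders one phase-contrast
#' proxy channel plus the requested fluorescence channels, with full ground
#' truth. Cells are 2D spherocylinders; cells past the growth model's
#' constriction onset narrow at mid-cell and darken there in the phase
#' channel. Leaky cells have their envelope (contour/periplasmic) signal
#' multiplied by the defect model's attenuation; blebs are Gaussian puncta
#' added to the first envelope channel just outside their parent cell.
#'
#' @param population A `rod_population`.
#' @param channels A [channel_model()] or list of them.
#' @param pixel_size Pixel size in micrometres (default 0.064).
#' @param defects A [defect_model()].
#' @param field_px Field size in pixels, `c(rows, cols)`; `NULL` sizes the
#'   field automatically to a packing fraction of about 7%.
#' @param phase_background Phase-channel background level.
#' @param phase_depth Fractional darkening of the cell body relative to the
#'   phase background.
#' @param phase_noise_sd Additive Gaussian noise of the phase channel.
#' @param min_separation_px Minimum clearance between cell outlines, pixels.
#' @param max_attempts Placement attempts per cell before giving up.
#' @param seed Optional seed; identical inputs give bit-identical images.
#' @return A list of class `rod_scene`: `images` (named list of numeric
#'   matrices, `"phase"` first), `labels` (integer matrix of ground-truth
#'   cell masks), `cells` (tibble with placement, `is_leaky`,
#'   `septal_present`), `blebs` (tibble, one row per punctum), `pixel_size`.
#' @export
render_scene <- function(population, channels, pixel_size = 0.064,
                         defects = defect_model(), field_px = NULL,
                         phase_background = 1000, phase_depth = 0.7,
                         phase_noise_sd = 0, min_separation_px = 5,
                         max_attempts = 5000, seed = NULL) {
  stopifnot(inherits(population, "rod_population"), pixel_size > 0)
  if (inherits(channels, "channel_model")) channels <- list(channels)
  stopifnot(all(vapply(channels, inherits, TRUE, "channel_model")))
  nm <- vapply(channels, function(ch) ch$name, "")
  if (anyDuplicated(nm)) stop("channel names must be unique", call. = FALSE)
  growth <- attr(population, "growth")
  n <- nrow(population)

  w_um <- growth$width
  w_px <- w_um / pixel_size
  len_px <- population$length_um / pixel_size

  if (is.null(field_px)) {
    cell_area <- sum(len_px * w_px) + 1
    side <- max(192L, as.integer(ceiling(sqrt(cell_area / 0.07))))
    field_px <- c(side, side)
  }
  nr <- field_px[1]; nc <- field_px[2]

  with_seed(seed, {
    # --- placement: spine segments with clearance ---------------------------
    margin <- max(len_px) / 2 + w_px + 2
    if (n > 0 && (nr < 2 * margin || nc < 2 * margin)) {
      stop(sprintf("field %dx%d too small for cells of length %.0f px; placed 0 of %d cells",
                   nr, nc, max(len_px), n), call. = FALSE)
    }
    A1 <- matrix(numeric(0), 0, 2); A2 <- matrix(numeric(0), 0, 2)
    cx <- cy <- th <- numeric(n)
    for (i in seq_len(n)) {
      half <- max(len_px[i] - w_px, 0) / 2
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        x <- runif(1, margin, nc - margin)
        y <- runif(1, margin, nr - margin)
        a <- runif(1, 0, pi)
        e1 <- c(x - half * cos(a), y - half * sin(a))
        e2 <- c(x + half * cos(a), y + half * sin(a))
        d <- seg_seg_dist(e1, e2, A1, A2)
        if (all(d >= w_px + min_separation_px)) {
          cx[i] <- x; cy[i] <- y; th[i] <- a
          A1 <- rbind(A1, e1); A2 <- rbind(A2, e2)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf("could not place all cells without overlap; placed %d of %d cells",
                     i - 1L, n), call. = FALSE)
      }
    }

    # --- defect assignment --------------------------------------------------
    is_leaky <- runif(n) < defects$leak_fraction
    septal_onsets <- vapply(channels, function(ch)
      if (ch$kind == "septal") ch$septal_onset_age else NA_real_, 0)
    septal_present <- if (all(is.na(septal_onsets))) rep(FALSE, n)
      else population$true_age >= min(septal_onsets, na.rm = TRUE)

    # --- rasterize ----------------------------------------------------------
    phase <- matrix(phase_background, nr, nc)
    labels <- matrix(0L, nr, nc)
    fluor <- lapply(channels, function(ch) matrix(0, nr, nc))
    sigma_c <- 0.12 # axial scale of the constriction notch, um
    depth_a <- constriction_depth_at(growth, population$true_age)

    env_idx <- which(vapply(channels, function(ch)
      ch$kind %in% c("contour", "periplasmic"), TRUE))

    for (i in seq_len(n)) {
      L <- population$length_um[i]
      half_spine <- max(L - w_um, 0) / 2
      ext <- ceiling(len_px[i] / 2 + 2)
      rows <- max(1, floor(cy[i] - ext)):min(nr, ceiling(cy[i] + ext))
      cols <- max(1, floor(cx[i] - ext)):min(nc, ceiling(cx[i] + ext))
      dx <- outer(rep(1, length(rows)), cols - cx[i]) * pixel_size
      dy <- outer(rows - cy[i], rep(1, length(cols))) * pixel_size
      s <- dx * cos(th[i]) + dy * sin(th[i])      # axial coordinate, um
      lat <- -dx * sin(th[i]) + dy * cos(th[i])   # lateral coordinate, um
      sc <- pmin(half_spine, pmax(-half_spine, s))
      d <- sqrt((s - sc)^2 + lat^2)               # distance to spine, um
      notch <- exp(-sc^2 / (2 * sigma_c^2))
      hw <- (w_um / 2) * (1 - depth_a[i] * notch)
      inside <- d <= hw
      if (!any(inside)) next

      sub <- cbind(rep(rows, times = length(cols))[as.vector(inside)],
                   rep(cols, each = length(rows))[as.vector(inside)])
      idx <- sub[, 1] + (sub[, 2] - 1L) * nr
      labels[idx] <- population$cell_id[i]
      phase[idx] <- phase_background * (1 - phase_depth) *
        (1 - depth_a[i] * notch[inside])

      for (k in seq_along(channels)) {
        ch <- channels[[k]]
        val <- switch(ch$kind,
          cytoplasmic = rep(ch$amplitude, sum(inside)),
          contour = ,
          periplasmic = {
            shell <- (hw[inside] - d[inside]) <= ch$shell_thickness
            amp <- ch$amplitude * if (is_leaky[i]) defects$leak_attenuation else 1
            ifelse(shell, amp, 0)
          },
          septal = {
            amp <- septal_amplitude_at(ch, population$true_age[i])
            amp * exp(-sc[inside]^2 / (2 * ch$septal_sigma^2))
          })
        if (any(val != 0)) fluor[[k]][idx] <- fluor[[k]][idx] + val
      }
    }

    # --- blebs --------------------------------------------------------------
    blebs <- tibble::tibble(bleb_id = integer(), cell_id = integer(),
                            x_px = numeric(), y_px = numeric(),
                            x_um = numeric(), y_um = numeric(),
                            radius_um = numeric(), amplitude = numeric())
    if (defects$bleb_rate > 0 && n > 0 && length(env_idx) > 0) {
      tgt <- env_idx[1]
      nb <- rpois(n, defects$bleb_rate)
      rows_list <- list()
      bid <- 0L
      for (i in which(nb > 0)) {
        L <- population$length_um[i]
        half_spine <- max(L - w_um, 0) / 2
        for (b in seq_len(nb[i])) {
          bid <- bid + 1L
          sb <- runif(1, -half_spine, half_spine)
          side <- sample(c(-1, 1), 1)
          off <- runif(1, 0.03, max(defects$bleb_max_offset, 0.04))
          latb <- side * (w_um / 2 + off)
          bx <- cx[i] + (sb * cos(th[i]) - latb * sin(th[i])) / pixel_size
          by <- cy[i] + (sb * sin(th[i]) + latb * cos(th[i])) / pixel_size
          r_px <- defects$bleb_radius / pixel_size
          ext <- ceiling(4 * r_px)
          rows <- max(1, floor(by - ext)):min(nr, ceiling(by + ext))
          cols <- max(1, floor(bx - ext)):min(nc, ceiling(bx + ext))
          d2 <- outer((rows - by)^2, rep(1, length(cols))) +
                outer(rep(1, length(rows)), (cols - bx)^2)
          fluor[[tgt]][rows, cols] <- fluor[[tgt]][rows, cols] +
            defects$bleb_amplitude * exp(-d2 / (2 * r_px^2))
          rows_list[[bid]] <- tibble::tibble(
            bleb_id = bid, cell_id = population$cell_id[i],
            x_px = bx, y_px = by,
            x_um = bx * pixel_size, y_um = by * pixel_size,
            radius_um = defects$bleb_radius, amplitude = defects$bleb_amplitude)
        }
      }
      if (bid > 0) blebs <- dplyr::bind_rows(rows_list)
    }

    # --- background + noise -------------------------------------------------
    if (phase_noise_sd > 0) phase <- phase + matrix(rnorm(nr * nc, 0, phase_noise_sd), nr, nc)
    for (k in seq_along(channels)) {
      ch <- channels[[k]]
      fluor[[k]] <- fluor[[k]] + ch$background
      if (ch$noise_sd > 0) {
        fluor[[k]] <- fluor[[k]] + matrix(rnorm(nr * nc, 0, ch$noise_sd), nr, nc)
      }
    }

    images <- c(list(phase = phase), setNames(fluor, nm))
    cells <- tibble::tibble(
      cell_id = population$cell_id,
      true_age = population$true_age,
      length_um = population$length_um,
      x_px = cx, y_px = cy, theta = th,
      is_leaky = is_leaky, septal_present = septal_present
    )
    structure(
      list(images = images, labels = labels, cells = cells, blebs = blebs,
           pixel_size = pixel_size, growth = growth, defects = defects),
      class = "rod_scene"
    )
  })
}

#' @export
print.rod_scene <- function(x, ...) {
  cat(sprintf("<rod_scene> %d x %d px (%.3f um/px), %d cells, %d blebs, channels: %s\n",
              nrow(x$images[[1]]), ncol(x$images[[1]]), x$pixel_size,
              nrow(x$cells), nrow(x$blebs),
              paste(names(x$images), collapse = ", ")))
  invisible(x)
}
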