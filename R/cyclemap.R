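#' Assign cell-cycle ages from length rank
#'
#' Maps each cell's length rank to a cell-cycle age under the steady-state
#' exponential-growth model: with rank fraction \eqn{F = (rank - 0.5)/n}
#' over ascending lengths (mid-rank convention), the age is the inverse of
#' the steady-state age CDF, \eqn{a = -\log_2(1 - F/2)}. Equal lengths are
#' tie-broken stably by `cell_id`.
#'
#' @param x A numeric vector of lengths (micrometres), or a data frame with
#'   a `length_um` column (e.g. a `rod_population` or `cell_table`; a
#'   `cell_id` column is used if present, otherwise row order).
#' @return A tibble of class `population_table` with columns `cell_id`,
#'   `length_um`, `rank_fraction` and `age` (plus `true_age` when the input
#'   carries it), sorted by ascending length.
#' @examples
#' assign_ages(c(2.2, 3.9, 2.8))
#' @export
assign_ages <- function(x) {
  if (is.data.frame(x)) {
    if (!"length_um" %in% names(x)) {
      stop("data-frame input must have a `length_um` column", call. = FALSE)
    }
    len <- x$length_um
    ids <- if ("cell_id" %in% names(x)) x$cell_id else seq_along(len)
    true_age <- if ("true_age" %in% names(x)) x$true_age else NULL
  } else {
    len <- as.numeric(x)
    ids <- seq_along(len)
    true_age <- NULL
  }
  n <- length(len)
  if (n == 0) {
    out <- tibble::tibble(cell_id = integer(), length_um = numeric(),
                          rank_fraction = numeric(), age = numeric())
    class(out) <- c("population_table", class(out))
    return(out)
  }
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("all lengths must be positive and finite", call. = FALSE)
  }
  ord <- order(len, ids)
  rk <- integer(n); rk[ord] <- seq_len(n)
  F <- (rk - 0.5) / n
  out <- tibble::tibble(
    cell_id = ids, length_um = len,
    rank_fraction = F, age = -log2(1 - F / 2)
  )
  if (!is.null(true_age)) out$true_age <- true_age
  out <- dplyr::arrange(out, .data$length_um, .data$cell_id)
  class(out) <- c("population_table", class(out))
  out
}

# resample one cell's profile (values over bins) onto n_cols normalized
# positions, conserving shape (linear interpolation of per-bin values)
.resample_profile <- function(values, n_cols) {
  nb <- length(values)
  if (nb == n_cols) return(values)
  pos <- (seq_len(nb) - 0.5) / nb
  out_pos <- (seq_len(n_cols) - 0.5) / n_cols
  approx(pos, values, xout = out_pos, rule = 2)$y * nb / n_cols
}

# long profiles -> named list of per-cell value vectors (bin-ordered)
.profiles_by_cell <- function(profiles) {
  stopifnot(all(c("cell_id", "bin", "value") %in% names(profiles)))
  sp <- split(profiles[order(profiles$cell_id, profiles$bin), ],
              f = factor(profiles$cell_id[order(profiles$cell_id, profiles$bin)]))
  lapply(sp, function(d) d$value)
}

#' Build a length-sorted profile map (demograph)
#'
#' Stacks per-cell axial profiles into a matrix whose rows are cells sorted
#' by ascending length (stable ties by `cell_id`) and whose columns are
#' normalized axial positions — the profile-map / demograph representation
#' in which each horizontal line is one cell and the vertical axis tracks
#' cell-cycle progression.
#'
#' @param profiles A long `axial_profiles` tibble.
#' @param table A `population_table` from [assign_ages()] covering every
#'   `cell_id` in `profiles`.
#' @param n_cols Number of normalized axial columns.
#' @return An object of class `profile_map`: list with `map` (cells x
#'   positions matrix), `cells` (tibble `row`, `cell_id`, `length_um`,
#'   `age`), `n_cols` and `channel`.
#' @export
build_profile_map <- function(profiles, table, n_cols = 50) {
  stopifnot(inherits(table, "population_table"), n_cols >= 2)
  by_cell <- .profiles_by_cell(profiles)
  ids <- as.integer(names(by_cell)) %||% names(by_cell)
  missing_ids <- setdiff(ids, table$cell_id)
  if (length(missing_ids) > 0) {
    stop(sprintf("profiles contain cell_id(s) absent from the population table: %s",
                 paste(head(missing_ids, 5), collapse = ", ")), call. = FALSE)
  }
  tab <- table[table$cell_id %in% ids, ]
  tab <- dplyr::arrange(tab, .data$length_um, .data$cell_id)
  m <- t(vapply(as.character(tab$cell_id),
                function(id) .resample_profile(by_cell[[id]], n_cols),
                numeric(n_cols)))
  rownames(m) <- NULL
  structure(
    list(
      map = m,
      cells = tibble::tibble(row = seq_len(nrow(tab)), cell_id = tab$cell_id,
                             length_um = tab$length_um, age = tab$age),
      n_cols = n_cols,
      channel = if ("channel" %in% names(profiles) && nrow(profiles) > 0)
        profiles$channel[1] else "fluor"
    ),
    class = "profile_map"
  )
}

#' @export
print.profile_map <- function(x, ...) {
  cat(sprintf("<profile_map> %s: %d cells x %d axial positions (lengths %.2f-%.2f um)\n",
              x$channel, nrow(x$map), x$n_cols,
              min(x$cells$length_um), max(x$cells$length_um)))
  invisible(x)
}

# sum of per-bin values over the axial interval [lo, hi] (um), fractional
# edge bins pro rata; bins have width length_um / n
.window_sum <- function(values, length_um, lo, hi) {
  nb <- length(values)
  bw <- length_um / nb
  lo <- max(0, lo); hi <- min(length_um, hi)
  if (hi <= lo) return(0)
  edges_lo <- (seq_len(nb) - 1) * bw
  edges_hi <- seq_len(nb) * bw
  cover <- pmax(0, pmin(hi, edges_hi) - pmax(lo, edges_lo)) / bw
  sum(values * cover)
}

#' Ring fraction: mid-cell share of total fluorescence
#'
#' Fraction of a cell's total fluorescence falling within an axial window
#' (default 0.8 µm) centred at mid-cell; fractional edge bins are counted
#' pro rata. The window is defined in absolute micrometres, applied before
#' any length normalization.
#'
#' @param values Per-bin integrated fluorescence of one cell.
#' @param length_um Cell length, micrometres.
#' @param window Mid-cell window width, micrometres.
#' @return A fraction in `[0, 1]` for nonnegative profiles; `NA` when the
#'   total is not positive (undefined, flagged rather than dropped).
#' @examples
#' ring_fraction(rep(1, 50), length_um = 4) # uniform: 0.8 / 4 = 0.2
#' @export
ring_fraction <- function(values, length_um, window = 0.8) {
  stopifnot(length_um > 0, window > 0)
  tot <- sum(values)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  mid <- length_um / 2
  .window_sum(values, length_um, mid - window / 2, mid + window / 2) / tot
}

#' Extra mid-cell fluorescence (FCplus)
#'
#' Fluorescence in the mid-cell window in excess of the local baseline: the
#' per-bin baseline is estimated as the mean over two flanking windows
#' (each `flank` µm wide, immediately adjacent to the mid-cell window), and
#' FCplus is the windowed sum minus baseline, clipped at zero. Uniform
#' profiles give 0; an added mid-cell band contributes its integrated
#' excess. Cells too short to fit the window plus both flanks return `NA`
#' (undefined, flagged).
#'
#' @inheritParams ring_fraction
#' @param flank Width of each flanking baseline window, micrometres.
#' @return Extra mid-cell fluorescence in integrated units (>= 0), or `NA`.
#' @export
fc_plus <- function(values, length_um, window = 0.8, flank = 0.8) {
  stopifnot(window > 0, flank > 0)
  if (length_um <= window + 2 * flank) return(NA_real_)
  nb <- length(values)
  bw <- length_um / nb
  mid <- length_um / 2
  w_lo <- mid - window / 2; w_hi <- mid + window / 2
  wsum <- .window_sum(values, length_um, w_lo, w_hi)
  fsum <- .window_sum(values, length_um, w_lo - flank, w_lo) +
          .window_sum(values, length_um, w_hi, w_hi + flank)
  baseline_per_bin <- fsum / (2 * flank / bw)
  max(0, wsum - baseline_per_bin * (window / bw))
}

#' Per-cell mid-cell statistics
#'
#' Computes [ring_fraction()] and [fc_plus()] for every cell of a profile
#' set, joined with assigned ages.
#'
#' @param profiles A long `axial_profiles` tibble.
#' @param table A `population_table` covering the profiled cells.
#' @param window,flank Mid-cell window and flank widths, micrometres.
#' @return A tibble of class `midcell_stats`: `cell_id`, `length_um`,
#'   `age`, `ring_fraction`, `fc_plus`, `fc_defined`.
#' @export
midcell_stats <- function(profiles, table, window = 0.8, flank = 0.8) {
  stopifnot(inherits(table, "population_table"))
  by_cell <- .profiles_by_cell(profiles)
  tab <- table[match(as.integer(names(by_cell)), table$cell_id), ]
  if (any(is.na(tab$cell_id))) {
    stop("profiles contain cell_ids absent from the population table", call. = FALSE)
  }
  out <- tibble::tibble(
    cell_id = tab$cell_id,
    length_um = tab$length_um,
    age = tab$age,
    ring_fraction = purrr::map2_dbl(by_cell, tab$length_um,
                                    ~ ring_fraction(.x, .y, window)),
    fc_plus = purrr::map2_dbl(by_cell, tab$length_um,
                              ~ fc_plus(.x, .y, window, flank))
  )
  out$fc_defined <- !is.na(out$fc_plus)
  out <- dplyr::arrange(out, .data$cell_id)
  attr(out, "window") <- window
  attr(out, "flank") <- flank
  class(out) <- c("midcell_stats", class(out))
  out
}

#' Age-class averaged profiles
#'
#' Bins cells into equal-width cell-cycle age classes (default 10 classes
#' of 10%), and for each class computes the mean length-normalized profile,
#' a peak-normalized copy (maximum scaled to 1), and the distribution of
#' per-cell extra mid-cell fluorescence (FCplus). Empty classes are
#' retained with count 0 and flagged, never dropped.
#'
#' @inheritParams midcell_stats
#' @param n_classes Number of equal-width age classes partitioning `[0, 1]`.
#' @param n_cols Number of normalized axial positions for the class-mean
#'   profiles; defaults to the profiles' bin count.
#' @return A tibble of class `age_class_summary`, one row per class:
#'   `class`, `age_lo`, `age_hi`, `n`, `mean_profile` and `peak_profile`
#'   (list-columns), `mid_excess` (list-column of per-cell FCplus),
#'   `mid_excess_mean`, `mid_excess_se`, `defined`.
#' @export
age_class_averages <- function(profiles, table, n_classes = 10,
                               window = 0.8, flank = 0.8, n_cols = NULL) {
  stopifnot(inherits(table, "population_table"), n_classes >= 2)
  by_cell <- .profiles_by_cell(profiles)
  n_cols <- n_cols %||% length(by_cell[[1]])
  tab <- table[match(as.integer(names(by_cell)), table$cell_id), ]
  if (any(is.na(tab$cell_id))) {
    stop("profiles contain cell_ids absent from the population table", call. = FALSE)
  }
  resampled <- lapply(by_cell, .resample_profile, n_cols = n_cols)
  fc <- purrr::map2_dbl(by_cell, tab$length_um, ~ fc_plus(.x, .y, window, flank))
  cls <- pmin(n_classes, findInterval(tab$age, seq(0, 1, length.out = n_classes + 1),
                                      rightmost.closed = TRUE))
  rows <- lapply(seq_len(n_classes), function(k) {
    sel <- which(cls == k)
    nk <- length(sel)
    if (nk > 0) {
      mp <- colMeans(do.call(rbind, resampled[sel]))
      pk <- if (max(mp) > 0) mp / max(mp) else mp
      ex <- fc[sel][!is.na(fc[sel])]
    } else {
      mp <- pk <- rep(NA_real_, n_cols)
      ex <- numeric(0)
    }
    tibble::tibble(
      class = k,
      age_lo = (k - 1) / n_classes, age_hi = k / n_classes,
      n = nk,
      mean_profile = list(mp), peak_profile = list(pk),
      mid_excess = list(ex),
      mid_excess_mean = if (length(ex) > 0) mean(ex) else NA_real_,
      mid_excess_se = if (length(ex) > 1) sd(ex) / sqrt(length(ex)) else NA_real_,
      defined = nk > 0
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_cols") <- n_cols
  attr(out, "window") <- window
  attr(out, "flank") <- flank
  class(out) <- c("age_class_summary", class(out))
  out
}

#' Initiation age of mid-cell localization
#'
#' The earliest age class whose mean extra mid-cell fluorescence rises more
#' than `se_mult` standard errors above the pooled level of all earlier
#' classes, with every later (nonempty) class also elevated above that same
#' level — a formalization of "the age class when increased localization at
#' mid-cell is first observed". Because ages come from length rank, a small
#' tail of post-onset cells is always smeared into earlier classes; at high
#' signal-to-noise a purely statistical rule would fire on that tail, so a
#' candidate class must additionally carry at least `min_rise` of the
#' maximal class-mean excess (a minimum effect size, i.e. an increase that
#' would actually be observed). Returns the lower bound of the winning
#' class, or `NA` if mid-cell signal never rises (a valid outcome).
#'
#' @param summary An `age_class_summary`.
#' @param se_mult Threshold multiplier on the pooled standard error.
#' @param min_rise Minimum class-mean excess above the pooled-earlier level,
#'   as a fraction of the maximal class-mean excess.
#' @return The initiation age (class lower bound, fraction of the cycle),
#'   or `NA_real_`.
#' @export
detect_initiation <- function(summary, se_mult = 2, min_rise = 0.1) {
  stopifnot(inherits(summary, "age_class_summary"))
  nonempty <- which(summary$n > 0 & !is.na(summary$mid_excess_mean))
  if (length(nonempty) < 3) return(NA_real_)
  peak <- max(summary$mid_excess_mean[nonempty])
  for (k in nonempty[-1]) {
    earlier <- unlist(summary$mid_excess[nonempty[nonempty < k]])
    if (length(earlier) < 2) next
    base <- mean(earlier)
    thr <- base + max(se_mult * sd(earlier) / sqrt(length(earlier)),
                      min_rise * (peak - base))
    later <- nonempty[nonempty >= k]
    if (all(summary$mid_excess_mean[later] > thr)) {
      return(summary$age_lo[k])
    }
  }
  NA_real_
}

#' Moment of peak mid-cell localization
#'
#' The age at which mid-cell fluorescence is highest: per-cell FCplus values
#' are averaged within equal-width age classes and the midpoint of the
#' maximal class is returned. `NA` when fewer than `min_cells` cells have a
#' defined FCplus or when no class has positive mean excess.
#'
#' @param stats A `midcell_stats` tibble (or any data frame with `age` and
#'   `fc_plus` columns).
#' @param n_classes Number of age classes.
#' @param min_cells Minimum number of cells with defined FCplus.
#' @return The moment age (class midpoint), or `NA_real_`.
#' @export
detect_moment <- function(stats, n_classes = 10, min_cells = 10) {
  stopifnot(all(c("age", "fc_plus") %in% names(stats)))
  ok <- !is.na(stats$fc_plus)
  if (sum(ok) < min_cells) return(NA_real_)
  age <- stats$age[ok]; fc <- stats$fc_plus[ok]
  cls <- pmin(n_classes, findInterval(age, seq(0, 1, length.out = n_classes + 1),
                                      rightmost.closed = TRUE))
  m <- tapply(fc, factor(cls, levels = seq_len(n_classes)), mean)
  if (all(is.na(m)) || max(m, na.rm = TRUE) <= 0) return(NA_real_)
  k <- unname(which.max(m))
  (k - 0.5) / n_classes
}
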