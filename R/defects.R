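abort_calibration <- function(msg) rlang::abort(msg, class = "rodmapr_calibration_error")

# linear-interpolation quantile (type 7), the fixed convention for every
# percentile threshold in this package
.lin_quantile <- function(x, q) unname(quantile(x, q, type = 7, names = FALSE))

#' Periplasmic-leakage threshold
#'
#' Calibrates the leakage threshold as a high percentile (default the 98th)
#' of the per-cell median contour fluorescences of a reference population
#' with known severe outer-membrane defects (a tolA-deletion-like
#' reference): by construction about 98% of the reference itself falls
#' below the threshold.
#'
#' @param reference Either a `contour_traces` tibble or a numeric vector of
#'   per-cell median contour fluorescences.
#' @param q Quantile used (default 0.98); linear-interpolation convention.
#' @param min_cells Minimum reference population size.
#' @return The threshold (single number) with the calibration size attached
#'   as attribute `n`.
#' @export
leakage_threshold <- function(reference, q = 0.98, min_cells = 50) {
  med <- if (inherits(reference, "contour_traces") || is.data.frame(reference)) {
    reference$median_value
  } else {
    as.numeric(reference)
  }
  med <- med[!is.na(med)]
  if (length(med) < min_cells) {
    abort_calibration(sprintf(
      "leakage threshold needs >= %d reference cells, got %d", min_cells, length(med)))
  }
  stopifnot(q > 0, q < 1)
  structure(.lin_quantile(med, q), n = length(med))
}

#' Classify periplasmic leakage
#'
#' A cell is called leaky when its median contour fluorescence falls
#' strictly below the calibrated threshold (a median exactly at the
#' threshold is not leaky).
#'
#' @param traces A `contour_traces` tibble.
#' @param threshold Threshold from [leakage_threshold()].
#' @return A tibble of class `leakage_calls`: `cell_id`,
#'   `median_contour_fluorescence`, `threshold_used`, `is_leaky`.
#' @export
classify_leakage <- function(traces, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  out <- tibble::tibble(
    cell_id = traces$cell_id,
    median_contour_fluorescence = traces$median_value,
    threshold_used = as.numeric(threshold),
    is_leaky = traces$median_value < as.numeric(threshold)
  )
  class(out) <- c("leakage_calls", class(out))
  out
}

#' Bleb brightness reference
#'
#' Calibrates the punctum brightness threshold as the 99.7th percentile of
#' wild-type cell brightness. "Cell brightness" is interpreted per pixel by
#' default — all fluorescence pixels inside reference cell masks pooled —
#' because puncta are pixel-scale objects; `mode = "per_cell_mean"` pools
#' per-cell mean brightnesses instead.
#'
#' @param cells A reference (wild-type-like) `cell_table`.
#' @param image Fluorescence channel matrix.
#' @param q Quantile (default 0.997); linear-interpolation convention.
#' @param min_cells Minimum reference population size.
#' @param mode `"per_pixel"` (default) or `"per_cell_mean"`.
#' @return The brightness threshold with calibration size attribute `n`.
#' @export
brightness_reference <- function(cells, image, q = 0.997, min_cells = 50,
                                 mode = c("per_pixel", "per_cell_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cells, "cell_table"), is.matrix(image), q > 0, q < 1)
  if (nrow(cells) < min_cells) {
    abort_calibration(sprintf(
      "brightness reference needs >= %d cells, got %d", min_cells, nrow(cells)))
  }
  nr <- nrow(image)
  vals <- lapply(cells$mask, function(m) image[m[, 1] + (m[, 2] - 1L) * nr])
  pool <- if (mode == "per_pixel") unlist(vals) else vapply(vals, mean, 0)
  structure(.lin_quantile(pool, q), n = nrow(cells))
}

# min Euclidean distance (um) from a set of pixel coordinates to the
# contour vertices of each cell; returns c(distance, cell_id)
.nearest_cell <- function(sub, cells, pixel_size) {
  best_d <- Inf; best_id <- NA_integer_
  rng_y <- range(sub[, 1]); rng_x <- range(sub[, 2])
  for (i in seq_len(nrow(cells))) {
    ct <- cells$contour[[i]]
    # bounding-box prefilter with the current best distance as margin
    marg <- if (is.finite(best_d)) best_d / pixel_size + 1 else Inf
    if (min(ct[, 1]) > rng_x[2] + marg || max(ct[, 1]) < rng_x[1] - marg ||
        min(ct[, 2]) > rng_y[2] + marg || max(ct[, 2]) < rng_y[1] - marg) next
    d2 <- outer(sub[, 1], ct[, 2], function(a, b) (a - b)^2) +
          outer(sub[, 2], ct[, 1], function(a, b) (a - b)^2)
    d <- sqrt(min(d2)) * pixel_size
    if (d < best_d) { best_d <- d; best_id <- cells$cell_id[i] }
  }
  c(best_d, best_id)
}

#' Detect outer-membrane blebs
#'
#' Finds isolated bright fluorescent puncta satisfying, simultaneously, the
#' three rules: mean brightness above the calibrated 99.7th-percentile
#' reference, area smaller than `area_max` (default 4 µm²), and lying
#' within `proximity_max` (default 0.3 µm) of a segmented cell. Candidate
#' puncta are connected components of supra-threshold pixels outside the
#' cell masks; each accepted bleb is assigned to its nearest cell.
#'
#' @param image Fluorescence channel matrix.
#' @param cells A `cell_table` of the segmented cells in the same field.
#' @param brightness_threshold Threshold from [brightness_reference()].
#' @param area_max Maximum punctum area, square micrometres (strict `<`).
#' @param proximity_max Maximum distance from punctum to the nearest cell
#'   contour, micrometres (inclusive `<=`).
#' @param pixel_size Pixel size, micrometres; defaults to the cell table's.
#' @return A tibble of class `bleb_calls`: `bleb_id`, centroid (`x_px`,
#'   `y_px`, `x_um`, `y_um`), `area_um2`, `mean_brightness`,
#'   `distance_um`, `cell_id` (nearest cell). Thresholds are attached as
#'   attributes. An empty tibble is a valid result.
#' @export
detect_blebs <- function(image, cells, brightness_threshold,
                         area_max = 4, proximity_max = 0.3,
                         pixel_size = attr(cells, "pixel_size") %||% 0.064) {
  stopifnot(is.matrix(image), inherits(cells, "cell_table"),
            is.numeric(brightness_threshold), area_max > 0, proximity_max >= 0)
  thr <- as.numeric(brightness_threshold)
  nr <- nrow(image)
  mask_all <- matrix(FALSE, nr, ncol(image))
  for (m in cells$mask) mask_all[m[, 1] + (m[, 2] - 1L) * nr] <- TRUE
  cand <- (image > thr) & !mask_all
  empty <- tibble::tibble(bleb_id = integer(), x_px = numeric(), y_px = numeric(),
                          x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
                          mean_brightness = numeric(), distance_um = numeric(),
                          cell_id = integer())
  finish <- function(tb) {
    attr(tb, "brightness_threshold") <- thr
    attr(tb, "area_max") <- area_max
    attr(tb, "proximity_max") <- proximity_max
    class(tb) <- c("bleb_calls", class(tb))
    tb
  }
  if (!any(cand)) return(finish(empty))
  lab <- as.matrix(EBImage::bwlabel(cand))
  px2 <- pixel_size^2
  rows <- list()
  bid <- 0L
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id)
    area_um2 <- length(idx) * px2
    if (area_um2 >= area_max) next
    mb <- mean(image[idx])
    if (mb <= thr) next
    sub <- cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
    nd <- .nearest_cell(sub, cells, pixel_size)
    if (!is.finite(nd[1]) || nd[1] > proximity_max) next
    bid <- bid + 1L
    rows[[bid]] <- tibble::tibble(
      bleb_id = bid,
      x_px = mean(sub[, 2]), y_px = mean(sub[, 1]),
      x_um = mean(sub[, 2]) * pixel_size, y_um = mean(sub[, 1]) * pixel_size,
      area_um2 = area_um2, mean_brightness = mb,
      distance_um = nd[1], cell_id = as.integer(nd[2])
    )
  }
  finish(if (bid > 0) dplyr::bind_rows(rows) else empty)
}

#' Summarise defect calls for a field
#'
#' @param leakage A `leakage_calls` tibble (or `NULL`).
#' @param blebs A `bleb_calls` tibble (or `NULL`).
#' @return A one-row tibble: `n_cells`, `fraction_leaky`, `n_blebs`,
#'   `blebs_per_100_cells`.
#' @export
defect_summary <- function(leakage = NULL, blebs = NULL) {
  n_cells <- if (!is.null(leakage)) nrow(leakage) else NA_integer_
  tibble::tibble(
    n_cells = n_cells,
    fraction_leaky = if (!is.null(leakage) && n_cells > 0)
      mean(leakage$is_leaky) else NA_real_,
    n_blebs = if (!is.null(blebs)) nrow(blebs) else NA_integer_,
    blebs_per_100_cells = if (!is.null(blebs) && !is.na(n_cells) && n_cells > 0)
      100 * nrow(blebs) / n_cells else NA_real_
  )
}
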