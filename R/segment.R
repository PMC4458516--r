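#' @importFrom dplyr bind_rows mutate filter arrange group_by summarise ungroup left_join n
NULL

# condition helpers
abort_shape <- function(msg) rlang::abort(msg, class = "rodmapr_shape_error")
abort_format <- function(msg) rlang::abort(msg, class = "rodmapr_format_error")

# core per-cell geometry: slices mask pixels along the principal axis into
# n_bins axial bins, returns the medial axis polyline, pole-to-pole length,
# per-bin diameter and per-bin mean image brightness, and the bin of every
# mask pixel.
.axis_profile <- function(sub, brightness, n_bins, min_aspect, pixel_size) {
  npx <- nrow(sub)
  if (npx < 4) abort_shape("object too small for axis fitting")
  y <- sub[, 1]; x <- sub[, 2]
  cx <- mean(x); cy <- mean(y)
  cv <- stats::cov(cbind(x - cx, y - cy))
  eg <- eigen(cv, symmetric = TRUE)
  u <- eg$vectors[, 1] # major axis direction (x, y)
  v <- c(-u[2], u[1])
  proj <- (x - cx) * u[1] + (y - cy) * u[2]
  lat <- (x - cx) * v[1] + (y - cy) * v[2]
  l_ext <- diff(range(proj)) + 1
  w_ext <- diff(range(lat)) + 1
  aspect <- l_ext / w_ext
  if (aspect < min_aspect) {
    abort_shape(sprintf(
      "object is not rod-shaped (aspect %.2f < %.2f): medial axis undefined",
      aspect, min_aspect))
  }

  edges <- seq(min(proj) - 0.5, max(proj) + 0.5, length.out = n_bins + 1)
  bin <- findInterval(proj, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1L; bin[bin > n_bins] <- n_bins

  mid <- tapply(lat, factor(bin, levels = seq_len(n_bins)), mean)
  dia <- tapply(lat, factor(bin, levels = seq_len(n_bins)),
                function(z) diff(range(z)) + 1)
  bri <- tapply(brightness, factor(bin, levels = seq_len(n_bins)), mean)
  # fill empty interior bins by interpolation
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  fill <- function(z) {
    ok <- !is.na(z)
    if (all(ok)) return(as.numeric(z))
    approx(centers[ok], z[ok], xout = centers, rule = 2)$y
  }
  mid <- fill(mid); dia <- fill(dia); bri <- fill(bri)
  # smooth the axis lateral offsets: slices are sub-pixel for long cells, so
  # per-slice means carry pixel noise that would inflate the arc length; a
  # lowess fit keeps mild curvature and suppresses that noise
  mid_s <- stats::lowess(centers, mid, f = 0.35, iter = 0)$y

  # axis polyline extended to the poles along the principal direction
  p_ax <- c(min(proj) - 0.5, centers, max(proj) + 0.5)
  l_ax <- c(mid_s[1], mid_s, mid_s[n_bins])
  ax <- cbind(x = cx + p_ax * u[1] + l_ax * v[1],
              y = cy + p_ax * u[2] + l_ax * v[2])
  arc <- sum(sqrt(diff(ax[, 1])^2 + diff(ax[, 2])^2))

  list(
    axis = ax,
    length_um = arc * pixel_size,
    aspect = aspect,
    diameter_profile = dia * pixel_size,
    phase_profile = bri,
    bin = as.integer(bin)
  )
}

# assemble a cell_table row set from a label matrix + phase image
.cells_from_label_matrix <- function(labels, phase, pixel_size, n_bins,
                                     min_aspect, min_area = NULL, max_area = NULL) {
  fg <- which(labels > 0)
  idx_by_id <- split(fg, labels[fg])
  idx_by_id <- idx_by_id[order(as.integer(names(idx_by_id)))]
  ids <- as.integer(names(idx_by_id))
  rows <- vector("list", length(ids))
  bad <- integer(0)
  px_area <- pixel_size^2
  nr_lab <- nrow(labels)
  for (j in seq_along(ids)) {
    id <- ids[j]
    idx <- idx_by_id[[j]]
    sub <- cbind(((idx - 1L) %% nr_lab) + 1L,
                 ((idx - 1L) %/% nr_lab) + 1L)
    area_um2 <- nrow(sub) * px_area
    if (!is.null(min_area) && area_um2 < min_area) next
    if (!is.null(max_area) && area_um2 > max_area) next
    # trace the boundary on a bounding-box crop (1-px pad)
    r0 <- min(sub[, 1]) - 1L; c0 <- min(sub[, 2]) - 1L
    crop <- matrix(0L, max(sub[, 1]) - r0 + 1L, max(sub[, 2]) - c0 + 1L)
    crop[cbind(sub[, 1] - r0, sub[, 2] - c0)] <- 1L
    oc <- EBImage::ocontour(crop)[[1]]
    # EBImage::ocontour: column 1 indexes dim1 (rows), column 2 dim2 (cols), 0-based
    contour <- cbind(x = oc[, 2] + c0 + 1L, y = oc[, 1] + r0 + 1L)
    geom <- tryCatch(
      .axis_profile(sub, phase[idx], n_bins, min_aspect, pixel_size),
      rodmapr_shape_error = function(e) e
    )
    ok <- !inherits(geom, "error")
    if (!ok) bad <- c(bad, id)
    rows[[j]] <- tibble::tibble(
      cell_id = id,
      area_px = nrow(sub),
      area_um2 = area_um2,
      centroid_x = mean(sub[, 2]),
      centroid_y = mean(sub[, 1]),
      length_um = if (ok) geom$length_um else NA_real_,
      aspect = if (ok) geom$aspect else NA_real_,
      shape_ok = ok,
      mask = list(if (ok) cbind(sub, bin = geom$bin) else cbind(sub, bin = NA_integer_)),
      contour = list(contour),
      axis = list(if (ok) geom$axis else NULL),
      diameter_profile = list(if (ok) geom$diameter_profile else NULL),
      phase_profile = list(if (ok) geom$phase_profile else NULL)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      cell_id = integer(), area_px = integer(), area_um2 = numeric(),
      centroid_x = numeric(), centroid_y = numeric(), length_um = numeric(),
      aspect = numeric(), shape_ok = logical(), mask = list(),
      contour = list(), axis = list(), diameter_profile = list(),
      phase_profile = list()
    )
  }
  if (length(bad) > 0) {
    warning(sprintf("%d object(s) not rod-shaped, profiles undefined: cell_id %s",
                    length(bad), paste(bad, collapse = ", ")), call. = FALSE)
  }
  attr(out, "pixel_size") <- pixel_size
  attr(out, "n_bins") <- n_bins
  attr(out, "field_dim") <- dim(labels)
  class(out) <- c("cell_table", class(out))
  out
}

#' Segment rod-shaped cells from a phase-contrast image
#'
#' Detects dark cells on a bright background: the image is inverted,
#' smoothed with a Gaussian, thresholded (Otsu), and connected components
#' are extracted, hole-filled and area-filtered. Each detected cell gets a
#' contour, a pole-to-pole medial axis, a length, and per-bin diameter and
#' phase-brightness profiles.
#'
#' Touching cells are not split; supply externally curated masks through
#' [cells_from_labels()] when cells may touch.
#'
#' @param phase_image Numeric matrix (single 2D channel).
#' @param pixel_size Pixel size in micrometres.
#' @param min_area,max_area Area filter bounds, in square micrometres.
#' @param n_bins Number of axial bins for the per-cell profiles.
#' @param min_aspect Minimum length/width ratio below which an object is
#'   flagged as not rod-shaped (its profiles are left undefined).
#' @param blur_sigma Gaussian smoothing sd before thresholding, pixels.
#' @return A tibble of class `cell_table`, one row per cell, with
#'   list-columns `mask` (pixel coordinates + axial bin), `contour`
#'   (ordered boundary polyline, x/y pixel coordinates), `axis`,
#'   `diameter_profile` and `phase_profile`. Pixel size, bin count and the
#'   field dimensions are attached as attributes.
#' @export
segment_cells <- function(phase_image, pixel_size = 0.064,
                          min_area = 0.5, max_area = 20,
                          n_bins = 50, min_aspect = 1.5, blur_sigma = 1) {
  if (!is.matrix(phase_image) || !is.numeric(phase_image)) {
    abort_format("`phase_image` must be a 2D numeric matrix")
  }
  stopifnot(pixel_size > 0)
  rng <- range(phase_image)
  empty <- .cells_from_label_matrix(matrix(0L, nrow(phase_image), ncol(phase_image)),
                                    phase_image, pixel_size, n_bins, min_aspect)
  if (diff(rng) < .Machine$double.eps * 10) return(empty) # uniform image
  inv <- rng[2] - phase_image
  if (blur_sigma > 0) inv <- as.matrix(EBImage::gblur(inv, sigma = blur_sigma))
  inv_n <- (inv - min(inv)) / diff(range(inv))
  thr <- EBImage::otsu(EBImage::Image(inv_n), range = c(0, 1))
  fg <- inv_n > thr
  if (mean(fg) > 0.5) return(empty) # no dark objects on bright background
  lab <- EBImage::bwlabel(EBImage::fillHull(fg))
  .cells_from_label_matrix(as.matrix(lab), phase_image, pixel_size, n_bins,
                           min_aspect, min_area, max_area)
}

#' Build a cell table from a label image
#'
#' Accepts externally supplied segmentation masks (integer label image,
#' 0 = background) and derives the same per-cell geometry as
#' [segment_cells()], preserving the label ids as `cell_id`.
#'
#' @param label_image Integer matrix; 0 is background.
#' @param intensity_image Optional matrix read for the brightness profile
#'   (defaults to the labels themselves, giving flat profiles).
#' @inheritParams segment_cells
#' @return A `cell_table` tibble; see [segment_cells()].
#' @export
cells_from_labels <- function(label_image, pixel_size = 0.064,
                              intensity_image = NULL,
                              n_bins = 50, min_aspect = 1.5) {
  if (!is.matrix(label_image)) abort_format("`label_image` must be a matrix")
  if (any(label_image != round(label_image)) || any(label_image < 0)) {
    abort_format("`label_image` must contain non-negative integer labels")
  }
  stopifnot(pixel_size > 0)
  if (is.null(intensity_image)) intensity_image <- label_image * 1.0
  .cells_from_label_matrix(matrix(as.integer(label_image), nrow(label_image)),
                           intensity_image, pixel_size, n_bins, min_aspect)
}

#' Recompute the medial axis and profiles of one cell
#'
#' Re-runs the axis/diameter/brightness extraction for a single row of a
#' `cell_table`, optionally with a different bin count. Round, blob-like
#' objects (aspect below `min_aspect`) raise a shape error rather than
#' being silently dropped.
#'
#' @param cell A one-row `cell_table`.
#' @param intensity_image Matrix to read brightness from; `NULL` reuses a
#'   flat image.
#' @inheritParams segment_cells
#' @return The input row with `axis`, `length_um`, `diameter_profile`,
#'   `phase_profile` and the per-pixel bin assignment updated.
#' @export
medial_axis_profile <- function(cell, intensity_image = NULL, n_bins = 50,
                                min_aspect = 1.5,
                                pixel_size = attr(cell, "pixel_size") %||% 0.064) {
  stopifnot(inherits(cell, "cell_table"), nrow(cell) == 1)
  sub <- cell$mask[[1]][, 1:2, drop = FALSE]
  bri <- if (is.null(intensity_image)) rep(1, nrow(sub))
         else intensity_image[sub[, 1] + (sub[, 2] - 1L) * nrow(intensity_image)]
  geom <- .axis_profile(sub, bri, n_bins, min_aspect, pixel_size)
  cell$length_um <- geom$length_um
  cell$aspect <- geom$aspect
  cell$shape_ok <- TRUE
  cell$mask[[1]] <- cbind(sub, bin = geom$bin)
  cell$axis[[1]] <- geom$axis
  cell$diameter_profile[[1]] <- geom$diameter_profile
  cell$phase_profile[[1]] <- geom$phase_profile
  attr(cell, "n_bins") <- n_bins
  cell
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells (%.3f um/px, %d axial bins)\n",
              nrow(x), attr(x, "pixel_size") %||% NA, attr(x, "n_bins") %||% NA))
  print(tibble::as_tibble(x[, setdiff(names(x), c("mask", "contour", "axis",
                                                  "diameter_profile", "phase_profile"))]), ...)
  invisible(x)
}
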