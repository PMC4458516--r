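# bilinear interpolation of a matrix at fractional (row, col) positions
.bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + (c0 - 1) * nr
  img[i00] * (1 - fr) * (1 - fc) + img[i00 + 1] * fr * (1 - fc) +
    img[i00 + nr] * (1 - fr) * fc + img[i00 + nr + 1] * fr * fc
}

#' Field background level
#'
#' Median intensity over all pixels not covered by any cell mask; the
#' baseline subtracted from fluorescence before profile integration, so
#' that percentile thresholds are comparable across fields.
#'
#' @param image Numeric matrix.
#' @param cells A `cell_table` whose masks are excluded.
#' @return A single number.
#' @export
field_background <- function(image, cells) {
  stopifnot(is.matrix(image), inherits(cells, "cell_table"))
  nr <- nrow(image)
  idx <- unlist(lapply(cells$mask, function(m) m[, 1] + (m[, 2] - 1L) * nr))
  if (length(idx) == 0) return(median(image))
  median(image[-idx])
}

#' Axial fluorescence profiles for a cell table
#'
#' Integrates background-subtracted fluorescence along each cell: every mask
#' pixel belongs to exactly one axial bin (nearest axial projection, ties to
#' the lower bin, as assigned during axis extraction), and bin values are
#' the sums of pixel intensities minus the field background. Cells without a
#' valid axis (blob-shaped) are skipped with a warning.
#'
#' @param cells A `cell_table`.
#' @param image Fluorescence channel, same dimensions as the segmented
#'   field.
#' @param channel Channel name recorded in the output.
#' @param background Background level; `NULL` (default) uses
#'   [field_background()].
#' @return A long tibble of class `axial_profiles`: `cell_id`, `channel`,
#'   `bin`, `position`, `value`; the background used is attached as an
#'   attribute.
#' @export
axial_profiles <- function(cells, image, channel = "fluor", background = NULL) {
  stopifnot(inherits(cells, "cell_table"), is.matrix(image))
  if (!is.null(attr(cells, "field_dim")) && !all(attr(cells, "field_dim") == dim(image))) {
    abort_format("image dimensions differ from the segmented field")
  }
  n_bins <- attr(cells, "n_bins")
  bg <- background %||% field_background(image, cells)
  nr <- nrow(image)
  usable <- cells$shape_ok
  if (any(!usable)) {
    warning(sprintf("skipping %d cell(s) without a valid axis", sum(!usable)),
            call. = FALSE)
  }
  rows <- lapply(which(usable), function(i) {
    m <- cells$mask[[i]]
    v <- image[m[, 1] + (m[, 2] - 1L) * nr] - bg
    vals <- vapply(seq_len(n_bins), function(b) sum(v[m[, 3] == b]), 0)
    tibble::tibble(
      cell_id = cells$cell_id[i], channel = channel,
      bin = seq_len(n_bins), position = (seq_len(n_bins) - 0.5) / n_bins,
      value = vals
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(cell_id = integer(), channel = character(),
                          bin = integer(), position = numeric(), value = numeric())
  }
  attr(out, "n_bins") <- n_bins
  attr(out, "background") <- bg
  class(out) <- c("axial_profiles", class(out))
  out
}

#' Per-cell diameter or phase-brightness profiles in long form
#'
#' Exposes the geometry profiles stored in a `cell_table` in the same long
#' format as [axial_profiles()], so diameter and phase-brightness maps can
#' be built with [build_profile_map()] exactly like fluorescence maps.
#'
#' @param cells A `cell_table`.
#' @param what `"diameter"` (micrometres) or `"phase"` (mean brightness).
#' @return A long tibble of class `axial_profiles`.
#' @export
cell_profiles <- function(cells, what = c("diameter", "phase")) {
  what <- match.arg(what)
  stopifnot(inherits(cells, "cell_table"))
  col <- if (what == "diameter") "diameter_profile" else "phase_profile"
  n_bins <- attr(cells, "n_bins")
  rows <- lapply(which(cells$shape_ok), function(i) {
    tibble::tibble(
      cell_id = cells$cell_id[i], channel = what,
      bin = seq_len(n_bins), position = (seq_len(n_bins) - 0.5) / n_bins,
      value = cells[[col]][[i]]
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_bins") <- n_bins
  class(out) <- c("axial_profiles", class(out))
  out
}

#' Contour fluorescence traces
#'
#' Samples fluorescence along each cell's closed contour at a fixed
#' arc-length spacing (default one pixel, 0.064 µm) by bilinear
#' interpolation, and records the median of the samples — the per-cell
#' statistic that the periplasmic-leakage classifier thresholds.
#'
#' @param cells A `cell_table`.
#' @param image Fluorescence channel matrix.
#' @param channel Channel name recorded in the output.
#' @param spacing Sample spacing along the contour, micrometres.
#' @param subtract_background Subtract the field background before sampling
#'   (default `TRUE`).
#' @param background Background level; `NULL` uses [field_background()].
#' @return A tibble of class `contour_traces`: `cell_id`, `channel`,
#'   `n_samples`, `perimeter_um`, `median_value`, and the raw `samples` as a
#'   list-column.
#' @export
contour_fluorescence <- function(cells, image, channel = "fluor",
                                 spacing = 0.064, subtract_background = TRUE,
                                 background = NULL) {
  stopifnot(inherits(cells, "cell_table"), is.matrix(image), spacing > 0)
  pixel_size <- attr(cells, "pixel_size")
  bg <- if (subtract_background) background %||% field_background(image, cells) else 0
  spacing_px <- spacing / pixel_size
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ct <- cells$contour[[i]]
    if (is.null(ct) || nrow(ct) < 3) {
      abort_shape(sprintf("cell %d has a degenerate contour (<3 vertices)",
                          cells$cell_id[i]))
    }
    ct <- rbind(ct, ct[1, , drop = FALSE]) # close
    seg <- sqrt(diff(ct[, 1])^2 + diff(ct[, 2])^2)
    arc <- c(0, cumsum(seg))
    per <- arc[length(arc)]
    n_s <- max(3L, floor(per / spacing_px))
    at <- (seq_len(n_s) - 1) * per / n_s
    xs <- approx(arc, ct[, 1], xout = at)$y
    ys <- approx(arc, ct[, 2], xout = at)$y
    smp <- .bilinear(image, ys, xs) - bg
    tibble::tibble(
      cell_id = cells$cell_id[i], channel = channel,
      n_samples = n_s, perimeter_um = per * pixel_size,
      median_value = median(smp), samples = list(smp)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(cell_id = integer(), channel = character(),
                          n_samples = integer(), perimeter_um = numeric(),
                          median_value = numeric(), samples = list())
  }
  attr(out, "spacing") <- spacing
  attr(out, "background") <- bg
  class(out) <- c("contour_traces", class(out))
  out
}
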