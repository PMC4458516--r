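#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an age-class summary
#'
#' One row per age class with the scalar statistics (list-column profiles
#' are dropped).
#'
#' @param x An `age_class_summary`.
#' @param ... Unused.
#' @return A tibble: `class`, `age_lo`, `age_hi`, `n`, `mid_excess_mean`,
#'   `mid_excess_se`, `defined`.
#' @export
tidy.age_class_summary <- function(x, ...) {
  tibble::as_tibble(x[, c("class", "age_lo", "age_hi", "n",
                          "mid_excess_mean", "mid_excess_se", "defined")])
}

#' Summarise an age-class summary in one row
#'
#' @param x An `age_class_summary`.
#' @param ... Unused.
#' @return A one-row tibble: `n_classes`, `n_cells`, `initiation_age`.
#' @export
glance.age_class_summary <- function(x, ...) {
  tibble::tibble(
    n_classes = nrow(x),
    n_cells = sum(x$n),
    initiation_age = detect_initiation(x)
  )
}

#' Tidy per-cell mid-cell statistics
#'
#' @param x A `midcell_stats` tibble.
#' @param ... Unused.
#' @return The per-cell tibble (plain).
#' @export
tidy.midcell_stats <- function(x, ...) tibble::as_tibble(x)

#' Summarise mid-cell statistics in one row
#'
#' @param x A `midcell_stats` tibble.
#' @param ... Passed to [detect_moment()].
#' @return A one-row tibble: `n_cells`, `n_fc_defined`,
#'   `mean_ring_fraction`, `moment_age`.
#' @export
glance.midcell_stats <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_fc_defined = sum(x$fc_defined),
    mean_ring_fraction = mean(x$ring_fraction, na.rm = TRUE),
    moment_age = detect_moment(x, ...)
  )
}

#' Tidy a profile map
#'
#' Long form of the map matrix, one row per (cell, axial position).
#'
#' @param x A `profile_map`.
#' @param ... Unused.
#' @return A tibble: `row`, `cell_id`, `length_um`, `age`, `position`,
#'   `value`.
#' @export
tidy.profile_map <- function(x, ...) {
  n_cols <- x$n_cols
  tibble::tibble(
    row = rep(x$cells$row, each = n_cols),
    cell_id = rep(x$cells$cell_id, each = n_cols),
    length_um = rep(x$cells$length_um, each = n_cols),
    age = rep(x$cells$age, each = n_cols),
    position = rep((seq_len(n_cols) - 0.5) / n_cols, nrow(x$map)),
    value = as.vector(t(x$map))
  )
}

#' @rdname tidy.profile_map
#' @export
glance.profile_map <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$map), n_cols = x$n_cols, channel = x$channel,
    min_length_um = min(x$cells$length_um),
    max_length_um = max(x$cells$length_um)
  )
}
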