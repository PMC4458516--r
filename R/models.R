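#' Growth model for a steady-state rod-shaped cell population
#'
#' Describes the deterministic growth law of a rod-shaped cell over one
#' division cycle. Length doubles exponentially with cell-cycle age
#' \eqn{a \in [0,1]}: \eqn{L(a) = L_0 \cdot 2^a}, so \eqn{L(0) = L_0} and
#' \eqn{L(1) = 2 L_0}. Cells past `constriction_onset_age` develop a mid-cell
#' constriction whose depth grows linearly with age, reaching
#' `constriction_depth` (as a fraction of the cell width) at division.
#'
#' @param birth_length Length at birth \eqn{L_0}, in micrometres.
#' @param width Cell width (diameter), in micrometres.
#' @param constriction_onset_age Age at which mid-cell constriction begins,
#'   as a fraction of the cycle in `[0, 1]`.
#' @param constriction_depth Fractional reduction of width at mid-cell at the
#'   end of the cycle, in `[0, 1)`.
#' @param length_cv Coefficient of variation of multiplicative length noise
#'   applied on top of the growth law when populations are sampled
#'   (biological + measurement variability).
#'
#' @return An object of class `growth_model` (a validated list).
#' @examples
#' growth_model(birth_length = 2, width = 0.9)
#' @export
growth_model <- function(birth_length = 2,
                         width = 0.9,
                         constriction_onset_age = 0.6,
                         constriction_depth = 0.6,
                         length_cv = 0.05) {
  stopifnot(
    is.numeric(birth_length), birth_length > 0,
    is.numeric(width), width > 0,
    constriction_onset_age >= 0, constriction_onset_age <= 1,
    constriction_depth >= 0, constriction_depth < 1,
    length_cv >= 0
  )
  structure(
    list(
      birth_length = birth_length,
      width = width,
      constriction_onset_age = constriction_onset_age,
      constriction_depth = constriction_depth,
      length_cv = length_cv
    ),
    class = "growth_model"
  )
}

#' Fluorescence channel model
#'
#' Describes one fluorescence channel of a synthetic scene by its
#' localization class:
#' \describe{
#'   \item{`cytoplasmic`}{uniform signal over the whole cell body.}
#'   \item{`contour` / `periplasmic`}{signal confined to a thin shell at the
#'     cell envelope (membrane stain or periplasm-confined protein). Both
#'     kinds render identically and both are attenuated in leaky cells.}
#'   \item{`septal`}{a Gaussian band across mid-cell, present only in cells
#'     whose age has passed `septal_onset_age` (a division protein recruited
#'     late in the cycle).}
#' }
#'
#' For septal channels the band amplitude can vary over the cycle: it ramps
#' linearly from 0 at `septal_onset_age` to the full `amplitude` at
#' `septal_peak_age`, then declines linearly to `septal_decline` times the
#' full amplitude at division. With `septal_peak_age = NULL` the band has
#' constant amplitude from onset onwards.
#'
#' @param kind One of `"cytoplasmic"`, `"contour"`, `"septal"`,
#'   `"periplasmic"`.
#' @param amplitude Per-pixel signal amplitude, arbitrary fluorescence units.
#' @param septal_onset_age Age (fraction of cycle) at which the septal band
#'   appears. Ignored for other kinds.
#' @param septal_peak_age Age of maximal septal band amplitude, or `NULL`
#'   for a constant band after onset.
#' @param septal_decline Fraction of the peak amplitude remaining at age 1
#'   when `septal_peak_age` is set.
#' @param septal_sigma Axial standard deviation of the septal band, in
#'   micrometres.
#' @param shell_thickness Thickness of the envelope shell for
#'   contour/periplasmic kinds, in micrometres.
#' @param noise_sd Per-pixel additive Gaussian noise, fluorescence units.
#' @param background Constant background level added to the channel.
#' @param name Channel name used in output tables; defaults to `kind`.
#'
#' @return An object of class `channel_model`.
#' @examples
#' channel_model("septal", amplitude = 50, septal_onset_age = 0.4)
#' @export
channel_model <- function(kind = c("cytoplasmic", "contour", "septal", "periplasmic"),
                          amplitude = 100,
                          septal_onset_age = 0.4,
                          septal_peak_age = NULL,
                          septal_decline = 0.2,
                          septal_sigma = 0.15,
                          shell_thickness = 0.13,
                          noise_sd = 0,
                          background = 0,
                          name = NULL) {
  kind <- match.arg(kind)
  stopifnot(
    amplitude >= 0, noise_sd >= 0,
    septal_onset_age >= 0, septal_onset_age <= 1,
    septal_sigma > 0, shell_thickness > 0,
    septal_decline >= 0, septal_decline <= 1
  )
  if (!is.null(septal_peak_age)) {
    stopifnot(septal_peak_age >= septal_onset_age, septal_peak_age <= 1)
  }
  structure(
    list(
      kind = kind,
      amplitude = amplitude,
      septal_onset_age = septal_onset_age,
      septal_peak_age = septal_peak_age,
      septal_decline = septal_decline,
      septal_sigma = septal_sigma,
      shell_thickness = shell_thickness,
      noise_sd = noise_sd,
      background = background,
      name = name %||% kind
    ),
    class = "channel_model"
  )
}

#' Envelope-defect model
#'
#' Parameters of the defects injected into synthetic scenes: periplasmic
#' leakage (a random fraction of cells whose envelope signal is attenuated)
#' and outer-membrane blebs/vesicles (bright Gaussian puncta placed just
#' outside the cell contour, rendered into the envelope channel).
#'
#' @param leak_fraction Fraction of cells that are leaky, in `[0, 1]`.
#' @param leak_attenuation Multiplicative factor applied to the
#'   contour/periplasmic signal of leaky cells (e.g. 0.2 keeps 20%).
#' @param bleb_rate Expected number of blebs per cell (Poisson).
#' @param bleb_amplitude Peak amplitude of a bleb punctum, fluorescence
#'   units.
#' @param bleb_radius Gaussian radius (sd) of a punctum, micrometres.
#' @param bleb_max_offset Maximum distance of a punctum centre from the
#'   parent cell's contour, micrometres.
#'
#' @return An object of class `defect_model`.
#' @export
defect_model <- function(leak_fraction = 0,
                         leak_attenuation = 0.2,
                         bleb_rate = 0,
                         bleb_amplitude = 500,
                         bleb_radius = 0.15,
                         bleb_max_offset = 0.2) {
  stopifnot(
    leak_fraction >= 0, leak_fraction <= 1,
    leak_attenuation >= 0, bleb_rate >= 0,
    bleb_amplitude >= 0, bleb_radius > 0, bleb_max_offset >= 0
  )
  structure(
    list(
      leak_fraction = leak_fraction,
      leak_attenuation = leak_attenuation,
      bleb_rate = bleb_rate,
      bleb_amplitude = bleb_amplitude,
      bleb_radius = bleb_radius,
      bleb_max_offset = bleb_max_offset
    ),
    class = "defect_model"
  )
}

# septal band amplitude at age a (0 before onset; optional ramp to a peak age)
septal_amplitude_at <- function(channel, age) {
  on <- channel$septal_onset_age
  amp <- rep(0, length(age))
  active <- age >= on
  if (is.null(channel$septal_peak_age)) {
    amp[active] <- channel$amplitude
  } else {
    pk <- channel$septal_peak_age
    rise <- active & age <= pk
    fall <- active & age > pk
    if (pk > on) {
      amp[rise] <- channel$amplitude * (age[rise] - on) / (pk - on)
    } else {
      amp[rise] <- channel$amplitude
    }
    if (any(fall)) {
      frac <- if (pk < 1) (age[fall] - pk) / (1 - pk) else 0
      amp[fall] <- channel$amplitude * (1 - (1 - channel$septal_decline) * frac)
    }
  }
  amp
}

# fractional constriction depth at age a under a growth model
constriction_depth_at <- function(growth, age) {
  on <- growth$constriction_onset_age
  d <- rep(0, length(age))
  past <- age >= on
  if (on < 1) {
    d[past] <- growth$constriction_depth * (age[past] - on) / (1 - on)
  } else {
    d[past] <- growth$constriction_depth
  }
  d
}
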