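---
title: "Methods: cell-cycle profile maps and envelope-defect quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle profile maps and envelope-defect quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodmapr)
```

## Scope

rodmapr quantifies where fluorescently labelled proteins sit along
rod-shaped bacterial cells as a function of cell-cycle progression, and
classifies two envelope defects — periplasmic leakage and outer-membrane
(OM) blebbing — from periplasmic fluorescence. Because population snapshots
carry no explicit time axis, all cell-cycle statements rest on a single
modelling assumption described next. A synthetic scene generator with full
ground truth backs every quantitative claim the package makes about itself.

## The steady-state age model

In a steady-state exponentially growing culture the distribution of
cell-cycle ages $a \in [0,1]$ is time-invariant,

$$p(a) = 2\ln 2\; 2^{-a}, \qquad F(a) = 2\,(1 - 2^{-a}),$$

with newborns twice as frequent as dividing cells. Assuming exponential
("logarithmic") growth of cell length, $L(a) = L_0 2^a$, length rank is a
monotone proxy for age, so the rank of a cell among $n$ cells sorted by
length determines its age:

$$F_i = \frac{\mathrm{rank}_i - 0.5}{n}, \qquad
  a_i = -\log_2\!\left(1 - F_i/2\right).$$

The mid-rank convention avoids the $F = 0$ and $F = 1$ singularities; ties
in length are broken stably by cell id so the mapping is deterministic.
The mean of $p$ is $1/\ln 2 - 1 \approx 0.4427$, which the test suite uses
as a closed-form oracle. Age assignment is exact by construction up to
length noise: with 5% multiplicative length variability the true/assigned
age correlation stays above 0.95 at $n \ge 1000$ (measured, not assumed).

This is the one place the pipeline injects biology into geometry: if a
culture is not in steady state (stressed, stationary, filamenting), the
rank-to-age mapping is not valid and downstream "ages" are only length
ranks in disguise.

## Per-cell measurements

**Segmentation.** Cells are detected in a phase-contrast-like channel as
dark objects on a bright background: intensity inversion, Gaussian
smoothing (sd 1 px), Otsu threshold, hole filling, connected components,
and an area filter (defaults 0.5–20 µm²). Touching cells are not split;
externally curated masks can be supplied as a label image instead
(`cells_from_labels()`), which yields identical downstream behaviour.

**Medial axis and profiles.** Mask pixels are sliced into `n_bins`
(default 50) bins along the principal axis; the per-slice lateral mean
gives the medial axis, the per-slice lateral extent the diameter profile,
and the per-slice mean phase brightness the brightness profile. Because
slices are narrower than one pixel for long cells, raw per-slice means
carry pixel noise that would inflate the axis arc length; the lateral
offsets are therefore smoothed with a lowess fit (span 0.35) before the
pole-to-pole length is measured. On noiseless synthetic rods this keeps
the mean absolute length error near 0.5 px (tested at 2 px). Objects with
a length-to-width ratio below 1.5 are flagged with a shape error rather
than silently dropped: a medial axis of a round blob is not meaningful.

**Axial fluorescence profiles.** Each mask pixel belongs to exactly one
axial bin (nearest projection, ties to the lower bin); bin values are sums
of background-subtracted intensities, where the background is the median
over all non-cell pixels of the field. Per-field median subtraction was
chosen because the defect classifiers compare percentile thresholds across
fields, which requires comparable baselines. Mass is conserved: the profile
total equals the background-subtracted mask total to within floating
error (tested at 1%).

**Contour traces.** The closed cell contour is resampled by arc length at
a fixed spacing (default one pixel, 0.064 µm) and fluorescence is read by
bilinear interpolation; the per-cell statistic is the median of the
samples. Background subtraction before sampling is on by default and
exposed as a switch, since either convention is defensible; the leakage
classifier is invariant to it as long as reference and test fields are
treated alike (tested as an affine-invariance property).

## Population statistics

**Profile maps.** Per-cell profiles are length-normalized, resampled to a
fixed number of columns (conserving each cell's total), and stacked in
ascending length order — the demograph representation. The vertical axis
can be labelled by cell row or by % cell-cycle progression; both are
provided because the mapping from row to age is nonlinear.

**Age classes.** Cells are binned into 10 equal-width age classes (10% of
the cycle each). Class profiles are averaged and optionally normalized to
their peak. Empty classes are kept with count 0 and flagged. At the
population sizes used here (3000–4000 cells) the central classes hold
roughly 300–500 cells.

**Ring fraction.** The fraction of a cell's total fluorescence inside an
axial window of 0.8 µm centred at mid-cell. The window is defined in
absolute micrometres and applied before length normalization; fractional
edge bins count pro rata. For a uniform profile this is exactly
window/length; for a mid-cell Gaussian with $\sigma = 0.2$ µm in a 3 µm
cell it agrees with the numerical integral (0.9545) to $10^{-6}$ when the
window edges align with bin boundaries and to $10^{-2}$ at the default 50
bins.

**FCplus (extra mid-cell fluorescence).** The published macro's formula is
not public, so the definition here is stated in full: the sum over the
0.8 µm mid-cell window minus a baseline, where the baseline is the mean
per-bin level over two flanking windows of 0.8 µm each (matching the
ring-fraction rectangle), clipped at zero. Uniform profiles give exactly
0; an injected mid-cell band of integrated excess $A$ (σ = 0.15 µm) is
recovered to within 2% (the missing mass is the ~1% of the band outside
the window); the statistic is linear in amplitude before clipping. Cells
shorter than window + 2·flank = 2.4 µm cannot support the baseline and
return `NA` — an explicit flagged result, never a silent drop.

**Initiation.** The earliest age class whose mean FCplus exceeds the
pooled FCplus of all earlier classes by more than 2 pooled standard
errors, with all later classes also above that level. Two refinements
proved necessary. First, the threshold multiplier is a parameter (default
2). Second, a pure significance rule is biased early at realistic
signal-to-noise: rank-based ages smear a small tail of post-onset cells
into earlier classes, and with hundreds of cells per class even a 1%
contamination is "significant". A candidate class must therefore also rise
by at least 10% of the maximal class-mean excess (`min_rise`), which
restores the intended meaning of an increase that would actually be
observed in the class profiles. With that rule, generative onsets of 0.3,
0.4 and 0.5 are recovered within one age class across seeds at $n = 3000$.

**Moment.** The midpoint of the age class with the maximal mean FCplus.
No smoothing over classes is applied (none is described for the original
procedure); the recovered moment for a generative amplitude peak at age
0.65 is 0.65–0.75 depending on onset, within one class. The late bias for
late onsets is a real property of the estimator: the amplitude ramp rises
faster than it falls, so age smearing pushes the class-mean maximum
slightly right.

## Envelope-defect classifiers

**Leakage.** The threshold is the 98th percentile of per-cell median
contour fluorescence in a reference population with known severe OM
defects (fully leaky in the synthetic case); a cell is leaky when its
median falls strictly below the threshold. By construction ~98% of the
reference itself is called leaky (tested at ±2% with 500 reference
cells). On mixed populations (30% leaky, envelope signal attenuated to
20%, 5% per-pixel noise) sensitivity and specificity both exceed 0.95
against ground truth.

**Blebs.** Candidate puncta are connected components of supra-threshold
pixels outside cell masks. A punctum is a bleb when, simultaneously, its
mean brightness exceeds the 99.7th percentile of reference ("wild-type")
cell brightness, its area is below 4 µm² (strict), and it lies within
0.3 µm of a segmented cell (inclusive). Three interpretation choices are
fixed and documented:

* "Cell brightness" is pooled per pixel over reference masks (default),
  not per-cell means — puncta are pixel-scale objects, so a pixel-level
  null is the meaningful comparison. `per_cell_mean` is available.
* "Isolated" means a distinct connected component; no extra separation
  radius is imposed.
* Punctum-to-cell distance is the Euclidean distance from component
  pixels to the nearest cell boundary pixel (sub-pixel only through pixel
  centres; the ≤ 0.5 px ≈ 0.03 µm discretisation is small against the
  0.3 µm rule). Brightness is not background-subtracted before
  comparison; reference and puncta are treated identically, so the
  comparison is internally consistent.

All quantile thresholds use the linear-interpolation convention
(`type = 7`), fixed for bit-reproducibility; the examples in the test
suite pin it with order-statistics oracles (1…100 at q = 0.98 gives
98.02; 1…1000 at q = 0.997 gives 997.003).

## The synthetic scene generator

The generator emulates exactly the statistical structure the analysis
assumes, with ground truth for every quantity:

* ages from $p(a)$ by inverse-CDF sampling; lengths $L_0 2^a$ with
  multiplicative log-normal noise (default CV 5%);
* 2D spherocylinders placed by rejection sampling with a minimum 5 px
  clearance (touching-cell resolution is deliberately out of scope);
* a phase-contrast proxy: dark rods (70% darkening) on a bright
  background; constriction as a geometric narrowing plus a Gaussian
  brightness notch at mid-cell (axial scale 0.12 µm), both growing
  linearly from the constriction onset age (default 0.6) to the final
  depth (default 60% of width);
* fluorescence classes: cytoplasmic (uniform), contour/periplasmic (a
  0.13 µm envelope shell), septal (Gaussian band, σ = 0.15 µm, gated by
  an onset age). Septal amplitude can ramp to a peak age and decline to
  20% of peak at division, emulating assembly and disassembly of the
  division ring — without a decline there would be no recoverable peak;
* defects: leaky cells with envelope signal multiplied by an attenuation
  factor; blebs as Gaussian puncta (σ = 0.15 µm) within 0.2 µm of the
  parent contour, drawn per cell from a Poisson rate;
* additive Gaussian per-pixel noise. Poisson (shot) noise is deliberately
  omitted: the classifiers under test are threshold rules, for which
  Gaussian noise of matched variance is an adequate stress.

The analytic profile path (`simulate_profiles()`) integrates the same
generative model per axial bin without rasterising, with per-bin noise
scaled to the bin's pixel area so that analytic and rendered experiments
share one noise parameterisation. Population-scale statistics
(n = 3000–10,000) are validated on this path; the pixel path (render →
segment → profile) is validated end-to-end at 60–500 cells per field.
These sizes make the whole validation suite run in about a minute while
keeping class occupancies (300–500 cells) at realistic levels.

What the generator does **not** emulate — and what passing tests therefore
do not establish for real data: realistic phase-contrast optics (only a
single Gaussian blur scale), shot noise and camera gain, cell curvature
and chaining, touching or overlapping cells, focal drift, uneven
illumination, and fixation artefacts. Real-data use should supply curated
masks via `cells_from_labels()` when segmentation conditions differ from
the generator's assumptions.

## Defaults and units

| Parameter | Default | Unit | Origin |
|---|---|---|---|
| pixel size | 0.064 | µm/px | imaging convention of the procedure |
| axial bins / map columns | 50 | – | profiles are length-normalized downstream |
| age classes | 10 | – | 10% classes |
| mid-cell window | 0.8 | µm | ring-fraction rectangle |
| baseline flank | 0.8 | µm | matched to the window |
| leakage quantile | 0.98 | – | reference-population percentile rule |
| bleb brightness quantile | 0.997 | – | reference-population percentile rule |
| bleb area cutoff | 4 | µm² | strict upper bound |
| bleb proximity cutoff | 0.3 | µm | inclusive upper bound |
| birth length / width | 2 / 0.9 | µm | typical slow-growing rod; generation-time differences between media change real length distributions, so these defaults are nominal |

## Known limitations

* The rank-to-age mapping inherits all caveats of the steady-state
  assumption; length noise propagates into ages as σ ≈ CV/ln 2.
* Initiation/moment are class-resolution estimates (±1 class); no
  sub-class interpolation is attempted.
* The segmentation is intentionally minimal (no watershed, no curvature
  model); it exists to reproduce the per-cell measurements the analysis
  consumes, not to compete with dedicated segmentation tools.
* FCplus follows the windowed-baseline definition stated above; other
  reasonable definitions (e.g. fitted baselines) would shift absolute
  values but not the class-level timing statistics.
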