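# rodmapr

Cell-cycle-resolved fluorescence localization analysis and envelope-defect
quantification for rod-shaped bacteria.

Snapshot microscopy of a growing *E. coli*-like culture contains a hidden
time axis: in a steady-state exponential population, a cell's length rank
encodes its cell-cycle age. rodmapr exploits this to answer two kinds of
questions microbiologists ask of such images:

1. **When in the division cycle does a protein move to mid-cell?**
   Per-cell axial fluorescence profiles are stacked into length-sorted
   *profile maps* (demographs), cells are assigned ages from length rank,
   and mid-cell recruitment is quantified per cell (*ring fraction*, extra
   mid-cell fluorescence *FCplus*) and per population (*initiation*: the
   age class where mid-cell enrichment first appears; *moment*: the age of
   maximal enrichment).
2. **Which cells have a compromised envelope?** From a periplasmic
   fluorescence channel, cells are classified as exhibiting *periplasmic
   leakage* when their median contour fluorescence falls below the 98th
   percentile of a defective reference population, and *OM blebs* are
   detected as isolated bright puncta (brightness above the 99.7th
   percentile of reference cell brightness, area < 4 µm², within 0.3 µm of
   a cell).

## The model

For a steady-state culture with exponential length growth
`L(a) = L0 * 2^a`, the age density is `p(a) = 2 ln2 * 2^(-a)` with CDF
`F(a) = 2 (1 - 2^(-a))`. Ages are assigned by inverting the CDF at the
mid-rank fraction:

```
F_i = (rank_i - 0.5) / n        (ascending length, stable ties)
a_i = -log2(1 - F_i / 2)
```

Mid-cell statistics use an absolute 0.8 µm axial window centred at
mid-cell: the ring fraction is the windowed share of total fluorescence;
FCplus is the windowed sum minus a baseline estimated from two adjacent
0.8 µm flanks, clipped at zero. All thresholds in the defect classifiers
are linear-interpolation quantiles. Full definitions, defaults and design
rationale are in `vignettes/methods.Rmd`.

Because no public imaging data accompany these procedures, the package
ships a synthetic scene generator (`sample_population()`,
`render_scene()`, `simulate_profiles()`) that emulates steady-state
populations, localization classes (cytoplasmic, envelope, septal with a
configurable onset), constriction, leaky cells and blebs — with complete
ground truth, so every stage is validated against known answers.

## Worked example

Simulate a 3000-cell steady-state population carrying a division-septum
marker that appears at 40% of the cycle and peaks at 65%, then recover
those timings:

```r
library(rodmapr)

pop <- sample_population(3000, growth_model(), seed = 1)
channels <- list(
  channel_model("cytoplasmic", amplitude = 80),
  channel_model("septal", amplitude = 60, septal_onset_age = 0.4,
                septal_peak_age = 0.65)
)
profiles <- simulate_profiles(pop, channels, noise_sd = 3, seed = 2)
ages <- assign_ages(profile_truth(profiles))

summary10 <- age_class_averages(profiles, ages)
tidy(summary10)
#> # A tibble: 10 × 7
#>    class age_lo age_hi     n mid_excess_mean mid_excess_se defined
#>    <int>  <dbl>  <dbl> <int>           <dbl>         <dbl> <lgl>
#>  1     1    0      0.1   402          NA           NA      TRUE
#>  2     2    0.1    0.2   375          NA           NA      TRUE
#>  3     3    0.2    0.3   349           0.261        0.0746 TRUE
#>  4     4    0.3    0.4   327           0.671        0.0938 TRUE
#>  5     5    0.4    0.5   304           3.81         0.250  TRUE
#>  6     6    0.5    0.6   284          10.8          0.338  TRUE
#>  7     7    0.6    0.7   266          16.0          0.197  TRUE
#>  8     8    0.7    0.8   247          15.0          0.200  TRUE
#>  9     9    0.8    0.9   231          10.9          0.233  TRUE
#> 10    10    0.9    1     215           7.43         0.176  TRUE

detect_initiation(summary10)
#> [1] 0.4

glance(midcell_stats(profiles, ages))
#> # A tibble: 1 × 4
#>   n_cells n_fc_defined mean_ring_fraction moment_age
#>     <int>        <int>              <dbl>      <dbl>
#> 1    3000         1977              0.318       0.65
```

Reading the output: classes 1–2 hold cells shorter than 2.4 µm, too short
for the FCplus baseline flanks, so their mid-cell excess is flagged `NA`
rather than silently dropped. Mean mid-cell excess rises sharply in class
`[0.4, 0.5)` — the detected initiation age, matching the generative onset
of 0.4 — and the per-cell FCplus-versus-age curve peaks at the class
midpoint 0.65, matching the generative amplitude peak. `autoplot()`
methods draw the profile map (demograph), the per-class average profiles
and the FCplus-vs-age curve; `tidy()`/`glance()` return the tabular forms
shown above.

For pixel-level work the same analysis runs on rendered images:
`render_scene()` → `segment_cells()` (or `cells_from_labels()` for
external masks) → `axial_profiles()` / `contour_fluorescence()` →
`leakage_threshold()` / `classify_leakage()` / `brightness_reference()` /
`detect_blebs()`. `run_pipeline()` chains everything from a YAML config
into a run directory of TIFF/TSV/JSON artifacts, and
`inst/cli/rodmap.R` exposes the stages as shell subcommands
(`simulate`, `segment`, `profile`, `map`, `defects`, `all`).

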