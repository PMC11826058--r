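# biosensr

Characterization of whole-cell biosensors from plate-reader time series, by
way of **expression fractions** rather than reporter yield at an arbitrary
time point.

## The problem and who this is for

Transcription-factor biosensors and other inducible circuits are routinely
summarized by Hill dose–response parameters, but the reporter signal used to
fit them depends strongly on *when* it is read: strains differ in lag,
growth rate and stationary-phase behaviour, so fixed-time or
peak-growth-rate readouts compare different physiological states. This
package is for synthetic biologists and metabolic engineers who want
dose–response parameters defined through the cell's biosynthesis
allocation, with the time window of validity made explicit.

## The framework

The proteome is modelled as fractions φᵢ (ribosomal R, nutrient-fixator C,
structural Q, heterologous reporter H; Σφᵢ = 1). With ρ(t) the total
per-biomass biosynthesis rate and fᵢ(t) the share of it allocated to group
i, every fraction obeys

    dφᵢ/dt = ρ(t) · [fᵢ(t) − φᵢ(t)]

Two estimators of the reporter's expression fraction f_H follow:

- **Maximum method** — at an interior maximum of φ_H the bracket vanishes,
  so φ_H = f_H there. φ_H is proxied by fluorescence/OD600; its
  per-replicate peak within an early window (default 10 h) is averaged
  across replicates.
- **Slope method** — while protein tracks biomass, ρ_H(t) = f_H · µ(t), so
  f_H is the slope of specific production rate against specific growth
  rate, both computed as raw forward differences:

      µ(t) = [OD(t+Δt) − OD(t)] / (Δt · OD(t))
      ρ_H(t) = [flu(t+Δt) − flu(t)] / (Δt · OD(t))

  The regression window is selected objectively: per-time-point t-tests
  (α = 0.05) keep only the growth phase, then the earliest points are
  trimmed while that increases R². An intercept variant
  ρ_H = f_H·(µ − b) covers production ceasing before growth; a
  through-origin variant covers continuously accumulating reporters.

Either method yields f_H(I) across inducer concentrations I, fitted by
bounded, inverse-variance-weighted nonlinear least squares to the Hill law

    f_H(I) = H · Iⁿ / (Iⁿ + k_Iⁿ)     (bounds H, k_I ≥ 0, n ≥ 1)

Agreement of the two fits (per-parameter z-scores) is itself the check that
f_H was constant over the analysis window.

A built-in proteome-allocation batch-culture simulator (Monod nutrient
fixation → precursor pool → biosynthesis, precursor-ratio allocation,
inducer-Hill f_H, optional inducer-import lag and early production arrest)
generates synthetic microtiter datasets with known ground truth, and every
stage of the analysis is validated against it.

## Worked example

```r
library(biosensr)

cfg <- sim_config(seed = 1)                       # ground truth: H*kappa = 9600 flu/OD,
tt  <- simulate_titration(cfg, c(0, 12.5, 25, 50, 100, 200))   # k_I = 50 uM, n = 2.5
pd  <- as_plate_data(tt$data, tt$layout)
res <- analyze_titration(pd, channel = "gfp")

res$hill_slope
#> <hill_params> (reduced form)
#>   H   = 9863.74 +/- 212
#>   k_I = 51.3198 +/- 1.23
#>   n   = 2.494 +/- 0.0451
#>   weighted RSS = 0.9039 over 6 points

res$comparison
#>   parameter     maximum       slope     abs_diff    rel_diff         z
#> 1         H 9721.480299 9863.740002 1.422597e+02 0.014633543 0.6684967
#> 2       k_I   49.942563   51.319792 1.377228e+00 0.027576243 1.1159878
#> 3         n    2.489075    2.494298 5.223665e-03 0.002098637 0.1157084
```

Reading: from noisy simulated wells, the slope method recovers the
generating Hill parameters (9600 flu/OD, 50 µM, 2.5) within ~3%, and the
maximum- and slope-method fits agree — the concordance that licenses
treating f_H as constant through the growth window. Across repeated
titrations, k_I and n concord robustly (median |z| ≈ 1.3); H is the fragile
one, since both estimators carry small replicate-shared systematics that
the fitted standard errors cannot see (see the vignette's limitations).

Real data enter through the same door: a tidy CSV (`time_h`, `well`,
`od600`, `flu_<channel>`) plus a plate-layout CSV (`well`, `strain`,
`inducer`, `concentration`, `conc_unit`, `replicate`, `is_blank`), read by
`read_tidy_csv()`; a converter from matrix-style exports is included. The
full pipeline — rates, both methods, Hill fits, comparison report,
diagnostic figures, manifest — runs from one YAML via `run_pipeline()`, or
from the shell via `inst/cli/biosensr.R` subcommands
(`simulate`, `rates`, `fit-max`, `fit-slope`, `fit-hill`, `run`).

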