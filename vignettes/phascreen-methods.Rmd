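---
title: "Methods: microplate screening of bacterial PHA production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microplate screening of bacterial PHA production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phascreen)
```

## The screening problem

Polyhydroxyalkanoates (PHA) are bacterial storage polyesters accumulated
under carbon excess and nutrient (typically nitrogen) limitation.
Screening a strain for PHA production classically requires milliliter- to
flask-scale cultures, solvent extraction, methanolysis and GC-FID — slow
and serial. phascreen implements the analysis side of a high-throughput
alternative: strains are profiled for carbon-substrate utilization on a
Biolog PM1 phenotype microarray, grown in 96-well plates on selected
substrates in nitrogen-limited media, and the harvested cells are read by
whole-cell FTIR, where the PHA ester carbonyl stretch (~1720–1745
cm^-1^) serves as a proxy for polymer content. GC-FID on scaled-up
cultures anchors the FTIR signal to absolute weight-percent numbers.

## FTIR model and the CA1 ratio

A whole-cell infrared spectrum is treated as additive band absorbances on
a slowly varying baseline. Two integration windows matter:

* the **carbonyl-ester** window (1705–1763 cm^-1^ for the ATR instrument,
  1710–1772 cm^-1^ for the high-throughput transmission unit), capturing
  the PHA C=O stretch;
* the **amide I** window (1580–1705 / 1600–1710 cm^-1^), the protein
  backbone C=O stretch, used as an internal standard for cell quantity.

Per spectrum the chain is, in order:

1. **Normalization** — multiply the spectrum so the absorbance at the
   1650 cm^-1^ anchor (linearly interpolated between grid points) equals
   0.5 AU. This makes everything downstream invariant to the amount of
   biomass deposited; the operation is idempotent.
2. **Global linear baseline** — subtract the line through the first and
   last spectral points. For chord-subtracted band areas this step is
   mathematically inert (the chord absorbs any affine term); it is kept
   so reported peak heights match the conventional desk workflow.
3. **Individual-baseline band integration** — for each window draw a
   chord from `(lo, A(lo))` to `(hi, A(hi))` and take the trapezoidal
   integral of `A − chord`, inserting the interpolated endpoints into the
   grid. Negative areas are floored at zero, consistent with screening
   reports in which substrate CA1 ratios are "above zero" or not.
4. **CA1 ratio** — carbonyl area divided by amide I area, a relative
   measure of PHA per unit cell protein. By construction the whole chain
   is invariant to positive scaling of the raw spectrum; CA1 is strictly
   increasing in the carbonyl band height.
5. **Peak localization and class call** — inside the carbonyl window the
   chord-subtracted signal is Savitzky–Golay smoothed (default window 9
   points, polynomial order 2) and the argmax is reported as the peak if
   its smoothed height reaches `min_prominence` (default 0.005 AU
   post-normalization). Short-chain-length PHA (PHB-type, crystalline)
   absorbs near 1723–1728 cm^-1^, medium-chain-length polymers near
   1738–1741 cm^-1^; the default class boundary 1733 cm^-1^ is the
   midpoint of the two regimes and is configurable.

### Numerical behaviour of the chord integral

The chord construction buys exact invariance to affine baselines, at the
cost of clipping band tails that reach the window edge. For a Gaussian
band of FWHM 20 cm^-1^ centered mid-window the loss is below 1% of the
closed-form area `h·w·sqrt(pi/(4 ln 2))`; for the same band centered at
1728 cm^-1^ — only 2.7 sigma from the 1705 cm^-1^ edge of the ATR window
— tail-plus-chord loss reaches ~3.9%. The test suite therefore checks the
implementation against a continuous-math oracle (adaptive quadrature of
the chord-subtracted analytic band) to 1%, and against the closed form at
the tolerance the geometry actually permits. "Individual baseline" is
interpreted as exactly this per-window endpoint chord; whether desk
spectroscopy tools floor negative integrals is not documented anywhere we
could verify, and the zero floor is our choice.

## Growth metrics

Each well's OD600 series is log-transformed (floored at 0.01 OD so
blank-level noise cannot produce `-Inf`) and smoothed; the four standard
metrics are the maximum of the smoothed d ln OD/dt (**gr**), its time
(**t_gr**), the trapezoidal area under the raw linear-OD curve
(**AUC**; a log-scale variant is available behind a flag, since reported
magnitudes in the hundreds of OD·h identify the linear variant as the
conventional one), and the smoother's mean squared residual (**MSE**).

The default smoother is a smoothing spline tuned by generalized
cross-validation with penalty 1.4. Plain leave-one-out CV undersmooths
15-minute kinetic reads badly enough to inflate gr by ~20% at realistic
noise (0.01 OD); the 1.4 penalty is the standard correction for GCV's
undersmoothing tendency. GCV can still rarely collapse to
near-interpolation on a noisy well, so the effective degrees of freedom
are capped at 25 — a microbial growth curve never warrants more
flexibility. Measured against the closed-form logistic oracles
(max d ln N/dt = r(1 − N0/K); integral (K/r)·ln(1 + (N0/K)(e^{rT} − 1))),
the clean-curve error is −2.4% for gr and <0.1% for AUC, and the mean
noisy-recovery error is ~5%. An optional `smoother = "gp"` mode uses an
mgcv Gaussian-process smooth (`bs = "gp"`, REML), mirroring GP-based
plate-fitting tools; it is nearly unbiased but heavier.

Outlier wells are flagged per metric by box-plot fences
(linear-interpolation quartiles, 1.5 IQR), matching the plate-QC
procedure used in screening studies; fewer than four curves yields a
warning and no flags. Group-versus-control comparisons report both the
figure-convention band rule (group mean outside control mean ± 2 control
SD, boundary counting as inside) and a two-sided Welch t-test — the test
is our choice, since screening reports typically state "p < .05" without
naming one.

## Biolog phenotype calls

The PM1 plate reports tetrazolium→formazan reduction at 590 nm in 95
carbon-substrate wells plus the A1 no-carbon control. The control trace
is subtracted timepoint-wise from every well; replicate plates are
averaged pointwise *before* thresholding (matching the convention of
averaging independent experiments first); and a substrate is called
metabolized at a cutoff when the **maximum over time** of its net trace
**strictly exceeds** the cutoff. The max-over-time rule is our documented
default — published heatmaps are shown at a handful of timepoints and a
substrate crossing the cutoff at any of them was of interest; an
endpoint rule is available by subsetting timepoints. Counts are monotone
non-increasing in the cutoff by construction. Negative net values are
retained in exported heatmap matrices; flooring is purely a display
concern.

## C:N medium design

The design ratio is **moles of acetyl-CoA equivalents per mole of
nitrogen**: `(conc/M)·e / Σ N_moles`. This is the only reading under
which the shipped substrate table (15 substrates, 0.20 g/L NH4Cl)
reproduces the conventional mean of ~24; elemental carbon-to-nitrogen
readings give ~65–76 for hexoses. Equivalents are user-supplied
constants — no pathway inference is attempted. Substrate-intrinsic
nitrogen (N-acetylglucosamine) is excluded from the denominator by
default (including it breaks the reference mean) but can be toggled.
Yeast extract has no defined nitrogen content; the default mass fraction
0.105 g N/g is the value consistent with the reference ratio pattern
(ammonium medium ≈ 24, 1 g/L yeast extract ≈ 12) and is configurable.
The inverse operation (`design_concentration`) is an exact algebraic
round-trip of the forward ratio. Molar masses refer to the supplied
forms; anhydrous sodium acetate (82.03 g/mol) is assumed — the
trihydrate would put acetate wildly off the reference pattern.

## GC-FID quantification

Calibration is linear, through the origin by default (FID response is
linear through zero; single-level standards are common); a non-positive
slope is a calibration failure. Monomer mass is `(area −
intercept)/slope`, expressed as weight percent of the freeze-dried
pellet; the total is the monomer sum and the volumetric titre is
`total/100 × CDW`. Replicate summaries average bottom-up (technical →
biological → experiment) and report SD across experiments, matching the
convention of quoting variability "between individual experiments"; with
a balanced design the hierarchical mean equals the flat mean. Note that
a mean-of-products (per-replicate percent × CDW) generally differs from
the product of means — published volumetric numbers derived from
replicate-level data therefore cannot be reproduced from group means
alone, and no attempt is made to.

## What the synthetic generator does and does not emulate

`generate_spectrum` builds spectra as sums of Gaussian bands (amide I at
1650, amide II at 1545, a configurable carbonyl at 1720–1745 cm^-1^) on
an affine baseline with additive homoscedastic Gaussian noise, on a
900–4000 cm^-1^ grid at 2 cm^-1^ (configurable; high-throughput
transmission units acquire at 6 cm^-1^). Gaussian shape was chosen over
Lorentzian/Voigt because its closed-form area makes oracle tests exact.
Defaults (amide I height 0.5 — the normalization target; noise 0.002 AU)
are loosely calibrated to published normalized whole-cell spectra. The
generator does **not** simulate ATR penetration-depth physics, water
vapor lines, CO2, Mie scattering, or correlated noise; a green test
establishes the correctness of the analysis arithmetic on the stated
band model, not instrument-level robustness.

`generate_growth_curve` is an exact logistic with lag and additive
noise; `generate_biolog_plate` gives every well a logistic-like formazan
accumulation over a background trace shared with the no-carbon control.
All generators are pure functions of their arguments including the seed.

`make_demo_fixture` writes a complete two-arm study: a 15-substrate scl
arm (carbonyl at 1728 cm^-1^, heights spanning CA1 ≈ 0.06–2.2), a
14-substrate mcl arm (1738 cm^-1^, 10 substrates with a band and 4
without), replicate Biolog plates whose amplitude tiers are constructed
to the published count structure (49/44/25 and 54/51/20), a growth
plate, and GC-FID tables. Because the original raw plate exports are not
publicly deposited, the count criterion is a **recovery-by-construction**
test of the parsing→subtraction→averaging→thresholding path, not a
reproduction from raw data. Substrate-level peak calls aggregate
technical replicates by majority vote (replicate-level false-positive
rate at default noise is ~1%; the majority vote was stable across all
seeds tested).

## Known limitations

* No atmospheric compensation, EMSC/vector normalization, second
  derivatives, or multivariate FTIR↔GC-FID calibration models — the
  pipeline is deliberately the desk workflow, not a chemometric one.
* JCAMP-DX reading covers AFFN `(XY..XY)` and `X++(Y..Y)` tables only;
  compressed SQZ/DIF encodings are not parsed.
* The scl/mcl boundary is a single wavenumber; crystallinity, hydration
  and instrument effects shift real peaks by a few cm^-1^, so calls near
  1733 cm^-1^ should be reviewed against the spectra.
* Acetyl-CoA equivalents are assumptions, not measurements; the C:N
  ratios inherit them linearly.
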