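---
title: "Methods: quantifying Wnt-evoked calcium transients and nuclear translocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Wnt-evoked calcium transients and nuclear translocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wntwave)
```

## The measurement problem

Non-canonical Wnt signalling releases calcium from intracellular stores.
In ratiometric live imaging, two calcium dyes are loaded together: Fluo-4,
whose emission rises with free Ca^2+^, and FuraRed, whose emission falls.
Their intensity ratio reports intracellular calcium largely independently
of dye loading and illumination, so the *waveform* of the Fluo4/FuraRed
ratio over time is the object analysed. `wntwave` quantifies these
waveforms and the downstream readouts of the same signalling axis:
beta-catenin nuclear translocation (pixel-wise colocalization) and cell
motility (scratch-wound closure).

Because the original imaging data are not publicly deposited, the package
pairs every analysis stage with a synthetic-data generator whose ground
truth is known exactly. The generators define the study conditions; the
analysis code never sees the generating parameters.

## Waveform model and time constants

A single calcium transient is modelled as a Gaussian bump on a baseline,

$$r(t) = y_0 + A\, e^{-(t - t_0)^2 / (2\sigma^2)},$$

fitted by nonlinear least squares (Levenberg–Marquardt via `minpack.lm`).
Initialisation follows the waveform itself: $y_0$ from the median of the
first 10% of samples, $A = \max(r) - y_0$, $t_0$ at the maximum, and
$\sigma$ from the full width at half maximum divided by 2.355. Bounds keep
$A \ge 0$ and $0 < \sigma \le$ the trace span; failures return a flagged
fit rather than an error.

The kinetic time constants use a lower (10%) and upper (90%) amplitude
threshold on the waveform:

* **rise time** — from the first up-crossing of the 10% level to the first
  up-crossing of the 90% level;
* **dwell time** — the time the signal is sustained at peak amplitude,
  i.e. between the first up-crossing and the last down-crossing of the 90%
  level;
* **fall time** — from the last 90% down-crossing to the last 10%
  down-crossing.

Two choices here were genuinely open:

* **Fit levels, data crossings.** A pure Gaussian forces rise = fall, yet
  measured distributions of rise and fall differ. We therefore take the
  *levels* ($y_0 + f A$) from the fit, which is robust to noise, but locate
  the *crossing times* on the measured ratio, which preserves asymmetry.
  A fit-only mode would discard exactly the asymmetry of interest.
* **Crossing interpolation.** Crossings are bracketed between adjacent
  samples and refined with a local cubic spline through the neighbouring
  points (`interp = "cubic"`, the default). Plain linear interpolation
  between samples carries a crossing-time error of order
  $h^2 |y''| / (8 |y'|) \approx 10^{-2}$ s on a 1.1 s grid at the 10%/90%
  levels of typical transients, which would dominate the comparison with
  the closed-form crossing times of noiseless Gaussians; the local cubic
  reduces this to $\sim 10^{-5}$ s while still passing exactly through the
  measured samples. `interp = "linear"` remains available.

The reported amplitude is the peak of the waveform, $\max(r) - y_0$, not
the fitted $A$; both are kept so they can be compared.

**Detection threshold.** Ligands that evoke no transient (Wnt11, vehicle)
must yield a flagged "no transient" result, never garbage times. A trace
is timed only when the fitted amplitude exceeds 5 times the robust noise
SD (MAD) of the pre-stimulus segment. The MAD of a noiseless flat trace is
exactly zero, so an absolute floor of 0.05 ratio units backs the rule;
with baselines near 1 this is a 5% bump, well below any real transient in
the presets. Traces with more than one excursion above the 90% level are
flagged `multi_peak`; their constants are still timed around the main peak
and the flag is carried through downstream tables.

## Ligand presets and kinetic classes

Dwell time separates the responding ligands into three classes:
short (Wnt3A, Wnt5A; DT < 15 s), long (Wnt7A, Wnt10B; DT > 25 s) and very
long (Wnt4, Wnt9B; DT > 30 s). Since "> 30" is a subset of "> 25", the
very-long rule takes precedence, and the unassigned 15–25 s gap is
labelled `intermediate` so that `classify_dwell()` is total.

Each preset couples a dose-response model for dwell time to its transient
shape:

```{r presets}
ligand_presets()[, c("ligand", "kinetic_class", "sigma", "dwell_ref_s", "dose_mode")]
```

The numeric preset constants (amplitudes, decay parameters, asymmetries)
are fixture constants stored in a versioned JSON file
(`inst/extdata/ligand_presets.json`). The Gaussian width of each preset is
*derived* from its dose-response curve at the reference concentration
(100 ng/ml): for an asymmetric Gaussian the 90%-level dwell is
$\sigma\,(2 + a)\sqrt{2\ln(10/9)}$ with asymmetry $a$, so
$\sigma = \mathrm{DT}(100) / \big((2+a)\sqrt{2\ln(10/9)}\big)$. This makes
the noiseless dwell of every preset land inside its class interval by
construction, and ties the trace generator and the concentration-series
generator to the same curve. Falling-limb asymmetries (0.15–0.4) grow with
class, reflecting the slower store re-uptake of long transients.

## Dose response: negative cooperativity vs Michaelis–Menten

Dwell time versus concentration is fitted on per-concentration means
(the analysis mirrors mean-based plotting; a replicate-weighted fit can be
run by passing replicate rows directly):

* first-order decay $y_0 + A_1 e^{-C/t_1}$, rate constant $k = 1/t_1$
  (negative cooperativity: dwell time *falls* as concentration rises);
* Michaelis–Menten $\mathrm{DT}_{max}\, C / (K_{1/2} + C)$, with the
  Wnt5A preset at $K_{1/2} = 67$ ng/ml.

`diagnose_dose_response()` first tests adjacent concentrations with
two-sided Mann-Whitney tests at $\alpha = 0.05$, uncorrected — the
direction of significant steps, not the curve fits, decides the call
(no significant step: flat/indeterminate; all significant steps decrease:
negative cooperativity; steps increase: Michaelis–Menten). Both fits are
attached and the lower-residual curve is recorded as support. A series
with significant steps in both directions is reported indeterminate rather
than forced into either model.

Noise on dwell times is multiplicative log-normal (dwell times are
positive and their scatter scales with their size); trace channel noise is
additive Gaussian, scaled per sample so the induced ratio noise has the
requested SD in ratio units.

## Wave-front speed and onset lags

Ligands added to a static dish reach cells by diffusion, so transient
onsets shift with distance from the entry point. `simulate_dish()` delays
each ROI's centre by distance / front speed (default 23.3 um/s, the
measured dish diffusion constant); `estimate_front_speed()` regresses
onset time on distance and inverts the slope, propagating the slope's
standard error by the delta method. Onset itself is the first up-crossing
of the 10% level, so the same crossing machinery serves both the time
constants and the lag analyses; the cytosol-to-nucleus onset lag
(`onset_lag()`) is simply the difference of two onsets and is reported
with its sign.

## Thapsigargin fixture

The store-depletion control is a gated transient: baseline until the
stimulus, one store-release bump (centre 40 s after addition,
$\sigma$ = 15 s, asymmetry 0.3), and nothing afterwards — in particular a
Wnt addition 190 s later finds depleted stores and produces a flat
segment whose fitted amplitude falls below the detection threshold.
With these constants the ratio re-enters the 5% baseline band (sustained
for 3 samples) about 86 s after stimulus onset, inside the 120 s window
the fixture is designed to respect.

## Colocalization of nuclear translocation

Nuclear translocation is quantified as the per-cell Pearson correlation
between the immunolabel (Cy3-like) and nuclear counterstain (DAPI-like)
channels. We deliberately use plain Pearson over the ROI pixels — no
intensity thresholding, no Costes randomisation — because that is the
simplest literal form of the coefficient; absolute values therefore depend
on ROI definition and background, and only the treated-vs-control ordering
and its Mann-Whitney significance are meaningful. The default ROI is a
whole-cell disk: the nucleus mask dilated to twice its equivalent radius
(nucleus-only mode is available). The synthetic image sets place
non-overlapping disk nuclei on a jittered grid and split each cell's
immunolabel budget between nucleus and cytoplasmic annulus with a
controllable nuclear fraction (control 0.2, treated 0.75); with 30 cells
per group the group comparison lands far below p = 0.001.

## Wound closure

Wound width declines linearly, so closure rate is the negated OLS slope
of width on time. Slope equality between conditions uses the
extra-sum-of-squares F test — separate slopes and intercepts versus a
common slope — which is the standard formulation of a slope-equality
"F-test" when no further detail is given. Zero-residual designs (noiseless
fixtures) report p = 0 below machine floor rather than failing. Widths are
floored at zero during generation, not during fitting; default presets
stay clear of the floor.

## Statistical primitives

Mann-Whitney U tests are two-sided by default and delegate to R's
`wilcox.test`: exact enumeration when the combined sample size is at most
12 with no ties, otherwise the normal approximation with mid-rank tie
correction and continuity correction. The test suite checks this exact
path against an independent enumeration of all rank arrangements and the
approximate path against enumeration just past the cutoff. Exact discrete
p-values are super-uniform under the null, so the null-calibration suite
(2000 seeded null comparisons) runs at n = 15 vs 15 on the approximate
path, where the rejection rate is expected at the nominal level within
Monte-Carlo error.

## Problem sizes and what the tests do not show

The shipped simulations use 600 s traces at 1.1 s sampling, 8-ROI dishes,
10 replicates per concentration, 30 cells per colocalization group and
2000-replicate null calibrations — sizes chosen to exercise every
estimator well into its asymptotic behaviour while keeping the whole
suite interactive. The generators emulate the *designed* structure of the
data: single transients, uniform sampling, disk nuclei, linear wounds.
They do not emulate photobleaching, dye saturation, calcium oscillations,
cell movement, segmentation errors or 3-D structure, so passing tests
demonstrate correctness of the estimators under the stated model, not
robustness to every artefact of real recordings. Multi-peak traces are
flagged rather than modelled; oscillation analysis is out of scope.
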