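# wntwave

Quantitative analysis of Wnt-evoked intracellular calcium transients and
their downstream readouts, for labs doing ratiometric (Fluo-4 / FuraRed)
live-cell calcium imaging.

Non-canonical Wnt signalling mobilises calcium from intracellular stores.
`wntwave` turns exported ROI intensity tables into the kinetic quantities
that discriminate Wnt ligands:

* **Waveform kinetics** — the Fluo4/FuraRed ratio is fitted to a single
  Gaussian, `y0 + A·exp(−(t−t0)²/(2σ²))`, and rise, dwell and fall time
  constants are read off 10%/90% amplitude threshold crossings located on
  the measured ratio. Dwell time (DT) is the time the signal is sustained
  at peak amplitude.
* **Kinetic classification** — ligands fall into dwell-time classes:
  short (DT < 15 s: Wnt3A, Wnt5A), long (DT > 25 s: Wnt7A, Wnt10B), very
  long (DT > 30 s: Wnt4, Wnt9B); groups are compared with Mann-Whitney U
  tests.
* **Dose response** — dwell time vs concentration is fitted to a
  first-order decay `y0 + A1·e^(−C/t1)` (negative cooperativity, rate
  constant `k = 1/t1`) or to Michaelis–Menten `DTmax·C/(K½ + C)`
  (Wnt5A preset: K½ = 67 ng/ml), and each series is diagnosed as
  negative-cooperative, Michaelis–Menten or flat.
* **Wave-front speed and onset lags** — transient onsets regressed on
  distance from the ligand entry point recover the dish wave-front speed
  (preset 23.3 µm/s); onset differences give cytosol→nucleus lags.
* **Nuclear translocation** — per-cell Pearson colocalization between
  immunolabel and nuclear stain, compared between groups.
* **Motility** — scratch-wound closure rates by linear regression, with an
  extra-sum-of-squares F test on slopes.

Every stage has a synthetic-data generator with known ground truth
(traces, multi-ROI dishes, two-channel nuclei images, wound tables), so
the whole pipeline is testable without the original microscope data.

## Worked example

```r
library(wntwave)

# a short-class (Wnt5A-like) transient with realistic channel noise
tr  <- simulate_trace(preset_transient_params("Wnt5A", noise_sd = 0.02), seed = 1)
fit <- fit_gaussian(tr)
glance(fit)[, c("y0", "A", "t0", "sigma", "converged")]
#>      y0     A    t0 sigma converged
#> 1  1.00  1.50  201.  13.1 TRUE

extract_time_constants(tr, fit)[, c("amplitude", "rise_s", "dwell_s", "fall_s", "flag")]
#>   amplitude rise_s dwell_s fall_s flag
#> 1      1.50   20.3    11.9   24.2 ok
```

The fitted baseline (1.00) and amplitude (1.50 ratio units) recover the
generating waveform; the dwell time of 11.9 s sits below the 15 s
short-class boundary (`classify_dwell(11.9)` returns `short`), and the
fall time exceeds the rise time because the falling limb of the preset is
stretched by its asymmetry factor.

```r
s <- simulate_concentration_series("Wnt5A", c(30, 100, 300),
                                   replicates = 10, noise_fraction = 0.05,
                                   seed = 42)
fit_michaelis_menten(s)
#> Michaelis-Menten fit: DTmax = 19.62 s, K1/2 = 63.53 ng/ml
diagnose_dose_response(s)$mode
#> [1] "michaelis_menten"
```

At 5% replicate noise the half-maximal concentration (truth 67 ng/ml) is
recovered within a few ng/ml, and the adjacent-concentration tests call
the series Michaelis–Menten. `run_wnt_pipeline(out_dir, seed)` chains all
stages (traces → kinetics → classes → dose response → colocalization →
wound closure) into CSV/JSON outputs that are byte-identical for a given
seed.

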