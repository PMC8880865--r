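# gammashape

Quantitative shape analysis of cortical gamma oscillations, and regime
mapping for two Wilson-Cowan-type rate models of gamma generation.

## The problem

Visually induced gamma oscillations (30-70 Hz) in primary visual cortex are
often non-sinusoidal: an "arch"-shaped cycle with a sharp trough and a broad
shallow crest. The distortion produces a spectral peak at the first harmonic
(twice the gamma fundamental), and the cycle *shape* is captured by the
phase relationship between fundamental and harmonic:

    Δ(t) = (2·φ_gamma(t) − φ_harmonic(t)) mod 360°

Δ = 180° corresponds to aligned troughs — the arch. Because a limit-cycle
oscillator repeats the same cycle shape while a noise-driven damped
oscillator does not, Δ and its cycle-to-cycle consistency (mean vector
strength, the resultant length of the unit vectors e^{iΔ}) discriminate
between mechanisms of gamma generation. The package implements:

* multitaper spectral estimation (3 DPSS tapers, NW = 2), change-in-power
  (dB) spectra, gamma/harmonic peak detection, and peak-frequency-ratio
  statistics (bootstrap SE of the median, Wilcoxon signed-rank test against
  a ratio of 2);
* zero-phase Butterworth band extraction, Hilbert instantaneous phase, the
  Δ statistic, and circular statistics (circular mean, von Mises 95% CI,
  Rayleigh test, vector strength);
* forward-Euler simulators for a stochastically driven linear
  three-population rate model and a sigmoidal two-population
  inhibition-stabilized (ISN) model, with LFP proxies (−(r_E+r_I), −r_E,
  −r_I);
* input-drive grid scans that locate the "in-regime" cells producing
  arch-shaped gamma (Δ within 22.5° of 180°, amplitude gates, and — for the
  stochastic model — a Rayleigh consistency gate across 50 repeats), plus
  superlinearity classification of the inhibitory operating point;
* a synthetic LFP trial-set generator (oscillation + broadband noise with
  baseline/stimulus epochs) so the whole pipeline runs without recordings.

## Worked example

Synthesize a 10-trial, 3-channel session with a 44 Hz arch-shaped gamma
(initial phase 90°, harmonic ratio 0.25) in noise, then run the full
analysis chain:

```r
library(gammashape)
spec <- synthetic_spec(fundamental_freq = 44, phi_G = 90, noise_sd = 0.3, seed = 6)
ts   <- make_trialset(spec, n_trials = 10, n_channels = 3)
res  <- cmd_analyze(ts)
res$peaks
#>   channel gamma_peak_hz harmonic_peak_hz    ratio gamma_db harmonic_db
#> 1       1            44               90 2.045455 30.55569    17.25716
#> 2       2            44               90 2.045455 30.81731    18.14124
#> 3       3            44               86 1.954545 30.55751    17.97489
res$phase_channels
#>   channel circ_mean_deg ci95_deg   rayleigh_p vector_strength n_trials
#> 1       1      178.5006 3.098648 5.540218e-07       0.9806621       10
#> 2       2      175.8143 2.874149 5.397209e-07       0.9857587       10
#> 3       3      181.0843 1.178635 4.708407e-07       0.9861930       10
```

Reading the output: each channel's change-in-power spectrum peaks at the
44 Hz gamma bin (~30 dB over baseline) and near the 88 Hz harmonic; detected
harmonic bins snap within ±1 grid step of 88 because the 3-taper estimate
flat-tops each peak, so ratios land inside the grid's error margin 2 ± 0.05.
The per-channel circular means of Δ recover 180° (the generating arch
phase) within a few degrees, with high vector strength (~0.98): the cycle
shape is consistent across the stimulus window.

The noiseless demonstration is exact: the wave
`cos(2π·45t + 90°) + 0.25·cos(2π·90t)` analyzed through the same
bandpass + Hilbert pipeline gives

```r
gamma_harmonic_phase(make_arch_wave(synthetic_spec(phi_G = 90)), 2000, 45)$summary
#> circular mean 180.04 deg (+/- 0.02 deg), vector strength 1.000, Rayleigh p = 0, n = 1600
```

Model-side, `scan_js()` sweeps the ISN model over the 41 × 41 drive grid and
`summarize_regime()` reports the in-regime set (63 cells with the defaults,
all inside the superlinear set, mean vector strength 0.999); `scan_jxk()`
does the analogous sweep for the stochastic model, whose in-regime cells
have far lower vector strength (≈ 0.2-0.36) — noise-driven gamma does not
hold its shape. A thin command-line wrapper for the pipeline lives at
`inst/cli/gammashape.R` (subcommands `synthesize`, `analyze`, `scan`,
`summarize`).

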