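---
title: "Quantifying the arch shape of gamma oscillations and mapping rate-model regimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the arch shape of gamma oscillations and mapping rate-model regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammashape)
```

## The problem

Stimulus-induced gamma oscillations (30-70 Hz) in visual cortex are often
visibly non-sinusoidal: cycles show a sharp, narrow trough and a broad,
shallow crest -- an "arch". A non-sinusoidal cycle shape shows up in the
power spectrum as a peak at the first harmonic (twice the gamma fundamental),
and the *shape* itself is captured by the phase relationship between the two
spectral components. This package quantifies that relationship and uses it to
constrain the operating regime of two mean-field models of gamma generation.

## The phase-difference statistic

Write the gamma-band component of a signal as having instantaneous phase
$\phi_\gamma(t)$ and the harmonic-band component $\phi_h(t)$. The shape
statistic is

$$\Delta(t) = \left(2\,\phi_\gamma(t) - \phi_h(t)\right) \bmod 360^\circ.$$

Doubling $\phi_\gamma$ puts the two phases on a common angular clock, so
$\Delta$ is constant whenever the waveform repeats the same cycle shape. For
a sum of two cosines, $\cos(2\pi f t + \phi_G) + a\cos(2\pi\,2f\,t)$,
substituting the analytic phases gives $\Delta \equiv 2\phi_G$ identically:
the statistic depends only on the *relative alignment* of fundamental and
harmonic, not on time or on $f$. Troughs align -- the arch -- exactly when
$\Delta = 180^\circ$ (initial gamma phase $90^\circ$).

The statistic lives on the full circle (not folded to $[0^\circ, 180^\circ]$)
because observed means fall on both sides of $180^\circ$; all averaging is
circular, and dispersion is summarized by the mean vector strength
$R = \lvert \tfrac1n \sum_t e^{i\Delta(t)} \rvert$: $R = 1$ means every cycle
has the same shape, $R \approx 0$ means the shape is uncorrelated across
cycles.

### Measurement chain and its tunables

1. **Spectral estimation** -- multitaper PSD with $K = 3$ DPSS tapers. Only
   the taper count is fixed by convention in three-taper analyses; we take
   the standard time-bandwidth relation $K = 2\,NW - 1$, hence $NW = 2$. With the
   0.5 s epochs used for LFP-style data the grid step is exactly
   $1/T = 2$ Hz. The tapers are computed from the classical tridiagonal
   eigenproblem and cached. A consequence worth knowing: a pure tone is
   flat-topped across $\pm 1$ bin (a $\sim 0.1$ dB plateau of width $2W$), so
   single-bin peak identification under a noisy baseline can snap one bin
   either way. This is exactly the "frequency-ratio snap" worked example: a
   41 Hz tone on the 2 Hz grid is reported at 40 or 42 Hz, so a 41 + 82 Hz
   pair yields a peak-frequency ratio of 2.05 or 1.95.
2. **Change in power** -- $10(\log_{10} P_{stim} - \log_{10} P_{base})$ per
   bin; PSDs are averaged across trials *before* dB conversion (the
   alternative order, dB per trial then averaging, gives slightly different
   values for noisy data; we document and use the former).
3. **Peak detection** -- band-restricted argmax: gamma in $[30, 70]$ Hz;
   harmonic in $(\gamma + 12, 140]$ Hz (lower edge exclusive, upper edge
   inclusive). Ties break to the lower bin. Both detectors are invariant to
   amplitude scaling.
4. **Band extraction** -- Butterworth bandpass, design order 4, applied
   forward-backward (zero phase, effective order 8), passband 20 Hz wide:
   gamma band centered on the detected peak, harmonic band centered at
   *twice* the detected gamma peak (not independently detected).
5. **Phase** -- analytic-signal (Hilbert) instantaneous phase; a cosine has
   phase 0 at its positive peak.
6. **Edge trimming** -- 100 ms are discarded from each end of every filtered
   window before phase statistics. Forward-backward IIR filtering leaves
   settling transients at both ends; 100 ms is several settling lengths of
   the 20 Hz-wide band filters at the rates used here. With this trim the
   circular mean of $\Delta$ for a noiseless two-cosine wave is within
   $0.1^\circ$ of $2\phi_G$; individual timepoints deep in the interior are
   within $1^\circ$.
7. **Circular summaries** -- circular mean, von Mises 95% CI
   (Zar's eq. 26.24 approximation; the CI is *flagged undefined* when the
   resultant is too small for the approximation, rather than fabricated),
   Rayleigh test of uniformity with the standard finite-$n$ correction, and
   mean vector strength. All three are validated in the test suite against
   Monte-Carlo resampling oracles at small $n$.

## Synthetic data: what it emulates and what it does not

There is no public accession for the recordings this analysis was designed
around, so `make_trialset()` builds surrogate sessions with the same
geometry: trials of white Gaussian noise throughout, a gamma + harmonic
oscillation added after stimulus onset, a baseline epoch $(-0.5, 0)$ s and a
stimulus epoch $(0.25, 0.75)$ s relative to onset (both 0.5 s so spectral
resolutions match, both half-open $[start, end)$ on a 0-based sample grid).
Per-trial phase jitter is off by default (worked examples are exact) and can
be switched on as a von Mises draw for recovery tests. Two single-segment
surrogates mimic the robustness checks one can run on real data: additive
Gaussian noise of chosen variance, and a weighted stimulus/baseline mixture.

What the generator does **not** emulate: spiking, broadband $1/f$ spectral
shape, spatial correlation across channels, or gamma burstiness. Passing
recovery tests on these surrogates therefore demonstrates correctness of the
estimator chain (no bias from noise, CI widening with noise), not performance
on every feature of cortical LFP. The noise ladder used in the recovery test
(SD 0.25, 1, 2.5 against a unit-amplitude fundamental) was chosen to span
weak to strong noise while the 20-trial von Mises CI is still computable;
beyond that the property being tested (CI width growth without mean bias) is
not defined.

## The two rate models

Both models are integrated by forward Euler with `dt = 0.1` ms over 2 s from
zero initial conditions, analyzing 1-2 s to skip the onset transient; halving
`dt` moves the gamma peak by less than 1 Hz (checked in the suite at dt,
dt/2, dt/4). The LFP proxy is $-(r_E + r_I)$ by default ($-r_E$ and $-r_I$
variants available), reflecting that both populations' synaptic currents
deflect superficial-layer LFP downward. Proxy traces are decimated from the
10 kHz integration grid to 1 kHz before analysis -- a 1 s window then gives
integer-Hz bins, and the Butterworth designs stay away from numerically
fragile normalized frequencies. Model spectra use the raw proxy PSD (models
have no baseline epoch).

**Stochastic three-population model.** Linear rectified dynamics for E and I
plus a slower global excitatory population whose feedback scales with
stimulus size as $r^2 W_{GE}$ ("recruited cortical area grows with $r^2$";
the exponent is configurable because the source typesetting is ambiguous).
Contrast sets the mean drives through a Naka-Rushton saturation
$I_E = 40\,c^2/(c^2 + 0.3^2)$, $I_I = 32\,c^2/(c^2 + 0.3^2)$; we read the
constant as $c_{50} = 0.3$ (the alternative literal reading 0.32 is
selectable via `c50`). Inputs approximate a Poisson process: counts per 1 ms
bin with mean equal to the drive, held constant within the bin, so the
time-average equals the nominal drive exactly; the fluctuation scale is a
knob (`noise_scale = 0` gives the deterministic skeleton). With mean inputs
the model is a damped oscillator -- its gamma exists only because noise keeps
re-exciting it -- so cycle shape is inconsistent: phase-difference vector
strengths stay low (about 0.2-0.36 across the scanned grid) even where the
iteration-averaged phase difference is near $180^\circ$.

**Sigmoidal ISN model.** Two populations with activation
$\sigma_P(x) = (1 + e^{m_P(\theta_P - x)})^{-1} - (1 + e^{m_P \theta_P})^{-1}$
(zero at rest by construction). Above a Hopf bifurcation it settles on a
gamma-band limit cycle: every cycle has the same shape, so the
phase-difference vector strength is 1 up to filter edge effects. The
"superlinear" classification asks whether the inhibitory population's summed
input at equilibrium, $W_{IE} r_E^* - W_{II} r_I^* + I_I$, lies strictly
below the sigmoid midpoint $\theta_I$ (where $\sigma_I$ curves upward). The
equilibrium is found by a 1-D reduction (the inhibitory consistency equation
is monotone and bracketed on $[0, 1]$, then the excitatory residual is rooted
over a fine bracket scan); when several equilibria exist the one nearest the
trajectory mean is used. Convergence is verified to residuals below
$10^{-9}$, and below the bifurcation the equilibrium matches the long-time
integration average.

## Regime scans

`scan_js()` sweeps the $41 \times 41$ drive grid ($I_E, I_I \in [0, 20]$,
step 0.5). A cell is **in-regime** when (i) its gamma and harmonic linear PSD
peak amplitudes exceed $10^{-3}$ and $10^{-6}$ model units (the source states
the thresholds but not their units; we apply them to linear multitaper PSD
peak values of the proxy and expose them), and (ii) the circular distance of
its phase difference from $180^\circ$ is at most $22.5^\circ$ (inclusive).
The gates matter: cells bordering the non-oscillatory region otherwise
produce spurious near-$180^\circ$ phases from numerical noise. With the
defaults, 63 of 1681 cells are in-regime, *all* of them inside the
superlinear set (inhibitory operating points 18.2-19.8, all below
$\theta_I = 20$), with mean vector strength 0.999.

`scan_jxk()` runs each (size, contrast) cell 50 times (independent Poisson
draws), averages PSDs across iterations for peak detection, summarizes the
phase difference per iteration, and additionally requires the pool of
per-iteration means to pass a Rayleigh consistency test ($p < 0.01$) before a
cell can be in-regime. The default contrast grid uses $\log_{10}$ steps of
0.25 over $[10^{-2}, 1]$ so it contains the demonstration contrast
$10^{-0.25}$; a coarser 0.5-step grid is available by argument.

### A deliberate discrepancy

Across the in-regime ISN cells the excitatory population leads the inhibitory
one -- E rises first in each cycle, as in standard E-I gamma mechanisms. Our
measured mean lead is $67.7^\circ$ ($\approx 4$ ms at 44 Hz). The value is
robust: Hilbert phase of band-passed rates, FFT phase at the gamma bin,
cross-correlation peak lag, and the linearized-Jacobian eigenvector angle at
the fixed point all agree within a few degrees, and the eigenvector angle
stays in $64$-$71^\circ$ across the entire oscillatory region. The commonly
quoted "about $50^\circ$ (2-3 ms)" for this model is therefore not reproduced
by this implementation under any measurement variant we tried; the
corresponding acceptance check is left failing rather than loosened, and the
package reports the honestly computed value. Note also the sign convention:
`e_i_phase_lead()` returns the circular mean of $\phi_{r_E} - \phi_{r_I}$,
so a quarter-cycle-delayed inhibitory copy yields $+90^\circ$.

## Numerical choices and degenerate inputs

* Peak argmax ties break to the lower bin (deterministic).
* `harmonic_amp_ratio = 0` reduces the generator to a pure sinusoid; the
  harmonic-band "phase" is then meaningless noise, which downstream analysis
  flags through the amplitude gates rather than silently returning.
* A segment shorter than one cycle of the lowest analyzed frequency is
  rejected by `multitaper_psd()`; bands outside (0, Nyquist) are rejected by
  `bandpass()`; zero-baseline bins in `change_in_power()` are flagged, not
  dropped.
* The bootstrap SE of the median ratio resamples N times with N draws
  (N = sample size) by default, on a dedicated seedable generator; the
  Wilcoxon test against a median ratio of 2 uses the exact distribution for
  $n \le 25$ without zeros/ties and the normal approximation otherwise.
* Problem sizes in the test suite: the full ISN scan (1681 cells, 20,000
  Euler steps each) runs once and is reused across checks; the stochastic
  model is exercised on a reduced 12-cell grid with the full 50 iterations.

## Known limitations

* The harmonic amplitude produced by the ISN model is far smaller than in
  strong-gamma recordings; mean-field models generally under-produce
  harmonic power.
* The in-regime criterion inherits the amplitude-gate units ambiguity noted
  above; gate values are configurable and recorded in scan provenance.
* No bicoherence/PAC metrics, no pedestal modeling, no slow-vs-fast gamma
  separation, and no spiking or conductance-based models: the scope is the
  phase-difference statistic and the two rate models.
* Trial sets serialize to CSV + JSON (portable text) rather than HDF5.

## Reproducing the headline numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` regenerates,
from scratch: the $180^\circ$ pipeline check on the noiseless arch wave, the
full ISN scan with its in-regime vector strength and E-lead, and the
frequency-ratio snap example. Everything it prints is computed at run time by
the same exported functions documented above.
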