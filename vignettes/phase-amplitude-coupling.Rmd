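---
title: "Detecting phase-amplitude coupling with phaseamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phase-amplitude coupling with phaseamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaseamp)
```

## The problem

In visual cortex, the amplitude of gamma-band activity (> 40 Hz) is coupled
to the phase of the ongoing alpha rhythm (7–13 Hz): gamma bursts ride on a
preferred alpha phase. Quantifying this phase-amplitude coupling (PAC) from
trial-epoched single-channel recordings — e.g. an MEG virtual-electrode
time course — is notoriously sensitive to filter bandwidths, edge
artifacts, trial length, non-sinusoidal waveform shape and the statistic
chosen. `phaseamp` implements a complete detection chain: analytic-signal
extraction, four modulation-index (MI) estimators, comodulograms with
trial-shuffled surrogate normalization, cluster-based permutation
comparison of conditions, a waveform-asymmetry diagnostic, and a
calibrated simulator used to validate every stage.

## Phase and amplitude extraction

Each trial is band-pass filtered with a fourth-order Butterworth applied
forward and backward (zero net phase shift), and the Hilbert analytic
signal provides instantaneous phase (for the low-frequency band) or the
amplitude envelope (for the high-frequency band).

Two bandwidth rules matter:

* **Phase band:** centre ± 1 Hz. Narrow, so the filtered waveform is
  near-sinusoidal and its phase well defined.
* **Amplitude band:** centre ± 0.4 × centre. The envelope of a carrier at
  $f_a$ modulated by phase frequency $f_p$ lives in the sidebands
  $f_a \pm f_p$; if the filter does not contain them, coupling is
  invisible no matter how strong. For a 60 Hz centre the rule gives
  [36, 84] Hz; detecting a 13 Hz modulation of 60 Hz needs at least
  [47, 73] Hz. On a 2 Hz amplitude grid the smallest admissible centre
  against 13 Hz phase is `min_amplitude_center(13, 0.4, 2)` = 34 Hz,
  which is where the default grid starts.

Numerical realisation: the 2 Hz-wide phase bands at a 1000 Hz sampling
rate put the digital poles so close to the unit circle that the expanded
transfer-function (b, a) form of the filter is unstable in double
precision. The filters are therefore designed in zero-pole-gain form
(analog Butterworth prototype, band transform, bilinear mapping) and
applied as a cascade of second-order sections, with each section started
in its steady state for the first input sample. Zero-phase filtering uses
an even-symmetric reflection of the whole trial as padding: the narrow
bands ring for hundreds of milliseconds, and shorter pads leave visible
envelope droop inside the epoch. With these choices a pure 10 Hz cosine
filtered at [9, 11] Hz keeps its interior envelope flat to better than
0.1 %.

Filtering and the Hilbert transform are computed on the full padded
epoch, and 500 ms (the recorded padding) is discarded from each end
*afterwards*, so one trim removes both filter and Hilbert edge
artifacts. Flat (dead-channel) trials are flagged `degenerate` rather
than raising, so batch runs survive them.

## The four modulation indices

Given phase $\varphi(n)$ and envelope $a(n)$, $n = 1 \dots N$:

* **MVL (Canolty):** $\mathrm{MI} = |\frac{1}{N}\sum a(n) e^{i\varphi(n)}|$.
  Scales linearly with envelope amplitude — raw values partly reflect
  gamma power, a documented confound (the package asserts this linearity
  in its tests rather than hiding it).
* **MVL (Özkurt):** the same resultant normalised by envelope power,
  $\mathrm{MI} = \frac{1}{\sqrt{N}}\,|\sum a e^{i\varphi}| / \sqrt{\sum a^2}$;
  scale-invariant and better suited to noisy MEG.
* **PLV (Cohen):** the envelope is demeaned (its DC component otherwise
  dominates the Hilbert phase), its own analytic phase $\varphi_a$ is
  taken, and $\mathrm{MI} = |\frac{1}{N}\sum e^{i(\varphi - \varphi_a)}|$.
* **KL (Tort):** phase is cut into 18 equal bins (left-closed,
  right-open over $[-\pi, \pi)$; exactly $\pi$ joins the last bin), the
  mean envelope per bin is normalised to a distribution $P$, and
  $\mathrm{MI} = D_{KL}(P \| U)/\log 18 \in [0, 1]$, natural logs, with
  $0 \log 0 = 0$. An empty bin leaves the mean amplitude undefined and is
  an error carrying the bin index (the package does not silently smooth);
  inside grid sweeps such trials become `NA` and drop out of the trial
  average. The bin count barely matters: across a coupling-depth sweep,
  KL values with 9, 18 and 36 bins correlate above 0.95.

## Comodulograms and surrogates

`compute_comodulogram()` sweeps phase centres 7–13 Hz (1 Hz steps) ×
amplitude centres 34–100 Hz (2 Hz steps) by default, computes each trial's
MI separately and averages across trials. Per-trial computation (rather
than concatenating trials) avoids the edge artifacts that concatenation
re-introduces at every seam; for the PLV estimator the envelope phase is
likewise taken within each trial.

The null reference is built by `generate_surrogates()`: the phase series
of the trials are reassigned by a random derangement (no trial keeps its
own phase), the trial-averaged MI is recomputed per cell, and this is
repeated `n = 200` times. `normalize_mi()` then standardizes each cell,
$(\mathrm{obs} - \mathrm{mean_{surr}})/\mathrm{sd_{surr}}$, preserving
sign for the downstream t statistics. Internally the MI of every
(amplitude-trial, phase-trial) pairing is computed once per cell as a
matrix cross-product, so the 200 draws cost indexing only — this is what
keeps a full 7 × 34 grid with surrogates at desk scale.

Two properties of this scheme are worth knowing. First, it only destroys
coupling if the low-frequency phase is incoherent across trials; for a
perfectly periodic carrier a constant phase offset leaves every MI
unchanged, which is why the simulator below uses a narrowband-noise alpha
rather than a pure sinusoid (real cortical alpha drifts the same way).
Second, with short trials the surrogate and observed series remain
temporally correlated, so surrogate normalization complements — it does
not replace — the condition contrast.

## Comparing conditions

`cluster_permutation_test()` implements the Maris–Oostenveld cluster
randomization for paired designs on the MI grid: a dependent-samples t
statistic per cell; cells beyond the two-tailed 5 % t quantile grouped
into clusters by 4-neighbour adjacency (diagonals excluded — the
conservative choice on a 2-D grid), positive and negative cells
separately; the maximum |t| within each cluster carried forward (the
more common cluster-mass sum is available via `stat = "mass"`); and a
null distribution of the largest cluster statistic from 1,000 random
per-subject condition swaps, which for paired differences are exactly
sign flips. A cluster's p value is the proportion of permutations whose
largest statistic reaches it. Under a 200-repetition null simulation with
16 synthetic subjects the family-wise error stays at the nominal 5 %
(the acceptance suite bounds it at 0.075, the binomial tolerance for 200
repetitions), and a planted 3 × 5-cell effect of two noise standard
deviations is recovered with over 80 % cell sensitivity.

Degenerate cells (zero difference variance) get t = 0: they carry no
evidence in either direction, and `paired_t()` flags rather than errors
on such input (variance at floating-point rounding scale counts as
zero).

## Waveform asymmetry diagnostic

Non-sinusoidal, sawtooth-like low-frequency oscillations create spurious
PAC through their harmonics. `rise_decay_ratio()` quantifies asymmetry as
the ratio of trough-to-peak (rise) to peak-to-trough (decay) time per
cycle. Cycle landmarks come from the narrowband phase (peak at the upward
zero crossing of phase, trough at the ±π wrap); because extrema of a
narrowband signal are sinusoidal by construction, the landmark times are
refined to the extrema of a ≤ 40 Hz low-passed copy of the raw signal
within each half cycle. A sinusoid yields ratio 1 (the suite requires
± 2 %); rising and falling sawtooths yield ratios above and below 1. The
exact broadband cutoff is a declared package choice — the diagnostic is
insensitive to it as long as a few harmonics pass.
`compare_sinusoidality()` runs a paired t test of the per-trial ratios
between conditions at every phase frequency; on matched null conditions
its p values are uniform (the suite checks ≥ 90 % of null comparisons
stay above 0.05).

## The simulator

`simulate_pac_trials()` generates the validation scenario: 64 trials of
1.2 s at 1000 Hz plus 0.5 s padding each side, with

* an **alpha component**: Gaussian noise band-passed to $f_p \pm 1$ Hz
  (default $f_p$ = 10), scaled to the power of a unit-amplitude sinusoid.
  Narrowband noise, not a sinusoid: trial-incoherent, drifting alpha
  phase is what real recordings show and what makes trial-shuffled
  surrogates a valid null (see above);
* a **gamma component**: Gaussian noise band-passed to 50–70 Hz with
  standard deviation 0.5 before modulation (gamma is the weaker rhythm in
  visual cortex), whose envelope is multiplied by the raised-cosine law
  $1 - c\,(1 - (1 + \cos\varphi_\alpha)/2)$ with coupling depth
  $c \in [0, 1]$ and $\varphi_\alpha$ the Hilbert phase of the alpha
  component, so at full depth the gamma envelope vanishes at the alpha
  trough;
* **white noise** scaled per trial so that the realised SNR
  ($10\log_{10}$ of signal power over noise power) equals a draw from
  uniform(−11.5, 0] dB unless pinned.

Everything is reproducible from the seed, and the generator leaves the
caller's RNG stream untouched. What it deliberately does *not* emulate:
1/f background spectra, evoked transients, inter-subject variability in
peak frequencies, or non-sinusoidal alpha. Passing tests on this
generator therefore validate the estimators and statistics under clean,
stationary coupling — not robustness to every pathology of real MEG.

With the default settings all four estimators localize the coupling: over
20 independent datasets, the comodulogram maximum falls inside phase
9–11 Hz × amplitude 50–70 Hz in at least 90 % of runs for every method.

## Trial length

`trial_length_study()` repeats the single-cell analysis (10 Hz phase,
60 Hz amplitude) for trial lengths from 0.1–10 s, averaging over trials
and over independent datasets. Every length is simulated with the full
0.5 s padding on each side and trimmed by exactly that padding, so filter
transients are excluded identically everywhere and the sweep isolates the
estimators' dependence on the amount of analysed data. (Scaling the trim
down with the trial length instead would let the phase-band filter's
~0.3–0.5 s ring leak into the analysis window for all but the longest
trials, conflating edge artifacts with small-sample bias.)

All four estimators are inflated at short lengths — the resultant of $N$
noisy unit vectors shrinks like $1/\sqrt{N}$, and the KL divergence of a
noisy 18-bin histogram like $(N_{bins}-1)/(2N\log N_{bins})$ — and decay
toward an asymptote. `stabilization_length()` reports the start of the
plateau: the smallest length from which the whole remaining curve stays
within 20 % of the 10 s value. Data segments under 1 s inflate every
estimator strongly (two- to four-fold at 0.2 s). How quickly the curves
then settle depends on the ratio of the true coupling value to the
small-sample bias, and at this generator's coupling visibility and SNR
range (drawn from (−11.5, 0] dB) the plateau comes later than 1 s: in
the shipped 20-dataset sweep the power-normalised mean vector length
stabilizes at 1.2 s, the raw mean vector length at 1.6 s, the
phase-locking value at 1.8 s, and the Kullback-Leibler estimator — whose
asymptote is smallest relative to its bias — at 2.8 s. The overall
stabilization length reported by the acceptance script is the largest of
the four, i.e. governed by the KL estimator. At a higher signal-to-noise
ratio or stronger coupling the same curves compress toward 1 s; the
shipped conditions deliberately keep the noise draw at the harder end.

## Problem sizes and numerical choices

The shipped suites run at desk scale, stated here as the package's own
choices: 64 trials per simulated dataset; 20 independent datasets for the
localization and trial-length claims; trial lengths 0.2–10 s in 0.2 s
steps; 200 surrogates in examples that normalize full grids and 100 in
single-cell tests; 1,000 permutations and 200 null repetitions for the
cluster-test calibration; the planted cluster effect is two noise
standard deviations. Tolerances that recur: envelope flatness < 1 % for a
pure tone; MI toy oracles exact to 10⁻¹²; PLV calibration ± 2 %;
histogram normalisation 10⁻⁹.

Tie-breaks and edge conventions: phase exactly π maps to the last
histogram bin; the comodulogram peak reports the first cell in
column-major order on exact ties; derangements are drawn by rejection
(expected < 2 attempts); the Monte-Carlo cluster p is the plain
proportion of permutations at or above the observed statistic.

## Known limitations

* Only the four estimators above: no GLM-based, direct, directed or
  time-resolved PAC variants.
* One analysis window per condition; no sliding-window PAC.
* The surrogate scheme reassigns whole phase series across trials;
  within-trial phase shifts are not implemented.
* Non-sinusoidal oscillations are diagnosed, not corrected for; where
  the diagnostic fires, MI values should not be interpreted as genuine
  coupling.
* Trial I/O is delimited text only.
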