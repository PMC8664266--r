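---
title: "Methods: inter-brain synchrony estimation and inference in dyadsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-brain synchrony estimation and inference in dyadsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The problem

In EEG hyperscanning, two interacting people — here an infant and an adult
— are recorded simultaneously on a shared clock, and the question is
whether their band-limited neural oscillations phase-couple above chance.
dyadsync implements the full analysis chain for two-condition within-dyad
designs: preprocessing of each member's continuous recording, theta-band
(4–7 Hz) inter-brain connectivity over an adult-by-infant electrode grid,
and permutation inference that controls the family-wise error rate across
the grid. Because no public infant–adult dataset accompanies this class of
study, the package ships a synthetic dyad generator whose ground truth is
known exactly; every downstream stage is validated against it.

## Connectivity model

Each matched 1-s epoch is demeaned, Hann-tapered, and Fourier-transformed;
1-s epochs put the DFT bins on integer frequencies, so the theta band
contributes the bins 4, 5, 6 and 7 Hz. For an adult channel $a$ and infant
channel $i$, the epoch cross-spectrum is $S_e(f) = X_a(f)\,\overline{X_i(f)}$
and the weighted phase lag index per bin is

$$\mathrm{wPLI}(f) \;=\;
\frac{\bigl|\sum_e \mathrm{Im}\,S_e(f)\bigr|}{\sum_e |\mathrm{Im}\,S_e(f)|},$$

with $0/0$ defined as 0. Weighting each phase difference by the magnitude
of its imaginary part makes near-zero-lag coupling — the signature of two
people receiving the same stimulus rather than interacting — contribute
only marginally. The phase locking value,
$\mathrm{PLV}(f) = |\tfrac1E\sum_e e^{i\,\arg S_e(f)}|$, is provided as the
zero-lag-sensitive comparison metric. Band values are the unweighted mean
of the per-bin metric (not a pooled cross-spectrum), which is the common
convention for band-level wPLI; the estimator itself (single Hann taper per
epoch) was chosen because it matches the 1-s epoch length and introduces no
further free parameters. Both metrics are symmetric in the two channels,
exactly invariant to rescaling either channel, and bounded in $[0,1]$; the
test suite checks all three properties plus the discriminating one: a
shared zero-lag source with independent sensor noise drives PLV above 0.5
while wPLI stays below 0.1.

The default analysis grid crosses C3, C4, T7, T8, P7 and P8 of each
subject — 36 inter-subject pairs per dyad per condition; both the grid and
the band are configurable, so all-band or all-pair control analyses are
expressible without code changes. The standard (not debiased-squared) wPLI
estimator is used, matching the $[0,1]$ range convention. A per-dyad floor
of 20 matched epochs is enforced with an explicit error below it.

## Preprocessing

* **Band-pass**: windowed-sinc (Hamming) linear-phase FIR, applied
  forward–backward per channel, so the effective filter is zero-phase.
  Transition bandwidth adapts to the band (half the low edge, clamped to
  0.5–2 Hz). Passband ripple is far below 1% and stopband attenuation far
  beyond 40 dB after the two passes. Filtering twice changes in-band
  content by less than 2% (tested).
* **Epoching**: half-open windows $[k\cdot0.5,\,k\cdot0.5+1)$ s anchored at
  t = 0, i.e. 1-s epochs with 500-ms overlap. Epoch length and step must be
  whole numbers of samples — at 125 Hz a 0.5-s step is not, and silently
  rounding it would make the claimed onset grid drift away from the data,
  so this is a hard error. Overlapping epochs are statistically dependent;
  this is accepted because the emulated pipeline does the same.
* **Rejection**: an epoch is bad when its worst channel's peak-to-peak
  amplitude exceeds a subject-wise threshold $\tau$, selected from a
  20-point log grid over 40–400 µV by minimizing the RMS difference between
  the mean retained epoch and the channel-wise median epoch (a robust,
  transparent surrogate of cross-validated threshold optimization).
  Reject-only: no channel repair or interpolation is attempted, trading
  fidelity to data-driven repair methods for exact reproducibility.
* **Ocular cleanup**: the recording is decomposed into as many maximally
  non-Gaussian (independent) components as channels — a package-internal
  symmetric FastICA with tanh contrast and a seeded, deterministic
  initialization — and components whose mixing pattern correlates with a
  supplied spatial template at $|r| \ge 0.8$ are zeroed before
  reconstruction. This is the template-correlation analog of
  component-matching cleanup across participants. Non-convergence returns
  the recording unmodified with a warning rather than failing the run.
* **Matching**: a dyad's two conditions are truncated to their common
  duration (from the recording start; the emulated protocol does not state
  which end, and the start is the anchored choice), and only epochs good in
  *both* members enter connectivity. Dyads whose matched span is under
  60 s can be excluded, and analysis can be capped to the first 90 s —
  both rules surface as explicit flags rather than silent drops.

## Inference

Per electrode pair, a one-way repeated-measures ANOVA compares conditions
within dyads; with two conditions $F$ is algebraically the squared paired
$t$, which the tests exploit as an oracle to $10^{-10}$. Family-wise error
across the 36 pairs is controlled with a max-statistic permutation test:
condition labels are shuffled independently within every dyad (a sign flip
of the paired difference when $k=2$), the largest $F$ over pairs is
retained per permutation, and each pair's observed $F$ is referred to that
null distribution of maxima. When $2^{n}\le 4096$ with two conditions, all
sign assignments are enumerated exactly and p-values are exact proportions
(identity assignment included); otherwise 1000 random assignments are drawn
by default and p-values use the add-one convention
$(1+\#\{\max F \ge F_{obs}\})/(1+n_{perm})$, which cannot return zero and
is the standard Monte-Carlo correction — a deliberate, documented
divergence from quoting a raw proportion. Uncorrected parametric p-values
are also exposed, since null reports of secondary contrasts are often
stated uncorrected.

Two further pieces of the inference surface:

* **Pseudo-dyad null**: each adult is re-paired with a uniformly drawn
  non-partner infant from the same condition (derangements, rejection
  sampled; at least 5 dyads required), and the target pair's wPLI is
  recomputed from the raw matched epochs of every surrogate pairing — not
  by shuffling connectivity values — giving the chance level of
  inter-brain synchrony for non-interacting pairs.
* **Change scores and exclusion**: paired measures are reduced to
  $(a-b)/\max(a,b)\in[-1,1]$ (0/0 defined as 0), and outliers are flagged
  in a single pass when $|x-\bar x| > 3\,\mathrm{SD}$, both moments
  computed once on the full vector. Whether the emulated analysis applied
  the rule once or iteratively is unstated; single-pass is the stated
  choice here.

## The synthetic world

Every channel is $A\cos\varphi(t)$ plus $1/f$ noise at 0 dB SNR
($A = 10\,\mu V$, slope 1). Adult channels run free theta oscillators
(default 5 Hz) whose phase wanders as a slow AR(1) process (sd $\pi$,
correlation time 0.75 s), so successive epochs carry effectively fresh
phases. A coupled infant channel follows its partner channel at a fixed
lag (default $\pi/4$ — wPLI is blind at 0 and $\pi$, and a quarter cycle
maximizes the imaginary cross-spectrum) plus a stationary Gaussian jitter
with marginal sd $\sigma(\kappa)=\pi(1-\kappa)$. One refinement over
drawing that jitter independently per sample: the jitter is an AR(1)
process with a 0.25-s correlation time, because i.i.d. per-sample phase
noise would whiten the signal and destroy the band-limited structure the
pipeline assumes. $\kappa=1$ still gives exactly zero jitter and
$\kappa=0$ is indistinguishable from independence. Because the carriers
are real (not analytic) signals, a little negative-frequency energy leaks
into the band bins, so a fully locked pair saturates just below 1
(≈ 0.998) — the exact-1 limit is reserved for the deterministic tone
fixtures.

Randomness is split into one stream per (dyad, condition, channel,
purpose) by counter-based hashing of the master seed, so adding artifacts
or behavior never perturbs the signal draws. Artifacts are 200-ms square
jumps on single channels at 5× the background peak-to-peak, and 0.5-s
frontal-dominated smooth deflections for ocular events; ground truth
(times, true spatial pattern, clean signal) rides along for assertions.
Behavior is an alternating-renewal process over the standard infant gaze
and affect code inventories, with exponential bout lengths calibrated so
the long-run attention and positive-affect proportions hit the condition's
targets. An optional per-dyad latent "engagement" scalar multiplies both
the coupling strength and the attention proportion in the non-baseline
condition(s) only — applying it to both conditions would cancel out of
change scores — giving a controllable ground-truth brain–behavior
correlation.

What the generator does **not** emulate: volume conduction and realistic
forward models (there is no cross-head conduction to confound, which is
precisely why the zero-lag property must be tested with explicit
shared-source fixtures), realistic EOG waveforms, non-stationary arousal
dynamics, or line noise. A green test therefore establishes that the
pipeline recovers the statistical structure it claims to measure — not
that it would be robust to every physiological contaminant of real infant
EEG.

## Behavioral measures

Visual attention is time in social gaze or joint attention, minus its
overlap with negative affect (crying/fussing), over the session time minus
uncodable-gaze and negative-affect time. Those two subtracted sets live on
different coding channels and can overlap, so their *union* is subtracted
(counting the overlap once) — the literal double subtraction could
undercount codable time. Positive arousal is positive-affect time over
codable affect time. Time not covered by any interval is treated as
uncodable with a warning, and a coverage warning fires when codable time
drops below 50% of the session; which denominator the emulated study used
is unstated, so the choice is surfaced in output rather than hidden. The
infant safety composite averages seven 5-point items after reversing
dyadic tension ($6-x$); the reversal is an involution, which the tests
assert.

## Calibration and scaling decisions

The generator's defaults are the stated world: 16-channel 10/20 montage,
250 Hz, 180-s conditions, theta 4–7 Hz. No effect size on the wPLI scale
is available from the emulated study, so the detection calibration is the
package's own: a contrast of $\kappa = 0.6$ versus 0 at (adult C4, infant
P8) with 20 dyads, fixed a priori. Under that world the localization test
detects the injected pair in well over 80% of simulated studies with no
other pair above 10%, and 200 global-null studies keep the family-wise
false-positive rate within its binomial band. To fit a desktop budget the
calibration suites run on 20-s recordings at 100 Hz rather than 3-min
recordings at 250 Hz — study counts, dyad counts, the 36-pair grid and
all thresholds are unchanged — and the brain–behavior power check runs 15
seeded studies of 16 dyads at 40 s instead of 100 full-scale runs.

## Numerical conventions

Degenerate cross-spectra (exactly zero imaginary part everywhere) give
wPLI 0 by the 0/0 convention; zero-variance ANOVA cells give $F=\infty$
with a warning when an effect exists and $F=0$ otherwise; `paired_t` on
identical vectors returns $t=0,\ p=1$ rather than failing on the zero
variance; permutation comparisons use a $10^{-12}$ tie tolerance so that
regenerated statistics equal to the observed one count as exceedances.
Epoch grids, half-open windows and 0-based onsets are exact in sample
units. All file formats are plain text (TSV + JSON sidecar, long-format
connectivity TSV, JSON stats with a plain-text null sample) except the
optional 16-bit EDF reader/writer, which round-trips to quantization
accuracy.

## Known limitations

Channel repair/interpolation is deliberately absent (rejection only);
the spectral estimator is fixed to one Hann taper per 1-s epoch; directed
and cross-frequency coupling are out of scope; the pseudo-dyad null
recomputes only a single target pair (not the full grid) per surrogate;
and the synthetic world's artifact models are schematic by design.
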