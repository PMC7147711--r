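---
title: "Phase-locking analysis of EEG during response inhibition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking analysis of EEG during response inhibition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaselock)
```

# Scope

`phaselock` implements an end-to-end analysis of cortical phase
synchronization during response inhibition in the auditory stop-signal
paradigm: a simulator of the task and of multichannel EEG with controlled
phase structure, broadband preprocessing, inter-trial coherence (ITC) on a
Morlet time-frequency decomposition, and phase-locking value (PLV)
connectivity over standard 10-20 electrode pairs. Because raw recordings
from such experiments are rarely shareable, the package treats the
synthetic-data generator as a first-class component: every statistic can be
validated against the generator's analytic ground truth.

# The stop-signal task and the race model

A session mixes 75% go trials (a square calls for a left-hand response, a
circle for a right-hand response) with 25% stop trials in uniformly random
order; the default is 180 go and 60 stop trials. On a stop trial a 750 Hz,
100 ms tone follows the go stimulus after the stop-signal delay (SSD). The
SSD starts at 250 ms and moves by +50 ms after every successful inhibition
and -50 ms after every failure (1-up/1-down staircase), so it tracks the
delay at which stopping succeeds on half the stop trials.

Trial outcomes follow the independent race model. The go process finishes
at an ex-Gaussian time, $T_g \sim \mu + \sigma Z + \mathrm{Exp}(\tau)$,
the standard skewed parameterization of reaction times; the stop process
finishes at $\mathrm{SSD} + T_s$ with $T_s \sim
\mathcal N(\mu_s, \sigma_s)$. The response is inhibited iff the stop
process wins. The defaults ($\mu = 450$, $\sigma = 60$, $\tau = 60$,
$\mu_s = 200$, $\sigma_s = 30$, all ms) give substantially overlapping
distributions, the regime in which the staircase can track its 50% target.
The task description fixes the staircase but not the finishing-time
distributions; the ex-Gaussian/Gaussian pair was chosen once as the field's
standard parameterization so that SSRT recovery is testable, and is not
tuned thereafter. Staircase bounds default to [50, 1000] ms (none are
stated for the task; these simply keep the delay inside the stimulus
period). Go omissions occur with probability `miss_rate` (default 0) and
are excluded from go-RT averages; an omission on a stop trial counts as a
successful stop, since no response occurred.

SSRT is estimated by the mean method only: mean go RT minus mean SSD over
all stop trials. Under a converged staircase the mean SSD approximates the
delay of 50% inhibition, making the difference an estimate of the stopping
latency. The mean method carries a known upward bias of roughly the
mean-median gap of the go distribution (about 15 ms at the defaults); the
package's recovery test therefore checks the pooled estimate to within
±25 ms of the true 200 ms, not to equality. The integration method is out
of scope.

# The synthetic EEG generator

Each trial's epoch (default -500 to +1300 ms around go onset, 500 Hz,
32-channel 10-20 montage) is white Gaussian noise (default SD 5 µV, an
optional 1/f component is available) plus event-locked oscillatory bursts.
A burst is a sinusoid at centre frequency $f$ under a Tukey envelope
(taper fraction 0.25, a free choice that avoids edge ringing) spanning
`[onset, offset]` ms relative to its locking event (go onset, the trial's
stop-signal onset, or the response). Its phase at onset is drawn once per
trial:

* independently, from a von Mises distribution with concentration
  $\kappa$ — the population resultant length, and hence the generator's
  ground-truth ITC, is the Bessel ratio $I_1(\kappa)/I_0(\kappa)$;
* or copied from another channel's burst with a constant offset plus
  Gaussian jitter of SD $\sigma_j$ — the ground-truth PLV is
  $\exp(-\sigma_j^2/2)$ for small-to-moderate jitter.

The phase is defined at burst onset and evolves at the centre frequency,
which is what makes these closed forms exact. Sampling uses the
Best-Fisher rejection algorithm for von Mises draws; all generation is
seeded and byte-reproducible.

What the generator does **not** emulate: volume conduction and shared
reference (which inflate zero-lag connectivity in real data), ocular and
muscle artifacts, non-stationary background rhythms, and realistic scalp
topography. Tests passing on this generator therefore validate the
statistics and their calibration, not robustness to those confounds; the
phase-lag-index family of measures, designed against volume conduction, is
deliberately out of scope.

# Preprocessing

Broadband filtering is a 4th-order Butterworth band-pass (default 1-40 Hz)
applied forward and backward (`filtfilt`), the de facto EEG standard. The
order and family are not dictated by the task description; zero-phase
application was chosen because group delay would bias every phase statistic
downstream, and a causal single-pass option is kept for completeness.
Epoch extraction takes exact sample slices (no resampling); events whose
window overhangs the recording are dropped with a warning rather than
failing the run, so long simulated sessions survive edge events. Artifact
removal (ICA) is not re-implemented; the pipeline accepts already-clean
data and the preprocessing stage is the place to plug a cleaning step in.
No baseline correction is applied before ITC: the statistic is
amplitude-free, and no baseline policy is prescribed for it.

# Inter-trial coherence

The Morlet decomposition uses wavelets with $\max(3, f/2)$ cycles on a
linear grid (1 Hz steps, 1-40 Hz where the epoch permits). The cycle rule
keeps time resolution at low frequencies while sharpening frequency
resolution higher up. Samples within half a wavelet of an epoch edge are
flagged invalid and can never be significant. A 1 Hz wavelet with 3 cycles
spans several seconds and cannot fit the default 1.8 s epoch, so the
pipeline's default grid starts at 2 Hz; the delta band is then represented
by its 2-4 Hz part.

For $N$ trials with coefficient phases $\varphi_n(c, f, t)$,

$$\mathrm{ITC}(c, f, t) = \left| \frac{1}{N} \sum_{n=1}^{N}
e^{i\varphi_n(c, f, t)} \right| ,$$

the modulus of the across-trial mean unit phasor: 0 for unrelated phases, 1
for perfectly reproducible phase. This is the standard inter-trial
coherence, the only reading consistent with the statistic's stated [0, 1]
range and its interpretation of 1 as perfect synchronization.

Significance uses the Rayleigh null: under uniform phases
$P(R \ge r) = e^{-N r^2}$, so the critical resultant at level $\alpha$ is
$\sqrt{-\ln\alpha / N}$ (0.2234 for $N = 60$, $\alpha = 0.05$). The
closed form is exact under the null and replaces any baseline-derived
threshold; Monte-Carlo calibration in the test suite confirms the empirical
false-positive rate sits at 5%. No multiple-comparison correction is
applied by default, matching per-cell $p < 0.05$ reporting; a
Benjamini-Hochberg option exists (`fdr = TRUE`). Condition contrasts
(successful stop minus successful go) are plain elementwise differences
with both masks carried along.

# PLV connectivity

Instantaneous phase is the angle of the analytic signal (FFT construction)
of the band-limited series, with the canonical bands delta 1-4, theta 4-7,
alpha 8-12 and beta 13-30 Hz, each extracted by the same zero-phase
Butterworth design. For two phase series over a window of $N$ samples,

$$\mathrm{PLV} = \left| \frac{1}{N} \sum_{k=1}^{N}
e^{i(\varphi_1(k) - \varphi_2(k))} \right| ,$$

the modulus of the mean difference phasor — again the only reading bounded
in [0, 1] with 1 attained when the phase difference is constant. PLV is
symmetric and invariant to constant phase offsets.

Analysis windows resolve against per-trial events: fixation
$[-250, 0)$ ms before go onset (the fixation-cross duration), the SSD
window from go onset to the trial's stop-signal onset, the SSRT window
from stop onset to stop onset plus the estimated SSRT, and the RT window
from go onset to the response. The windows are named but not bounded in
the task description; these resolutions follow directly from the events
that define them. Variable-length windows are concatenated across trials
before the PLV sum (sample-weighted); a per-trial-average mode is available
behind `per_trial = TRUE`.

Edge significance uses a trial-shuffling surrogate null: channel 2's trials
are re-paired at random (200 permutations by default), which destroys
within-trial coupling while preserving each channel's phase dynamics; an
edge is significant when the observed PLV exceeds the surrogate 95th
percentile. When re-paired trials have unequal window lengths the shared
prefix is used. The connectivity graph for a stimulus window keeps edges
that are significant *and* exceed their fixation-window PLV, annotated with
the PLV increase.

One caveat the test scenarios make visible: zero-phase narrow-band filters
are acausal, so a strong stop-locked burst leaks backwards in time by
roughly the inverse band width (~300 ms in theta). Coupled pairs can
therefore show elevated pre-stimulus PLV purely through filter leakage.
The fixation-baseline contrast absorbs most of this, but fixation-window
PLV of strongly coupled pairs should not be over-interpreted — in real
recordings the same artifact arises.

# Numerical choices and degenerate inputs

* ITC with a single trial is degenerate (always 1) and is rejected.
* Zero-amplitude coefficients contribute a zero phasor rather than NaN;
  an all-zero band-limited signal raises an undefined-phase error.
* Sequences, sessions, epochs and surrogate permutations are all seeded;
  seeds are recorded in the pipeline manifest, and the generator restores
  the caller's RNG state.
* Surrogate PLV uses a cross-trial phasor cross-product with zero padding,
  which truncates each re-paired dot product to the shorter trial exactly.
* The EDF writer scales each channel into signed 16-bit integers over a
  symmetric digital range (±32767) so the affine read-back inverts the
  write mapping to within one quantization step; header dates are fixed
  constants so identical data give identical files.

# Problem sizes used in the shipped checks

The package's own validation runs at sizes a desk machine handles in
seconds to a couple of minutes: 200 sessions for staircase tracking, 200
trials per concentration level for ITC recovery (checked within ±0.05 of
the Bessel ratio), 1000-repetition Monte-Carlo for mask calibration,
200-surrogate nulls for the connectivity-recovery scenario, and a reduced
pipeline (60 trials, nine channels, 2-30 Hz grid) for the byte-identity
rerun check. These sizes were chosen as the smallest at which the
statistics' sampling noise is well inside the asserted tolerances.

# Known limitations

* The mean-method SSRT bias noted above; no integration estimator.
* ITC values on the default pipeline grid exclude 1 Hz (epoch too short
  for the wavelet).
* The surrogate null assumes trials are exchangeable within a condition;
  slow drifts across a session would violate that.
* The connectivity stage analyzes successful-stop trials; failed-stop
  contrasts, directed measures and source-space analyses are out of scope.
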