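---
title: "Methods: intermittent theta dynamics during real and imagined navigation"
author: "thetanav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intermittent theta dynamics during real and imagined navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetanav)
```

## The scientific problem

Human medial-temporal-lobe (MTL) field potentials show theta-range (3-12 Hz)
oscillations in brief bouts rather than continuously. During real-world
navigation along a learned route of linear segments joined by turns, these
bouts align with particular positions along the route — most prominently the
approach to each upcoming turn — and similar temporally structured dynamics
appear when the same routes are merely imagined while walking on a treadmill.
`thetanav` implements the full analysis chain needed to establish and
quantify this: time-frequency extraction, individualized theta-band
selection, epileptiform-artifact rejection, oscillatory-bout detection,
trial time-warping, split-half temporal-consistency statistics, and a linear
decoder that reconstructs the relative position within route segments as a
circular variable.

Because chronic ambulatory intracranial recordings are rare, the package
ships a synthetic-session generator that emulates the statistical structure
of such an experiment with known ground truth. Every pipeline stage is
validated against that ground truth.

## The signal model behind the generator

A session consists of real-world walking trials along a route template
(default: five segments joined by four turns, segment lengths 2.4-3.4 m,
walked at ~1.35 m/s, so trials last roughly 12-14 s), imagined-navigation
trials and control (treadmill-only) trials, 24 of each, recorded on 18
bipolar MTL channels across 5 participants at 250 Hz.

The relative position within the current segment is the circular variable
$\varphi \in [0, 2\pi)$: 0 at segment entry, $2\pi$ at the turn that ends
the segment. Channel $c$ carries intermittent theta bouts whose occurrence
rate *and* within-bout envelope follow

$$m_c(t) = a + b\,\cos(\varphi(t) - \theta_c),$$

with preferred phases $\theta_c$ tiling $[0, 2\pi)$ across channels (so the
population contains cosine-like and $-$sine-like modulations, the two
orthogonal components the decoder uses). Defaults $a = 1$, $b = 0.8$. Bouts
last $0.52 \pm 0.08$ s (at least two theta cycles), cover ~21% of trial
time, and ride on a 1/f$^{1.5}$ Gaussian background (unit SD, rolled off
outside the 1-90 Hz acquisition band, as recording hardware would) plus
continuous delta (2 Hz) and beta (16 Hz) components that give the spectra
their flanking peaks. Per-participant theta frequencies span 4.5-8.5 Hz.
Bout amplitude is `bout_amp_snr` (default 2) background-SDs at the peak of
$m_c$, scaled per channel by a heterogeneous gain pattern that emulates
anatomy: some sites are strongly modulated, others weakly, and the pattern
is identical across conditions. That shared heterogeneity — not anything in
the analysis — is what makes temporal consistency spatially correlated
between real and imagined navigation.

Imagined trials replay the same $\varphi$ dynamics with distorted timing:
each turn anchor is shifted by a participant-level systematic offset
(SD 0.75 s, shared across a participant's trials and channels) plus smaller
per-trial jitter (SD 0.25 s), the total truncated at ±2 s. The systematic
component is deliberate: the alignment stage learns a per-participant time
warp from training trials, which is only possible if part of the distortion
is reproducible. Control trials contain bouts at the same rate and
amplitude but uniformly placed — no $\varphi$-locking at all. Interictal
discharges (70 ms biphasic spike at 8 background-SDs followed by a 300 ms
slow wave) are injected session-wide at 1/min, emulating participants
selected for low epileptiform activity.

What the generator does *not* emulate: volume conduction and channel
cross-talk, non-sinusoidal theta waveform shape, movement artifacts,
behaviour-dependent amplitude confounds (speed, head turns), and
non-stationarity of the background over a session. Passing tests therefore
demonstrate that the pipeline recovers the structure it is designed for,
not that real recordings are free of those confounds.

## Pipeline stages and their parameters

**Time-frequency decomposition.** Continuous wavelet transform with
generalized Morse wavelets, symmetry $\gamma = 3$ and time-bandwidth
$P^2 = \gamma\beta = 60$, 10 voices per octave over 1-90 Hz, bandpass
normalized so a unit sinusoid yields amplitude 1. The implementation
evaluates each wavelet from the spectral slice covering its frequency
support (truncated below $10^{-8}$ of the peak) and emits the amplitude
envelope at 50 Hz; envelopes are band limited far below that, so nothing is
lost (the test suite checks agreement with the full-rate transform to
$10^{-6}$). The first and last 2 s of every trial are treated as cone of
influence and excluded from all normalization statistics.

**Normalization and band selection.** Amplitudes are z-scored per channel
and frequency over the session's artifact-free samples. The theta band is
individualized per participant: the largest strict local maximum of the
participant-mean amplitude spectrum within 3-12 Hz, extended to the
neighbouring spectral minima on either side (ties toward the lower
frequency; the flanking delta and beta peaks are what terminate the search
in practice). Analyses in this vignette use a 1-30 Hz grid: every band of
interest lies below 30 Hz, while the 1-90 Hz default mirrors the recording
bandwidth.

**Artifact rejection.** Interictal discharges are flagged where the
analytic-signal envelope of the broadband (1-90 Hz) or 15-80 Hz band-passed
signal exceeds 5x its per-channel session median; flagged runs are extended
by 256 ms on both sides, any-channel flags mask all channels, and trials
with > 50% flagged coverage are dropped. For a Gaussian process the
envelope is Rayleigh, so 5x the median (~5.9 SD) has false-positive
probability ~3e-8 per sample — the flagged fraction tracks the injected
artifact load, not the background.

**Bout detection.** Oscillatory episodes follow the BOSC family: the
background is a robust (Huber) log-log regression of mean wavelet power on
frequency — fitted with the theta band excluded so the oscillation does not
inflate its own threshold — and power is flagged above the 0.95 quantile of
the $\chi^2(2)$-scaled background, for at least two cycles. Two
implementation points matter and are deliberate. First, detection runs on a
short Morse wavelet ($P^2 = 36$, the six-cycle convention of BOSC
detectors) rather than the long $P^2 = 60$ analysis wavelet: a long wavelet
smears episode edges so badly that durations overshoot by ~70% and the
union of neighbouring frequency bins pushes pure-noise prevalence to ~15%.
Second, episode edges are corrected for the detection wavelet's own
temporal smearing: a finite burst of peak amplitude $A$ crosses an
amplitude threshold $T$ roughly $\sigma_t\,\Phi^{-1}(1 - T/A)$ before its
true edge ($\sigma_t = \sqrt{P^2}/2\pi f$), and each episode is trimmed by
that amount per side before the two-cycle criterion. With both in place,
injected 0.52 s bouts at 3 background-SDs are recovered with ~100%
sensitivity, prevalence and duration within ~15% of the injected values,
and pure-1/f prevalence around 2%. Prevalence is reported as Pepisode — the
fraction of time covered, per frequency bin, averaged over the band — while
merged band-level intervals feed indicator-based summaries (bout rate
timecourses, pre-turn coverage). A note on slopes: wavelet-measured power
spectra of 1/f$^\alpha$ noise have log-log slope $-(\alpha - 1)$, not
$-\alpha$, because log-spaced wavelet bandwidth grows proportionally to
frequency; the background fit recovers whatever slope the supplied spectrum
has.

**Trial alignment.** Real trials are aligned by dynamic time warping of 2D
positions (Euclidean cost, symmetric unit-slope steps, computed on 30 Hz
decimated trajectories) against the medoid trial — the trial minimizing
summed DTW distance, which avoids any ordering dependence. Turns are
located on the medoid as the largest peaks of smoothed heading angular
velocity and mapped through each trial's warping path; behavioural and
neural series are then piecewise-linearly warped so all trials share the
mean anchor timing. Imagined and control trials, lacking motion anchors,
are linearly warped to the same common duration.

**Temporal consistency.** Per channel and condition, trials are randomly
split in halves 1000 times; the consistency is the mean Pearson correlation
between the two half-mean time courses (odd counts: the larger half gets
the extra trial at random). Condition contrasts use a block permutation
test: the observed statistic is the mean paired difference over channels,
the null flips each channel's condition labels, participants are recorded
as exchangeability blocks, confidence intervals come from a cluster
bootstrap resampling participants, and Cohen's d (mean/SD of channel
differences, condition A minus B) is reported alongside. One-sided tests
are used where the hypothesis is directional (structured conditions more
consistent than control). The spatial correlation between conditions is
Pearson across channels with channel pairings permuted within participant
blocks.

**Decoding.** The route structure is abstracted into the responses
$(\cos\varphi, -\sin\varphi)$ — the cosine peaks at each turn, the negative
sine at three quarters of each segment, i.e. before turns. An ordinary
least-squares model maps the pooled z-scored band amplitudes of all 18
channels (plus intercept) to the two responses; trials are assigned whole
to folds in a 10-fold scheme repeated 10 times, and predictions are emitted
only for held-out trials. The decoded position is the angle of the
resultant, $\hat\varphi = \mathrm{atan2}(-\hat y_{-\sin}, \hat y_{\cos})$.
Reported reconstructions average held-out component predictions across
trials (each trial predicted from folds excluding it) before taking the
angle; errors are the circular differences $\hat\varphi - \varphi$ in
$(-\pi, \pi]$, summarized as mean absolute error in degrees, mean resultant
length, and an actual-by-estimated density normalized so uniform estimates
give 1 everywhere. The chance reference refits the decoder on responses
circularly shifted per trial; a single shuffle draw leaves a residual
common rotation (the resultant of 24 random rotations), so every repeat
draws fresh shifts and errors are pooled — even so this reference carries
Monte-Carlo spread of roughly ±15 degrees around 90.

**Imagined decoding.** The real-trained model is applied to imagined
trials. Because imagined velocity is unobservable, estimates are aligned to
the structure by Sakoe-Chiba-banded DTW on squared circular distance with a
±2 s cap. The alignment is learned per participant — from the marginal
estimate computed with only that participant's channels (the others sit at
their z-scored mean of zero), averaged over the training trials of each
fold — and the learned path is applied unchanged to the held-out trials'
channel series, preserving relative timing between a participant's
channels; the pooled model then decodes the aligned data (10 x 10 scheme).
Significance of error concentration uses a circular-shift null: 10000
whole-series rotations of the estimate relative to the structure, which
preserve autocorrelation. With near-equal segment durations, rotations near
multiples of one segment partially realign the periodic structure, so this
null is conservative for strongly periodic routes — worth remembering when
a genuinely structured reconstruction yields an unremarkable p.

**Turn-locked statistics.** Event-locked averages around turns are tested
with a cluster-based sign-flip permutation test: point-wise two-sided
primary threshold at the 0.05 quantiles of the sign-flip null, clusters by
1D adjacency (4-connectivity for time-frequency maps), cluster sizes scored
against the permutation distribution of the maximal cluster. The null flips
each channel independently: flipping exactly half the channels — a
described variant — constrains the flip sum to zero and shrinks the null
variance (measured point-wise rate 10% at nominal 5%), so independent flips
are used to keep the family-wise error at its nominal level (measured
<= 0.075 at 0.05 over 200 null simulations). Peak latencies (argmax within
the window, ties toward earlier) are tested against zero by sign-flipping
within participants. Single-trial regressions of band amplitude on
behavioural variables are tested jointly with a max-statistic correction
across variables.

## Numerical choices and degenerate inputs

Time is in seconds with 0-based samples and half-open intervals
`[start, stop)`. Local-extremum ties break toward lower frequency; latency
ties toward earlier lags. Degenerate inputs fail loudly: constant channels
cannot be z-scored, flat spectra have no band, fewer than four trials have
no split-half estimate, rank-deficient decoder designs fall back to a
lightly regularized solve with a warning, a single participant degrades the
block test to a within-participant permutation with a warning, and DTW
bands narrower than one sample are rejected. Permutation p-values are
never below `1/(n_perm + 1)`.

## Problem sizes

The default study conditions are 18 channels, 5 participants, 24 trials per
condition, ~12-14 s trials, bout SNR 2. Session-mean spectra are averaged
over 8 evenly spaced real trials (they stabilize after a handful);
replicate studies (e.g. the 50-seed imagined-generalization study) switch
off bout detection and artifact scanning via the stage toggles and use 6
spectrum trials, since those stages do not enter the quantity under study.
Split-half replicate studies use 200-250 partitions, which estimates the
consistency to within ±0.02 of the 1000-partition value.

## A worked miniature

```{r mini, eval = FALSE}
session <- simulate_session(synth_config(), seed = 1)
config <- pipeline_config(f_range = c(1, 30), n_spectrum_trials = 8)
proc <- process_session(session, config)
dec <- decode_study(session, config, seed = 1, proc = proc)
dec$real$mean_abs_err_deg      # ~8 degrees
dec$shuffled$mean_abs_err_deg  # ~86 degrees (chance reference)
dec$imag$report$mean_abs_err_deg   # ~20 degrees
dec$ctrl$report$mean_abs_err_deg   # ~93 degrees
```

The quantities the package claims are exactly those its tests and
`scripts/acceptance.R` compute; nothing beyond them is asserted here.

## Known limitations

* The generator's bouts are narrowband sinusoids at one per-participant
  frequency; real theta bouts drift in frequency and shape.
* The smearing correction for episode edges assumes an approximately
  Gaussian wavelet envelope and a roughly boxcar burst; it is a first-order
  correction, not a deconvolution.
* The circular-shift null is conservative on near-periodic structures (see
  above).
* Per-participant alignment assumes the systematic part of imagined-timing
  distortion dominates the per-trial jitter; if imagination timing were
  pure per-trial noise, no alignment could generalize and imagined
  decoding would degrade toward the control condition.
* The pooled decoder assumes all channels share one task structure; routes
  with participant-specific turn counts are handled by building the task
  structure with a different `n_turns`, not by mixing structures within
  one fit.
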