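# thetanav

Analysis pipeline for intermittent theta dynamics in human
medial-temporal-lobe (MTL) field potentials during real-world and imagined
navigation, together with a synthetic-session generator that makes every
stage testable against known ground truth.

## The problem and who this is for

During navigation along a learned route of linear segments joined by
turns, human MTL theta (3–12 Hz) appears as brief oscillatory bouts that
align with particular positions along the route — most prominently the
approach to upcoming turns — and similar structured dynamics occur when
the route is merely imagined. Establishing this from chronic ambulatory
intracranial recordings requires a long chain of signal processing and
nonparametric statistics. `thetanav` implements that chain for
electrophysiologists and methods researchers:

* Morse-wavelet time–frequency amplitudes (γ = 3, P² = 60, 10
  voices/octave, 1–90 Hz) with per-participant theta bands picked between
  neighbouring spectral minima around the 3–12 Hz peak;
* interictal-discharge rejection (5× median envelope, 256 ms extension,
  50% trial-exclusion rule);
* BOSC-style bout detection against a robust 1/f background fit (0.95
  χ²(2) threshold, ≥ 2 cycles, Pepisode prevalence);
* DTW alignment of walking trials, turn identification, piecewise-linear
  time warping to a common timeline;
* split-half temporal consistency with multilevel block-permutation
  inference and cluster-bootstrap CIs;
* a cross-validated (10 × 10) linear decoder of relative segment position
  as a circular variable: responses (cos φ, −sin φ), position
  φ̂ = atan2(−ŷ₋ₛᵢₙ, ŷ_cos), with per-participant capped-DTW (±2 s)
  alignment for imagined trials and circular-shift nulls;
* cluster-based sign-flip permutation tests and turn-locked latency
  statistics.

## Worked example

```r
library(thetanav)

session <- simulate_session(synth_config(), seed = 1)   # 18 channels, 5
                                                        # participants, 24
                                                        # trials/condition
config  <- pipeline_config(f_range = c(1, 30), n_spectrum_trials = 8)
proc    <- process_session(session, config)   # artifacts, spectra, bands,
                                              # bouts, warped trials
dec     <- decode_study(session, config, seed = 1, proc = proc)

dec$real$mean_abs_err_deg          # 7.8   cross-validated real-walk error
dec$shuffled$mean_abs_err_deg      # 85.6  shuffled-structure chance level
dec$imag$report$mean_abs_err_deg   # 20.5  held-out imagined-trial error
dec$ctrl$report$mean_abs_err_deg   # 93.2  treadmill-only control
dec$ctrl_null$p                    # 0.94  control shows no concentration

cons <- consistency_study(proc, seed = 2)
aggregate(value ~ condition, cons$consistency, mean)
#   condition  value
#     control  0.045
#    imagined  0.43
#        real  0.45
cons$real_vs_ctrl$p                # 0.000999 (one-sided block permutation)
cons$spatial$statistic             # 0.88  same sites structured in both
```

Mean absolute circular error is in degrees: ~90° is chance, small values
mean the decoded position tracks the actual (real walks) or task-defined
(imagined) position within each route segment. Consistency is the mean
split-half correlation of a channel's trial-averaged band dynamics; ~0
for unstructured treadmill walking, well above 0 when dynamics repeat
across trials.

A file-based driver (`write_session()` / `run_pipeline()`) and a thin CLI
(`inst/cli/thetanav.R` with `simulate` and `run` subcommands) cover script
use.

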