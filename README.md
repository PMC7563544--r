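# intentnet

Multilayer analysis of motor intent from upper-body kinematics and a
single-lead ECG.

A pointing trial holds two movements with different levels of intent: the
instructed, goal-directed reach toward the target (forward–deliberate) and
the uninstructed retraction of the hand back to rest
(backward–spontaneous). A second axis separates the performing side of the
body from its non-performing mirror. `intentnet` quantifies both axes from
the moment-to-moment fluctuations of the recorded biorhythms:

- **Micro-movement spikes (MMS).** Each local maximum `p` of a waveform
  with flanking valley values `m1`, `m2` becomes the unitless amplitude
  `p / (p + (m1 + m2)/2)` in (1/2, 1] — exactly invariant under rescaling,
  so effectors of different sizes are comparable.
- **Noise-to-signal ratio (NSR).** MMS amplitudes of the angular
  acceleration (per sensor, and of pairwise absolute differences per
  sensor pair) are fitted with a two-parameter Gamma by maximum
  likelihood; the NSR is the fitted scale `b` (95% CIs from the inverse
  observed Fisher information on log-parameters).
- **Earth mover's distance (EMD).** Distance between normalized MMS
  amplitude histograms (Freedman–Diaconis binning); in 1-D computed as
  `∫ |F_P − F_Q| dz`, equal to the optimal-transport cost.
- **Connectivity networks.** Per-trial maximal cross-correlations of
  linear speed between all sensor pairs form a weighted undirected graph;
  weighted clustering coefficients use geometric-mean triangle
  intensities, `C_i = t_i / (k_i (k_i − 1) / 2)` with
  `t_i = Σ (ŵ_ij ŵ_ih ŵ_jh)^{1/3}`.
- **Heart–body lead/lag.** The band-passed (5–30 Hz Butterworth,
  zero-phase) ECG's amplitude envelope is cross-correlated per trial with
  each body part's speed at 256 Hz; positive lag means the ECG leads the
  kinematics.

Because no public recordings of this kind exist, the package includes a
synthetic session generator (`generate_session`) producing motion-capture
kinematics (10 sensors, 240 Hz), ECG (256 Hz) and ground truth with the
full statistical structure the analysis assumes — configurable Gamma laws
for MMS amplitudes, segment- and side-dependent coupling, and per-segment
heart leads.

## Worked example

```r
library(intentnet)

cfg <- session_config(n_trials = 30, seed = 101)  # defaults: 180 trials
ses <- generate_session(cfg)
m   <- analyze_session(ses)
m
#> <intent_metrics> 30 valid trials; median NSR fwd 0.00165 / bwd 0.001362

cp <- aggregate_metrics(m, participant = "P1")
subset(cp$cells, metric %in% c("nsr_aa", "xcorr_body", "lag_heart"))
#>        metric          cell         value
#> 1      nsr_aa       forward  0.0016498049
#> 2      nsr_aa      backward  0.0013623467
#> 3      nsr_aa    performing  0.0026900297
#> 4      nsr_aa nonperforming  0.0009457412
#> 9  xcorr_body       forward  0.9695580525
#> 10 xcorr_body      backward  0.9391584811
#> 11 xcorr_body    performing  0.9933819141
#> 12 xcorr_body nonperforming  0.9294709100
#> 25  lag_heart       forward  0.0234375000
#> 26  lag_heart      backward -0.3300781250
#> 27  lag_heart    performing  0.0244140625
#> 28  lag_heart nonperforming -0.2207031250
```

Read: NSR (noise level of the angular-acceleration fluctuations) is higher
for forward reaches and on the performing side; body-network
cross-correlation is stronger under higher intent; the median heart–body
lag is positive (ECG leads) for forward segments and the performing side,
negative (kinematics lead) for backward segments and the non-performing
side.

Across a cohort, `summarize_cohort(list_of_comparisons)` reduces each
metric and contrast to a consistency symbol — `o` when the favored
category is higher for every participant, a triangle when higher for most
— and reports which signal leads per cell.

A command-line front end for the simulate / analyze / summarize cycle is
installed under `inst/scripts/intentnet.R`; sessions round-trip through a
plain CSV + JSON + YAML schema (`write_session` / `read_session`).

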