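---
title: "Differentiating levels of motor intent from kinematics and cardiac biorhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiating levels of motor intent from kinematics and cardiac biorhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intentnet)
```

## The problem

A pointing trial contains two qualitatively different movements: an
instructed, goal-directed reach toward a target (the *forward–deliberate*
segment, high motor intent) and the uninstructed retraction of the hand back
to rest (the *backward–spontaneous* segment, low motor intent). A second
axis of intent separates the *performing* side of the body — scapula, upper
arm, forearm and the hand/index finger executing the task — from its
*non-performing* mirror set. `intentnet` implements a multilayer analysis
that asks whether the moment-to-moment fluctuations of upper-body kinematics
and of the cardiac signal carry enough structure to separate these levels of
intent, and in which direction the heart and the body lead each other.

The pipeline ingests per-session multi-sensor kinematics (ten upper-body
sensors, 3-D position plus unit orientation quaternion per frame, nominally
240 Hz), a single-channel ECG (mV, nominally 256 Hz) and per-trial target
positions. No public recordings of this kind exist, so the package ships a
synthetic session generator that carries the full statistical structure the
analysis assumes; every downstream stage is testable against known ground
truth.

## The analysis chain

**Kinematic derivations.** Linear speed is the Euclidean norm of the
central-difference velocity. Angular speed comes from the orientation
quaternions: after enforcing sign continuity (q and −q encode the same
rotation), the rotation angle of the relative quaternion between frames
t−1 and t+1 is divided by the two-frame interval, which is the rotational
analogue of a central difference. The scalar angular acceleration is the
derivative of angular speed, d|ω|/dt; spike extraction operates on its
magnitude. The alternative reading — the norm of the angular-acceleration
vector — coincides with the default for fixed-axis rotation and is offered
as `angular_acceleration(..., mode = "magnitude")`.

**Trial segmentation.** Within each trial window the forward reach runs
from the last near-zero-speed frame before the speed rises toward the
target to the first near-zero-speed frame at the target (minimum distance);
the backward retraction runs from where speed rises away from zero at the
target to the next near-zero rest. "Near zero" is 5% of the per-trial peak
speed — a deliberately scale-free threshold, so the same rule applies to
participants with different limb lengths and speed ranges. Trials whose
window contains a single-frame position jump above 10 cm on any sensor are
excluded as sensor noise (`flag_noisy_trials`); this adapts a
participant-level 10 cm accuracy criterion to the trial level, since no
finer rule is available.

**Micro-movement spikes (MMS).** Every interior local maximum `p` of a
nonnegative waveform, flanked by valley values `m1`, `m2`, is standardized
to `p / (p + (m1 + m2)/2)`. The result is unitless and exactly invariant
under positive rescaling of the waveform — the allometric normalization
that lets effectors of different sizes be compared. Two properties of this
statistic matter for everything downstream:

* amplitudes always lie in (1/2, 1], because a maximum exceeds the mean of
  its flanking minima; distributions of MMS amplitudes therefore live in a
  narrow band and their *dispersion* is the informative quantity;
* the flanking valley on each side is the minimum of the waveform between
  the peak and its neighboring peak (or the series boundary), so the first
  and last peak of a window use the boundary stretch as their outer flank.

Plateaus collapse to their midpoint sample and extrema alternate by
construction; both choices make extraction deterministic and orientation
invariant. Peaks whose peak and flanks are all zero are dropped (0/0).

**Gamma noise-to-signal ratio.** Pooled MMS amplitudes per (sensor,
segment) — and per (sensor pair, segment) for the elementwise
absolute-difference waveform |α_i − α_j| — are fitted with a two-parameter
Gamma by maximum likelihood (shape from the standard log-mean equation by
root finding, scale as mean/shape). The noise-to-signal ratio (NSR) is the
fitted scale: a more dispersed amplitude distribution means noisier
fluctuations. 95% confidence intervals use the inverse observed Fisher
information with a normal approximation on the log-parameters, which keeps
them positive; the exact CI construction is a package choice since only the
confidence level is prescribed by the method. No location shift is used:
amplitudes are strictly positive and bounded. Fits require at least 100
pooled spikes (configurable); cells of several thousand pooled spikes are
the intended regime, which the generator reaches at full session length.

**Earth mover's distance.** Histograms use the Freedman–Diaconis rule
(bin width `2 IQR n^(-1/3)`), falling back to the square-root rule when the
IQR is zero. The EMD between two normalized 1-D histograms is computed as
the integral of the absolute CDF difference over the union of supports,
which equals the optimal-transport cost with ground distance
|center_i − center_j|; the generic linear-program formulation is kept in
the test suite as an independent oracle (a greedy sorted-transport solver,
exact for convex 1-D costs, plus `boot::simplex` where it converges). Each
histogram keeps its own Freedman–Diaconis edges — the fast path operates on
the union of the two supports, so shared binning is not required.

**Connectivity networks.** For each segment type, per-trial windows of
linear speed are cross-correlated pairwise. The coefficient at lag L is the
Pearson correlation over the overlapping stretch (means and variances
recomputed per lag). This choice matters: normalizing once globally and
scanning a biased estimator pulls the argmax toward zero lag whenever the
window contains baseline stretches, a bias we measured at 2–3 samples on
synthetic data; the overlap-Pearson form removed it. Lags are capped so at
least half the samples overlap. The edge weight is the per-pair median
across trials of the maximal |r| (ties broken toward the smallest |lag|,
then the positive one); lags are stored antisymmetrically. Weighted
clustering coefficients use geometric-mean triangle intensities on weights
normalized by the largest weight: t_i sums `(w_ij w_ih w_jh)^(1/3)` over
neighbor pairs and C_i divides by the `k_i (k_i − 1)/2` possible pairs.
The printed form of this statistic in the source literature omits the
pair-count factor; the implementation follows the cited algorithm's
standard form, verified against exhaustive triangle enumeration.

**Heart–body layer.** The ECG is band-passed 5–30 Hz with a 2nd-order
Butterworth, applied forward and backward. Zero-phase filtering is a
deliberate choice: a single pass would inject a frequency-dependent delay
that directly confounds lead/lag estimates. Kinematics are up-sampled from
240 to 256 Hz with componentwise cubic splines (quaternions renormalized)
only where the joint analysis needs a shared time base; segmentation runs
on the native 240 Hz series. For the temporal analysis each body part's
speed is cross-correlated per trial with the ECG amplitude envelope:
rectified voltage, a 0.25 s running median (wide enough to suppress a QRS
complex, narrow relative to a movement segment), then an 80 ms moving
average. Both stages are symmetric, so the envelope introduces no timing
shift; without the median stage the QRS train biases lag estimates toward
zero. Positive lag means the ECG leads the kinematics. For the spatial
analysis the EMD is computed between each body part's angular-acceleration
MMS histogram and the MMS histogram of the rectified filtered ECG
(rectification makes the waveform nonnegative, as spike standardization
requires). A `filter_ecg = FALSE` switch reruns the heart analyses on the
raw ECG.

**Aggregation and the consistency grid.** Per participant, medians are
formed per marginal cell — forward, backward (across sensors, pairs or
nodes), performing, non-performing (across the side's members, pooling
segments) — plus the full segment-by-side grid for the heart metrics, whose
contrasts are also evaluated conditionally within each segment and side.
Across participants each metric and contrast is reduced to a symbol: `o`
when the favored category is higher for every participant, a triangle when
higher for most (strictly more than half — the threshold is a package
choice), `-` otherwise. MMS pooling happens after per-segment, per-trial
extraction: spikes are found within each segment window and their
amplitudes pooled, never extracted across window boundaries. No
null-hypothesis significance testing is produced by default; the
per-participant median differences are the result. An optional exact sign
test (`sign_test_deltas`) is available but not part of any summary.

## What the synthetic generator emulates

A session is a deterministic function of its configuration
(`session_config`), including the seed; per-trial seeds are derived so each
trial fragment is independently reproducible.

**Reaches.** The end effector performs a minimum-jerk reach (bell-shaped
speed, monotone decreasing distance, near-zero speed at both ends) to a
per-trial target, then a minimum-jerk retraction. Both profiles carry
smooth multiplicative speed fluctuations (spline noise with 30 ms knots, in
the physiological tremor band); the backward fluctuation level is about
twice the forward one, encoding that spontaneous retractions are more
variable than deliberate reaches. Ground-truth segment boundaries are
recorded operationally, as the 5%-of-peak threshold crossings of the
generated speed — the same rule the segmenter applies — so recovery can be
scored frame by frame.

**Coupling.** Other sensors carry an attenuated copy of the end-effector
displacement, scaled by a per-segment coupling (stronger forward than
backward) and a per-side multiplier (performing > midline >
non-performing), plus independent smooth noise that grows as coupling
falls. Non-performing and midline sensors move with a small *anticipatory*
offset (their coupled motion precedes the end effector, as postural
adjustments do); this makes their kinematics lead the cardiac signal while
the performing side trails it, which is what produces the side cells of the
lead/lag pattern. The net displacement bookkeeping closes every trial
through a slow, edge-tapered drift that stays quasi-constant inside any
analysis window.

**Orientation dynamics and injected Gamma laws.** The angular-acceleration
magnitude of each sensor is built directly as a chain of isolated cosine
arcs on a per-sensor floor, separated by valley shelves carrying a shallow
triangular dip (so every flank has one clean minimum and numerical noise
cannot create spurious extrema). The analysis recovers this waveform
through two central-difference stages whose composition is a short linear
smoothing kernel; because the shelves are wider than the kernel's reach,
each recovered peak is an exact linear function of its own injected peak.
The generator measures that linear response once per configuration by
pushing a single isolated arc through the very operators the pipeline
applies, then inverts it, so the spike amplitudes recovered by the full
pipeline equal the drawn ones to numerical precision. Amplitudes are drawn
from the configured Gamma laws truncated to (0.505, 0.985) — the
representable band, since a standardized peak with equal flanks always
exceeds 1/2. The default laws place cell means between 0.56 and 0.70 with
side-dependent shapes, encoding NSR higher forward than backward and higher
on the performing side; for the lowest-mean cell the truncation clips about
2% of the left tail and deflates its variance by roughly 10%, which only
widens the injected ordering. Arc phases are randomized per sensor and the
per-sensor floors are spread widely on the performing side and narrowly on
the non-performing side, so pairwise-difference waveforms — each sensor's
peaks standing on the pair's floor gap — inherit a higher NSR among
performing pairs.

**ECG.** A template QRS train (Gaussian R bump, small S dip) runs at the
configured heart rate. Around every segment onset an in-band (18 Hz)
oscillatory burst is added whose amplitude profile is the same min-jerk
bell as the movement it is locked to, shifted by the configured per-segment
heart lead: positive lead places the burst before the movement, so the ECG
envelope precedes the kinematics. The defaults (+150 ms forward, −90 ms
backward) make the heart lead deliberate reaches and trail spontaneous
retractions; their asymmetry, combined with the anticipatory follower
offsets, keeps every marginal cell of the lead/lag grid sign-determinate.
No empirical effect size exists for such leads — motion-capture and ECG
devices are typically not clock-synchronized, which is also why absolute
lags must be read with care — so the magnitudes are package defaults, not
measured values. The ECG clock can be offset from
the kinematics clock by a configurable sub-second shift (bounded by 1 s);
the default is zero rather than a random draw, because the lead/lag summary
reads raw lag signs and a per-session random offset would render absolute
lags meaningless — exactly the caveat that motivates the bound. Setting
`clock_offset_s = "random"` restores the uniform draw on (−1, 1).

**What passing tests do and do not show.** The generator realizes exactly
the statistical structure the analysis assumes: synchronized trial
structure, Gamma-distributed spike amplitudes, linear coupling with fixed
delays, a movement-locked in-band cardiac modulation. Real recordings
violate all of these in degree — non-stationary coupling, heteroscedastic
sensor noise, heart-rate variability, electrode drift. Green tests
therefore certify that the pipeline measures what it claims to measure
when the signal is present, and that each operator matches its independent
oracle; they do not certify that human data carry the injected effects.

## Numerical choices and problem sizes

* Extrema: strict inequalities after plateau collapse; boundary samples are
  never extrema; Eq.-1 flanks may come from boundary stretches.
* Gamma fit: root finding on a bracketed interval expanded from Minka's
  closed-form start; degenerate (zero-dispersion) samples are an error.
* Cross-correlation ties: smallest |lag| wins, then the positive lag.
* Histogram fallback: square-root rule with a warning when the IQR is zero;
  a fully degenerate sample occupies a single narrow bin.
* Resampling spans the original time range without extrapolation; output
  length is `round(N * target/source)` within one sample.
* The test suite and the acceptance script use scaled-down cohorts chosen
  to keep every Gamma cell above its minimum spike count: 8 participants
  at 30 trials for the directional summary, 40 trials for segmentation
  scoring, 50 seeded 8-trial sessions for lead/lag recovery, and
  100–130-trial single sessions where pooled cells need 2500+ spikes.

## Known limitations

* The generator's coupling and leads are stationary within a session;
  condition-dependent (cognitive-load) contrasts are out of scope.
* Timing-based MMS (inter-spike intervals) are not implemented; only the
  amplitude variant feeds the analyses.
* The EMD fast path is 1-D by construction; multidimensional histograms
  would need the full transport formulation kept in the tests.
* Left-handed sessions mirror the layout and side assignment; no
  handedness-specific asymmetries beyond the mirror are modeled.
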