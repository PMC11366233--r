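---
title: "Estimating running ground reaction forces from wearable insole and IMU data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating running ground reaction forces from wearable insole and IMU data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grfest)
```

## The problem

Ground reaction forces (GRFs) are the backbone of running kinetics: peak
vertical force, loading patterns and braking/propulsion balance feed both
performance feedback and injury-risk modelling. They are normally measured
with an instrumented treadmill or force plates — lab equipment that cannot
follow a runner through everyday training. A consumer wearable stack (a
pressure insole with 16 force-sensitive resistors per foot plus a
shoe-mounted IMU) collects signals that are *related* to the GRF but are not
forces: FSR output saturates logarithmically, covers only part of the foot,
and the devices run on independent clocks. `grfest` implements a supervised
pipeline that learns the mapping from these wearable signals to the
treadmill-measured vertical (GRF~v~) and anteroposterior (GRF~ap~) force
waveforms of each foot contact, and quantifies how well it generalizes to
unseen runners.

Because no public dataset pairs these exact devices, the package ships a
synthetic-session generator with a fully known forward model. It is
first-class, tested code: every downstream stage is validated against the
generator's retained ground truth, and the headline evaluation asks whether
the estimator can recover the generator's input-output mapping from raw
simulated streams ("parameter recovery").

## The pipeline

### Synthetic sessions

`generate_cohort()` draws runner profiles from truncated normals — mass
$\mathcal{N}(66, 10^2)$ kg on [45, 100], easy running speed
$\mathcal{N}(11, 1.5^2)$ km/h on [7, 16], insole length
$\mathcal{N}(265, 15^2)$ mm — spanning a heterogeneous recreational cohort.
A latent footstrike scalar in [0, 1] is drawn as a tercile mixture
(rear/mid/fore probabilities 0.54/0.30/0.16, a rearfoot-dominant
distribution typical of distance runners); stride-time variability
(coefficient of variation) is truncated-normal around 0.03, the magnitude
seen in steady treadmill running.

For each stance phase the vertical force is an *active* component — a
half-period raised sine warped so its peak lands at 45% of stance, about
2.5 BW at easy speed and growing by 0.08 BW per km/h — plus an *impact
transient* at 15% of stance whose amplitude scales with $1 -$ footstrike
(an extreme forefoot striker produces none). The anteroposterior force is
$-\sin(2\pi \tilde t)$ braking-then-propulsion whose time-integral is zero
on the flat; incline adds a $\sin(\pi \tilde t)$ term (0.02 BW per %) that
shifts the balance toward propulsion uphill and braking downhill. Gaussian
noise of SD 0.05 BW is added during stance, and the force plate sees 2 N
flight noise so the 40 N contact threshold is meaningfully exercised.

The insole model spreads each force sample over a 4 × 4 sensor grid with a
Gaussian kernel (SD 30 mm) centred on a centroid that travels from a
footstrike-dependent touchdown position toward the forefoot; each sensor
reports $a \ln(1 + b F)$ — the saturating FSR response — and the true
centroid path is retained for testing. Pressure is logged the way the
hardware does it: 20 ms moving-average windows at 50 Hz, within stance
only, everything else discarded. The IMU vertical axis is
$F_v/(mg) - 1$ in g (free fall reads $-1$ g) plus a smooth low-frequency
segment-dynamics perturbation, resampled to 1,138 Hz and clipped at
±30 g. Each device starts recording at an independent random delay, so the
three streams disagree about which contact is their first — the clock
problem the synchronization stage must solve.

What the generator does *not* emulate: treadmill vibration and drift,
soft-tissue artefact spectra, FSR hysteresis and creep, within-session
fatigue drift, or bilateral asymmetry (left-foot data only). Passing tests
therefore demonstrate internal consistency of the pipeline and
recoverability of a known model at realistic noise levels — not
field accuracy on human data.

### Preprocessing

* **Filtering** — `butterworth_lowpass()` designs an order-4 Butterworth
  (via `signal::butter`) and applies it forward and backward, for zero
  phase lag and the squared magnitude response: at the cutoff the
  attenuation is exactly $1/\sqrt{2}^2 = 0.5$. Signals are extended by odd
  reflection (five cutoff periods) before filtering so short per-contact
  segments have no start-up transient. The continuous force stream is
  filtered at 15 Hz for event detection; segmented force traces at 15 Hz
  and accelerometer traces at 10 Hz; upsampled pressure is left
  unfiltered, since 20 ms averaging already band-limits it.
* **Contact detection** — maximal runs of filtered vertical force above
  40 N (strictly greater; ties toward the earlier sample). Intervals are
  half-open `[ic, to)` in 0-based indices. Runs shorter than 80 ms are
  treated as noise, and runs touching the first or last sample of a
  recording are partial contacts (the device powered on or off mid-stance)
  and are dropped.
* **Pressure reconstruction** — the stance-only 50 Hz log is upsampled
  back to 1,000 Hz with an interpolating quadratic (degree-2) B-spline;
  with fewer than three knots the function falls back to linear
  interpolation with a warning. Spline overshoot below zero is clamped
  before CoP computation.
* **Centre of pressure** — the pressure-weighted average of the sensor
  coordinates. A zero-pressure sample inside a contact carries the last
  valid CoP forward; before any valid sample the geometric centroid of
  the layout is used.
* **Time normalization** — every per-contact trace is linearly
  interpolated onto 400 points (no real contact exceeds ~361 ms at
  1,000 Hz, so 400 points lose no resolution); endpoints are preserved
  exactly. Ground contact time is recorded in seconds beforehand.

### Synchronization

The three devices share no clock, but they all observe the same stride
times — and stride-to-stride variability acts as a shared fingerprint.
`align_streams()` evaluates the Pearson correlation of two stride-time
vectors at every integer contact offset within ±20 (at least 10
overlapping stride pairs) and takes the maximizing lag, accepting the
alignment only if $r > 0.85$; ties break toward the smaller absolute lag
for reproducibility. `synchronize_session()` anchors both pairwise
alignments on the force stream and keeps only contacts visible on all
three devices. A rejected alignment flags the session unsynchronizable;
nothing is repaired silently. Because the pressure log is stance-only, a
burst truncated by power-on cannot be distinguished from a complete short
contact, so the first pressure burst of a session is always discarded
rather than risking a corrupted stride time.

### Features and leak-free standardization

`build_features()` stacks each contact into a `[N × 400 × 26]` array with
a fixed, documented channel order: 16 FSR channels, CoP~x~, CoP~y~, three
accelerometer axes (x mediolateral, y anteroposterior, z vertical), then
the five discrete descriptors (ground contact time, mass, speed, gradient,
insole length) duplicated along the time axis. `fit_standardizer()` pools
each channel over contacts and time to a mean and SD; validation data is
always transformed with training statistics only. A zero-variance channel
(e.g., gradient within a single stage) gets SD 1 with a warning, mapping
to zeros. Applying a standardizer twice is an error, guarded by a flag on
the array.

### The estimator

`build_model()` constructs a sequence-to-sequence regressor: input dropout,
a bi-directional LSTM whose per-timestep concatenated hidden state (size
$2H$) feeds three linear layers $2H \to L_2 \to L_3 \to 1$ with the
configured activation and dropout after the first two, applied at every
timestep. One independent model is trained per force component. Training
(`train_estimator()`) minimizes the batch RMSE
$\sqrt{\mathrm{mean}((\hat y - y)^2)}$ over all timesteps jointly with
Adam; batches are reshuffled each epoch and inverted-dropout masks redrawn,
all driven by the configuration seed, so training is exactly reproducible.
Inference disables dropout and is deterministic. The forward pass and full
backpropagation through time are implemented in compiled code
(RcppArmadillo), and the analytic gradients are verified against central
finite differences in the test suite at tolerance $10^{-4}$.

Design choices worth recording:

* **Targets are trained in bodyweight units** (force / mass·g). Errors are
  reported in BW, and removing the mass scale from the targets removes
  between-participant variance the network would otherwise spend capacity
  on. Newton-scale targets remain available via `build_targets()`.
* **Default hyperparameters** are the full-scale tuned selections for the
  vertical model (hidden 512, linear layers 64/32, learning rate 5e-4,
  batch 8, ReLU, dropout 0.2/0.2). All desk-scale work here uses reduced
  sizes (hidden 64) — the architecture is unchanged, only widths shrink.
* **Dropout placement**: on the input array, and after each of the first
  two linear activations — the two rates the configuration exposes.
* **Hyperparameter search** (`tune_hyperparameters()`) is random search
  over the documented space (learning rate log-uniform $10^{-5}$–$10^{-1}$,
  epochs 1–15, batch {8…128}, hidden {32…512}, dropouts 0.1–0.5, linear
  sizes {32…512}, four activations), scored by mean validation RMSE over
  subject-disjoint k-fold groups with per-fold standardization. The trial
  log is returned so the argmin is auditable. Sequential model-based
  search would need an optimizer the package deliberately does not depend
  on; at the trial counts used here random search explores the space
  adequately.

### Evaluation

`run_loso()` performs leave-one-subject-out validation: every fold fits
the standardizer and the model on all other participants and predicts the
held-out runner's contacts, so no information about the evaluated subject
— not even channel means — touches training. Per-contact metrics
(`contact_metrics()`): RMSE in BW; relative RMSE as a percentage of the
measured waveform's range; Pearson r; for the vertical component the
percentage differences in peak and in impulse (trapezoidal area of the
400-point BW trace); for the anteroposterior component signed differences
(estimated − measured) in peak braking and peak propulsion, in BW and N.
`bland_altman()` summarizes discrete-metric agreement as bias, ±1.96 SD
limits, and the slope of difference against measured magnitude — the
regression-toward-the-mean diagnostic. `pfi()` computes permutation
feature importance: a channel's values are replaced by standard-normal
draws (legitimate because inputs are z-scored) and the RMSE ratio to the
original is averaged over 100 repetitions; a provably ignored channel
yields exactly 1.0, and both mean and median aggregations are reported
since conventions differ. `cop_error_profile()` bins peak errors by the
touchdown CoP position to expose footstrike-dependent accuracy loss.

## Problem sizes and what the tests show

The package's own evaluation runs at desk scale, chosen once: protocol
stages of 30 s (the full-scale protocol uses 2–5 min stages; speed ratios
are preserved), a 10-participant cohort with ~200 contacts each for the
parameter-recovery check, a reduced hidden size of 64, two training
epochs, and 25-trial searches where tuning is exercised (the full-scale
budget was 250). Under those conditions the LOSO grand-mean vertical
rRMSE required by the acceptance suite is at most 10%; the pinned
configuration achieves roughly half that, with the familiar pattern that
the single extreme-rearfoot runner in the cohort is markedly harder to
estimate than everyone else — the same heterogeneity effect that motivates
subject-wise validation in the first place. Stride-time alignment on 100
synthetic two-device sessions at stride CV 0.03 recovers the true offset
with $r$ comfortably above the 0.85 acceptance bound in every session.

Numerical corner cases are pinned by tests: quadratic upsampling
reproduces quadratics exactly; time normalization preserves endpoints
bit-for-bit; the degenerate zero-width pressure kernel collapses to the
nearest sensor; a flat measured trace makes rRMSE undefined and errors
explicitly; alignment of zero-variance stride vectors returns an explicit
failure rather than NaN.

## Limitations

The estimator's accuracy statements are conditional on the synthetic
forward model; real FSR drift, treadmill vibration, or surface changes are
outside it. Only left-foot stance-phase waveforms are modelled, and only
the vertical and anteroposterior components — mediolateral force and
swing-phase dynamics are out of scope. Sample-level (sub-contact) clock
alignment and within-session drift correction are not attempted: the
alignment is exact at contact resolution only.
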