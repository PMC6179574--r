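---
title: "Methods: decoding working memory and its eye-movement confound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding working memory and its eye-movement confound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`oculomem` implements a complete in-silico version of an orientation
working-memory (VWM) / mental-rotation (MR) decoding study: a generator
that produces MEG-like and gaze epochs with a controllable eye-movement
confound, and the analysis chain that makes the confound visible — a
probabilistic classifier cross-validated within the task, a continuous
orientation decoder trained on an independent functional localizer, and
cluster-based permutation inference. This vignette documents the models,
the parameter choices, and the numerical decisions, in that order.

## 1. The simulated experiment

A task trial is: rotation cue (0.417 s) → blank (0.417 s) → grating
(0.217 s, orientation in {15°, 75°, 135°}, measured clockwise from
vertical, half-open range [0°, 180°)) → retention delay (8.017 s by
default) → jittered probe. The eight design cells (rotation {0°, 60°,
120°, 180°} × direction {CW, CCW}) are filled with `n_trials_per_cell = 3`
trials per block and `n_blocks = 6` blocks, i.e. 144 trials per subject;
orientations are balanced within every cell across blocks. Epoch time 0 is
grating onset; the cue sits at −0.834 s. The localizer presents six
orientations (15°–165° in 30° steps, 0.25 s each, 1 s trial spacing,
120 trials per orientation by default) while gaze stays at fixation.
Catch trials (early probes) are not generated: they are excluded from the
analyses this package reproduces.

### Signal model

For subject `s` with `n_sensors` sensors the generator draws two mixing
matrices:

* `A` (sensors × 2), orthonormal columns — the stand-in cortical
  orientation code. An orientation α produces the sensor pattern
  `A [cos 2α, sin 2α]'` (doubling makes the pattern 180°-periodic and
  gives patterns of orientations 90° apart opposite sign); the orthonormal
  columns make the pattern norm independent of α.
* `G` (sensors × 2), the eyeball-dipole coupling, with loadings decaying
  exponentially from the low ("frontal") sensor indices. By default `G` is
  orthogonalized against `span(A)`, so a decoder built on the neural
  subspace is *exactly* blind to the dipole and vice versa; setting
  `confound_overlap = TRUE` skips the orthogonalization for realism
  studies where the two topographies mix.

A task epoch is the sum of

1. a transient evoked response: `A`-pattern of the *presented* orientation
   times an alpha-function envelope `(t/τ)e^{1−t/τ}` with τ = 0.12 s (the
   latency of the early visual response; decayed by ~0.6 s);
2. optionally (`neural_sustained_gain > 0`) a sustained `A`-pattern of the
   *current mental* orientation, ramping in over 0.2–0.5 s and held
   through the delay — the "genuine memory code" world;
3. the dipole artifact `eye_dipole_gain · G · gaze(t)`, where `gaze(t)` is
   the *measured* gaze (drift plus measurement noise), so the artifact
   mirrors exactly what the eye tracker records;
4. spatially correlated Gaussian noise with covariance
   `σ² r^{|i−j|}` (`noise_sd = 0.3`, `noise_spatial_corr = 0.5`), white in
   time. Temporal whiteness is a deliberate simplification: it leaves every
   claim about *which* signals a decoder uses intact, but it makes
   effective trial-to-trial noise slightly more independent than real MEG.

The gaze trajectory implements the confound mechanism: fixation until
`drift_onset_s = 0.3` s, then a 0.2 s ramp to a point at distance
`gaze_amplitude_deg` along the current mental orientation axis
(α ↦ amplitude · (sin α, cos α); an orientation axis has two ends, and
each subject deterministically prefers one of them), tracking mental
rotation at `rotation_speed_deg_per_s = 30` but clipped at
`gaze_saturation_deg = 60` from the start orientation, held until probe.
The 0.3 s onset is a free parameter — the analyses only constrain the
drift to be established by ~0.5 s — and is documented as such rather than
claimed. Subject amplitudes are drawn log-normally (median 0.25°,
spanning roughly 0.05°–1.5° across subjects) to match the order of
magnitude of involuntary fixational drift reported for human observers;
a scalar `gaze_amplitude_deg` overrides the draw.

The defaults use 64 sensors at 120 Hz as a scaled stand-in for a
275-sensor, 1200 Hz acquisition. The generator does **not** attempt
biophysical head modeling, saccade main-sequence dynamics, pupil signals,
or real sensor geometry — which is why sensor-space cluster tests and
source localization are out of its scope.

### What passing tests do and do not show

Because the generator's neural and ocular subspaces are known (and by
default disjoint), the test suite can verify *identifiability*: that the
analysis chain attributes delay-period decoding to the dipole when only
the dipole carries it, and to the neural code when only the neural code
does. Passing these tests shows the machinery is correct and that the
confound mechanism is sufficient to produce sustained "memory" decoding;
it does not show that any particular real dataset is confounded — real
data have overlapping topographies, temporally structured noise, and
imperfect artifact removal.

## 2. Preprocessing

`baseline_correct()` subtracts the per-trial, per-feature mean over a
window (closed interval, `t0 ≤ t ≤ t1`); MEG epochs use −0.2–0 s relative
to stimulus onset, gaze epochs −0.2–0 s relative to *cue* onset (removing
slow eye-tracker drift). `smooth_moving_average()` applies a centered
100 ms boxcar; at the epoch edges the window truncates symmetrically
toward the boundary, which avoids both missing values and phase shift
(the edge rule is a package decision; nothing in the analyses depends on
it). Both operations are linear.

## 3. The probabilistic classifier

Class-conditional Gaussians with shared covariance, inverted by Bayes'
rule under a flat prior. The shared covariance is the *unweighted* mean of
the per-class sample covariances (denominator `n_k − 1`), then shrunk:

```
S = (1 − λ) S_raw + λ ν I,  ν = mean(diag(S_raw)).
```

The shrinkage target `ν I` (the standard single-parameter choice in
neuroimaging decoding) guarantees positive definiteness for any λ > 0.
λ = 0.05 is used for MEG features and 0.01 for the two-dimensional gaze
features. Posteriors are computed from the linear discriminants
`a_k = (S⁻¹m_k)'x − ½ m_k'S⁻¹m_k` with max-subtraction before
exponentiation (log-sum-exp stabilization), making them exactly invariant
to any constant added to all discriminants.

`crossval_temporal_generalization()` trains at every time point on trials
*pooled over all rotation conditions* — regardless of condition, the
subject must first perceive and encode the grating, so the presented
stimulus is decodable early in every trial — using stratified, seeded
8-fold cross-validation, and evaluates held-out posteriors at every time
point. Test trials are aggregated by rotation condition and by the
class's offset relative to the presented stimulus (0°, 60° or 120°,
signed by the cued rotation direction), so one pass supports every view
of the result: decoding of the presented stimulus per condition
(train-window cross-sections), decoding of the rotation target, and the
rise of intermediate orientations during mental rotation.
`spatial_pattern()` recovers what a decoder uses, as the difference
between each class's evoked field and the grand mean — on confound-only
data this pattern concentrates on the frontal-weighted dipole sensors.

When λ = 0, decoding is invariant to any shared invertible affine feature
transform (the discriminants whiten by `S⁻¹`); with λ > 0 the shrinkage
target breaks exact invariance — the identity matrix is not
basis-independent — which is the usual price of regularization.

## 4. The inverted encoding model

24 von Mises channels, concentration κ = 5, centered every 7.5° (equally
spaced once angles are doubled), peak-normalized:
`C[t, j] = exp(κ(cos(2φ_t − 2μ_j) − 1))`. All circular bookkeeping lives
in one utility pair (`orientation_to_doubled_rad()` /
`doubled_rad_to_orientation()`); the von Mises scaling is arbitrary for
the decoded angle (it cancels in the circular mean) but fixed for
reproducibility.

Inversion is the one step the underlying analysis tradition leaves
under-specified, so the package commits to a documented choice:

* **patterns** are estimated per channel, independently, by univariate
  least squares, `p_j = X'c_j / (c_j'c_j)`. With only six distinct
  localizer orientations a joint multivariate regression on all 24
  channels would be rank-deficient; independent estimation is exactly
  what makes "more channels than stimulus classes" possible. Its cost is
  a known blur: the estimated patterns equal the true ones convolved with
  a symmetric kernel on the doubled circle (the channel overlap), which
  spreads the reconstructed channel profile but leaves the circular-mean
  orientation estimate unbiased;
* **noise covariance** Σ comes from the residuals of the forward
  prediction, shrunk toward `ν I` exactly as in the classifier
  (λ = 0.05);
* **filters** are unit-gain and noise-suppressing:
  `w_j = Σ⁻¹p_j / (p_j'Σ⁻¹p_j)`, which reduces to pure pattern projection
  when Σ ∝ I and down-weights correlated noise directions otherwise.

Decoded channel activities collapse to
`θ = arg Σ_j c_j e^{i·2μ_j}` (mapped back to [0°, 180°)). A trial whose
resultant vector is numerically zero (relative modulus < 1e−12) has no
defined orientation; such trials are returned as `NA`, counted, reported,
and excluded from ρ — under continuous noise they occur with probability
zero.

The score `ρ = Re[(1/N) Σ_k e^{i(2θ_k − 2φ_k)}]` is the V-test statistic
with the prespecified direction "decoded = true". On doubled angles, a
systematic 90° orientation error is counterphase (ρ = −1) and a 45° error
is orthogonal (ρ = 0); the package adopts this doubled-space reading
because it is the only one under which ρ = Re(z) produces those values.
Since ρ is a mean over trials, condition-wise values pool exactly by
trial-count weighting.

`localizer_generalization()` fits the model at every localizer time point
and decodes every task trial at every task time point, giving a ρ surface
whose training-window cross-sections (0.09–0.12 s, the evoked-response
peak) are the confound-resistant readout of sensory content in the task.

## 5. Cluster-based permutation inference

Subject-level maps (1-D profiles or 2-D generalization surfaces) are
tested against a chance level: per point a two-tailed one-sample t test
(threshold p < 0.05), clusters by chain adjacency in 1-D and
4-connectivity in 2-D (the field's standard; the underlying tradition
does not specify connectivity), summed-t cluster masses, sign-flip null
(each subject's centered map flipped with probability ½, 10,000
permutations at full scale), and the add-one estimator
`p = (1 + #{perm mass ≥ observed}) / (1 + n_perm)` — so the smallest
reportable p is `1/(1 + n_perm)` and p = 0 never occurs. Positive and
negative clusters are compared against their own max-mass null
distributions, each at α = 0.05; the two one-sided families are *not*
jointly corrected (a documented choice), so "type-I error" statements in
the tests refer to one sign family. The permutation engine exploits the
sign-invariance of Σx² to compute all permutation t maps with one matrix
product, and cluster masks depend only on the observed data — changing
`n_perm` changes p resolution, never the clusters.

## 6. The staircase

Probe jitter starts at 15°; an error adds 1°, two consecutive correct
responses subtract 0.5488° and reset the streak counter (the counter also
resets on every error). "Decrease by 0.5488" is read as subtraction, not
as a multiplicative factor: the subtractive reading yields the documented
~80% equilibrium, a multiplicative one would not. At equilibrium the
up- and down-drift cancel, `1·(1 − p²) = 0.5488·p²`, giving
`p = √(1/1.5488) ≈ 0.8036` (the same equation follows from the exact
Markov chain on the streak counter). The jitter is floored at 0.1° so a
perfect observer cannot drive it negative. `simulate_observer()` runs the
rule against a cumulative-Gaussian observer
(`0.5 + (0.5 − lapse)·Φ((j − threshold)/slope)`, threshold 8°, slope 4°,
lapse 0.02 — guessing at zero jitter, near-ceiling at large jitter) and
reports percent correct over the second half of trials (burn-in = first
half). Matching any particular real observer's final jitter values is
explicitly not a goal; those depend on human psychometric functions.

## 7. The pipeline and reproducibility

`run_full()` chains the stages with one master seed from which every
stage derives child seeds by a fixed affine-mod-2³¹ scheme, so the entire
bundle — including the JSON summary — is byte-identical under a repeated
seed. The summary flags, per analysis, whether delay-period decoding in
the 0° condition is significant; the confound signature is "within-task
significant AND localizer-trained not significant". Every figure-like
result is also written as a TSV, so no number exists only as an image.

### Problem sizes used by the test suite

The package's own test and reference computations run at deliberately
scaled sizes, chosen once as representative rather than exhaustive:

* dissociation worlds: 8 subjects, 24 sensors, 40 Hz, 3 s delay, 72 task
  trials and 240 localizer trials per subject, 1,000 permutations;
* chance calibration: 20 simulated subjects of 144 trials × 10 features
  (3 classes, λ = 0.05) and 720 trials × 2 features (6 classes,
  λ = 0.01), all subjects drawn from a single RNG stream;
* cluster-test calibration: 500 null datasets of 12 subjects × 40 points
  at 500 permutations, scoring the positive-cluster family;
* staircase: 20,000 trials, asymptote over the final 10,000.

Full-scale parameters (64+ sensors, 120 Hz, 8 s delay, 10,000
permutations) remain the generator and pipeline defaults.

## 8. Known limitations

* Noise is temporally white and spatially stationary; real MEG noise has
  1/f structure and sensor-specific variances.
* The default orthogonality of neural and ocular subspaces makes the
  "localizer filters ignore the confound" property exact rather than
  approximate; real topographies overlap (use `confound_overlap = TRUE`
  to study that regime).
* Gaze is drift-plus-noise; saccade dynamics, microsaccade statistics and
  pupil effects are not modeled.
* The container format for epochs is an RDS array plus a TSV trial table —
  deliberately simple plumbing, not an interchange format; raw MEG
  readers (FIF/CTF) and BIDS layouts are out of scope.
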