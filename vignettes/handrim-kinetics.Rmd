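---
title: "Estimating handrim kinetics from wrist inertial sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating handrim kinetics from wrist inertial sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelkin)
```

## What the package computes

During straight-line manual wheelchair propulsion, the hand applies a
quasi-periodic force to the handrim: a *push phase* of a few hundred
milliseconds in which the propulsive sagittal moment Mz is active, followed
by a recovery phase with the hand off the rim. `wheelkin` estimates the
anteroposterior force Fx, vertical force Fy and sagittal moment Mz at the
handrim from the norms of the linear acceleration (m/s²) and angular
velocity (rad/s) of a wrist-worn IMU — the minimal sensor configuration
that survives outside the laboratory.

Two estimators are implemented. Both operate on dimensionless,
per-cycle RMS-normalized signals and are trained against reference
kinetics from an instrumented wheel; the trained model then runs on IMU
data alone (with the caveat on de-normalization discussed under
*Limitations*).

## Signal preparation

**Synchronization.** The instrumented wheel samples at 240 Hz and the IMU
at 120 Hz on independent clocks. Trials are book-ended by two handrim
kicks, visible as isolated transients in both the force and acceleration
streams. `detect_sync_events()` locates them on the absolute first
difference of each channel with a robust threshold (median + 6 MAD),
clusters super-threshold local maxima, refines each event to the channel's
amplitude peak, and keeps the first and last clusters at least 5 s apart.
Temporal order, not amplitude, decides which event is which.
`align_streams()` then downsamples the kinetics, shifts the axes so the
first events coincide, and removes residual clock drift with a linear
(two-point) time rescaling so the second events coincide too. A two-point
clock model is exact for a constant rate offset, which is the dominant
error mode of independent sampling clocks over a 40 s trial.

**Resampling.** Rational-ratio polyphase resampling (zero-stuffing,
windowed-sinc FIR kernel from `signal::fir1()`, decimation) with exact
group-delay compensation and odd-reflection edge padding; each polyphase
branch of the kernel is normalized to unit sum so constants pass through
bit-exactly. The anti-alias kernel is an intrinsic part of rational-ratio
resampling — decimating 240→120 Hz without one would alias the sharp force
transients — and no further smoothing is applied on top of it.

**Push-cycle segmentation.** The push phase is a maximal run of samples
with Mz above 10 % of the trial-level Mz RMS. The threshold is relative,
so segmentation is invariant to rescaling of the moment channel; a 50 ms
hysteresis merges sub-threshold dropouts and discards chatter. Each push
`[start, end)` receives an *extended window* adding 20 % of the push
duration on each side — about 140 % of the push in total — so the model
also sees the hand-approach and release transients. Cycles whose extended
window leaves the record (including the kick transients sitting at the
crop edges) are dropped.

**RMS normalization.** Every channel is divided, per cycle, by its root
mean square over the push phase, making the normalized push-phase RMS
exactly 1; the factor is stored and de-normalization is exact to machine
precision. A configuration flag (`window = "extended"`) computes the factor
over the 140 % window instead; the push-phase convention is the default
because the push phase is what defines the cycle. One consequence worth
stating: because the mean of a signal can never exceed its RMS over the
same window, the normalized push-phase *mean* is bounded above by 1 under
this convention — for a half-sine-like pulse it is about
2√2/π ≈ 0.90. Descriptions of the normalized moment "fluctuating around
2.5" match instead the normalized *amplitude* when the RMS is taken over
the full propulsion period (for a half-sine pulse of duty d, peak/RMS =
√(2/d) ≈ 2.4 at d = 0.35); with a per-push-phase RMS no waveform can
place the push-phase mean near 2.5, and the corresponding acceptance check
documents that distance rather than silently redefining the normalization.

**Generic pattern.** The per-subject average of the RMS-normalized,
time-rescaled (length L = 140, one point per percent of the cycle)
extended windows of the target channel. As the third input of the HW model
it acts as a modulator carrying the subject's typical waveform.
`pattern_as_input()` lays it back onto continuous time by rescaling it to
each cycle's extended duration; overlapping adjacent windows are averaged
(keeping the channel single-valued) and gaps take the mean of the
pattern's two boundary values. The placement rule is a package design
choice — any rule that reproduces the pattern inside each window would do,
and the round-trip property (pattern → channel → pattern) is tested.

## The Hammerstein–Wiener estimator

Each output channel and side gets its own MISO model:

$$y(t) = f_{\mathrm{out}}\!\left(\sum_{i=1}^{3} H_i(z)\, f_i(u_i(t))\right)$$

with inputs \(u_1 = \lVert a\rVert\), \(u_2 = \lVert\omega\rVert\),
\(u_3\) the generic pattern, all normalized.

**Nonlinear blocs** are continuous piecewise-linear maps with 4 nodes and
linear extrapolation. The breakpoints are fixed at the 10/37/63/90 %
quantiles of the corresponding training signal (output bloc: of the
target), leaving exactly 4 free ordinates per bloc — 16 nonlinear
parameters in the 4 blocs. Fixing breakpoints keeps the estimation problem
well-posed; roughly equidistant interior quantiles spread the nodes over
the data mass so no segment is starved.

**Linear blocs** are causal rational transfer functions in z⁻¹, stored as
factored real first/second-order sections (the conventional printed form of
identified models), with \(q < p\) zeros/poles per block and at most
6 poles; at full order the three blocks carry 3 × (6 + 5) = 33
parameters. Published example blocks contain roots exactly on the unit
circle, so construction tolerates \(|z| \le 1 + 10^{-6}\): marginally
stable integrators are legitimate over a 140 %-cycle simulation horizon.
During identification, poles are constrained to \(|z| \le 0.999\) —
fitting with free integrators destabilizes the error surface.
`lb_simplify()` removes exactly cancelling factor pairs before filtering.

**Identification** minimizes the mean squared one-pass simulation error
over the training cycles (each cycle simulated from zero initial state over
its extended window). The scheme:

1. nonlinearities start at identity;
2. each block's denominator comes from a per-block equation-error (ARX)
   least squares against the target — a one-shot least-squares fit of the
   full linear layer does not exist because the per-block denominators
   enter the output error nonlinearly;
3. all numerators are then fit jointly by least squares at those
   denominators;
4. the full parameter vector (filter coefficients + all 16 ordinates) is
   refined by Levenberg–Marquardt with an analytic Jacobian. Damping makes
   every accepted step decrease the training error (the monotonicity
   contract tested in the suite); after each step, poles outside the limit
   are projected radially back inside. Iteration stops after 50 steps or
   when the relative error improvement falls below 10⁻⁶.

Joint LM was chosen over alternating block refits: with the analytic
Jacobian it converges in a few dozen iterations and handles the
gain-exchange degeneracies between blocs (an HW model is only identifiable
up to exchanging gains between the nonlinear and linear stages, which is
why recovery experiments assert agreement of *predictions*, not
coefficients). The fit error is reported as NRMSE = RMS(error)/RMS(target)
with an absolute fallback when the target RMS is below 10⁻⁹.

**Order selection** enumerates all \((\sum_{p=1}^{6} p)^3 = 9261\)
combinations in deterministic lexicographic order, fits each on the
training cycles (by default the first 15; the remaining cycles are held
out), ranks by training NRMSE with ties broken by fewer parameters and
then spec order, keeps the best 111 and evaluates their held-out error.
Failed fits are recorded and skipped, never aborting the sweep. The
pipeline caches each completed spec on disk so an interrupted sweep
resumes for free.

## The BiLSTM estimator

A stacked bidirectional LSTM (default 3 layers × 400 hidden units per
direction) with a per-sample linear readout maps the two normalized IMU
channels to the normalized target sequence; it uses no generic pattern.
Training minimizes MSE with Adam (learning rate 10⁻³, batch 16 sequences,
300 epochs — optimizer settings are package choices, exposed in
`seqreg_config()`). Sequences are consumed per extended-cycle window,
which matches the HW framing and bounds memory. The train/validation split
(80/20) stratifies cycles by peak-amplitude quartile so both sets see the
same peak range. The implementation is plain R matrix code with
hand-derived backpropagation through time, validated in the test suite
against finite-difference gradients; everything is deterministic given the
seed, including the whole leave-one-subject-out loop.

Training curves (loss and RMSE per epoch for both sets) are returned so
"successful training" — finite, non-diverging validation loss — is a
testable property rather than a judgement call.

## The synthetic generator

No public propulsion dataset with paired wrist-IMU and handrim kinetics
exists, so the package ships a generator whose defaults encode the study
conditions it emulates: 34 cycles (range 30–38) at ~1 Hz cadence, push
duty 0.35, wrist acceleration norm with steady-region mean 7.89, SD 5.12
and max 52.13 m/s², angular velocity mean 2.98, SD 1.18, max 9.75 rad/s,
horizontal force peaks around 60 N, kinetics at 240 Hz and IMU at 120 Hz
with configurable clock offset/drift, and 3-sample kick transients at 8×
steady amplitude 2 s outside the first/last cycle.

Waveforms are raised half-sines with an asymmetric rise (rise fraction
0.4), lognormal per-cycle amplitude jitter (σ = 0.2, mean-corrected) and a
narrow hand-contact transient at each push onset. The smooth template is
calibrated *per realization*: an affine map sets the noise-free
steady-region mean and SD exactly to target, and the contact-spike height
is solved (monotone root-finding) so the noise-free maximum hits the max
target; without amplitude jitter the achievable peak-to-SD ratio is
bounded and the generator then keeps the closest achievable maximum. The
mz peak default (12 N·m) is a realistic propulsion torque for
self-selected-speed pushing given ~60 N tangential peak force on a
standard 0.25–0.27 m handrim; the moment channel is zero in recovery, as
the hand is off the rim.

What the generator does *not* emulate: 3-D vector kinematics, wheel
camber, curvilinear paths, soft-tissue artifacts, or inter-subject
waveform idiosyncrasies beyond amplitude/duration jitter. Tests passing on
synthetic data therefore demonstrate the *pipeline's* correctness and
recoverability properties, not field accuracy on human data.

`generate_from_hw()` produces recordings whose kinetics come from a known
HW model driven by the generated inputs — the recovery harness. The exact
normalized dataset used in the simulation travels in the ground truth, so
identification experiments can run free of resampling round-trip error.

## Evaluation

Reported RMSE and MAE are computed in physical units after de-normalizing
both measured and predicted signals by the *measured* cycle RMS. This
deserves a loud flag: deployment on IMU-only data has no measured RMS, so
field use requires an external de-normalization strategy (see
*Limitations*). Peak-level agreement uses Bland–Altman analysis (bias ±
1.96·SD of paired differences, sample SD) on per-subject means — one point
per subject and side — and a one-way ANOVA on the peaks
(`stats::oneway.test`, equal variances; for two groups F equals the
squared pooled t, a property the suite verifies against a hand-coded
sums-of-squares computation). MAE ≤ RMSE holds by Jensen's inequality and
is asserted globally.

## Numerical choices and degenerate inputs

* Problem sizes in the test suite are chosen for a laptop-class CPU:
  recovery experiments use 15 training cycles of ~150 samples at 2-pole
  orders (seconds per fit), the order-grid contract is exercised on the
  27-spec `max_poles = 2` grid, and BiLSTM checks use 1×8-unit networks —
  the full 3×400 configuration runs through the identical code path.
* Zero-RMS cycles raise a normalization error; an all-zero moment channel
  raises a segmentation error; a zero target is fitted to a near-zero
  simulation (absolute-error fallback in the NRMSE denominator).
* `resample()` falls back to linear interpolation below 4 samples, where no
  kernel fits.
* Ties in the grid ranking are broken by parameter count, then by the
  deterministic spec order, so parallel and serial sweeps agree exactly.
* All fits and the generator are bitwise-deterministic given their seeds.

## Known limitations

* **De-normalization in deployment.** Predictions are dimensionless; the
  measured per-cycle RMS used to restore physical units does not exist
  without an instrumented wheel. Estimating that scale from IMU features
  is open future work.
* **Generic pattern dependency.** The HW path needs the subject's average
  force/moment pattern, i.e. at least one instrumented session per
  subject; the BiLSTM path does not.
* The per-push-phase RMS convention bounds the normalized push-phase mean
  at 1 (see *RMS normalization*).
* Straight-line, zero-camber propulsion only; no shoulder inverse
  dynamics; one model per channel and side (no joint multi-output fit).
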