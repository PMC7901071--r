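---
title: "Classifying seabird movement modes from IMU data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying seabird movement modes from IMU data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soarhmm)
```

## The problem

Albatrosses and other procellariiform seabirds move through a small set of
kinematically distinct modes: powered **flapping flight** (a strong
dorso-ventral oscillation near the species-typical 2.5–2.7 Hz wingbeat),
**soaring flight** (almost no wingbeat energy, but slow periodic heading
arcs over tens of seconds as the bird extracts energy from the wind
gradient), and **on-water** drifting (heave pinned near 1 g, near-constant
heading). Back-mounted inertial measurement units — a tri-axial
accelerometer (g) plus a tri-axial magnetometer (µT) sampled at 25 Hz —
record these kinematics continuously for days. `soarhmm` is an end-to-end,
fully testable pipeline that turns such records into a decoded behavioral
time series and time-activity budgets using an unsupervised hidden Markov
model, together with a seeded synthetic-deployment generator that provides
ground truth for every stage.

## Frames and preprocessing

All processing uses a single frame convention: tag/bird axes
[forward (surge), right (sway), up (heave)], navigation axes
[north, east, up], heading measured clockwise from magnetic north in
[0, 360)°. The attitude is `R = Rz(psi) Ry(-pitch) Rx(roll)` (tag to nav; pitch
positive nose-up, roll positive raising the right axis),
so a resting tag reads static acceleration
`(sin pitch, sin roll cos pitch, cos roll cos pitch)` and pitch/roll are
recovered as `pitch = atan2(surge, sqrt(sway^2 + heave^2))`,
`roll = atan2(sway, heave)` — stable for the heave-dominant postures of a
resting or gliding bird. Two anchor identities pin the heading convention:
a level tag seeing the field `(Bh, 0, -Bv)` reads heading 0°, and rotating
the tag 90° clockwise about the vertical reads 90°.

The preprocessing chain is:

1. **Decimation** (75 → 25 Hz where needed): a symmetric FIR low-pass
   (window-design, cutoff at 0.9 × target Nyquist, order ≈ 34 per
   decimation factor) applied as a centered convolution with reflected
   ends, then integer downsampling. The symmetric kernel makes the filter
   exactly zero-phase, so flap onsets are not displaced across window
   boundaries; the passband (≤ 0.8 × target Nyquist) is preserved within
   2% and aliasable content is suppressed by more than 40 dB.
2. **Roll-offset correction**: tags mounted on feathers commonly sit with
   a constant roll tilt. Samples flagged as resting-on-water (smoothed
   ODBA below 0.15 g with static norm near 1 g) should average sway 0 and
   heave 1 g; the offset is `atan2(mean sway, mean heave)` over that mask,
   and the whole record (both sensors) is rotated back by it.
3. **Magnetometer cleaning**: a configurable start/end trim marks samples
   invalid (default 7200 s at the start of real deployments, where tag
   handling and field gear distort the field; synthetic deployments carry
   no handling period, so pipeline runs on generated data use 0), and a
   5-sample running median (0.2 s at 25 Hz) removes isolated spikes.
4. **Hard/soft-iron calibration**: an undistorted magnetometer in a
   constant field traces a sphere as the tag rotates; iron distortions
   shift (hard) and stretch (soft) it into an ellipsoid. We fit the
   10-parameter quadric by total least squares (smallest singular vector
   of the design), require a one-dimensional null space and positive
   shape eigenvalues (otherwise the orientation coverage is degenerate and
   the fit is refused), take the center as the hard-iron vector, and use
   the symmetric inverse square root of the shape matrix — scaled so
   corrected norms match the mean raw norm — as the correction. Physical
   soft-iron distortions are symmetric, so the symmetric square root
   recovers field directions, not just magnitudes; because the roll-offset
   rotation is applied to the magnetometer *before* calibration, the
   distortion seen by the fit is a conjugated (still symmetric) matrix and
   the correction remains exact.
5. **Tilt-compensated heading**: pitch and roll from the static
   (gravity) component de-rotate the calibrated magnetometer;
   heading is `atan2(-m_y, m_x)` of the leveled components. Samples with a
   zero-norm static vector are flagged invalid rather than fabricated.

On synthetic deployments the composed chain (calibration plus tilt
correction) recovers headings with a median error well under 1°; the error
is concentrated in banked soaring turns, where accelerometer-only attitude
estimation is physically degraded because the load-factor oscillation is
indistinguishable from gravity at the 2-s smoothing scale. With the
generator's true attitude substituted, the residual (calibration-only)
error is ~0.3° at every quantile.

## Movement features

Features are computed over fixed, non-overlapping 30-s windows (750
samples at 25 Hz) anchored at the record start; incomplete trailing
windows are dropped, and windows with more than 50% invalid samples are
emitted as missing. The static component of acceleration is a centered
running mean over 2 s (51 samples — rounded to odd for exact symmetry) and
the dynamic component is the remainder, so the split reconstructs the
total exactly. The eight candidate features: `df`/`hf` — dominant and
highest dominant frequency (Hz) of the mean-removed total-heave power
spectrum, where "dominant" means a local maximum with power at least 5% of
the spectral maximum (DC excluded; an effectively flat window returns the
0 Hz sentinel); `ms`, `ss`, `p5` — mean, SD, and 95th percentile
(linear-interpolation definition of the "top fifth percentile" boundary)
of static heave (g); `iqr` — interquartile range of dynamic heave (g);
`mo` — mean ODBA (g); `sh` — circular standard deviation of heading,
`sqrt(-2 ln Rbar)` in radians, floored at 1e-6 and capped at 4 so it stays
inside the Weibull support and finite. No taper is applied before the FFT:
30-s windows give 1/30 Hz bins, ample separation between the wingbeat
(~2.6 Hz) and swell (~0.1 Hz) tones, and a single-tone periodogram has no
sidelobe local maxima. A correlation screen (greedy elimination above
|r| = 0.7, dropping the member of the worst pair with the larger mean
absolute correlation; ties drop the later-listed feature; constant columns
drop first) supports reducing the eight candidates to a minimally
correlated working set; the default model uses `hf`, `p5`, `sh`, and the
accelerometer-only alternative uses `hf`, `p5`.

## The hidden Markov model

Windows are modeled by an N-state HMM (default N = 3) with conditionally
independent Weibull state distributions per feature — each state–feature
pair has one shape and one scale, both strictly positive — and a
multinomial-logit transition model: `gamma_ij = exp(eta_ij) / sum_j
exp(eta_ij)` with the diagonal as reference (`eta_ii = 0`). A categorical
covariate (species) acts additively on the off-diagonal logits, one
coefficient set per non-reference level, so each level has its own
row-stochastic matrix. Individuals are treated as independent realizations
of a common model with a shared initial distribution estimated as a free
parameter; fixing it to the stationary distribution instead was
considered and rejected because it couples the initial-distribution and
transition updates and breaks the closed-form M-steps, for negligible
benefit on chains hundreds of windows long.
The likelihood is the scaled forward recursion (implemented in C++), safe
for chains beyond 1e5 windows. Missing windows contribute emission factor
1 — parameters are informed by non-missing observations only while the
transition structure bridges the gap — and missing runs longer than 10
windows split the chain into separate segments. Features are floored at
1e-6 before fitting so they stay inside the Weibull support.

**Free parameters**: `2·N·F` emission parameters, `N(N-1)·L` transition
coefficients for `L` covariate levels, and `N-1` initial-distribution
parameters; AIC is `-2 loglik + 2 npar` with exactly this count.

**Estimation.** Each of 25 restarts draws random starting values — scale
anchors at the data quantiles `(s-1/2)/N` with a random state assignment
and ±30% log-jitter, shapes from a log-uniform coefficient-of-variation
envelope (CV 0.02–1.0), transitions near a diagonally dominant matrix —
and runs Baum–Welch EM: the E-step is a scaled forward–backward pass
(C++); the M-steps are closed-form for the initial distribution and for
each covariate level's transition matrix (the logit parameterization is
saturated per level, so normalized expected transition counts are exact),
and a safeguarded Newton iteration on the Weibull profile likelihood in
the shape for each state–feature pair. EM stops when the relative
log-likelihood change falls below 1e-8 or after 500 iterations. The
restart with the largest log-likelihood is then polished by a bounded
quasi-Newton pass (`L-BFGS-B`, objective tolerance ~2e-9, Nelder–Mead
fallback) on the unconstrained scale (log shape/scale, logit transitions,
additive-log-ratio initial distribution). EM-with-polish replaced a pure
multi-start quasi-Newton scheme during development: numerical gradients
on this likelihood were markedly slower per restart at the benchmark
size and converged to the global optimum from a much smaller fraction of
random starts, while monotone EM restarts are cheap and reliable. The
stability report counts restarts within 1e-3 log-likelihood units of the
winner. For nested transition-model comparisons, `fit_hmm(init = )`
additionally warm-starts the richer model from the simpler fit, the
standard guard against the richer model losing an AIC comparison through
a local optimum. Identical seeds reproduce the identical fit.

**Decoding and diagnostics.** The Viterbi algorithm (log space, C++) with
ties broken toward the lower state index returns the most probable path;
state labels are resolved by fitted feature means (largest mean `hf` →
flapping; of the rest, larger mean `sh` — or `p5` if `sh` was not
modeled — → soaring), with exact ties broken toward the lower index and
flagged. Forecast pseudo-residuals push each observation through its
model-implied conditional CDF given the past and the standard normal
quantile; under a correctly specified model they are standard normal,
which the test suite verifies by Kolmogorov–Smirnov calibration under the
truth and rejection under halved shapes.

## Evaluation

Validation sampling draws a fixed number of windows per bird (default 50)
without replacement, then removes windows flagged as colony-period,
reporting the count. Confusion matrices follow the convention rows =
model-assigned, columns = true, cells = column percentages, with counts
retained; overall accuracy carries an exact Clopper–Pearson 95% interval
(`binom.test`), so any small discrepancy with intervals computed by other
software is attributable to the interval method. Bouts are maximal runs of
equal decoded state (durations in minutes = windows × 30/60), and activity
budgets are per-state shares of (optionally at-sea-masked) windows,
summing to 100.

## The synthetic deployment generator

The generator is a stylized emulator, not a physical model: its purpose is
to give every pipeline stage data with the statistical structure the
analysis assumes, plus exact ground truth. State dwell structure is Markov
at the 30-s window scale — matching the HMM's time resolution, so truth
labels align one-to-one with observations — rendered at 25 Hz within
windows. The default per-species transition matrices are the two
literature-style 3-decimal matrices (rows renormalized to sum exactly to
one), giving a stationary mix of roughly 17% flapping, 42% soaring, and
40% on-water, and a realistic (small) species effect on transitions.

Default regimes, chosen once for realism and fixed: flapping heave
oscillation at N(2.6, 0.1²) Hz with amplitude 0.9 g (±15% per-window
log-jitter) and 0.05 g/axis noise; soaring heading arcs of 80° amplitude
and N(10, 1²) s period with banked turns (roll 40° following the arc
derivative, pitch 10° at twice the arc frequency), a 0.25 g load-factor
heave oscillation at twice the arc frequency, and 0.03 g noise; on-water
heave at 1 g with a 0.05 g swell tone at N(0.10, 0.02²) Hz and 0.02 g
noise. The swell default is 0.1 Hz — a 10-s open-ocean swell period —
which both is more realistic than wind-chop frequencies and preserves the
intended feature ordering (flap `hf` > soar `hf` ≥ water `hf`, since
soaring heave content sits at ~0.2 Hz, two load peaks per arc). Heading
wanders slowly within windows (2–5° scale random walk) and the per-bird
mean heading drifts 25° SD between windows, so on-water `sh` is small but
never degenerate. The magnetic field defaults to 45 µT at 60° downward
inclination; the magnetometer is distorted by a hard-iron offset
(10, −5, 3) µT, a symmetric soft-iron matrix diag(1.1, 1.0, 0.9), and
0.1 µT noise; the tag mount carries a 5° roll offset. All of this is
exercised (and undone) by the preprocessing chain in every end-to-end run.

What the generator does **not** emulate: hydro/aerodynamic realism,
sub-window behavioral mixtures (within-window purity is assumed; real
windows spanning transitions were labeled by the dominant behavior),
wave-field structure, GPS tracks, handling artifacts, sensor drift, or
non-Markovian dwell times. Passing end-to-end tests therefore demonstrates
that the pipeline machinery is correct and well-calibrated under its own
assumptions — decoded-versus-truth accuracy on synthetic deployments
(~100%) naturally exceeds expert-validation accuracy on field data
(~92%), where the truth itself is a visual classification and the states
are less cleanly separated.

## Problem sizes used by the checks

The end-to-end benchmark runs five seeded default deployments of 20
individuals × 500 windows (10,000 windows each, about 4.2 h of 25 Hz
signal per bird), fits with 25 restarts, and reports mean decoded accuracy
— sizes chosen to exercise multi-individual pooling and the covariate path
at a desk-scale runtime. Parameter recovery uses 5 × 2,000 windows;
exhaustive-path oracle equivalence uses 200 random instances with up to 6
windows; covariate discrimination uses 20 replicates of 4 birds × 250
windows with a deliberately strong transition contrast between levels.

## Known limitations

- Attitude from the accelerometer alone is biased inside banked,
  load-bearing turns; heading during soaring is correspondingly noisier
  than during level behaviors. The dispersion feature `sh` is robust to
  this, but fine-scale dynamic-soaring geometry should not be read from
  these headings.
- The ellipsoid calibration needs orientation diversity; it refuses
  near-coplanar coverage rather than returning an unstable fit.
- Model selection by AIC between transition-covariate variants is
  supported, but AIC on real data tends to favor more states than are
  interpretable; the intended use is the comparison of fixed 3-state
  variants.
- The magnetometer-free path (features `hf`, `p5`) is supported end to
  end, but state labeling then falls back to the `p5` ordering, which is
  the weaker separator.
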