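---
title: "Methods: simulating and measuring muscle co-contraction during pedaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring muscle co-contraction during pedaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedalcoi)
```

## The measurement problem

Co-contraction — simultaneous activation of an agonist and its antagonist —
wastes mechanical work and is a hallmark of unskilled movement. During
pedaling, the knee extensor vastus lateralis (VL) and knee flexor
semitendinosus (ST) form one such pair, and the hip flexor rectus femoris
(RF) and hip extensor biceps femoris (BF) another. This package implements a
complete, testable pipeline for quantifying co-contraction from surface EMG
(sEMG) recorded during cycling, together with a simulator of the auditory
biofeedback system whose effect on co-contraction such a study measures, and
the repeated-measures comparison across feedback conditions.

Because no raw recordings are publicly available for this design, the
package's first module is a synthetic-data generator with *known* ground
truth. Every downstream stage is validated against quantities the generator
can state analytically.

## The co-contraction index

Given two non-negative envelopes $E_1(k)$ and $E_2(k)$ on a shared cycle
base, the common-area co-contraction index is

$$\mathrm{COI} = \frac{2 \int \min(E_1, E_2)}{\int E_1 + \int E_2}
  \times 100\,\%$$

i.e. twice the area simultaneously under both envelopes, relative to the sum
of the individual areas (Winter's convention: "common area" is the integral
of the pointwise minimum). COI is 100% when the envelopes coincide and 0%
when their supports are disjoint; it is symmetric and invariant to scaling
both envelopes by the same factor.

**Integration rule.** Envelopes live on a half-open periodic 200-point cycle
base: point $k$ sits at cycle fraction $k/200$, and the wrap point at 100%
is the same crank position as 0% and is not duplicated. The trapezoidal rule
over the wrap-closed periodic domain therefore reduces to the plain sum of
the values, which is how areas are computed (`common_area`, `coi`). The
pointwise minimum is formed at grid points only; the minimum of two
piecewise-linear envelopes can in principle have extra knots where the
envelopes cross between grid points, but resolving those knots changes the
common area by a one-sided, second-order amount (quantified in the test
suite at below 2% on deliberately rough random envelopes, and far less on
smooth physiological envelopes). Ignoring sub-knots is the simplest
defensible reading and is the package's documented choice.

**Basis.** `coi_for_trial` computes the COI either from the two
ensemble-averaged waveforms (`basis = "ensemble"`, the default, matching how
cycle-normalized sEMG is usually presented) or per cycle with subsequent
averaging (`basis = "per_cycle_mean"`). Both are always present in the
output table; the statistics step consumes the configured basis.

## Offline envelope chain

The offline conditioning (`offline_envelope`) applies, in this exact order:

1. zero-phase 4th-order Butterworth **high-pass at 20 Hz** (motion-artifact
   removal),
2. mean subtraction,
3. full-wave rectification,
4. zero-phase 4th-order Butterworth **low-pass at 15 Hz**.

"Zero-phase 4th-order" is implemented as a 4th-order design run forward and
backward (doubling the magnitude order to 8, with no cutoff correction) —
the dominant convention in biomechanics when papers report a "zero-lag
fourth-order" filter. Edge handling: the signal is extended by odd
reflection over three filter lengths and each pass starts in the steady
state of its first sample (a constant input produces exactly its DC
response, so a pure offset leaves a residual below $10^{-6}$ of the offset).
Small negative excursions after the final low-pass are clipped to zero.

Cycle envelopes are cut at upper-dead-center boundaries and linearly
resampled onto the 200-point base (`cut_and_resample`); linear interpolation
is shape-preserving and keeps non-negative data non-negative. Each
participant-muscle is then normalized by its single peak across *all*
conditions (`normalize_to_peak`), making amplitudes comparable across
conditions while preserving within-participant effects; the divisor is
recorded as `normalization_peak`.

## Cycle segmentation

Crank angle is measured from pedal and crank-axis markers
(`compute_crank_angle`): the pedal-minus-axis vector is projected onto the
plane of maximal marker variance (the crank plane — the paper's lab axes are
not needed), the angle is measured from the projected vertical so that the
upper dead center is 0°, and the sign is chosen so the angle increases in
the direction of rotation. Cycles run from one upper dead center to the next
(`segment_cycles`): boundaries are upward crossings of multiples of 360° in
the unwrapped angle, located by linear interpolation between the bracketing
100 Hz frames (sub-frame precision matters because the sEMG runs at
1000 Hz). Partial leading/trailing cycles are discarded. A 1° tolerance at
the first and last frame prevents marker jitter from dropping a boundary
that falls exactly on the recording edge; retained cycles still span
360° ± 1°. Boundaries (mocap clock) are mapped onto envelope samples by
linear interpolation of the envelope, with constant extrapolation if the
final boundary falls within one frame past the last sEMG sample; the two
clocks are assumed synchronized at $t_0$.

## The synthetic study

`simulate_study` emulates the design under test: **13 participants × 4
feedback conditions (NFB, VLFB, STFB, VL-STFB) × 90 s at 80 rpm**, sEMG at
1000 Hz, markers at 100 Hz. At 80 rpm a 90 s trial contains exactly 120
cycles; marker trajectories are endpoint-inclusive with a 50 ms capture tail
so the final upper-dead-center crossing is always observed.

**Activation templates.** Each muscle's expected activation over the cycle
is a sum of periodic raised-cosine bursts (`build_template`), parameterized
to encode the qualitative activation phases of pedaling: VL bursts around
the top dead center (center 350°, width 90°); ST is active over the
downstroke and again late in the upstroke (centers 90° and 315°, widths
180° and 90°); RF is active except over roughly 90–180°; BF covers the
downstroke (center 90°, width 180°). Exact burst shapes are a free choice —
validated in the tests against those phase descriptions — because published
figures specify phases, not waveforms. (The literature describes knee
extensor activity "around the top dead center"; the VL default follows
that.)

**Raw sEMG surrogate.** A channel is amplitude-modulated, band-limited
(20–450 Hz) Gaussian noise:
$x_t = (\mathrm{floor} + g\,T(\theta_t))\, w_t$, with $w_t$ zero-mean
unit-variance and $g$ set so the envelope rises `snr`-fold above the resting
floor at the burst peak (defaults: floor 0.02 mV, snr 10). Rectifying and
smoothing such a signal recovers an envelope proportional to the modulation,
which makes the surrogate a valid end-to-end test bed; it does *not* model
motor-unit physiology, fatigue, or workload dynamics, so passing tests
demonstrate pipeline correctness, not physiological realism. Note the
resting floor forms a pedestal under both envelopes, so even muscles with
disjoint bursts have a designed COI well above zero — as real envelopes do.

**Ground truth.** For every trial the generator records the analytic COI of
the modelled envelopes (template plus pedestal, each normalized to its own
peak — mirroring the pipeline's per-muscle normalization) in
`ground_truth$designed_coi`. The pipeline must recover these within 3 points
at snr 10; residual bias comes from envelope ripple inflating the
cross-cycle normalization peak and from the 15 Hz low-pass slightly rounding
burst shoulders.

**Between-participant variability.** Burst centers (sd 8°), widths
(log-normal, sdlog 0.08) and amplitudes (log-normal, sdlog 0.15) are drawn
independently per muscle and per participant, shared across that
participant's conditions — a repeated-measures structure in which conditions
differ only through fresh noise and any designed effect. Draws must be
independent per muscle: a timing shift or gain applied to *all* muscles of a
participant cancels in the normalized COI and would make subjects
artificially identical. With these magnitudes the between-participant COI
spread is about 5 points.

**Condition effects.** `condition_overlap_shift` translates the ST burst
centers by a stated number of degrees in chosen conditions; over shifts of
0–30° the designed VL–ST template COI increases strictly, giving a
controlled alternative hypothesis. The default is a null design (all shifts
zero), matching the null result the statistics must be calibrated against.

**Seeding.** Every stream derives deterministically from `master_seed` via a
stable integer hash (`derive_seed(master_seed, participant, condition,
stream)`), all below $2^{31}$; identical configurations reproduce the study
bitwise, and simulation never perturbs the caller's RNG state.

## The auditory feedback simulation

The real-time path (`causal_envelope`) rectifies and smooths with a strictly
causal weighted moving average: a 100 ms trailing window with linearly
increasing weights (newest sample weighted most), normalized to sum to 1;
partial leading windows renormalize over the available samples. The window
and weight profile are configurable — published descriptions name the
smoother but not its parameters; 100 ms is a common low-latency sEMG choice.

Thresholds (`calibrate_threshold`) implement the rest-referenced 5% rule
using a rest recording and a calibration-pedaling recording. When
`run_pipeline` simulates the feedback stage for whole-study trials, no
separate rest recording exists per trial, so the resting level is proxied
by the mean of the lowest decile of that trial's own causal envelope (the
quiet phase of the cycle); `analysis/03_biofeedback.R` shows the explicit
two-recording calibration instead. The rule:
$\mathrm{thr} = \mathrm{rest} + 0.05(\max_\mathrm{pedaling} -
\mathrm{rest})$, reading "exceeding 5% of the maximum amplitude during
pedaling from the amplitude at rest" as using both named quantities. The
alternative reading ($0.05 \times \max$) is exposed as `rule = "absolute"`.
Beeps sound while the causal envelope exceeds the threshold
(`detect_beep_events`), at 400 Hz for VL and 800 Hz for ST; gaps and events
shorter than 50 ms are merged/dropped by default to suppress chatter near
the threshold. Overlap between the two muscles' beep trains — the quantity
dual-feedback riders are asked to minimize — is the length of the
intersection of the two interval unions, reported also as a fraction of the
smaller on-time (`overlap_metrics`). `render_audio` synthesizes the pure
tones with 10 ms raised-cosine ramps, peak-normalized to 0.9 full scale;
`write_wav` emits 16-bit PCM. Real-time behaviour is simulated
sample-synchronously at 1000 Hz with no latency model.

## Statistics

`rm_anova` implements the one-way repeated-measures ANOVA by explicit
sum-of-squares decomposition ($SS_\mathrm{total} = SS_\mathrm{subjects} +
SS_\mathrm{conditions} + SS_\mathrm{error}$), reporting $F$, the
sphericity-assumed $p$ (primary, matching a default JASP report), partial
$\eta^2 = SS_\mathrm{cond}/(SS_\mathrm{cond} + SS_\mathrm{err})$, and always
alongside, the Greenhouse–Geisser $\varepsilon$ with its corrected $p$. The
implementation is cross-checked in the tests against `aov()`'s
within-subject stratum and against the squared paired $t$ for $k = 2$; its
null rejection rate is Monte-Carlo calibrated at $\alpha = 0.05$.
Shapiro–Wilk screening wraps `stats::shapiro.test` with precondition checks.
No post-hoc tests are run: the design's omnibus question is the endpoint.

## Numerical choices and degenerate inputs

- Filters error below a stated minimum signal length rather than returning
  transient-dominated output.
- `coi` distinguishes an undefined COI (both envelopes identically zero,
  an error) from a valid 0 (disjoint supports); negative envelope values are
  rejected as unrectified input.
- `normalize_to_peak` errors on a dead channel (global peak 0).
- Coincident pedal/axis markers error with the offending frame; a
  non-rotating marker set errors before angle computation.
- `rm_anova` refuses incomplete tables (no imputation).

## Problem sizes

The test suite validates COI properties on thousands of random envelope
pairs, envelope fidelity over 20 seeded 15 s trials, and the full
13 × 4 × 90 s study once end to end; the ANOVA's null calibration uses 1000
exchangeable-normal replicate tables (13 × 4), a size at which the
Monte-Carlo binomial error comfortably brackets the nominal 5% level. The
acceptance script re-runs the full-scale study plus the calibration in a
couple of minutes on one CPU.

## Limitations

- The sEMG surrogate is statistical, not physiological; crosstalk,
  electrode lift, fatigue drift and workload changes are not modelled.
- Marker jitter is isotropic white noise (0.5 mm); real optical capture has
  correlated soft-tissue artifact.
- The feedback simulation is open-loop: simulated riders do not react to
  the beeps, so condition effects must be injected via
  `condition_overlap_shift` rather than emerging from behaviour.
- Clock synchronization between sEMG and motion capture is assumed perfect.
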