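---
title: "Models and methods behind mechanoephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mechanoephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanoephys)
```

mechanoephys analyses experiments in which an AFM probe mechanically
characterizes or stimulates a neuron while an HD-MEA records the
surrounding network and a camera follows a fluorescent calcium
indicator. This vignette explains the models each stage assumes, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
design was genuinely open.

## Contact mechanics

### Model

Soma stiffness is summarized as an apparent Young's modulus from the
Hertz model for a rigid sphere indenting an elastic half-space,

$$F(\delta) \;=\; \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

with bead radius $R$ (default 2.5 µm, a 5 µm bead), Poisson ratio $\nu$
(default 0.5, the incompressible-cell limit standard in AFM cell
mechanics; configurable and recorded in every result) and indentation
depth $\delta$. "Apparent" is deliberate: cells are viscoelastic, the
half-space assumption fails at depths comparable to cell thickness, and
the estimate depends on probing speed. Two guards keep the fit inside
the model's domain of validity:

- **approach-only fitting** — retract segments carry adhesion and
  relaxation history that the model does not describe;
- **depth cutoff** (default 750 nm) — samples deeper than the cutoff are
  discarded before fitting, so soft and stiff cells are compared over
  the same depth range.

With $R$ and $\nu$ fixed, $F = c\,\delta^{3/2}$ is linear in
$c \propto E$, so the least-squares problem has a closed-form solution
(a regression through the origin of $F$ on $\delta^{3/2}$); the
positivity constraint that a log-parameterization would enforce is
simply checked — a non-positive estimate marks the curve unusable
rather than being clipped.

### Contact-point detection and refinement

The contact point is first located by the classical threshold rule: the
approach force, baseline-subtracted, must exceed `threshold_multiple`
(default 5) times the baseline noise SD *and stay above it for the rest
of the approach*. The persistence requirement is a deterministic
replacement for manual curation: an isolated noise excursion that
returns to baseline never qualifies. The reported height is the
x-intercept at zero force of the line through the accepted sample and
the interpolated threshold crossing, and crossings in the last 5% of
the approach raise a review flag.

Threshold crossing alone, however, is systematically late on soft
samples: at 0.1 kPa with a 10 pN noise floor the force only reaches
5 SD ≈ 50 pN at roughly 300 nm of true indentation, and
back-extrapolating the local tangent still leaves a ~100 nm bias —
enough to corrupt the modulus by tens of percent. `fit_force_curve()`
therefore *refines* the contact point by minimizing the Hertz-fit mean
squared residual over candidate contact heights in a ±0.5 µm window
around the detected value (golden-section search). The detection result
seeds the search, its review flag is propagated, and the refined height
is reported with the fit. The mean squared (not summed) residual is the
objective so that candidate heights with different numbers of
in-cutoff samples are comparable.

The baseline window defaults to the first 30% of the approach segment;
the baseline SD is computed on the raw baseline by default, with an
optional linear detrend for drifting set-ups.

### Cycles and pressure

A stiffness measurement is the mean ± SD of the usable fits of one
cycle of repeated curves, requiring at least `min_curves = 3` (matching
the at-least-three convention for reported soma stiffness values; five
curves per cycle is the typical protocol).

`nominal_pressure()` converts a setpoint force to a pressure
$P = F/A$. The default area is the bead cross-section $\pi R^2$
(19.6 µm² for $R$ = 2.5 µm), which maps 200 nN to 10.2 kPa. Published
set-ups sometimes quote roughly half that pressure for the same force,
implying an effective contact area of ~40 µm² (bead plus the deformed
membrane annulus). Because the correct effective area depends on
geometry we cannot observe, both models are exposed, the model used is
recorded in every output, and nothing in the package silently converts
between them.

## Spike-train analytics

Rates are spike counts over window lengths. Binned rates use
left-closed right-open bins, so a spike exactly on an edge belongs to
the bin on its right and counts are conserved for every bin width.
Epoch analysis splits time into before / during / after windows around
a stimulus contact (defaults 150 s on either side of the contact
window, i.e. 2.5 min). Two mean-rate conventions exist — averaging
binned rates versus total count over total time; they coincide only
for full bin coverage. The package computes total-count rates by
default and exposes the binned series separately.

Unit curation follows standard spike-sorting quality metrics: the
ISI-violation ratio (fraction of inter-spike intervals below a
refractory period, default 2 ms — the threshold ratio 0.5 is the
conventional curation bound, the refractory window itself is
configurable) and the template SNR (trough magnitude over recording
noise SD, pass at ≥ 5).

### Network-burst detection

No standard burst-detection algorithm exists, so the package uses a
deterministic population-rate threshold detector: spike counts in
`bin` = 25 ms bins are converted to a per-unit population rate, bins at
or above `rate_threshold` = 3× a baseline level become candidates,
candidate runs shorter than `min_duration` = 50 ms are dropped, and
surviving runs separated by less than `merge_gap` = 100 ms are merged.
The baseline level is the **lower quartile of the nonzero bin rates**
rather than their median: for dense background activity the two are
identical (most nonzero bins hold a single spike), but when bursts
contribute a large share of the nonzero bins — sparse background, long
or frequent bursts — the median is dragged up to the in-burst level and
the detector would see nothing. The lower quartile stays at the
single-spike level in every regime we simulate. All four knobs are
exposed.

Burst/IBI labelling of stiffness-curve timestamps uses closed
intervals: a curve collected exactly at a burst boundary is a burst
curve.

### Evoked latency

The latency of a mechanically evoked spike is the time from contact to
the first spike strictly after contact within a 500 ms search window
(the timescale of a transient stimulus). When no spike falls in the
window the latency is reported missing, never imputed. The estimator is
exact when spontaneous activity is silenced (the condition under which
evoked latencies are measured experimentally, with glutamate-receptor
antagonists). Under substantial spontaneous background it is biased
early — the first spike is sometimes a background spike — and this
bias is inherent to any first-spike definition; at 2 Hz background and
~130 ms true latency the expected first-spike time is
$\mathbb{E}[\min(T_{bg}, L)] \approx 115$ ms. Analyses of evoked
latency should therefore be run on pharmacologically silenced or
very-low-rate recordings, which is how the package's own acceptance
checks configure the generator.

## Waveform features

Features are extracted from mean templates (per electrode, per epoch):

- **amplitude** — baseline-to-trough magnitude, with the baseline taken
  as the mean of the first 10% of samples. Trough magnitude (not
  peak-to-peak) is the default because published extracellular spike
  amplitudes of ~200 µV refer to the negative trough; peak-to-peak is
  available as an option.
- **halfwidth** — full width of the trough at half depth, with linear
  interpolation at the two crossings (first crossing on each side of
  the trough as the tie-break).
- **repolarization slope** — least-squares slope from the trough to the
  first baseline re-crossing; a maximum-post-trough-derivative variant
  is available behind a flag, since the feature's operational
  definition is not standardized.

Epoch comparisons divide the during-compression feature by the
before-compression feature per electrode, and
`amplitude_change_vs_distance()` tabulates these ratios against the
Euclidean distance of each electrode from the target electrode (the one
under the compression site). Distance separates contact artefacts —
the target electrode's amplitude rises trivially because compression
improves the membrane–electrode seal — from genuine excitability
changes visible ~50 µm away.

## Calcium analysis

ΔI/I is $(I - I_0)/I_0$ with $I_0$ the pre-stimulus mean by default (a
low-percentile option, the 8th percentile, is provided for traces whose
"baseline" window contains activity). Peaks are strict maxima within a
±1.5 s half-window (the 3 s window is interpreted as centred; edge
frames use the truncated window; plateau ties are not peaks, which
makes the detector deterministic). Response onset is the latest
pre-peak up-crossing of 10% of peak amplitude that stays above
threshold until the peak, linearly interpolated between frames — the
*latest sustained* crossing rather than the first-ever crossing, so
baseline noise cannot pull the onset early. Aligned response windows
span 2.5 s before to 10 s after onset with time re-zeroed at onset.

Decay constants are fit as a single exponential
$A\,e^{-(t-t_{peak})/\tau}$ on ΔI/I from the peak down to 10% of peak,
by nonlinear least squares seeded with the log-linear slope (the
log-linear start is near-exact on clean data; the nonlinear step
removes the log-transform's noise bias). Non-decaying or non-positive
tails yield a missing τ with a warning. A single exponential on ΔI/I is
the default because slow indicators (GCaMP6s-class, τ on the order of
tens of seconds) are well described by one dominant time constant at
these frame rates; bi-exponential fits are out of scope.

Responder classification — needed to compare response fractions across
stimulation speeds — calls a neuron a responder iff a detected peak
within 10 s after contact exceeds `k` = 5 pre-stimulus noise SDs. All
criteria are recorded in the output. A flat noiseless trace is a
non-responder by construction (no strict maximum, threshold not
exceeded).

Soma morphometry measures the largest directional diameter change
between polygonal outlines: both outlines are translated to their area
centroids, the projection width is computed for 180 directions sampled
uniformly over $[0, \pi)$, and the change is the maximum over
directions of (during − before). Projection widths make the measure
vertex-count independent and rotation-insensitive up to the 1°
angular resolution, matching the "most-changed diagonal" reading of a
fitted polygon in the dense-sampling limit.

## Clock synchronization

The HD-MEA acquisition (20 kHz) is the master clock; AFM and camera
events arrive both on their own clocks and, via TTL pulses, as
master-clock timestamps. `build_sync_map()` pairs the two event lists
greedily in time order within a pairing tolerance (default 1 s; sync
markers must be spaced more than twice the worst-case offset apart for
greedy pairing to be unambiguous) and estimates the affine map
$t_{master} = a\,t_{stream} + b$ by least squares, warning when the
drift leaves [0.99, 1.01]. Unpaired events are counted, never silently
dropped. Mapping is exactly invertible, and noiseless event pairs
recover injected offset and drift to numerical precision.

## Statistics

Paired comparisons use the Wilcoxon signed-rank test, two-sided, with
zero differences dropped and reported. For up to 25 non-zero pairs the
p-value is exact, computed by convolving the distribution of the
positive-rank sum over all $2^n$ sign assignments *with tied (average)
ranks doubled to integers* — classical exact tables assume no ties, but
tied differences are routine in count-derived rates. Independent groups
use the Mann–Whitney U test, exact by enumeration of all
$\binom{m+n}{m}$ rank assignments for pooled sizes up to 12. Both
two-sided p-values are defined symmetrically,
$P(|T - \mathbb{E}T| \ge |t_{obs} - \mathbb{E}T|)$, which reduces to
the usual doubled tail for symmetric distributions. Above the exact
limits, normal approximations with tie corrections take over (no
continuity correction, matching the tie-corrected normal theory).
Pearson correlations and χ² proportion tests delegate to the standard
implementations. Following the reporting convention of the experiments
this package serves, p > 0.05 is treated as non-significant and no
multiple-testing correction is applied — the results report states
this.

## The synthetic-data generator

The generator exists so that every analysis stage can be verified by
parameter recovery without access to raw recordings. Design choices:

- **Force curves** solve the implicit cantilever–sample balance
  $k d = \tfrac{4}{3}\tfrac{E}{1-\nu^2}\sqrt{R}\,((z - z_0) - d)^{3/2}$
  per piezo height by Newton iteration (the balance is increasing and
  concave in $d$, so iteration from 0 converges monotonically; relative
  tolerance 1e-12, hard error on non-convergence). This makes synthetic
  deflections physically consistent with what the fitter assumes, and
  the forward force at any depth is checkable against the closed form.
  The out-of-contact baseline equals the in-contact span, so a fixed
  baseline *fraction* of the approach is valid at any stiffness.
  Gaussian force noise (default 10 pN) and optional linear drift are
  added last.
- **Spike populations** share a two-state Markov burst schedule
  (exponential sojourns; defaults: mean IBI 20 s, mean burst 2 s,
  2 Hz base and 50 Hz in-burst per-unit rates — free parameters chosen
  as typical of mature dissociated cortical cultures, since no
  quantitative burst statistics were available to copy). Each unit is
  an inhomogeneous Poisson process on this shared schedule, which
  produces network-synchronous bursts by construction. Stimuli can
  multiply the during-contact rate and/or inject one evoked spike per
  unit at contact plus a truncated-normal latency.
- **Footprints** place a stereotyped biphasic template (negative
  Gaussian trough, σ = 0.14 ms, so FWHM ≈ 0.33 ms; delayed positive
  rebound at 25% amplitude) on the 17.5 µm electrode pitch grid, scaled
  by $e^{-d/\lambda}$ with λ = 30 µm. The two lobes are separated
  widely enough that trough depth and FWHM are analytically known,
  which is what the feature-extraction tests check against. The
  during-compression epoch multiplies all templates by `during_scale`
  (default 1.13).
- **Calcium traces** convolve spikes with a causal kernel (0.2 s linear
  rise, exponential decay with τ = 26.2 s by default, amplitude 0.5
  ΔI/I) sampled at 45 fps. With the default 10% onset fraction, the
  measured onset sits 0.1 × rise = 20 ms after the spike — within one
  frame at 45 fps, which is why onset recovery is specified to
  one-frame accuracy.
- **Clocks**: stream time = drift × master time + offset per stream;
  TTL sync markers are emitted every 10 s on each stream together with
  their master-clock (FPGA-style) timestamps.
- **RNG**: one substream per artefact, keyed off the master seed, so
  adding an artefact never perturbs the others; identical configs
  reproduce byte-identical bundles and reports.

What the generator does **not** emulate — and hence what green tests do
not demonstrate about real data: raw 20 kHz voltage with spike
collisions and sorting errors (templates and sorted times are taken as
given); viscoelastic or depth-dependent mechanics (the synthetic cell
is exactly Hertzian, so recovery tests measure estimator correctness,
not model adequacy); pixel-level imaging (mean-intensity traces and
outlines are the inputs); electrode-contact artefacts at the target
electrode (the injected fold-change is spatially uniform).

## Problem sizes and tolerances in the tests

The test suite simulates at desk scale, chosen to make sampling error
comfortably smaller than the tolerances asserted: 100 force curves per
stiffness decade (0.1/1/10 kPa) at 50 kHz AFM sampling for modulus
recovery (< 5% median error with 10 pN noise, < 0.1% noiseless); 20
units × 400 s for the 25% rate-change recovery (±5 percentage points);
500 spikes per epoch at 5 µV template noise for the 1.13 amplitude
fold-change (±0.02); 200 stimuli for latency recovery (2 standard
errors of the injected 50 ms spread); 100 replicates for τ recovery at
5%-of-peak noise (±2%); 2000 null simulations for the signed-rank
type-I check (≤ 0.06 at nominal 0.05). End-to-end determinism is
asserted at the byte level on the written report.

## Known limitations

- The Hertz stage reports an *apparent* modulus at one speed; no
  microrheology (frequency-dependent moduli) is attempted.
- Contact-point refinement assumes the Hertz form; on strongly
  non-Hertzian curves it will converge to the best Hertzian
  explanation and the residual RMS is the only warning.
- The burst detector is threshold-based; populations whose "baseline"
  bins are mostly multi-spike would need a rescaled threshold.
- First-spike latency is biased early under spontaneous background (see
  above); silence the background or treat the estimate as a lower
  bound.
- Greedy TTL pairing assumes sync markers sparser than twice the
  worst-case clock offset.
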