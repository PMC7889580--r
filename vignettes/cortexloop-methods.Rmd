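---
title: "Models and methods behind cortexloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cortexloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexloop)
```

# The closed loop

cortexloop simulates and analyses an areal-activity brain–machine
interface: the dF/F of two small cortical control regions, sampled at
40 Hz, is transmuted online into one of eight discrete cursor positions,

$$p(t) = A_1 F_{R1}(t) - A_2 F_{R2}(t) + B,$$

rounded to the nearest integer and clipped to $[1, 8]$; position 8 is the
rewarded target. The subject (here, a synthetic agent) closes the loop:
whatever activity pattern moves the cursor to the target and holds it for
300 ms earns a reward.

This vignette documents the modelling choices, the parameters that
matter, and what the synthetic data can and cannot establish.

## The decoder

**dF/F.** The running baseline $F_0(t)$ is the 10th percentile of the raw
fluorescence in the preceding 20 s, and $\mathrm{dF/F} = (F - F_0)/F_0$.
Frames with less than a full window of history use all preceding frames,
floored at 1 s, so the earliest frames share the initial window. A
non-positive baseline aborts with an error: it signals raw input that is
not physical fluorescence. The 20 s window is a parameter (`window_s`)
because a longer, minutes-scale baseline is an equally defensible
convention for online use; both readings are reproducible with one
argument.

**Calibration.** Each coefficient is the region's baseline dynamic range
divided by half the number of cursor positions, $A = (\max F - \min F)/4$,
computed on dF/F. The offset $B$ is defined here as
`start_position - median(A1*F_R1 - A2*F_R2)` over the calibration
baseline, with a default resting position of 3: the baseline median then
decodes to the resting position, and the single knob `start_position`
controls how difficult the target is to reach. The baseline mean and SD
of the differential are stored with the decoder for the engine's
return-to-baseline rule. A calibration baseline must span at least 10
minutes (configurable floor), and a zero dynamic range in either region
is an error.

**Rounding and range.** "Nearest integer" is implemented half-up
(`floor(p + 0.5)`), and out-of-range values clip to $[1, 8]$. Both rules
are stated once and tested against a brute-force oracle, because cursor
discretization is load-bearing for every downstream analysis.

**Auditory mode.** The pitch transform
$f(t) = A_1 e^{F_{R1}} - A_2 e^{F_{R2}} + B$ is floored at a configurable
minimum audible frequency (default 1 kHz) and binned in quarter-octave
steps (`bin_ratio = 2^(1/4)`) around a 5 kHz reference; reference and
floor are configuration because no canonical values exist for them.

**Chance rate.** Chance performance is not a formula but a replay: the
spontaneous baseline is run through the decoder *and* the full trial
engine (30 s trials, hold detection, timeouts), and hits are counted per
minute of baseline. This makes the chance estimate sensitive to the same
trial structure as the behavioral measurements.

## The trial engine

Defaults: 300 ms hold (12 frames at 40 Hz, by rounding), 30 s trial
limit, 1 s reward delay, 10 s miss timeout, and an inter-trial wait of at
most 5 s until the differential activation returns within 0.5 spontaneous
SDs of the spontaneous mean. The 0.5 SD tolerance is our choice: the
protocol only requires a "return to the mean", and at this tolerance the
expert-agent simulations trigger the cap rarely, matching the intended
rarity of the condition. The 30 s trial clock does not pause during the
hold. The cursor is marked absent between trials, so the trial log and
the cursor stream are mutually redundant records — a consistency the
tests exploit.

Control conditions: `random_reward` keeps the cursor activity-driven but
draws rewards from an independent Poisson schedule (default 1.5/min,
matched to expert performance) and leaves target hits unrewarded;
`random_feedback` displays a per-frame Gaussian cursor moment-matched to
a reference session and binned by the same round-and-clip rule, while hit
detection continues on the true decoded activity; `playback` replays a
reference session's cursor and trial timing with no decoding.
Moment-matching is applied to the Gaussian before binning; rounding and
clipping distort the displayed moments by an amount that shrinks with the
reference SD and is ~1% in the regimes we test.

The ghost-decoder evaluation replays one stretch of activity through two
decoders' hold detection (no trial structure) and reports hits/min in
sliding windows. A control-region swap is expressed with
`swap_regions_new = TRUE`: both decoders see identical cortical activity
but assign the control roles oppositely, which is how a mid-session swap
works in the rig.

## Signal metrics

Spectral entropy uses the raw periodogram (no taper) of each 10 s window,
stepped by 5 s, normalized to sum 1 over $[0, f_s/2]$ with the DC bin
included, and $SE = -\sum \mathrm{PSD}_n \log_2 \mathrm{PSD}_n$ in bits
with $0 \log 0 = 0$. The estimator choice matters: a raw periodogram's
bin noise keeps white-noise entropy ~8% below the $\log_2 N_f$ ceiling,
which is why the tests assert "within 10% of the maximum" rather than
equality, and why a Welch variant (4 half-overlapping Hann segments) is
available behind a flag for smoother spectra. An all-zero window is
defined to have zero entropy and raises a warning. Entropy is reported
unnormalized by default; `normalized = TRUE` divides by $\log_2 N_f$ for
cross-window comparability.

Hit-rate curves tile the session with non-overlapping windows by default
so that rate times duration sums exactly to the hit count. Time to
criterion is the first time a 10-trial moving average of the hit
indicator reaches 0.5. Variance around hits is the across-hit variance
at each lag; hits too close to the record edge are dropped with a
message.

## Maps

The activation map is, per pixel, (mean over task frames − mean over
non-task frames) / SD over non-task frames. "Normalized" is not defined
canonically for such maps, so the off-period z-score is the default and a
plain mean difference is available via `normalize = "none"` (which is
exactly antisymmetric under swapping the masks). Pixels with zero
off-period SD are flagged `NA`. Seed and affiliation maps are plain
Pearson correlations of each pixel with the seed-mean trace or the
frame-binned spike train; constant pixels and silent units are flagged
rather than silently zeroed. Region masks live in movie pixel
coordinates; no atlas registration is attempted. An optional balancer
subsamples the larger of two frame masks with a seed, for early/late
comparisons with comparable frame counts.

## Single units and the classifier

Units split into fast-spiking (width < 0.66 ms) and regular-spiking;
a width exactly at the cutoff goes to the broad class. A cursor onset is
any frame where the displayed position changes or the cursor appears.
Tuning is the mean per-event rate in the 80–200 ms post-onset window;
rates are averaged across events (not pooled counts) so positions with
unequal event counts are comparable, and onsets closer together than the
window are both counted — with 250 ms dwells, the default in our
simulations, windows never overlap. Sweep direction is the direction of
the most recent transition (toward the target if it reduced the distance
to it) and persists over the dwell; appearances carry no direction.

The population classifier bins spikes in 50 ms bins over a configurable
$[-250, +500]$ ms event window (pre-onset bins included so
before-presentation decoding is computable), partitions events into 40
contiguous segments by event order, and per repeat holds one segment out,
z-scores each unit with training-fold statistics only (zero-SD units are
dropped for that repeat), forms class-mean vectors per time bin, and
predicts each test event by maximum Pearson correlation to the class
means. Ties and undefined correlations fall to the lowest class index
and are counted. Shuffling permutes training labels each repeat. The
time-blocked split was chosen over interleaving because adjacent events
share slow state; holding out a contiguous block is the stricter test.
Pooling events and bins for the z-score (rather than per-bin statistics)
treats the unit's overall rate scale as the nuisance being removed.

A structural consequence worth knowing: because Pearson correlation is
invariant to scaling a population vector, a gain that multiplies all
units alike is nearly invisible to this classifier. In the synthetic
populations the uniform sweep gain therefore leaves direction decoding
near its 50% chance level even though the underlying rate effect is real
and recovered by the sweep-conditioned tuning analysis — while
heterogeneous position tuning *does* carry a decodable pattern. The test
suite asserts exactly this dissociation.

## The synthetic generator

The generator defines the study conditions; its defaults are fixed once
and the tests run against them.

**Region traces.** Each region is a unit-variance Ornstein–Uhlenbeck
latent (autocorrelation time `ou_tau` = 1 s) convolved with a
single-exponential calcium-indicator kernel (`calcium_tau` = 1.5 s,
GCaMP6s-scale), scaled to a stationary SD of `amp_sd` dF/F units, plus
white observation noise (`noise_sd` = 0.05). Pairwise correlation is
imposed by a shared latent whose mixing weight is solved in closed form,
inflated so the *observed* (noise-included) correlation hits the target;
an unattainable combination errors out. The spontaneous default
`pair_correlation = 0.7` reflects strongly coupled neighboring regions.

**Amplitude calibration.** Taking the decoder equations literally, the
coefficient $A$ has units of position per dF/F and equals range/4, so the
decoded excursion of spontaneous activity scales with the *square* of the
trace range. Spontaneous replay can only reach the target at all if the
traces span several dF/F units. `amp_sd` = 1.23 is therefore a
calibrated constant, fixed once so that replaying the 20-min spontaneous
default through range/4 calibration and the trial engine yields a chance
rate near 0.3 hits/min, and not revisited. These are synthetic units; no
claim is made that real widefield dF/F has this scale.

**The agent.** Learning is a convex policy blend: the emission policy
starts at zero (naive) or at the exploit pattern (expert), and each
internally rewarded trial moves it toward the exploit pattern by
`learning_rate` (default 0.25). Exploration adds, per region, random
half-cosine bursts (rate 0.4/s, amplitude SD 1.5 dF/F) plus broadband
white noise (SD 0.4 dF/F), all scaled by the remaining exploration level;
pattern emissions replace the background during their window and carry
per-frame jitter (SD 0.1). A trial is internally rewarded when its peak
R1−R2 differential exceeds 65% of the exploit pattern's peak — a
threshold at which a substantial minority of pure-exploration trials
succeed, so naive sessions transition from exploration to exploitation
within a few dozen trials rather than instantly or never. The exploit
pattern is a 2 s Hann bump, +2.5 `amp_sd` in R1 and the negative in R2,
which reliably decodes to the target under default calibration. The
broadband exploration noise is what gives the exploration phase its high
spectral entropy; the stereotyped emissions are what collapse
hit-aligned variance late in a session.

**Spiking.** Units are inhomogeneous Poisson processes with rate
`baseline * position_gain[pos] * sweep_gain * task_boost` (boost only in
the task condition). Heterogeneity enters as a per-unit tuning exponent,
`position_gain^e_u` with $e_u \sim N(1, 0.5)$: units share the
toward-target tuning shape with varying steepness (occasionally
inverted), so the population has distinct per-position patterns while the
population-mean tuning follows the configured gains. Widths are drawn
per class (RS 0.95 ± 0.15 ms, FS 0.45 ± 0.08 ms, 20% FS). Expected
counts are exactly rate × duration, and per-frame counts pass a
dispersion test — properties the suite checks.

**What the generator does not emulate.** No biophysical neurons, no
hemodynamic artifacts, no vessel or skull optics, no pupil/locomotion
coupling into the neural signal, no full-resolution movies, and no
across-animal variability. Passing tests therefore certify the
*analyses* — that each estimator recovers known ground truth and
reproduces the qualitative signatures (learning curves, explore→exploit
contraction, decorrelation under task, target-shifted tuning,
task-vs-playback differences) under the stated statistical model — not
that real cortex behaves like the model.

## Problem sizes and seeds

The packaged simulations are sized for interactive use: 20-min baselines
for calibration and chance estimation (10 seeds), 40-trial agent sessions
for the learning-signature Monte Carlos (50 seeds per directional
property), 1,200 cursor events for the classifier chance checks, and
10,000 events for parameter recovery. Every generator and every
stochastic stage takes an explicit seed, identical configuration plus
seed is bit-reproducible end to end (bundle regeneration and pipeline
determinism are tested), and the acceptance script threads a single
`--seed` through all of it.

## Known limitations

- The literal range/4 coefficient convention makes decoded excursions
  quadratic in trace amplitude; the generator is calibrated around it,
  but real-data use would likely renormalize the traces first.
- The agent's internal reward rule (peak-differential threshold) is a
  proxy for the engine's hold rule; the two agree closely but not
  exactly, so agent-rewarded trials and engine hits can differ on the
  margin.
- Direction decoding sits near, not at, chance: a uniform gain leaks
  weakly through unit-specific baselines after z-scoring.
- The auditory pathway is implemented and tested at the transform level
  only; no auditory trial engine variant is provided beyond the shared
  hold logic.
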