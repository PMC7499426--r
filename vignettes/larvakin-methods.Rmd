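---
title: "larvakin: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{larvakin: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

larvakin is a complete, ground-truthed re-implementation of a
kinematic-phenotyping pipeline for larval zebrafish locomotion: synthetic
behavior generation, silhouette tracking, swim-bout segmentation, bout
classification, escape-response selection, per-fish aggregation, and
genotype comparison with a mixed model and an effective-number-of-tests
multiplicity correction. This vignette documents the underlying models, the
measurement conventions, and the choices made where the design was open.

## The behavioral model

Five-day-old zebrafish larvae swim in a "beat-and-glide" style: discrete
swim bouts of a few hundred milliseconds separated by rest periods, at about
one bout per second. Slow exploratory bouts are either **forward swims**
(small, roughly symmetric side-to-side tail bends, maximal bend amplitude
below 25 degrees) or **routine turns** (a large initial bend above 25
degrees that reorients the fish). A threatening acousto-vestibular stimulus
instead triggers an **escape response**: a large C-bend (on the order of
100 degrees), an opposite-direction counter bend, then fast decaying
oscillations at a tail beat frequency several times higher than slow swim.

The quantity every stage works on is the **tail angle**: the signed angle
between the heading (the direction the head points) and the vector from the
head to the tail tip, zero for a straight body, positive for bends toward
the fish's left.

## The synthetic generator

No public raw recordings exist for this assay class, so the package ships a
generator whose defaults are calibrated to published group-level kinematics
of a *sst1.1* knockout cohort versus wild-type siblings, and which records
exact ground truth for every injected event.

### Hierarchy

`generateCohort()` draws per-fish latent parameters as
*genotype level x clutch offset x fish offset*. Offsets are additive on the
log scale for strictly positive parameters (distance, speed, bend
amplitude, oscillation count, rates, latency) and additive on the natural
scale for the escape bend angles, with the variance correction chosen so
that the expectation of a latent across fish equals the genotype-level
value. The clutch offset is shared by both genotypes of a clutch, which is
exactly what makes the downstream clutch random intercept meaningful.

Two dispersion conventions matter and are deliberate:

* **Slow-swim per-bout draws are median-parametrized** (the per-bout
  distribution's median equals the fish latent). The published slow-swim
  statistics are means across fish of per-fish *medians*; with this
  convention the pipeline's mean-of-medians estimator is unbiased for the
  calibrated genotype value.
* **Escape per-trial draws are mean-parametrized**, because escape
  statistics are means across fish of per-fish *means* over the ten trials.

### Mutual consistency of the calibrated values

The published forward-swim triple (distance 0.56 mm, duration 0.27 s, speed
1.96 mm/s for the mutant group) is not internally consistent with
speed = distance/duration (0.56/0.27 = 2.07). The generator therefore draws
per-bout (distance, speed) as correlated lognormals with medians at the
calibrated values and **derives duration as distance/speed** (median
0.286 s). The same holds for escapes, where the printed oscillation count
(8.27), duration (0.27 s) and TBF (37.56 Hz) cannot hold simultaneously per
bout: the generator draws TBF and the oscillation count and derives the
duration as n_osc/TBF. Distance, speed, bend amplitude, TBF (escape),
latency and C-bend are exactly calibrated; duration and slow-swim TBF are
emergent and land within ~6% of the printed values.

### Waveform

A bout with bend peaks $p_1 \dots p_{n_p}$ and duration $d$ is a chain of
half-beats: the $i$-th half-beat occupies $[(i-1)d/n_p, i\,d/n_p)$ and the
tail angle follows a half-sine reaching the signed peak $p_i$ at its
centre. Peak magnitudes decay geometrically (ratio 0.78 forward / 0.80
turn, floored at a fraction of the per-bout median bend) and are scaled so
that the **median absolute peak equals the drawn per-bout bend amplitude**
exactly; signs alternate. Turns draw a large first bend (normal, mean 45,
SD 8, truncated to 28-90 degrees) and rotate the heading by 0.6 x the
signed first bend, linearly across the bout (the gain is a placeholder;
ground truth records the realized heading change so nothing downstream
depends on it). With $n_{osc}$ oscillations the waveform has
$n_p = 2 n_{osc} - 1$ peaks, so the standard count
$n_{osc} = \lceil n_p / 2 \rceil$ recovers the drawn value.

The head advances along the (possibly rotating) heading with per-frame
steps proportional to the local half-beat amplitude, summing exactly to the
drawn bout distance; propulsion therefore tracks beat strength, as in real
fish.

Bout onsets follow a renewal process: glide = 0.1 s minimum plus a
gamma-distributed time (shape 2) whose mean is set from the fish's latent
bout rate minus the expected bout duration, so bouts can never overlap and
the expected onset rate equals the calibrated bout rate.

Sensor noise defaults: 0.15 degrees SD on the tail angle and 0.01 mm on
head position. The angle noise is set at ~5% of the calibrated forward
median bend amplitude (2.88 degrees) — the signal this assay actually
measures is small, and a noise floor comparable to it would make the
published bend statistics unmeasurable. The per-bout median bend draw is
floored at 1.5 degrees so every injected bout is detectable in the
noise-free limit.

### Between-fish dispersions

For the six forward-swim parameters the between-fish SDs are set so that
the *expected Wald chi-square at the study's sample size (58 vs 62 fish)*
matches the published statistics; printed SEMs and chi-squares are not
jointly consistent with a single fish-level variance model (the mixed model
removes clutch variance), and the chi-square calibration is what makes the
qualitative significance pattern reproducible. All other families use
SEM-implied SDs (SD = SEM x sqrt(n), minus the within-fish trial-averaging
share for escapes). The clutch share of the between-fish SD defaults to
0.1: the split is not published, and with only four clutches a large share
would make the cohort mean a poorly-determined quantity relative to its
conventional standard error sd/sqrt(n).

### What the generator does not emulate

Real video artifacts (occlusion, reflections, low contrast), habituation
across the ten escape trials, wall interactions, multi-fish interactions,
3-D posture, and any within-session drift of kinematics. Passing the
recovery tests shows that the *measurement pipeline* is unbiased for data
of this structure — not that it would be unbiased on real video.

## Tracking

`renderFrames()` draws the larva as a head disc (radius 0.3 mm), a straight
neck (0.8 mm), a constant-curvature bend section (1.4 mm) and a straight
distal tail (1.1 mm), tapering in width, inside a 15-mm circular well at 16
px/mm (the camera sampling of multi-well rigs of this class), with a
Gaussian point-spread blur of 0.08 mm. The arc's turn angle is solved per
frame so that the head-to-tip chord reproduces the trace's tail angle; the
mapping is monotone up to ~139 degrees, covering C-bends.

`trackStack()` inverts the geometry without knowing it: background
subtraction and a fixed-fraction threshold (0.5 of the frame's contrast),
connected-component labelling (exactly one plausible component, otherwise
the frame is flagged — zero or multiple components mirror real tracking
failures), Zhang-Suen thinning, longest skeleton path, head end
identified by the larger local width (distance transform), arc-length
resampling to ten tail points, and sub-pixel refinement: head centre and
neck direction from intensity-weighted centroids (the PSF carries sub-pixel
boundary information), and the tail tip projected laterally onto a
total-least-squares line through the distal midline. The heading is the
direction from the neck annulus (0.35-1.05 mm behind the head centre,
angularly gated so a curled tail cannot contaminate it) to the head centre.

Accuracy on clean synthetic stacks at the default resolution: ~0.3-0.5
degrees static error, session RMSE ~0.5 degrees, zero flagged frames, and
C-bends recovered within ~4 degrees. A known limitation: the round-trip
correlation criterion r > 0.99 is resolution-marginal — below ~15 px/mm it
fails for forward-dominated sessions simply because forward bends are only
a few degrees, although the absolute error budget (RMSE < 3 degrees,
flagged < 0.5%) holds with a wide margin from 14 px/mm up.

## Bout segmentation and kinematics

Detection is an envelope-with-hysteresis scheme on the tail angle: sliding
RMS (50 ms window at 100 Hz; 12 ms in the escape regime), a bout opens when
the envelope exceeds 1.0 degree sustained 20 ms and closes below 0.5
degrees sustained 50 ms; intervals closer than 30 ms are merged
(beat-and-glide glides are much longer); interval edges are then refined to
the first/last frame whose |angle| exceeds 0.45 degrees (3 sigma of the
sensor noise; refining on a smoothed copy would smear the edges). All
thresholds are config-exposed (`detectionParams()`). They are set for the
published bend scale — typical forward bouts peak at only 3-7 degrees, so
an envelope threshold of several degrees would miss a large fraction of
real forward swims.

Bend peaks are located on a Savitzky-Golay-smoothed copy (quadratic, 5
frames), required to exceed a 1-degree prominence floor (2 degrees for
escapes), forced to alternate in sign, and their amplitudes re-measured on
the raw trace by a three-point parabolic fit (removing the sampling-offset
bias); the floor is re-applied to the refined amplitudes. Envelope
crossings with no qualifying peak are treated as micro-movements and
dropped.

Per-bout parameters follow the standard definitions: duration =
(offset - onset)/rate on the half-open frame interval; distance = path
length of the head trajectory (positions smoothed by a 5-frame running
mean; the path sum is padded by the smoothing half-window so edge
displacement is not lost — with `smooth_window = 1` the estimator reduces
exactly to the plain displacement-step convention); speed =
distance/duration; oscillations = ceiling(peaks/2); TBF =
oscillations/duration; maximal and median absolute bend amplitudes.

Residual systematic errors of these conventions are sub-frame (duration
within ~half a frame, distance within ~1-2%, bends within ~0.2 degrees,
escape latency +0.8 ms because the onset uses the bout-onset frame's
timestamp — frame start, not mid-frame). The recovery tests assert
unbiasedness up to exactly these discretization allowances; a paired test
at n = 1000 bouts with no allowance would reject any real detector.

## Classification, selection, aggregation

Forward iff maximal |bend| < 25 degrees, strictly: a bout at exactly 25
degrees is a turn. Escape selection takes the first post-stimulus bout with
latency < 30 ms (strict) and first |bend| > 60 degrees (strict); a bout
overlapping the stimulus marks the trial as contaminated by spontaneous
motion and nothing is selected. Fish with fewer than 30 bouts in the 5-min
session fail QC (exactly 30 passes). Per-fish slow-swim values are medians
per category over all of that fish's bouts; escape values are means over
selected trials only — trials with no qualifying bout contribute nothing,
not zeros. A fish with no selected trial is excluded from the escape
comparison only.

## Genotype comparison

Each parameter is compared with the linear mixed model
`value ~ genotype + (1 | clutch)` (random intercept only; the design names
only the clutch as a grouping factor), using the 1-df Type II Wald
chi-square for genotype — for a single two-level factor this is exactly the
squared Wald z of the coefficient, and it is cross-checked against
`car::Anova` in the test suite. If the mixed fit fails (degenerate
random-effect variance), the marginal fixed-effects model supplies the
statistic, so a finite result is always returned.

Before fitting, each parameter may be log- or square-root-transformed: the
transform minimizing the absolute skewness of the residuals after removing
genotype means is chosen automatically (log only for strictly positive
data). Group means and SEMs are always reported on the original scale.

Multiplicity within a family (8 escape parameters; 6 forward; 6 turn) is
handled with the effective number of independent tests:
$M_{eff} = 1 + (k - 1)(1 - V_{corr}/k)$, where $V_{corr}$ is the variance
of the eigenvalues of the parameters' Spearman rank-correlation matrix.
$V_{corr}$ uses the **sample variance (denominator k - 1)**: that is the
only choice under which perfect correlation gives $M_{eff} = 1$ exactly.
Independence gives $M_{eff} = k$; $k = 1$ degenerates to 1. Raw p-values
are multiplied by $M_{eff}$ and capped at 1. The bout rate is a standalone
unadjusted test. On summary-level cohorts at the study size the escape
family's $M_{eff}$ comes out around 7.2-7.4 and the slow-swim families
around 4-5, in line with the published per-family values — which depend on
the real data's correlation structure and are used only as plausibility
ranges here.

## Simulation sizes and numerical choices

Statistical calibration studies (null uniformity, family-wise error, the
forward-family power pattern) run on `simulateFishSummaries()`, a
summary-level simulator that draws per-fish summaries from the same
bout-level distributions as the trace generator but skips trace synthesis
and detection; this is what makes hundreds of replicate cohorts practical.
The shipped suite uses 600 null replicates for the calibration checks and
120 replicates at n = 58/62 for the effect pattern. The pattern thresholds
(affected parameters flagged in more than 35% of replicates, unaffected in
fewer) derive from the design's expected Wald statistics: with
chi-square-matched dispersions the four affected parameters have expected
flag rates near 55% at the study size while the oscillation count and TBF
sit near 20% and below 1% — the published contrast is reproducible as a
rate ordering, not as a deterministic single-run outcome, because the
published duration and oscillation-count effects are barely one standard
error apart.

The family-wise error criterion is tested as a one-sided binomial test that
the FWER does not exceed 0.05 (the no-flag rate under the null is ~0.95 by
construction, so asserting "at least 95% of replicates flag nothing" on a
finite simulation would be a coin flip at the boundary).

Tie-breaks and degenerate inputs: equal adjacent samples at a peak resolve
to the earlier frame; a constant parameter column makes the Spearman matrix
undefined and raises an error naming the column; traces with more than 20%
flagged frames are rejected with a diagnostic; a tail tip coincident with
the head yields a flagged frame rather than an angle.

## Known limitations

* The generator's waveform is a stand-in: no published waveform equation
  exists, and all calibration rests on ground-truth bookkeeping rather than
  waveform realism.
* The tail angle is the head-to-tip chord, not integrated curvature; both
  agree for the synthetic shapes used here but can diverge for real,
  strongly curled postures.
* The published duration/speed/TBF triples are mutually inconsistent at the
  printed precision; derived quantities here land within ~6% of the printed
  values and the exact calibration is placed on the parameters the
  acceptance targets measure.
* The escape latency estimator carries a +0.8 ms frame-quantization bias at
  650 Hz (frame-start convention), within the one-frame allowance stated
  for it.
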