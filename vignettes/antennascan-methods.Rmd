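---
title: "antennascan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{antennascan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antennascan)
```

`antennascan` quantifies active antennal smelling: how a tethered insect's
antennae move before, during and after an odour stimulus, and how those
movements interact with the plume. This vignette is the package's account
of its methods — the models and conventions behind each statistic, the
tunable parameters with their defaults and rationale, what the synthetic
generator does and does not emulate, and the design choices made where the
problem was genuinely open.

## Coordinate conventions and angles

Raw tracking tables live in the tunnel frame: x in mm, negative left of
the animal's initial midline; y positive upwind/forward; z positive up.
Each antenna is treated as a straight line from the tracked head point to
the tracked tip — flagella cannot be bent voluntarily and passive bending
is negligible at the low air speeds involved — so two angles describe it
completely:

* **azimuth**: the signed angle between the horizontal projection of the
  head-to-tip vector and the forward head-line; 0° is parallel to the
  head-line, negative left, positive right;
* **elevation**: the signed angle between the head-to-tip vector and its
  horizontal projection; negative below head level.

The *head-line* is fixed to the tunnel +y midline through the head point
(`head_line = "tunnel"`). A body-locked alternative (the tether-to-head
axis) is exposed as `head_line = "body"`; the tunnel choice keeps antennal
angles and heading measured against the same reference, which matters when
the head itself turns toward a moving stream. Heading is the signed angle
of the tether-to-head line against the midline through the fixed tether
point; its absolute value measures deviation from straight ahead.

Angular speeds are forward finite differences at the native frame rate
(100 frames/s in the emulated recordings) with **no implicit smoothing**;
`smoothSeries()` (centred moving average, shrinking at the edges, default
window 1 s) is applied only where an analysis explicitly asks for it. The
combined angular speed is the Euclidean norm of the azimuth and elevation
rates; a sum-of-absolute-values convention is available
(`combined_speed = "abs_sum"`) since "combined" admits either reading.

## Normalized coordinates and spatial metrics

Tip coordinates are centred on the head at every frame and scaled per axis
by the within-trial maximum absolute value, so the head is (0,0,0), every
axis lies in [−1, 1], and metrics are proportions of the animal's antennal
length (the recovered scale factor on simulated 50 mm antennae is within
5%). Both antennae share one scale per axis by default
(`normalize_axes = "joint"`): a per-antenna option exists, but joint
scaling keeps left/right positions comparable within a trial, which the
responsive-antenna analysis needs. Cross-trial maps are re-expressed
against the maximum coordinate across the dataset
(`crossTrialNormalize()`); that constant is returned for the run manifest.

Occupancy maps use 24 bins per axis over [−1, 1] and are normalized to sum
to 1. Density curves use base R's Gaussian kernel density; one bandwidth
must be shared across curves that are compared in one panel, and
zero-variance input demands an explicit bandwidth rather than silently
degenerating.

**Distance to the stream** is the perpendicular distance, in the
normalized frame, from the tip to the stream centre line — a line running
along y at lateral position `streamX(t)` and at the stream's nominal
height. The text definition of the centre line does not fix the height
convention, so the package defaults to the x–z perpendicular distance with
the stream at head level and offers `distance_mode = "x_only"` (lateral
only); the two agree whenever the tip is at stream height.

**Ranges**: the antennal range is max − min of one antenna's normalized x
within a window; the overall range spans both antennae. Both are exactly
the brute-force maximum pairwise difference, and the overall range can
never be below either individual range.

## Event-triggered changes, sham correction, responsive antenna

Odour-induced effects compare the stimulus window against a pre-stimulus
window of the same length ending at onset: each metric becomes its
difference from the pre-window mean, so pre-stimulus averages are zero by
construction. Window means ignore invalid frames; a window over half
invalid yields a missing value. For the moving-stream protocol every
odour trial is additionally corrected by the same animal's sham (air-only)
trial, frame-aligned on time from onset, removing mechanical components of
the response.

The **responsive antenna** of a trial is the one with the more negative
odour-window mean change in distance to the stream, regardless of
left/right identity; that identity is transferred to the range analysis.
The control labelling applies the same rule to two consecutive pre-onset
windows (clean air only), without transferring identities — on
stimulus-free data it splits at chance, which the tests verify. Ties
break deterministically to the left antenna with a warning; they are
measure-zero on real data.

Group-level uncertainty on window summaries uses a seeded nonparametric
bootstrap over trials (default 2000 resamples) rather than model-based
posterior intervals: deterministic, dependency-light, and with the same
decision semantics. The slope intervals of the PID regression use the
t-scaled bootstrap-standard-error interval, which holds nominal coverage
at the few tens of windows a single recording yields, where the percentile
interval undercovers.

## Stepping

Steps are prominence-filtered peaks of a tarsus's forward (y) coordinate:
default prominence 0.5 mm and minimum separation 0.15 s, consistent with
slow walking around 2 Hz; both are configuration parameters since no
thresholds are canonical. The per-frame instantaneous rate is the
reciprocal of the enclosing inter-step interval held constant between
steps, reading 0 after 2 s without a step so pauses count as non-walking.
Only the reliably tracked front and middle legs (L1, L2, R1, R2) enter the
stepping rate; each leg is normalized by its within-trial mean rate
("normalized" is not otherwise pinned down; a max-normalization switch
exists) and the final series is the per-frame mean of the four. The
leg-speed correlation matrix is the pairwise Pearson correlation of
frame-to-frame 3-D speed magnitudes of all six legs; under a double-tripod
gait, within-tripod correlations exceed cross-tripod ones.

## Spectral analysis

Summary spectra use a one-sided FFT amplitude spectrum (mean removed, no
taper), scaled so a sinusoid of amplitude A peaks at height A.

The band-power statistic uses a continuous wavelet transform with an
analytic **Morlet mother, centre frequency 6**, on a dyadic grid of 12
voices per octave spanning 0.5–10 Hz, implemented by FFT convolution with
zero padding to the next power of two. The Morlet-6 choice is the de facto
default of wavelet analysis tooling for this kind of time–frequency
decomposition; both the centre frequency and the voice density are
configurable. Power is averaged in 1 s time bins and the bands
{[0.5–1), [1–2), [2–3), [3–5), [5–10)} Hz, then scaled per band as
(P~t~ − P₀)/P₀ with P₀ the band's mean over the complete pre-stimulus
bins. The statistic is therefore bounded below by −1, averages 0 over the
pre-window by construction, and is invariant to uniform amplitude scaling
of the signal. A band with zero pre-stimulus power is reported missing
with a warning rather than dividing by zero. Time bins overlapping the
largest scale's cone of influence (√2·s~max~ from either end) are flagged
`@edgeBin` but retained, since edge treatment is a presentation choice,
not part of the statistic.

When bands are pooled into coarser ranges, raw power is recombined
weighted by band occupancy (number of scales per band) and rescaled
against the recombined baseline — never by averaging ratios, which would
bias toward low-power bands.

## Plume analysis

Smoke frames are binarized with one threshold per sequence, restricted to
a region of interest in front of the head, and cleared of body pixels with
a hand-drawn (here: generated) mask; thresholding and masking commute and
the implementation is order-invariant. The row-wise white-pixel counts
along the left-to-right axis give the smoke distribution; the **profile
width** is the longest contiguous run of rows whose count exceeds 5% of
the profile maximum (the floor absorbs speckle stragglers; it is
configurable since no width definition is canonical), normalized against a
reference frame whose width is 1. Which matrix axis runs left-to-right is
declared in the sequence metadata, never guessed from the image.

PID extrema are prominence-filtered local minima and maxima (default
prominence 2% of the window's voltage range) with alternation enforced by
keeping the more extreme of same-type neighbours. The fluctuation rate is
the mean instantaneous frequency — reciprocal inter-event intervals of the
pooled, ordered min+max sequence, averaged per window; a count/duration
alternative is available. Pooling the two event streams is the default
because the quantity of interest is the rate of concentration transients
of either sign. The magnitude is the mean positive contrast: voltage rise
from each minimum to its next maximum. Analysis windows of 2 s are centred
on local peaks of the 0.5 s moving-average-smoothed combined antennal
speed (the unaltered speed feeds the analysis), kept non-overlapping; the
control mode draws seeded random windows for fixed-antenna recordings.

## Valence assay

Shelter occupancy counts frames whose tracked centroid lies inside each
shelter disc, times the frame interval; the preference index is
(T~odour~ − T~control~)/T~total~, exactly antisymmetric under zone swap
and invariant to time rescaling. Partial-body occupancy is out of scope.

## The synthetic generator

Every input format has a generator with serialized ground truth, and every
pipeline stage has a recovery test against that truth. The emulated trial:
head with smoothed jitter (s.d. 0.3 mm); antennae of 50 mm sweeping
sinusoidally (amplitude 30°, ~0.7 Hz with 10% per-trial jitter) about
±50° from the midline, elevation around −20° (amplitude 8°, ~1.1 Hz),
white angle noise of 2°; a 2 s odour pulse after a 5 s baseline in a 12 s
trial (the 5:2 baseline:stimulus proportion is kept at other durations).
During the stimulus the responsive antenna shifts its azimuth 15° toward
the stream, doubles its elevation amplitude and adds a 4 Hz burst of 6°
(three times the angle noise); six tarsi step in two antiphase tripods at
2 Hz with an asymmetric swing/stance cycle (25% swing), halving their rate
during odour. Sham trials drop all odour effects but keep any declared
mechanical artifact. The PID generator couples event rate (4 Hz + 0.01 Hz
per deg/s) and positive contrast (0.05 V + 0.001 V per deg/s) affinely to
a quasi-steady multi-regime speed trace, with band-limited sensor noise
(the detector's response time keeps sample-to-sample noise from spawning
spurious extrema). The smoke generator draws a Gaussian-profile band
(peak 0.8, s.d. 15 rows) plus speckle noise and carves a wake of known
row count from the visible band edge — the gap an antenna leaves when
capturing smoke particles, entering from one side. The arena generator
runs a Markov state walk whose stationary distribution matches the
prescribed shelter occupancy fractions, with ~1–4 s visits.

All randomness flows from one master seed through `splitSeed()`, so
scenarios are byte-identical under a fixed seed and individual trials are
independently reproducible.

What the generator does **not** emulate: coupled left/right oscillator
dynamics, casting structure or odour-driven feedback in the sweep pattern;
tracking artifacts beyond simple dropouts; turbulent plume physics (the
wake is a geometric carve-out); arena thigmotaxis. Passing recovery tests
therefore demonstrate that the estimators are correct and well-calibrated
under the stated statistical structure — not that real recordings satisfy
that structure.

## Numerical choices and degenerate inputs

* Tracking dropouts ≤ 0.1 s are linearly interpolated; longer runs stay
  invalid and are excluded from window statistics (the upstream tracker's
  missing-data convention is unknown; the threshold is configurable).
* Zero-length head-to-tip vectors, head-on-tether frames, constant series
  in correlations, and zero pre-stimulus band power all yield explicit
  invalid/missing values or errors, never silent zeros.
* An axis with no motion passes through normalization unscaled, with a
  warning.
* The responsive-antenna tie-break is deterministic (left, warned).
* Window means with > 50% invalid frames are missing and excluded from
  summaries.

## Problem sizes in the tests

The recovery suite runs 12 s trials at 100 frames/s; the
responsive-antenna calibration uses 100 null and 100 pilot trials to set
the 3σ shift condition and 200 trials to measure accuracy; the PID
coverage check uses 50 replicate 60 s recordings of ~20 windows each; the
wavelet checks use single trials plus a 6-trial pooled cohort. These sizes
give the assertions comfortable statistical margins while keeping the
default suite around a minute of CPU.

## Known limitations

* The ΔP/P normalization follows the proportional-change definition; a
  log-ratio variant would order results identically but differ in value.
* The pooled mean-reciprocal fluctuation rate is event-weighted and sits
  slightly above the time-averaged rate when the rate varies within a
  window; the count/duration mode is unbiased in that case.
* Sham correction assumes frame-aligned protocols; mismatches beyond
  50 ms are an error rather than being resampled.
* Bootstrap intervals quantify sampling uncertainty over trials/windows
  only; they do not model animal-level hierarchy.
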