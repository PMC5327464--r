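---
title: "Methods: decoding wheel locomotion, hippocampal states and calcium stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding wheel locomotion, hippocampal states and calcium stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`wheelphys` implements the complete analysis stack of a head-fixed
awake-mouse experiment on a free-spinning wheel: optical-encoder
decoding of locomotion, behavioural-state segmentation and gait
analysis, hippocampal LFP state detection (ripples and theta), and
two-photon calcium-movie processing (motion correction, axial-stability
probability maps, ΔF/F, transient detection, population sparseness),
together with the resampling statistics used to test day trends and
speed coupling. Because no public recordings accompany this preparation,
a synthetic-data module emulates all three input streams with known
ground truth; every downstream stage is validated by recovering what the
generators injected. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic validation
does and does not establish.

## Wheel encoder model and quadrature decoding

The wheel (circumference 24.19 cm) carries a quadrature optical encoder:
channels A and B emit 500 square fringes per turn, phase-offset by a
quarter pitch so that the lead/lag of A versus B encodes the rotation
direction, and channel I emits one 5 V index pulse per turn. One fringe
is one full A/B square cycle, i.e. `24.19 / 500 = 0.04838` cm of travel;
the four gray-coded quadrature states within a fringe give a position
resolution of a quarter fringe (0.0121 cm). At the 10 kHz digitizer
rate, the top of the validated speed range (120 cm/s) advances the wheel
by 0.0120 cm per sample — just under one quarter fringe — which is why
10 kHz is the minimal rate at which every state transition is observed
and the decoder stays valid over the whole 0–120 cm/s range.

`decode_quadrature()` thresholds each channel at half its amplitude
range, maps (A,B) to the quarter index, and advances the position by
±pitch/4 per valid transition. Transitions in which both channels change
within one sample are invalid (the state skips two quarters); they are
counted and the position is held, rather than aborting, because a single
glitch should not corrupt a session. Instantaneous speed is the
sample-wise position derivative smoothed by a 100 ms centered moving
average: long enough to suppress quarter-fringe quantization (0.121 cm/s
per window), short enough to preserve the ~4 Hz step oscillation. The
resolution floor matters at low speed: at 1–2 cm/s the per-sample
relative error is quantization-bound at roughly 2–12%, so per-sample
accuracy claims in the tests are made on the median (and absolutely,
against twice the resolution), not on the extreme percentiles.

Per-turn speed uses the channel-I markers: for consecutive index peaks
the per-turn value is displacement over elapsed time.

## Behavioural segmentation and gait

Three states partition every recording. Locomotion epochs are contiguous
runs with speed above 2 cm/s covering at least 2 cm; flickering is
movement above 0.25 cm/s that does not qualify (including fast but
sub-distance bursts); immobility is no wheel rotation. Runs above the
locomotion threshold separated by gaps shorter than 0.5 s are merged
before the distance criterion is applied — the gait oscillation crosses
the threshold at every step trough, and without bridging each step
would fragment the epoch.

Walking steps are read off the speed oscillation: the two forelimbs are
anti-phase, so the wheel is pulled twice per full limb cycle and the
speed signal oscillates at twice the limb frequency. Peaks of the
smoothed speed within locomotion epochs are step events; the position
difference between consecutive peaks is the speed-signal step length,
and the limb step length is twice that. Peak criteria (prominence ≥ 25%
of the epoch median speed, separation ≥ 100 ms) are not specified by the
experimental protocol; they were fixed once against the synthetic gait
recovery suite and are exposed as arguments.

Two session-level dispersion measures are reconstructed from their
stated properties (their typeset definitions are unavailable in the
source material): stereotypy is `iqr(D)/median(D)` — zero for a point
mass, scale-invariant, robust to outliers, near/above one for broad
distributions — and the variability of locomotion probability is the
mean within-unit interquartile range, with units = animals (spread
across days) for the intra-individual condition and units = days
(spread across animals) for the inter-individual condition. The
source's n/m sample-size table reads opposite to its own verbal
definition; the verbal definition is implemented, and it is the one
under which "every mouse constant across days" yields zero
intra-individual variability.

The synthetic gait generator drives these analyses: locomotion speed is
a baseline plus a rectified-sinusoid oscillation at twice the limb
frequency (depth 0.6 of baseline, mean preserved), flickering is a slow
wobble held inside (0.25, 2) cm/s, immobility is exactly zero. Defaults:
5.0 cm limb step, 7.5 cm/s base speed — typical values for habituated
mice. The rectified-sinusoid is one plausible limb–wheel coupling, not a
biomechanical model; it reproduces the twofold step-size relation and
the speed-trace rhythm, which is all the downstream analyses consume.

## LFP: ripples

Ripple detection band-passes the LFP to 100–250 Hz (fourth-order
Butterworth, applied forward–backward so event timing is phase-true)
and thresholds the power envelope — squared magnitude of the analytic
signal, smoothed 10 ms. Candidate cores are regions at or above
mean + 3 SD of the full-trace power; boundaries extend to the
surrounding mean + 1 SD crossings, a rule that reproduces the ~40 ms
duration scale of real events. The intra-ripple frequency is 1/lag of
the first positive-lag autocorrelation peak of the 100 ms band-passed
segment around the power peak. Events with fewer than 4 cycles
(duration × F < 4) are rejected, and a final validation step — standing
in for the manual review of preselected candidates that an experimenter
would perform — requires the event's integrated supra-mean power to
reach 150 SD·ms. That energy criterion was calibrated once on the
synthetic suite: chance band-power fluctuations in 1/f noise reach
~130 SD·ms at their 99.9th percentile while generated ripples sit near
230, so the two populations separate essentially completely (null
false-positive rate below 0.01 events/s at a ~93% hit rate on injected
events). Occurrence is N/D with D the analysed (immobility) duration.

All Butterworth filtering in the package applies the forward–backward
magnitude response on the FFT grid from the closed-form bilinear-mapped
Butterworth formula. Evaluating the filter's transfer-function
polynomials recursively — what `filtfilt` does — is numerically unstable
for bands that are narrow relative to the sampling rate (5–15 Hz at
10 kHz places all poles against the unit circle and yields NaN on
minute-long traces); the closed form is exact and stable for any band,
at the cost of circular edge behaviour that is negligible on traces
minutes long.

The LFP generator produces 1/f background noise (spectral exponent 1),
Gaussian-windowed ripple bursts during immobility as a Poisson process
(rate 0.11 Hz; carrier drawn per event from a normal with mean 143 Hz
and SD 14 Hz truncated to 100–250 Hz; amplitude 5× the in-band noise
SD), and a theta sinusoid during locomotion. The nominal ripple duration
(37.7 ms) is mapped to the envelope as σ = duration/3 and slow-carrier
draws are widened to at least 4.5 cycles, so that every emitted event
passes the detector's own cycle definition by construction — with a
narrower envelope the boundary-measured extent falls below 4 cycles for
a quarter of the events, and a 100 Hz draw would fail even nominally.

## LFP: theta

Theta analysis decimates the LFP to 200 Hz (anti-aliased), computes a
Morlet scalogram (ω₀ = 6) over 5–15 Hz in 0.25 Hz steps, and defines
the instantaneous frequency as the squared-power-weighted mean
frequency. Squared weights matter: with plain power weights the
asymmetric wavelet response and the in-band 1/f floor bias a pure 8 Hz
tone to 8.24 Hz, while squared weights read 8.06 Hz and restore the
speed-slope recovery. Theta power is the band power integrated over a
1 s window, in dB. For the speed relation, frequency and speed are
smoothed over a common 0.25 s window (the wavelet's own temporal
support; mismatched timescales attenuate the regression slope), samples
within 0.5 s of bout edges are excluded (the 1 s power window otherwise
mixes immobility), speed is binned at 0.1 cm/s, and per-bin means are
fitted linearly, reporting both slopes with Pearson r and P. On
generator ground truth (0.01 Hz and 0.023 dB per cm/s) the frequency
slope recovers within ~5%; the power slope in dB of *total* band power
under-recovers by roughly a third because the noise floor dilutes the
theta amplitude change — it is reported, but quantitative claims in the
tests rest on the frequency slope. Theta epochs (for the overlap-with-
locomotion fractions) are periods where the 1 s band power exceeds its
own mean + 1 SD; the threshold is a module parameter since the epoch
definition is not fixed by the protocol.

## Imaging: motion and axial stability

Motion correction is rigid and integer-pixel: each frame's shift is the
argmax of the FFT cross-correlation with a reference image, searched
within a quarter of the frame size per axis (excluding circularly
wrapped matches); frames whose estimate sits on that bound are flagged
`saturated`. The reference is chosen in two passes: a median projection
of immobility frames yields provisional shifts, then the mean of the 10
lowest-motion immobility frames — a period free of motion and activity —
anchors the final pass. Shifts are only identifiable relative to the
reference, so "exact recovery" of ground-truth shifts holds when the
recording contains a genuinely motion-free reference epoch, which the
exactness tests therefore include. Featureless frames get zero shift
and a low-confidence flag.

The more-stable template is the subset of immobility frames whose
per-axis |shift| stays below the recording's mean motion-vector length
(behavioural immobility does not guarantee brain immobility). Motion by
state reports median vector lengths for the more-stable and locomotion
groups, their fold change, and the onset-triggered displacement profile
(median and IQR in an 8 s window around locomotion onsets).

Axial stability: over a chosen frame template, each ROI frame is
binarized at its own 90th intensity percentile (making the map invariant
to global intensity rescaling), and the stability map is the per-pixel
fraction of frames above threshold. Chance is estimated by permuting the
pixels within each frame — 1000 surrogates by default — and taking the
per-pixel 95th percentile of the surrogate maps. The supra-chance region
is the connected component above that threshold containing the peak
(optionally the local peak nearest a nominated structure, so one
terminal can be quantified in a crop containing several); its
equivalent-circle diameter `2·sqrt(area/π)·pixel_size` is the reported
structure size. Because the per-frame mask always marks the top decile
of pixels, the measured size is meaningful when the crop's stable
structures occupy roughly that decile — the geometry of a bouton-rich
field of view; in a crop containing a single faint structure the mask
spills into the Gaussian skirt and the region reads large. The peak is
reported both as % of frames and relative to the chance level at the
peak, since either normalization is defensible.

ΔF/F uses `(F − F0)/F0` with F0 the main mode (50-bin histogram) of the
trace values lying between its 5th and 10th percentiles: a baseline
estimate that transients cannot contaminate, at the cost of requiring
the trace to actually spend ~5% of its time at baseline.

The movie generator renders structures as 2-D Gaussians (FWHM = nominal
diameter) on a constant background, with per-frame axial in-focus
Bernoulli draws, difference-of-exponentials GCaMP6f-like transients
(the rise parameter is the time-to-peak, 30 ms, with 400 ms decay),
state-coupled lateral shifts (per-axis SD 0.27 µm in immobility and
1.53 µm during locomotion — a ~5.6× state ratio with a 1.8 µm median
run-epoch motion vector — boosted 1.5× within 1 s of locomotion onsets),
rounded to the pixel grid and rendered exactly, plus Poisson shot noise
and Gaussian read noise. The default field of view is a diagonal
dendrite with irregular varicosity brightness plus one bright 1 µm
bouton; the irregularity is deliberate — a periodic blob row makes rigid
registration ambiguous under translation.

## Calcium activity

The adaptive activity threshold iteratively withdraws the highest
sample and recomputes the adjusted Fisher–Pearson skewness (running
raw-moment updates, O(1) per iteration); at the first crossing of
skewness ≤ 0 the threshold is the SD of the surviving data — the noise
σ of a positively contaminated sample. If skewness never crosses zero
before half the data are removed, the routine falls back to
median + 2·MAD with a warning.

Transient detection thresholds the first derivative of the lightly
smoothed trace at mean + 2 SD. Two acceptance gates follow. First, the
trace-level skewness must exceed 1: a positively skewed trace is the
signature of genuine transients, and this single gate rejects pure
noise (false-positive rate ≈ 0) and symmetric signals such as
sinusoids. Applying the skewness rule to the individual event segment
instead would fail in both directions — a fast-rise/slow-decay event
sampled from onset to half-peak return concentrates its values near the
peak and is *left*-skewed, while short noise segments are often
right-skewed. Second, each event's peak must exceed the trace median +
2 robust SDs (1.4826·MAD), a floor that the trace SD cannot inflate.
Kinetics are measured on the raw trace: the event peak, and the onset
as the last raw-derivative threshold crossing before the peak (the
smoothed crossing is spread one frame early by the smoothing kernel,
which would read a 30 ms rise as 66 ms at 30 Hz sampling).

Population sparseness is the per-500 ms-bin fraction of cells "off".
A cell's binned response is the mean of its trace within the bin,
compared against its own adaptive threshold. The binned-mean choice is
load-bearing: the bin *maximum* of pure noise exceeds the frame-level
noise SD in ~90% of bins, which would read near-zero sparseness for
silent cells — the opposite of sparse coding — while the bin mean of
noise shrinks as 1/√(bin size) and a 0.4 s-decay transient still lifts
its bin far above threshold, so sub-bin transients continue to mark
bins "on". Sparseness is invariant to cell relabelling and duplication
and to per-cell rescaling (thresholds scale with their traces); it is
not invariant to adding a constant offset, because the threshold is a
spread, not a location — ΔF/F traces are zero-based by construction.

Pairwise correlations are zero-lag cross-covariances normalized by the
two SDs (Pearson correlations of the mean-removed traces); zero-lag
rather than the covariance-function maximum, flagged as a choice. The
speed–calcium relation uses the circular normalized cross-covariance
over ±10 s lags. The null comes from circular time shifts of the trace,
which preserve autocorrelation and destroy alignment; since a circular
shift merely translates the circular covariance curve, the full
5000-surrogate null is read off the base curve at random offsets
(restricted to at least twice the window so surrogate windows never
touch the true alignment). Significance uses the max-over-window
statistic against its surrogate 99th percentile — a max-statistic null
is required because the window spans hundreds of correlated lags, and a
pointwise band would reject almost surely under the null; the pointwise
band is also returned, for plotting. Empirical null rejection runs at
1–3%.

## Resampling statistics

The day-trend test compares the least-squares slope of value against
day with the slopes of full reshuffles — random permutations of all
values across days, preserving the value multiset. "Full dataset
reshuffling" permutes raw values, not day summaries. With 10000
surrogates and the 5th/95th percentile rule the two-sided type-I error
is 10% by construction; the calibration test verifies 10% ± 2% over 500
null replicates (at 2000 surrogates each, for speed) and ≥95% power on
a monotone trend at the generator's effect size.

## Problem sizes and determinism

The test suite validates on sizes chosen to estimate the relevant rates
without waste: 600 s LFP at 10 kHz for ripple occurrence (≈ 66 expected
events) and false positives; 30 locomotion bouts spanning 3–28 cm/s for
the theta slope; 120 s movies at 30 Hz, 64×64 px at 0.3 µm, for motion
and stability (1000 spatial surrogates; 300-frame templates put the
binomial SE of a 0.6 peak probability at 0.028); 500 null replicates
for the slope-test calibration. Every stochastic component draws from
an explicit seed and restores the caller's RNG state, so whole-session
reports are reproducible bit for bit.

## What the synthetic validation does not show

The generators reproduce the statistical structure the analyses assume
— quadrature geometry, threshold-crossing behaviour, Poisson event
counts, spectral laws, Gaussian structures with GCaMP6f kinetics — not
the physiology behind it. Real recordings add non-stationary noise,
electromyographic and chewing artifacts in the LFP, neuropil
contamination and bleaching in fluorescence, non-rigid tissue
deformation, and depth-dependent point-spread-function broadening (so
measured bouton diameters are upper bounds axially). Passing the
recovery suite shows the implementations are faithful to their
definitions and invertible on data matching their assumptions; it does
not certify performance on any particular real recording. Non-rigid
registration, spike inference, and ROI auto-segmentation are out of
scope; ROIs are inputs.
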