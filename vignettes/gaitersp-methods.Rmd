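---
title: "Gait-cycle electrocortical dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-cycle electrocortical dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Walking on progressively uneven terrain demands more active cortical control,
and that demand changes with age. Mobile high-density EEG recorded during
treadmill walking lets one ask two kinds of questions: how *average* band
power (theta 4–8 Hz, alpha 8–13 Hz, beta 13–30 Hz) at cortical sources shifts
with terrain difficulty and age group, and how power *fluctuates within each
stride* (event-related synchronization in double support, desynchronization
in swing). `gaitersp` implements the full analysis chain for such a study —
from raw multichannel EEG plus insole forces to terrain-by-age mixed-model
contrasts — together with a synthetic data generator with exact ground truth,
so that every stage has a parameter-recovery test surface.

## The synthetic generator

Cortical sources are band-decomposed colored noise. A source's spectrum
follows the aperiodic-plus-peaks model used throughout the field:

log10 S(f) = offset − exponent · log10 f + Σ h_k · exp(−(f − c_k)² / 2w_k²)

The time series is synthesized from a single white-noise draw filtered with
disjoint spectral masks (theta, alpha, beta, remainder). Because a condition
or group effect of d dB multiplies one band's mask by 10^(d/10), the injected
band-power shifts are exact by construction, and doubling d doubles the
measured dB difference. Within-stride modulation multiplies a band's
amplitude by 10^(g(φ)/20), where g is a zero-mean cosine profile of stated
peak-to-peak amplitude (dB) over the gait phase φ, evaluated through the same
piecewise-linear phase model used by the time-warping stage. Each band also
receives a slowly varying lognormal amplitude envelope (waxing and waning
oscillations, as in real EEG), normalized to unit mean square so the power
bookkeeping is untouched; the envelope makes the sources identifiable to ICA.

Sources are mixed to scalp channels through an idealized dipolar forward
model: the potential of a current dipole in a homogeneous conductor sampled
on a spherical Fibonacci montage and average-referenced. We chose this over
a multi-shell model deliberately: the generator and the dipole fitter share
the model, so the fitting round-trip is exact, and shell conductivity ratios
would only rescale the spatial smoothness of the maps without adding any
testable behavior. Dipole locations therefore live in model coordinates; no
template warping is attempted.

Artifacts: EMG contamination with a spectrum flat to 20 Hz and rising at
0.3 dB/Hz above it (applied to dedicated EMG channels and to a configurable
fraction of scalp channels), 60/120 Hz mains sinusoids, and white sensor
noise. Noise-role channels carry each scalp channel's artifact-plus-line
mixture but none of the cortical sources, emulating mechanically coupled
dual-layer reference electrodes.

Gait: stride durations are truncated normal with per-(terrain, age) means
and coefficients of variation; insole force traces are smooth stance bumps
crossing the 20 N detection threshold exactly at the true foot strike and
foot off; sacral excursion traces oscillate once (mediolateral) or twice
(anteroposterior) per stride with per-stride peak-to-peak amplitudes of
stated mean and CV. Where the study design did not pin a number (e.g. sacral
excursion means) we fixed one realistic value and did not revisit it: stride
means 1.20–1.28 s (young) and 1.45–1.56 s (old) rising with terrain, stride
CVs 3–7.5% (young) and 4–12% (old), sacral means 15 mm AP / 40 mm ML.

What the generator does *not* emulate: realistic head anatomy, eye blinks
and saccades, electrode impedance drift, heteroscedastic sensor noise, and
non-stationarities between trials. Passing tests therefore demonstrate that
the algorithms recover what they claim under a faithful signal model, not
that any specific human dataset will behave as well.

## Preprocessing chain

The cleaning order is fixed and logged: 1 Hz zero-phase FIR high-pass
(windowed-sinc, −6 dB at 0.5 Hz), 20 Hz high-pass on EMG channels only,
sliding-window sinusoidal regression of the 60/120 Hz lines (4-s Hann
windows, overlap-add), bad-channel rejection (per role, MAD amplitude metric
z > 3), per-role average reference, reference-guided cleaning against the
noise electrodes (windowed canonical correlation, R² ≥ 0.65, 4-s windows)
then against the EMG electrodes (R² ≥ 0.4), bad-window marking (windows
where > 40% of channels either fail a 0.7 reconstruction-correlation
criterion or exceed a robust amplitude z of 10), re-reference, and ICA on
the concatenated walking-plus-rest data with masked samples excluded.

Two ICA estimators are provided. The default is SOBI — joint diagonalization
of time-lagged covariance matrices — because oscillatory cortical sources
are distinguished chiefly by their spectra, SOBI is deterministic, and it
needs no non-Gaussianity assumption. Symmetric FastICA (logcosh) is
available for strongly non-Gaussian sources and is exercised against known
mixings in the tests. Components are retained when all four criteria hold: a
transparent heuristic brain score ≥ 0.5 (equal-weight combination of map
dipolarity, spectral 1/f-ness and low high-frequency fraction), a negative
2–40 Hz PSD slope, dipole residual variance < 0.15, and a dipole inside the
model head radius. Retained dipoles are clustered by k-means (default
k = 11, 100 restarts; desk-scale runs use fewer); components farther than 3
pooled SDs from every centroid are outliers; clusters missing half of either
age group are dropped; within a (subject, cluster) pair only the highest
brain score survives. A diagnostic report of Calinski–Harabasz,
Davies–Bouldin and silhouette indices over k = 9…14 supports the choice of k.

## Spectral analysis

Walking data are epoched from 1 s before to 4.25 s after each right foot
strike (5.25 s total, so even slow strides fit; epochs may overlap).
Epochs whose gait-event latencies deviate more than 3 SD from the mean
latency are dropped. PSDs are Welch estimates (2-s Hann segments, 50%
overlap); dB is 10·log10(power) everywhere. Time-frequency maps use complex
Morlet wavelets with the [3, 0.8] cycles convention, read as: 3 cycles at
the lowest analyzed frequency, expanding as a power law so that the count at
the highest frequency equals 20% of the fixed-window (FFT-taper) count.
Each epoch's stride is time-warped piecewise-linearly so its five anchors
(right foot strike, left foot off, left foot strike, right foot off, next
right foot strike) land on the template anchors (median latencies), on a
200-point gait-percentage grid; power is averaged linearly across epochs
before conversion to dB.

Muscle-artifact residue is removed by spectral PCA: uncentered PCA over the
(component × frequency) matrix of walking-minus-rest spectral changes
averaged across conditions; the first principal component — the largest
eigenvalue, rising above 20 Hz in contaminated data — is zeroed and the rest
back-projected with the same weighting matrix for every condition. PSD and
ERSP corrections use separate bases fit to their own observation matrices
(they live on different grids and mix different variance sources); both
remove PC1. For PSDs the resting spectrum is added back so the
aperiodic/periodic decomposition sees absolute spectra.

That decomposition fits, over 3–40 Hz in log10-power units, an aperiodic
line plus at most two Gaussian peaks with width limits [1, 8] Hz and a
minimum height of 0.05 log10 units. The aperiodic fit is made robust by
iteratively excluding points more than 2.5 robust SDs from the line in
*either* direction, so narrowband peaks and band-limited condition dips do
not bias the slope. Band power is the mean of the flattened (aperiodic-
subtracted) spectrum over the band. Intra-stride fluctuation is the
peak-to-peak range of the band's gait-cycle curve on a within-condition
normalized map, unsmoothed by default (a smoothing window is exposed but
off).

ERSP normalization modes: within-condition (each condition's own gait-cycle
mean subtracted per frequency; zero gait-axis mean by construction) for
fluctuation metrics, and common-baseline (the across-condition mean
subtracted) for between-condition comparisons, plus walking-versus-rest
differences for the sPCA observations.

## Statistics

Bootstrap ERSP masking: per time-frequency bin, the deviation of the
epoch-mean map from its gait-cycle mean is compared with a null built by
resampling epochs with replacement and independently shuffling each
resampled epoch's gait-axis bins — under no gait-phase structure the bins
are exchangeable — with two-sided p-values corrected by Benjamini–Hochberg
across the grid (default 4000 iterations). The permutation PSD test computes
a per-frequency F statistic and permutes labels within the appropriate
exchangeability blocks: across subjects for age, within subject for terrain
(main effects only). Cluster-based permutation on time-frequency maps uses
two-sided bin-level t thresholds at α = 0.05, 4-connected clusters scored by
summed t, and the Monte-Carlo null of the maximum cluster score (default
10000 permutations). All resampling p-values include the observed statistic
in the null, so p ≥ 1/(n+1). Band-power and fluctuation outcomes are
analyzed with linear mixed models (`value ~ condition * group + speed +
(1 | subject)`), after excluding values more than 8 SD from the mean;
F tests use Satterthwaite degrees of freedom, partial eta-squared is
F·df1/(F·df1 + df2), the interaction is dropped and the model refit when its
p ≥ 0.05, and pairwise estimated-marginal-means contrasts are FDR adjusted.

## Numerical and design choices

* dB convention: 10·log10(power) throughout.
* High-pass design: Hamming windowed-sinc, transition band equal to the
  cutoff for the 1 Hz drift filter (hence −6 dB at 0.5 Hz), applied once
  with group-delay compensation (linear phase, zero net delay).
* Welch: 2-s Hann segments, 50% overlap.
* Warped gait grid: 200 points; anchor template = median latencies; linear
  interpolation; epochs with non-monotone latencies are dropped with a log
  entry.
* Band edges are configuration, defaulting to theta 4–8, alpha 8–13, beta
  13–30 Hz; the theta lower edge is left configurable because conventions
  (3 vs 4 Hz) differ.
* "Step duration" is the time between consecutive contralateral foot
  strikes (two steps per stride); outlier rejection (±2.5 SD) is applied
  once per trial, non-iteratively, before pooling the two trials of a
  condition.
* Threshold-crossing detection uses a 50 ms debounce against chatter near
  the 20 N threshold; configurable.
* ICA dimensionality defaults to the number of principal components clearly
  above the sensor-noise floor (eigenvalue > 2% of the largest, capped at
  20 and at rank − 1).
* k-means and ICA seeds are configuration fields with fixed defaults; the
  whole pipeline is deterministic given its configuration.
* Degenerate inputs: zero-variance series pass through the outlier rule
  unchanged; a zero-mean series makes the CoV an error; recordings where
  more than half a role's channels fail the amplitude criterion, or more
  than 70% of samples are masked, abort with a hard failure rather than
  silently continuing.

## Problem sizes used by the tests

The test suite and the acceptance script run at desk scale, chosen so the
whole suite completes on one CPU in well under half an hour: 32 scalp + 32
noise + 2–4 EMG channels, 40–120 s trials at 250–500 Hz, 2–4 subjects per
group for end-to-end runs, and 12 + 12 subjects of clean-source signals for
the power analysis of the terrain-by-age pattern (120 s per condition,
matching two 60-s walking trials). Error-rate checks use 50–100 null
replicates at reduced resampling counts (300–500 iterations). All sizes are
configurable upward; the statistical procedures' defaults (α = 0.05, 4000
bootstrap, 2000 and 10000 permutations, k = 11) follow the study design the
package models.

## Known limitations

* The spherical-montage forward model supports method validation, not
  anatomical inference; dipole coordinates are not comparable to template
  (e.g. MNI) space.
* The brain-score heuristic is transparent but cruder than a trained
  component classifier; its 0.5 threshold is a score threshold, not a
  probability.
* SOBI separates sources by spectral diversity; two sources with identical
  spectra and no amplitude structure would not be separable (the generator
  gives regions individually distinct peak frequencies, as real cortex
  does).
* The flattened-band-power pathway slightly attenuates band-limited
  condition shifts (edge bins and residual aperiodic absorption, of order
  0.1–0.2 dB for a 2 dB shift at 120 s of data); the recovery tests bound
  this.
* Eye-artifact handling is limited to a frontal/low-frequency heuristic in
  scope; the generator does not simulate ocular sources.
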