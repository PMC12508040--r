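---
title: "Models and methods behind pocketpaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pocketpaint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pocketpaint analyzes single-molecule fluorescence videos from low-cost
smartphone-based microscopes, and ships a forward simulator of such videos
so that every stage of the analysis can be validated against known ground
truth. This vignette explains the models, the tunable parameters and the
numerical choices; it states no measured result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The imaging model

A color smartphone sensor observes the sample through a Bayer color-filter
array (CFA, default RGGB). The simulator works entirely on the mosaic:

* **Optics.** Point emitters are blurred by a symmetric Gaussian PSF. The
  conversion between full width at half maximum and standard deviation is
  fixed package-wide at FWHM = 2.35 sigma. The smartphone preset uses a
  PSF FWHM of 1.3 um, the research-grade ("high_end") preset 0.27 um.
* **Sampling.** For the smartphone preset the mosaic pixel pitch projected
  on the sample plane is 215 nm, so that the channel-split images analyzed
  by the localizer sample at 430 nm/px, about 3 pixels per PSF FWHM — the
  sampling regime a well-configured single-molecule camera aims for. The
  high-end preset is a monochrome sensor at 108 nm/px. Neither pitch is a
  measured quantity; both are package assumptions consistent with the
  stated PSF widths, and both are configurable.
* **Photon budget.** Expected photons per pixel are computed by the
  *integrated* (pixel-area-averaged) Gaussian, i.e. products of
  differences of normal CDFs, so photon flux is conserved to better than
  0.1% for windows of at least 5 sigma. Per-pixel photoelectrons are
  Poisson distributed after weighting by that pixel's channel sensitivity;
  counts are `gain x photoelectrons + baseline + N(0, read noise)`,
  rounded and clipped to the ADC range. With `noise = FALSE` every random
  term and the quantization are disabled, which the photon-conservation
  tests exploit.
* **Spectra.** A green-emitting dye is detected with relative channel
  sensitivities G = 1.0, R = 0.45, B = 0 (the blue channel is blocked by
  the 550 nm long-pass filter of the emission path). The diffuse
  background has its own weights (G = 1.0, R = 0.85, B = 0.1) because
  background light is spectrally broader than the dye emission. These
  numbers are qualitative choices, made once: they reproduce the
  *ordering* of per-channel contrast (G best, then G+R, then R) and are
  not fitted to any measured value. Because the Weber contrast
  (S - B)/B is invariant under any per-channel gain, the ordering can
  only come from the background spectrum differing from the dye spectrum
  — this is why the background weights exist at all.
* **Background.** A uniform background flux (default 10 photons per
  mosaic pixel per second in the DNA-PAINT scenarios) models unquenched
  imager fluorescence and scattered light. Together with the default
  emitter flux of 1700 detected photons/s it puts the single-frame,
  5-frame-summed Weber contrast of a single dye near 1, the regime the
  smartphone instrument operates in. The elliptical TIR illumination
  profile of the real instrument is not modelled; illumination is uniform.

## Binding kinetics and photophysics

Docking sites blink with exponential waiting times (`1/event_rate`,
default 0.02-0.05 events per site per second depending on scenario) and
exponential on-times (`mean_dwell`, default 1.05 s — the dwell of a
12-nt imager with a 3-bp mismatch). Fixed dyes are on from the start and
photobleach in a single step after an exponential time; fiducial markers
(gold nanoparticles) are always on, never bleach, and are brighter than a
single dye by a configurable factor (default 25). Binding positions of
docking events are jittered uniformly on a disc of diameter equal to the
docking-site extent (28 nm), one draw per event.

Stage drift is a deterministic linear velocity plus an isotropic random
walk; the desktop preset drifts at 3.5 um/hour. The exact cumulative
trajectory is exported with every simulation.

## Analysis chain

**Preprocessing.** The camera baseline (from a dark video or a scalar) is
subtracted without clipping — the detectability metrics are
difference-based and need signed values. Bayer splitting yields
quarter-resolution R and B stacks and a G stack that is the *mean* of the
two green subsamples, keeping all channels on one intensity scale; each
channel records the half-pixel offset of its sampling grid so that
localizations from different channels share coordinates. Outlier pixels
are replaced by their neighborhood median when they deviate by more than
`k = 5` scaled MADs (radius 1 by default; radius 2 gives a more stable
MAD on noisy backgrounds). This replacement is deterministic, unlike the
interactive despeckle tools it mimics, and is exactly idempotent only
when outliers are isolated on smooth backgrounds. Frame averaging and
summation track the effective exposure (`n x frame_time`).

**Detectability metrics.** The signal-to-background ratio of a spot is
the Weber contrast computed from an inner 6x6 px ROI and the 28-pixel
ring between it and an 8x8 px outer ROI, both anchored on the detected
centroid rounded to the nearest half-pixel grid. (The companion text of
the original protocol calls this ring "2 pixels wide", which is
inconsistent with the explicit 6x6/8x8 sizes; the explicit sizes win
here.) Spots whose outer ROIs overlap are excluded. Intensity traces are
means over a 6-pixel-diameter circular ROI using a pixel-center inclusion
rule, with no time averaging. Photobleaching steps are found by
exhaustive two-segment piecewise-constant fitting; a step is accepted
when the drop is at least 2 pooled standard deviations (the acceptance
threshold is a package decision — step detection is never quantified in
the protocols this mimics). The SNR is `(S - B)/sigma_S` with `S`,
`sigma_S` from the pre-bleach trace and `B` by default the post-bleach
trace mean; a ring-trace background estimator is available via the
`background_trace` argument.

**Localization.** Candidates are local maxima above
`median + k x MAD`; detection optionally smooths with a matched filter
(`sigma/sqrt(2)`) — fits always see raw counts. Each candidate ROI is fit
by a 5-parameter (x, y, photons, background, sigma) maximum-likelihood
estimator for Poisson noise and an integrated symmetric Gaussian, using
Fisher-scoring Newton updates with backtracking; convergence requires
position changes below 1e-4 px and relative photon changes below 1e-3
(max 100 iterations). A symmetric sigma is fitted because 3-frame
pre-averaging symmetrizes the smartphone spots; fits wider than half the
box are rejected as background artifacts. The localization precision is
the Mortensen approximation
`var = sa2/N (16/9 + 8 pi sa2 b / (N a^2))`, `sa2 = sigma^2 + a^2/12`,
with photon counts scaled by the pre-averaging factor. The 31 nm
precision filter used for research-grade data is available
(`filter_localizations`); the smartphone preset applies no precision
filter by default. A separate photon filter
(`filter_photon_outliers`, default 1.3 x median) removes localizations
brighter than a single emitter: frames in which both docking sites of a
structure emit produce one fit at the photon-weighted centroid, and
leaving them in biases distance measurements inward by several
nanometers.

**Drift.** Fiducials are localization tracks linked greedily
frame-to-frame (nearest neighbor within a radius, small gaps bridged)
that are present in at least 80% of frames and span at least 90% of the
acquisition — transient ~1 s binders cannot qualify. The trajectory is
the mean over tracks of the position relative to each track's start,
linearly interpolated across gaps, smoothed by a centered moving average
(window 50 frames by default; shorter windows suit coarsely sampled
acquisitions such as 1 frame / 10 s) and anchored to zero at frame 1.
Fiducials are masked out of downstream metrology within a 500 nm radius.

**Metrology.** Rendering uses half-open square bins anchored at the
table's bounding-box minimum (25 nm bins for smartphone data, 10 nm for
high-end, matching the scales the two instruments resolve). Structures
are connected components at a linking distance (300 nm) with a minimum
size; each cluster is centered, rotated onto its principal axis (180°
ambiguity resolved toward the brighter lobe; ties unflipped; isotropic
clusters flagged), pooled, and the axis histogram is fitted with a
shared-sigma double Gaussian by least squares with multi-start
initialization. The reported FWHM is exactly 2.35 sigma. The NeNa
precision estimator fits the first-neighbor density
`p(d) = d/(2 sigma^2) exp(-d^2/(4 sigma^2))` plus a linear background
term to consecutive-frame nearest-neighbor distances (the multi-term
correction of the published estimator is not reproduced; the basic
density plus background is fixed in code). Mean imager dwell times are
estimated from linked events: because an exponential on-time sampled in
frames of length dt touches K frames with `P(K > k) = C exp(-k dt/tau)`,
the distribution of K-1 given K >= 2 is geometric with ratio
`exp(-dt/tau)` *independently of how partial edge frames are detected*;
the estimator drops 1-frame events and inverts
`tau = -dt / log(1 - 1/mean(K - 1))`. When all event durations are equal
the distribution is degenerate and the plain mean duration is returned.

**Bioassay.** The ~600 nm dimer sensor carries three control sites and
one target site, collinear at 0/260/340/600 nm by default. The central
pair (80 nm apart) is chosen to be resolvable by the high-end instrument
but merged at smartphone resolution, which is what makes the spot counts
mode-dependent: control/detected = 3/4 spots (high-end) or 2/3 spots
(smartphone). Localizations of one sensor are merged into spots by
average-linkage hierarchical clustering cut at 1.4 x the mode's
resolution FWHM. Single linkage at FWHM/2 was rejected after testing: at
smartphone precision (sigma 84 nm) bridging points chain neighboring
sites into one spot essentially always, while the average-linkage cut
separates sites beyond the resolution limit and keeps single-site clouds
intact (97-100% correct spot counts in the seeded validation). A length
gate on the end-to-end spot extent rejects malformed structures; it is
pattern-conditional ([200, 450] nm for control patterns, [400, 800] nm
for detected patterns) because the control-active sites span only ~340 nm
of the 600 nm sensor — a single gate around the full design length would
reject every control. The detection fraction is
detected/(detected + control) with a Wilson score interval; rejects are
excluded but reported.

## Problem sizes and study conditions

The quantitative recovery checks run on reduced but honest scales, chosen
once:

* Nanoruler distance: 30 8HB structures (3 um minimum separation) in a
  30 um field, 18000 frames of 250 ms, event rate 0.02/site/s
  (>= 5000 binding events), 3 fiducials, desktop drift preset. The event
  rate keeps the probability that both sites of a ruler emit within one
  averaged frame at a few percent; together with the photon filter this
  keeps the inward distance bias well inside the 10 nm acceptance band.
* Dwell time: 25 isolated docking sites, 7200 frames, event rate
  0.05/site/s (>= 2000 events), localized without pre-averaging.
* Drift: 3 fiducials over one simulated hour at 1 frame / 10 s
  (360 frames), smoothing window 5 frames.

## Known limitations

The PSF is scalar and aberration-free (no astigmatism, no z), noise is
spatially uniform (no per-pixel sCMOS maps), illumination is flat, and
multi-emitter fitting is not attempted — overlapping-emitter frames are
filtered, not deconvolved. The simulator emulates the statistics that
matter for validating the estimators (PSF width, Bayer sampling, shot and
read noise, binding kinetics, drift); it does not emulate fixed-pattern
noise, rolling-shutter effects, compression artifacts, or the spatial
inhomogeneity of real illumination, so green tests certify the analysis
chain, not any physical instrument.
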