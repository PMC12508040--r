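# pocketpaint

Single-molecule detection and DNA-PAINT super-resolution analysis for
smartphone-based fluorescence microscopes.

Low-cost portable microscopes built around ordinary smartphone cameras can
detect the fluorescence of individual dye molecules directly, with no
chemical or plasmonic amplification, and — via DNA-PAINT localization
microscopy — resolve structures far below their ~1.3 µm diffraction limit.
Doing science with such data requires a chain of quantitative steps that
ordinary SMLM software does not cover end to end for raw Bayer-mosaic phone
video: baseline subtraction and color-channel splitting, single-molecule
detectability metrics on the split channels, localization at very low SNR,
fiducial drift correction over hour-long acquisitions, nanostructure
metrology, and digital bioassay calling. pocketpaint implements that chain
in R, together with a full forward simulator of smartphone single-molecule
videos so every stage can be verified against ground truth.

## The quantities at the core

* **Weber contrast (SBR)** of a spot: `SBR = (S − B)/B`, with `S` the mean
  over an inner 6×6 px ROI and `B` the mean over the ring between it and an
  8×8 px outer ROI, on baseline-subtracted, frame-summed images.
* **Trace SNR**: `SNR = (S − B)/σ_S`, with `S`, `σ_S` the mean and SD of a
  molecule's intensity trace before its single-step photobleach and `B` the
  background after it.
* **Localization**: per-candidate maximum-likelihood fit of an integrated
  symmetric Gaussian under Poisson noise (5 parameters: x, y, photons,
  background, σ), precision by the Mortensen approximation
  `var = s_a²/N·(16/9 + 8π s_a² b/(N a²))`, `s_a² = σ² + a²/12`.
* **Distance metrology**: structures are clustered, aligned on their
  principal axes, pooled, and the axis histogram fit with a shared-σ double
  Gaussian `A₁N(µ₁,σ) + A₂N(µ₂,σ)`; reported width is `FWHM = 2.35σ`, and
  the resolution gain is `FWHM_PSF / FWHM_site`.
* **Kinetics**: mean imager dwell from linked localizations, using the fact
  that the frame count K of an exponential on-time obeys
  `P(K > k) ∝ exp(−k·Δt/τ)`, so `τ = −Δt / log(1 − 1/mean(K−1))` over
  events with K ≥ 2.
* **Digital bioassay**: each ~600 nm DNA-origami sensor is called
  `control` or `detected` from its count of resolvable spots (an extra
  DNA-PAINT site appears when the target RNA is captured), and the
  detection fraction gets a Wilson 95% interval.

## Worked example

Simulate a small smartphone acquisition of 8HB nanorulers (two docking
sites 256 nm apart), localize the green channel with 3-frame averaging,
drift-correct on the fiducials and measure the site separation:

```r
library(pocketpaint)

kin <- kinetics_model(event_rate = 0.03, photons_per_second_on = 1700)
sim <- simulate_paint_video("8HB", "smartphone", field_size_nm = 24000,
                            density = 20 / 576, n_frames = 4000, seed = 11,
                            kinetics = kin, drift = drift_preset_desktop(),
                            n_fiducials = 3, min_separation_nm = 3000,
                            edge_margin_nm = 2000)
tab <- localize_video(sim$stack, sim$camera$baseline, channel = "G",
                      pre_average_n = 3, sigma_init_px = 1.29)
dc  <- drift_correct(tab, smooth_window_frames = 25)
res <- nanoruler_distance(filter_photon_outliers(dc$table),
                          eps_nm = 300, min_pts = 30, bin_size_nm = 25)
res$fit
resolution_gain(1300, res$fit$fwhm)
```

```
<double_gaussian_fit> distance 249.1 nm, sigma 64.9 nm (FWHM 152.4 nm)
[1] 8.5
```

The fitted distance (here 249 nm from ~1100 binding events on 20
structures) recovers the 256 nm design separation of the nanoruler; the
shared σ of the two lobes is the effective localization precision of this
simulation, and dividing the 1300 nm PSF FWHM by the super-resolved site
FWHM gives the resolution gain. Larger simulated acquisitions (≥ 5000
events) push the distance estimate within a few nanometers of design; see
the test suite and acceptance script.

## Command-line use

A thin CLI wraps the same functions:

```sh
pocketpaint sim --design 8HB --preset smartphone --frames 4000 --seed 1 --out sim/
pocketpaint localize --stack sim/simulation.tif --baseline 64 --channel G --out locs.csv
pocketpaint drift --table locs.csv --out corrected.csv
pocketpaint distance --table corrected.csv --bin 25
pocketpaint bioassay --table sensors.csv --mode smartphone
```

See `vignettes/methods.Rmd` for the models, parameter choices and known
limitations.
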