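# Physical model descriptions used by the simulator and the analysis chain:
# camera, optics, DNA-PAINT kinetics, and stage drift.

BAYER_PATTERNS <- c("RGGB", "BGGR", "GRBG", "GBRG", "mono")

#' Camera model
#'
#' Describes the sensor of the recording device: pixel pitch projected on the
#' sample plane, Bayer color-filter layout, baseline offset, read noise, gain
#' and per-channel sensitivities for the simulated emission color.
#'
#' @param pixel_size_sample sensor (mosaic) pixel pitch on the sample plane, nm.
#' @param bayer_pattern one of `"RGGB"`, `"BGGR"`, `"GRBG"`, `"GBRG"`, `"mono"`.
#' @param baseline dark offset added to every pixel, counts.
#' @param read_noise_sd Gaussian read noise, counts (>= 0).
#' @param gain counts per photoelectron (> 0).
#' @param channel_sensitivity named vector `c(R=, G=, B=)` of relative quantum
#'   efficiencies in `[0, 1]` for the simulated dye emission (scalar for mono).
#' @param background_sensitivity like `channel_sensitivity` but for the diffuse
#'   background light, which generally has a different spectrum than the dye.
#' @param bit_depth ADC bit depth; saturation is `2^bit_depth - 1`.
#' @param frame_time exposure time of one frame, seconds.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(pixel_size_sample, bayer_pattern = "RGGB",
                         baseline = 64, read_noise_sd = 2, gain = 1,
                         channel_sensitivity = c(R = 0.45, G = 1, B = 0),
                         background_sensitivity = c(R = 0.85, G = 1, B = 0.1),
                         bit_depth = 16, frame_time = 0.25) {
  stopifnot_scalar(pixel_size_sample, "pixel_size_sample", positive = TRUE)
  stopifnot_scalar(read_noise_sd, "read_noise_sd")
  stopifnot_scalar(gain, "gain", positive = TRUE)
  stopifnot_scalar(frame_time, "frame_time", positive = TRUE)
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  bayer_pattern <- match.arg(bayer_pattern, BAYER_PATTERNS)
  if (bayer_pattern == "mono") {
    channel_sensitivity <- c(mono = unname(channel_sensitivity[1]))
    background_sensitivity <- c(mono = unname(background_sensitivity[1]))
  } else {
    channel_sensitivity <- channel_sensitivity[c("R", "G", "B")]
    background_sensitivity <- background_sensitivity[c("R", "G", "B")]
  }
  if (any(channel_sensitivity < 0 | channel_sensitivity > 1) ||
      any(background_sensitivity < 0 | background_sensitivity > 1)) {
    stop("channel sensitivities must lie in [0, 1]")
  }
  structure(list(
    pixel_size_sample = pixel_size_sample,
    bayer_pattern = bayer_pattern,
    baseline = baseline,
    read_noise_sd = read_noise_sd,
    gain = gain,
    channel_sensitivity = channel_sensitivity,
    background_sensitivity = background_sensitivity,
    bit_depth = as.integer(bit_depth),
    saturation = 2^bit_depth - 1,
    frame_time = frame_time
  ), class = "camera_model")
}

#' Optics model
#'
#' @param psf_fwhm point spread function full width at half maximum, nm.
#' @param name preset label.
#' @return an object of class `optics_model` with `psf_sigma = psf_fwhm / 2.35`.
#' @export
optics_model <- function(psf_fwhm, name = "custom") {
  stopifnot_scalar(psf_fwhm, "psf_fwhm", positive = TRUE)
  structure(list(psf_fwhm = psf_fwhm,
                 psf_sigma = psf_fwhm / FWHM_PER_SIGMA,
                 name = name),
            class = "optics_model")
}

#' DNA-PAINT kinetics model
#'
#' Transient docking-site binding (exponential dwell), fixed dyes that bleach
#' in a single step after an exponential waiting time, and always-on fiducial
#' markers.
#'
#' @param mean_dwell mean on-time of a transient binding event, seconds.
#' @param event_rate binding events per docking site per second.
#' @param bleach_mean_time mean single-step photobleaching time of fixed
#'   dyes, seconds.
#' @param photons_per_second_on detected photon flux of one emitter while on.
#' @param fiducial_flux_factor brightness of a fiducial marker relative to a
#'   single dye (gold nanoparticles scatter/luminesce far above one dye).
#' @return an object of class `kinetics_model`.
#' @export
kinetics_model <- function(mean_dwell = 1.05, event_rate = 0.04,
                           bleach_mean_time = 20,
                           photons_per_second_on = 1000,
                           fiducial_flux_factor = 25) {
  for (nm in c("mean_dwell", "event_rate", "bleach_mean_time",
               "photons_per_second_on", "fiducial_flux_factor")) {
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  }
  structure(list(mean_dwell = mean_dwell, event_rate = event_rate,
                 bleach_mean_time = bleach_mean_time,
                 photons_per_second_on = photons_per_second_on,
                 fiducial_flux_factor = fiducial_flux_factor),
            class = "kinetics_model")
}

#' Stage drift model
#'
#' Slow mechanical drift as a deterministic linear velocity plus an isotropic
#' per-frame random walk.
#'
#' @param linear_velocity length-2 vector (vx, vy), nm per second.
#' @param random_walk_sd per-axis random-walk step, nm per sqrt(frame).
#' @return an object of class `drift_model`.
#' @export
drift_model <- function(linear_velocity = c(0, 0), random_walk_sd = 0) {
  if (length(linear_velocity) != 2 || !all(is.finite(linear_velocity))) {
    stop("linear_velocity must be a finite length-2 vector")
  }
  stopifnot_scalar(random_walk_sd, "random_walk_sd")
  if (random_walk_sd < 0) stop("random_walk_sd must be >= 0")
  structure(list(linear_velocity = as.numeric(linear_velocity),
                 random_walk_sd = random_walk_sd),
            class = "drift_model")
}

#' Instrument presets
#'
#' `"smartphone"`: RGGB sensor, 215 nm mosaic pitch (so channel-split images
#' sample at 430 nm/px, about 3 px per 1.3 um PSF FWHM), 250 ms frames.
#' `"high_end"`: monochrome research camera, 108 nm/px, 100 ms frames,
#' 0.27 um PSF FWHM.
#'
#' @param preset `"smartphone"` or `"high_end"`.
#' @return a list with elements `camera` and `optics`.
#' @export
instrument_preset <- function(preset = c("smartphone", "high_end")) {
  preset <- match.arg(preset)
  if (preset == "smartphone") {
    list(camera = camera_model(pixel_size_sample = 215, bayer_pattern = "RGGB",
                               baseline = 64, read_noise_sd = 2, gain = 1,
                               bit_depth = 16, frame_time = 0.25),
         optics = optics_model(1300, name = "smartphone"))
  } else {
    list(camera = camera_model(pixel_size_sample = 108, bayer_pattern = "mono",
                               baseline = 100, read_noise_sd = 1.5, gain = 1,
                               channel_sensitivity = 1,
                               background_sensitivity = 1,
                               bit_depth = 16, frame_time = 0.1),
         optics = optics_model(270, name = "high_end"))
  }
}

#' Drift preset emulating a desktop acquisition
#'
#' Linear drift of ~3.5 um per hour plus a small random-walk component.
#'
#' @param direction_deg direction of the linear term, degrees.
#' @param random_walk_sd per-axis random-walk step, nm per sqrt(frame).
#' @return a `drift_model`.
#' @export
drift_preset_desktop <- function(direction_deg = 35, random_walk_sd = 1) {
  v <- 3500 / 3600  # nm per second
  a <- direction_deg * pi / 180
  drift_model(linear_velocity = v * c(cos(a), sin(a)),
              random_walk_sd = random_walk_sd)
}
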