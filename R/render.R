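# Forward camera model: turn an emission schedule into a raw Bayer video
# with shot noise, read noise, baseline, drift and ground truth.

# Per-pixel color labels of a mosaic frame.
bayer_color_mask <- function(n_r, n_c, pattern) {
  if (pattern == "mono") return(matrix("mono", n_r, n_c))
  quad <- switch(pattern,
    RGGB = matrix(c("R", "G", "G", "B"), 2, 2, byrow = TRUE),
    BGGR = matrix(c("B", "G", "G", "R"), 2, 2, byrow = TRUE),
    GRBG = matrix(c("G", "R", "B", "G"), 2, 2, byrow = TRUE),
    GBRG = matrix(c("G", "B", "R", "G"), 2, 2, byrow = TRUE))
  quad[cbind(rep((seq_len(n_r) - 1L) %% 2L + 1L, n_c),
             rep((seq_len(n_c) - 1L) %% 2L + 1L, each = n_r))] |>
    matrix(n_r, n_c)
}

sensitivity_mask <- function(n_r, n_c, pattern, sens) {
  cols <- bayer_color_mask(n_r, n_c, pattern)
  matrix(sens[cols], n_r, n_c)
}

# Cumulative drift trajectory: linear term + random-walk partial sums,
# anchored at zero for frame 1.
draw_drift_trajectory <- function(drift, n_frames, frame_time) {
  t <- (seq_len(n_frames) - 1) * frame_time
  if (is.null(drift)) drift <- drift_model()
  steps_x <- c(0, stats::rnorm(n_frames - 1, 0, drift$random_walk_sd))
  steps_y <- c(0, stats::rnorm(n_frames - 1, 0, drift$random_walk_sd))
  data.frame(frame = seq_len(n_frames),
             dx = drift$linear_velocity[1] * t + cumsum(steps_x),
             dy = drift$linear_velocity[2] * t + cumsum(steps_y))
}

#' Render an emission schedule into a raw camera video
#'
#' For each frame, emitter positions are shifted by the cumulative stage
#' drift; docking-event positions are additionally jittered uniformly within
#' the docking-site extent (one draw per binding event). Expected photons
#' are spread over pixels with an integrated (pixel-area-averaged) symmetric
#' Gaussian PSF of `sigma = FWHM / 2.35`. Per pixel, photoelectrons are
#' Poisson with mean `expectation x channel sensitivity of that pixel's
#' Bayer color`; counts are `gain x photoelectrons + baseline + Gaussian
#' read noise`, rounded and clipped to `[0, saturation]`.
#'
#' @param schedule an [simulate_schedule()] `emission_schedule`.
#' @param layout the `emitter_layout` the schedule was built from.
#' @param optics an [optics_model()].
#' @param camera a [camera_model()].
#' @param drift a [drift_model()] or `NULL` for no drift.
#' @param seed integer seed.
#' @param noise if `FALSE`, all noise terms (shot, read) and quantization are
#'   disabled and counts are exactly `gain x expectation + baseline`.
#' @param background_flux diffuse fluorescence background, photons per
#'   mosaic pixel per second (weighted per channel by the camera's
#'   `background_sensitivity`).
#' @return a `sim_video`: list with `stack` (a [mosaic_stack()]), `truth`
#'   (per event x frame: true position, expected photons), `drift`
#'   (the exact cumulative drift trajectory), `layout`, `optics`, `camera`.
#' @export
render_video <- function(schedule, layout, optics, camera, drift = NULL,
                         seed = NULL, noise = TRUE, background_flux = 0) {
  field <- attr(layout, "field_size")
  if (is.null(field)) stop("layout lacks a field_size attribute")
  px <- camera$pixel_size_sample
  n_r <- 2L * as.integer(ceiling(field[2] / px / 2))
  n_c <- 2L * as.integer(ceiling(field[1] / px / 2))
  n_fr <- schedule$n_frames
  sigma <- optics$psf_sigma
  w <- as.integer(ceiling(5 * sigma / px))
  sens <- sensitivity_mask(n_r, n_c, camera$bayer_pattern,
                           camera$channel_sensitivity)
  bg_sens <- sensitivity_mask(n_r, n_c, camera$bayer_pattern,
                              camera$background_sensitivity)
  with_seed(seed, {
    traj <- draw_drift_trajectory(drift, n_fr, schedule$frame_time)
    ev <- schedule$events
    # one binding-position jitter per event (uniform disc of diameter extent)
    ext <- layout$extent[match(ev$site, layout$site)]
    jit_r <- (ext / 2) * sqrt(stats::runif(nrow(ev)))
    jit_a <- stats::runif(nrow(ev), 0, 2 * pi)
    jitter <- cbind(jx = jit_r * cos(jit_a), jy = jit_r * sin(jit_a))
    jitter[ev$type != "docking", ] <- 0
    site_x <- layout$x[match(ev$site, layout$site)]
    site_y <- layout$y[match(ev$site, layout$site)]
    expo <- schedule$exposure
    i_ev <- match(expo$event, ev$event)
    truth <- data.frame(
      frame = expo$frame, event = expo$event, site = expo$site,
      structure = ev$structure[i_ev],
      type = ev$type[i_ev],
      x = site_x[i_ev] + jitter[i_ev, "jx"] + traj$dx[expo$frame],
      y = site_y[i_ev] + jitter[i_ev, "jy"] + traj$dy[expo$frame],
      photons = expo$photons)
    # counts are integer after quantization; integer storage halves memory
    frames <- if (noise) array(0L, c(n_r, n_c, n_fr)) else
      array(0, c(n_r, n_c, n_fr))
    bg_frame <- background_flux * schedule$frame_time * bg_sens
    by_frame <- split(seq_len(nrow(truth)), truth$frame)
    for (f in seq_len(n_fr)) {
      e_sig <- matrix(0, n_r, n_c)
      rows <- by_frame[[as.character(f)]]
      for (i in rows) {
        x <- truth$x[i]; y <- truth$y[i]
        rc <- as.integer(round(y / px)); cc <- as.integer(round(x / px))
        r0 <- max(1L, rc - w); r1 <- min(n_r, rc + w + 1L)
        c0 <- max(1L, cc - w); c1 <- min(n_c, cc + w + 1L)
        if (r0 > r1 || c0 > c1) next
        rr <- r0:r1; cs <- c0:c1
        gr <- gauss_int((rr - 1) * px, rr * px, y, sigma)
        gc <- gauss_int((cs - 1) * px, cs * px, x, sigma)
        e_sig[rr, cs] <- e_sig[rr, cs] + truth$photons[i] * outer(gr, gc)
      }
      expect <- e_sig * sens + bg_frame
      if (noise) {
        pe <- stats::rpois(length(expect), expect)
        counts <- camera$gain * pe + camera$baseline +
          stats::rnorm(length(expect), 0, camera$read_noise_sd)
        frames[, , f] <- as.integer(pmin(pmax(round(counts), 0),
                                         camera$saturation))
      } else {
        frames[, , f] <- pmin(camera$gain * expect + camera$baseline,
                              camera$saturation)
      }
    }
    # drift taking every emitter out of the field is a degenerate but legal
    # input: warn, don't fail
    if (nrow(layout) > 0 && n_fr > 1) {
      lx <- layout$x + traj$dx[n_fr]; ly <- layout$y + traj$dy[n_fr]
      if (all(lx < 0 | lx > n_c * px | ly < 0 | ly > n_r * px)) {
        warning("cumulative drift moved all emitters outside the field")
      }
    }
    stack <- mosaic_stack(frames, bayer_pattern = camera$bayer_pattern,
                          frame_time = schedule$frame_time,
                          bit_depth = camera$bit_depth,
                          pixel_size_nm = px, baseline = camera$baseline)
    structure(list(stack = stack, truth = truth, drift = traj,
                   layout = layout, optics = optics, camera = camera,
                   background_flux = background_flux),
              class = "sim_video")
  })
}

#' Simulate a dark (shutter-closed) stack
#'
#' Counts contain only the camera baseline and Gaussian read noise.
#'
#' @param camera a [camera_model()].
#' @param n_frames number of frames (>= 1).
#' @param n_rows,n_cols frame geometry in pixels.
#' @param seed integer seed.
#' @return a [mosaic_stack()].
#' @export
simulate_dark_stack <- function(camera, n_frames, n_rows = 64, n_cols = 64,
                                seed = NULL) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  with_seed(seed, {
    counts <- camera$baseline +
      stats::rnorm(n_rows * n_cols * n_frames, 0, camera$read_noise_sd)
    if (camera$read_noise_sd > 0) counts <- round(counts)
    frames <- array(pmin(pmax(counts, 0), camera$saturation),
                    c(n_rows, n_cols, n_frames))
    mosaic_stack(frames, bayer_pattern = camera$bayer_pattern,
                 frame_time = camera$frame_time, bit_depth = camera$bit_depth,
                 pixel_size_nm = camera$pixel_size_sample,
                 baseline = camera$baseline)
  })
}

#' Write a simulated dataset to disk
#'
#' Writes the video as a multi-page 16-bit TIFF, the ground truth as CSV and
#' all model parameters (plus the seed, if recorded) as a YAML sidecar.
#'
#' @param sim a `sim_video` from [render_video()].
#' @param dir output directory (created if missing).
#' @param name basename for the files.
#' @param seed seed to record in the sidecar.
#' @return the directory, invisibly.
#' @export
write_sim_dataset <- function(sim, dir, name = "simulation", seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_stack_tiff(sim$stack, file.path(dir, paste0(name, ".tif")))
  gt <- sim$truth[, c("frame", "site", "x", "y", "photons")]
  names(gt) <- c("frame", "site_id", "x_nm", "y_nm", "photons")
  utils::write.csv(gt, file.path(dir, paste0(name, "_truth.csv")),
                   row.names = FALSE)
  utils::write.csv(sim$drift, file.path(dir, paste0(name, "_drift.csv")),
                   row.names = FALSE)
  meta <- list(
    camera = unclass(sim$camera), optics = unclass(sim$optics),
    background_flux = sim$background_flux,
    design = attr(sim$layout, "design"),
    field_size_nm = as.numeric(attr(sim$layout, "field_size")),
    n_frames = n_frames(sim$stack), seed = seed)
  yaml::write_yaml(meta, file.path(dir, paste0(name, ".yaml")))
  invisible(dir)
}
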