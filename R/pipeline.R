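# High-level convenience wrappers chaining the simulator and the analysis
# modules the way a real acquisition is processed.

#' Simulate a DNA-PAINT acquisition end to end
#'
#' Builds a layout, draws the binding schedule and renders the raw video
#' for one of the instrument presets.
#'
#' @param design layout preset (see [make_layout()]).
#' @param preset `"smartphone"` or `"high_end"`.
#' @param field_size_nm field of view, nm.
#' @param density structures per square micrometer.
#' @param n_frames number of camera frames.
#' @param seed integer seed (all randomness derives from it).
#' @param kinetics a [kinetics_model()].
#' @param drift a [drift_model()] or `NULL`.
#' @param n_fiducials fiducial markers to add.
#' @param min_separation_nm minimum structure separation, nm.
#' @param background_flux diffuse background, photons/mosaic px/s.
#' @param ... forwarded to [make_layout()].
#' @return a `sim_video` (see [render_video()]) plus elements `schedule`
#'   and `preset`.
#' @export
simulate_paint_video <- function(design = "8HB",
                                 preset = c("smartphone", "high_end"),
                                 field_size_nm = 15000, density = 0.1,
                                 n_frames = 2000, seed = 1,
                                 kinetics = kinetics_model(),
                                 drift = NULL, n_fiducials = 0,
                                 min_separation_nm = 0,
                                 background_flux = 10, ...) {
  preset <- match.arg(preset)
  inst <- instrument_preset(preset)
  layout <- make_layout(design, field_size_nm, density, seed = seed,
                        n_fiducials = n_fiducials,
                        min_separation_nm = min_separation_nm, ...)
  duration <- n_frames * inst$camera$frame_time
  sched <- simulate_schedule(layout, kinetics, duration,
                             inst$camera$frame_time, seed = seed + 1L)
  sim <- render_video(sched, layout, inst$optics, inst$camera, drift = drift,
                      seed = seed + 2L, background_flux = background_flux)
  sim$schedule <- sched
  sim$preset <- preset
  sim
}

#' Preprocess and localize a simulated (or recorded) raw video
#'
#' Baseline subtraction, Bayer split, channel selection and MLE
#' localization with optional pre-averaging.
#'
#' @param stack a [mosaic_stack()].
#' @param baseline scalar baseline or dark `mosaic_stack`.
#' @param channel channel to analyze after splitting (`"G"` for the green
#'   dye on an RGGB sensor; `"mono"` for mono cameras).
#' @param pre_average_n frames to average before fitting.
#' @param box_px fitting box, odd.
#' @param threshold_k candidate threshold.
#' @param gain camera gain, counts per photoelectron.
#' @param sigma_init_px starting PSF sigma for the fits, channel pixels.
#' @return a [loc_table()].
#' @export
localize_video <- function(stack, baseline, channel = "G",
                           pre_average_n = 3, box_px = 7, threshold_k = 4,
                           gain = 1, sigma_init_px = NULL) {
  # split first, subtract second: avoids a full-size signed copy of the
  # mosaic video on long acquisitions
  chans <- split_bayer(stack, channels = channel)
  if (!channel %in% names(chans)) {
    stop(sprintf("channel %s not available for pattern %s", channel,
                 stack$bayer_pattern))
  }
  ch <- chans[[channel]]
  rm(chans)
  dark <- if (inherits(baseline, "mosaic_stack")) {
    split_bayer(baseline, channels = channel)[[channel]]
  } else baseline
  ch <- subtract_baseline(ch, dark)
  localize_stack(ch, box_px = box_px,
                 threshold_k = threshold_k, pre_average_n = pre_average_n,
                 gain = gain, sigma_init_px = sigma_init_px)
}

#' Drift-correct a localization table using its fiducials
#'
#' Finds fiducial tracks, estimates and applies the drift trajectory, and
#' masks the fiducials out of the corrected table.
#'
#' @param table a `loc_table`.
#' @param link_radius_nm fiducial linking radius, nm.
#' @param smooth_window_frames moving-average smoothing window, frames.
#' @param mask_radius_nm radius around each fiducial to exclude, nm.
#' @return list with `table` (corrected, fiducials masked), `trajectory`,
#'   `tracks`.
#' @export
drift_correct <- function(table, link_radius_nm = 500,
                          smooth_window_frames = 50, mask_radius_nm = 500) {
  tracks <- find_fiducials(table, link_radius_nm = link_radius_nm)
  if (length(tracks) == 0) {
    return(list(table = table, trajectory = NULL, tracks = tracks))
  }
  traj <- estimate_drift(tracks, smooth_window_frames)
  corrected <- apply_drift(table, traj)
  list(table = mask_fiducials(corrected, tracks, mask_radius_nm),
       trajectory = traj, tracks = tracks)
}

#' Measure the inter-site distance of nanoruler structures
#'
#' Clusters a (drift-corrected) localization table into structures, aligns
#' each on its principal axis, pools them and fits the shared-width double
#' Gaussian along the axis.
#'
#' @param table a `loc_table`.
#' @param eps_nm clustering distance, nm.
#' @param min_pts minimum localizations per structure.
#' @param bin_size_nm axis histogram bin size, nm.
#' @return list with `fit` (a `double_gaussian_fit`), `clusters`,
#'   `average` (output of [align_and_average()]).
#' @export
nanoruler_distance <- function(table, eps_nm = 300, min_pts = 30,
                               bin_size_nm = 25) {
  clusters <- cluster_structures(table, eps_nm = eps_nm, min_pts = min_pts)
  if (length(clusters) == 0) stop("no structures found")
  avg <- align_and_average(clusters, table, bin_size_nm = bin_size_nm)
  keep <- !avg$degenerate
  pooled <- avg$pooled[avg$pooled$cluster %in% which(keep), ]
  fit <- axis_profile_fit(pooled$x, bin_size_nm)
  list(fit = fit, clusters = clusters, average = avg)
}
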