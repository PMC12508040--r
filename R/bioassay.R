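# Digital bioassay caller: classify each origami sensor's super-resolved
# spot pattern as control (target RNA absent) or detected (target
# captured), and summarize the detection fraction.

#' Default sensor geometry and per-mode calling parameters
#'
#' The ~600 nm dimer sensor carries three control DNA-PAINT sites (both
#' ends of the A monomer plus the adjacent B-monomer site near the center)
#' and one target site at the far end. The two central control sites are
#' close enough to merge into one spot at smartphone resolution but are
#' resolved by a research-grade microscope, so a complete sensor shows 2
#' spots (control) / 3 spots (detected) in smartphone mode and 3 / 4 in
#' high-end mode.
#'
#' @param instrument_mode `"smartphone"` or `"high_end"`.
#' @return list with `fwhm_nm` (the mode's resolution), `merge_radius_nm`
#'   (average-linkage cut height used to merge localizations into spots,
#'   1.4 x FWHM: a single spot's localization cloud must stay in one piece
#'   while sites separated by more than the resolution stay apart),
#'   `control_spots`, `control_extent_nm` and `detected_extent_nm` gates.
#' @export
bioassay_mode_config <- function(instrument_mode = c("smartphone",
                                                     "high_end")) {
  instrument_mode <- match.arg(instrument_mode)
  if (instrument_mode == "smartphone") {
    list(fwhm_nm = 197, merge_radius_nm = 1.4 * 197, control_spots = 2L,
         control_extent_nm = c(200, 450), detected_extent_nm = c(400, 800))
  } else {
    list(fwhm_nm = 56, merge_radius_nm = 1.4 * 56, control_spots = 3L,
         control_extent_nm = c(200, 450), detected_extent_nm = c(400, 800))
  }
}

#' Classify one origami sensor from its localizations
#'
#' Localizations of a single clustered structure are grouped into resolvable
#' spots by average-linkage hierarchical clustering cut at the instrument
#' mode's resolution FWHM; spots with fewer than `min_pts` localizations
#' are discarded as noise. A sensor showing the mode's control spot count
#' is labeled `control`, one extra spot means `detected`, anything else is
#' rejected. A length sanity gate on the end-to-end extent of the spot
#' centers (scaled to the active-site span of each pattern) rejects
#' monomers and aggregates.
#'
#' @param locs data.frame with `x`, `y` (nm) for one structure (e.g. one
#'   cluster from [cluster_structures()]).
#' @param instrument_mode `"smartphone"` or `"high_end"`.
#' @param config calling parameters, see [bioassay_mode_config()].
#' @param min_pts minimum localizations per resolvable spot.
#' @param structure_id identifier copied into the call.
#' @return a `sensor_call`: list with `structure`, `n_spots`, `label`
#'   (`"control"`, `"detected"` or `"reject"`), `reason`, `spot_axis_nm`
#'   (spot positions along the sensor axis), `extent_nm`,
#'   `instrument_mode`.
#' @export
classify_sensor <- function(locs, instrument_mode = c("smartphone",
                                                      "high_end"),
                            config = bioassay_mode_config(instrument_mode),
                            min_pts = 4, structure_id = NA_integer_) {
  instrument_mode <- match.arg(instrument_mode)
  call_out <- function(n_spots, label, reason, axis = numeric(),
                       extent = NA_real_) {
    structure(list(structure = structure_id, n_spots = n_spots,
                   label = label, reason = reason, spot_axis_nm = axis,
                   extent_nm = extent, instrument_mode = instrument_mode),
              class = "sensor_call")
  }
  if (nrow(locs) < 2 * min_pts) {
    return(call_out(0L, "reject", "too few localizations"))
  }
  xy <- cbind(locs$x, locs$y)
  cl <- stats::cutree(stats::hclust(stats::dist(xy), method = "average"),
                      h = config$merge_radius_nm)
  sizes <- table(cl)
  spots <- as.integer(names(sizes)[sizes >= min_pts])
  if (length(spots) < 1) return(call_out(0L, "reject", "no resolvable spot"))
  centers <- t(vapply(spots, function(s) colMeans(xy[cl == s, , drop = FALSE]),
                      numeric(2)))
  n_spots <- nrow(centers)
  if (n_spots == 1) {
    return(call_out(1L, "reject", "single spot: geometry unresolved"))
  }
  extent <- max(stats::dist(centers))
  # spot coordinates along the sensor axis (principal axis of the centers)
  cc <- sweep(centers, 2, colMeans(centers))
  ax <- eigen(stats::cov(cc) + diag(1e-9, 2), symmetric = TRUE)$vectors[, 1]
  axis_pos <- sort(as.numeric(cc %*% ax))
  label <- if (n_spots == config$control_spots) "control"
           else if (n_spots == config$control_spots + 1L) "detected"
           else "reject"
  if (label == "reject") {
    return(call_out(n_spots, "reject", "unexpected spot count",
                    axis_pos, extent))
  }
  gate <- if (label == "control") config$control_extent_nm
          else config$detected_extent_nm
  if (extent < gate[1] || extent > gate[2]) {
    return(call_out(n_spots, "reject", "extent outside length gate",
                    axis_pos, extent))
  }
  call_out(n_spots, label, NA_character_, axis_pos, extent)
}

#' @export
print.sensor_call <- function(x, ...) {
  cat(sprintf("<sensor_call> structure %s: %d spot(s) -> %s (%s mode)\n",
              x$structure, x$n_spots, x$label, x$instrument_mode))
  invisible(x)
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = center - half, upper = center + half)
}

#' Detection fraction of a set of sensor calls
#'
#' `detected / (detected + control)` with a 95% Wilson score interval;
#' rejected sensors are excluded and reported separately.
#'
#' @param calls list of `sensor_call`s (or a character vector of labels).
#' @param conf confidence level of the score interval.
#' @return list with `fraction`, `ci` (Wilson interval), `n_detected`,
#'   `n_control`, `n_rejected`.
#' @export
detection_fraction <- function(calls, conf = 0.95) {
  labels <- if (is.character(calls)) calls else
    vapply(calls, function(x) x$label, character(1))
  n_det <- sum(labels == "detected")
  n_ctl <- sum(labels == "control")
  n_rej <- sum(labels == "reject")
  n <- n_det + n_ctl
  if (n == 0) stop("all sensors were rejected; no callable fraction")
  list(fraction = n_det / n, ci = wilson_interval(n_det, n, conf),
       n_detected = n_det, n_control = n_ctl, n_rejected = n_rej)
}
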