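# Emission schedules: when each site is "on" and how many photons each
# on-interval contributes to every camera frame.

#' Simulate an emission schedule for a layout
#'
#' Docking sites blink: waiting times between binding events are exponential
#' with mean `1/event_rate`, on-times exponential with mean `mean_dwell`.
#' Fixed dyes are on from t = 0 until a single exponential photobleaching
#' time, then off forever. Fiducials are on throughout and never bleach.
#' The expected photon count of an event in frame f is
#' `photon flux x overlap(on-interval, frame f)`.
#'
#' @param layout an [make_layout()] `emitter_layout`.
#' @param kinetics a [kinetics_model()].
#' @param duration acquisition length, seconds (> 0).
#' @param frame_time frame exposure, seconds (> 0).
#' @param seed integer seed.
#' @param bleach_times optional numeric vector of forced photobleaching times
#'   (seconds) for the fixed-dye sites in layout order, overriding the
#'   exponential draw; used for deterministic tests.
#' @return an `emission_schedule`: list with `events` (one row per
#'   on-interval: `event`, `site`, `structure`, `type`, `t_on`, `t_off`,
#'   `flux`), `exposure` (one row per event x frame with expected `photons`),
#'   `n_frames`, `frame_time`, `duration`.
#' @export
simulate_schedule <- function(layout, kinetics, duration, frame_time,
                              seed = NULL, bleach_times = NULL) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(frame_time, "frame_time", positive = TRUE)
  n_fr <- as.integer(ceiling(duration / frame_time))
  with_seed(seed, {
    ev <- list()
    dye_idx <- 0L
    for (i in seq_len(nrow(layout))) {
      type <- layout$type[i]
      flux <- kinetics$photons_per_second_on
      if (type == "fiducial") {
        flux <- flux * kinetics$fiducial_flux_factor
        ints <- data.frame(t_on = 0, t_off = duration)
      } else if (type == "fixed_dye") {
        dye_idx <- dye_idx + 1L
        tb <- if (!is.null(bleach_times) && dye_idx <= length(bleach_times)) {
          bleach_times[dye_idx]
        } else {
          stats::rexp(1, rate = 1 / kinetics$bleach_mean_time)
        }
        ints <- data.frame(t_on = 0, t_off = min(tb, duration))
      } else {  # docking
        t <- 0
        on <- numeric(0); off <- numeric(0)
        repeat {
          t <- t + stats::rexp(1, rate = kinetics$event_rate)
          if (t >= duration) break
          d <- stats::rexp(1, rate = 1 / kinetics$mean_dwell)
          on <- c(on, t); off <- c(off, min(t + d, duration))
          t <- t + d
        }
        ints <- data.frame(t_on = on, t_off = off)
      }
      if (nrow(ints) > 0) {
        ints$site <- layout$site[i]
        ints$structure <- layout$structure[i]
        ints$type <- type
        ints$flux <- flux
        ev[[length(ev) + 1L]] <- ints
      }
    }
    events <- do.call(rbind, ev)
    if (is.null(events)) {
      events <- data.frame(t_on = numeric(), t_off = numeric(),
                           site = integer(), structure = integer(),
                           type = character(), flux = numeric())
    }
    rownames(events) <- NULL
    events$event <- seq_len(nrow(events))
    events <- events[, c("event", "site", "structure", "type",
                         "t_on", "t_off", "flux")]
    exposure <- schedule_exposure(events, n_fr, frame_time)
    structure(list(events = events, exposure = exposure, n_frames = n_fr,
                   frame_time = frame_time, duration = duration,
                   kinetics = kinetics),
              class = "emission_schedule")
  })
}

# Expand on-intervals into per-frame expected photon counts.
schedule_exposure <- function(events, n_frames, frame_time) {
  out <- list()
  for (i in seq_len(nrow(events))) {
    f0 <- max(1L, as.integer(floor(events$t_on[i] / frame_time)) + 1L)
    f1 <- min(n_frames, as.integer(ceiling(events$t_off[i] / frame_time)))
    if (f1 < f0) next
    fr <- f0:f1
    ov <- pmax(0, pmin(events$t_off[i], fr * frame_time) -
                  pmax(events$t_on[i], (fr - 1) * frame_time))
    keep <- ov > 0
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      event = events$event[i], site = events$site[i],
      frame = fr[keep], photons = events$flux[i] * ov[keep])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(event = integer(), site = integer(),
                      frame = integer(), photons = numeric())
  }
  rownames(res) <- NULL
  res
}

#' @export
print.emission_schedule <- function(x, ...) {
  cat(sprintf("<emission_schedule> %d event(s), %d frame(s) of %.3g s\n",
              nrow(x$events), x$n_frames, x$frame_time))
  invisible(x)
}
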