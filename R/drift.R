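# Fiducial-based drift estimation and correction of localization tables.

# Greedy frame-to-frame nearest-neighbor linking of localizations into
# tracks. Returns an integer track id per table row.
link_localizations <- function(table, link_radius_nm, max_gap = 0) {
  n <- nrow(table)
  track <- integer(n)
  if (n == 0) return(track)
  tr_x <- numeric(0); tr_y <- numeric(0); tr_last <- integer(0)
  by_frame <- split(seq_len(n), table$frame)
  for (fr_name in names(by_frame)) {
    f <- as.integer(fr_name)
    idx <- by_frame[[fr_name]]
    active <- which(tr_last >= f - 1L - max_gap & tr_last < f)
    if (length(active) && length(idx)) {
      dmat <- sqrt(outer(table$x[idx], tr_x[active], `-`)^2 +
                   outer(table$y[idx], tr_y[active], `-`)^2)
      repeat {
        m <- which.min(dmat)
        if (!length(m) || dmat[m] >= link_radius_nm) break
        i <- (m - 1) %% nrow(dmat) + 1
        j <- (m - 1) %/% nrow(dmat) + 1
        track[idx[i]] <- active[j]
        tr_x[active[j]] <- table$x[idx[i]]
        tr_y[active[j]] <- table$y[idx[i]]
        tr_last[active[j]] <- f
        dmat[i, ] <- Inf
        dmat[, j] <- Inf
        if (all(!is.finite(dmat))) break
      }
    }
    new <- idx[track[idx] == 0L]
    for (i in new) {
      tr_x <- c(tr_x, table$x[i]); tr_y <- c(tr_y, table$y[i])
      tr_last <- c(tr_last, f)
      track[i] <- length(tr_x)
    }
  }
  track
}

#' Find fiducial tracks in a localization table
#'
#' Localizations are linked frame-to-frame by greedy nearest-neighbor
#' matching within `link_radius_nm` (ties go to the nearest neighbor; short
#' gaps up to `max_gap` frames are bridged). Tracks present in at least
#' `min_presence` of all frames and spanning at least 90% of the
#' acquisition are reported as fiducials — transient DNA-PAINT binding
#' events (~1 s dwell) can never satisfy the presence requirement.
#'
#' @param table a `loc_table`.
#' @param min_presence minimum fraction of frames with a localization.
#' @param link_radius_nm linking radius, nm.
#' @param max_gap frames a track may go undetected without being broken.
#' @return list of per-track data.frames (`frame`, `x`, `y`, `id`), with
#'   attribute `n_frames`; empty list when none qualify.
#' @export
find_fiducials <- function(table, min_presence = 0.8, link_radius_nm = 500,
                           max_gap = 5) {
  if (nrow(table) == 0) stop("localization table is empty")
  n_fr <- loc_attr(table, "n_frames")
  if (is.na(n_fr)) n_fr <- max(table$frame)
  track <- link_localizations(table, link_radius_nm, max_gap)
  out <- list()
  for (t_id in unique(track)) {
    rows <- which(track == t_id)
    frames <- table$frame[rows]
    span <- (max(frames) - min(frames) + 1) / n_fr
    if (length(unique(frames)) / n_fr >= min_presence && span >= 0.9) {
      df <- data.frame(frame = frames, x = table$x[rows], y = table$y[rows],
                       id = if (!is.null(table$id)) table$id[rows] else rows)
      out[[length(out) + 1L]] <- df[order(df$frame), , drop = FALSE]
    }
  }
  structure(out, n_frames = n_fr)
}

#' Estimate the drift trajectory from fiducial tracks
#'
#' Per frame, the mean over tracks of (position - the track's starting
#' position); gaps are linearly interpolated, the result is smoothed with a
#' centered moving average (window shrinking at the edges) and anchored to
#' (0, 0) at frame 1.
#'
#' @param tracks output of [find_fiducials()] (>= 1 track).
#' @param smooth_window_frames moving-average window, frames.
#' @param n_frames total frames; defaults to the tracks' attribute.
#' @return a `drift_trajectory` data.frame (`frame`, `dx`, `dy`), nm.
#' @export
estimate_drift <- function(tracks, smooth_window_frames = 50,
                           n_frames = attr(tracks, "n_frames")) {
  if (length(tracks) == 0) stop("no fiducial tracks supplied")
  grid <- seq_len(n_frames)
  rel <- vapply(tracks, function(tr) {
    dx <- stats::approx(tr$frame, tr$x - tr$x[1], xout = grid, rule = 2)$y
    dy <- stats::approx(tr$frame, tr$y - tr$y[1], xout = grid, rule = 2)$y
    c(dx, dy)
  }, numeric(2 * n_frames))
  rel <- matrix(rowMeans(rel), ncol = 2)
  h <- max(0L, as.integer(floor(smooth_window_frames / 2)))
  smooth_ma <- function(v) {
    vapply(grid, function(f) {
      mean(v[max(1, f - h):min(n_frames, f + h)])
    }, numeric(1))
  }
  dx <- smooth_ma(rel[, 1]); dy <- smooth_ma(rel[, 2])
  structure(data.frame(frame = grid, dx = dx - dx[1], dy = dy - dy[1]),
            class = c("drift_trajectory", "data.frame"))
}

#' Apply a drift correction to a localization table
#'
#' Subtracts the per-frame drift from every localization.
#'
#' @param table a `loc_table`.
#' @param trajectory a `drift_trajectory` whose length matches the table's
#'   frame count.
#' @return the corrected `loc_table` (provenance updated).
#' @export
apply_drift <- function(table, trajectory) {
  n_fr <- loc_attr(table, "n_frames")
  if (is.na(n_fr)) n_fr <- if (nrow(table)) max(table$frame) else 0L
  if (nrow(trajectory) != n_fr) {
    stop("trajectory length does not match the table's frame count")
  }
  out <- table
  if (nrow(out)) {
    out$x <- out$x - trajectory$dx[out$frame]
    out$y <- out$y - trajectory$dy[out$frame]
  }
  attr(out, "provenance") <- c(loc_attr(table, "provenance"), "apply_drift")
  out
}

#' Remove fiducial localizations from a table
#'
#' Masks a disc around every fiducial track center (centers recomputed from
#' the current, typically drift-corrected, table by record id).
#'
#' @param table a `loc_table`.
#' @param tracks fiducial tracks from [find_fiducials()].
#' @param radius_nm masking radius around each track center, nm.
#' @return the masked `loc_table`.
#' @export
mask_fiducials <- function(table, tracks, radius_nm = 500) {
  if (length(tracks) == 0) return(table)
  keep <- rep(TRUE, nrow(table))
  for (tr in tracks) {
    rows <- match(tr$id, table$id)
    rows <- rows[!is.na(rows)]
    cx <- if (length(rows)) mean(table$x[rows]) else mean(tr$x)
    cy <- if (length(rows)) mean(table$y[rows]) else mean(tr$y)
    keep <- keep & (sqrt((table$x - cx)^2 + (table$y - cy)^2) > radius_nm)
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "provenance") <- c(loc_attr(table, "provenance"),
                               "mask_fiducials")
  out
}
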