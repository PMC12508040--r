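# Single-molecule detectability metrics: spot detection, SBR (Weber
# contrast) with the exact inner/outer ROI geometry, intensity traces,
# photobleaching step detection and trace SNR.
#
# Continuous image coordinates are in pixel units: pixel (r, c) covers
# [r-1, r] x [c-1, c] and its center is (r - 0.5, c - 0.5).

#' Detect diffraction-limited spots in a single image
#'
#' The image is smoothed with a Gaussian of `sigma_px / sqrt(2)` (matched
#' filter for a PSF of width `sigma_px`); local maxima above
#' `median + threshold_k x MAD` of the smoothed image are kept. Maxima
#' closer than `min_separation_px` keep only the brightest (ties: smallest
#' row, then column). Centers are refined to the intensity-weighted centroid
#' of a 6x6 window.
#'
#' @param image 2D numeric matrix (typically baseline-subtracted).
#' @param sigma_px expected PSF sigma in pixels.
#' @param min_separation_px minimum distance between detections, pixels.
#' @param threshold_k MAD multiplier for the detection threshold.
#' @return data.frame with continuous `row`, `col` centers (pixel units) and
#'   the peak value `intensity`; zero rows if nothing is found.
#' @export
detect_spots <- function(image, sigma_px, min_separation_px = 5,
                         threshold_k = 5) {
  empty <- data.frame(row = numeric(), col = numeric(),
                      intensity = numeric())
  if (length(image) == 0) return(empty)
  sm <- gauss_blur(image, sigma_px / sqrt(2))
  thr <- stats::median(sm) + threshold_k * stats::mad(sm)
  cand <- which(sm > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  n_r <- nrow(image); n_c <- ncol(image)
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    nb <- sm[max(1, r - 1):min(n_r, r + 1), max(1, c - 1):min(n_c, c + 1)]
    sm[r, c] >= max(nb)
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  val <- sm[cand]
  ord <- order(-val, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]; val <- val[ord]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d <- sqrt((cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2)
      keep[j[d < min_separation_px]] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]; val <- val[keep]
  ref <- t(vapply(seq_len(nrow(cand)), function(i) {
    centroid_6x6(image, cand[i, 1], cand[i, 2])
  }, numeric(2)))
  out <- data.frame(row = ref[, 1], col = ref[, 2], intensity = val)
  out[order(out$row, out$col), , drop = FALSE]
}

# Intensity-weighted centroid of the 6x6 window around pixel (r, c),
# returned in continuous pixel coordinates (pixel center r - 0.5).
centroid_6x6 <- function(image, r, c) {
  rr <- max(1, r - 2):min(nrow(image), r + 3)
  cc <- max(1, c - 2):min(ncol(image), c + 3)
  w <- pmax(image[rr, cc, drop = FALSE], 0)
  if (sum(w) <= 0) return(c(r - 0.5, c - 0.5))
  c(sum((rr - 0.5) * rowSums(w)) / sum(w),
    sum((cc - 0.5) * colSums(w)) / sum(w))
}

# Inner (6x6) and outer (8x8) ROI row/col index ranges for a spot center.
sbr_roi_indices <- function(center) {
  a_r <- round(center[1]); a_c <- round(center[2])
  list(inner_r = (a_r - 2):(a_r + 3), inner_c = (a_c - 2):(a_c + 3),
       outer_r = (a_r - 3):(a_r + 4), outer_c = (a_c - 3):(a_c + 4))
}

#' Signal-to-background ratio (Weber contrast) of one spot
#'
#' `S` is the mean over an inner 6x6 px ROI, `B` the mean over the 28 pixels
#' of the surrounding 8x8 minus 6x6 ring, and `SBR = (S - B) / B`. Both ROIs
#' are anchored so their common center is the detected centroid rounded to
#' the nearest half-pixel grid. A spot whose outer ROI overlaps another
#' detected spot's outer ROI is excluded; a non-positive `B` makes the
#' metric undefined.
#'
#' By convention the image should be baseline-subtracted and, following the
#' acquisition recipe, the sum of the first few frames (see [sum_frames()]).
#'
#' @param image 2D numeric matrix.
#' @param center length-2 `(row, col)` continuous center, pixel units.
#' @param other_centers optional matrix/data.frame of other detected centers
#'   used for the overlap exclusion.
#' @return list with `sbr`, `S`, `B`, `excluded`, `reason`.
#' @export
compute_sbr <- function(image, center, other_centers = NULL) {
  center <- as.numeric(center)
  roi <- sbr_roi_indices(center)
  if (min(roi$outer_r) < 1 || max(roi$outer_r) > nrow(image) ||
      min(roi$outer_c) < 1 || max(roi$outer_c) > ncol(image)) {
    stop("outer 8x8 ROI extends beyond the image")
  }
  if (!is.null(other_centers)) {
    oc <- as.matrix(other_centers)
    for (i in seq_len(nrow(oc))) {
      if (all(abs(oc[i, 1:2] - center) < 1e-9)) next
      o <- sbr_roi_indices(oc[i, 1:2])
      if (max(roi$outer_r) >= min(o$outer_r) &&
          min(roi$outer_r) <= max(o$outer_r) &&
          max(roi$outer_c) >= min(o$outer_c) &&
          min(roi$outer_c) <= max(o$outer_c)) {
        return(list(sbr = NA_real_, S = NA_real_, B = NA_real_,
                    excluded = TRUE, reason = "outer ROI overlap"))
      }
    }
  }
  inner <- image[roi$inner_r, roi$inner_c]
  outer <- image[roi$outer_r, roi$outer_c]
  s <- mean(inner)
  b <- (sum(outer) - sum(inner)) / (length(outer) - length(inner))
  if (b <= 0) {
    return(list(sbr = NA_real_, S = s, B = b, excluded = TRUE,
                reason = "non-positive background"))
  }
  list(sbr = (s - b) / b, S = s, B = b, excluded = FALSE, reason = NA_character_)
}

#' Extract a single-spot intensity trace
#'
#' Per-frame mean over the pixels whose centers lie within 3 px of the spot
#' center (6-pixel-diameter circular ROI, pixel-center inclusion rule). No
#' time averaging is applied.
#'
#' @param stack a `channel_stack` or `mosaic_stack`.
#' @param center length-2 `(row, col)` continuous center, pixel units.
#' @return an `intensity_trace`: list with `values` (one per frame),
#'   `frame_time`, `center`, `n_pixels`.
#' @export
extract_trace <- function(stack, center) {
  center <- as.numeric(center)
  d <- dim(stack$frames)
  rr <- seq_len(d[1]); cc <- seq_len(d[2])
  inside <- outer((rr - 0.5 - center[1])^2, (cc - 0.5 - center[2])^2, `+`) < 9
  # the full disc must fit: if the bounding box of the 3 px circle leaves
  # the frame, the ROI is clipped
  if (center[1] - 3 < 0 || center[1] + 3 > d[1] ||
      center[2] - 3 < 0 || center[2] + 3 > d[2]) {
    stop("circular ROI clipped by the image border")
  }
  idx <- which(inside)
  vals <- vapply(seq_len(d[3]), function(f) mean(stack$frames[, , f][idx]),
                 numeric(1))
  ft <- if (!is.null(stack$frame_time)) stack$frame_time else NA_real_
  structure(list(values = vals, frame_time = ft, center = center,
                 n_pixels = length(idx)),
            class = "intensity_trace")
}

trace_values <- function(trace) {
  if (inherits(trace, "intensity_trace")) trace$values else as.numeric(trace)
}

#' Detect a single photobleaching step in a trace
#'
#' Exhaustive two-segment piecewise-constant fit: every split point is
#' scored by the total within-segment sum of squares and the best split is
#' accepted if the drop is at least 2 pooled standard deviations and goes
#' downward. Returns `NULL` when no acceptable step exists.
#'
#' @param trace an `intensity_trace` or numeric vector (>= 10 frames).
#' @return `NULL`, or a list with `step_frame` (first frame after the drop),
#'   `level_before`, `level_after`.
#' @export
detect_bleach_step <- function(trace) {
  v <- trace_values(trace)
  n <- length(v)
  if (n < 10) stop("need at least 10 frames to detect a bleaching step")
  splits <- 3:(n - 1)  # >= 2 frames in each segment
  sse <- vapply(splits, function(s) {
    pre <- v[1:(s - 1)]; post <- v[s:n]
    sum((pre - mean(pre))^2) + sum((post - mean(post))^2)
  }, numeric(1))
  s <- splits[which.min(sse)]
  pre <- v[1:(s - 1)]; post <- v[s:n]
  m1 <- mean(pre); m2 <- mean(post)
  pooled <- sqrt((sum((pre - m1)^2) + sum((post - m2)^2)) / (n - 2))
  drop_ok <- if (pooled > 0) (m1 - m2) / pooled >= 2 else m1 > m2
  if (!drop_ok || m1 <= m2) return(NULL)
  list(step_frame = s, level_before = m1, level_after = m2)
}

#' Signal-to-noise ratio of a single-molecule trace
#'
#' `SNR = (S - B) / sigma_S` where `S` and `sigma_S` are the mean and sample
#' standard deviation of the trace before the photobleaching step and `B`
#' is the time average of the background. By default the background is the
#' post-bleach trace segment; alternatively a separately extracted
#' background trace can be supplied.
#'
#' @param trace an `intensity_trace` or numeric vector.
#' @param step a step from [detect_bleach_step()] (required).
#' @param background_trace optional trace whose time average replaces the
#'   post-bleach background estimate.
#' @return list with `snr`, `S`, `sigma_S`, `B`, `undefined` (TRUE when the
#'   pre-bleach variance is zero).
#' @export
compute_snr <- function(trace, step, background_trace = NULL) {
  if (is.null(step)) stop("compute_snr requires a detected bleaching step")
  v <- trace_values(trace)
  s <- step$step_frame
  if (s - 1 < 5 || length(v) - s + 1 < 5) {
    stop("need at least 5 frames on each side of the step")
  }
  pre <- v[1:(s - 1)]
  sig <- stats::sd(pre)
  b <- if (is.null(background_trace)) mean(v[s:length(v)]) else
    mean(trace_values(background_trace))
  if (sig == 0) {
    return(list(snr = NA_real_, S = mean(pre), sigma_S = 0, B = b,
                undefined = TRUE))
  }
  list(snr = (mean(pre) - b) / sig, S = mean(pre), sigma_S = sig, B = b,
       undefined = FALSE)
}
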