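# Containers for image stacks: raw Bayer mosaic videos and the single-color
# channel stacks derived from them.

#' Raw mosaic stack
#'
#' A multi-frame raw sensor video. Frames are stored as a 3D array
#' `[row, col, frame]` of counts.
#'
#' @param frames 3D numeric array `[row, col, frame]` (a matrix is promoted
#'   to a single-frame stack).
#' @param bayer_pattern color-filter layout tag (see [camera_model()]).
#' @param frame_time frame exposure, seconds.
#' @param bit_depth ADC bit depth.
#' @param pixel_size_nm mosaic pixel pitch on the sample plane, nm.
#' @param baseline nominal dark offset in counts (metadata only).
#' @return an object of class `mosaic_stack`.
#' @export
mosaic_stack <- function(frames, bayer_pattern = "mono", frame_time = 1,
                         bit_depth = 16, pixel_size_nm = NA_real_,
                         baseline = NA_real_) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (length(dim(frames)) != 3L || dim(frames)[3] < 1L) {
    stop("frames must be a [row, col, frame] array with >= 1 frame")
  }
  bayer_pattern <- match.arg(bayer_pattern, BAYER_PATTERNS)
  structure(list(frames = frames, bayer_pattern = bayer_pattern,
                 frame_time = frame_time, bit_depth = as.integer(bit_depth),
                 pixel_size_nm = pixel_size_nm, baseline = baseline,
                 baseline_subtracted = FALSE),
            class = "mosaic_stack")
}

#' @export
print.mosaic_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<mosaic_stack> %d x %d px, %d frame(s), pattern %s, %.3g s/frame\n",
              d[1], d[2], d[3], x$bayer_pattern, x$frame_time))
  invisible(x)
}

#' Number of frames in a stack
#' @param x a `mosaic_stack` or `channel_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(x) dim(x$frames)[3]

#' Single-channel stack
#'
#' A stack of one color channel extracted from a mosaic video (or a mono
#' video passed through). Values may be signed after baseline subtraction.
#'
#' @param frames 3D numeric array `[row, col, frame]`.
#' @param channel channel label: `"R"`, `"G"`, `"B"`, `"G+R"` or `"mono"`.
#' @param frame_time original frame exposure, seconds.
#' @param effective_exposure seconds of integration represented by one output
#'   frame (`frame_time * frames averaged or summed`).
#' @param pixel_size_nm channel pixel pitch on the sample plane, nm.
#' @param origin_nm length-2 (x, y) offset of this channel's pixel grid with
#'   respect to the mosaic frame, nm. The half-pixel shifts between Bayer
#'   subsamples are tracked here so localizations from different channels
#'   share one coordinate frame.
#' @param provenance character vector of operations applied so far.
#' @return an object of class `channel_stack`.
#' @export
channel_stack <- function(frames, channel, frame_time,
                          effective_exposure = frame_time,
                          pixel_size_nm = NA_real_, origin_nm = c(0, 0),
                          provenance = character()) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  channel <- match.arg(channel, c("R", "G", "B", "G+R", "mono"))
  structure(list(frames = frames, channel = channel, frame_time = frame_time,
                 effective_exposure = effective_exposure,
                 pixel_size_nm = pixel_size_nm,
                 origin_nm = as.numeric(origin_nm),
                 provenance = provenance),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<channel_stack:%s> %d x %d px, %d frame(s), eff. exposure %.3g s\n",
    x$channel, d[1], d[2], d[3], x$effective_exposure))
  if (length(x$provenance)) cat(" ops:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Write a stack as a multi-page 16-bit TIFF
#'
#' One little-endian page per frame; counts are stored as 16-bit integers.
#'
#' @param stack a `mosaic_stack` or `channel_stack` (values must be
#'   non-negative).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  fr <- stack$frames
  if (min(fr) < 0) stop("cannot write signed values to 16-bit TIFF")
  pages <- lapply(seq_len(dim(fr)[3]), function(f) fr[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a mosaic stack
#'
#' @param path TIFF file (8- or 16-bit, one page per frame).
#' @inheritParams mosaic_stack
#' @return a `mosaic_stack`.
#' @export
read_stack_tiff <- function(path, bayer_pattern = "mono", frame_time = 1,
                            bit_depth = 16, pixel_size_nm = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  fr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]  # grayscale stored as RGB
    fr[, , f] <- pg * 65535
  }
  mosaic_stack(round(fr), bayer_pattern = bayer_pattern,
               frame_time = frame_time, bit_depth = bit_depth,
               pixel_size_nm = pixel_size_nm)
}
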