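# Raw mosaic preprocessing: baseline subtraction, Bayer channel splitting,
# outlier-pixel removal, frame averaging and summation.

#' Subtract the camera baseline
#'
#' Subtracts either a scalar baseline or the per-pixel temporal mean of a
#' dark stack from every frame. Negative values are preserved: downstream
#' SBR/SNR metrics are difference-based and clipping would bias them.
#'
#' @param stack a [mosaic_stack()] or [channel_stack()].
#' @param dark a stack of dark frames of the same type and geometry, or a
#'   scalar baseline in counts.
#' @return same type as `stack`, with signed values (mosaic stacks
#'   additionally get `baseline_subtracted = TRUE`).
#' @export
subtract_baseline <- function(stack, dark) {
  if (inherits(dark, c("mosaic_stack", "channel_stack"))) {
    if (!all(dim(dark$frames)[1:2] == dim(stack$frames)[1:2])) {
      stop("dark stack geometry does not match")
    }
    ref <- apply(dark$frames, c(1, 2), mean)
  } else {
    stopifnot_scalar(dark, "dark")
    ref <- matrix(dark, dim(stack$frames)[1], dim(stack$frames)[2])
  }
  out <- stack
  out$frames <- stack$frames - as.vector(ref)  # recycles over frames
  if (inherits(out, "mosaic_stack")) out$baseline_subtracted <- TRUE
  if (inherits(out, "channel_stack")) {
    out$provenance <- c(out$provenance, "subtract_baseline")
  }
  out
}

# Row/col parity of each color's subsample(s) for a 2x2 CFA quad.
bayer_quad <- function(pattern) {
  switch(pattern,
    RGGB = matrix(c("R", "G", "G", "B"), 2, 2, byrow = TRUE),
    BGGR = matrix(c("B", "G", "G", "R"), 2, 2, byrow = TRUE),
    GRBG = matrix(c("G", "R", "B", "G"), 2, 2, byrow = TRUE),
    GBRG = matrix(c("G", "B", "R", "G"), 2, 2, byrow = TRUE),
    stop("unknown Bayer pattern"))
}

#' Split a mosaic stack into color channels
#'
#' R and B channels are the corresponding quarter-resolution subsamples of
#' the 2x2 color-filter array; the G channel is the mean of the two green
#' subsamples so that all channels share one intensity scale. `"G+R"` is the
#' pixelwise sum of the G and R stacks. A mono stack passes through
#' unchanged as a single `"mono"` channel.
#'
#' Each channel records the sub-pixel offset of its sampling grid
#' (`origin_nm`) so localizations from different channels live in the same
#' sample-plane coordinates.
#'
#' @param stack a [mosaic_stack()] (even dimensions for a 2x2 CFA).
#' @param pattern CFA layout; defaults to the stack's own tag.
#' @param channels which channels to materialize (subset of `R`, `G`, `B`,
#'   `G+R`); `NULL` for all. Restricting this saves memory on long videos.
#' @return a named list of [channel_stack()]s: `R`, `G`, `B`, `G+R` (or
#'   `mono`).
#' @export
split_bayer <- function(stack, pattern = stack$bayer_pattern,
                        channels = NULL) {
  fr <- stack$frames
  d <- dim(fr)
  p <- stack$pixel_size_nm
  prov <- sprintf("split_bayer(%s)", pattern)
  if (pattern == "mono") {
    return(list(mono = channel_stack(fr, "mono", stack$frame_time,
                                     pixel_size_nm = p, origin_nm = c(0, 0),
                                     provenance = prov)))
  }
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
    stop("mosaic dimensions must be even for a 2x2 CFA")
  }
  quad <- bayer_quad(pattern)
  sub <- function(a, b) fr[seq(a, d[1], by = 2), seq(b, d[2], by = 2), ,
                           drop = FALSE]
  # nominal sub-pixel offset (in nm) of a subsample grid from the 2x2 block
  # centers: subsample at parity 1 sits half a mosaic pixel before the block
  # center, parity 2 half a pixel after
  p_off <- if (is.na(p)) 0 else p
  if (is.null(channels)) channels <- c("R", "G", "B", "G+R")
  want <- unique(c(channels, if ("G+R" %in% channels) c("G", "R")))
  chans <- list()
  for (col in intersect(c("R", "G", "B"), want)) {
    pos <- which(quad == col, arr.ind = TRUE)
    stacks <- lapply(seq_len(nrow(pos)), function(i) sub(pos[i, 1], pos[i, 2]))
    m <- Reduce(`+`, stacks) / length(stacks)
    o <- c(mean((pos[, 2] - 1.5) * p_off),   # x offset from col parity
           mean((pos[, 1] - 1.5) * p_off))   # y offset from row parity
    chans[[col]] <- channel_stack(m, col, stack$frame_time,
                                  pixel_size_nm = 2 * p,
                                  origin_nm = o, provenance = prov)
  }
  if ("G+R" %in% channels) {
    gr <- chans$G
    gr$frames <- chans$G$frames + chans$R$frames
    gr$channel <- "G+R"
    gr$provenance <- c(prov, "G+R sum")
    chans[["G+R"]] <- gr
  }
  chans[intersect(c("R", "G", "B", "G+R"), channels)]
}

#' Remove outlier (hot/cold) pixels
#'
#' Per frame, a pixel whose absolute deviation from the median of its
#' `(2 radius + 1)^2` neighborhood exceeds `k` times the scaled MAD of that
#' neighborhood is replaced by the neighborhood median; all other pixels are
#' untouched. Deterministic replacement for the despeckle step usually done
#' interactively in ImageJ-style tools.
#'
#' @param stack a `mosaic_stack`, `channel_stack`, or plain matrix.
#' @param radius neighborhood radius in pixels (>= 1).
#' @param k MAD multiplier (> 0).
#' @return same type as the input, with outliers replaced.
#' @export
remove_outlier_pixels <- function(stack, radius = 1, k = 5) {
  if (radius < 1) stop("radius must be >= 1")
  if (k <= 0) stop("k must be > 0")
  fix_frame <- function(m) {
    nb <- neighborhood_matrix(m, radius)
    med <- row_median(nb)
    mad <- 1.4826 * row_median(abs(nb - med))
    v <- as.vector(m)
    out <- ifelse(abs(v - med) > k * mad, med, v)
    matrix(out, nrow(m), ncol(m))
  }
  if (is.matrix(stack)) return(fix_frame(stack))
  out <- stack
  for (f in seq_len(dim(stack$frames)[3])) {
    out$frames[, , f] <- fix_frame(stack$frames[, , f])
  }
  if (inherits(out, "channel_stack")) {
    out$provenance <- c(out$provenance,
                        sprintf("remove_outlier_pixels(r=%d,k=%g)", radius, k))
  }
  out
}

#' Average non-overlapping blocks of frames
#'
#' Replaces each block of `n` consecutive frames by its mean; a trailing
#' partial block is dropped. The effective exposure per output frame becomes
#' `n x frame_time`.
#'
#' @param stack a `channel_stack` or `mosaic_stack`.
#' @param n frames per block (1 <= n <= total frames).
#' @return same type as the input with `floor(F / n)` frames.
#' @export
average_frames <- function(stack, n) {
  n <- as.integer(n)
  n_f <- dim(stack$frames)[3]
  if (n < 1) stop("n must be >= 1")
  if (n > n_f) stop("n exceeds the number of frames")
  n_out <- n_f %/% n
  d <- dim(stack$frames)
  out_fr <- array(0, c(d[1], d[2], n_out))
  for (b in seq_len(n_out)) {
    idx <- ((b - 1L) * n + 1L):(b * n)
    acc <- stack$frames[, , idx[1]]
    for (i in idx[-1]) acc <- acc + stack$frames[, , i]
    out_fr[, , b] <- acc / n
  }
  out <- stack
  out$frames <- out_fr
  if (inherits(out, "channel_stack")) {
    out$effective_exposure <- stack$effective_exposure * n
    out$provenance <- c(out$provenance, sprintf("average_frames(%d)", n))
  } else {
    out$effective_exposure <- stack$frame_time * n
  }
  out
}

#' Sum consecutive frames into one image
#'
#' Pixelwise sum of `k` frames starting at 0-based frame `start`; used to
#' virtually increase the exposure time before computing the SBR (e.g.,
#' 5 frames of 0.25 s give an effective exposure of 1.25 s).
#'
#' @param stack a `channel_stack` or `mosaic_stack`.
#' @param k number of frames to sum.
#' @param start 0-based index of the first frame.
#' @return a matrix of summed counts with attribute `effective_exposure`
#'   (seconds).
#' @export
sum_frames <- function(stack, k, start = 0) {
  n_f <- dim(stack$frames)[3]
  if (k < 1 || start < 0 || start + k > n_f) {
    stop("frame range [start, start + k) out of range")
  }
  acc <- stack$frames[, , start + 1L]
  for (i in seq_len(k - 1L)) acc <- acc + stack$frames[, , start + 1L + i]
  ft <- if (inherits(stack, "channel_stack")) stack$effective_exposure
        else stack$frame_time
  attr(acc, "effective_exposure") <- k * ft
  acc
}
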