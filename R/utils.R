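# Shared numerical helpers.

# Package-wide FWHM <-> sigma conversion for Gaussian profiles.
#' Conversion factor between Gaussian FWHM and standard deviation
#'
#' Fixed at 2.35 for the whole package, so that every reported FWHM equals
#' exactly 2.35 times the underlying sigma.
#' @export
FWHM_PER_SIGMA <- 2.35

#' Run code with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded simulator calls are bit-reproducible without clobbering the global
#' random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Integral of a unit-area 1D Gaussian over [lo, hi].
gauss_int <- function(lo, hi, mu, sigma) {
  stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma)
}

# Expected fraction of photons of an emitter at (x, y) nm landing in pixel
# (row r, col c) of a grid with pitch `px` nm (1-based indices; pixel (r, c)
# spans x in [(c-1) px, c px], y in [(r-1) px, r px]).
pixel_fraction <- function(rows, cols, x, y, px, sigma) {
  gauss_int((cols - 1) * px, cols * px, x, sigma) *
    gauss_int((rows - 1) * px, rows * px, y, sigma)
}

# Separable Gaussian blur with edge replication; sigma in pixels.
gauss_blur <- function(im, sigma) {
  if (sigma <= 0) return(im)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  blur_axis <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    out <- 0
    for (i in seq_along(k)) {
      s <- i - h - 1L
      idx <- pmin(pmax(seq_len(n) + s, 1L), n)
      out <- out + k[i] * (if (along_rows) m[idx, , drop = FALSE]
                           else m[, idx, drop = FALSE])
    }
    out
  }
  blur_axis(blur_axis(im, TRUE), FALSE)
}

# Stack the (2r+1)^2 neighborhood of every pixel (edge-replicated) as columns.
neighborhood_matrix <- function(m, radius) {
  n_r <- nrow(m); n_c <- ncol(m)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  out <- matrix(0, n_r * n_c, nrow(offs))
  for (i in seq_len(nrow(offs))) {
    ri <- pmin(pmax(seq_len(n_r) + offs$dr[i], 1L), n_r)
    ci <- pmin(pmax(seq_len(n_c) + offs$dc[i], 1L), n_c)
    out[, i] <- as.vector(m[ri, ci])
  }
  out
}

row_median <- function(m) apply(m, 1, stats::median)

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
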