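# Shared fixtures: all built in code at test time.

# Noise-free integrated-Gaussian ROI (pixel i covers [i-1, i]).
make_gauss_roi <- function(x, y, photons, background, sigma, box = 7) {
  ex <- stats::pnorm((1:box) - x, sd = sigma) -
    stats::pnorm((0:(box - 1)) - x, sd = sigma)
  ey <- stats::pnorm((1:box) - y, sd = sigma) -
    stats::pnorm((0:(box - 1)) - y, sd = sigma)
  photons * outer(ey, ex) + background
}

# Minimal localization table from bare coordinates.
make_table <- function(x, y, frame = seq_along(x), photons = 1000,
                       precision = 20, frame_time = 0.25,
                       n_frames = max(frame, 1L), pixel_size_nm = 430) {
  n <- length(x)
  loc_table(data.frame(frame = frame, x = x, y = y,
                       photons = rep_len(photons, n),
                       background = rep_len(1, n),
                       sigma = rep_len(550, n),
                       precision = rep_len(precision, n),
                       iterations = rep_len(1L, n),
                       converged = rep_len(TRUE, n)),
            pixel_size_nm = pixel_size_nm, frame_time = frame_time,
            n_frames = n_frames)
}

# Tiny mono camera for exact-arithmetic rendering tests.
mono_camera <- function(read_noise_sd = 0, baseline = 10, gain = 1,
                        pixel_size = 100, frame_time = 1) {
  camera_model(pixel_size, "mono", baseline = baseline,
               read_noise_sd = read_noise_sd, gain = gain,
               channel_sensitivity = 1, background_sensitivity = 1,
               frame_time = frame_time)
}

# Synthetic localization cloud of one dimer sensor (loc-table level):
# control sites always active, target site active when `target`.
simulate_sensor_locs <- function(target, precision_nm,
                                 geometry = c(0, 260, 340, 600),
                                 locs_per_site = 30, angle = 0,
                                 center = c(0, 0)) {
  sites <- if (target) geometry else geometry[-length(geometry)]
  n <- stats::rpois(length(sites), locs_per_site)
  n <- pmax(n, 5)
  u <- rep(sites, n) - mean(range(geometry))
  x0 <- u + stats::rnorm(sum(n), 0, precision_nm)
  y0 <- stats::rnorm(sum(n), 0, precision_nm)
  data.frame(x = center[1] + cos(angle) * x0 - sin(angle) * y0,
             y = center[2] + sin(angle) * x0 + cos(angle) * y0)
}

# Brute-force likelihood grid-search oracle for the MLE fitter: scans
# (x, y) on a regular grid, profiling photons and background at each grid
# point by vectorized 2-parameter Fisher scoring (sigma fixed).
grid_search_mle <- function(roi, sigma, x_range, y_range, step = 0.005) {
  box_r <- nrow(roi); box_c <- ncol(roi)
  xs <- seq(x_range[1], x_range[2], by = step)
  ys <- seq(y_range[1], y_range[2], by = step)
  ex <- vapply(xs, function(x) {
    stats::pnorm((1:box_c) - x, sd = sigma) -
      stats::pnorm((0:(box_c - 1)) - x, sd = sigma)
  }, numeric(box_c))
  ey <- vapply(ys, function(y) {
    stats::pnorm((1:box_r) - y, sd = sigma) -
      stats::pnorm((0:(box_r - 1)) - y, sd = sigma)
  }, numeric(box_r))
  yv <- as.vector(roi)
  best <- list(nll = Inf)
  n_tot <- sum(yv)
  for (j in seq_along(ys)) {
    # model matrix for all x grid points at this y: npx x nx
    Ey <- ey[, j]
    P <- apply(ex, 2, function(e) as.vector(outer(Ey, e)))
    Nv <- rep(max(n_tot - length(yv) * min(yv), 1), ncol(P))
    bv <- rep(max(min(yv), 1e-3), ncol(P))
    for (it in 1:40) {
      mu <- sweep(P, 2, Nv, `*`) + rep(bv, each = nrow(P))
      mu <- pmax(mu, 1e-12)
      r <- yv / mu - 1
      w <- 1 / mu
      gN <- colSums(P * r); gb <- colSums(r)
      iNN <- colSums(P^2 * w); ibb <- colSums(w); iNb <- colSums(P * w)
      det <- iNN * ibb - iNb^2
      dN <- (ibb * gN - iNb * gb) / det
      db <- (iNN * gb - iNb * gN) / det
      Nv <- pmax(Nv + dN, 1e-6)
      bv <- pmax(bv + db, 0)
    }
    mu <- pmax(sweep(P, 2, Nv, `*`) + rep(bv, each = nrow(P)), 1e-12)
    nll <- colSums(mu - yv * log(mu))
    i <- which.min(nll)
    if (nll[i] < best$nll) {
      best <- list(nll = nll[i], x = xs[i], y = ys[j], N = Nv[i], b = bv[i])
    }
  }
  best
}
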