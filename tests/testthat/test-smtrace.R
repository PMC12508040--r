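# Single-molecule detectability metrics.

test_that("detect_spots finds isolated spots and nothing in blank images", {
  img <- make_gauss_roi(10.5, 14.5, 2000, 0, 1.3, box = 31)
  det <- detect_spots(img, sigma_px = 1.3)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$row[1] - 14.5), 1)
  expect_lt(abs(det$col[1] - 10.5), 1)
  expect_equal(nrow(detect_spots(matrix(0, 20, 20), 1.3)), 0)
})

test_that("detect_spots recovers a field of dim spots (SBR ~ 1)", {
  set.seed(5)
  n <- 20
  grid <- expand.grid(r = seq(8, 68, by = 15), c = seq(8, 68, by = 15))
  pos <- grid[sample(nrow(grid), n), ] + matrix(runif(2 * n, -2, 2), n, 2)
  bg <- 50
  img <- matrix(bg, 76, 76)
  for (i in 1:n) {
    img <- img + make_gauss_roi(pos$c[i], pos$r[i], 36 * bg, 0, 1.3,
                                box = 76)
  }
  img <- matrix(rpois(length(img), img), 76, 76) - bg
  det <- detect_spots(img, sigma_px = 1.3, min_separation_px = 6,
                      threshold_k = 5)
  match_d <- vapply(seq_len(n), function(i) {
    if (nrow(det) == 0) return(Inf)
    min(sqrt((det$row - pos$r[i])^2 + (det$col - pos$c[i])^2))
  }, numeric(1))
  recall <- mean(match_d < 2)
  used <- vapply(seq_len(nrow(det)), function(j) {
    min(sqrt((pos$r - det$row[j])^2 + (pos$c - det$col[j])^2)) < 2
  }, logical(1))
  precision <- mean(used)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("compute_sbr implements the exact 6x6 / 8x8 ROI arithmetic", {
  flat <- matrix(3, 20, 20)
  expect_equal(compute_sbr(flat, c(10.5, 10.5))$sbr, 0)

  img <- matrix(100, 20, 20)
  roi <- pocketpaint:::sbr_roi_indices(c(10.5, 10.5))
  img[roi$inner_r, roi$inner_c] <- 200
  r <- compute_sbr(img, c(10.5, 10.5))
  expect_equal(r$sbr, 1.0)
  expect_equal(r$S, 200); expect_equal(r$B, 100)

  # brute-force oracle on a simulated noisy spot: exact agreement
  set.seed(9)
  spot <- matrix(rpois(400, make_gauss_roi(10.2, 9.8, 800, 20, 1.3,
                                           box = 20)), 20, 20)
  ctr <- c(9.8, 10.2)
  got <- compute_sbr(spot, ctr)
  a <- round(ctr)
  inner <- spot[(a[1] - 2):(a[1] + 3), (a[2] - 2):(a[2] + 3)]
  outer_px <- spot[(a[1] - 3):(a[1] + 4), (a[2] - 3):(a[2] + 4)]
  S <- mean(inner)
  B <- (sum(outer_px) - sum(inner)) / 28
  expect_equal(got$sbr, (S - B) / B, tolerance = 1e-12)

  # overlap exclusion and out-of-range errors
  two <- rbind(c(10.5, 10.5), c(10.5, 16.5))
  expect_true(compute_sbr(img, two[1, ], two)$excluded)
  big <- matrix(100, 30, 30)
  far <- rbind(c(10.5, 10.5), c(22.5, 22.5))
  expect_false(compute_sbr(big, far[1, ], far)$excluded)
  expect_error(compute_sbr(img, c(2, 2)), "beyond")
})

test_that("sbr is invariant under multiplicative gain", {
  set.seed(3)
  img <- matrix(rpois(400, make_gauss_roi(10.5, 10.5, 500, 30, 1.3,
                                          box = 20)), 20, 20)
  a <- compute_sbr(img, c(10.5, 10.5))$sbr
  b <- compute_sbr(img * 7.3, c(10.5, 10.5))$sbr
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("extract_trace uses the pixel-center circular ROI rule", {
  st <- channel_stack(array(4, c(20, 20, 5)), "G", 0.25)
  tr <- extract_trace(st, c(10.5, 10.5))
  expect_equal(tr$values, rep(4, 5))

  # single bright pixel: mean = v / (ROI pixel count), counted brute force
  fr <- array(0, c(20, 20, 1)); fr[10, 10, 1] <- 70
  st2 <- channel_stack(fr, "G", 0.25)
  ctr <- c(9.5, 9.5)
  n_in <- sum(outer((seq_len(20) - 0.5 - ctr[1])^2,
                    (seq_len(20) - 0.5 - ctr[2])^2, `+`) < 9)
  tr2 <- extract_trace(st2, ctr)
  expect_equal(tr2$n_pixels, n_in)
  expect_equal(tr2$values, 70 / n_in)
  expect_error(extract_trace(st, c(2, 10)), "clipped")

  # blinking emitter: on-frames clearly above off-frames
  on <- rep(c(TRUE, FALSE), each = 10)
  fr3 <- array(rpois(20 * 20 * 20, 2), c(20, 20, 20))
  for (f in which(on)) {
    fr3[, , f] <- fr3[, , f] +
      matrix(rpois(400, make_gauss_roi(10.5, 10.5, 600, 0, 1.3, box = 20)),
             20, 20)
  }
  tr3 <- extract_trace(channel_stack(fr3, "G", 0.25), c(10.5, 10.5))
  expect_gt(mean(tr3$values[on]), mean(tr3$values[!on]) + 3)
})

test_that("bleach step detection is exact on noiseless steps", {
  v <- c(rep(10, 49), rep(0, 51))
  st <- detect_bleach_step(v)
  expect_equal(st$step_frame, 50)
  expect_equal(st$level_before, 10)
  expect_equal(st$level_after, 0)
  expect_null(detect_bleach_step(rep(5, 50)))
  expect_null(detect_bleach_step(seq(0, 5, length.out = 60)))  # upward
  expect_error(detect_bleach_step(1:5), "at least 10")
})

test_that("noisy steps are localized within +/-2 frames in >=95% of runs", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    v <- c(rnorm(60, 20, 2), rnorm(40, 5, 2))
    st <- detect_bleach_step(v)
    !is.null(st) && abs(st$step_frame - 61) <= 2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("snr matches hand-computed sample statistics", {
  v <- c(rep(c(90, 110), 10), rep(50, 10))
  st <- list(step_frame = 21)
  r <- compute_snr(v, st)
  sd_pre <- stats::sd(rep(c(90, 110), 10))
  expect_equal(sd_pre, 10.2598, tolerance = 1e-4)
  expect_equal(r$snr, (100 - 50) / sd_pre, tolerance = 1e-12)
  expect_equal(r$snr, 4.87, tolerance = 0.01)

  flatpre <- c(rep(100, 20), rep(50, 10))
  expect_true(compute_snr(flatpre, st)$undefined)
  expect_error(compute_snr(v, NULL), "requires")
  expect_error(compute_snr(v, list(step_frame = 3)), "at least 5")
})

test_that("snr follows the square-root law on Poisson traces", {
  snrs <- vapply(1:100, function(s) {
    set.seed(s)
    v <- c(rpois(60, 400), rpois(40, 100))
    compute_snr(v, list(step_frame = 61))$snr
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 300 / 20) / (300 / 20), 0.15)
})

test_that("snr numerator is gain-invariant", {
  set.seed(1)
  v <- c(rnorm(30, 200, 10), rnorm(30, 20, 5))
  st <- detect_bleach_step(v)
  a <- compute_snr(v, st)
  b <- compute_snr(v * 3, detect_bleach_step(v * 3))
  expect_equal(b$S - b$B, 3 * (a$S - a$B), tolerance = 1e-9)
  expect_equal(b$snr, a$snr, tolerance = 1e-9)  # sd scales too
})

test_that("green channel beats red on SBR for a green dye (direction)", {
  inst <- instrument_preset("smartphone")
  ly <- make_layout("single", 16000, 6 / 256, seed = 31,
                    min_separation_nm = 4000, edge_margin_nm = 2500)
  kin <- kinetics_model(photons_per_second_on = 1700,
                        fiducial_flux_factor = 1)
  # fixed dyes so the first 5 frames are all "on"
  ly$type <- "fixed_dye"
  sc <- simulate_schedule(ly, kin, duration = 2.5, frame_time = 0.25,
                          seed = 32, bleach_times = rep(100, nrow(ly)))
  sim <- render_video(sc, ly, inst$optics, inst$camera, seed = 33,
                      background_flux = 10)
  sub <- subtract_baseline(sim$stack, inst$camera$baseline)
  chans <- split_bayer(sub)
  sbr_of <- function(ch) {
    img <- sum_frames(ch, 5)
    vapply(seq_len(nrow(ly)), function(i) {
      ctr <- c(ly$y[i] / ch$pixel_size_nm, ly$x[i] / ch$pixel_size_nm)
      compute_sbr(img, ctr)$sbr
    }, numeric(1))
  }
  expect_gt(stats::median(sbr_of(chans$G)), stats::median(sbr_of(chans$R)))
})
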