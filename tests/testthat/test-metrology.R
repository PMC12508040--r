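# Super-resolution metrology.

test_that("histogram rendering conserves counts with half-open bins", {
  one <- make_table(x = 101, y = 57, frame = 1)
  im <- render_histogram(one, 25)
  expect_equal(sum(im$counts), 1)
  expect_equal(dim(im$counts), c(1, 1))

  set.seed(1)
  tab <- make_table(x = runif(500, 0, 1000), y = runif(500, 0, 1000),
                    frame = rep(1, 500))
  im2 <- render_histogram(tab, 50)
  expect_equal(sum(im2$counts), 500)

  # uniform cloud: chi-square uniformity not rejected at alpha = 0.01
  set.seed(2)
  u <- make_table(x = runif(4000, 0, 800), y = runif(4000, 0, 800),
                  frame = rep(1, 4000))
  cts <- render_histogram(u, 100)$counts
  inner <- cts[2:7, 2:7]  # avoid partial edge bins
  p <- stats::chisq.test(as.vector(inner))$p.value
  expect_gt(p, 0.01)

  empty <- make_table(numeric(0), numeric(0), frame = integer(0),
                      n_frames = 1)
  expect_equal(dim(render_histogram(empty, 10)$counts), c(0, 0))
})

test_that("density clustering separates structures and flags noise", {
  set.seed(3)
  a <- cbind(rnorm(60, 0, 50), rnorm(60, 0, 50))
  b <- cbind(rnorm(60, 5000, 50), rnorm(60, 5000, 50))
  tab <- make_table(c(a[, 1], b[, 1]), c(a[, 2], b[, 2]),
                    frame = rep(1, 120))
  cl <- cluster_structures(tab, eps_nm = 200, min_pts = 10)
  expect_length(cl, 2)
  expect_setequal(lengths(cl), c(60, 60))

  expect_length(cluster_structures(make_table(numeric(0), numeric(0),
                                              frame = integer(0),
                                              n_frames = 1), 100), 0)
  dense <- make_table(runif(30, 0, 50), runif(30, 0, 50),
                      frame = rep(1, 30))
  expect_length(cluster_structures(dense, eps_nm = 100), 1)
})

test_that("alignment is rotation invariant and averages nanorulers", {
  set.seed(4)
  ruler <- function(angle, center) {
    u <- c(rnorm(80, -128, 40), rnorm(80, 128, 40))
    v <- rnorm(160, 0, 40)
    cbind(center[1] + u * cos(angle) - v * sin(angle),
          center[2] + u * sin(angle) + v * cos(angle))
  }
  r0 <- ruler(0, c(0, 0))
  tab0 <- make_table(r0[, 1], r0[, 2], frame = rep(1, 160))
  cl0 <- cluster_structures(tab0, 300, 10)
  av0 <- align_and_average(cl0, tab0, bin_size_nm = 25)

  # identical cluster rotated by 37 degrees gives the same aligned cloud
  th <- 37 * pi / 180
  r37 <- cbind(r0[, 1] * cos(th) - r0[, 2] * sin(th),
               r0[, 1] * sin(th) + r0[, 2] * cos(th))
  tab37 <- make_table(r37[, 1], r37[, 2], frame = rep(1, 160))
  av37 <- align_and_average(cluster_structures(tab37, 300, 10), tab37,
                            bin_size_nm = 25)
  # compare binned renderings on a common grid
  grid_of <- function(av) {
    h <- graphics::hist(av$pooled$x, breaks = seq(-400, 400, 25),
                        plot = FALSE)$counts
  }
  expect_gt(stats::cor(grid_of(av0), grid_of(av37)), 0.99)

  # ten rulers at random angles pool into a two-lobe profile
  rows <- list()
  for (i in 1:10) {
    rows[[i]] <- ruler(runif(1, 0, pi), c(i * 5000, 0))
  }
  all10 <- do.call(rbind, rows)
  tab10 <- make_table(all10[, 1], all10[, 2], frame = rep(1, nrow(all10)))
  cl10 <- cluster_structures(tab10, 300, 10)
  expect_length(cl10, 10)
  av10 <- align_and_average(cl10, tab10, bin_size_nm = 25)
  fit <- axis_profile_fit(av10$pooled$x, 25)
  expect_lt(abs(fit$distance - 256), 15)
})

test_that("double-Gaussian axis fit recovers the generator parameters", {
  # two delta trains at +/-128 nm smeared by sigma = 84 nm
  set.seed(5)
  n <- 6000
  x <- c(rnorm(n / 2, -128, 84), rnorm(n / 2, 128, 84))
  fit <- axis_profile_fit(x, 25)
  se_mu <- 84 / sqrt(n / 2)
  expect_lt(abs(fit$distance - 256), 3 * sqrt(2) * se_mu)
  se_s <- 84 / sqrt(2 * n)
  expect_lt(abs(fit$sigma - 84), 3 * se_s + 2)  # + binning allowance
  # FWHM identity, exact: sigma 84 -> 197.4
  expect_equal(fit$fwhm, 2.35 * fit$sigma)

  # unimodal input with means forced equal: distance exactly 0, width kept
  set.seed(6)
  x1 <- rnorm(3000, 0, 60)
  fit1 <- axis_profile_fit(x1, 20, force_equal_means = TRUE)
  expect_equal(fit1$distance, 0)
  expect_lt(abs(fit1$sigma - 60) / 60, 0.1)
})

test_that("axis distance is invariant under table rotation/translation", {
  set.seed(7)
  u <- c(rnorm(400, -128, 50), rnorm(400, 128, 50))
  v <- rnorm(800, 0, 50)
  d0 <- axis_profile_fit(u, 25)$distance
  for (th in c(0.4, 1.2)) {
    x <- 3000 + u * cos(th) - v * sin(th)
    y <- -2000 + u * sin(th) + v * cos(th)
    tab <- make_table(x, y, frame = rep(1, 800))
    av <- align_and_average(cluster_structures(tab, 300, 10), tab, 25)
    expect_lt(abs(axis_profile_fit(av$pooled$x, 25)$distance - d0), 25)
  }
})

test_that("PSF width fit reproduces known widths and scales linearly", {
  # sigma = 110 nm on a 10 nm grid: omega = 220 nm, FWHM = 258.5 nm
  img <- make_gauss_roi(20.5, 20.5, 1e5, 10, 11, box = 41)
  psf <- fit_psf_fwhm(img, pixel_size_nm = 10)
  expect_equal(psf$omega_nm, 220, tolerance = 0.5)
  expect_equal(psf$fwhm_nm, 258.5, tolerance = 0.5)

  img2 <- make_gauss_roi(20.5, 20.5, 1e5, 10, 22, box = 41)
  psf2 <- fit_psf_fwhm(img2, pixel_size_nm = 10)
  expect_equal(psf2$fwhm_nm / psf$fwhm_nm, 2, tolerance = 0.01)
})

test_that("resolution gain reproduces the printed ratios", {
  expect_equal(resolution_gain(1300, 197), 6.6)
  expect_equal(resolution_gain(270, 56), 4.8)
  expect_equal(resolution_gain(500, 500), 1.0)
  expect_error(resolution_gain(-1, 5), "> 0")
})

test_that("NeNa recovers injected precision and reacts to nonspecific noise", {
  set.seed(8)
  n_fr <- 600
  pts <- cbind(rep(c(1000, 4000, 7000), each = 1), rep(4000, 3))
  rows <- list()
  for (f in seq_len(n_fr)) {
    rows[[f]] <- data.frame(frame = f,
                            x = pts[, 1] + rnorm(3, 0, 50),
                            y = pts[, 2] + rnorm(3, 0, 50))
  }
  df <- do.call(rbind, rows)
  tab <- make_table(df$x, df$y, frame = df$frame, n_frames = n_fr)
  s <- nena_precision(tab, cap_nm = 1000)
  expect_lt(abs(s - 50) / 50, 0.1)

  # zero noise: estimate collapses below bin resolution
  df0 <- df; df0$x <- rep(pts[, 1], n_fr); df0$y <- rep(pts[, 2], n_fr)
  tab0 <- make_table(df0$x, df0$y, frame = df0$frame, n_frames = n_fr)
  expect_lt(nena_precision(tab0, cap_nm = 1000), 5)

  # uniform nonspecific localizations can only inflate the estimate
  set.seed(9)
  extra <- data.frame(frame = sample(n_fr, 1200, TRUE),
                      x = runif(1200, 0, 8000), y = runif(1200, 0, 8000))
  both <- rbind(df, extra)
  tabn <- make_table(both$x, both$y, frame = both$frame, n_frames = n_fr)
  expect_gte(nena_precision(tabn, cap_nm = 1000), s)
})

test_that("binding-time estimator handles degenerate and scaled inputs", {
  # all events exactly 4 frames at 0.25 s: degenerate, mean duration 1 s
  rows <- do.call(rbind, lapply(1:60, function(i) {
    data.frame(frame = (i * 10):(i * 10 + 3), x = i * 2000, y = 1000)
  }))
  tab <- make_table(rows$x, rows$y, frame = rows$frame,
                    n_frames = max(rows$frame), frame_time = 0.25)
  expect_equal(as.numeric(estimate_binding_time(tab, 300)), 1.0)

  # doubling the frame time doubles the estimate
  tab2 <- make_table(rows$x, rows$y, frame = rows$frame,
                     n_frames = max(rows$frame), frame_time = 0.5)
  expect_equal(as.numeric(estimate_binding_time(tab2, 300)), 2.0)
})

test_that("binding-time estimator is consistent for exponential dwells", {
  # exact frame-touch counts for exponential on-times, uniform phases
  set.seed(10)
  n_ev <- 4000
  dt <- 0.25
  dur <- rexp(n_ev, 1 / 1.05)
  phase <- runif(n_ev, 0, dt)
  k <- floor((dur + phase) / dt) + 1
  # lay events out far apart so linking cannot confuse them
  rows <- do.call(rbind, lapply(seq_len(n_ev), function(i) {
    f0 <- (i - 1) * 40 + 1
    data.frame(frame = f0:(f0 + k[i] - 1),
               x = 1000 + rnorm(k[i], 0, 60), y = 1000 + rnorm(k[i], 0, 60))
  }))
  tab <- make_table(rows$x, rows$y, frame = rows$frame,
                    n_frames = max(rows$frame), frame_time = dt)
  est <- estimate_binding_time(tab, link_radius_nm = 500)
  se <- 1.05 / sqrt(sum(k >= 2))
  expect_lt(abs(est - 1.05), 3 * se)
})
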