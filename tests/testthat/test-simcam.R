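# Synthetic video generator: layouts, schedules, rendering, dark frames.

test_that("layout presets place the documented geometries", {
  # 8HB nanoruler: two docking sites 256 nm apart, any orientation
  ly <- make_layout("8HB", 10000, density = 1 / 100, seed = 2)
  expect_equal(nrow(ly), 2)
  expect_equal(sqrt(diff(ly$x)^2 + diff(ly$y)^2), 256)
  expect_true(all(ly$extent == 28))

  # 2LS: second fixed dye 22 nm away when requested
  ly2 <- make_layout("2LS", 10000, 1 / 100, seed = 3, two_dyes = TRUE)
  expect_equal(nrow(ly2), 2)
  expect_equal(sqrt(diff(ly2$x)^2 + diff(ly2$y)^2), 22)
  expect_true(all(ly2$type == "fixed_dye"))

  # dimer sensor spans ~600 nm end to end with one target site
  ly3 <- make_layout("dimer_sensor", 10000, 1 / 100, seed = 4)
  expect_equal(nrow(ly3), 4)
  expect_equal(max(dist(cbind(ly3$x, ly3$y))), 600, tolerance = 1e-9)
  expect_equal(sum(ly3$role == "target"), 1)
})

test_that("layout generation is seeded, bounded, and validates input", {
  a <- make_layout("8HB", 20000, 0.05, seed = 7, n_fiducials = 2)
  b <- make_layout("8HB", 20000, 0.05, seed = 7, n_fiducials = 2)
  expect_identical(a, b)
  expect_true(all(a$x >= 0 & a$x <= 20000 & a$y >= 0 & a$y <= 20000))

  empty <- make_layout("8HB", 20000, 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(make_layout("nope", 20000, 0.1), "should be one of")
  expect_error(make_layout("8HB", 200, 1000, seed = 1), "too small")
})

test_that("schedules obey the kinetics contracts", {
  kin <- kinetics_model()
  ly <- make_layout("single", 5000, 0, seed = 1, n_fiducials = 1)
  sc <- simulate_schedule(ly, kin, duration = 10, frame_time = 0.5, seed = 2)
  # fiducial: on-fraction 1 in every frame
  expo <- sc$exposure
  expect_equal(nrow(expo), sc$n_frames)
  expect_equal(expo$photons,
               rep(kin$photons_per_second_on * kin$fiducial_flux_factor * 0.5,
                   sc$n_frames))
  expect_error(simulate_schedule(ly, kin, duration = -1, frame_time = 0.5),
               "> 0")
  expect_error(simulate_schedule(ly, kin, duration = 1, frame_time = 0),
               "> 0")
})

test_that("a forced bleach draw turns a fixed dye off at the given time", {
  ly <- make_layout("2LS", 5000, 1 / 25, seed = 1)
  kin <- kinetics_model()
  sc <- simulate_schedule(ly, kin, duration = 20, frame_time = 1, seed = 2,
                          bleach_times = 10)
  expo <- sc$exposure
  flux <- kin$photons_per_second_on
  expect_equal(sort(expo$frame), 1:10)
  expect_equal(expo$photons, rep(flux, 10))
})

test_that("docking on-times recover the mean dwell (law of large numbers)", {
  kin <- kinetics_model(event_rate = 0.5)
  ly <- make_layout("single", 5000, 1 / 25, seed = 3)
  sc <- simulate_schedule(ly, kin, duration = 7500, frame_time = 0.25,
                          seed = 4)
  ev <- sc$events[sc$events$type == "docking", ]
  # drop intervals clipped by the acquisition end
  dur <- (ev$t_off - ev$t_on)[ev$t_off < sc$duration]
  expect_gt(length(dur), 2000)
  se <- stats::sd(dur) / sqrt(length(dur))
  expect_lt(abs(mean(dur) - 1.05), 3 * se)
})

test_that("renderer: dark limit, photon conservation, determinism", {
  cam <- mono_camera(read_noise_sd = 2, baseline = 50)
  # zero flux -> counts are baseline within 3 SE of the read noise
  ly0 <- make_layout("single", 1600, 0, seed = 1)
  sc0 <- simulate_schedule(ly0, kinetics_model(), 3, 1, seed = 2)
  dark <- render_video(sc0, ly0, optics_model(270), cam, seed = 3)
  n_px <- length(dark$stack$frames)
  expect_lt(abs(mean(dark$stack$frames) - 50), 3 * 2 / sqrt(n_px) + 0.5)

  # photon conservation with noise off: one always-on emitter well inside
  # the field
  ly <- make_layout("2LS", 3000, 1 / 9, seed = 5, edge_margin_nm = 700)
  kin <- kinetics_model(photons_per_second_on = 500)
  sc <- simulate_schedule(ly, kin, 3, 1, seed = 6, bleach_times = 100)
  cam2 <- mono_camera(baseline = 10, gain = 2)
  sim <- render_video(sc, ly, optics_model(270), cam2, seed = 7,
                      noise = FALSE)
  for (f in 1:3) {
    tot <- sum(sim$stack$frames[, , f] - 10)
    expect_lt(abs(tot - 2 * 500) / (2 * 500), 1e-3)  # 0.1% PSF truncation
  }

  # bit-identical outputs under the same seed
  s1 <- render_video(sc, ly, optics_model(270), cam, seed = 11)
  s2 <- render_video(sc, ly, optics_model(270), cam, seed = 11)
  expect_identical(s1$stack$frames, s2$stack$frames)
})

test_that("rendered smartphone spot has the preset PSF width", {
  inst <- instrument_preset("smartphone")
  ly <- make_layout("single", 8000, 0, seed = 5, n_fiducials = 1)
  kin <- kinetics_model(photons_per_second_on = 20000,
                        fiducial_flux_factor = 1)
  sc <- simulate_schedule(ly, kin, 5, 0.25, seed = 6)
  sim <- render_video(sc, ly, inst$optics, inst$camera, seed = 7)
  g <- split_bayer(subtract_baseline(sim$stack, inst$camera$baseline))$G
  img <- sum_frames(g, dim(g$frames)[3])
  psf <- fit_psf_fwhm(img, pixel_size_nm = g$pixel_size_nm)
  expect_lt(abs(psf$fwhm_nm - 1300) / 1300, 0.1)
})

test_that("exported drift trajectory is exactly linear + random-walk sums", {
  dm <- drift_model(linear_velocity = c(1, -0.5), random_walk_sd = 2)
  ly <- make_layout("single", 1600, 0, seed = 1)
  sc <- simulate_schedule(ly, kinetics_model(), 5, 0.5, seed = 2)
  sim <- render_video(sc, ly, optics_model(270), mono_camera(),
                      drift = dm, seed = 42)
  tr <- sim$drift
  expect_equal(tr$dx[1], 0)
  expect_equal(tr$dy[1], 0)
  t <- (tr$frame - 1) * 0.5
  rw_x <- tr$dx - 1 * t
  rw_y <- tr$dy - (-0.5) * t
  # random-walk part must be a cumulative sum starting at 0 with iid steps
  expect_equal(rw_x[1], 0)
  steps <- diff(rw_x)
  expect_equal(cumsum(c(0, steps)), rw_x)
  expect_true(stats::sd(c(diff(rw_x), diff(rw_y))) < 3 * 2)
})

test_that("dark stacks are baseline plus read noise and seeded", {
  cam <- mono_camera(read_noise_sd = 0, baseline = 64)
  d0 <- simulate_dark_stack(cam, 3, 8, 8, seed = 1)
  expect_true(all(d0$frames == 64))

  cam2 <- mono_camera(read_noise_sd = 3, baseline = 64)
  d1 <- simulate_dark_stack(cam2, 50, 16, 16, seed = 2)
  se <- 3 / sqrt(length(d1$frames))
  expect_lt(abs(mean(d1$frames) - 64), 3 * se + 0.2)  # + rounding margin
  d2 <- simulate_dark_stack(cam2, 50, 16, 16, seed = 2)
  expect_identical(d1$frames, d2$frames)
  expect_error(simulate_dark_stack(cam2, 0), ">= 1")
})

test_that("simulated datasets round-trip through TIFF/CSV/YAML", {
  dir <- withr::local_tempdir()
  ly <- make_layout("single", 1600, 0, seed = 1, n_fiducials = 1)
  sc <- simulate_schedule(ly, kinetics_model(photons_per_second_on = 200,
                                             fiducial_flux_factor = 1),
                          3, 1, seed = 2)
  sim <- render_video(sc, ly, optics_model(270), mono_camera(read_noise_sd = 1),
                      seed = 3)
  write_sim_dataset(sim, dir, name = "demo", seed = 3)
  back <- read_stack_tiff(file.path(dir, "demo.tif"), frame_time = 1)
  expect_equal(back$frames, sim$stack$frames + 0, tolerance = 1e-9)
  gt <- read.csv(file.path(dir, "demo_truth.csv"))
  expect_equal(nrow(gt), nrow(sim$truth))
  meta <- yaml::read_yaml(file.path(dir, "demo.yaml"))
  expect_equal(meta$seed, 3)
})
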