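test_that("trajectory CSV loads with unit normalisation", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(particle_id = rep(1:2, each = 4),
                   t = rep(c(0, 0.5, 1, 1.5), 2),
                   y = c(20, 30, 45, 60, 150, 140, 120, 100))
  write.csv(df, f, row.names = FALSE)
  trajs <- load_trajectories(f, t_unit = "s", y_unit = "um")
  expect_length(trajs, 2)
  expect_equal(trajs[[1]]$y, c(20, 30, 45, 60) * 1e-6)
  # pixel-space file: positions scale by the pixel size
  trajs_px <- load_trajectories(f, y_unit = "px", pixel_size_um = 1.63)
  expect_equal(trajs_px[[1]]$y, c(20, 30, 45, 60) * 1.63e-6)
  # millisecond time stamps
  df$t <- df$t * 1000
  write.csv(df, f, row.names = FALSE)
  trajs_ms <- load_trajectories(f, t_unit = "ms", y_unit = "um")
  expect_equal(trajs_ms[[1]]$t, c(0, 0.5, 1, 1.5))
})

test_that("corrupt particles are rejected individually, NA rows dropped", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(particle_id = c(rep(1, 4), rep(2, 4), rep(3, 2)),
                   t = c(0, 0.5, 1, 1.5, 0, 0.5, 0.4, 1.5, 0, 0.5),
                   y = c(20, 30, NA, 60, 30, 35, 40, 50, 10, 20))
  write.csv(df, f, row.names = FALSE)
  trajs <- load_trajectories(f, y_unit = "um")
  expect_length(trajs, 1)  # particle 2 non-monotone, particle 3 too short
  expect_equal(attr(trajs, "dropped_rows"), 1)
  expect_named(attr(trajs, "rejected"), c("2", "3"))
  expect_error(load_trajectories({
    f2 <- tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), f2, row.names = FALSE); f2
  }), "columns")
})

test_that("noiseless synthetic paths are recovered exactly by all methods", {
  acq <- acquisition_spec(noise_px = 0, n_particles = 6)
  df <- generate_trajectories(7.25, bead4, ref_medium, ref_geometry, acq,
                              seed = 12, quantize = FALSE)
  trajs <- trajs_from_df(df)
  for (m in c("path_fit", "regression", "endpoints")) {
    est <- estimate_energy_density(trajs, bead4, ref_medium, ref_geometry,
                                   method = m)
    expect_lt(abs(est$mean - 7.25) / 7.25, 1e-9)
    expect_lt(est$sd / 7.25, 1e-9)
    expect_equal(est$n, 6)
  }
})

test_that("stationary track yields zero energy density", {
  w <- ref_geometry$width
  traj <- list(t = seq(0, 10, 0.5), y = rep(0.2 * w, 21))
  expect_equal(estimate_per_particle(traj, bead4, ref_medium, ref_geometry,
                                     method = "regression"), 0)
  expect_equal(estimate_per_particle(traj, bead4, ref_medium, ref_geometry,
                                     method = "endpoints"), 0)
})

test_that("wrong-way and too-short tracks raise errors", {
  w <- ref_geometry$width
  away <- list(t = c(0, 1, 2, 3), y = c(0.4, 0.3, 0.2, 0.1) * w)
  expect_error(estimate_per_particle(away, bead4, ref_medium, ref_geometry),
               "away from the node")
  short <- list(t = c(0, 1), y = c(0.2, 0.3) * w)
  expect_error(estimate_per_particle(short, bead4, ref_medium, ref_geometry),
               "3 samples")
  # all tracks at the node: every sample excluded
  atnode <- list(t = c(0, 1, 2, 3), y = rep(w / 2 - 1e-7, 4))
  expect_error(estimate_per_particle(atnode, bead4, ref_medium, ref_geometry),
               "usable")
})

test_that("a noisy 60-sample track is recovered within 10 percent", {
  # slow drive so the transient spans most of the 60 frames
  w <- ref_geometry$width
  fld <- ref_drive(1)
  set.seed(31)
  tt <- seq(0, 29.5, by = 0.5)
  ytrue <- transverse_path(0.12 * w, tt, bead4, ref_medium, fld, ref_geometry)
  yobs <- ytrue + rnorm(length(tt), sd = 1.63e-6)
  est <- estimate_per_particle(list(t = tt, y = yobs), bead4, ref_medium,
                               ref_geometry, method = "regression")
  expect_lt(abs(est - 1) / 1, 0.10)
})

test_that("estimates are invariant to declared unit rescaling", {
  acq <- acquisition_spec(n_particles = 8)
  df <- generate_trajectories(7.25, bead4, ref_medium, ref_geometry, acq,
                              seed = 5)
  f_si <- tempfile(fileext = ".csv"); f_scaled <- tempfile(fileext = ".csv")
  write.csv(df, f_si, row.names = FALSE)
  df2 <- transform(df, t = t * 1000, y = y * 1e6)
  write.csv(df2, f_scaled, row.names = FALSE)
  t_si <- load_trajectories(f_si)
  t_sc <- load_trajectories(f_scaled, t_unit = "ms", y_unit = "um")
  # closed-form methods: identical to rounding
  for (m in c("regression", "endpoints")) {
    e1 <- estimate_energy_density(t_si, bead4, ref_medium, ref_geometry,
                                  method = m)
    e2 <- estimate_energy_density(t_sc, bead4, ref_medium, ref_geometry,
                                  method = m)
    expect_equal(e1$mean, e2$mean, tolerance = 1e-12)
    expect_equal(e1$sd, e2$sd, tolerance = 1e-12)
  }
  # the iterative path fit is deterministic but its stopping rule leaves
  # optimizer-tolerance-level differences under representation changes
  e1 <- estimate_energy_density(t_si, bead4, ref_medium, ref_geometry)
  e2 <- estimate_energy_density(t_sc, bead4, ref_medium, ref_geometry)
  expect_equal(e1$mean, e2$mean, tolerance = 1e-6)
})

test_that("ensemble estimate attaches the pressure amplitude consistently", {
  acq <- acquisition_spec(noise_px = 0, n_particles = 4)
  df <- generate_trajectories(7.25, bead4, ref_medium, ref_geometry, acq,
                              seed = 2, quantize = FALSE)
  est <- estimate_energy_density(trajs_from_df(df), bead4, ref_medium,
                                 ref_geometry)
  expect_equal(est$pressure_amplitude,
               pressure_amplitude(est$mean, ref_medium))
  expect_equal(est$pressure_amplitude / 1e6, 0.252, tolerance = 1e-3)
})

test_that("all-rejected input raises an informative error", {
  w <- ref_geometry$width
  bad <- list(list(id = "a", t = c(0, 1, 2, 3), y = c(0.4, 0.3, 0.2, 0.1) * w))
  expect_error(estimate_energy_density(bad, bead4, ref_medium, ref_geometry),
               "all trajectories rejected")
})

test_that("recovery experiment: small bias and calibrated spread", {
  # 50 seeded replicates of 20 noisy paths at the measured operating point
  truth <- 7.25
  acq <- acquisition_spec()
  reps <- vapply(1:50, function(s) {
    df <- generate_trajectories(truth, bead4, ref_medium, ref_geometry, acq,
                                seed = 1000 + s)
    est <- estimate_energy_density(trajs_from_df(df), bead4, ref_medium,
                                   ref_geometry)
    c(est$mean, est$sd, est$n)
  }, numeric(3))
  bias <- mean(reps[1, ]) / truth - 1
  expect_lt(abs(bias), 0.02)
  covered <- abs(reps[1, ] - truth) <= 2 * reps[2, ] / sqrt(reps[3, ])
  expect_gte(mean(covered), 0.9)
})
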