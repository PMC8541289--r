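test_that("contrast factor matches hand arithmetic and limit cases", {
  # medium-matched particle: exactly zero
  m <- ref_medium
  neutral <- baw_species(1e-6, m$density, m$compressibility)
  expect_identical(contrast_factor(neutral, m), 0)
  # polystyrene in water with beta_m = 4.48e-10 /Pa: value frozen from
  # independent spreadsheet arithmetic
  m448 <- baw_medium(998, sqrt(1 / (998 * 4.48e-10)), 1e-3,
                     compressibility = 4.48e-10)
  ps <- baw_species(2e-6, 1050, 2.16e-10)
  expect_equal(contrast_factor(ps, m448), 0.5682122106428109,
               tolerance = 1e-12)
  # rigid dense limit: phi -> 5/2
  rigid <- baw_species(1e-6, 1e9, 1e-30)
  expect_equal(contrast_factor(rigid, m), 2.5, tolerance = 1e-3)
})

test_that("radiation force vanishes at the node and for neutral particles", {
  fld <- ref_drive(7.25)
  w <- ref_geometry$width
  expect_equal(radiation_force(w / 2, bead4, ref_medium, fld, ref_geometry), 0)
  neutral <- baw_species(2e-6, ref_medium$density, ref_medium$compressibility)
  y <- seq(0.05, 0.95, by = 0.1) * w
  expect_equal(radiation_force(y, neutral, ref_medium, fld, ref_geometry),
               rep(0, length(y)))
  expect_error(radiation_force(-1e-6, bead4, ref_medium, fld, ref_geometry),
               "inside the channel")
})

test_that("radiation force at quarter width matches the independent oracle", {
  # frozen from an independent symbolic evaluation of Vp k Eac phi sin(2ky)
  # (positive: at y = w/4 a positive-contrast bead is pushed toward the node)
  fld <- ref_drive(7.25)
  F <- radiation_force(ref_geometry$width / 4, bead4, ref_medium, fld,
                       ref_geometry)
  expect_equal(F, 2.3200236084142558e-12, tolerance = 1e-9)
})

test_that("pressure-amplitude and energy-density forms of the force agree", {
  fld <- ref_drive(3.1)
  w <- ref_geometry$width
  y <- seq(0.02, 0.98, length.out = 41) * w
  phi <- contrast_factor(bead4, ref_medium)
  alt <- bead4$volume * fld$wavenumber * fld$Eac * phi *
    sin(2 * fld$wavenumber * y)
  expect_equal(radiation_force(y, bead4, ref_medium, fld, ref_geometry), alt,
               tolerance = 1e-12)
})

test_that("Stokes drag is linear in radius and velocity", {
  m <- baw_medium(998, 1481, 1.0e-3)
  s <- baw_species(2e-6, 1050, 2.16e-10)
  expect_equal(stokes_drag(0, s, m), 0)
  # frozen hand arithmetic: -6 pi 1e-3 2e-6 1e-4
  expect_equal(stokes_drag(1e-4, s, m), -3.769911184307751e-12,
               tolerance = 1e-12)
  s2 <- baw_species(4e-6, 1050, 2.16e-10)
  expect_equal(stokes_drag(1e-4, s2, m), 2 * stokes_drag(1e-4, s, m))
})

test_that("transverse path: fixed points, monotonicity, symmetry", {
  w <- ref_geometry$width
  t <- seq(0, 10, by = 0.5)
  # no field: stationary
  f0 <- ref_drive(0)
  expect_equal(transverse_path(0.2 * w, t, bead4, ref_medium, f0, ref_geometry),
               rep(0.2 * w, length(t)))
  # node is a fixed point
  fld <- ref_drive(7.25)
  expect_equal(transverse_path(w / 2, t, bead4, ref_medium, fld, ref_geometry),
               rep(w / 2, length(t)))
  # anti-node: unchanged with a warning
  expect_warning(
    y0out <- transverse_path(0, t, bead4, ref_medium, fld, ref_geometry),
    "anti-node")
  expect_equal(y0out, rep(0, length(t)))
  # monotone toward the node from both halves
  y_lo <- transverse_path(0.1 * w, t, bead4, ref_medium, fld, ref_geometry)
  expect_true(all(diff(y_lo) > 0) && all(y_lo < w / 2))
  y_hi <- transverse_path(0.9 * w, t, bead4, ref_medium, fld, ref_geometry)
  expect_true(all(diff(y_hi) < 0) && all(y_hi > w / 2))
  # reflection symmetry about the node
  expect_equal(y_hi, w - y_lo, tolerance = 1e-12)
  # larger Eac gets closer to the node at fixed t
  y_stronger <- transverse_path(0.1 * w, 2, bead4, ref_medium,
                                ref_drive(10), ref_geometry)
  expect_gt(y_stronger, transverse_path(0.1 * w, 2, bead4, ref_medium,
                                        ref_drive(5), ref_geometry))
})

test_that("path/energy-density inversion round-trips to 1e-9 over 1000 draws", {
  w <- ref_geometry$width
  set.seed(101)
  n <- 1000
  y0 <- runif(n, 0.02 * w, 0.48 * w)
  Eac <- runif(n, 0.1, 20)
  tt <- runif(n, 0.05, 30)
  rel <- vapply(seq_len(n), function(i) {
    fld <- ref_drive(Eac[i])
    yt <- transverse_path(y0[i], tt[i], bead4, ref_medium, fld, ref_geometry)
    if (yt >= w / 2 - 1e-12) return(0)  # numerically at the node: skip
    est <- energy_density_from_displacement(y0[i], yt, tt[i], bead4,
                                            ref_medium, fld, ref_geometry)
    abs(est - Eac[i]) / Eac[i]
  }, numeric(1))
  expect_lt(max(rel), 1e-9)
})

test_that("energy-density inversion flags degenerate and wrong-way input", {
  w <- ref_geometry$width
  fld <- ref_drive(1)
  expect_equal(energy_density_from_displacement(0.1 * w, 0.1 * w, 5, bead4,
                                                ref_medium, fld, ref_geometry), 0)
  expect_error(energy_density_from_displacement(0.3 * w, 0.1 * w, 5, bead4,
                                                ref_medium, fld, ref_geometry),
               "away from the node")
  expect_error(energy_density_from_displacement(0, 0.1 * w, 5, bead4,
                                                ref_medium, fld, ref_geometry),
               "degenerate")
  expect_error(energy_density_from_displacement(0.1 * w, 0.7 * w, 5, bead4,
                                                ref_medium, fld, ref_geometry),
               "same half")
  # halving the time doubles the estimate for fixed endpoints
  e1 <- energy_density_from_displacement(0.1 * w, 0.3 * w, 5, bead4,
                                         ref_medium, fld, ref_geometry)
  e2 <- energy_density_from_displacement(0.1 * w, 0.3 * w, 2.5, bead4,
                                         ref_medium, fld, ref_geometry)
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
})

test_that("closed-form path matches numerical ODE integration to 1e-6", {
  skip_if_not_installed("deSolve")
  w <- ref_geometry$width
  fld <- ref_drive(7.25)
  drag <- 6 * pi * ref_medium$viscosity * bead4$radius
  rhs <- function(t, y, parms) {
    list(radiation_force(y, bead4, ref_medium, fld, ref_geometry) / drag)
  }
  tt <- seq(0, 10, by = 0.1)
  for (y0 in c(0.05, 0.25, 0.45, 0.7, 0.95) * w) {
    ode <- deSolve::lsoda(y0, tt, rhs, NULL, rtol = 1e-12, atol = 1e-18)[, 2]
    cf <- transverse_path(y0, tt, bead4, ref_medium, fld, ref_geometry)
    expect_lt(max(abs(ode - cf)) / (w / 2), 1e-6)
  }
})

test_that("pressure amplitude follows the square-root law and its inverse", {
  expect_equal(pressure_amplitude(0, ref_medium), 0)
  expect_equal(pressure_amplitude(4 * 7.25, ref_medium),
               2 * pressure_amplitude(7.25, ref_medium))
  # frozen hand arithmetic: 2 * 1481 * sqrt(7.25 * 998)
  expect_equal(pressure_amplitude(7.25, ref_medium), 251952.88063842413,
               tolerance = 1e-12)
  expect_equal(energy_density_from_pressure(
    pressure_amplitude(7.25, ref_medium), ref_medium), 7.25,
    tolerance = 1e-12)
  expect_error(pressure_amplitude(-1, ref_medium), "non-negative")
})

test_that("design width is the half wavelength and inverts exactly", {
  m <- baw_medium(998, 1497, 1e-3)
  expect_equal(design_width(m, 4e6), 1.87125e-4, tolerance = 1e-12)
  expect_equal(design_width(m, 8e6), design_width(m, 4e6) / 2)
  wch <- design_width(m, 4e6)
  expect_equal(m$sound_speed / (2 * wch), 4e6)
})

test_that("voltage calibration is quadratic and anchored", {
  expect_equal(eac_from_voltage(0), 0)
  expect_equal(eac_from_voltage(52.92), 7.25, tolerance = 1e-12)
  expect_equal(eac_from_voltage(26.46), 7.25 / 4, tolerance = 1e-12)
  expect_error(eac_from_voltage(-1), "non-negative")
})

test_that("critical diameter scales as 1/sqrt(f) and needs positive contrast", {
  phi <- contrast_factor(bead4, ref_medium)
  d1 <- critical_diameter(phi, ref_medium, drive_field(4.623e6, ref_medium))
  d4 <- critical_diameter(phi, ref_medium, drive_field(4 * 4.623e6, ref_medium))
  expect_equal(d4, d1 / 2, tolerance = 1e-12)
  # decreasing in contrast
  expect_gt(critical_diameter(phi / 2, ref_medium,
                              drive_field(4.623e6, ref_medium)), d1)
  expect_error(critical_diameter(-0.1, ref_medium,
                                 drive_field(4.623e6, ref_medium)),
               "positive contrast")
  # micrometre scale for the reference device
  expect_gt(d1, 0.5e-6)
  expect_lt(d1, 5e-6)
})

test_that("critical diameter agrees with the radiation/streaming force balance", {
  # independent route: equate the maximum acoustophoretic velocity with the
  # maximum slip speed computed by the streaming module, solve for diameter
  fld <- ref_drive(7.25)
  f1 <- first_order_field(fld, ref_geometry, ref_medium, ny = 128, nz = 64)
  slip_max <- max(abs(limiting_velocity(f1)$vL_bottom))
  phi <- contrast_factor(bead4, ref_medium)
  k <- pi / ref_geometry$width
  a_bal <- sqrt(slip_max * 9 * ref_medium$viscosity /
                  (2 * phi * k * fld$Eac))
  d_formula <- critical_diameter(
    phi, ref_medium,
    drive_field(fld$frequency, ref_medium, Eac = fld$Eac,
                wavelength = fld$wavelength))
  expect_equal(2 * a_bal, d_formula, tolerance = 0.01)
})
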