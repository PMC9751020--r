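test_that("steady-state time follows the diagonal transit formula", {
  expect_identical(steady_state_time(0, 0, 1481), 0)
  expect_equal(steady_state_time(0.2, 0.2, 1481), sqrt(0.08) / 1481)
  expect_equal(steady_state_time(0.2, 0.2, 1481), 1.9098e-4, tolerance = 1e-4)
  # the printed 190 us at the water speed implies a ~0.281 m diagonal
  diag_len <- 190e-6 * 1481
  expect_equal(diag_len, 0.281, tolerance = 2e-3)
  expect_equal(steady_state_time(diag_len / sqrt(2), diag_len / sqrt(2), 1481),
               190e-6)
  expect_error(steady_state_time(0.1, 0.1, 0), "domain error")
  expect_error(steady_state_time(-0.1, 0.1, 1481), "domain error")
})

test_that("a plane wave propagates at the drive amplitude and intensity", {
  fx <- generate_fixture("plane-wave-medium", nx = 400L, ny = 120L,
                         dx = 0.5e-3, amplitude = 1e5, window = 300e-6)
  probe <- cbind(100e-3, 30e-3)  # 87 mm downstream, on the mid line
  cfg <- solver_config(trace_points = probe, check_steady = FALSE,
                       smoothing_sigma = 0)
  field <- simulate_acoustic(fx$medium, fx$source, cfg)
  tr <- field$traces$p[, 1]
  sel <- field$traces$t > 150e-6  # well after arrival (~59 us)
  amp <- max(abs(tr[sel]))
  expect_lt(abs(amp - 1e5) / 1e5, 0.02)
  # intensity of a 100 kPa plane wave in water: p0^2 / (2 rho c) = 0.338 W/cm^2
  I <- compute_avg_intensity(tr[sel], dt = field$dt, rho = 998, c = 1481,
                             frequency = 250e3)
  expect_equal(I, 1e10 / (2 * 998 * 1481), tolerance = 0.02)
  expect_equal(I / 1e4, 0.338, tolerance = 0.02)
})

test_that("the solver is linear in the source amplitude", {
  fx <- generate_fixture("plane-wave-medium", nx = 150L, ny = 60L,
                         dx = 1e-3, amplitude = 1e5, window = 80e-6)
  cfg <- solver_config(check_steady = FALSE, smoothing_sigma = 0)
  f1 <- simulate_acoustic(fx$medium, fx$source, cfg)
  fx$source$amplitude <- 2e5
  f2 <- simulate_acoustic(fx$medium, fx$source, cfg)
  sel <- f1$max_pressure > 1e3
  expect_lt(max(abs(f2$max_pressure[sel] / f1$max_pressure[sel] - 2)) / 2,
            1e-3)
  expect_lt(max(abs(f2$avg_intensity[sel] / f1$avg_intensity[sel] - 4)) / 4,
            1e-3)
})

test_that("a zero-amplitude source yields identically zero fields", {
  fx <- generate_fixture("plane-wave-medium", nx = 100L, ny = 40L, dx = 1e-3,
                         amplitude = 0, window = 50e-6)
  f <- simulate_acoustic(fx$medium, fx$source,
                         solver_config(check_steady = FALSE))
  expect_identical(max(f$max_pressure), 0)
  expect_identical(max(f$avg_intensity), 0)
})

test_that("the field is zero beyond the wavefront reach on short runs", {
  fx <- generate_fixture("plane-wave-medium", nx = 300L, ny = 40L, dx = 1e-3,
                         source_x = 26L, window = 50e-6)
  f <- simulate_acoustic(fx$medium, fx$source,
                         solver_config(check_steady = FALSE,
                                       smoothing_sigma = 0))
  # source at x ~ 25.5 mm; reach after 50 us of water travel is ~74 mm
  # further. The discrete stencil carries a tiny numerical precursor ahead of
  # the physical front (at most one pixel per step), so the field beyond the
  # physical reach is bounded near zero and beyond the numerical cone it is
  # exactly zero.
  reach_px <- ceiling((25.5e-3 + 1481 * 50e-6) / 1e-3) + 2
  expect_lt(max(f$max_pressure[(reach_px + 1):300, ]) / 1e5, 1e-3)
  cone_px <- 26 + f$nsteps + 2
  expect_identical(max(f$max_pressure[(cone_px + 1):300, ]), 0)
  expect_gt(max(f$max_pressure[1:reach_px, ]), 0)
})

test_that("head-model fields are mirror-symmetric about the transducer axis", {
  f <- cached_head_field_coarse()
  mp <- f$max_pressure
  expect_lt(max(abs(mp - mp[, rev(seq_len(ncol(mp)))])) / max(mp), 1e-10)
})

test_that("acoustic energy is conserved without absorption or PML", {
  nx <- 200L; ny <- 200L; dx <- 1e-3
  water <- default_media()$water
  medium <- structure(list(label = matrix(0L, nx, ny),
                           sound_speed = matrix(water$sound_speed, nx, ny),
                           density = matrix(water$density, nx, ny),
                           alpha0 = matrix(0, nx, ny), dx = dx,
                           origin = c(0, 0), geometry = NULL),
                      class = "tfus_medium_map")
  mask <- matrix(FALSE, nx, ny); mask[100, 100] <- TRUE
  src <- source_definition(mask, 1e5, 250e3, on_time = 20e-6,
                           total_time = 60e-6)
  f <- simulate_acoustic(medium, src,
                         solver_config(pml_size = 0, smoothing_sigma = 0,
                                       track_energy = TRUE, ramp_cycles = 2,
                                       check_steady = FALSE))
  en <- f$energy
  i1 <- round(30e-6 / f$dt); i2 <- round(55e-6 / f$dt)  # wavefront still inside
  expect_lt(abs(en[i2] - en[i1]) / en[i1], 0.01)
})

test_that("halving dx changes the focal maximum by less than 5%", {
  focal_max <- function(dxv) {
    L <- 120e-3
    geom <- head_geometry(grid_nx = round(L / dxv), grid_ny = round(L / dxv),
                          dx = dxv, brain_outer_radius = 1e-3,
                          skull_thickness = 0, transducer_aperture = 32e-3,
                          transducer_roc = 31.6e-3, apex_x = 15e-3,
                          head_center = c(60e-3, 60e-3))
    src <- build_transducer_source(geom, duty_cycle = 1, window = 150e-6)
    water <- default_media()$water
    n <- geom$grid_nx
    medium <- structure(list(label = matrix(0L, n, n),
                             sound_speed = matrix(water$sound_speed, n, n),
                             density = matrix(water$density, n, n),
                             alpha0 = matrix(water$alpha0, n, n), dx = dxv,
                             origin = c(0, 0), geometry = geom),
                        class = "tfus_medium_map")
    f <- simulate_acoustic(medium, src,
                           solver_config(check_steady = FALSE,
                                         smoothing_sigma = 0))
    max(f$max_pressure)
  }
  m1 <- focal_max(0.5e-3)
  m2 <- focal_max(0.25e-3)
  expect_lt(abs(m2 - m1) / m1, 0.05)
})

test_that("configuration errors are raised", {
  fx <- generate_fixture("plane-wave-medium", nx = 60L, ny = 40L, dx = 1e-3)
  expect_error(simulate_acoustic(fx$medium, fx$source,
                                 solver_config(dt = 1e-6,
                                               check_steady = FALSE)),
               "CFL")
  expect_error(simulate_acoustic(fx$medium, fx$source,
                                 solver_config(record_window = c(-1, 1),
                                               check_steady = FALSE)),
               "record_window")
  expect_error(solver_config(cfl = 0), "cfl")
})

test_that("the intensity estimator handles windows and degenerate input", {
  f0 <- 250e3; dt <- 1e-8
  t <- seq(0, 400e-6 - dt, by = dt)
  p <- 1e5 * sin(2 * pi * f0 * t)
  I_cw <- compute_avg_intensity(p, dt, 998, 1481, frequency = f0)
  expect_equal(I_cw, 1e10 / (2 * 998 * 1481), tolerance = 1e-3)
  expect_identical(compute_avg_intensity(0 * p, dt, 998, 1481), 0)
  # 50% silent window halves the window-averaged intensity
  p_half <- p
  p_half[t >= 200e-6] <- 0
  I_half <- compute_avg_intensity(p_half, dt, 998, 1481)
  expect_equal(I_half / I_cw, 0.5, tolerance = 1e-3)
  expect_error(compute_avg_intensity(p[1:100], dt, 998, 1481,
                                     frequency = f0),
               "one acoustic period")
})

test_that("free-water calibration reports quadratic amplitude scaling", {
  geom <- head_geometry(dx = 1e-3, grid_nx = 280, grid_ny = 280)
  r1 <- free_water_calibration(geom, amplitude = 50e3, window = 300e-6,
                               config = solver_config(check_steady = FALSE))
  r2 <- free_water_calibration(geom, amplitude = 100e3, window = 300e-6,
                               config = solver_config(check_steady = FALSE))
  expect_equal(r2$max_intensity / r1$max_intensity, 4, tolerance = 1e-3)
  r0 <- free_water_calibration(geom, amplitude = 0, window = 100e-6,
                               config = solver_config(check_steady = FALSE))
  expect_identical(r0$max_intensity, 0)
  expect_true(r0$passes)
  expect_error(free_water_calibration(geom, threshold = -1), "threshold")
})
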