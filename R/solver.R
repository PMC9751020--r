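#' Time to acoustic steady state of the grid
#'
#' Transit time of the grid diagonal at the slowest sound speed,
#' `sqrt(sx^2 + sy^2) / v_min`. Simulations meant to reach a steady focal
#' field should run at least this long.
#'
#' @param grid_length_x,grid_length_y physical grid lengths, m (>= 0)
#' @param v_min minimum sound speed among the media, m/s (> 0)
#' @return time in seconds
#' @export
steady_state_time <- function(grid_length_x, grid_length_y, v_min) {
  if (any(v_min <= 0)) stop("domain error: v_min must be > 0")
  if (any(grid_length_x < 0) || any(grid_length_y < 0))
    stop("domain error: grid lengths must be >= 0")
  sqrt(grid_length_x^2 + grid_length_y^2) / v_min
}

#' Acoustic solver configuration
#'
#' @param total_time simulated time, s; defaults to the source window
#' @param dt time step, s; derived from the CFL number when `NULL`
#' @param cfl Courant number relative to the 2D stability limit
#'   `dx / (c_max * sqrt(2))`, in (0, 1]
#' @param pml_size perfectly-matched-layer thickness in pixels (on all sides)
#' @param pml_r0,pml_m PML target reflection coefficient and profile order
#' @param absorption_exponent exponent `gamma` of the power-law absorption
#'   `alpha(f) = alpha0 * (f/1 MHz)^gamma`
#' @param smoothing_sigma Gaussian smoothing of the property rasters, metres
#'   (0 disables). Damps staircase and thin-layer resonance artifacts, as the
#'   reference pseudospectral toolboxes do by default.
#' @param record_window `(t_start, t_end)` of the intensity average, s;
#'   defaults to the whole run
#' @param trace_points optional n x 2 matrix of `(x, y)` positions (m) where
#'   the full pressure time series is kept
#' @param ramp_cycles smooth onset ramp of the drive, in acoustic cycles
#' @param track_energy record total acoustic energy per step (diagnostics)
#' @param check_steady warn when `total_time` is below [steady_state_time()]
#' @return an object of class `tfus_solver_config`
#' @export
solver_config <- function(total_time = NULL, dt = NULL, cfl = 0.9,
                          pml_size = 20, pml_r0 = 1e-6, pml_m = 3,
                          absorption_exponent = 1, smoothing_sigma = 1e-3,
                          record_window = NULL, trace_points = NULL,
                          ramp_cycles = 5, track_energy = FALSE,
                          check_steady = TRUE) {
  if (!(cfl > 0 && cfl <= 1)) stop("configuration error: cfl must be in (0, 1]")
  if (pml_size < 0) stop("configuration error: pml_size must be >= 0")
  structure(list(total_time = total_time, dt = dt, cfl = cfl,
                 pml_size = as.integer(pml_size), pml_r0 = pml_r0,
                 pml_m = as.integer(pml_m),
                 absorption_exponent = absorption_exponent,
                 smoothing_sigma = smoothing_sigma,
                 record_window = record_window, trace_points = trace_points,
                 ramp_cycles = ramp_cycles, track_energy = track_energy,
                 check_steady = check_steady),
            class = "tfus_solver_config")
}

# separable Gaussian blur with reflective padding
smooth_raster <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- ceiling(3 * sigma_px)
  k <- dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  nx <- nrow(m); ny <- ncol(m)
  pad <- function(v) c(v[r:1], v, v[length(v):(length(v) - r + 1)])
  m <- apply(m, 2, function(col) stats::filter(pad(col), k)[(r + 1):(r + nx)])
  t(apply(m, 1, function(row) stats::filter(pad(row), k)[(r + 1):(r + ny)]))
}

#' Propagate the drive through the medium
#'
#' Runs the staggered-grid finite-difference time-domain solve of the
#' first-order pressure/velocity equations with split-field PML boundaries
#' and a first-order power-law loss term, and accumulates the per-pixel
#' maximum pressure and the time-averaged intensity
#' `<p^2> / (rho c)` (plane-wave-impedance estimator) over the record window.
#'
#' @param medium a `tfus_medium_map` from [build_head_map()] (or any object
#'   with `sound_speed`, `density`, `alpha0`, `dx` entries)
#' @param source a `tfus_source`
#' @param config a [solver_config()]
#' @return an object of class `tfus_field_maps`: `max_pressure` (Pa) and
#'   `avg_intensity` (W/m^2) matrices, grid metadata, recorded traces and a
#'   config echo
#' @export
simulate_acoustic <- function(medium, source, config = solver_config()) {
  stopifnot(inherits(source, "tfus_source"))
  dx <- medium$dx
  total_time <- config$total_time %||% source$total_time
  cmax <- max(medium$sound_speed)
  dt_stab <- dx / (cmax * sqrt(2))
  dt <- config$dt %||% (config$cfl * dt_stab)
  if (dt > dt_stab)
    stop(sprintf("configuration error: dt = %g violates the CFL limit %g", dt, dt_stab))
  nx <- nrow(medium$sound_speed); ny <- ncol(medium$sound_speed)
  if (config$check_steady) {
    tss <- steady_state_time(nx * dx, ny * dx, min(medium$sound_speed))
    message(sprintf("steady-state time t_ss = %.1f us; source on %.1f us of %.1f us simulated%s",
                    tss * 1e6, source$on_time * 1e6, total_time * 1e6,
                    if (source$on_time < tss)
                      " [on-time below the steady-state bound]" else ""))
  }
  f <- source$frequency
  alpha_np <- medium$alpha0 * (f / 1e6)^config$absorption_exponent * NP_PER_DB_CM
  sig_px <- config$smoothing_sigma / dx
  cmap <- smooth_raster(medium$sound_speed, sig_px)
  rho <- smooth_raster(medium$density, sig_px)
  alpha_np <- smooth_raster(alpha_np, sig_px)
  nsteps <- round(total_time / dt)
  rw <- config$record_window %||% c(0, total_time)
  if (rw[1] < 0 || rw[2] > total_time + dt || rw[2] <= rw[1])
    stop("configuration error: record_window outside [0, total_time]")
  trace_idx <- integer(0)
  if (!is.null(config$trace_points)) {
    tp <- config$trace_points
    i <- pmin(pmax(round(tp[, 1] / dx + 0.5), 1), nx)
    j <- pmin(pmax(round(tp[, 2] / dx + 0.5), 1), ny)
    trace_idx <- as.integer((j - 1L) * nx + i - 1L)
  }
  out <- fdtd_core(cmap, rho, alpha_np, as.integer(which(source$mask) - 1L),
                   source$amplitude, f, source$on_time, dx, dt, nsteps,
                   config$pml_size, config$pml_r0, config$pml_m,
                   as.integer(floor(rw[1] / dt)), as.integer(ceiling(rw[2] / dt)),
                   trace_idx, isTRUE(config$track_energy), config$ramp_cycles)
  traces <- NULL
  if (length(trace_idx) > 0)
    traces <- list(t = (seq_len(nsteps)) * dt, p = out$traces)
  structure(list(max_pressure = out$max_pressure,
                 avg_intensity = out$avg_intensity,
                 dx = dx, origin = c(0, 0), dt = dt, nsteps = nsteps,
                 traces = traces,
                 energy = if (isTRUE(config$track_energy)) out$energy else NULL,
                 label = medium$label, geometry = medium$geometry,
                 source = source[c("amplitude", "frequency", "on_time", "total_time")],
                 config = config),
            class = "tfus_field_maps")
}

#' @export
print.tfus_field_maps <- function(x, ...) {
  cat(sprintf("<tfus_field_maps> %d x %d, dx = %g mm, %d steps of %.3g ns\n",
              nrow(x$max_pressure), ncol(x$max_pressure), x$dx * 1e3,
              x$nsteps, x$dt * 1e9))
  cat(sprintf("  max pressure %.1f kPa | max avg intensity %.3f W/cm^2\n",
              max(x$max_pressure) / 1e3, max(x$avg_intensity) / 1e4))
  invisible(x)
}

#' Time-averaged intensity of a pressure record
#'
#' Plane-wave-impedance estimator `<p^2>_window / (rho c)`. Exact for
#' travelling plane waves; an approximation near a focus.
#'
#' @param p pressure samples, Pa: a vector, or a matrix with time in rows and
#'   one column per pixel
#' @param dt sampling interval, s
#' @param rho,c density (kg/m^3) and sound speed (m/s) at the recorded
#'   pixel(s); scalars or vectors matching the columns of `p`
#' @param window `(t_start, t_end)` in seconds relative to the first sample;
#'   defaults to the whole record
#' @param frequency optional drive frequency; when given, the window must
#'   span at least 5 acoustic periods (and always at least one)
#' @return intensity in W/m^2 (scalar or per-column vector)
#' @export
compute_avg_intensity <- function(p, dt, rho, c, window = NULL,
                                  frequency = NULL) {
  p <- as.matrix(p)
  n <- nrow(p)
  window <- window %||% c(0, n * dt)
  i0 <- max(1L, floor(window[1] / dt) + 1L)
  i1 <- min(n, ceiling(window[2] / dt))
  if (i1 <= i0) stop("estimator error: empty averaging window")
  span <- (i1 - i0 + 1L) * dt
  if (!is.null(frequency)) {
    if (span < 1 / frequency)
      stop("estimator error: window shorter than one acoustic period")
    if (span < 5 / frequency)
      warning("averaging window spans fewer than 5 acoustic periods")
  }
  out <- colMeans(p[i0:i1, , drop = FALSE]^2) / (rho * c)
  if (length(out) == 1L) out[[1]] else out
}

#' Free-water safety calibration
#'
#' Re-runs the configured transducer drive in an all-water domain (same grid,
#' no head) and reports the spatial maximum of the time-averaged intensity
#' against a safety threshold, conventionally the 3 W/cm^2 physiotherapy
#' limit.
#'
#' @param geometry a [head_geometry()] (its skull/brain discs are ignored)
#' @param amplitude drive amplitude, Pa; defaults to the geometry's
#' @param threshold safety threshold, W/m^2 (3 W/cm^2 = 3e4 W/m^2)
#' @param duty_cycle,window drive gating passed to
#'   [build_transducer_source()]
#' @param config a [solver_config()]
#' @param media media table; only the water entry is used
#' @return list with `max_intensity` (W/m^2), `max_pressure` (Pa), `passes`
#'   flag and the `field` maps
#' @export
free_water_calibration <- function(geometry, amplitude = NULL, threshold = 3e4,
                                   duty_cycle = 0.9, window = 500e-6,
                                   config = solver_config(),
                                   media = default_media()) {
  if (threshold <= 0) stop("threshold must be > 0")
  g <- geometry
  g$skull_thickness <- 0
  g$brain_outer_radius <- 0
  water <- media$water
  nxy <- c(g$grid_nx, g$grid_ny)
  medium <- structure(list(
    label = matrix(0L, nxy[1], nxy[2]),
    sound_speed = matrix(water$sound_speed, nxy[1], nxy[2]),
    density = matrix(water$density, nxy[1], nxy[2]),
    alpha0 = matrix(water$alpha0, nxy[1], nxy[2]),
    dx = g$dx, origin = c(0, 0), geometry = g, media = media),
    class = "tfus_medium_map")
  src <- build_transducer_source(geometry, duty_cycle = duty_cycle,
                                 window = window)
  if (!is.null(amplitude)) src$amplitude <- amplitude
  field <- simulate_acoustic(medium, src, config)
  max_i <- max(field$avg_intensity)
  list(max_intensity = max_i, max_pressure = max(field$max_pressure),
       passes = max_i <= threshold, threshold = threshold, field = field)
}
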