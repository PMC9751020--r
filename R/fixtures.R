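#' Deterministic synthetic fixtures for tests and demos
#'
#' Three kinds are supported:
#'
#' * `"gaussian-focus"`: a `tfus_field_maps`-like object whose
#'   maximum-pressure raster is an isotropic Gaussian with a known peak and
#'   centre (`peak`, `center`, `sigma`, `nx`, `ny`, `dx`, optional
#'   `noise_sd`);
#' * `"plane-wave-medium"`: a homogeneous water `tfus_medium_map` plus a
#'   full-height line source (`nx`, `ny`, `dx`, `amplitude`, `frequency`,
#'   `source_x`, `window`, `duty_cycle`);
#' * `"spike-trace"`: a membrane-potential trace with linear-ramp
#'   depolarizations whose upward zero-crossings sit exactly at
#'   `crossing_times` (`duration`, `dt`, `baseline`, `peak`, `rise`).
#'
#' Fixtures are deterministic given `seed` (randomness only enters through
#' optional additive noise).
#'
#' @param kind fixture kind, see above
#' @param ... kind-specific parameters
#' @param seed integer seed for any randomized component
#' @return the fixture object
#' @export
generate_fixture <- function(kind, ..., seed = 1) {
  set.seed(seed)
  args <- list(...)
  switch(kind,
    "gaussian-focus" = {
      nx <- args$nx %||% 200L; ny <- args$ny %||% 200L
      dx <- args$dx %||% 0.5e-3
      peak <- args$peak %||% 0.6e6
      sigma <- args$sigma %||% 4e-3
      center <- args$center %||% c(nx * dx / 2, ny * dx / 2)
      noise_sd <- args$noise_sd %||% 0
      xs <- (seq_len(nx) - 0.5) * dx
      ys <- (seq_len(ny) - 0.5) * dx
      D2 <- outer((xs - center[1])^2, (ys - center[2])^2, `+`)
      mp <- peak * exp(-D2 / (2 * sigma^2))
      if (noise_sd > 0) mp <- mp + matrix(rnorm(nx * ny, sd = noise_sd), nx, ny)
      water <- default_media()$water
      structure(list(max_pressure = mp,
                     avg_intensity = mp^2 / (2 * water$density * water$sound_speed),
                     dx = dx, origin = c(0, 0), dt = NA_real_,
                     nsteps = 0L, traces = NULL, energy = NULL, label = NULL,
                     geometry = list(head_center = c(center[1], args$y_axis %||% center[2])),
                     source = NULL, config = NULL),
                class = "tfus_field_maps")
    },
    "plane-wave-medium" = {
      nx <- args$nx %||% 400L; ny <- args$ny %||% 120L
      dx <- args$dx %||% 0.5e-3
      water <- default_media()$water
      medium <- structure(list(
        label = matrix(0L, nx, ny),
        sound_speed = matrix(water$sound_speed, nx, ny),
        density = matrix(water$density, nx, ny),
        alpha0 = matrix(water$alpha0, nx, ny),
        dx = dx, origin = c(0, 0), geometry = NULL,
        media = default_media()), class = "tfus_medium_map")
      mask <- matrix(FALSE, nx, ny)
      mask[args$source_x %||% 26L, ] <- TRUE
      window <- args$window %||% 300e-6
      src <- source_definition(mask, args$amplitude %||% 1e5,
                               args$frequency %||% 250e3,
                               on_time = (args$duty_cycle %||% 1) * window,
                               total_time = window)
      list(medium = medium, source = src)
    },
    "spike-trace" = {
      crossing_times <- args$crossing_times %||% c(10e-3, 20e-3, 30e-3)
      duration <- args$duration %||% 50e-3
      dt <- args$dt %||% 1e-5
      baseline <- args$baseline %||% -70
      peak <- args$peak %||% 30
      rise <- args$rise %||% 0.5e-3
      t <- seq(0, duration, by = dt)
      Vm <- rep(baseline, length(t))
      for (tc in crossing_times) {
        # linear ramp reaching 0 mV exactly at tc, then to peak and back
        ramp_up <- t >= tc - rise & t < tc + rise
        Vm[ramp_up] <- baseline + (0 - baseline) * (t[ramp_up] - (tc - rise)) / rise
        decay <- t >= tc + rise & t < tc + 3 * rise
        Vm[decay] <- pmax(baseline,
                          peak - (peak - baseline) * (t[decay] - tc - rise) / (2 * rise))
      }
      Vm <- pmin(Vm, peak)
      data.frame(t = t, Vm = Vm)
    },
    stop("unknown fixture kind: ", kind))
}
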