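# shared fixtures, memoised so expensive objects are built once per test run

.tfus_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .tfus_cache)) {
    assign(key, force(expr), envir = .tfus_cache)
  }
  get(key, envir = .tfus_cache)
}

cached_bls <- function() memo("bls", bls_params())
cached_rs <- function() memo("rs", rs_neuron_params())
cached_rest <- function() memo("rest", rs_resting_state(cached_rs()))

# coarse but wide lookup table shared by the neuron and pipeline tests
cached_table <- function() memo("table", build_lookup_table(
  cached_bls(), cached_rs(), f = 250e3,
  PA_grid = c(0, 25, 50, 100, 150, 200, 300) * 1e3,
  Qm_grid = seq(-100, 50, by = 5) * 1e-5))

# macroscale head solve, default-resolution (dx = 0.5 mm) grid
cached_head_field <- function(skull_mm = 5.4, dc = 0.9) {
  memo(sprintf("field_%s_%s", skull_mm, dc), {
    geom <- head_geometry(skull_thickness = skull_mm * 1e-3)
    medium <- build_head_map(geom)
    src <- build_transducer_source(geom, duty_cycle = dc, window = 500e-6)
    suppressMessages(simulate_acoustic(medium, src, solver_config()))
  })
}

# coarse (dx = 1 mm) head solve for cheap structural checks
cached_head_field_coarse <- function(skull_mm = 5.4, dc = 0.9) {
  memo(sprintf("cfield_%s_%s", skull_mm, dc), {
    geom <- head_geometry(dx = 1e-3, grid_nx = 280, grid_ny = 280,
                          skull_thickness = skull_mm * 1e-3)
    medium <- build_head_map(geom)
    src <- build_transducer_source(geom, duty_cycle = dc, window = 500e-6)
    suppressMessages(simulate_acoustic(medium, src, solver_config()))
  })
}

# the expensive co-integration oracle at the acceptance operating point
cached_nbls_100 <- function() memo("nbls100", {
  prot <- stimulus_protocol(PA = 100e3, duty_cycle = 1, duration = 30e-3)
  simulate_full_nbls(prot, cached_bls(), cached_rs())
})

cached_sonic_100 <- function() memo("sonic100", {
  prot <- stimulus_protocol(PA = 100e3, duty_cycle = 1, duration = 30e-3)
  simulate_sonic(prot, cached_table(), cached_rs())
})

# independent R-side implementation of the textbook rate functions (1/s, mV),
# written directly from the published regular-spiking formulas; deliberately
# separate from the compiled implementation it checks
hh_rates_oracle <- function(V, rs) {
  vt <- V - rs$VT
  trap <- function(x, k) ifelse(abs(x / k) < 1e-7, k + x / 2,
                                x / (1 - exp(-x / k)))
  pinf <- 1 / (1 + exp(-(V + 35) / 10))
  taup <- rs$tau_max / (3.3 * exp((V + 35) / 20) + exp(-(V + 35) / 20))
  cbind(alpha_m = 1e3 * 0.32 * trap(vt - 13, 4),
        beta_m = 1e3 * 0.28 * trap(-(vt - 40), 5),
        alpha_h = 1e3 * 0.128 * exp(-(vt - 17) / 18),
        beta_h = 1e3 * 4 / (1 + exp(-(vt - 40) / 5)),
        alpha_n = 1e3 * 0.032 * trap(vt - 15, 5),
        beta_n = 1e3 * 0.5 * exp(-(vt - 10) / 40),
        alpha_p = pinf / taup,
        beta_p = (1 - pinf) / taup)
}

# tiny pipeline configuration: coarse grid, short protocol
tiny_config <- function(amplitude_kpa = 0, skull_mm = c(5.4, 7.6, 10.5),
                        dc = c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9)) {
  cfg <- default_config()
  cfg$geometry$dx_mm <- 1.4
  cfg$geometry$grid_nx <- 200L
  cfg$geometry$grid_ny <- 200L
  cfg$geometry$amplitude_kpa <- amplitude_kpa
  cfg$sweep$skull_mm <- skull_mm
  cfg$sweep$dc <- dc
  cfg$protocol$duration_ms <- 50
  cfg
}
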