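#' Run the full multiscale sweep
#'
#' Orchestrates the macro-to-micro coupling: for every (skull thickness,
#' duty cycle) condition the macroscale solve is run, the focal-region
#' pressures are sampled at the ROI positions, and each sampled pressure
#' drives the effective-variable neuron model under the pulsed protocol
#' (carrier = macroscale frequency, configured PRF, duty cycle matching the
#' macroscale condition). Latency and firing rate are computed per position.
#'
#' The macroscale solves for all conditions run first; one lookup table is
#' then built whose amplitude axis is auto-extended to cover the largest
#' sampled pressure (plus margin), and reused for every microscale run.
#'
#' @param config a `tfus_config` (see [default_config()], [load_config()])
#' @param params a [bls_params()] (built from defaults when `NULL`)
#' @param table optional pre-built `tfus_lookup`; must cover the sampled
#'   pressures
#' @param progress print per-condition progress lines
#' @return data frame of class `tfus_records`, one row per (condition,
#'   position): `skull_thickness` (m), `duty_cycle`, `x`, `y` (m), `PA` (Pa),
#'   `latency` (s or NA), `firing_rate` (spikes/s or NA)
#' @export
run_multiscale <- function(config = default_config(), params = NULL,
                           table = NULL, progress = TRUE) {
  cfg <- config
  media <- config_media(cfg)
  roi <- config_roi(cfg)
  scfg <- config_solver(cfg)
  window <- cfg$solver$window_us * 1e-6
  conditions <- expand.grid(skull_mm = cfg$sweep$skull_mm, dc = cfg$sweep$dc,
                            KEEP.OUT.ATTRS = FALSE)
  # macroscale pass
  samples <- vector("list", nrow(conditions))
  for (k in seq_len(nrow(conditions))) {
    sk <- conditions$skull_mm[k]; dc <- conditions$dc[k]
    if (progress)
      message(sprintf("macro solve: skull %.1f mm, DC %.0f%%", sk, dc * 100))
    pts <- tryCatch({
      geom <- config_geometry(cfg, skull_mm = sk)
      medium <- build_head_map(geom, media)
      src <- build_transducer_source(geom, duty_cycle = dc, window = window)
      field <- suppressMessages(simulate_acoustic(medium, src, scfg))
      extract_roi_points(field, roi)
    }, error = function(e)
      stop(sprintf("multiscale failure at skull = %.1f mm, DC = %.0f%% (macro stage): %s",
                   sk, dc * 100, conditionMessage(e)), call. = FALSE))
    samples[[k]] <- pts
  }
  pa_max <- max(vapply(samples, function(s) max(s$max_pressure), numeric(1)))
  # microscale pass
  rs <- config_rs(cfg)
  if (pa_max > 0) {
    if (is.null(params)) params <- bls_params()
    tcfg <- cfg$neuron$table
    if (is.null(table)) {
      step <- tcfg$pa_step_kpa * 1e3
      pa_top <- max(step, ceiling(pa_max * 1.05 / step) * step)
      if (progress)
        message(sprintf("building lookup table: PA 0..%g kPa", pa_top / 1e3))
      table <- build_lookup_table(
        params, rs, f = cfg$geometry$frequency_khz * 1e3,
        PA_grid = seq(0, pa_top, by = step),
        Qm_grid = seq(tcfg$qm_min_ncc, tcfg$qm_max_ncc,
                      by = tcfg$qm_step_ncc) * 1e-5,
        nsamples = tcfg$nsamples, rtol = tcfg$rtol)
    } else if (max(table$PA) < pa_max) {
      stop(sprintf("lookup table tops out at %g Pa but the sampled maximum is %g Pa",
                   max(table$PA), pa_max))
    }
  }
  prot <- cfg$protocol
  out <- vector("list", nrow(conditions))
  for (k in seq_len(nrow(conditions))) {
    sk <- conditions$skull_mm[k]; dc <- conditions$dc[k]
    pts <- samples[[k]]
    if (progress)
      message(sprintf("micro runs: skull %.1f mm, DC %.0f%% (%d points)",
                      sk, dc * 100, nrow(pts)))
    lat <- fr <- rep(NA_real_, nrow(pts))
    for (ip in seq_len(nrow(pts))) {
      res <- tryCatch({
        p <- stimulus_protocol(PA = pts$max_pressure[ip],
                               f = cfg$geometry$frequency_khz * 1e3,
                               prf = prot$prf_hz, duty_cycle = dc,
                               duration = prot$duration_ms * 1e-3)
        tr <- simulate_sonic(p, table = table, rs = rs,
                             dt_out = prot$dt_out_us * 1e-6)
        spikes <- detect_spikes(tr, threshold = prot$spike_threshold_mv,
                                refractory = prot$refractory_ms * 1e-3)
        list(lat = compute_latency(spikes, onset = p$onset),
             fr = compute_firing_rate(spikes,
                                      c(p$onset, p$onset + p$duration)))
      }, error = function(e)
        stop(sprintf("multiscale failure at skull = %.1f mm, DC = %.0f%%, point (%.1f, %.1f) mm: %s",
                     sk, dc * 100, pts$x[ip] * 1e3, pts$y[ip] * 1e3,
                     conditionMessage(e)), call. = FALSE))
      lat[ip] <- res$lat; fr[ip] <- res$fr
    }
    out[[k]] <- data.frame(skull_thickness = sk * 1e-3, duty_cycle = dc,
                           x = pts$x, y = pts$y, PA = pts$max_pressure,
                           latency = lat, firing_rate = fr)
  }
  records <- do.call(rbind, out)
  attr(records, "config_hash") <- config_hash(cfg)
  attr(records, "table") <- table
  class(records) <- c("tfus_records", "data.frame")
  records
}

#' Condition-level summary of multiscale records
#'
#' @param records a `tfus_records` data frame
#' @return data frame with one row per (skull thickness, duty cycle):
#'   activated-point count and min/median/max of latency and firing rate
#'   (NA when no point is activated)
#' @export
summarize_responses <- function(records) {
  if (nrow(records) == 0) stop("records must be nonempty")
  key <- interaction(records$skull_thickness, records$duty_cycle, drop = TRUE)
  rows <- lapply(split(records, key), function(d) {
    lat <- d$latency[!is.na(d$latency)]
    fr <- d$firing_rate[!is.na(d$firing_rate)]
    q <- function(v, f) if (length(v)) f(v) else NA_real_
    data.frame(skull_thickness = d$skull_thickness[1],
               duty_cycle = d$duty_cycle[1], n_points = nrow(d),
               n_activated = sum(!is.na(d$latency)),
               latency_min = q(lat, min), latency_median = q(lat, median),
               latency_max = q(lat, max),
               firing_rate_min = q(fr, min),
               firing_rate_median = q(fr, median),
               firing_rate_max = q(fr, max))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$skull_thickness, out$duty_cycle), ]
  rownames(out) <- NULL
  out
}
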