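#' Default run configuration
#'
#' Nested configuration of the whole multiscale pipeline. Numeric keys carry
#' their unit in the name (mm, kPa, kHz, ...), which keeps the config file
#' unambiguous. Every default traces to a study value or a documented design
#' choice; see the methods vignette.
#'
#' @return nested list of class `tfus_config`
#' @export
default_config <- function() {
  structure(list(
    geometry = list(
      dx_mm = 0.5, grid_nx = 560, grid_ny = 560,
      brain_outer_radius_mm = 85, standoff_mm = 40,
      aperture_mm = 64, roc_mm = 63.2, apex_x_mm = 25,
      frequency_khz = 250, amplitude_kpa = 100,
      points_per_wavelength = 4),
    media = list(
      water = list(sound_speed = 1481, density = 998, alpha0 = 0.002),
      skull = list(sound_speed = 2820, density = 1732, alpha0 = 7.75),
      brain = list(sound_speed = 1500, density = 1000, alpha0 = 0.8)),
    solver = list(
      cfl = 0.9, pml = 20, absorption_exponent = 1,
      smoothing_mm = 1, window_us = 500, ramp_cycles = 5),
    sweep = list(
      skull_mm = c(5.4, 7.6, 10.5),
      dc = c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9)),
    roi = list(
      y_rows_mm = c(-10.19, -5.56, -0.92), n_columns = 5,
      column_spacing_mm = 5, x_extent_mm = 20, mirror = FALSE),
    neuron = list(
      rs = list(gNa = 560, gKd = 60, gM = 0.75, gLeak = 0.205, VNa = 50,
                VK = -90, VLeak = -70.3, VT = -56.2, tau_max = 0.608,
                Cm0_uF_cm2 = 1),
      table = list(pa_step_kpa = 25, qm_min_ncc = -100, qm_max_ncc = 50,
                   qm_step_ncc = 5, nsamples = 1000, rtol = 1e-6)),
    protocol = list(
      prf_hz = 500, duration_ms = 100, dt_out_us = 10,
      spike_threshold_mv = 0, refractory_ms = 1),
    output = list(dir = "tfus-out"),
    seed = 1),
    class = "tfus_config")
}

# recursively drop "_"-prefixed comment keys
strip_comments <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!startsWith(names(x) %||% character(length(x)), "_")]
  lapply(x, strip_comments)
}

# recursively list unknown key paths relative to a template
unknown_keys <- function(x, template, path = "") {
  if (!is.list(x) || !is.list(template)) return(character(0))
  out <- character(0)
  for (nm in names(x)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(template)) {
      out <- c(out, here)
    } else if (is.list(x[[nm]]) && is.list(template[[nm]]) &&
               !is.null(names(template[[nm]]))) {
      out <- c(out, unknown_keys(x[[nm]], template[[nm]], here))
    }
  }
  out
}

# deep merge of user values over defaults
merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  problems <- character(0)
  need_pos <- c("geometry.dx_mm", "geometry.grid_nx", "geometry.grid_ny",
                "geometry.brain_outer_radius_mm", "geometry.standoff_mm",
                "geometry.aperture_mm", "geometry.roc_mm",
                "geometry.frequency_khz", "solver.window_us",
                "protocol.prf_hz", "protocol.duration_ms",
                "protocol.dt_out_us")
  for (key in need_pos) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      problems <- c(problems, sprintf("%s must be a positive number", key))
  }
  if (is.numeric(cfg$geometry$amplitude_kpa) && cfg$geometry$amplitude_kpa < 0)
    problems <- c(problems, "geometry.amplitude_kpa must be >= 0")
  if (any(cfg$sweep$dc <= 0 | cfg$sweep$dc > 1))
    problems <- c(problems, "sweep.dc values must be in (0, 1]")
  if (any(cfg$sweep$skull_mm < 0))
    problems <- c(problems, "sweep.skull_mm values must be >= 0")
  for (med in c("water", "skull", "brain")) {
    m <- cfg$media[[med]]
    if (!is.numeric(m$sound_speed) || m$sound_speed <= 0 ||
        !is.numeric(m$density) || m$density <= 0 ||
        !is.numeric(m$alpha0) || m$alpha0 < 0)
      problems <- c(problems, sprintf("media.%s must have positive sound_speed/density and alpha0 >= 0", med))
  }
  problems
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration, strips `_`-prefixed comment keys, rejects
#' unknown keys, fills in defaults, and validates values. All violations are
#' reported together, not just the first. An empty file yields the full
#' default configuration.
#'
#' @param path JSON file path
#' @return a `tfus_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  user <- strip_comments(user)
  defaults <- default_config()
  bad <- unknown_keys(user, defaults)
  problems <- if (length(bad)) paste("unknown config key:", bad) else character(0)
  cfg <- merge_config(unclass(defaults), user)
  problems <- c(problems, validate_config(cfg))
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  structure(cfg, class = "tfus_config")
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialization; identical configurations hash
#' identically across sessions.
#'
#' @param cfg a `tfus_config` (or any serializable list)
#' @return hex string
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  unname(tools::md5sum(tmp))
}

# -- conversions from config units to the SI objects used by the modules ----

config_geometry <- function(cfg, skull_mm = NULL) {
  g <- cfg$geometry
  head_geometry(grid_nx = g$grid_nx, grid_ny = g$grid_ny, dx = g$dx_mm * 1e-3,
                brain_outer_radius = g$brain_outer_radius_mm * 1e-3,
                skull_thickness = (skull_mm %||% cfg$sweep$skull_mm[1]) * 1e-3,
                standoff = g$standoff_mm * 1e-3,
                transducer_aperture = g$aperture_mm * 1e-3,
                transducer_roc = g$roc_mm * 1e-3,
                source_frequency = g$frequency_khz * 1e3,
                source_amplitude = g$amplitude_kpa * 1e3,
                apex_x = g$apex_x_mm * 1e-3,
                points_per_wavelength = g$points_per_wavelength,
                min_sound_speed = min(cfg$media$water$sound_speed,
                                      cfg$media$skull$sound_speed,
                                      cfg$media$brain$sound_speed))
}

config_media <- function(cfg) {
  lapply(cfg$media, function(m)
    medium_properties(m$sound_speed, m$density, m$alpha0))
}

config_solver <- function(cfg, ...) {
  s <- cfg$solver
  solver_config(total_time = s$window_us * 1e-6, cfl = s$cfl,
                pml_size = s$pml, absorption_exponent = s$absorption_exponent,
                smoothing_sigma = s$smoothing_mm * 1e-3,
                ramp_cycles = s$ramp_cycles, ...)
}

config_roi <- function(cfg) {
  r <- cfg$roi
  roi_spec(y_rows = r$y_rows_mm * 1e-3, n_columns = r$n_columns,
           column_spacing = r$column_spacing_mm * 1e-3,
           x_extent = r$x_extent_mm * 1e-3, mirror = isTRUE(r$mirror))
}

config_rs <- function(cfg) {
  r <- cfg$neuron$rs
  rs_neuron_params(gNa = r$gNa, gKd = r$gKd, gM = r$gM, gLeak = r$gLeak,
                   VNa = r$VNa, VK = r$VK, VLeak = r$VLeak, VT = r$VT,
                   tau_max = r$tau_max, Cm0 = r$Cm0_uF_cm2 * 1e-2)
}
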