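#' Low-level source constructor
#'
#' Wraps a logical pixel mask and drive parameters into the source object the
#' solver consumes. `on_time` is the portion of the simulated window during
#' which the sinusoidal drive is active (duty-cycle gating at the window
#' level); the drive is smoothly ramped by the solver.
#'
#' @param mask logical matrix of driven pixels (same shape as the grid)
#' @param amplitude drive pressure amplitude, Pa
#' @param frequency drive frequency, Hz
#' @param on_time seconds the source is on (<= total_time)
#' @param total_time simulated window, s
#' @return an object of class `tfus_source`
#' @export
source_definition <- function(mask, amplitude, frequency, on_time, total_time) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (on_time > total_time) stop("on_time must not exceed total_time")
  structure(list(mask = mask, amplitude = amplitude, frequency = frequency,
                 on_time = on_time, total_time = total_time),
            class = "tfus_source")
}

# rasterize the transducer arc by marching along it: guaranteed connected and
# exactly mirror-symmetric about the axis (theta grid symmetric around 0)
arc_mask <- function(geometry) {
  g <- geometry
  fx <- g$apex_x + g$transducer_roc          # geometric focus, on the axis
  fy <- g$head_center[2]
  half <- asin((g$transducer_aperture / 2) / g$transducer_roc)
  n <- max(65L, ceiling(4 * g$transducer_roc * 2 * half / g$dx))
  if (n %% 2 == 0) n <- n + 1L               # odd count keeps theta = 0 on grid
  th <- seq(-half, half, length.out = n)
  i <- round((fx - g$transducer_roc * cos(th)) / g$dx + 0.5)
  j <- round((fy + g$transducer_roc * sin(th)) / g$dx + 0.5)
  if (any(i < 1 | i > g$grid_nx | j < 1 | j > g$grid_ny))
    stop("bounds error: transducer arc does not fit in the grid")
  mask <- matrix(FALSE, g$grid_nx, g$grid_ny)
  mask[cbind(i, j)] <- TRUE
  # enforce exact mirror symmetry about the axis (rounding ties at the pixel
  # boundary would otherwise bias one side on even-sized grids)
  mask | mask[, rev(seq_len(g$grid_ny)), drop = FALSE]
}

#' Build the focused transducer source
#'
#' Places the curved source arc so its apex sits `standoff` metres from the
#' outer skull boundary along the beam axis, and gates the sinusoidal drive
#' at the window level: `on_time = duty_cycle * window`.
#'
#' @param geometry a [head_geometry()]
#' @param duty_cycle fraction of the window the drive is on, in (0, 1]
#' @param window simulated window, s
#' @return an object of class `tfus_source`
#' @export
build_transducer_source <- function(geometry, duty_cycle = 1, window = 500e-6) {
  stopifnot(inherits(geometry, "tfus_geometry"))
  if (!(duty_cycle > 0 && duty_cycle <= 1)) stop("duty_cycle must be in (0, 1]")
  if (window <= 0) stop("window must be > 0")
  source_definition(arc_mask(geometry), geometry$source_amplitude,
                    geometry$source_frequency,
                    on_time = duty_cycle * window, total_time = window)
}
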