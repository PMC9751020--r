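#' Acoustic properties of one medium
#'
#' Bundles the three acoustic constants used by the propagation model: sound
#' speed, mass density and the absorption constant `alpha0` expressed in
#' dB/(MHz·cm), i.e. the absorption in dB/cm at 1 MHz of a power-law
#' absorption model `alpha(f) = alpha0 * (f / 1 MHz)^gamma`.
#'
#' @param sound_speed sound speed in m/s (> 0)
#' @param density mass density in kg/m^3 (> 0)
#' @param alpha0 absorption constant in dB/(MHz·cm) (>= 0)
#' @return an object of class `tfus_medium`
#' @export
medium_properties <- function(sound_speed, density, alpha0) {
  if (!is.numeric(sound_speed) || sound_speed <= 0)
    stop("sound_speed must be a positive number")
  if (!is.numeric(density) || density <= 0)
    stop("density must be a positive number")
  if (!is.numeric(alpha0) || alpha0 < 0)
    stop("alpha0 must be non-negative")
  structure(list(sound_speed = sound_speed, density = density, alpha0 = alpha0),
            class = "tfus_medium")
}

#' Default media table: water, skull, brain
#'
#' Sound speed (m/s), density (kg/m^3) and absorption constant (dB/(MHz·cm))
#' for the three media of the simplified head model: degassed water coupling
#' medium, cranial bone, and brain tissue.
#'
#' @return named list of [medium_properties()] objects with entries
#'   `water`, `skull`, `brain`
#' @export
default_media <- function() {
  list(water = medium_properties(1481, 998, 0.002),
       skull = medium_properties(2820, 1732, 7.75),
       brain = medium_properties(1500, 1000, 0.8))
}

#' Head-model geometry configuration
#'
#' Describes the 2D simulation domain: a disc-shaped brain wrapped by a skull
#' annulus of configurable thickness, immersed in water, insonified by a
#' focused arc transducer whose apex sits `standoff` metres from the outer
#' skull surface along the beam axis. The x axis is the propagation
#' direction; the transducer axis runs along y = ny*dx/2. Pixel centres sit
#' at `(i - 0.5) * dx`.
#'
#' @param grid_nx,grid_ny grid size in pixels
#' @param dx pixel size in metres
#' @param brain_outer_radius outer skull radius in metres (the skull annulus
#'   grows inward, so the outer head surface is fixed)
#' @param skull_thickness skull layer thickness in metres (>= 0)
#' @param standoff transducer-apex to outer-skull distance along the axis, m
#' @param transducer_aperture arc chord (active diameter), m
#' @param transducer_roc arc radius of curvature (geometric focal length), m
#' @param source_frequency drive frequency, Hz
#' @param source_amplitude drive pressure amplitude, Pa
#' @param apex_x x position of the transducer arc apex, m
#' @param points_per_wavelength minimum spatial sampling used to validate dx
#'   against the slowest medium
#' @param head_center optional `(x, y)` centre of the head in metres;
#'   computed from `apex_x + standoff + brain_outer_radius` when `NULL`
#' @param min_sound_speed slowest sound speed used for the dx check, m/s
#' @return an object of class `tfus_geometry`
#' @export
head_geometry <- function(grid_nx = 560, grid_ny = 560, dx = 0.5e-3,
                          brain_outer_radius = 85e-3, skull_thickness = 5.4e-3,
                          standoff = 40e-3, transducer_aperture = 64e-3,
                          transducer_roc = 63.2e-3, source_frequency = 250e3,
                          source_amplitude = 100e3, apex_x = 25e-3,
                          points_per_wavelength = 4, head_center = NULL,
                          min_sound_speed = 1481) {
  if (skull_thickness < 0) stop("geometry error: skull_thickness must be >= 0")
  if (standoff <= 0) stop("geometry error: standoff must be > 0")
  if (dx <= 0) stop("geometry error: dx must be > 0")
  dx_max <- min_sound_speed / (source_frequency * points_per_wavelength)
  if (dx > dx_max)
    stop(sprintf("geometry error: dx = %g m exceeds %g m required by %g points per wavelength",
                 dx, dx_max, points_per_wavelength))
  if (is.null(head_center))
    head_center <- c(apex_x + standoff + brain_outer_radius, grid_ny * dx / 2)
  structure(list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
                 dx = dx, brain_outer_radius = brain_outer_radius,
                 skull_thickness = skull_thickness, standoff = standoff,
                 transducer_aperture = transducer_aperture,
                 transducer_roc = transducer_roc,
                 source_frequency = source_frequency,
                 source_amplitude = source_amplitude, apex_x = apex_x,
                 points_per_wavelength = points_per_wavelength,
                 head_center = head_center),
            class = "tfus_geometry")
}

#' Build the per-pixel property rasters of the simplified head
#'
#' Labels every pixel water, skull or brain (two concentric circles: the
#' inner disc is brain, the annulus is skull) and populates sound-speed,
#' density and absorption rasters from the media table. Pixels are classified
#' by their centre; the label rasters therefore tile the grid exactly.
#'
#' @param geometry a [head_geometry()]
#' @param media named list with `water`, `skull`, `brain` entries of class
#'   `tfus_medium` (see [default_media()])
#' @return an object of class `tfus_medium_map`: integer `label` matrix
#'   (0 = water, 1 = skull, 2 = brain), `sound_speed`, `density`, `alpha0`
#'   matrices, grid metadata and a geometry echo
#' @export
build_head_map <- function(geometry, media = default_media()) {
  stopifnot(inherits(geometry, "tfus_geometry"))
  for (nm in c("water", "skull", "brain"))
    if (!inherits(media[[nm]], "tfus_medium"))
      stop(sprintf("media table lacks a valid '%s' entry", nm))
  g <- geometry
  if (g$skull_thickness > g$brain_outer_radius)
    stop("geometry error: skull_thickness exceeds brain_outer_radius")
  cx <- g$head_center[1]; cy <- g$head_center[2]
  Lx <- g$grid_nx * g$dx; Ly <- g$grid_ny * g$dx
  if (cx - g$brain_outer_radius < 0 || cx + g$brain_outer_radius > Lx ||
      cy - g$brain_outer_radius < 0 || cy + g$brain_outer_radius > Ly)
    stop("bounds error: head extends beyond the grid")
  xs <- (seq_len(g$grid_nx) - 0.5) * g$dx
  ys <- (seq_len(g$grid_ny) - 0.5) * g$dx
  D2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
  lab <- matrix(0L, g$grid_nx, g$grid_ny)
  lab[D2 <= g$brain_outer_radius^2] <- 1L
  lab[D2 <= (g$brain_outer_radius - g$skull_thickness)^2] <- 2L
  pick <- function(field) {
    v <- c(media$water[[field]], media$skull[[field]], media$brain[[field]])
    matrix(v[lab + 1L], g$grid_nx, g$grid_ny)
  }
  structure(list(label = lab, sound_speed = pick("sound_speed"),
                 density = pick("density"), alpha0 = pick("alpha0"),
                 dx = g$dx, origin = c(0, 0), geometry = g, media = media),
            class = "tfus_medium_map")
}

#' @export
print.tfus_medium_map <- function(x, ...) {
  n <- tabulate(x$label + 1L, 3L)
  cat(sprintf("<tfus_medium_map> %d x %d pixels, dx = %g mm\n",
              nrow(x$label), ncol(x$label), x$dx * 1e3))
  cat(sprintf("  water %d | skull %d | brain %d pixels\n", n[1], n[2], n[3]))
  invisible(x)
}
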