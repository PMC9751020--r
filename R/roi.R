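#' Focal region-of-interest sampling specification
#'
#' Defines the 3 x 5 grid of focal positions where pressures are read off
#' the macroscale maps: three lateral rows (offsets from the transducer
#' axis; the defaults are the printed study positions, all on one side plus
#' the near-axis row) times five axial columns spanning the focal length
#' scale, starting at the axial position of the focal peak.
#'
#' @param y_rows lateral offsets from the transducer axis, m
#' @param n_columns axial sample count per row
#' @param column_spacing axial spacing, m
#' @param x_extent axial span covered by the columns, m (consistency check:
#'   `(n_columns - 1) * column_spacing <= x_extent`)
#' @param mirror also sample the mirrored (`y -> -y`) rows
#' @return an object of class `tfus_roi`
#' @export
roi_spec <- function(y_rows = c(-10.19, -5.56, -0.92) * 1e-3, n_columns = 5,
                     column_spacing = 5e-3, x_extent = 20e-3,
                     mirror = FALSE) {
  if (n_columns < 1 || column_spacing <= 0)
    stop("n_columns and column_spacing must be positive")
  if ((n_columns - 1) * column_spacing > x_extent + 1e-12)
    stop("columns exceed the configured axial extent")
  structure(list(y_rows = y_rows, n_columns = as.integer(n_columns),
                 column_spacing = column_spacing, x_extent = x_extent,
                 mirror = mirror),
            class = "tfus_roi")
}

#' Sample focal-region pressures from a field map
#'
#' Finds the focal peak of the maximum-pressure map (restricted to the brain
#' region when labels are available), lays out the ROI columns starting at
#' that axial position, and samples the map at the nearest pixel of each of
#' the `length(y_rows) * n_columns` positions.
#'
#' @param field a `tfus_field_maps`
#' @param roi a [roi_spec()]
#' @param y_axis lateral position of the transducer axis, m; defaults to the
#'   head-centre y of the geometry carried by `field`
#' @param x_start axial position of the first column, m; defaults to the
#'   focal-peak position
#' @param require_brain error when a sample falls outside the brain region
#'   (needs labels in `field`)
#' @param edge_clearance minimum distance of the peak-search region from the
#'   skull inner surface, m. Pressure maxima right at the bone-brain
#'   interface are near-field artifacts of the transmitted/reflected wave;
#'   the focal peak of interest lies at cortical depth.
#' @return data frame with columns `x`, `y` (m) and `max_pressure` (Pa)
#' @export
extract_roi_points <- function(field, roi = roi_spec(), y_axis = NULL,
                               x_start = NULL, require_brain = TRUE,
                               edge_clearance = 5e-3) {
  stopifnot(inherits(field, "tfus_field_maps") || is.list(field))
  mp <- field$max_pressure
  dx <- field$dx
  nx <- nrow(mp); ny <- ncol(mp)
  lab <- field$label
  have_lab <- !is.null(lab) && any(lab == 2L)
  y_axis <- y_axis %||% field$geometry$head_center[2]
  if (is.null(y_axis)) stop("y_axis is required when the field carries no geometry")
  if (is.null(x_start)) {
    m <- mp
    if (have_lab) {
      keep <- lab == 2L
      geom <- field$geometry
      if (edge_clearance > 0 && !is.null(geom$brain_outer_radius)) {
        r_in <- geom$brain_outer_radius - geom$skull_thickness
        xs <- (seq_len(nx) - 0.5) * dx
        ys2 <- (seq_len(ny) - 0.5) * dx
        D2 <- outer((xs - geom$head_center[1])^2,
                    (ys2 - geom$head_center[2])^2, `+`)
        keep <- keep & D2 <= (r_in - edge_clearance)^2
      }
      m[!keep] <- -Inf
    }
    k <- arrayInd(which.max(m), dim(m))
    x_start <- (k[1] - 0.5) * dx
  }
  ys <- y_axis + roi$y_rows
  if (isTRUE(roi$mirror)) ys <- c(ys, y_axis - roi$y_rows)
  xs <- x_start + (seq_len(roi$n_columns) - 1) * roi$column_spacing
  pts <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  i <- round(pts$x / dx + 0.5); j <- round(pts$y / dx + 0.5)
  if (any(i < 1 | i > nx | j < 1 | j > ny))
    stop("geometry error: ROI extends beyond the grid")
  if (require_brain && have_lab && any(lab[cbind(i, j)] != 2L))
    stop("geometry error: ROI sample outside the brain region")
  pts$max_pressure <- mp[cbind(i, j)]
  pts
}
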