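#' Plot a field map
#'
#' @param x a `tfus_field_maps`
#' @param which `"pressure"` or `"intensity"`
#' @param ... passed to [graphics::image()]
#' @return `x`, invisibly
#' @export
plot.tfus_field_maps <- function(x, which = c("pressure", "intensity"), ...) {
  which <- match.arg(which)
  m <- if (which == "pressure") x$max_pressure / 1e3 else x$avg_intensity / 1e4
  lab <- if (which == "pressure") "max pressure (kPa)" else
    "avg intensity (W/cm^2)"
  xs <- (seq_len(nrow(m)) - 0.5) * x$dx * 1e3
  ys <- (seq_len(ncol(m)) - 0.5) * x$dx * 1e3
  graphics::image(xs, ys, m, xlab = "x (mm)", ylab = "y (mm)",
                  main = lab, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Latency / firing-rate profiles along the beam axis direction
#'
#' One panel per lateral row: the chosen response metric against the axial
#' coordinate, one line per condition (duty cycle or skull thickness).
#'
#' @param records a `tfus_records` data frame
#' @param metric `"latency"` (ms) or `"firing_rate"` (spikes/s)
#' @param by condition variable distinguishing the lines
#' @return invisibly, `records`
#' @export
plot_response_profiles <- function(records,
                                   metric = c("latency", "firing_rate"),
                                   by = c("duty_cycle", "skull_thickness")) {
  metric <- match.arg(metric)
  by <- match.arg(by)
  v <- records[[metric]]
  if (metric == "latency") v <- v * 1e3
  ylab <- if (metric == "latency") "latency (ms)" else "firing rate (sp/s)"
  rows <- sort(unique(records$y))
  conds <- sort(unique(records[[by]]))
  old <- graphics::par(mfrow = c(1, length(rows)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (yr in rows) {
    sel <- records$y == yr
    rng <- range(v[sel], na.rm = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    graphics::plot(NA, xlim = range(records$x[sel]) * 1e3, ylim = rng,
                   xlab = "x (mm)", ylab = ylab,
                   main = sprintf("y = %.2f mm", yr * 1e3))
    for (ic in seq_along(conds)) {
      s2 <- sel & records[[by]] == conds[ic]
      o <- order(records$x[s2])
      graphics::lines(records$x[s2][o] * 1e3, v[s2][o], col = ic, type = "b")
    }
    graphics::legend("topleft", legend = signif(conds, 3), col =
                       seq_along(conds), lty = 1, cex = 0.7, bty = "n")
  }
  invisible(records)
}
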