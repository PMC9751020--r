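#' Export field maps as portable CSV + JSON metadata
#'
#' Writes the maximum-pressure and time-averaged-intensity rasters as plain
#' CSV matrices together with a JSON sidecar holding grid metadata and the
#' solver configuration echo, plus a per-region (water/skull/brain) summary
#' when labels are available.
#'
#' @param field a `tfus_field_maps`
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return character vector of written paths, invisibly
#' @export
write_field_maps <- function(field, dir, prefix = "field") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("max_pressure", "avg_intensity")) {
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, nm))
    utils::write.table(field[[nm]], p, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(dx = field$dx, origin = field$origin, dt = field$dt,
               nsteps = field$nsteps, source = field$source,
               max_pressure_pa = max(field$max_pressure),
               max_avg_intensity_w_m2 = max(field$avg_intensity))
  mpath <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, mpath, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  paths <- c(paths, mpath)
  if (!is.null(field$label)) {
    reg <- region_summary(field)
    rpath <- file.path(dir, paste0(prefix, "_regions.csv"))
    utils::write.csv(reg, rpath, row.names = FALSE)
    paths <- c(paths, rpath)
  }
  invisible(paths)
}

#' Export a medium map for inspection
#'
#' Writes the label raster and the three property rasters as CSV matrices
#' with a JSON sidecar carrying the grid metadata and geometry echo.
#'
#' @param medium a `tfus_medium_map`
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return character vector of written paths, invisibly
#' @export
write_medium_map <- function(medium, dir, prefix = "medium") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("label", "sound_speed", "density", "alpha0")) {
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, nm))
    utils::write.table(medium[[nm]], p, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(dx = medium$dx, origin = medium$origin,
               labels = c(water = 0, skull = 1, brain = 2),
               geometry = medium$geometry[setdiff(names(medium$geometry),
                                                  character(0))])
  mpath <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, mpath, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(paths, mpath))
}

#' Per-region maxima of a field map
#'
#' @param field a `tfus_field_maps` carrying a label raster
#' @return data frame with per-region pixel count, maximum pressure (Pa) and
#'   maximum time-averaged intensity (W/m^2)
#' @export
region_summary <- function(field) {
  if (is.null(field$label)) stop("field carries no region labels")
  labs <- c(water = 0L, skull = 1L, brain = 2L)
  rows <- lapply(names(labs), function(nm) {
    sel <- field$label == labs[[nm]]
    data.frame(region = nm, n_pixels = sum(sel),
               max_pressure = if (any(sel)) max(field$max_pressure[sel]) else NA_real_,
               max_avg_intensity = if (any(sel)) max(field$avg_intensity[sel]) else NA_real_)
  })
  do.call(rbind, rows)
}

# records in reporting units
records_csv_frame <- function(records) {
  data.frame(skull_mm = records$skull_thickness * 1e3,
             dc = records$duty_cycle,
             x_mm = records$x * 1e3, y_mm = records$y * 1e3,
             pa_kpa = records$PA / 1e3,
             latency_ms = records$latency * 1e3,
             firing_rate_sps = records$firing_rate)
}

#' Write pipeline outputs with a manifest
#'
#' Writes the per-point records CSV, the condition summary CSV, optional
#' field-map exports, and a `manifest.json` listing every file with its MD5,
#' the configuration hash and the package version. Identical runs produce
#' byte-identical CSVs.
#'
#' @param records a `tfus_records` data frame (may have zero rows)
#' @param maps optional named list of `tfus_field_maps` to export
#' @param out_dir output directory
#' @param config optional `tfus_config` used to stamp the manifest
#' @return the manifest, invisibly
#' @export
write_outputs <- function(records, maps = NULL, out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  rpath <- file.path(out_dir, "records.csv")
  utils::write.csv(records_csv_frame(records), rpath, row.names = FALSE)
  paths <- c(paths, rpath)
  if (nrow(records) > 0) {
    spath <- file.path(out_dir, "summary.csv")
    utils::write.csv(summarize_responses(records), spath, row.names = FALSE)
    paths <- c(paths, spath)
  }
  for (nm in names(maps))
    paths <- c(paths, write_field_maps(maps[[nm]], out_dir, prefix = nm))
  hash <- if (!is.null(config)) config_hash(config) else
    attr(records, "config_hash") %||% NA_character_
  manifest <- list(
    files = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    config_hash = hash,
    tool = "tfusim",
    version = as.character(utils::packageVersion("tfusim")))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
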