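#' Build the cycle-averaged effective-variable lookup table
#'
#' For every node of the (pressure amplitude x membrane charge) grid, the
#' sonophore mechanics are run to their periodic steady state and the
#' electrical quantities are averaged over the final acoustic cycle:
#' the inverse-capacitance average `<1/Cm>_T` (so the effective potential is
#' `V* = Qm * <1/Cm>_T`) and the effective rate constants
#' `alpha*_x = <alpha_x(V(t))>_T` with `V(t) = Qm / Cm(t)`.
#'
#' The `PA = 0` row is the unsonicated membrane and is filled exactly:
#' `<1/Cm> = 1/Cm0` and textbook rates at `V = Qm / Cm0`.
#'
#' @param params a [bls_params()]
#' @param rs a [rs_neuron_params()]
#' @param f acoustic frequency, Hz
#' @param PA_grid strictly increasing amplitudes, Pa; must include 0
#' @param Qm_grid strictly increasing charge densities, C/m^2
#' @param nsamples per-cycle samples used for the averages
#' @param rtol mechanical integrator tolerance
#' @param progress print one line per amplitude row
#' @return an object of class `tfus_lookup`
#' @export
build_lookup_table <- function(params, rs = rs_neuron_params(), f = 250e3,
                               PA_grid = seq(0, 150e3, by = 10e3),
                               Qm_grid = seq(-100, 50, by = 1) * 1e-5,
                               nsamples = 1000, rtol = 1e-6,
                               progress = FALSE) {
  stopifnot(inherits(params, "tfus_bls"))
  if (any(diff(PA_grid) <= 0) || any(diff(Qm_grid) <= 0))
    stop("PA_grid and Qm_grid must be strictly increasing")
  if (PA_grid[1] != 0) stop("PA_grid must include 0 as its first entry")
  nP <- length(PA_grid); nQ <- length(Qm_grid)
  rate_names <- c("alpha_m", "beta_m", "alpha_h", "beta_h",
                  "alpha_n", "beta_n", "alpha_p", "beta_p")
  invcm <- matrix(NA_real_, nP, nQ)
  rates <- array(NA_real_, c(nP, nQ, 8), dimnames = list(NULL, NULL, rate_names))
  # unsonicated row: exact
  invcm[1, ] <- 1 / params$Cm0
  rates[1, , ] <- rs_rates_cpp(Qm_grid / params$Cm0 * 1e3, rs)
  for (ip in seq_len(nP)[-1]) {
    if (progress)
      message(sprintf("lookup row PA = %g kPa (%d/%d)", PA_grid[ip] / 1e3, ip, nP))
    for (iq in seq_len(nQ)) {
      cyc <- tryCatch(
        mechanical_steady_cycle(PA_grid[ip], Qm_grid[iq], params, f,
                                rtol = rtol, nsamples = nsamples),
        error = function(e)
          stop(sprintf("lookup node PA = %g Pa, Qm = %g C/m^2 failed: %s",
                       PA_grid[ip], Qm_grid[iq], conditionMessage(e)),
               call. = FALSE))
      invcm[ip, iq] <- mean(1 / cyc$Cm)
      rates[ip, iq, ] <- colMeans(rs_rates_cpp(Qm_grid[iq] / cyc$Cm * 1e3, rs))
    }
  }
  structure(list(PA = PA_grid, Qm = Qm_grid, f = f, invcm = invcm,
                 rates = rates, params = params[setdiff(names(params),
                                                        c("pm_z", "pm_val"))],
                 rs = unclass(rs), version = 1L),
            class = "tfus_lookup")
}

#' @export
print.tfus_lookup <- function(x, ...) {
  cat(sprintf("<tfus_lookup> f = %g kHz, PA 0..%g kPa (%d) x Qm %g..%g nC/cm^2 (%d)\n",
              x$f / 1e3, max(x$PA) / 1e3, length(x$PA),
              min(x$Qm) * 1e5, max(x$Qm) * 1e5, length(x$Qm)))
  invisible(x)
}

# 1D slice of the table at amplitude PA (linear interpolation along PA)
lookup_slice <- function(table, PA) {
  stopifnot(inherits(table, "tfus_lookup"))
  if (PA < min(table$PA) || PA > max(table$PA))
    stop(sprintf("range error: PA = %g Pa outside the lookup range [%g, %g]",
                 PA, min(table$PA), max(table$PA)))
  if (PA %in% table$PA) {
    ip <- match(PA, table$PA)
    return(list(Qm = table$Qm, invcm = table$invcm[ip, ],
                rates = table$rates[ip, , ]))
  }
  hi <- which(table$PA > PA)[1]
  lo <- hi - 1L
  w <- (PA - table$PA[lo]) / (table$PA[hi] - table$PA[lo])
  list(Qm = table$Qm,
       invcm = (1 - w) * table$invcm[lo, ] + w * table$invcm[hi, ],
       rates = (1 - w) * table$rates[lo, , ] + w * table$rates[hi, , ])
}

#' Bilinear interpolation of the effective variables
#'
#' @param table a `tfus_lookup`
#' @param PA amplitude, Pa (within table range)
#' @param Qm charge density, C/m^2 (within table range)
#' @return named list: `invcm` plus the eight effective rates
#' @export
lookup_interp <- function(table, PA, Qm) {
  sl <- lookup_slice(table, PA)
  if (Qm < min(sl$Qm) || Qm > max(sl$Qm))
    stop("range error: Qm outside the lookup range")
  out <- c(invcm = approx(sl$Qm, sl$invcm, xout = Qm)$y,
           apply(sl$rates, 2, function(v) approx(sl$Qm, v, xout = Qm)$y))
  as.list(out)
}

#' Write / read a lookup table as portable JSON
#'
#' @param table a `tfus_lookup`
#' @param path file path
#' @return `read_lookup` returns the restored `tfus_lookup`;
#'   `write_lookup` returns `path` invisibly
#' @export
write_lookup <- function(table, path) {
  stopifnot(inherits(table, "tfus_lookup"))
  obj <- unclass(table)
  # store arrays flattened (column-major) for an unambiguous round trip
  obj$invcm <- as.numeric(table$invcm)
  obj$rates <- lapply(seq_len(dim(table$rates)[3]),
                      function(k) as.numeric(table$rates[, , k]))
  names(obj$rates) <- dimnames(table$rates)[[3]]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rate_names <- names(obj$rates)
  rates <- array(NA_real_, c(length(obj$PA), length(obj$Qm), length(rate_names)),
                 dimnames = list(NULL, NULL, rate_names))
  for (k in seq_along(rate_names)) rates[, , k] <- obj$rates[[rate_names[k]]]
  structure(list(PA = obj$PA, Qm = obj$Qm, f = obj$f,
                 invcm = matrix(obj$invcm, length(obj$PA), length(obj$Qm)),
                 rates = rates, params = obj$params, rs = obj$rs,
                 version = obj$version),
            class = "tfus_lookup")
}
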