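#' Periodic steady state of the sonophore mechanics
#'
#' Integrates the modified Rayleigh-Plesset deflection equation together with
#' the trans-leaflet gas exchange at fixed membrane charge and drive
#' amplitude until the oscillation is cycle-to-cycle periodic, then returns
#' the last acoustic cycle uniformly resampled. Integration starts from the
#' charge-balanced quasi-static equilibrium, so with `PA = 0` the state
#' simply stays there.
#'
#' @param PA acoustic pressure amplitude, Pa (>= 0)
#' @param Qm membrane charge density held fixed during the cycle, C/m^2
#' @param params a [bls_params()]
#' @param f drive frequency, Hz
#' @param rtol relative tolerance of the adaptive integrator
#' @param max_cycles convergence error is raised beyond this many cycles
#' @param conv_tol relative cycle-to-cycle change of the deflection extrema
#'   accepted as periodic
#' @param nsamples uniform samples of the returned cycle
#' @return an object of class `tfus_cycle`: `t` (s, within `[0, 1/f)`),
#'   `Z` (m), `ng` (mol), `Cm` (F/m^2), plus convergence metadata
#' @export
mechanical_steady_cycle <- function(PA, Qm, params, f = 250e3, rtol = 1e-6,
                                    max_cycles = 100, conv_tol = 1e-3,
                                    nsamples = 1000) {
  stopifnot(inherits(params, "tfus_bls"))
  if (PA < 0) stop("PA must be >= 0")
  out <- mech_cycle_cpp(PA, Qm, params, f, rtol, as.integer(max_cycles),
                        conv_tol, as.integer(nsamples), 5e7)
  if (!out$converged)
    stop(sprintf("convergence error: mechanical cycle at PA = %g Pa, Qm = %g C/m^2 not periodic after %d cycles",
                 PA, Qm, max_cycles))
  structure(list(t = out$t, Z = out$Z, ng = out$ng,
                 Cm = cm_cpp(out$Z, params), PA = PA, Qm = Qm, f = f,
                 ncycles = out$ncycles, nsteps = out$nsteps),
            class = "tfus_cycle")
}

#' @export
print.tfus_cycle <- function(x, ...) {
  cat(sprintf("<tfus_cycle> PA = %g kPa, Qm = %g nC/cm^2: Z in [%.3g, %.3g] nm after %d cycles\n",
              x$PA / 1e3, x$Qm * 1e5, min(x$Z) * 1e9, max(x$Z) * 1e9,
              x$ncycles))
  invisible(x)
}
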