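#' Brute-force co-integration oracle of the full cavitation-neuron system
#'
#' Integrates the sonophore mechanics and the voltage-form membrane equation
#' (`dVm/dt = -(1/Cm)(Vm dCm/dt + sum_i I_i)`) together at sub-acoustic-cycle
#' resolution with an adaptive scheme (the step never exceeds 1/40 of an
#' acoustic period during sonication). This is the expensive reference
#' implementation against which the effective-variable integration is
#' validated; it is deliberately capped in duration.
#'
#' @param protocol a [stimulus_protocol()]
#' @param params a [bls_params()]
#' @param rs a [rs_neuron_params()]
#' @param max_duration refuse protocols longer than this, s
#' @param rtol integrator relative tolerance
#' @param dt_out uniform output sampling interval, s
#' @param tail extra unstimulated time after the protocol, s
#' @return a data frame of class `tfus_trace` with columns `t`, `Z` (m),
#'   `ng` (mol), `Qm` (C/m^2), `Vm` (mV, instantaneous), gates and `us_on`
#' @export
simulate_full_nbls <- function(protocol, params, rs = rs_neuron_params(),
                               max_duration = 50e-3, rtol = 1e-6,
                               dt_out = 1e-5, tail = 0) {
  stopifnot(inherits(protocol, "tfus_protocol"), inherits(params, "tfus_bls"))
  p <- protocol
  if (p$duration > max_duration)
    stop(sprintf("oracle duration %g s exceeds max_duration = %g s (the full co-integration is expensive by design)",
                 p$duration, max_duration))
  tend <- p$onset + p$duration + tail
  out <- nbls_cpp(p$PA, p$f, p$prf, p$duty_cycle, p$onset, p$duration, tend,
                  params, rs, rtol, dt_out, 2000)
  Cm <- cm_cpp(out$Z, params)
  res <- data.frame(t = out$t, Z = out$Z, ng = out$ng,
                    Qm = Cm * out$Vm * 1e-3, Vm = out$Vm, m = out$m,
                    h = out$h, n = out$n, p = out$p,
                    us_on = protocol_on(out$t, p))
  attr(res, "protocol") <- p
  class(res) <- c("tfus_trace", "data.frame")
  res
}
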