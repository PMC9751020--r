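#' Pulsed ultrasound stimulation protocol
#'
#' @param PA in-situ acoustic pressure amplitude at the neuron, Pa
#' @param f acoustic carrier frequency, Hz
#' @param prf pulse repetition frequency, Hz
#' @param duty_cycle on-fraction of each repetition period, in `[0, 1]`
#' @param duration total stimulation time, s
#' @param onset stimulus onset, s
#' @return an object of class `tfus_protocol`
#' @export
stimulus_protocol <- function(PA, f = 250e3, prf = 500, duty_cycle = 1,
                              duration = 100e-3, onset = 0) {
  if (duty_cycle < 0 || duty_cycle > 1) stop("duty_cycle must be in [0, 1]")
  if (PA < 0) stop("PA must be >= 0")
  if (onset < 0) stop("onset must be >= 0")
  if (duty_cycle < 1 && f < 10 * prf)
    stop("carrier frequency must be well above the pulse repetition frequency")
  structure(list(PA = PA, f = f, prf = prf, duty_cycle = duty_cycle,
                 duration = duration, onset = onset),
            class = "tfus_protocol")
}

# ultrasound-ON flag at times t for a protocol
protocol_on <- function(t, protocol) {
  p <- protocol
  rel <- t - p$onset
  inside <- rel >= 0 & rel < p$duration & p$PA > 0 & p$duty_cycle > 0
  if (p$duty_cycle >= 1) return(inside)
  phase <- rel %% (1 / p$prf)
  inside & phase < p$duty_cycle / p$prf
}

#' Integrate the charge-cast membrane with effective variables
#'
#' During ultrasound-ON intervals the membrane evolves under the
#' cycle-averaged effective variables interpolated from the lookup table
#' (`dQm/dt = -sum_i G_i (V* - V_i)` with `V* = Qm <1/Cm>_T`, and effective
#' gate rates); during OFF intervals it is the standard
#' resting-capacitance Hodgkin-Huxley system with `Vm = Qm / Cm0`.
#'
#' @param protocol a [stimulus_protocol()]
#' @param table a `tfus_lookup` covering `protocol$PA` (may be `NULL` when
#'   `PA = 0`)
#' @param rs a [rs_neuron_params()]
#' @param rtol integrator relative tolerance
#' @param dt_out uniform output sampling interval, s
#' @param tail extra unstimulated time simulated after the protocol, s
#' @return a data frame of class `tfus_trace` with columns `t`, `Qm` (C/m^2),
#'   `Vm` (mV; the effective potential during ON intervals), the four gates
#'   and the `us_on` flag
#' @export
simulate_sonic <- function(protocol, table = NULL, rs = rs_neuron_params(),
                           rtol = 1e-6, dt_out = 1e-5, tail = 0) {
  stopifnot(inherits(protocol, "tfus_protocol"))
  p <- protocol
  tend <- p$onset + p$duration + tail
  stimulated <- p$PA > 0 && p$duty_cycle > 0
  if (stimulated) {
    if (is.null(table)) stop("a lookup table is required when PA > 0")
    if (!isTRUE(all.equal(table$f, p$f)))
      warning("protocol frequency differs from the lookup-table frequency")
    sl <- lookup_slice(table, p$PA)
    out <- sonic_cpp(p$prf, p$duty_cycle, p$onset, p$duration, tend, rs,
                     sl$Qm, sl$invcm, sl$rates, rtol, dt_out)
  } else {
    out <- sonic_cpp(p$prf, 0, p$onset, p$duration, tend, rs,
                     numeric(0), numeric(0), matrix(0, 0, 8), rtol, dt_out)
  }
  on <- protocol_on(out$t, p)
  Vm <- out$Qm / rs$Cm0 * 1e3
  if (stimulated && any(on)) {
    qc <- pmin(pmax(out$Qm[on], min(sl$Qm)), max(sl$Qm))
    Vm[on] <- out$Qm[on] * approx(sl$Qm, sl$invcm, xout = qc)$y * 1e3
  }
  res <- data.frame(t = out$t, Qm = out$Qm, Vm = Vm, m = out$m, h = out$h,
                    n = out$n, p = out$p, us_on = on)
  attr(res, "protocol") <- p
  class(res) <- c("tfus_trace", "data.frame")
  res
}
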