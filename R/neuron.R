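#' Regular-spiking cortical neuron membrane parameters
#'
#' The standard published regular-spiking (RS) cortical point-neuron set used
#' by the effective-variable sonication literature: sodium, delayed-rectifier
#' potassium, slow non-inactivating potassium (M-type) and leak currents.
#' These values are reference-derived (they are not printed in every study
#' that uses the model) and are deliberately exposed as an editable block.
#'
#' @param gNa,gKd,gM,gLeak maximal conductances, S/m^2
#' @param VNa,VK,VLeak reversal potentials, mV
#' @param VT spike-threshold adjustment of the rate functions, mV
#' @param tau_max slow non-inactivating gate time-constant scale, s
#' @param Cm0 resting membrane capacitance, F/m^2
#' @return an object of class `tfus_rs`
#' @export
rs_neuron_params <- function(gNa = 560, gKd = 60, gM = 0.75, gLeak = 0.205,
                             VNa = 50, VK = -90, VLeak = -70.3, VT = -56.2,
                             tau_max = 0.608, Cm0 = 1e-2) {
  structure(list(gNa = gNa, gKd = gKd, gM = gM, gLeak = gLeak, VNa = VNa,
                 VK = VK, VLeak = VLeak, VT = VT, tau_max = tau_max,
                 Cm0 = Cm0),
            class = "tfus_rs")
}

#' Voltage-dependent activation/inactivation rate constants
#'
#' Rates of the four gates (`m`, `h` sodium; `n` delayed-rectifier; `p` slow
#' non-inactivating), in 1/s, at membrane potential(s) in mV. Rates are
#' capped at 1e5/s: beyond that they act as instantaneous equilibration and
#' only destabilise the integrators (the cap only binds at non-physiological
#' potentials reached transiently inside an acoustic cycle).
#'
#' @param Vm membrane potential(s), mV
#' @param rs a [rs_neuron_params()]
#' @return matrix with columns `alpha_m`, `beta_m`, ..., `beta_p`
#' @export
rs_rates <- function(Vm, rs = rs_neuron_params()) {
  rs_rates_cpp(Vm, rs)
}

#' Resting state of the membrane
#'
#' Root of the steady-state current at resting capacitance: resting
#' potential, charge density and gate values.
#'
#' @param rs a [rs_neuron_params()]
#' @return list with `Vm0` (mV), `Qm0` (C/m^2), `m0`, `h0`, `n0`, `p0`
#' @export
rs_resting_state <- function(rs = rs_neuron_params()) {
  rs_steady_cpp(rs)
}
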