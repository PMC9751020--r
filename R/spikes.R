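#' Detect spikes as refractory-filtered upward threshold crossings
#'
#' @param trace a `tfus_trace` data frame, or a numeric time vector when `Vm`
#'   is given separately
#' @param Vm membrane potential samples, mV (taken from `trace$Vm` when
#'   `trace` is a data frame)
#' @param threshold detection threshold, mV
#' @param refractory minimum spacing between detected spikes, s
#' @return numeric vector of spike times, s (possibly empty)
#' @export
detect_spikes <- function(trace, Vm = NULL, threshold = 0, refractory = 1e-3) {
  if (is.data.frame(trace)) {
    t <- trace$t
    Vm <- trace$Vm
  } else {
    t <- trace
  }
  stopifnot(length(t) == length(Vm))
  if (length(t) < 2) return(numeric(0))
  up <- which(Vm[-1] >= threshold & Vm[-length(Vm)] < threshold) + 1L
  out <- numeric(0)
  last <- -Inf
  for (tt in t[up]) {
    if (tt - last >= refractory) {
      out <- c(out, tt)
      last <- tt
    }
  }
  out
}

#' Latency of the first spike after stimulus onset
#'
#' @param spike_times sorted spike times, s
#' @param onset stimulus onset, s (>= 0)
#' @return first spike time minus onset, or `NA_real_` when there is no spike
#' @export
compute_latency <- function(spike_times, onset = 0) {
  if (onset < 0) stop("onset must be >= 0")
  if (length(spike_times) == 0) return(NA_real_)
  spike_times[1] - onset
}

#' Firing rate as the mean reciprocal inter-spike interval
#'
#' Mean of `1 / ISI` over consecutive spike pairs falling inside the
#' stimulation window.
#'
#' @param spike_times sorted spike times, s
#' @param stim_window `(t_start, t_end)` of the stimulation, s; defaults to
#'   an unbounded window
#' @return firing rate in spikes/s, or `NA_real_` with fewer than two spikes
#'   in the window
#' @export
compute_firing_rate <- function(spike_times, stim_window = NULL) {
  if (is.unsorted(spike_times)) stop("spike_times must be sorted")
  if (!is.null(stim_window))
    spike_times <- spike_times[spike_times >= stim_window[1] &
                               spike_times <= stim_window[2]]
  if (length(spike_times) < 2) return(NA_real_)
  mean(1 / diff(spike_times))
}
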