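# Readout: feed-forward inhibition from the population firing rate, FFI
# gating of the pooled S-cell drive, per-polarity channel LIF neurons and
# the single output neuron.

#' Delayed population firing rate (FFI signal)
#'
#' The fraction of active output-grid units `epsilon` phases ago, weighted
#' by the delayed phase weight:
#' `F(t) = omega(t - epsilon) * n_active(t - epsilon) / dl^2`; zero while
#' `t < epsilon`. Whole-field events (flashes, rapid view shifts) drive this
#' rate up and trigger the feed-forward inhibition gate.
#'
#' @param spikes_delayed Binary grid spike matrix from phase `t - epsilon`
#'   (may be NULL while `t < epsilon`).
#' @param dl Output grid side.
#' @param t Phase time.
#' @param epsilon Phase delay (default 2).
#' @return The population rate, a scalar in `[0, omega(t - epsilon)]`.
#' @export
ffi_rate <- function(spikes_delayed, dl, t, epsilon = 2) {
  if (t < epsilon) return(0)
  phase_weight(t - epsilon) * sum(spikes_delayed) / dl^2
}

#' FFI-gated pooling of S-cell spikes
#'
#' If the population rate has reached the gate threshold (`F >= s_th`) the
#' channel receives no input this phase. Otherwise the S-cell spikes are
#' pooled through the full-connection kernel `w3`:
#' `I = omega(t) * sum(S * w3) * rho`.
#'
#' @param s_spikes Binary S-cell spike matrix at phase `t`.
#' @param w3 Full-connection kernel (`dl x dl`, from [make_kernels()]).
#' @param f_rate Population rate from [ffi_rate()].
#' @param s_th Gate threshold (default 0.1).
#' @param t Phase time.
#' @param rho Gain factor (default 0.9).
#' @return Scalar channel current.
#' @export
gate_and_pool <- function(s_spikes, w3, f_rate, s_th = 0.1, t, rho = 0.9) {
  if (f_rate >= s_th) return(0)
  phase_weight(t) * sum(s_spikes * w3) * rho
}

#' Advance a polarity-channel LIF neuron by one phase
#'
#' Single LIF unit per polarity with phase-weight-scaled threshold and
#' reset, charged by the gated channel current.
#'
#' @param input Scalar channel current (from [gate_and_pool()]).
#' @param state A [lif_state()] with one unit.
#' @param t Phase time.
#' @return List with `spike` (0/1) and updated `state`.
#' @export
channel_lif <- function(input, state, t) {
  if (state$n != 1) stop("channel_lif expects a single-unit state")
  res <- lif_step(state, input, omega = phase_weight(t))
  list(spike = res$spikes, state = res$state)
}

#' Advance the output neuron by one phase
#'
#' The ON and OFF channel spikes are linearly combined,
#' `I(t) = omega(t) * (theta1 * S_on + theta2 * S_off)`, and drive one more
#' LIF unit whose spike train is the network's looming signal. With equal
#' coefficients the network spikes for both bright and dark looming objects;
#' biasing toward the OFF channel (e.g. `theta = {0.3, 0.7}`) restricts
#' spiking to dark looming objects.
#'
#' @param s_on,s_off Channel spikes (0/1 scalars) at phase `t`.
#' @param theta1,theta2 Channel mixing coefficients (defaults 0.5, 0.5).
#' @param state A [lif_state()] with one unit.
#' @param t Phase time.
#' @return List with `spike` (0/1), `current` (the injected current), and
#'   updated `state`.
#' @export
output_neuron <- function(s_on, s_off, theta1 = 0.5, theta2 = 0.5, state, t) {
  if (theta1 < 0 || theta2 < 0) stop("theta coefficients must be >= 0")
  if (state$n != 1) stop("output_neuron expects a single-unit state")
  input <- phase_weight(t) * (theta1 * s_on + theta2 * s_off)
  res <- lif_step(state, input, omega = phase_weight(t))
  list(spike = res$spikes, current = input, state = res$state)
}
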