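# Leaky integrate-and-fire state and per-phase update, shared by the four
# LIF populations (RF layer, output grid, summation cells, readout neurons).

#' Create a LIF population state
#'
#' Holds the membrane potentials and last-spike phase times of a population
#' of leaky integrate-and-fire units. Time is measured in phase ticks
#' (8 per video frame); the membrane decays by `exp(-1/tau)` per tick.
#'
#' @param n Number of units.
#' @param tau Leak time constant in phase ticks. The default, `1000 / fps`
#'   ticks with `fps = 30`, gives meaningful decay over a few frames.
#' @param rho Firing threshold (default 0.9).
#' @return An object of class `lif_state` with fields `v` (membrane
#'   potentials, start at 0), `last_spike_t` (NA before any spike), `tau`,
#'   `rho`, `n`, and `t` (current phase time, -1 before the first update).
#' @export
lif_state <- function(n, tau = 1000 / 30, rho = 0.9) {
  if (n < 1) stop("n must be >= 1")
  if (tau <= 0) stop("tau must be positive")
  structure(list(v = numeric(n), last_spike_t = rep(NA_integer_, n),
                 tau = tau, rho = rho, n = as.integer(n), t = -1L),
            class = "lif_state")
}

#' @export
print.lif_state <- function(x, ...) {
  cat(sprintf("lif_state: %d units, tau = %.3g ticks, rho = %g, t = %d\n",
              x$n, x$tau, x$rho, x$t))
  invisible(x)
}

#' Advance a LIF population by one phase tick
#'
#' `v' = v * exp(-1/tau) + input`. With `omega = NULL` (hard reset, used by
#' the RF and grid layers) a unit fires when `v' >= rho` and resets to 0.
#' With a phase weight `omega` (summation cells and readout neurons) the
#' threshold is the weight-scaled `omega * rho`, the reset subtracts
#' `omega * rho`, and the membrane is floored at the resting level 0 (net
#' currents may be negative but never drive the potential below rest).
#'
#' @param state A [lif_state()].
#' @param input Numeric vector of injected currents (length `n` or 1).
#' @param omega Phase weight for weight-scaled threshold/reset, or `NULL`.
#' @return List with `spikes` (0/1 numeric vector) and updated `state`.
#' @export
lif_step <- function(state, input, omega = NULL) {
  decay <- exp(-1 / state$tau)
  v <- state$v * decay + input
  t_now <- state$t + 1L
  if (is.null(omega)) {
    s <- as.numeric(v >= state$rho)
    v[s == 1] <- 0
  } else {
    thr <- omega * state$rho
    s <- as.numeric(v >= thr)
    v <- pmax(v - thr * s, 0)
  }
  state$v <- v
  state$t <- t_now
  state$last_spike_t[s == 1] <- t_now
  list(spikes = s, state = state)
}
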