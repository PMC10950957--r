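# Spiking interaction layer: excitatory and phase-delayed inhibitory
# post-synaptic currents on the down-sampled grid, competing at summation
# (S) cells.

#' Build the Gaussian connection kernels
#'
#' Three centered, reflection-symmetric Gaussian kernels: a 3x3 excitatory
#' kernel (`sigma1`), a 9x9 inhibitory kernel (`sigma2`; the inhibitory
#' surround is both wider and phase-delayed), and the `dl x dl` full-
#' connection kernel pooling summation cells onto each readout neuron
#' (`sigma3`). Kernels are normalized to unit sum by default so that every
#' current is bounded by `omega(t) * rho`.
#'
#' The standard deviations are expressed relative to each kernel's
#' half-width (`(size - 1) / 2` cells): `sigma1 = 1` on the 3x3 kernel is a
#' standard deviation of 1 cell, `sigma2 = 0.5` on the 9x9 kernel is 2
#' cells -- a genuinely wider inhibitory surround than the excitatory
#' center -- and `sigma3 = 1` on the full-connection kernel spans the whole
#' grid with a foveal (center) emphasis. A single absolute-cell scale would
#' make the inhibitory kernel a near-delta and blind the global pool to all
#' but the central cells.
#'
#' @param dl Output grid side.
#' @param sigma1,sigma2,sigma3 Gaussian standard deviations in units of the
#'   respective kernel's half-width (defaults 1, 0.5, 1).
#' @param normalize Normalize each kernel to unit sum (default TRUE).
#' @return List of class `kernel_set` with matrices `w1` (3x3), `w2` (9x9),
#'   `w3` (`dl x dl`).
#' @export
make_kernels <- function(dl, sigma1 = 1, sigma2 = 0.5, sigma3 = 1,
                         normalize = TRUE) {
  if (sigma1 <= 0 || sigma2 <= 0 || sigma3 <= 0)
    stop("kernel standard deviations must be positive")
  structure(list(w1 = .gauss_kernel(3L, sigma1, normalize),
                 w2 = .gauss_kernel(9L, sigma2, normalize),
                 w3 = .gauss_kernel(as.integer(dl), sigma3, normalize)),
            class = "kernel_set")
}

.gauss_kernel <- function(size, sigma, normalize = TRUE) {
  c0 <- (size + 1) / 2
  sd_cells <- sigma * max((size - 1) / 2, 1)
  d2 <- outer((seq_len(size) - c0)^2, (seq_len(size) - c0)^2, `+`)
  k <- exp(-d2 / (2 * sd_cells^2))
  if (normalize) k <- k / sum(k)
  k
}

# 2-D "same" convolution with zero padding, by kernel-offset shift-and-add.
# Kernels here are symmetric, so convolution equals correlation.
.conv2_same <- function(mat, k) {
  n1 <- nrow(mat); n2 <- ncol(mat)
  h <- (nrow(k) - 1L) / 2L
  out <- matrix(0, n1, n2)
  for (di in -h:h) {
    sr <- max(1, 1 - di):min(n1, n1 - di)
    tr <- sr + di
    for (dj in -h:h) {
      w <- k[di + h + 1L, dj + h + 1L]
      if (w == 0) next
      sc <- max(1, 1 - dj):min(n2, n2 - dj)
      tc <- sc + dj
      out[tr, tc] <- out[tr, tc] + w * mat[sr, sc]
    }
  }
  out
}

#' Excitatory post-synaptic current
#'
#' The grid spikes of the current phase, weighted by the 3x3 excitatory
#' kernel and scaled by the phase weight and the gain `rho`:
#' `E(x, y, t) = omega(t) * conv(S, w1) * rho`, zero-padded at borders.
#'
#' @param spikes Binary grid spike matrix at phase `t`.
#' @param w1 3x3 excitatory kernel (from [make_kernels()]).
#' @param t Phase time.
#' @param rho Gain factor (default 0.9).
#' @return Numeric matrix, the EPSC field.
#' @export
epsc <- function(spikes, w1, t, rho = 0.9) {
  phase_weight(t) * .conv2_same(spikes, w1) * rho
}

#' Phase-delayed inhibitory post-synaptic current
#'
#' The grid spikes from `epsilon` phases ago, spread by the 9x9 inhibitory
#' kernel: `I(x, y, t) = omega(t - epsilon) * conv(S[t - epsilon], w2) *
#' rho`; identically zero while `t < epsilon`. The delayed phase weight
#' makes inhibition from earlier (heavier) phases stronger than the
#' concurrent excitation, the competition that shapes looming selectivity.
#'
#' @param spikes_delayed Binary grid spike matrix from phase `t - epsilon`
#'   (ignored, may be NULL, while `t < epsilon`).
#' @param w2 9x9 inhibitory kernel.
#' @param t Phase time.
#' @param rho Gain factor (default 0.9).
#' @param epsilon Phase delay in ticks, integer in `[0, 8]` (default 2).
#' @return Numeric matrix, the IPSC field.
#' @export
ipsc <- function(spikes_delayed, w2, t, rho = 0.9, epsilon = 2) {
  if (epsilon < 0 || epsilon > 8) stop("epsilon must lie in [0, 8]")
  if (t < epsilon) {
    d <- if (is.null(spikes_delayed)) stop("grid dimensions unknown for t < epsilon with NULL history") else dim(spikes_delayed)
    return(matrix(0, d[1], d[2]))
  }
  phase_weight(t - epsilon) * .conv2_same(spikes_delayed, w2) * rho
}

#' Net current at the summation sub-layer
#'
#' Elementwise competition `G = E - I`; may be negative (fed to the S-cell
#' LIF as a signed current).
#'
#' @param E,I EPSC and IPSC fields of matching shape.
#' @return Numeric matrix.
#' @export
summation <- function(E, I) {
  if (!all(dim(E) == dim(I))) stop("E and I must have matching shapes")
  E - I
}

#' Advance the summation (S) cells by one phase
#'
#' S-cells are LIF units driven by the signed net current `G` with the
#' phase-weight-scaled threshold and reset: a cell fires when
#' `V * exp(-1/tau) + G >= omega(t) * rho`, the reset subtracts
#' `omega(t) * rho`, and the membrane never falls below the resting level 0.
#'
#' @param G Net current matrix (from [summation()]).
#' @param state A [lif_state()] with one unit per grid cell.
#' @param t Phase time.
#' @return List with `spikes` (binary matrix like `G`) and updated `state`.
#' @export
s_cell_update <- function(G, state, t) {
  if (length(G) != state$n) stop("state size does not match the grid")
  res <- lif_step(state, as.numeric(G), omega = phase_weight(t))
  res$spikes <- matrix(res$spikes, nrow(G), ncol(G))
  res
}
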