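# Neural encoding layer: frame differencing, ON/OFF half-wave rectification
# with a temporal residual, and 8-phase weighted binary spike coding.

#' Weight of a spike phase
#'
#' Each video frame is encoded into eight spike phases. The weight of phase
#' time `t` is `2^-(1 + t mod 8)`: the first phase of every period carries
#' weight 1/2, the last 1/256, so early spikes matter most.
#'
#' @param t Integer phase time(s), `t >= 0`.
#' @return Numeric vector of weights in `(0, 1/2]`.
#' @examples
#' phase_weight(0:7)   # 2^-1 ... 2^-8
#' phase_weight(8)     # back to 2^-1
#' @export
phase_weight <- function(t) {
  if (any(t < 0)) stop("phase time 't' must be non-negative")
  if (any(t != floor(t))) stop("phase time 't' must be integer")
  2^-(1 + t %% 8)
}

#' Frame-to-frame luminance change
#'
#' Computes the signed luminance change field `P(x, y, f) = L(f) - L(f - 1)`
#' for every frame of a stream. The first frame has no predecessor and yields
#' an all-zero field, so the encoded spike volume starts with an empty period.
#'
#' @param stream A [frame_stream].
#' @return Numeric array `H x W x F` of signed changes; slice 1 is zero.
#' @export
frame_difference <- function(stream) {
  stopifnot(inherits(stream, "frame_stream"))
  fr <- stream$frames
  nf <- dim(fr)[3]
  if (nf < 2) stop("frame stream must contain at least 2 frames")
  P <- array(0, dim = dim(fr))
  P[, , 2:nf] <- fr[, , 2:nf, drop = FALSE] - fr[, , 1:(nf - 1), drop = FALSE]
  P
}

#' Split a luminance-change field into ON/OFF channels
#'
#' Half-wave rectification with a one-frame residual: brightness increments
#' flow into the ON channel, decrements into the OFF channel, and a fraction
#' `alpha1` of the previous frame's channel value persists,
#' `P_on(f) = [P(f)]^+ + alpha1 * P_on(f-1)` (and mirrored for OFF).
#'
#' @param P Numeric matrix, the signed change field of one frame.
#' @param previous List with elements `on` and `off` (matrices) carrying the
#'   channel state of the previous frame, or `NULL` at the first frame.
#' @param alpha1 Residual coefficient in `[0, 1)`; default 0.1.
#' @return List with matrices `on` and `off`, both non-negative.
#' @export
split_on_off <- function(P, previous = NULL, alpha1 = 0.1) {
  if (alpha1 < 0 || alpha1 >= 1) stop("'alpha1' must lie in [0, 1)")
  on <- pmax(P, 0)
  off <- pmax(-P, 0)
  if (!is.null(previous)) {
    on <- on + alpha1 * previous$on
    off <- off + alpha1 * previous$off
  }
  list(on = on, off = off)
}

# Largest value representable by the 8-bit phase code.
.code_max <- 255 / 256

#' Encode normalized channel values into eight binary phase slices
#'
#' Fixed-point binary coding: a value `v` in `[0, 1)` is expanded as
#' `v = sum_i b_i * 2^-(i+1)` and bit `b_i` (most-significant first) is
#' emitted as the spike of phase `i`. The phase-weighted sum of the spikes
#' ([phase_decode()]) recovers `v` to within `2^-8`. Values above the largest
#' representable code (255/256, possible after residual accumulation) are
#' clipped; the number of clipped entries is attached as attribute
#' `n_clipped`.
#'
#' @param v Numeric vector, matrix or array of values in `[0, 1]`, i.e.
#'   channel values already normalized by the intensity scale 256.
#' @return Array with an extra trailing dimension of length 8 holding the
#'   binary phase slices, attribute `n_clipped`.
#' @export
phase_encode <- function(v) {
  if (any(v < 0)) stop("phase_encode() expects non-negative normalized values")
  n_clip <- sum(v > .code_max)
  v <- pmin(v, .code_max)
  d <- if (is.null(dim(v))) length(v) else dim(v)
  bits <- array(0, dim = c(d, 8L))
  flat <- as.numeric(v)
  n <- length(flat)
  for (i in 0:7) {
    bits[seq_len(n) + i * n] <- floor(flat * 2^(i + 1)) %% 2
  }
  attr(bits, "n_clipped") <- n_clip
  bits
}

#' Decode eight phase slices back to the normalized value
#'
#' Inverse of [phase_encode()]: the weighted sum `sum_i b_i * 2^-(i+1)`,
#' which equals the phase-weight (`omega`) weighted spike sum within one
#' period.
#'
#' @param bits Array as returned by [phase_encode()] (last dimension 8).
#' @return Numeric array of decoded values (the trailing dimension dropped).
#' @export
phase_decode <- function(bits) {
  d <- dim(bits)
  k <- length(d)
  if (is.null(d) || d[k] != 8L) stop("'bits' must have a trailing dimension of length 8")
  n <- prod(d[-k])
  out <- numeric(n)
  for (i in 0:7) out <- out + bits[seq_len(n) + i * n] * 2^-(i + 1)
  if (k > 2) dim(out) <- d[-k] else if (k == 2) out <- as.numeric(out)
  out
}

#' Encode a whole frame stream into ON/OFF spike events
#'
#' Runs frame differencing, ON/OFF rectification with residual, and phase
#' coding over a stream and returns the spikes as an event list (one row per
#' spike), the package's interchange format for spike volumes.
#'
#' @param stream A [frame_stream].
#' @param alpha1 Residual coefficient, see [split_on_off()].
#' @return A `data.frame` with columns `polarity` ("on"/"off"), `x`, `y`
#'   (0-based pixel coordinates, x = column), and `t` (phase time,
#'   `t = 8 * (f - 1) + i`). Attributes: `dims` (H, W), `n_phases`
#'   (`8 * frames`), `n_clipped`.
#' @export
encode_stream <- function(stream, alpha1 = 0.1) {
  P <- frame_difference(stream)
  nf <- dim(P)[3]
  state <- NULL
  rows <- vector("list", 2L * nf)
  n_clipped <- 0L
  for (f in seq_len(nf)) {
    state <- split_on_off(P[, , f], state, alpha1)
    for (pol in c("on", "off")) {
      bits <- phase_encode(state[[pol]] / 256)
      n_clipped <- n_clipped + attr(bits, "n_clipped")
      idx <- which(bits == 1, arr.ind = TRUE)
      if (nrow(idx)) {
        rows[[(f - 1) * 2 + (pol == "off") + 1]] <- data.frame(
          polarity = pol,
          x = idx[, 2] - 1L,
          y = idx[, 1] - 1L,
          t = 8L * (f - 1L) + idx[, 3] - 1L
        )
      }
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(polarity = character(), x = integer(),
                      y = integer(), t = integer())
  }
  out <- out[order(out$t, out$polarity, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dims") <- dim(P)[1:2]
  attr(out, "n_phases") <- 8L * nf
  attr(out, "n_clipped") <- n_clipped
  out
}
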