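# Synthetic stimulus generators: looming/receding squares, translating bars
# and drifting sinusoidal gratings, the standard test battery for looming
# detectors.

#' Construct a frame stream
#'
#' A frame stream is an ordered set of grayscale frames with a sampling
#' rate. Intensities are 8-bit, `[0, 255]`.
#'
#' @param frames A numeric `H x W x F` array, or a list of `H x W` matrices.
#' @param fps Sampling rate in frames per second (default 30).
#' @return An object of class `frame_stream` with elements `frames`
#'   (integer array), `fps`, `side_length` (pixels per axis; equal H and W).
#' @export
frame_stream <- function(frames, fps = 30) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("all frames must share identical dimensions")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3) stop("'frames' must be an H x W x F array")
  if (any(frames < 0 | frames > 255)) stop("intensities must lie in [0, 255]")
  structure(
    list(frames = round(frames), fps = fps,
         side_length = dim(frames)[2], n_frames = dim(frames)[3]),
    class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stream: %d frames of %d x %d px at %g fps (%.2f s)\n",
              d[3], d[1], d[2], x$fps, d[3] / x$fps))
  cat(sprintf("  intensity range [%d, %d]\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' Specify a synthetic stimulus
#'
#' Parameter container consumed by [make_square_motion()],
#' [make_translating_bar()] and [make_grating()].
#'
#' @param kind One of `"looming"`, `"receding"`, `"translating"`,
#'   `"grating"`.
#' @param object_intensity,background_intensity Intensities in `[0, 255]`.
#'   Their signed difference is the stimulus contrast (dark object on light
#'   background or the reverse).
#' @param start_size,end_size Square side in pixels at the first/last frame
#'   (looming: strictly growing; receding: strictly shrinking).
#' @param speed Pixels per frame (translating bar) or temporal frequency in
#'   cycles per frame (grating).
#' @param spatial_frequency Cycles per image width (grating only).
#' @param width Bar width in pixels (translating only, default 10).
#' @param n_frames Number of frames; defaults to 90 (3 s at 30 fps), or the
#'   full traversal for a translating bar.
#' @param side_length Frame side in pixels, default 100.
#' @param fps Sampling rate, default 30.
#' @param growth Size trajectory of the square, `"linear"` (default) or
#'   `"exponential"`.
#' @param seed Integer seed for any stochastic element (none of the shipped
#'   generators uses randomness; kept for interface stability).
#' @return An object of class `stim_spec`.
#' @export
stim_spec <- function(kind = c("looming", "receding", "translating", "grating"),
                      object_intensity = 40, background_intensity = 220,
                      start_size = 10, end_size = 80,
                      speed = 2, spatial_frequency = 4, width = 10,
                      n_frames = NULL, side_length = 100, fps = 30,
                      growth = c("linear", "exponential"), seed = NULL) {
  kind <- match.arg(kind)
  growth <- match.arg(growth)
  if (object_intensity < 0 || object_intensity > 255 ||
      background_intensity < 0 || background_intensity > 255)
    stop("intensities must lie in [0, 255]")
  structure(
    list(kind = kind, object_intensity = object_intensity,
         background_intensity = background_intensity,
         start_size = start_size, end_size = end_size, speed = speed,
         spatial_frequency = spatial_frequency, width = width,
         n_frames = n_frames, side_length = side_length, fps = fps,
         growth = growth, seed = seed),
    class = "stim_spec")
}

#' @export
print.stim_spec <- function(x, ...) {
  cat("stim_spec:", x$kind,
      sprintf("(object %d on background %d, contrast %+d)\n",
              x$object_intensity, x$background_intensity,
              x$object_intensity - x$background_intensity))
  invisible(x)
}

# Pixels whose centers fall inside [c - s/2, c + s/2] (0-based indices).
.pixel_span <- function(center, size, L) {
  lo <- ceiling(center - size / 2 - 0.5 - 1e-9)
  hi <- floor(center + size / 2 - 0.5 + 1e-9)
  lo <- max(lo, 0L); hi <- min(hi, L - 1L)
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

#' Looming or receding square
#'
#' A centered square whose side follows a linear (default) or exponential
#' trajectory between `start_size` and `end_size` over the clip. Looming
#' requires a strictly increasing trajectory, receding strictly decreasing;
#' reversing a looming spec's sizes yields the receding clip frame-for-frame.
#'
#' @param spec A [stim_spec()] with `kind` `"looming"` or `"receding"`.
#' @return A [frame_stream].
#' @export
make_square_motion <- function(spec) {
  stopifnot(inherits(spec, "stim_spec"))
  if (!spec$kind %in% c("looming", "receding"))
    stop("spec kind must be 'looming' or 'receding'")
  L <- spec$side_length
  nf <- if (is.null(spec$n_frames)) 90L else spec$n_frames
  s0 <- spec$start_size; s1 <- spec$end_size
  if (max(s0, s1) > L)
    stop(sprintf("square size %g exceeds frame side %d", max(s0, s1), L))
  if (spec$kind == "looming" && s1 <= s0)
    stop("looming requires end_size > start_size")
  if (spec$kind == "receding" && s1 >= s0)
    stop("receding requires end_size < start_size")
  u <- if (nf == 1) 0 else (seq_len(nf) - 1) / (nf - 1)
  sizes <- switch(spec$growth,
    linear = s0 + (s1 - s0) * u,
    exponential = s0 * (s1 / s0)^u)
  fr <- array(spec$background_intensity, dim = c(L, L, nf))
  ctr <- L / 2
  for (f in seq_len(nf)) {
    px <- .pixel_span(ctr, sizes[f], L)
    if (length(px)) fr[px + 1, px + 1, f] <- spec$object_intensity
  }
  frame_stream(fr, spec$fps)
}

#' Translating vertical bar
#'
#' A vertical bar of width `width` entering at the left edge and crossing
#' the frame at constant `speed` (pixels/frame); its left edge at frame `f`
#' is `-width + speed * (f - 1)`. The default clip length is the full
#' traversal, `ceiling((side_length + width) / speed)` frames.
#'
#' @param spec A [stim_spec()] with `kind = "translating"`.
#' @return A [frame_stream].
#' @export
make_translating_bar <- function(spec) {
  stopifnot(inherits(spec, "stim_spec"))
  if (spec$kind != "translating") stop("spec kind must be 'translating'")
  if (spec$speed <= 0) stop("translating bar requires speed > 0")
  L <- spec$side_length
  w <- spec$width
  nf <- if (is.null(spec$n_frames)) ceiling((L + w) / spec$speed) else spec$n_frames
  fr <- array(spec$background_intensity, dim = c(L, L, nf))
  for (f in seq_len(nf)) {
    left <- -w + spec$speed * (f - 1)
    cols <- .pixel_span(left + w / 2, w, L)
    if (length(cols)) fr[, cols + 1, f] <- spec$object_intensity
  }
  frame_stream(fr, spec$fps)
}

#' Drifting sinusoidal grating
#'
#' Vertical sinusoidal luminance pattern with `spatial_frequency` cycles per
#' image drifting at `speed` cycles per frame, quantized to `[0, 255]`. The
#' intensity range spans between `object_intensity` and
#' `background_intensity`.
#'
#' @param spec A [stim_spec()] with `kind = "grating"`.
#' @return A [frame_stream].
#' @export
make_grating <- function(spec) {
  stopifnot(inherits(spec, "stim_spec"))
  if (spec$kind != "grating") stop("spec kind must be 'grating'")
  if (spec$spatial_frequency <= 0) stop("grating requires spatial_frequency > 0")
  L <- spec$side_length
  nf <- if (is.null(spec$n_frames)) 90L else spec$n_frames
  lo <- min(spec$object_intensity, spec$background_intensity)
  hi <- max(spec$object_intensity, spec$background_intensity)
  mid <- (lo + hi) / 2; amp <- (hi - lo) / 2
  x <- (seq_len(L) - 0.5) / L
  fr <- array(0, dim = c(L, L, nf))
  for (f in seq_len(nf)) {
    row <- mid + amp * sin(2 * pi * (spec$spatial_frequency * x -
                                       spec$speed * (f - 1)))
    fr[, , f] <- matrix(row, nrow = L, ncol = L, byrow = TRUE)
  }
  frame_stream(fr, spec$fps)
}

#' The standard synthetic stimulus suite
#'
#' The battery used throughout the experiments: looming and receding squares
#' at four contrasts (dark-on-light and light-on-dark at two luminance gaps),
#' translating bars at the same four contrasts, and drifting gratings at four
#' temporal frequencies.
#'
#' @param side_length Frame side in pixels (default 100).
#' @param n_frames Clip length (default 90 frames, 3 s at 30 fps).
#' @param fps Sampling rate (default 30).
#' @param include Character vector choosing categories, subset of
#'   `c("looming", "receding", "translating", "grating")`.
#' @return Named list of [frame_stream] objects; the names encode category
#'   and contrast (e.g. `"looming_dark_strong"`). Attribute `categories` is a
#'   data.frame with columns `name` and `kind`.
#' @export
loom_suite <- function(side_length = 100, n_frames = 90, fps = 30,
                       include = c("looming", "receding", "translating",
                                   "grating")) {
  contrasts <- list(
    dark_strong  = c(obj = 40,  bg = 220),
    dark_weak    = c(obj = 160, bg = 220),
    white_strong = c(obj = 220, bg = 40),
    white_weak   = c(obj = 100, bg = 40))
  out <- list(); kinds <- character()
  add <- function(name, stream, kind) {
    out[[name]] <<- stream; kinds[name] <<- kind
  }
  for (cn in names(contrasts)) {
    cc <- contrasts[[cn]]
    if ("looming" %in% include)
      add(paste0("looming_", cn), make_square_motion(stim_spec(
        "looming", cc["obj"], cc["bg"], start_size = 10, end_size = 80,
        n_frames = n_frames, side_length = side_length, fps = fps)),
        "looming")
    if ("receding" %in% include)
      add(paste0("receding_", cn), make_square_motion(stim_spec(
        "receding", cc["obj"], cc["bg"], start_size = 80, end_size = 10,
        n_frames = n_frames, side_length = side_length, fps = fps)),
        "receding")
    if ("translating" %in% include)
      add(paste0("translating_", cn), make_translating_bar(stim_spec(
        "translating", cc["obj"], cc["bg"], speed = 2, width = 10,
        n_frames = n_frames, side_length = side_length, fps = fps)),
        "translating")
  }
  if ("grating" %in% include) {
    for (tf in c(0.05, 0.1, 0.2, 0.4))
      add(sprintf("grating_tf%g", tf), make_grating(stim_spec(
        "grating", 220, 40, speed = tf, spatial_frequency = 4,
        n_frames = n_frames, side_length = side_length, fps = fps)),
        "grating")
  }
  attr(out, "categories") <- data.frame(name = names(out),
                                        kind = unname(kinds))
  out
}
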