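# Model configuration: the reference parameter set and a flat text
# serialization.

#' Model configuration
#'
#' Collects every tunable parameter of the network. The defaults are the
#' reference parameter set used throughout the experiments.
#'
#' @param alpha1 Residual coefficient of the ON/OFF split (default 0.1).
#' @param max_rs Largest receptive-field size in pixels (default 10).
#' @param tau Leak time constant in phase ticks; default `1000 / fps`
#'   (about 33 ticks at 30 fps).
#' @param r_k Percentage-area current factor of the RF layer (default 0.6).
#' @param rho LIF firing threshold / current gain (default 0.9).
#' @param sigma1,sigma2,sigma3 Gaussian kernel widths (defaults 1, 0.5, 1).
#' @param epsilon Phase delay of the inhibitory current, integer in
#'   `[0, 8]` (default 2).
#' @param side_length Input frame side in pixels (default 100).
#' @param dl Expected output grid side. `NULL` (default) derives it from the
#'   eccentric layout; if supplied it is validated against the built layout
#'   and a mismatch is an error.
#' @param s_th FFI gate threshold (default 0.1).
#' @param theta1,theta2 Output mixing coefficients (defaults 0.5, 0.5).
#' @param fps Sampling rate of the input (default 30).
#' @param fovea_fraction Nominal foveal dimension as a fraction of the image
#'   side (default 0.1).
#' @param downsampling Entry down-sampling mode: `"eccentric"` (default,
#'   the foveated RF network), `"none"` (full-resolution grid) or
#'   `"average"` (uniform block averaging to the same grid side).
#' @param rf_current RF current semantics, `"normalized"` (default) or
#'   `"raw"`; see [rf_integrate_fire()].
#' @param normalize_kernels If `FALSE` (default) the 3x3 and 9x9 kernels are
#'   connection-weight surfaces with peak 1 -- the wider inhibitory kernel
#'   then dominates the excitatory one pointwise and the network is exactly
#'   silent at zero phase delay -- while the global pooling kernel stays
#'   unit-sum. `TRUE` normalizes all three kernels to unit sum.
#' @return An object of class `loom_config`.
#' @export
loom_config <- function(alpha1 = 0.1, max_rs = 10, tau = NULL, r_k = 0.6,
                        rho = 0.9, sigma1 = 1, sigma2 = 0.5, sigma3 = 1,
                        epsilon = 2, side_length = 100, dl = NULL,
                        s_th = 0.1, theta1 = 0.5, theta2 = 0.5, fps = 30,
                        fovea_fraction = 0.1,
                        downsampling = c("eccentric", "none", "average"),
                        rf_current = c("normalized", "raw"),
                        normalize_kernels = FALSE) {
  downsampling <- match.arg(downsampling)
  rf_current <- match.arg(rf_current)
  if (is.null(tau)) tau <- 1000 / fps
  if (alpha1 < 0 || alpha1 >= 1) stop("alpha1 must lie in [0, 1)")
  if (epsilon < 0 || epsilon > 8 || epsilon != floor(epsilon))
    stop("epsilon must be an integer in [0, 8]")
  if (rho <= 0) stop("rho must be positive")
  if (tau <= 0) stop("tau must be positive")
  if (theta1 < 0 || theta2 < 0) stop("theta coefficients must be >= 0")
  structure(list(alpha1 = alpha1, max_rs = max_rs, tau = tau, r_k = r_k,
                 rho = rho, sigma1 = sigma1, sigma2 = sigma2,
                 sigma3 = sigma3, epsilon = as.integer(epsilon),
                 side_length = side_length, dl = dl, s_th = s_th,
                 theta1 = theta1, theta2 = theta2, fps = fps,
                 fovea_fraction = fovea_fraction,
                 downsampling = downsampling, rf_current = rf_current,
                 normalize_kernels = normalize_kernels),
            class = "loom_config")
}

#' @export
print.loom_config <- function(x, ...) {
  cat("loom_config:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-18s %s\n", k, if (is.null(v)) "(derived)" else format(v)))
  }
  invisible(x)
}

#' Write / read a configuration as flat `key: value` text
#'
#' @param config A [loom_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `loom_config`. The round trip is the identity.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "loom_config"))
  keys <- names(config)
  lines <- vapply(keys, function(k) {
    v <- config[[k]]
    sprintf("%s: %s", k,
            if (is.null(v)) "NULL"
            else if (is.numeric(v)) format(v, digits = 17)
            else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  args <- list()
  for (m in kv) {
    if (length(m) != 3) stop("malformed config line: ", m[1])
    key <- trimws(m[2]); val <- trimws(m[3])
    args[[key]] <-
      if (val == "NULL") NULL
      else if (key %in% c("downsampling", "rf_current")) val
      else if (key == "normalize_kernels") as.logical(val)
      else as.numeric(val)
  }
  do.call(loom_config, args)
}
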