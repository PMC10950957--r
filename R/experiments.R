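# Experiment drivers: phase-delay sweep and the down-sampling ablation.

#' Sweep the inhibitory phase delay
#'
#' Runs the network on each stimulus for every delay in `delays` and
#' records whether the clip is detected (at least one output spike), the
#' spike count and the first spike phase. With no delay the excitatory and
#' inhibitory currents cancel phase-for-phase and the network is silent; a
#' delay of 1 already responds to both approach and recession; from a delay
#' of 2 the network distinguishes the two.
#'
#' @param stimuli Named list of [frame_stream] objects (e.g. from
#'   [loom_suite()]).
#' @param config Base [loom_config()]; its `epsilon` is overridden.
#' @param delays Integer vector of delays to test, within `0:8`.
#' @return A data.frame (class `loom_sweep`) with columns `stimulus`,
#'   `epsilon`, `detected`, `n_spikes`, `first_spike`.
#' @export
sweep_delay <- function(stimuli, config = loom_config(), delays = 0:8) {
  if (!all(delays %in% 0:8)) stop("delays must lie within 0:8")
  layout <- if (config$downsampling != "none")
    ec_layout(config$side_length, config$max_rs, config$fovea_fraction)
  else NULL
  rows <- list()
  for (eps in delays) {
    cfg <- config
    cfg$epsilon <- as.integer(eps)
    for (nm in names(stimuli)) {
      tr <- run_loom(stimuli[[nm]], cfg, layout = layout, record = "output")
      rows[[length(rows) + 1L]] <- data.frame(
        stimulus = nm, epsilon = eps, detected = tr$detected,
        n_spikes = tr$n_spikes, first_spike = tr$first_spike)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("loom_sweep", "data.frame")
  out
}

#' Down-sampling ablation
#'
#' Compares the eccentric entry layer against no down-sampling (the
#' interaction layer runs at full image resolution and the FFI rate is
#' normalized by the pixel count) and uniform block-average down-sampling
#' to the same grid side, all downstream stages identical.
#'
#' @param stimuli Named list of [frame_stream] objects.
#' @param config Base [loom_config()]; its `downsampling` is overridden.
#' @param modes Subset of `c("eccentric", "none", "average")`.
#' @return A data.frame (class `loom_ablation`) with columns `model`,
#'   `stimulus`, `detected`, `n_spikes`, `first_spike`.
#' @export
ablate_downsampling <- function(stimuli, config = loom_config(),
                                modes = c("eccentric", "none", "average")) {
  modes <- match.arg(modes, several.ok = TRUE)
  rows <- list()
  for (mode in modes) {
    cfg <- config
    cfg$downsampling <- mode
    cfg$dl <- NULL
    layout <- if (mode != "none")
      ec_layout(cfg$side_length, cfg$max_rs, cfg$fovea_fraction)
    else NULL
    for (nm in names(stimuli)) {
      tr <- run_loom(stimuli[[nm]], cfg, layout = layout, record = "output")
      rows[[length(rows) + 1L]] <- data.frame(
        model = mode, stimulus = nm, detected = tr$detected,
        n_spikes = tr$n_spikes, first_spike = tr$first_spike)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("loom_ablation", "data.frame")
  out
}
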