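# Spike-raster export (event CSV) and per-clip summaries.

#' Export a layer's spike events as CSV
#'
#' One row per spike with columns `layer`, `polarity`, `x`, `y`, `t`
#' (0-based coordinates and phase time). Scalar layers (`channel`,
#' `output`) use `NA` coordinates; the channel's polarity identifies the
#' neuron and the output neuron's polarity is empty.
#'
#' @param trace A [run_loom()] trace. Grid and S-cell layers require
#'   `record = "full"`.
#' @param layer One of `"grid"`, `"s_cell"`, `"channel"`, `"output"`.
#' @param path Output CSV path.
#' @return The exported data.frame, invisibly.
#' @export
export_raster <- function(trace, layer = c("grid", "s_cell", "channel",
                                           "output"), path) {
  stopifnot(inherits(trace, "loom_trace"))
  layer <- match.arg(layer)
  ev <- raster_events(trace, layer)
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(ev)
}

#' @rdname export_raster
#' @export
raster_events <- function(trace, layer = c("grid", "s_cell", "channel",
                                           "output")) {
  layer <- match.arg(layer)
  if (layer %in% c("grid", "s_cell")) {
    if (is.null(trace$events))
      stop("trace was recorded with record = 'output'; no ", layer, " events")
    ev <- trace$events[[layer]]
    return(data.frame(layer = rep(layer, nrow(ev)), ev))
  }
  if (layer == "channel") {
    idx <- which(trace$channel == 1, arr.ind = TRUE)
    return(data.frame(layer = rep("channel", nrow(idx)),
                      polarity = rownames(trace$channel)[idx[, 1]],
                      x = rep(NA_integer_, nrow(idx)),
                      y = rep(NA_integer_, nrow(idx)),
                      t = idx[, 2] - 1L))
  }
  tt <- which(trace$output == 1) - 1L
  data.frame(layer = rep("output", length(tt)),
             polarity = rep("", length(tt)),
             x = rep(NA_integer_, length(tt)),
             y = rep(NA_integer_, length(tt)), t = tt)
}

#' Read back an exported raster CSV
#'
#' @param path CSV written by [export_raster()].
#' @return The event data.frame.
#' @export
read_raster <- function(path) {
  utils::read.csv(path, colClasses = c(layer = "character",
                                       polarity = "character"))
}

#' Per-clip summary of a trace
#'
#' @param trace A [run_loom()] trace.
#' @return A list: `detected`, `output_spike_phases`, per-channel spike
#'   counts, FFI activation phases (phases at which the gate was closed),
#'   and the phase count.
#' @export
clip_summary <- function(trace) {
  stopifnot(inherits(trace, "loom_trace"))
  gate <- trace$ffi >= trace$config$s_th
  list(detected = trace$detected,
       n_output_spikes = trace$n_spikes,
       output_spike_phases = as.integer(which(trace$output == 1) - 1L),
       first_spike = trace$first_spike,
       channel_spike_counts = list(on = sum(trace$channel["on", ]),
                                   off = sum(trace$channel["off", ])),
       ffi_gate_phases = list(on = as.integer(which(gate["on", ]) - 1L),
                              off = as.integer(which(gate["off", ]) - 1L)),
       n_phases = trace$n_phases)
}

#' Write a per-clip summary as JSON
#'
#' @param trace A [run_loom()] trace.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary <- function(trace, path) {
  jsonlite::write_json(clip_summary(trace), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
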