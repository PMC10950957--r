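# print / summary / plot methods for simulation traces.

#' @export
print.loom_trace <- function(x, ...) {
  cat(sprintf("loom_trace: %d phases (%d frames), %s down-sampling, grid %d x %d\n",
              x$n_phases, x$n_phases / 8, x$mode, x$dl, x$dl))
  if (x$detected) {
    cat(sprintf("  LOOMING DETECTED: %d output spike(s), first at phase %d (%.2f s)\n",
                x$n_spikes, x$first_spike, x$first_spike / (8 * x$fps)))
  } else {
    cat("  no output spikes\n")
  }
  invisible(x)
}

#' @export
summary.loom_trace <- function(object, ...) {
  s <- clip_summary(object)
  cat(sprintf("loom_trace over %d phases:\n", s$n_phases))
  cat(sprintf("  output spikes: %d%s\n", s$n_output_spikes,
              if (s$n_output_spikes)
                sprintf(" (first at phase %d)", s$first_spike) else ""))
  cat(sprintf("  channel spikes: ON %d, OFF %d\n",
              s$channel_spike_counts$on, s$channel_spike_counts$off))
  cat(sprintf("  FFI gate closed at %d (ON) / %d (OFF) phases\n",
              length(s$ffi_gate_phases$on), length(s$ffi_gate_phases$off)))
  cat(sprintf("  grid activity peak: ON %d, OFF %d cells in a phase\n",
              max(object$counts$grid_on), max(object$counts$grid_off)))
  invisible(s)
}

#' Plot a simulation trace
#'
#' Draws the spike rasters of the recorded layers (grid and S cells when
#' available, as linear cell index over phase time), the channel spikes and
#' the output spike train with the output membrane potential.
#'
#' @param x A [run_loom()] trace.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.loom_trace <- function(x, ...) {
  has_ev <- !is.null(x$events)
  npan <- 2L + if (has_ev) 2L else 0L
  op <- par(mfrow = c(npan, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(par(op))
  if (has_ev) {
    for (ly in c("grid", "s_cell")) {
      ev <- x$events[[ly]]
      plot(NA, xlim = c(0, x$n_phases), ylim = c(0, x$dl^2),
           xlab = "", ylab = "cell", main = paste(ly, "spikes"))
      if (nrow(ev)) {
        col <- ifelse(ev$polarity == "on", "#D55E00", "#0072B2")
        points(ev$t, ev$y * x$dl + ev$x, pch = ".", col = col)
      }
    }
  }
  plot(NA, xlim = c(0, x$n_phases), ylim = c(0.5, 2.5), xlab = "",
       ylab = "channel", yaxt = "n", main = "channel spikes")
  axis(2, at = 1:2, labels = c("on", "off"))
  for (i in 1:2) {
    tt <- which(x$channel[i, ] == 1) - 1L
    if (length(tt)) points(tt, rep(i, length(tt)), pch = "|")
  }
  plot(x$membrane$out, type = "l", xlab = "phase", ylab = "V out",
       main = sprintf("output neuron (%d spike(s))", x$n_spikes))
  tt <- which(x$output == 1)
  if (length(tt)) points(tt, x$membrane$out[tt], pch = 4, col = "red")
  invisible(x)
}

#' @export
print.loom_sweep <- function(x, ...) {
  cat("phase-delay sweep:\n")
  tab <- with(x, tapply(detected, list(stimulus, epsilon), any))
  print(ifelse(tab, "spike", "-"), quote = FALSE)
  invisible(x)
}

#' @export
print.loom_ablation <- function(x, ...) {
  cat("down-sampling ablation:\n")
  tab <- with(x, tapply(detected, list(stimulus, model), any))
  print(ifelse(tab, "spike", "-"), quote = FALSE)
  invisible(x)
}

#' @export
plot.frame_stream <- function(x, frame = 1, ...) {
  m <- x$frames[, , frame]
  image(t(m)[, nrow(m):1], col = gray(0:255 / 255), zlim = c(0, 255),
        axes = FALSE, main = sprintf("frame %d / %d", frame, x$n_frames))
  invisible(x)
}
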