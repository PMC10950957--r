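# The online per-phase simulation loop: encode -> down-sample -> EPSC/IPSC
# competition -> summation cells -> FFI gate -> channel LIF -> output neuron.

#' Run the looming-detection network on a frame stream
#'
#' Executes the full feed-forward cascade, one phase tick at a time
#' (8 ticks per frame): frame differencing and ON/OFF splitting, 8-phase
#' binary spike coding, entry down-sampling (eccentric RF network by
#' default), excitatory vs. phase-delayed inhibitory current competition at
#' the summation cells, feed-forward inhibition gating, per-polarity channel
#' LIF neurons, and the single output neuron. Fully deterministic for a
#' fixed `(config, stream)` pair.
#'
#' @param stream A [frame_stream] whose frames are square and match
#'   `config$side_length`.
#' @param config A [loom_config()].
#' @param layout Optionally a pre-built [ec_layout()] (must match the
#'   config); built on the fly otherwise.
#' @param record `"full"` records per-phase spike events of the grid and
#'   S-cell layers (needed for rasters); `"output"` records only the
#'   channel/output series and per-layer counts.
#' @return An object of class `loom_trace`. Fields include `output`
#'   (0/1 per phase), `channel` (2 x T matrix, ON/OFF), `membrane` (output
#'   and channel potentials per phase), `ffi` (2 x T population rates),
#'   `counts` (per-phase active-cell counts per layer and polarity),
#'   `events` (spike event data.frames, `record = "full"` only),
#'   `detected` (any output spike), `first_spike` (phase of the first
#'   output spike or NA), `n_phases`, `dl`, `config`.
#' @export
run_loom <- function(stream, config = loom_config(), layout = NULL,
                     record = c("full", "output")) {
  record <- match.arg(record)
  stopifnot(inherits(stream, "frame_stream"), inherits(config, "loom_config"))
  d <- dim(stream$frames)
  if (d[3] < 2) stop("stream too short: need at least 2 frames")
  if (d[1] != d[2]) stop("frames must be square")
  L <- config$side_length
  if (d[1] != L)
    stop(sprintf("stream is %d px but config$side_length is %d", d[1], L))

  mode <- config$downsampling
  if (mode == "eccentric") {
    if (is.null(layout))
      layout <- ec_layout(L, config$max_rs, config$fovea_fraction)
    dl <- layout$dl
  } else if (mode == "average") {
    if (is.null(layout))
      layout <- ec_layout(L, config$max_rs, config$fovea_fraction)
    dl <- layout$dl           # same grid side as the eccentric model
  } else {
    dl <- L                   # no down-sampling: grid is the image itself
  }
  if (!is.null(config$dl) && config$dl != dl)
    stop(sprintf("config$dl = %d but the layout yields dl = %d",
                 config$dl, dl))

  # w1/w2 are connection-weight surfaces (peak 1): the wider inhibitory
  # kernel then dominates the excitatory one pointwise, which silences the
  # network exactly at zero phase delay. w3 is kept unit-sum so the channel
  # current is bounded by omega(t) * rho. normalize_kernels = TRUE switches
  # all three to unit-sum.
  kern <- make_kernels(dl, config$sigma1, config$sigma2, config$sigma3,
                       normalize = config$normalize_kernels)
  if (!config$normalize_kernels) {
    kern$w1 <- .gauss_kernel(3L, config$sigma1, normalize = FALSE)
    kern$w2 <- .gauss_kernel(9L, config$sigma2, normalize = FALSE)
    kern$w3 <- .gauss_kernel(as.integer(dl), config$sigma3, normalize = TRUE)
  }
  tau <- config$tau; rho <- config$rho; eps <- config$epsilon

  # block-average operator for mode "average": pixel -> dl x dl block mean
  if (mode == "average") {
    bx <- floor((0:(L - 1)) * dl / L)
    cell <- as.vector(outer(bx + 1L, bx * dl, `+`))  # per-pixel cell id
    bsz <- tabulate(cell, nbins = dl * dl)
    avg_op <- Matrix::sparseMatrix(i = cell, j = seq_len(L * L),
                                   x = 1 / bsz[cell], dims = c(dl * dl, L * L))
  }

  # LIF populations
  if (mode == "eccentric") {
    m <- nrow(layout$rf)
    st_rf <- list(on = lif_state(m, tau, rho), off = lif_state(m, tau, rho))
  }
  if (mode != "none") {
    st_grid <- list(on = lif_state(dl^2, tau, rho),
                    off = lif_state(dl^2, tau, rho))
  }
  st_s <- list(on = lif_state(dl^2, tau, rho), off = lif_state(dl^2, tau, rho))
  st_ch <- list(on = lif_state(1, tau, rho), off = lif_state(1, tau, rho))
  st_out <- lif_state(1, tau, rho)

  nf <- d[3]
  TT <- 8L * nf
  zeros <- matrix(0, dl, dl)
  hist_grid <- list(on = vector("list", 8), off = vector("list", 8))

  out_spk <- integer(TT)
  ch_spk <- matrix(0, 2, TT, dimnames = list(c("on", "off"), NULL))
  v_out <- numeric(TT)
  v_ch <- matrix(0, 2, TT, dimnames = list(c("on", "off"), NULL))
  ffi <- matrix(0, 2, TT, dimnames = list(c("on", "off"), NULL))
  counts <- list(grid_on = integer(TT), grid_off = integer(TT),
                 s_on = integer(TT), s_off = integer(TT))
  ev_grid <- list(); ev_s <- list()
  n_clipped <- 0L

  P <- frame_difference(stream)
  ch_state <- NULL

  for (f in seq_len(nf)) {
    ch_state <- split_on_off(P[, , f], ch_state, config$alpha1)
    bits <- list()
    for (pol in c("on", "off")) {
      b <- phase_encode(ch_state[[pol]] / 256)
      n_clipped <- n_clipped + attr(b, "n_clipped")
      bits[[pol]] <- b
    }
    for (i in 0:7) {
      t <- 8L * (f - 1L) + i
      w_t <- phase_weight(t)
      slot <- t %% 8L + 1L
      s_grid <- list()
      for (pol in c("on", "off")) {
        slice <- bits[[pol]][, , i + 1L]
        if (mode == "eccentric") {
          r1 <- rf_integrate_fire(slice, layout, st_rf[[pol]],
                                  r_k = config$r_k,
                                  rf_current = config$rf_current)
          st_rf[[pol]] <- r1$state
          r2 <- pool_to_grid(r1$spikes, layout, st_grid[[pol]])
          st_grid[[pol]] <- r2$state
          s_grid[[pol]] <- r2$spikes
        } else if (mode == "average") {
          cur <- as.numeric(avg_op %*% as.numeric(slice))
          r2 <- lif_step(st_grid[[pol]], cur)
          st_grid[[pol]] <- r2$state
          s_grid[[pol]] <- matrix(r2$spikes, dl, dl)
        } else {
          s_grid[[pol]] <- slice
        }
      }

      out <- .phase_core(s_grid, hist_grid, t, eps, w_t, kern, rho,
                         config, st_s, st_ch, st_out, dl, zeros)
      st_s <- out$st_s; st_ch <- out$st_ch; st_out <- out$st_out

      hist_grid$on[[slot]] <- s_grid$on
      hist_grid$off[[slot]] <- s_grid$off

      ti <- t + 1L
      out_spk[ti] <- out$s_out
      ch_spk[, ti] <- c(out$s_ch$on, out$s_ch$off)
      v_out[ti] <- st_out$v
      v_ch[, ti] <- c(st_ch$on$v, st_ch$off$v)
      ffi[, ti] <- c(out$f_rate$on, out$f_rate$off)
      counts$grid_on[ti] <- sum(s_grid$on)
      counts$grid_off[ti] <- sum(s_grid$off)
      counts$s_on[ti] <- sum(out$s_cells$on)
      counts$s_off[ti] <- sum(out$s_cells$off)

      if (record == "full") {
        for (pol in c("on", "off")) {
          g <- which(s_grid[[pol]] == 1, arr.ind = TRUE)
          if (nrow(g)) ev_grid[[length(ev_grid) + 1L]] <- data.frame(
            polarity = pol, x = g[, 2] - 1L, y = g[, 1] - 1L, t = t)
          s <- which(out$s_cells[[pol]] == 1, arr.ind = TRUE)
          if (nrow(s)) ev_s[[length(ev_s) + 1L]] <- data.frame(
            polarity = pol, x = s[, 2] - 1L, y = s[, 1] - 1L, t = t)
        }
      }
    }
  }

  events <- NULL
  if (record == "full") {
    bindev <- function(lst) {
      if (!length(lst)) data.frame(polarity = character(), x = integer(),
                                   y = integer(), t = integer())
      else do.call(rbind, lst)
    }
    events <- list(grid = bindev(ev_grid), s_cell = bindev(ev_s))
  }
  first <- if (any(out_spk == 1)) which(out_spk == 1)[1] - 1L else NA_integer_
  structure(list(config = config, mode = mode, dl = dl, n_phases = TT,
                 fps = stream$fps, output = out_spk, channel = ch_spk,
                 membrane = list(out = v_out, on = v_ch["on", ],
                                 off = v_ch["off", ]),
                 ffi = ffi, counts = counts, events = events,
                 detected = any(out_spk == 1), first_spike = first,
                 n_spikes = sum(out_spk), n_clipped = n_clipped),
            class = "loom_trace")
}

# one phase of the interaction + readout cascade, shared by all modes
.phase_core <- function(s_grid, hist_grid, t, eps, w_t, kern, rho, config,
                        st_s, st_ch, st_out, dl, zeros) {
  s_cells <- list(); s_ch <- list(); f_rate <- list()
  for (pol in c("on", "off")) {
    delayed <- if (t >= eps) hist_grid[[pol]][[(t - eps) %% 8L + 1L]] else NULL
    E <- epsc(s_grid[[pol]], kern$w1, t, rho)
    I <- if (t >= eps && eps > 0L) ipsc(delayed, kern$w2, t, rho, eps)
         else if (eps == 0L) ipsc(s_grid[[pol]], kern$w2, t, rho, 0L)
         else zeros
    G <- E - I
    rs <- s_cell_update(G, st_s[[pol]], t)
    st_s[[pol]] <- rs$state
    s_cells[[pol]] <- rs$spikes

    fr <- if (t >= eps) {
      dsp <- if (eps == 0L) s_grid[[pol]] else delayed
      ffi_rate(dsp, dl, t, eps)
    } else 0
    f_rate[[pol]] <- fr
    cur <- gate_and_pool(rs$spikes, kern$w3, fr, config$s_th, t, rho)
    rc <- channel_lif(cur, st_ch[[pol]], t)
    st_ch[[pol]] <- rc$state
    s_ch[[pol]] <- rc$spike
  }
  ro <- output_neuron(s_ch$on, s_ch$off, config$theta1, config$theta2,
                      st_out, t)
  list(s_cells = s_cells, s_ch = s_ch, s_out = ro$spike, f_rate = f_rate,
       st_s = st_s, st_ch = st_ch, st_out = ro$state)
}
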