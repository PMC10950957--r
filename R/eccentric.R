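# Foveated (eccentric) receptive-field geometry and the local LIF network
# that down-samples pixel spikes onto a coarse output grid.
#
# Geometry conventions (calibrated so the reference configuration --
# 100 px image, largest RF 10, fovea 10% of the image side -- yields a
# 58 x 58 output grid):
#   * coordinates are continuous, pixel p occupies [p, p+1), center p + 0.5,
#     origin top-left, x = column, y = row, 0-based;
#   * ring anchor centers follow the half-step recursion in real arithmetic,
#     RF sizes are floored to integer pixel counts;
#   * the recursion stops at the first layer whose (floored) size is < 2;
#   * an RF of size s centered at c covers the pixels whose centers fall in
#     [c - s/2, c + s/2]; overlapping RFs are allowed.

#' Build the eccentric receptive-field layout
#'
#' Constructs square rings of receptive fields (RFs) that shrink linearly
#' from `max_rs` at the image border toward a central fovea of 1-pixel RFs,
#' the boundary/region partition of the image, and the mapping from output
#' neurons to the RFs intersecting their region.
#'
#' The anchor (upper-left corner) RF of ring `i` has center
#' `Rc(i) = Rc(i-1) + Rs(i-1)/2` and size
#' `Rs(i) = max_rs - (max_rs / d_fovea) * Rc(i)` floored to an integer,
#' where `d_fovea = side_length * (1 - fovea_fraction) / 2` is the distance
#' from the border to the nominal foveal edge. Rings stop at the first size
#' below 2; the fovea (unit RFs, one per pixel) fills the remaining center.
#' The per-axis region count `dl = 2 l + n + 1` (`l` ring layers, `n` foveal
#' points) is the side of the down-sampled output grid.
#'
#' @param side_length Image side in pixels (default 100).
#' @param max_rs Largest RF size, at the image border (default 10).
#' @param fovea_fraction Nominal foveal dimension as a fraction of the image
#'   side (default 0.1).
#' @return An object of class `ec_layout`. Main fields: `dl` (output grid
#'   side), `l` (last ring layer), `n` (foveal point count), `rings`
#'   (per-layer center and size, raw and floored), `rf` (one row per RF:
#'   layer, center, size, pixel bounds), `boundaries` (region edges),
#'   `rf_pixels` (sparse RF x pixel incidence), `pool` (sparse output-neuron
#'   x RF map), `npix` (pixels per RF).
#' @export
ec_layout <- function(side_length = 100, max_rs = 10, fovea_fraction = 0.1) {
  L <- side_length
  if (max_rs < 2) stop("max_rs must be >= 2")
  if (L < 2 * max_rs) stop("side_length must be at least 2 * max_rs")
  if (fovea_fraction <= 0 || fovea_fraction >= 1)
    stop("fovea_fraction must lie in (0, 1)")
  d_fovea <- (L - fovea_fraction * L) / 2
  if (d_fovea <= max_rs) stop("fovea larger than the ring geometry allows")

  ## ring recursion: real centers, floored integer sizes
  centers <- max_rs / 2
  sizes_raw <- max_rs
  sizes <- max_rs
  repeat {
    cn <- centers[length(centers)] + sizes[length(sizes)] / 2
    sraw <- max_rs - (max_rs / d_fovea) * cn
    if (floor(sraw) < 2) break
    centers <- c(centers, cn)
    sizes_raw <- c(sizes_raw, sraw)
    sizes <- c(sizes, floor(sraw))
  }
  l <- length(centers) - 1L
  rings <- data.frame(layer = 0:l, center = centers,
                      size_raw = sizes_raw, size = as.integer(sizes))

  ## region boundary points: ring corners, foveal unit steps, mirrored corners
  xs_b <- c(0, centers[-1] - sizes[-1] / 2)        # x_0 .. x_l
  x_l <- xs_b[length(xs_b)]
  fov_start <- centers[length(centers)]            # Rc(l)
  gap <- (L - x_l) - fov_start
  n <- as.integer(ceiling(gap - 1e-9))
  if (n < 1) stop("degenerate geometry: no foveal region left")
  xs_c <- fov_start + 0:(n - 1)
  xs_d <- L - rev(xs_b)
  boundaries <- c(xs_b, xs_c, xs_d)
  if (any(diff(boundaries) <= 0))
    stop("degenerate geometry: non-monotone region boundaries")
  dl <- length(boundaries) - 1L
  stopifnot(dl == 2L * l + n + 1L)

  ## receptive fields: square rings + foveal unit RFs
  rf_rows <- vector("list", l + 2L)
  for (i in 0:l) {
    cc <- centers[i + 1]; ss <- sizes[i + 1]
    # anchor positions spaced by the RF size along each ring side, the last
    # forced onto the mirrored corner so consecutive gaps never exceed the
    # RF size; the mirror union keeps the ring symmetric
    left <- cc + ss * (0:floor((L - 2 * cc) / ss + 1e-9))
    if (max(left) < L - cc - 1e-9) left <- c(left, L - cc)
    pos <- sort(unique(round(c(left, L - left), 6)))
    k <- length(pos)
    onring <- outer(seq_len(k), seq_len(k), function(a, b)
      a == 1 | a == k | b == 1 | b == k)
    idx <- which(onring, arr.ind = TRUE)
    rf_rows[[i + 1]] <- data.frame(layer = i, cx = pos[idx[, 1]],
                                   cy = pos[idx[, 2]], size = ss)
  }
  fov_px <- floor(xs_c + 1e-9)                     # pixel column of each unit RF
  fov <- expand.grid(cx = fov_px + 0.5, cy = fov_px + 0.5)
  rf_rows[[l + 2L]] <- data.frame(layer = l + 1L, cx = fov$cx, cy = fov$cy,
                                  size = 1L)
  rf <- do.call(rbind, rf_rows)
  rf$x0 <- pmax(ceiling(rf$cx - rf$size / 2 - 0.5 - 1e-9), 0L)
  rf$x1 <- pmin(floor(rf$cx + rf$size / 2 - 0.5 + 1e-9), L - 1L)
  rf$y0 <- pmax(ceiling(rf$cy - rf$size / 2 - 0.5 - 1e-9), 0L)
  rf$y1 <- pmin(floor(rf$cy + rf$size / 2 - 0.5 + 1e-9), L - 1L)
  rf$k <- seq_len(nrow(rf))
  m <- nrow(rf)

  ## RF x pixel incidence (pixels in column-major order of the L x L frame)
  ii <- vector("list", m); jj <- vector("list", m)
  for (k in seq_len(m)) {
    xr <- rf$x0[k]:rf$x1[k]; yr <- rf$y0[k]:rf$y1[k]
    pix <- as.vector(outer(yr + 1L, xr * L, `+`))   # row + col*L, 1-based rows
    ii[[k]] <- rep.int(k, length(pix)); jj[[k]] <- pix
  }
  rf_pixels <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                    x = 1, dims = c(m, L * L))
  npix <- Matrix::rowSums(rf_pixels)
  if (any(Matrix::colSums(rf_pixels) == 0))
    stop("internal error: receptive fields do not cover the image")

  ## region -> pixel ranges, then output neuron -> RF map
  reg_lo <- floor(boundaries[-length(boundaries)] + 1e-9)
  reg_hi <- ceiling(boundaries[-1] - 1e-9) - 1
  ox <- lapply(seq_len(m), function(k)
    which(reg_lo <= rf$x1[k] & reg_hi >= rf$x0[k]))
  oy <- lapply(seq_len(m), function(k)
    which(reg_lo <= rf$y1[k] & reg_hi >= rf$y0[k]))
  pi_ <- vector("list", m); pj <- vector("list", m)
  for (k in seq_len(m)) {
    cells <- as.vector(outer(oy[[k]], (ox[[k]] - 1L) * dl, `+`))
    pi_[[k]] <- cells; pj[[k]] <- rep.int(k, length(cells))
  }
  pool <- Matrix::sparseMatrix(i = unlist(pi_), j = unlist(pj), x = 1,
                               dims = c(dl * dl, m))

  structure(list(side_length = L, max_rs = max_rs,
                 fovea_fraction = fovea_fraction, d_fovea = d_fovea,
                 rings = rings, l = l, n = n, dl = dl,
                 boundaries = boundaries, region_lo = reg_lo,
                 region_hi = reg_hi, rf = rf, rf_pixels = rf_pixels,
                 npix = npix, pool = pool),
            class = "ec_layout")
}

#' @export
print.ec_layout <- function(x, ...) {
  cat(sprintf("ec_layout: %d x %d px -> %d x %d output grid\n",
              x$side_length, x$side_length, x$dl, x$dl))
  cat(sprintf("  %d ring layers (RF sizes %s), fovea %d x %d unit RFs, %d RFs total\n",
              x$l + 1, paste(range(x$rings$size), collapse = ".."),
              x$n, x$n, nrow(x$rf)))
  invisible(x)
}

#' Leak-integrate one phase of pixel spikes into the RF layer
#'
#' Every RF is a leaky integrate-and-fire unit that accumulates the spikes
#' of the pixels it contains. The per-pixel injected current is `r_k` for a
#' unit-area (foveal) RF and, with `rf_current = "normalized"` (default),
#' `r_k / npix` for larger RFs, so a peripheral RF demands more stimulation
#' to fire. The membrane decays by `exp(-1/tau)` per phase tick, fires when
#' it reaches `rho`, and resets to 0.
#'
#' @param slice Binary `L x L` matrix, one polarity of one phase slice.
#' @param layout An [ec_layout].
#' @param state A [lif_state()] with one unit per RF.
#' @param r_k Percentage-area current factor (default 0.6).
#' @param rf_current `"normalized"` (default) or `"raw"` (per-pixel current
#'   `r_k` regardless of RF area).
#' @return List with `spikes` (0/1 vector over RFs) and the updated `state`.
#' @export
rf_integrate_fire <- function(slice, layout, state, r_k = 0.6,
                              rf_current = c("normalized", "raw")) {
  rf_current <- match.arg(rf_current)
  m <- nrow(layout$rf)
  if (state$n != m) stop("state has ", state$n, " units but layout has ", m, " RFs")
  if (!all(dim(slice) == layout$side_length))
    stop("slice dimensions do not match the layout")
  counts <- as.numeric(layout$rf_pixels %*% as.numeric(slice))
  input <- if (rf_current == "normalized") counts * (r_k / layout$npix)
           else counts * r_k
  lif_step(state, input)
}

#' Pool RF spikes onto the down-sampled output grid
#'
#' Each output neuron leak-integrates the number of spikes among its mapped
#' RFs (the RFs intersecting its image region) and fires at threshold `rho`,
#' resetting to 0. Foveal output neurons map one-to-one onto unit RFs.
#'
#' @param rf_spikes 0/1 vector over RFs (from [rf_integrate_fire()]).
#' @param layout An [ec_layout].
#' @param state A [lif_state()] with `dl^2` units.
#' @return List with `spikes` (binary `dl x dl` matrix) and updated `state`.
#' @export
pool_to_grid <- function(rf_spikes, layout, state) {
  dl <- layout$dl
  if (state$n != dl * dl) stop("state must have dl^2 = ", dl * dl, " units")
  input <- as.numeric(layout$pool %*% rf_spikes)
  res <- lif_step(state, input)
  res$spikes <- matrix(res$spikes, dl, dl)
  res
}

#' Export the layout as plain-text tables
#'
#' Writes one row per RF (`k`, `layer`, `center_x`, `center_y`, `size`) to
#' `<path>_rf.csv` and one row per output neuron with the ids of its mapped
#' RFs to `<path>_map.csv`.
#'
#' @param layout An [ec_layout].
#' @param path File prefix.
#' @return The two file names, invisibly.
#' @export
export_layout <- function(layout, path) {
  f1 <- paste0(path, "_rf.csv")
  f2 <- paste0(path, "_map.csv")
  utils::write.csv(data.frame(k = layout$rf$k, layer = layout$rf$layer,
                              center_x = layout$rf$cx, center_y = layout$rf$cy,
                              size = layout$rf$size),
                   f1, row.names = FALSE)
  trip <- Matrix::summary(layout$pool)
  map <- vapply(split(trip$j, factor(trip$i, levels = seq_len(layout$dl^2))),
                function(k) paste(sort(k), collapse = " "), character(1))
  utils::write.csv(data.frame(
    x = rep(0:(layout$dl - 1), each = layout$dl),
    y = rep(0:(layout$dl - 1), layout$dl),
    rf_ids = map), f2, row.names = FALSE)
  invisible(c(f1, f2))
}
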