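# Eccentric receptive-field geometry and the entry LIF network.

test_that("the reference configuration yields a 58-cell output grid", {
  lay <- ref_layout()
  expect_equal(lay$dl, 58L)
  expect_equal(lay$l, 14L)
  expect_equal(lay$n, 29L)
  expect_equal(lay$dl, 2L * lay$l + lay$n + 1L)
  expect_equal(range(lay$boundaries), c(0, 100))
  expect_true(all(diff(lay$boundaries) > 0))
})

test_that("the raw ring recursion starts Rc(0)=5, Rc(1)=10, Rs(1)=70/9", {
  lay <- ref_layout()
  expect_equal(lay$d_fovea, 45)
  expect_equal(lay$rings$center[1:2], c(5, 10))
  expect_equal(lay$rings$size_raw[2], 70 / 9)
})

test_that("ring sizes are non-increasing and the fovea is one-to-one", {
  lay <- ref_layout()
  expect_true(all(diff(lay$rings$size) <= 0))
  expect_true(all(lay$rf$size[lay$rf$layer == lay$l + 1] == 1))
  # an interior foveal output neuron maps exactly one unit RF
  j <- which(lay$region_lo == 50 & lay$region_hi == 50)
  cell <- j + (j - 1) * lay$dl
  rfs <- which(lay$pool[cell, ] != 0)
  expect_length(rfs, 1)
  expect_equal(lay$rf$size[rfs], 1L)
})

test_that("every pixel is covered by at least one receptive field", {
  for (lay in list(ref_layout(), small_layout())) {
    expect_true(all(Matrix::colSums(lay$rf_pixels) >= 1))
  }
})

test_that("a minimal outer ring terminates the recursion immediately", {
  lay <- ec_layout(20, 2, 0.1)
  expect_equal(lay$l, 0L)         # Rs(1) < 2 already
})

test_that("enlarging the fovea never shrinks the output grid", {
  dls <- vapply(c(0.05, 0.1, 0.2, 0.3), function(ff)
    ec_layout(100, 10, ff)$dl, integer(1))
  expect_true(all(diff(dls) >= 0))
})

test_that("degenerate geometries are rejected", {
  expect_error(ec_layout(15, 10), "side_length")
  expect_error(ec_layout(100, 1), "max_rs")
  expect_error(ec_layout(100, 10, 0), "fovea_fraction")
  expect_error(ec_layout(100, 10, 1), "fovea_fraction")
})

test_that("RF units integrate, leak and fire like per-pixel LIF neurons", {
  lay <- small_layout()
  m <- nrow(lay$rf)
  st <- lif_state(m, tau = 1000 / 30, rho = 0.9)
  zero <- matrix(0, 50, 50)

  # silence forever: no spikes, membranes at zero
  r <- rf_integrate_fire(zero, lay, st)
  expect_true(all(r$spikes == 0) && all(r$state$v == 0))

  # a foveal pixel: one spike is subthreshold (0.6 < 0.9), a second fires
  fov_rf <- which(lay$rf$size == 1)[10]
  slice <- zero
  slice[lay$rf$y0[fov_rf] + 1, lay$rf$x0[fov_rf] + 1] <- 1
  r1 <- rf_integrate_fire(slice, lay, st)
  expect_equal(r1$spikes[fov_rf], 0)
  expect_equal(r1$state$v[fov_rf], 0.6)
  r2 <- rf_integrate_fire(slice, lay, r1$state)
  expect_equal(r2$spikes[fov_rf], 1)   # 0.6 * exp(-1/tau) + 0.6 >= 0.9
  expect_equal(r2$state$v[fov_rf], 0)  # hard reset

  # saturated input: foveal RFs behave exactly like a per-pixel LIF oracle
  ones <- matrix(1, 50, 50)
  sta <- lif_state(m, tau = 1000 / 30, rho = 0.9)
  a1 <- rf_integrate_fire(ones, lay, sta)
  a2 <- rf_integrate_fire(ones, lay, a1$state)
  oracle <- lif_state(1, tau = 1000 / 30, rho = 0.9)
  o1 <- lif_step(oracle, 0.6); o2 <- lif_step(o1$state, 0.6)
  fov <- lay$rf$size == 1
  expect_true(all(a1$spikes[fov] == o1$spikes))
  expect_true(all(a2$spikes[fov] == o2$spikes))

  expect_error(rf_integrate_fire(zero, lay, lif_state(3)), "units")
})

test_that("grid neurons sum the spikes of their mapped RFs", {
  lay <- small_layout()
  none <- pool_to_grid(numeric(nrow(lay$rf)), lay,
                       lif_state(lay$dl^2, rho = 0.9))
  expect_true(all(none$spikes == 0))

  # a cell mapped to m RFs receives current m before thresholding
  fanin <- Matrix::rowSums(lay$pool)
  cell <- which(fanin >= 3)[1]
  m <- fanin[cell]
  spikes <- as.numeric(lay$pool[cell, ] != 0)
  big_rho <- lif_state(lay$dl^2, rho = m + 0.5)   # keep it subthreshold
  r <- pool_to_grid(spikes, lay, big_rho)
  expect_equal(r$state$v[cell], m)
  expect_true(all(r$spikes == 0))
  # at the default threshold the same input fires the cell
  r2 <- pool_to_grid(spikes, lay, lif_state(lay$dl^2, rho = 0.9))
  expect_equal(as.numeric(r2$spikes)[cell], 1)
})

test_that("the layout exports as plain-text tables", {
  lay <- small_layout()
  pref <- file.path(withr::local_tempdir(), "layout")
  files <- export_layout(lay, pref)
  rf <- utils::read.csv(paste0(pref, "_rf.csv"))
  expect_equal(nrow(rf), nrow(lay$rf))
  mp <- utils::read.csv(paste0(pref, "_map.csv"))
  expect_equal(nrow(mp), lay$dl^2)
})
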