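# FFI gating, channel LIF neurons and the output neuron.

test_that("the population rate is the weighted active fraction of the grid", {
  expect_equal(ffi_rate(matrix(0, 4, 4), dl = 4, t = 5, epsilon = 2), 0)
  expect_equal(ffi_rate(matrix(1, 4, 4), dl = 4, t = 5, epsilon = 2),
               phase_weight(3))
  half <- matrix(c(1, 0), 4, 4)
  expect_equal(ffi_rate(half, dl = 4, t = 2, epsilon = 2), 0.5 * 0.5)
  expect_equal(ffi_rate(NULL, dl = 4, t = 1, epsilon = 2), 0)
})

test_that("the FFI gate zeroes the channel current at and above threshold", {
  k <- make_kernels(6)
  S <- matrix(1, 6, 6)
  # inclusive gate: F exactly at threshold blocks the input
  expect_equal(gate_and_pool(S, k$w3, f_rate = 0.1, s_th = 0.1, t = 0), 0)
  expect_equal(gate_and_pool(S, k$w3, f_rate = 0.25, s_th = 0.1, t = 0), 0)
  # open gate, all cells active, unit-sum kernel: omega(0) * 1 * rho
  expect_equal(gate_and_pool(S, k$w3, f_rate = 0, s_th = 0.1, t = 0), 0.45)
  expect_equal(gate_and_pool(0 * S, k$w3, f_rate = 0, s_th = 0.1, t = 0), 0)
})

test_that("raising the gate threshold never reduces the open phases", {
  set.seed(21)
  f <- runif(50, 0, 0.3)
  drives <- runif(50)
  k <- make_kernels(4)
  open <- function(s_th) sum(vapply(seq_along(f), function(i)
    gate_and_pool(matrix(drives[i] > 0.2, 4, 4), k$w3, f[i], s_th,
                  t = i - 1), numeric(1)) > 0)
  ns <- vapply(c(0.05, 0.1, 0.2, 0.5), open, numeric(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("channel neurons integrate gated currents against the scaled threshold", {
  st <- lif_state(1, rho = 0.9)
  # silence never fires
  for (t in 0:7) {
    r <- channel_lif(0, st, t); st <- r$state
    expect_equal(r$spike, 0)
  }
  # sustained current at omega(t) * rho fires from the first phase
  st <- lif_state(1, rho = 0.9)
  spikes <- vapply(0:15, function(t) {
    r <- channel_lif(phase_weight(t) * 0.9, st, t)
    st <<- r$state
    r$spike
  }, numeric(1))
  expect_equal(spikes[1], 1)     # first phase of the first period
  expect_equal(spikes[9], 1)     # first phase of the next period
  # one subthreshold kick decays geometrically without firing
  st <- lif_state(1, rho = 0.9)
  r <- channel_lif(0.1, st, 0)
  v0 <- r$state$v
  r <- channel_lif(0, r$state, 1)
  expect_equal(r$state$v, v0 * exp(-1 / r$state$tau))
  expect_equal(r$spike, 0)
})

test_that("the output neuron combines the channels with theta weights", {
  # both channels spiking at theta 0.5/0.5: I = omega(t) >= 0.9 * omega(t)
  r <- output_neuron(1, 1, 0.5, 0.5, lif_state(1, rho = 0.9), t = 3)
  expect_equal(r$spike, 1)
  expect_equal(r$current, phase_weight(3))
  # an isolated ON spike under theta1 = 0.3 stays subthreshold
  r <- output_neuron(1, 0, 0.3, 0.7, lif_state(1, rho = 0.9), t = 0)
  expect_equal(r$spike, 0)
  expect_equal(r$state$v, 0.3 * 0.5)
  # silent channels, silent output
  r <- output_neuron(0, 0, 0.5, 0.5, lif_state(1, rho = 0.9), t = 0)
  expect_equal(r$spike, 0)
  expect_error(output_neuron(1, 1, -0.1, 0.5, lif_state(1), t = 0), "theta")
})

test_that("swapping polarities and thetas mirrors the channels, not the output", {
  dark <- run_loom(small_loom(12), small_config(theta1 = 0.3, theta2 = 0.7),
                   layout = small_layout(), record = "output")
  # inverted contrast: every luminance change flips sign, ON <-> OFF
  inv <- make_square_motion(stim_spec("looming", 220, 40, start_size = 6,
                                      end_size = 40, n_frames = 12,
                                      side_length = 50))
  white <- run_loom(inv, small_config(theta1 = 0.7, theta2 = 0.3),
                    layout = small_layout(), record = "output")
  expect_equal(dark$channel["off", ], white$channel["on", ])
  expect_equal(dark$channel["on", ], white$channel["off", ])
  expect_equal(dark$output, white$output)
  expect_equal(dark$ffi["off", ], white$ffi["on", ])
})
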