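# EPSC/IPSC generation and the summation-cell competition.

test_that("unit-sum kernels are normalized, symmetric and peak at the center", {
  k <- make_kernels(58)
  for (w in k) {
    expect_equal(sum(w), 1)
    expect_equal(w, w[nrow(w):1, ], ignore_attr = TRUE)
    expect_equal(w, t(w), ignore_attr = TRUE)
  }
  expect_equal(which.max(k$w1), 5L)            # center of the 3 x 3
  # flat limit: enormous sigma approaches uniform weights
  flat <- make_kernels(9, sigma1 = 1e6, sigma2 = 1e6, sigma3 = 1e6)
  expect_true(all(abs(flat$w1 - 1 / 9) < 1e-9))
  expect_error(make_kernels(58, sigma1 = 0), "positive")
})

test_that("the inhibitory surround dominates the excitatory center pointwise", {
  # peak-1 connection surfaces: w2 is wider at equal peak, so E - I <= 0
  # whenever both reference the same spikes -- the zero-delay silence
  w1 <- loomnet:::.gauss_kernel(3L, 1, normalize = FALSE)
  w2 <- loomnet:::.gauss_kernel(9L, 0.5, normalize = FALSE)
  expect_true(all(w2[4:6, 4:6] >= w1))
})

test_that("EPSC stamps the phase-weighted kernel on the spike field", {
  k <- make_kernels(9)
  none <- epsc(matrix(0, 9, 9), k$w1, t = 0)
  expect_true(all(none == 0))
  allon <- epsc(matrix(1, 9, 9), k$w1, t = 0)
  expect_equal(allon[5, 5], 0.5 * 1 * 0.9)     # omega(0) * unit sum * rho
  one <- matrix(0, 9, 9); one[5, 5] <- 1
  E <- epsc(one, k$w1, t = 0)
  expect_equal(E[4:6, 4:6], 0.45 * k$w1, ignore_attr = TRUE)
  expect_true(all(E[-(4:6), ] == 0))
})

test_that("IPSC is phase-delayed, zero before the delay and range-checked", {
  k <- make_kernels(11)
  expect_true(all(ipsc(matrix(1, 11, 11), k$w2, t = 1, epsilon = 2) == 0))
  I <- ipsc(matrix(1, 11, 11), k$w2, t = 4, epsilon = 2)
  expect_equal(I[6, 6], phase_weight(2) * 0.9)
  expect_error(ipsc(matrix(1, 11, 11), k$w2, t = 4, epsilon = 9), "epsilon")
  expect_error(ipsc(matrix(1, 11, 11), k$w2, t = 4, epsilon = -1), "epsilon")
})

test_that("summation is elementwise E - I with shape checking", {
  E <- matrix(0.45, 2, 2); I <- matrix(0.1, 2, 2)
  expect_equal(summation(E, I), matrix(0.35, 2, 2))
  expect_equal(summation(E, E), matrix(0, 2, 2))
  expect_equal(summation(E, 0 * E), E)
  expect_error(summation(E, matrix(0, 3, 3)), "shape")
})

test_that("EPSC/IPSC match a brute-force quadruple loop on a small grid", {
  set.seed(5)
  n <- 5
  k <- make_kernels(n)
  hist <- lapply(1:3, function(i) matrix(rbinom(n * n, 1, 0.4), n, n))
  brute <- function(S, w, t_eff) {
    h <- (nrow(w) - 1) / 2
    out <- matrix(0, n, n)
    for (x in 1:n) for (y in 1:n) {
      acc <- 0
      for (i in -h:h) for (j in -h:h) {
        xi <- x + i; yj <- y + j
        if (xi >= 1 && xi <= n && yj >= 1 && yj <= n)
          acc <- acc + S[xi, yj] * w[i + h + 1, j + h + 1]
      }
      out[x, y] <- phase_weight(t_eff) * acc * 0.9
    }
    out
  }
  for (t in 0:2) {
    expect_equal(epsc(hist[[t + 1]], k$w1, t), brute(hist[[t + 1]], k$w1, t))
    if (t >= 2) {
      expect_equal(ipsc(hist[[t - 1]], k$w2, t, epsilon = 2),
                   brute(hist[[t - 1]], k$w2, t - 2))
    }
  }
})

test_that("currents are invariant under whole-period time shifts", {
  set.seed(9)
  S <- matrix(rbinom(49, 1, 0.3), 7, 7)
  k <- make_kernels(7)
  expect_equal(epsc(S, k$w1, 3), epsc(S, k$w1, 11))
  expect_equal(ipsc(S, k$w2, 4, epsilon = 2), ipsc(S, k$w2, 12, epsilon = 2))
})

test_that("summation cells fire against the phase-scaled threshold and floor at rest", {
  st <- lif_state(4, rho = 0.9)
  # subthreshold current accumulates without firing
  G <- matrix(0.2, 2, 2)
  r <- s_cell_update(G, st, t = 0)             # threshold 0.45 at phase 0
  expect_true(all(r$spikes == 0))
  expect_equal(r$state$v, rep(0.2, 4))
  # current equal to omega(0) * rho fires immediately from rest
  r2 <- s_cell_update(matrix(0.45, 2, 2), lif_state(4, rho = 0.9), t = 0)
  expect_true(all(r2$spikes == 1))
  # negative net current never fires and never drives V below zero
  r3 <- s_cell_update(matrix(-5, 2, 2), r$state, t = 1)
  expect_true(all(r3$spikes == 0))
  expect_true(all(r3$state$v == 0))
})
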