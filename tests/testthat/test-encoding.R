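# Phase coding: weights, frame differencing, ON/OFF split, binary encoding.

test_that("phase weights decay 2^-1 .. 2^-8 and repeat every period", {
  expect_identical(phase_weight(0:7), 2^-(1:8))
  expect_identical(phase_weight(8), phase_weight(0))
  expect_identical(phase_weight(0:15), rep(2^-(1:8), 2))
  expect_error(phase_weight(-1), "non-negative")
  expect_error(phase_weight(1.5), "integer")
})

test_that("frame differencing is pixelwise subtraction with a zero first slice", {
  fr <- array(0, dim = c(4, 4, 3))
  fr[2, 3, 1] <- 4; fr[2, 3, 2] <- 10; fr[2, 3, 3] <- 7
  P <- frame_difference(frame_stream(fr))
  expect_true(all(P[, , 1] == 0))
  expect_equal(P[2, 3, 2], 6)
  expect_equal(P[2, 3, 3], -3)
  expect_error(frame_difference(frame_stream(array(1, dim = c(4, 4, 1)))),
               "at least 2 frames")
})

test_that("constant streams yield zero motion and time reversal negates P", {
  expect_true(all(frame_difference(constant_stream()) == 0))
  set.seed(11)
  fr <- array(sample(0:255, 5 * 5 * 6, TRUE), dim = c(5, 5, 6))
  P1 <- frame_difference(frame_stream(fr))
  P2 <- frame_difference(frame_stream(fr[, , 6:1]))
  # P_rev(f) = L(7-f) - L(8-f) = -P(8-f) for f = 2..6
  for (f in 2:6) expect_equal(P2[, , f], -P1[, , 8 - f])
})

test_that("ON/OFF split rectifies with the alpha1 residual", {
  prev <- list(on = matrix(0, 1, 1), off = matrix(2, 1, 1))
  ch <- split_on_off(matrix(-3, 1, 1), prev, alpha1 = 0.1)
  expect_equal(ch$off[1, 1], 3.2)   # [P]^- + 0.1 * 2
  expect_equal(ch$on[1, 1], 0)
  expect_error(split_on_off(matrix(0, 1, 1), alpha1 = 1), "alpha1")
})

test_that("with alpha1 = 0 the channels are exclusive rectifications", {
  set.seed(7)
  P <- matrix(rnorm(400, sd = 50), 20, 20)
  ch <- split_on_off(P, NULL, alpha1 = 0)
  expect_true(all(ch$on >= 0) && all(ch$off >= 0))
  expect_true(all(ch$on * ch$off == 0))
  expect_equal(ch$on - ch$off, P)
})

test_that("channels decay geometrically under zero input", {
  st <- split_on_off(matrix(100, 2, 2), NULL, alpha1 = 0.1)
  for (k in 1:4) st <- split_on_off(matrix(0, 2, 2), st, alpha1 = 0.1)
  expect_equal(st$on[1, 1], 100 * 0.1^4)
})

test_that("phase encoding matches an independent binary-expansion oracle", {
  v <- (0:255) / 256
  bits <- phase_encode(v)
  # oracle: MSB-first bits of the integer k = 256 * v
  oracle <- t(vapply(0:255, function(k) rev(as.integer(intToBits(k))[1:8]),
                     integer(8)))
  expect_equal(unname(bits[, ]), unname(oracle), ignore_attr = TRUE)
  expect_equal(as.numeric(phase_encode(0.5)), c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(phase_encode(2^-1 + 2^-8)), c(1, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(as.numeric(phase_encode(0)), rep(0, 8))
})

test_that("the omega-weighted decode recovers every 8-bit value within 2^-8", {
  v <- (0:255) / 256
  dec <- phase_decode(phase_encode(v))
  expect_true(all(abs(dec - v) <= 2^-8))
  # arbitrary values in [0, 1) truncate downward by < 2^-8
  set.seed(3)
  u <- runif(200)
  err <- u - phase_decode(phase_encode(u))
  expect_true(all(err >= 0 & err <= 2^-8))
})

test_that("values above the representable code are clipped and counted", {
  b <- phase_encode(c(0.3, 1.0, 2.5))
  expect_equal(attr(b, "n_clipped"), 2)
  expect_equal(phase_decode(b)[2], 255 / 256)
  expect_error(phase_encode(-0.1), "non-negative")
})

test_that("weighted spike mass is monotone in the channel value", {
  set.seed(42)
  v <- sort(runif(100))
  mass <- phase_decode(phase_encode(v))
  expect_true(all(diff(mass) >= 0))
})

test_that("encode_stream emits ordered events covering 8 phases per frame", {
  st <- small_loom(6)
  ev <- encode_stream(st)
  expect_named(ev, c("polarity", "x", "y", "t"))
  expect_equal(attr(ev, "n_phases"), 48L)
  expect_true(all(diff(ev$t) >= 0))
  expect_true(all(ev$t >= 8))      # first frame encodes an empty period
  expect_true(all(ev$polarity %in% c("on", "off")))
  # constant stream encodes nothing
  expect_equal(nrow(encode_stream(constant_stream())), 0L)
})
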