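test_that("channel geometry constructors validate dimensions", {
  g <- channel_geometry()
  expect_s3_class(g, "channel_geometry")
  expect_equal(c(g$L, g$H, g$W), c(1e-2, 1e-3, 5e-5))
  w <- wide_channel_geometry()
  expect_equal(c(w$L, w$H, w$W), c(1e-2, 5e-5, 1e-3))
  expect_error(channel_geometry(L = 0), "strictly positive")
  expect_error(channel_geometry(H = -1e-5), "strictly positive")
  expect_error(channel_geometry(W = Inf), "strictly positive")
})

test_that("waveform constructors evaluate exactly", {
  expect_equal(eval_waveform(flow_steady(2e-10), c(0, 5, 10)), rep(2e-10, 3))

  w <- flow_sinusoidal(1.5e-10, delta = 0.5, freq = 0.1)
  t <- c(0, 2.5, 5, 7.5, 10)
  expect_equal(eval_waveform(w, t),
               1.5e-10 * (1 + 0.5 * sin(2 * pi * 0.1 * t)))
  # quarter period hits the extremes
  expect_equal(eval_waveform(w, 2.5), 1.5e-10 * 1.5)
  expect_equal(eval_waveform(w, 7.5), 1.5e-10 * 0.5)

  s <- flow_sampled(c(0, 1, 2), c(1e-10, 3e-10, 1e-10))
  expect_equal(eval_waveform(s, 0.5), 2e-10)  # linear interpolation
  expect_equal(eval_waveform(s, c(0, 2)), c(1e-10, 1e-10))
})

test_that("waveform constructors reject invalid input", {
  expect_error(flow_steady(-1e-10), "nonnegative")
  expect_error(flow_sinusoidal(1e-10, delta = 1.2, freq = 0.1), "delta")
  expect_error(flow_sinusoidal(1e-10, delta = 0.5, freq = 0), "frequency")
  expect_error(flow_sampled(c(0, 0, 1), c(1, 1, 1) * 1e-10),
               "strictly increasing")
  expect_error(flow_sampled(c(0, 1), c(1e-10, -1e-10)), "nonnegative")
  expect_error(eval_waveform(flow_sampled(c(0, 1), c(1e-10, 1e-10)), 2),
               "outside its time span")
})

test_that("flow program derives total flow, stream fraction and shear", {
  prog <- flow_program(1.5e-10, flow_sinusoidal(1.5e-10, 0.5, 0.1))
  expect_equal(total_flow(prog, 0), 3e-10)
  expect_equal(flow_fraction(prog, 0), 0.5)
  # at the perfusion maximum the ATP stream narrows to 1/(1+1.5)
  expect_equal(flow_fraction(prog, 2.5), 1.5 / (1.5 + 2.25))

  # printed-geometry shear at equal steady flows: 6*eta*Q/(W*H^2) = 0.036 Pa
  g <- channel_geometry()
  prog2 <- flow_program(1.5e-10, flow_steady(1.5e-10))
  expect_equal(wall_shear_stress(prog2, g, eta = 1e-3, t = 0),
               6 * 1e-3 * 3e-10 / (5e-5 * 1e-6))

  # degenerate zero-flow program cannot define a stream fraction
  prog0 <- flow_program(0, flow_steady(0))
  expect_error(flow_fraction(prog0, 0), "degenerate")

  # numeric Q2 is promoted to a steady waveform
  expect_equal(total_flow(flow_program(1e-10, 2e-10), 3), 3e-10)
})

test_that("find_peaks honors topographic prominence", {
  t <- seq(0, 10, by = 0.01)
  v <- sin(2 * pi * 0.5 * t)            # 5 peaks of prominence ~2
  pk <- find_peaks(v, prominence = 1)
  expect_length(pk, 5L)
  expect_equal(t[pk], c(0.5, 2.5, 4.5, 6.5, 8.5), tolerance = 1e-8)

  # a small bump riding a large peak is filtered out by prominence
  v2 <- exp(-(t - 5)^2) + 0.01 * sin(2 * pi * 5 * t)
  expect_gt(length(find_peaks(v2, prominence = 0)), 1L)
  expect_length(find_peaks(v2, prominence = 0.5), 1L)

  expect_identical(find_peaks(c(1, 2), prominence = 0), integer(0))
  expect_identical(find_peaks(rep(1, 10), prominence = 0), integer(0))
})

test_that("signal_metrics recovers mean, amplitude and frequency of a sine", {
  t <- seq(0, 80, by = 0.05)   # analysis window [20, 80] s: 6 full periods
  v <- 2 + 0.5 * sin(2 * pi * 0.1 * t)
  m <- signal_metrics(t, v)
  expect_equal(m$mean, 2, tolerance = 1e-3)
  expect_equal(m$peak_to_peak, 1, tolerance = 1e-3)
  # one frequency bin of the post-transient window
  expect_lt(abs(m$dominant_frequency - 0.1), 1 / 60)
  expect_equal(m$first_peak_time, 2.5, tolerance = 0.1)
})

test_that("dominant frequency is robust to a linear trend", {
  t <- seq(0, 100, by = 0.1)
  v <- 5 + 0.02 * t + 0.3 * sin(2 * pi * 0.1 * t)
  m <- signal_metrics(t, v)
  expect_lt(abs(m$dominant_frequency - 0.1), 2 / 75)
})

test_that("signal_metrics handles constant and irregular input", {
  t <- seq(0, 10, by = 0.1)
  m <- signal_metrics(t, rep(3, length(t)))
  expect_equal(m$mean, 3)
  expect_equal(m$peak_to_peak, 0)
  expect_true(is.na(m$dominant_frequency))
  expect_true(is.na(m$first_peak_time))
  expect_error(signal_metrics(c(0, 1, 3), c(1, 2, 3)), "uniform")
})

test_that("transient exclusion window is honored", {
  t <- seq(0, 40, by = 0.05)
  # large start-up bump confined to the first quarter of the record
  v <- 1 + 4 * exp(-t) + 0.2 * sin(2 * pi * 0.5 * t)
  m <- signal_metrics(t, v, transient_frac = 0.25)
  expect_equal(m$mean, 1, tolerance = 0.01)
  expect_equal(m$peak_to_peak, 0.4, tolerance = 0.01)
})
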