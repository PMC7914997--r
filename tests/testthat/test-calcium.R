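test_that("parameter assembly validates, derives rest values and round-trips", {
  p <- calcium_params()
  expect_s3_class(p, "calcium_params")
  # store load from the restore/leak balance at rest
  expect_equal(p$Cs_rest, sqrt(p$k4 / p$k5) * p$C0 / (p$K3 + p$C0))
  # buffered load at binding equilibrium
  expect_equal(p$Cb_rest, p$k6 * p$C0 * p$BT / (p$k7 + p$k6 * p$C0))
  # passive influx calibrated to balance clearance at rest
  expect_equal(p$qin_pass, q_out(p$C0, p))

  expect_error(calcium_params(bogus = 1), "unknown calcium parameter")
  expect_error(calcium_params(k2 = -1), "nonnegative")
  expect_error(calcium_params(fe = 2), "fe")
  expect_error(calcium_params(Cex = 0.05), "Cex > C0")

  p2 <- calcium_params(k8 = 1.2)
  expect_equal(p2$k8, 1.2)
  expect_equal(p2$qin_pass, q_out(p2$C0, p2))  # recalibrated after override

  path <- tempfile(fileext = ".txt")
  write_calcium_params(p, path)
  back <- read_calcium_params(path)
  for (k in c("k1", "k3", "qmax", "kp2x4", "Cs_rest", "qin_pass"))
    expect_equal(back[[k]], p[[k]], info = k)
})

test_that("the unstimulated resting state is an exact equilibrium", {
  p <- calcium_params()
  r <- calcium_rhs(initial_state(p), phi = 0, tauw = 0, p = p)
  expect_lt(max(abs(r$deriv)), 1e-12)

  # and the integrated trajectory stays there
  tr <- simulate_calcium(p, constant_stimulus(0, 0, t_end = 200),
                         t_end = 200, keep_fluxes = FALSE)
  expect_lt(max(abs(tr$C - p$C0)), 1e-6)
  expect_lt(max(abs(tr$Cs - p$Cs_rest)), 1e-4)
  expect_lt(max(abs(tr$i)), 1e-9)
})

test_that("the resting state attracts +/-10% cytosolic perturbations", {
  p <- calcium_params()
  st <- constant_stimulus(0, 0, t_end = 300)
  for (s in c(0.9, 1.1)) {
    x0 <- initial_state(p)
    x0[["C"]] <- p$C0 * s
    tr <- simulate_calcium(p, st, t_end = 300, state0 = x0,
                           keep_fluxes = FALSE)
    expect_lt(abs(tail(tr$C, 1) - p$C0) / p$C0, 0.01)
    expect_lt(abs(tail(tr$Cs, 1) - p$Cs_rest) / p$Cs_rest, 0.01)
  }
})

test_that("trajectories respect nonnegativity and the buffer cap", {
  p <- calcium_params()
  tr <- fx_validation_traj()
  for (col in c("C", "Cs", "Cb", "i"))
    expect_true(all(tr[[col]] >= -1e-9), info = col)
  expect_true(all(tr$Cb <= p$BT))
  expect_true(all(tr$C < p$Cex))
})

test_that("flux bookkeeping identity holds to machine precision", {
  # dC/dt + dCb/dt + (1/Vc_over_Vs) dCs/dt == q_in - q_out along any path
  p <- calcium_params()
  stim <- sinusoidal_stimulus(5, 1, 0.1, shear = 0.3, t_end = 60)
  tr <- simulate_calcium(p, stim, t_end = 60, keep_fluxes = FALSE)
  aphi <- approxfun(stim$t, stim$atp, rule = 2)
  resid <- vapply(seq_len(nrow(tr)), function(k) {
    st <- c(C = tr$C[k], Cs = tr$Cs[k], Cb = tr$Cb[k], i = tr$i[k])
    r <- calcium_rhs(st, aphi(tr$t[k]), 0.3, p)
    d <- r$deriv
    abs(d[["C"]] + d[["Cb"]] + d[["Cs"]] / p$Vc_over_Vs -
          (r$fluxes[["qin"]] - r$fluxes[["qout"]]))
  }, numeric(1))
  expect_lt(max(resid), 1e-12)
})

test_that("gating probabilities stay within their analytic bounds", {
  p <- calcium_params()
  tau <- seq(0, 10, by = 0.1)
  p1 <- gate_p1(tau, p)
  # analytic range [1/(1+alpha), 1); the upper bound saturates in floating
  # point once the gating exponent underflows
  expect_true(all(p1 >= 1 / (1 + p$alpha) & p1 <= 1))
  expect_equal(p1[1], 1 / (1 + p$alpha))     # no-load open probability
  expect_true(all(diff(p1) >= 0))            # monotone in shear

  ip3 <- seq(0, 5, by = 0.05)
  p2 <- gate_p2(ip3, p)
  expect_true(all(p2 >= p$b1 & p2 <= p$b1 * (1 + p$a1)))
  expect_equal(gate_p2(0, p), p$b1)

  C <- seq(0, 3, by = 0.05)
  p3 <- gate_p3(C, p)
  expect_true(all(p3 > p$c1 & p3 <= p$c1 + p$c2))
  expect_true(all(diff(p3) < 0))             # decays with Ca2+
})

test_that("membrane strain energy vanishes at rest and grows with load", {
  p <- calcium_params()
  expect_equal(strain_energy(0, p), 0)
  tau <- seq(0, 5, by = 0.05)
  w <- strain_energy(tau, p)
  expect_true(all(diff(w) > 0))
  expect_message(strain_energy(-1, p), "magnitude")
  suppressMessages(expect_equal(strain_energy(-1, p), strain_energy(1, p)))
})

test_that("a stronger ATP step produces a higher first calcium peak", {
  peaks <- vapply(c(1, 5, 10), function(phi) {
    st <- constant_stimulus(phi, 0.3, t_end = 120)
    max(simulate_calcium(calcium_params(), st, t_end = 120,
                         keep_fluxes = FALSE)$C)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("validation protocol: first peak near 25 s, entrained at 0.1 Hz", {
  tr <- fx_validation_traj()
  m <- classify_response(tr)
  expect_gt(m$first_peak_time, 15)
  expect_lt(m$first_peak_time, 35)
  expect_lt(abs(m$dominant_frequency - 0.1), 1 / 450 + 1e-12)
  expect_gt(m$oscillation_amplitude, 0.01)
})

test_that("non-finite stimulus is rejected with the offending flux named", {
  p <- calcium_params()
  expect_error(calcium_rhs(initial_state(p), phi = NaN, tauw = 0, p = p),
               "non-finite flux")
})

test_that("trajectory serialization round-trips", {
  p <- calcium_params()
  tr <- simulate_calcium(p, constant_stimulus(1, 0.3, t_end = 10),
                         t_end = 10)
  path <- tempfile(fileext = ".csv")
  write_calcium_trajectory(tr, path)
  back <- read.csv(path)
  expect_equal(back$C, tr$C)
  expect_equal(nrow(back), nrow(tr))
})
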