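test_that("mean velocity and effective diffusivity follow the channel model", {
  g <- wide_channel_geometry()
  prog <- flow_program(1.5e-10, flow_steady(1.5e-10))
  u <- mean_velocity(prog, g, 0)
  expect_equal(u, 3e-10 / (g$H * g$W))

  D <- 5e-10
  de_ta <- effective_diffusivity(u, g, D, form = "taylor_aris")
  de_pp <- effective_diffusivity(u, g, D, form = "plane_poiseuille")
  de_mo <- effective_diffusivity(u, g, D, form = "molecular")
  # printed dispersion formula: the width factors cancel algebraically,
  # leaving D * (1 + Pe_H^2 / 210)
  expect_equal(de_ta, D * (1 + (u * g$H / D)^2 / 210))
  expect_equal(de_pp, D * (1 + 2 * (u * g$H / D)^2 / 105))
  expect_equal(de_mo, D)
  expect_gt(de_ta, D)
  # zero flow: no dispersion enhancement
  expect_equal(effective_diffusivity(0, g, D), D)
})

test_that("inlet profile is a truncated linear ramp over the ATP stream", {
  W <- 1e-3
  x <- seq(0, W, length.out = 11)
  phi <- inlet_profile(x, eps = 0.5, phi0 = 10, W = W)
  expect_equal(phi[1], 10)
  expect_equal(phi[3], 6)                # x = 2e-4: 10 * (1 - 0.2/0.5)
  expect_true(all(phi[x > 0.5e-3] == 0)) # perfusion side carries no ATP
  expect_true(all(diff(phi) <= 0))
})

test_that("explicit step restriction is enforced with a helpful message", {
  g <- wide_channel_geometry()
  grid <- transport_grid(32, 64, t_end = 1, dt = 0.5)
  expect_error(
    simulate_transport(g, transport_params(),
                       flow_program(1.5e-10, flow_steady(1.5e-10)), grid),
    "stability")
})

test_that("steady fill-in satisfies the maximum principle and settles near 4 s", {
  f <- fx_steady_field()
  expect_gte(f$phi_range[1], 0)
  expect_lte(f$phi_range[2], 10 * (1 + 1e-12))
  ts <- settling_time(f)
  expect_false(is.na(ts))
  expect_gt(ts, 1)
  expect_lt(ts, 8)
})

test_that("steady state preserves the inlet gradient to the outlet", {
  f <- fx_steady_field()
  g <- f$geom
  stations <- g$W * c(1, 2, 3, 4) / 5
  atp <- vapply(stations,
                function(x) tail(sample_wall_stimulus(f, x)$atp, 1L),
                numeric(1))
  # near-linear inlet ramp phi0*(1 - x/(eps*W)) survives transit: ~6, 2, 0, 0
  expect_equal(atp[1], 6, tolerance = 0.05)
  expect_equal(atp[2], 2, tolerance = 0.10)
  expect_lt(atp[4], 0.01)
  expect_true(all(diff(atp) < 1e-9))  # non-increasing across the width
})

test_that("transport solution converges under grid refinement", {
  f2 <- fx_steady_field()             # 64 x 256
  g <- f2$geom
  f1 <- simulate_transport(g, transport_params(),
                           flow_program(1.5e-10, flow_steady(1.5e-10)),
                           transport_grid(32, 128, t_end = 8))
  v1 <- tail(sample_wall_stimulus(f1, g$W / 5)$atp, 1L)
  v2 <- tail(sample_wall_stimulus(f2, g$W / 5)$atp, 1L)
  expect_lt(abs(v1 - v2) / v2, 0.01)
})

test_that("the transport solver is deterministic", {
  g <- wide_channel_geometry()
  prog <- flow_program(1.5e-10, flow_sinusoidal(1.5e-10, 0.5, 0.1))
  run <- function() {
    f <- simulate_transport(g, transport_params(), prog,
                            transport_grid(24, 48, t_end = 5))
    sample_wall_stimulus(f, g$W / 5)
  }
  a <- run(); b <- run()
  expect_identical(a$atp, b$atp)
  expect_identical(a$shear, b$shear)
})

test_that("sampled wall stimulus carries the drive frequency and shear", {
  f <- fx_sine_field()
  g <- f$geom
  stim <- sample_wall_stimulus(f, g$W / 5)
  expect_s3_class(stim, "wall_stimulus")
  m <- signal_metrics(stim$t, stim$atp)
  expect_lt(abs(m$dominant_frequency - 0.1), 1 / 45)
  expect_gt(m$peak_to_peak, 0.5)
  # shear follows the total flow: tau = 6*eta*(Q1+Q2(t))/(W*H^2)
  tau_expect <- wall_shear_stress(f$prog, g, 1e-3, stim$t)
  expect_equal(stim$shear, tau_expect, tolerance = 1e-10)
})

test_that("wall stimulus constructor validates and serializes", {
  t <- seq(0, 1, by = 0.1)
  st <- wall_stimulus(t, atp = rep(1, 11), shear = 0.3)
  expect_length(st$shear, 11)
  expect_error(wall_stimulus(t, atp = rep(-1, 11), shear = 0.3), "nonnegative")
  path <- tempfile(fileext = ".csv")
  write_wall_stimulus(st, path)
  back <- read.csv(path)
  expect_equal(back$atp_uM, st$atp)
  expect_equal(back$shear_Pa, st$shear)
})

test_that("field snapshots serialize with a sidecar", {
  f <- fx_steady_field()
  d <- file.path(tempdir(), "snaps")
  write_field_snapshots(f, d)
  expect_true(length(list.files(d, pattern = "\\.csv$")) >= 1L)
  expect_true(file.exists(file.path(d, "field_grid.json")))
})
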