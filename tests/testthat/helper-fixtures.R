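# Shared, lazily computed fixtures.  The expensive simulations (transport
# fields, the coupled chip runs) are computed once per test session and
# reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# steady equal-flow fill-in of the wide channel (settling-time protocol)
fx_steady_field <- function() fixture("steady_field", function() {
  simulate_transport(wide_channel_geometry(), transport_params(),
                     flow_program(1.5e-10, flow_steady(1.5e-10)),
                     transport_grid(64, 256, t_end = 8))
})

# sinusoidal perfusion (mean 1.5e-10 m^3/s, delta 0.5, 0.1 Hz), 60 s
fx_sine_field <- function() fixture("sine_field", function() {
  simulate_transport(wide_channel_geometry(), transport_params(),
                     flow_program(1.5e-10, flow_sinusoidal(1.5e-10, 0.5, 0.1)),
                     transport_grid(64, 256, t_end = 60))
})

# calcium validation protocol: sinusoidal ATP peaking at 10 uM at 0.1 Hz,
# constant 0.3 Pa shear, 600 s record
fx_validation_traj <- function() fixture("validation_traj", function() {
  stim <- sinusoidal_stimulus(5, 1, 0.1, shear = 0.3, t_end = 600)
  simulate_calcium(calcium_params(), stim, t_end = 600)
})

# coupled chip experiment at pulsatile frequency fq, 600 s record
fx_chip <- function(fq) fixture(sprintf("chip_%g", fq), function() {
  cfg <- experiment_config(
    prog = flow_program(1.5e-10, flow_sinusoidal(1.5e-10, 0.5, fq)),
    grid = transport_grid(48, 192, t_end = 600),
    t_end = 600)
  run_chip_experiment(cfg)
})
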