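# Example configuration for the calchip CLI (the published operating point
# of the chip).
#
#   Rscript calchip-cli.R chip --config chip-example.yml --out out/
#
# The 600 s horizon (~1 min runtime) lets the response-mode classifier see
# past the initial Ca2+ transient; short records classify every station as
# transient-dominated.

geometry:
  assignment: wide        # wide (Hele-Shaw) | printed
transport:
  D: 5.0e-10              # ATP diffusivity, m^2/s
  eta: 1.0e-3             # viscosity, Pa s
  phi0: 10                # ATP stock concentration, uM
flow:
  Q1: 1.5e-10             # steady ATP-stream inlet, m^3/s
  Q2:                     # perfusion-stream waveform
    kind: sinusoidal      # steady | sinusoidal | sampled | cell
    mean: 1.5e-10
    delta: 0.5
    freq: 0.1
grid:
  nx: 48
  nz: 192
t_end: 600

# the calcium subcommand additionally reads a stimulus block, e.g.
stimulus:
  kind: sinusoidal        # constant | sinusoidal | file
  mean_atp: 5             # uM
  delta: 1
  freq: 0.1               # Hz
  shear: 0.3              # Pa
  t_end: 600

# the sweep subcommand reads
sweep:
  fQ: [0.05, 0.1, 0.2, 0.5]
  delta: 0.5
  grid_nx: 48
  grid_nz: 192
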