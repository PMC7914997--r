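#' Chip experiment configuration
#'
#' Bundles everything one run of the coupled simulator needs: channel
#' geometry, transport parameters, flow program, finite-difference grid,
#' the observation points on the channel floor (default the four stations
#' `x = W * {1, 2, 3, 4} / 5` at the outlet `z = L`), the calcium parameter
#' profile and the simulation horizon.
#'
#' @param geom a [channel_geometry()]; the default is the wide-channel
#'   (Hele-Shaw) assignment under which the channel preserves the inlet
#'   gradient to the outlet
#' @param params a [transport_params()]
#' @param prog a [flow_program()]; default steady ATP stream
#'   `Q1 = 1.5e-10` m^3/s co-flowing with the sinusoidal perfusion stream
#'   `Q2(t) = 1.5e-10 (1 + 0.5 sin(2 pi 0.1 t))` m^3/s
#' @param grid a [transport_grid()]; default `64 x 256` nodes
#' @param obs_x transverse observation positions (m)
#' @param z_obs axial observation position (m)
#' @param cal a [calcium_params()] profile
#' @param t_end simulation horizon (s) for both transport and calcium
#' @param outdir optional output directory for run artifacts
#' @return an object of class `experiment_config`
#' @export
experiment_config <- function(geom = wide_channel_geometry(),
                              params = transport_params(),
                              prog = flow_program(
                                1.5e-10,
                                flow_sinusoidal(1.5e-10, 0.5, 0.1)),
                              grid = transport_grid(64, 256, t_end = t_end),
                              obs_x = geom$W * c(1, 2, 3, 4) / 5,
                              z_obs = geom$L,
                              cal = calcium_params(),
                              t_end = 300,
                              outdir = NULL) {
  stopifnot(inherits(geom, "channel_geometry"),
            inherits(params, "transport_params"),
            inherits(prog, "flow_program"),
            inherits(grid, "transport_grid"),
            inherits(cal, "calcium_params"))
  if (any(obs_x < 0 | obs_x > geom$W) || z_obs < 0 || z_obs > geom$L)
    stop("observation points must lie inside the channel")
  structure(list(geom = geom, params = params, prog = prog, grid = grid,
                 obs_x = obs_x, z_obs = z_obs, cal = cal,
                 t_end = t_end, outdir = outdir),
            class = "experiment_config")
}

#' Run a coupled chip experiment
#'
#' Runs the transport solver once over the configured horizon, samples the
#' wall stimulus at every observation point, integrates the calcium model
#' per point (one-way coupling: the cells do not release ATP back into the
#' channel), and summarizes each trace with [signal_metrics()] and
#' [classify_response()].  If `cfg$outdir` is set, all series are written
#' as CSV together with a JSON run manifest listing each file with its
#' MD5 checksum; identical configurations reproduce identical files.
#'
#' @param cfg an [experiment_config()]
#' @param verbose print per-stage progress
#' @return a list with the `concentration_field`, and per observation point
#'   the `wall_stimulus`, `calcium_trajectory`, metric summaries and
#'   response classification
#' @export
run_chip_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  say("transport: %d x %d grid to t = %g s", cfg$grid$nx, cfg$grid$nz, cfg$t_end)
  field <- simulate_transport(cfg$geom, cfg$params, cfg$prog, cfg$grid,
                              obs_x = cfg$obs_x, z_obs = cfg$z_obs)
  say("transport done (%.1f s elapsed)", proc.time()[["elapsed"]] - t0)
  points <- lapply(seq_along(cfg$obs_x), function(k) {
    x <- cfg$obs_x[k]
    stim <- sample_wall_stimulus(field, x)
    say("calcium at x = %.3g m", x)
    traj <- tryCatch(
      simulate_calcium(cfg$cal, stim, t_end = cfg$t_end),
      error = function(e) stop("calcium stage failed at observation point x = ",
                               signif(x, 4), " m: ", conditionMessage(e)))
    list(x = x,
         stimulus = stim,
         trajectory = traj,
         metrics = list(atp = signal_metrics(stim$t, stim$atp),
                        shear = signal_metrics(stim$t, stim$shear),
                        C = signal_metrics(traj$t, traj$C)),
         response = classify_response(traj))
  })
  names(points) <- sprintf("x=%.4g", cfg$obs_x)
  out <- list(field = field, points = points, config = cfg)
  if (!is.null(cfg$outdir)) out$manifest <- write_run_artifacts(out, cfg$outdir)
  say("experiment done (%.1f s elapsed)", proc.time()[["elapsed"]] - t0)
  out
}

write_run_artifacts <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(run$points)) {
    pt <- run$points[[nm]]
    f1 <- file.path(outdir, sprintf("stimulus_%s.csv", gsub("[^0-9a-zA-Z=._-]", "", nm)))
    write_wall_stimulus(pt$stimulus, f1)
    f2 <- file.path(outdir, sprintf("calcium_%s.csv", gsub("[^0-9a-zA-Z=._-]", "", nm)))
    write_calcium_trajectory(pt$trajectory, f2)
    files <- c(files, f1, f2)
  }
  pf <- file.path(outdir, "calcium_params.txt")
  write_calcium_params(run$config$cal, pf)
  files <- c(files, pf)
  summary <- lapply(run$points, function(pt)
    c(list(x_m = pt$x), pt$response,
      atp_mean_uM = pt$metrics$atp$mean,
      atp_p2p_uM = pt$metrics$atp$peak_to_peak))
  sf <- file.path(outdir, "metrics.json")
  jsonlite::write_json(summary, sf, auto_unbox = TRUE, digits = NA,
                       na = "null")
  files <- c(files, sf)
  cfg <- run$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("calchip")),
    config = list(
      geometry = unclass(cfg$geom),
      transport = unclass(cfg$params),
      Q1 = cfg$prog$Q1, Q2 = unclass(cfg$prog$Q2),
      grid = unclass(cfg$grid),
      obs_x = cfg$obs_x, z_obs = cfg$z_obs,
      t_end = cfg$t_end,
      calcium_profile = cfg$cal$profile),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       na = "null")
  manifest
}

#' Frequency/amplitude sweep of the channel's signal transmission
#'
#' Characterizes the channel as a chemical-signal filter: for each
#' combination of pulsatile frequency `fQ` and amplitude fraction `delta`
#' of the perfusion stream, runs the transport solver to the periodic
#' steady state (the analysis window keeps at least `periods` full drive
#' periods after discarding the settling transient) and records the
#' peak-to-peak ATP amplitude at the observation point.  The channel acts
#' as a low-pass filter: at fixed `delta` the amplitude decays with `fQ`,
#' and at fixed `fQ` it grows with `delta`.
#'
#' @param fQ vector of pulsatile frequencies (Hz)
#' @param delta vector of amplitude fractions in `[0, 1]`
#' @param geom,params channel geometry and transport parameters
#' @param Q1,Q2_mean inlet flow rates (m^3/s)
#' @param point transverse observation position (m), default `W/5` at `z = L`
#' @param grid_nx,grid_nz grid resolution
#' @param settle_t settling allowance before the analysis window (s)
#' @param periods drive periods in the analysis window
#' @return a data frame `(fQ, delta, p2p_atp, mean_atp, settled)` with class
#'   `sweep_result`.  `settled` certifies the periodic steady state: the last
#'   full drive period of the observed ATP series repeats the preceding one
#'   to within 0.1 % of `phi0` (for `delta = 0`, the last second repeats the
#'   preceding second).  A non-repeating run is flagged `settled = FALSE`
#'   rather than failing the sweep
#' @export
frequency_sweep <- function(fQ, delta,
                            geom = wide_channel_geometry(),
                            params = transport_params(),
                            Q1 = 1.5e-10, Q2_mean = 1.5e-10,
                            point = geom$W / 5,
                            grid_nx = 48, grid_nz = 192,
                            settle_t = 6, periods = 3) {
  cells <- expand.grid(fQ = fQ, delta = delta, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(r) {
    f <- cells$fQ[r]; d <- cells$delta[r]
    prog <- if (d == 0) flow_program(Q1, flow_steady(Q2_mean)) else
      flow_program(Q1, flow_sinusoidal(Q2_mean, d, f))
    t_end <- settle_t + (periods + 1) / f
    grid <- transport_grid(grid_nx, grid_nz, t_end = t_end)
    field <- simulate_transport(geom, params, prog, grid, obs_x = point)
    stim <- sample_wall_stimulus(field, point)
    win <- stim$t >= settle_t + 1 / f
    # periodic steady state: the last drive period repeats the previous one
    # (compared at an exact lag of one period, by linear interpolation)
    per <- if (d == 0) 1 else 1 / f
    last <- stim$t >= max(stim$t) - per
    rep_err <- if (min(stim$t) <= max(stim$t) - 2 * per)
      max(abs(stim$atp[last] -
                stats::approx(stim$t, stim$atp, xout = stim$t[last] - per)$y))
    else NA_real_
    c(p2p_atp = diff(range(stim$atp[win])),
      mean_atp = mean(stim$atp[win]),
      settled = as.numeric(!is.na(rep_err) && rep_err < 1e-3 * params$phi0))
  })
  out <- cbind(cells, do.call(rbind, res))
  out$settled <- out$settled > 0
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Classify a calcium response
#'
#' Labels a trajectory as `"oscillatory"` when its post-transient
#' peak-to-peak excursion exceeds `ripple_frac` of the trajectory's global
#' range and a dominant oscillation frequency is detectable, and
#' `"unimodal"` otherwise (a single sustained rise with at most weak
#' ripple).  These are the two response regimes of endothelial Ca2+ under
#' combined ATP/shear stimulation: high mean ATP drives an acute unimodal
#' transient, while low ATP with pulsatile drive yields entrained
#' oscillations.
#'
#' @param traj a `calcium_trajectory` (or any data frame with `t` and `C`)
#' @param transient_frac fraction of the record treated as transient
#' @param ripple_frac oscillation threshold as a fraction of the global range
#' @return a list: `mode` (`"unimodal"` or `"oscillatory"`),
#'   `oscillation_amplitude` (post-transient peak-to-peak of `C`),
#'   `dominant_frequency` (Hz or `NA`), `first_peak_time` (s), and the
#'   thresholds used
#' @export
classify_response <- function(traj, transient_frac = 0.25, ripple_frac = 0.1) {
  stopifnot(all(c("t", "C") %in% names(traj)))
  if (nrow(as.data.frame(traj)) < 16L)
    stop("trajectory too short to classify")
  m <- signal_metrics(traj$t, traj$C, transient_frac = transient_frac)
  rng <- diff(range(traj$C))
  oscillatory <- rng > 0 && m$peak_to_peak > ripple_frac * rng &&
    !is.na(m$dominant_frequency)
  list(mode = if (oscillatory) "oscillatory" else "unimodal",
       oscillation_amplitude = m$peak_to_peak,
       dominant_frequency = m$dominant_frequency,
       first_peak_time = m$first_peak_time,
       transient_frac = transient_frac, ripple_frac = ripple_frac)
}

#' CELL-shaped sample waveform
#'
#' A piecewise-linear perfusion waveform tracing block letters ("CELL"),
#' demonstrating that an arbitrary drawn waveform can drive the generator.
#' Its sharp transitions carry high-frequency content that the channel's
#' low-pass transmission visibly attenuates.  One letter cycle spans
#' `period` seconds; the waveform is tiled to cover `[0, t_end]`.
#'
#' @param mean mean flow rate (m^3/s)
#' @param amplitude relative excursion of the letter strokes
#' @param period duration of one CELL cycle (s)
#' @param t_end total duration (s)
#' @return a [flow_sampled()] waveform
#' @export
cell_waveform <- function(mean = 1.5e-10, amplitude = 0.5, period = 20,
                          t_end = period) {
  # one cycle: four block letters drawn as high/low strokes, unit time 0..1
  u <- c(0, .02, .04, .20, .22, .24,            # C: rise, plateau, drop
         .26, .28, .40, .42, .46, .48,          # E
         .52, .54, .66, .68, .72, .74,          # L
         .78, .80, .92, .94, .98, 1)
  v <- c(0, 1, 1, 1, 0, 0,
         1, 1, 1, 0, 0, 0,
         1, 1, .4, .4, 0, 0,
         1, 1, .4, .4, 0, 0)
  ncyc <- max(1L, ceiling(t_end / period))
  tt <- as.vector(outer(u * period, (seq_len(ncyc) - 1L) * period, `+`))
  vv <- rep(v, ncyc)
  keep <- !duplicated(tt)
  flow_sampled(tt[keep], mean * (1 + amplitude * (2 * vv[keep] - 1)))
}
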