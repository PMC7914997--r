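#' Transport parameters
#'
#' Fluid and solute parameters of the extracellular ATP transport model.
#' Defaults are the published chip operating values: molecular diffusivity
#' of ATP `D = 5e-10` m^2/s, viscosity `eta = 1e-3` Pa s, ATP stock
#' concentration `phi0 = 10` uM.
#'
#' @param D molecular diffusivity of ATP (m^2/s)
#' @param eta fluid viscosity (Pa s)
#' @param phi0 inlet ATP stock concentration (uM)
#' @return an object of class `transport_params`
#' @export
transport_params <- function(D = 5e-10, eta = 1e-3, phi0 = 10) {
  stopifnot(is.numeric(D), is.numeric(eta), is.numeric(phi0))
  if (D <= 0 || eta <= 0 || phi0 < 0)
    stop("D and eta must be positive; phi0 nonnegative")
  structure(list(D = D, eta = eta, phi0 = phi0), class = "transport_params")
}

#' Finite-difference grid
#'
#' Grid for [simulate_transport()].  `nx` transverse and `nz` axial nodes
#' (both at least 16), simulation horizon `t_end`, time step `dt` (if
#' `NULL`, chosen automatically from the explicit-scheme stability bound
#' with a safety factor) and output cadence `dt_out` at which observation
#' series, the settling monitor and the field extrema cadence are recorded.
#'
#' @param nx transverse nodes (>= 16)
#' @param nz axial nodes (>= 16)
#' @param t_end simulation horizon (s)
#' @param dt time step (s) or `NULL` for automatic selection; a supplied
#'   value violating the stability bound is refused at solve time with the
#'   computed bound
#' @param dt_out output-series cadence (s); coerced to a multiple of `dt`
#' @return an object of class `transport_grid`
#' @export
transport_grid <- function(nx = 64, nz = 256, t_end, dt = NULL, dt_out = 0.02) {
  stopifnot(is.numeric(nx), is.numeric(nz), is.numeric(t_end))
  nx <- as.integer(nx); nz <- as.integer(nz)
  if (nx < 16L || nz < 16L) stop("nx and nz must be at least 16")
  if (t_end <= 0) stop("t_end must be positive")
  if (!is.null(dt) && (!is.numeric(dt) || dt <= 0)) stop("dt must be positive")
  if (dt_out <= 0) stop("dt_out must be positive")
  structure(list(nx = nx, nz = nz, t_end = t_end, dt = dt, dt_out = dt_out),
            class = "transport_grid")
}

#' Mean axial velocity
#'
#' Cross-section-averaged velocity `u(t) = Q(t) / (H * W)` of the plane
#' Poiseuille flow in the main channel.
#'
#' @inheritParams total_flow
#' @param geom a [channel_geometry()]
#' @return numeric vector of velocities (m/s)
#' @export
mean_velocity <- function(prog, geom, t) {
  stopifnot(inherits(geom, "channel_geometry"))
  total_flow(prog, t) / (geom$H * geom$W)
}

#' Effective (Taylor-Aris) axial diffusivity
#'
#' Shear flow between the channel's top and bottom walls disperses the
#' depth-averaged solute axially.  With the Peclet number
#' `Pe = ubar * W / D`, the default form is
#' `Deff = D * (1 + Pe^2 / 210 * (H / W)^2)`; the width factors cancel, so
#' this equals `D * (1 + Pe_H^2 / 210)` with `Pe_H = ubar * H / D` and is
#' governed by the height (the averaging direction) alone.  The classic
#' plane-Poiseuille dispersion coefficient `D * (1 + 2 * Pe_H^2 / 105)` is
#' available as `form = "plane_poiseuille"`, and `form = "molecular"`
#' disables the enhancement (useful for advection-dominated checks).
#' `Deff` is evaluated per time step from the instantaneous `ubar(t)`
#' (quasi-steady dispersion).
#'
#' @param ubar mean axial velocity (m/s), may be a vector
#' @param geom a [channel_geometry()]
#' @param D molecular diffusivity (m^2/s)
#' @param form dispersion formula variant
#' @return effective diffusivity (m^2/s), `>= D`
#' @export
effective_diffusivity <- function(ubar, geom, D,
                                  form = c("taylor_aris", "plane_poiseuille",
                                           "molecular")) {
  form <- match.arg(form)
  stopifnot(inherits(geom, "channel_geometry"), all(ubar >= 0), D > 0)
  switch(form,
    taylor_aris = {
      Pe <- ubar * geom$W / D
      D * (1 + Pe^2 / 210 * (geom$H / geom$W)^2)
    },
    plane_poiseuille = {
      PeH <- ubar * geom$H / D
      D * (1 + 2 * PeH^2 / 105)
    },
    molecular = rep_len(D, length(ubar)))
}

#' Inlet concentration profile
#'
#' The gradient-generator network delivers a linear ATP profile across the
#' ATP stream at the channel entrance: `phi0 * (1 - x / (eps * W))` for
#' `0 <= x <= eps * W`, and 0 across the perfusion stream
#' (`eps * W < x <= W`), continuous at the stream interface.  With
#' `eps = 0` the whole inlet is perfusion solution and the profile is 0.
#'
#' @param x transverse position(s) in `[0, W]` (m)
#' @param eps ATP stream-width fraction in `[0, 1]`
#' @param phi0 stock concentration (uM)
#' @param W channel width (m)
#' @return concentrations (uM)
#' @export
#' @examples
#' inlet_profile(c(0, 1e-5, 2.5e-5, 4e-5), eps = 0.5, phi0 = 10, W = 5e-5)
inlet_profile <- function(x, eps, phi0, W) {
  stopifnot(all(x >= -1e-15), all(x <= W * (1 + 1e-12)),
            eps >= 0, eps <= 1)
  if (eps == 0) return(numeric(length(x)) * 0)
  v <- phi0 * (1 - x / (eps * W))
  v[x > eps * W] <- 0
  pmax(v, 0)
}

## stability bound of the explicit upwind/central scheme, using the max over
## the horizon of u(t) and Deff(t)
stability_bound <- function(geom, params, prog, grid, deff_form) {
  dx <- geom$W / (grid$nx - 1L)
  dz <- geom$L / (grid$nz - 1L)
  tt <- seq(0, grid$t_end, length.out = 2001L)
  u <- mean_velocity(prog, geom, tt)
  de <- effective_diffusivity(u, geom, params$D, form = deff_form)
  1 / (max(u) / dz + 2 * params$D / dx^2 + 2 * max(de) / dz^2)
}

#' Solve the depth-averaged ATP transport equation
#'
#' Explicit finite-difference solution of
#' `d(phi)/dt + ubar(t) d(phi)/dz = D d2(phi)/dx2 + Deff(t) d2(phi)/dz2`
#' on `0 <= x <= W`, `0 <= z <= L`, starting from an ATP-free channel.
#' Axial convection is discretized first-order upwind and both diffusion
#' terms second-order central, a sign-preserving combination that honors
#' the discrete maximum principle (at the cost of some numerical axial
#' diffusion).  The inlet Dirichlet row at `z = 0` is re-evaluated every
#' step from the instantaneous stream-width fraction `eps(t)`
#' ([inlet_profile()]); the side walls are no-flux; the far-field
#' zero-gradient condition is truncated at `z = L` with a zero-gradient
#' outflow closure.
#'
#' The time step must satisfy
#' `dt <= 1 / (u_max/dz + 2 D/dx^2 + 2 Deff_max/dz^2)`; an automatic step
#' uses this bound with safety factor `courant`, and a user-supplied step
#' violating it is refused with the computed bound.
#'
#' @param geom a [channel_geometry()]
#' @param params a [transport_params()]
#' @param prog a [flow_program()]
#' @param grid a [transport_grid()]
#' @param obs_x transverse observation positions (m) at which time series
#'   are recorded every `dt_out`; default the four stations
#'   `W * c(1, 2, 3, 4) / 5`
#' @param z_obs axial observation position (m), default the outlet `L`
#' @param snapshot_times times (s) at which full-field snapshots are stored;
#'   default the final time
#' @param deff_form dispersion variant, see [effective_diffusivity()]
#' @param courant safety factor applied to the stability bound when `dt` is
#'   chosen automatically
#' @return an object of class `concentration_field`: observation series
#'   (`$t`, `$series`), field snapshots (`$snapshots`, an `nx x nz x k`
#'   array with `$x`, `$z`, `$snapshot_times`), the extrema attained over
#'   the whole run (`$phi_range`), and the settling monitor (`$settle`, the
#'   per-second maximum field change at each output time)
#' @export
simulate_transport <- function(geom, params, prog, grid,
                               obs_x = geom$W * c(1, 2, 3, 4) / 5,
                               z_obs = geom$L,
                               snapshot_times = grid$t_end,
                               deff_form = "taylor_aris",
                               courant = 0.9) {
  stopifnot(inherits(geom, "channel_geometry"),
            inherits(params, "transport_params"),
            inherits(prog, "flow_program"),
            inherits(grid, "transport_grid"))
  if (any(obs_x < 0 | obs_x > geom$W) || z_obs < 0 || z_obs > geom$L)
    stop("observation point outside the channel")
  dx <- geom$W / (grid$nx - 1L)
  dz <- geom$L / (grid$nz - 1L)
  bound <- stability_bound(geom, params, prog, grid, deff_form)
  if (is.null(grid$dt)) {
    dt0 <- courant * bound
  } else {
    if (grid$dt > bound)
      stop(sprintf(paste0("time step %.3g s violates the explicit stability",
                          " bound %.3g s for this grid and flow program"),
                   grid$dt, bound))
    dt0 <- grid$dt
  }
  # align nsteps with the output cadence so t_out is uniform
  nsteps0 <- max(1L, ceiling(grid$t_end / dt0))
  out_every <- max(1L, ceiling(grid$dt_out / (grid$t_end / nsteps0)))
  nsteps <- out_every * ceiling(nsteps0 / out_every)
  dt <- grid$t_end / nsteps
  dt_out <- out_every * dt

  tk <- (0:nsteps) * dt
  u <- mean_velocity(prog, geom, tk)
  de <- effective_diffusivity(u, geom, params$D, form = deff_form)
  eps <- flow_fraction(prog, tk)

  snap_steps <- sort(unique(pmin(nsteps, pmax(0L, as.integer(
    round(snapshot_times / dt))))))
  # observation interpolation weights (bilinear)
  ox <- pmin(pmax(obs_x / dx, 0), grid$nx - 1L)
  oi <- pmin(as.integer(floor(ox)), grid$nx - 2L)
  wx <- ox - oi
  oz <- pmin(pmax(z_obs / dz, 0), grid$nz - 1L)
  oj <- pmin(as.integer(floor(oz)), grid$nz - 2L)
  wz <- oz - oj
  sec_every <- as.integer(round(1 / dt_out))

  res <- transport_fd_core(grid$nx, grid$nz, dx, dz, dt, u, de, eps,
                           params$D, params$phi0, geom$W,
                           out_every, snap_steps,
                           oi, wx, rep_len(oj, length(oi)),
                           rep_len(wz, length(oi)), sec_every)
  if (res$bad_step >= 0)
    stop(sprintf("numerical failure: non-finite field first detected at step %d (t = %.4g s)",
                 res$bad_step, res$bad_step * dt))
  colnames(res$series) <- sprintf("x=%.4g", obs_x)
  # normalize the trailing-window change to a per-second rate (the window is
  # sec_every output frames, i.e. sec_every * dt_out seconds)
  settle_rate <- if (sec_every > 0L) res$settle / (sec_every * dt_out) else
    rep(NA_real_, length(res$t))
  structure(list(
    x = (0:(grid$nx - 1L)) * dx,
    z = (0:(grid$nz - 1L)) * dz,
    t = res$t,
    series = res$series,
    obs_x = obs_x, z_obs = z_obs,
    snapshots = res$snapshots,
    snapshot_times = snap_steps * dt,
    phi_range = c(res$phimin, res$phimax),
    settle = data.frame(t = res$t, dphi_per_s = settle_rate),
    dt = dt, dt_out = dt_out,
    geom = geom, params = params, prog = prog, grid = grid,
    deff_form = deff_form
  ), class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(paste0("depth-averaged ATP field: %d x %d grid, t in [0, %g] s",
                     " (dt = %.3g s, output every %.3g s)\n"),
              length(x$x), length(x$z), max(x$t), x$dt, x$dt_out))
  cat(sprintf("  field extrema over the run: [%.4g, %.4g] uM\n",
              x$phi_range[1], x$phi_range[2]))
  invisible(x)
}

#' Field settling time
#'
#' First time at which the per-second maximum field change drops below
#' `tol_frac` of the stock concentration (default 0.1 %), i.e. the time the
#' field is considered to have reached steady state after the fill-in
#' transient.
#'
#' @param field a `concentration_field`
#' @param tol_frac threshold as a fraction of `phi0`
#' @return settling time (s), or `NA` if the field has not settled
#' @export
settling_time <- function(field, tol_frac = 0.001) {
  stopifnot(inherits(field, "concentration_field"))
  s <- field$settle
  ok <- which(!is.na(s$dphi_per_s) &
                s$dphi_per_s < tol_frac * field$params$phi0)
  if (!length(ok)) return(NA_real_)
  s$t[ok[1L]]
}

#' Sample the wall stimulus at an observation point
#'
#' Extracts the paired `{ATP(t), tau_w(t)}` stimulus a cell at position
#' `(x_obs, z_obs)` on the channel floor experiences: the ATP series is the
#' depth-averaged concentration bilinearly interpolated at the point, and
#' the shear series is the (floor-uniform) wall shear stress of the flow
#' program.  If the point was among the recorded observation points of the
#' run the stored series is used; otherwise the series is interpolated from
#' the stored field snapshots (which must then cover the run densely).
#'
#' @param field a `concentration_field` from [simulate_transport()]
#' @param x_obs,z_obs observation position (m)
#' @param eta viscosity (Pa s); defaults to the run's transport parameters
#' @return an object of class `wall_stimulus` with components `t`, `atp`
#'   (uM), `shear` (Pa) and `position`
#' @export
sample_wall_stimulus <- function(field, x_obs, z_obs = field$z_obs,
                                 eta = field$params$eta) {
  stopifnot(inherits(field, "concentration_field"))
  geom <- field$geom
  if (x_obs < 0 || x_obs > geom$W || z_obs < 0 || z_obs > geom$L)
    stop("observation position outside the channel")
  hit <- which(abs(field$obs_x - x_obs) <= 1e-12 * geom$W)
  if (length(hit) && abs(z_obs - field$z_obs) <= 1e-12 * geom$L) {
    t <- field$t
    atp <- field$series[, hit[1L]]
  } else {
    if (length(field$snapshot_times) < 2L)
      stop("position was not recorded during the run and too few snapshots ",
           "are stored to interpolate a time series")
    t <- field$snapshot_times
    atp <- vapply(seq_along(t), function(k)
      bilinear_at(field$snapshots[, , k], field$x, field$z, x_obs, z_obs),
      numeric(1L))
  }
  wall_stimulus(t = t, atp = atp,
                shear = wall_shear_stress(field$prog, geom, eta, t),
                position = c(x = x_obs, z = z_obs))
}

bilinear_at <- function(m, x, z, x0, z0) {
  i <- min(max(findInterval(x0, x), 1L), length(x) - 1L)
  j <- min(max(findInterval(z0, z), 1L), length(z) - 1L)
  wx <- (x0 - x[i]) / (x[i + 1L] - x[i])
  wz <- (z0 - z[j]) / (z[j + 1L] - z[j])
  (1 - wx) * ((1 - wz) * m[i, j] + wz * m[i, j + 1L]) +
    wx * ((1 - wz) * m[i + 1L, j] + wz * m[i + 1L, j + 1L])
}

#' Wall stimulus constructor
#'
#' The transport-to-calcium interface: paired ATP concentration and wall
#' shear stress time series on a shared time grid.  Usually produced by
#' [sample_wall_stimulus()]; the constructor is exported so synthetic
#' stimuli (e.g. the validation protocol's sinusoidal ATP with constant
#' shear) can be fed to [simulate_calcium()] directly.
#'
#' @param t sample times (s)
#' @param atp ATP concentration (uM), nonnegative
#' @param shear wall shear stress (Pa)
#' @param position optional `(x, z)` position label (m)
#' @return an object of class `wall_stimulus`
#' @export
wall_stimulus <- function(t, atp, shear, position = c(x = NA_real_, z = NA_real_)) {
  stopifnot(is.numeric(t), is.numeric(atp), is.numeric(shear),
            length(t) == length(atp))
  if (length(shear) == 1L) shear <- rep_len(shear, length(t))
  stopifnot(length(shear) == length(t))
  if (any(atp < -1e-9)) stop("ATP concentrations must be nonnegative")
  structure(list(t = as.numeric(t), atp = pmax(as.numeric(atp), 0),
                 shear = as.numeric(shear), position = position),
            class = "wall_stimulus")
}

#' @export
as.data.frame.wall_stimulus <- function(x, ...) {
  data.frame(t = x$t, atp_uM = x$atp, shear_Pa = x$shear)
}

#' Write transport artifacts
#'
#' `write_wall_stimulus()` writes a 3-column CSV `(t, atp_uM, shear_Pa)`.
#' `write_field_snapshots()` writes one CSV matrix per stored snapshot time
#' plus a JSON sidecar with the grid metadata.
#'
#' @param stim a `wall_stimulus`
#' @param path output CSV path
#' @return the written path(s), invisibly
#' @export
write_wall_stimulus <- function(stim, path) {
  stopifnot(inherits(stim, "wall_stimulus"))
  utils::write.csv(as.data.frame(stim), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wall_stimulus
#' @param field a `concentration_field`
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @export
write_field_snapshots <- function(field, dir, prefix = "field") {
  stopifnot(inherits(field, "concentration_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (k in seq_along(field$snapshot_times)) {
    p <- file.path(dir, sprintf("%s_t%08.3fs.csv", prefix,
                                field$snapshot_times[k]))
    utils::write.table(field$snapshots[, , k], p, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- file.path(dir, paste0(prefix, "_grid.json"))
  jsonlite::write_json(list(x_m = field$x, z_m = field$z,
                            snapshot_times_s = field$snapshot_times,
                            units = "uM", layout = "rows are x, columns are z"),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}
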