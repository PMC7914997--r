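#' Calcium fluxes and channel gating
#'
#' Elementary fluxes (all in uM/s) and gating probabilities of the
#' endothelial Ca2+ model.  States: `C` cytosolic free Ca2+, `Cs` store
#' Ca2+, `Cb` buffered Ca2+, `i` IP3 concentration (all uM); `phi` is the
#' wall ATP concentration (uM) and `tauw` the wall shear stress (Pa).
#'
#' \describe{
#'   \item{`q_rel`}{CICR store release
#'     `k3 * C/(KCICR + C) * (i/(i + K2))^3 * Cs`: gated by cytosolic Ca2+
#'     (positive feedback) and cooperatively by three IP3 molecules, and
#'     proportional to the store load.}
#'   \item{`q_res`}{restore minus leak
#'     `k4 * (C/(K3 + C))^2 - k5 * Cs^2`: a SERCA-type pump with Hill
#'     coefficient 2 against a store leak quadratic in the store load.}
#'   \item{`q_out`}{saturable clearance `k8 * C/(K4 + C)`.}
#'   \item{`q_buf`}{net buffering `k6 * C * (BT - Cb) - k7 * Cb`.}
#'   \item{`q_in_p2x4`}{ATP-gated influx
#'     `kp2x4 * (phi/(Kp2x4 + phi))^3 * (Cex - C)`.}
#'   \item{`q_in_trp`}{mechanosensitive influx
#'     `qmax * p1 * p2 * p3 * (Cs_rest - Cs) * (Cex - C)`, with store
#'     feedback through the depletion `Cs_rest - Cs`.}
#'   \item{`gate_p1`}{shear-gated open probability
#'     `1 / (1 + alpha * exp(-fe * W(tauw) / (gating_scale * kB * Temp * N)))`;
#'     `1/(1 + alpha)` with no load, approaching 1 at large shear.}
#'   \item{`gate_p2`}{IP3-dependent factor
#'     `b1 * (1 + a1 * i^3 / (Ki + i^3))`, in `[b1, b1 * (1 + a1)]`.}
#'   \item{`gate_p3`}{Ca2+-dependent decay `c1 + c2 * exp(-c3 * C)`.}
#'   \item{`strain_energy`}{membrane strain energy density (J/m^2)
#'     `W(tauw) = (A + B - 4 delta_m)^2 / (A + B)` with
#'     `A = eps_m * tauw * l_cell` (the membrane's share of the applied
#'     load, per unit depth) and `B = sqrt(16 delta_m^2 + A^2)`; `W(0) = 0`
#'     and `W` grows monotonically with shear.  A negative `tauw` is used
#'     in magnitude (oscillatory flow reverses direction; the stored energy
#'     depends on the load magnitude only).}
#'   \item{`ip3_rhs`}{IP3 balance
#'     `k1 * phi/(Kc + phi) * C/(K1 + C) - k2 * i`.}
#' }
#'
#' @param C,Cs,Cb,i state components (uM)
#' @param phi wall ATP concentration (uM)
#' @param tauw wall shear stress (Pa)
#' @param p a [calcium_params()] object
#' @return flux (uM/s), probability, or energy density (J/m^2)
#' @name calcium_fluxes
NULL

#' @rdname calcium_fluxes
#' @export
q_rel <- function(C, Cs, i, p) {
  p$k3 * (C / (p$KCICR + C)) * (i / (i + p$K2))^3 * Cs
}

#' @rdname calcium_fluxes
#' @export
q_res <- function(C, Cs, p) {
  p$k4 * (C / (p$K3 + C))^2 - p$k5 * Cs^2
}

#' @rdname calcium_fluxes
#' @export
q_out <- function(C, p) {
  p$k8 * C / (p$K4 + C)
}

#' @rdname calcium_fluxes
#' @export
q_buf <- function(C, Cb, p) {
  p$k6 * C * (p$BT - Cb) - p$k7 * Cb
}

#' @rdname calcium_fluxes
#' @export
strain_energy <- function(tauw, p) {
  if (any(tauw < 0)) {
    message("strain_energy: negative shear stress supplied; using |tauw| ",
            "(membrane strain energy depends on the load magnitude)")
    tauw <- abs(tauw)
  }
  A <- p$eps_m * tauw * p$l_cell
  B <- sqrt(16 * p$delta_m^2 + A^2)
  (A + B - 4 * p$delta_m)^2 / (A + B)
}

#' @rdname calcium_fluxes
#' @export
gate_p1 <- function(tauw, p) {
  w <- strain_energy(tauw, p)
  1 / (1 + p$alpha * exp(-p$fe * w / (p$gating_scale * p$kB * p$Temp * p$N)))
}

#' @rdname calcium_fluxes
#' @export
gate_p2 <- function(i, p) {
  p$b1 * (1 + p$a1 * i^3 / (p$Ki + i^3))
}

#' @rdname calcium_fluxes
#' @export
gate_p3 <- function(C, p) {
  p$c1 + p$c2 * exp(-p$c3 * C)
}

#' @rdname calcium_fluxes
#' @export
q_in_p2x4 <- function(phi, C, p) {
  p$kp2x4 * (phi / (p$Kp2x4 + phi))^3 * (p$Cex - C)
}

#' @rdname calcium_fluxes
#' @export
q_in_trp <- function(C, Cs, i, tauw, p) {
  p$qmax * gate_p1(tauw, p) * gate_p2(i, p) * gate_p3(C, p) *
    (p$Cs_rest - Cs) * (p$Cex - C)
}

#' @rdname calcium_fluxes
#' @export
ip3_rhs <- function(i, C, phi, p) {
  p$k1 * (phi / (p$Kc + phi)) * (C / (p$K1 + C)) - p$k2 * i
}

#' Resting state
#'
#' The unstimulated initial condition: `C = C0`; the buffered load at its
#' binding equilibrium `Cb0 = k6 C0 BT / (k7 + k6 C0)`; the store load at
#' the restore/leak balance `Cs0 = sqrt(k4/k5) * C0 / (K3 + C0)`; and IP3 at
#' its zero-ATP steady state `i = 0`.  With the `qin_pass` calibration of
#' [calcium_params()], this state is an exact equilibrium of the full
#' system under zero stimulus.
#'
#' @param p a [calcium_params()] object
#' @return named numeric vector `c(C, Cs, Cb, i)` (uM)
#' @export
initial_state <- function(p) {
  stopifnot(inherits(p, "calcium_params"))
  c(C = p$C0, Cs = p$Cs_rest, Cb = p$Cb_rest, i = 0)
}

#' Full model right-hand side
#'
#' Assembles the state derivatives
#' `dC/dt = q_rel - q_res + q_in - q_out - q_buf`,
#' `dCs/dt = Vc_over_Vs * (q_res - q_rel)`, `dCb/dt = q_buf`,
#' `di/dt = ip3_rhs`, with total influx
#' `q_in = q_in_p2x4 + q_in_trp + qin_pass`.
#'
#' @param state named numeric vector `c(C, Cs, Cb, i)`
#' @param phi wall ATP concentration (uM)
#' @param tauw wall shear stress (Pa)
#' @param p a [calcium_params()] object
#' @return list with `deriv` (named derivative vector) and `fluxes`
#'   (named vector of `qrel, qres, qin, qout, qbuf`)
#' @export
calcium_rhs <- function(state, phi, tauw, p) {
  C <- state[["C"]]; Cs <- state[["Cs"]]; Cb <- state[["Cb"]]; i <- state[["i"]]
  fl <- c(qrel = q_rel(C, Cs, i, p),
          qres = q_res(C, Cs, p),
          qin = q_in_p2x4(phi, C, p) + q_in_trp(C, Cs, i, tauw, p) + p$qin_pass,
          qout = q_out(C, p),
          qbuf = q_buf(C, Cb, p))
  if (any(!is.finite(fl))) {
    bad <- names(fl)[!is.finite(fl)]
    stop("non-finite flux term(s): ", paste(bad, collapse = ", "))
  }
  list(deriv = c(C = fl[["qrel"]] - fl[["qres"]] + fl[["qin"]] -
                   fl[["qout"]] - fl[["qbuf"]],
                 Cs = p$Vc_over_Vs * (fl[["qres"]] - fl[["qrel"]]),
                 Cb = fl[["qbuf"]],
                 i = ip3_rhs(i, C, phi, p)),
       fluxes = fl)
}

#' Integrate the calcium model
#'
#' Integrates the four-state Ca2+ system driven by a [wall_stimulus()]
#' (ATP and shear series entering the right-hand side through linear
#' interpolation), using a stiff solver (`deSolve`, `lsoda` by default)
#' from the resting [initial_state()].
#'
#' @param p a [calcium_params()] object
#' @param stim a [wall_stimulus()] covering `[0, t_end]`
#' @param t_end horizon (s); defaults to the stimulus span
#' @param dt_out output grid spacing (s)
#' @param state0 initial state; defaults to [initial_state()]
#' @param rtol,atol solver tolerances
#' @param method `deSolve` integration method
#' @param keep_fluxes record the instantaneous fluxes at the output samples
#' @return an object of class `calcium_trajectory`: a data frame with
#'   columns `t, C, Cs, Cb, i` (and the fluxes if requested), with the
#'   parameters and stimulus attached as attributes
#' @export
#' @examples
#' p <- calcium_params()
#' stim <- wall_stimulus(t = c(0, 60), atp = c(0, 0), shear = 0)
#' traj <- simulate_calcium(p, stim, dt_out = 1)
#' max(abs(traj$C - p$C0))   # resting homeostasis
simulate_calcium <- function(p, stim, t_end = max(stim$t), dt_out = 0.1,
                             state0 = initial_state(p),
                             rtol = 1e-6, atol = 1e-9,
                             method = "lsoda", keep_fluxes = TRUE) {
  stopifnot(inherits(p, "calcium_params"), inherits(stim, "wall_stimulus"))
  if (max(stim$t) < t_end - 1e-9)
    stop("stimulus does not cover the requested horizon [0, ", t_end, "] s")
  phi_fun <- if (length(stim$t) > 1L)
    stats::approxfun(stim$t, stim$atp, rule = 2) else function(t) stim$atp[1L]
  tau_fun <- if (length(stim$t) > 1L)
    stats::approxfun(stim$t, stim$shear, rule = 2) else function(t) stim$shear[1L]
  rhs <- function(t, y, parms) {
    list(calcium_rhs(y, phi_fun(t), tau_fun(t), parms)$deriv)
  }
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::ode(y = state0, times = times, func = rhs, parms = p,
                      method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("stiff solver failed; last accepted time ", max(sol[, "time"]), " s")
  out <- as.data.frame(sol)
  names(out)[1L] <- "t"
  if (keep_fluxes) {
    fl <- t(vapply(seq_len(nrow(out)), function(k) {
      calcium_rhs(c(C = out$C[k], Cs = out$Cs[k], Cb = out$Cb[k],
                    i = out$i[k]),
                  phi_fun(out$t[k]), tau_fun(out$t[k]), p)$fluxes
    }, numeric(5L)))
    out <- cbind(out, fl)
  }
  structure(out, class = c("calcium_trajectory", "data.frame"),
            params = p, stimulus = stim)
}

#' Write a calcium trajectory as CSV
#'
#' @param traj a `calcium_trajectory`
#' @param path output path
#' @return the path, invisibly
#' @export
write_calcium_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "calcium_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Convenience stimulus constructors
#'
#' `constant_stimulus()` holds ATP and shear fixed; `sinusoidal_stimulus()`
#' builds `mean_atp * (1 + delta * sin(2 pi f t))` ATP with constant shear
#' (the validation protocol's drive, e.g. peak 10 uM = mean 5 uM with
#' `delta = 1`).
#'
#' @param atp ATP concentration (uM)
#' @param shear wall shear stress (Pa)
#' @param t_end horizon (s)
#' @param dt sample spacing (s)
#' @return a [wall_stimulus()]
#' @export
constant_stimulus <- function(atp, shear, t_end, dt = 0.05) {
  t <- seq(0, t_end, by = dt)
  wall_stimulus(t, rep_len(atp, length(t)), rep_len(shear, length(t)))
}

#' @rdname constant_stimulus
#' @param mean_atp mean ATP concentration (uM)
#' @param delta relative oscillation amplitude (peak = `mean_atp * (1 + delta)`)
#' @param freq stimulation frequency (Hz)
#' @export
sinusoidal_stimulus <- function(mean_atp, delta, freq, shear, t_end, dt = 0.05) {
  t <- seq(0, t_end, by = dt)
  wall_stimulus(t, mean_atp * (1 + delta * sin(2 * pi * freq * t)),
                rep_len(shear, length(t)))
}
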