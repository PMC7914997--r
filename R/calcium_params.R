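## Default parameter profile for the endothelial Ca2+ dynamics model.
##
## None of these constants are measured here; they are assembled from the
## antecedent endothelial Ca2+ modeling literature that this model family
## descends from:
##   - store release / restore / leak, clearance and buffering constants in
##     the range used by Plank, Wall & David (J Theor Biol 2006) and the
##     combined shear+ATP endothelial models that build on them,
##   - shear-stress gating of mechanosensitive channels via membrane strain
##     energy after Wiesner, Berk & Nerem (Ann Biomed Eng 1996 / PNAS 1997),
##   - P2X4 ATP-gated influx with Hill coefficient 3 and half-saturation in
##     the tens of micromolar, as in purinergic-receptor models.
## Within those literature ranges, k1 (IP3 production), qmax (TRP inflow
## scale) and kp2x4 (P2X4 flux rate) are the three constants adjusted so
## that (a) the validation protocol (0.1 Hz sinusoidal ATP peaking at 10 uM
## with 0.3 Pa steady shear) reproduces the observed initial Ca2+ peak near
## 25 s with an entrained 0.1 Hz post-transient ripple, and (b) the coupled
## chip experiment reproduces the two observed response regimes: an acute
## unimodal transient at the high-mean-ATP station and sustained entrained
## oscillations at the low-ATP pulsatile stations.  All other values are
## used as cited.  Every value is overridable.

calcium_default_table <- function() {
  list(
    ## --- IP3 dynamics -----------------------------------------------------
    k1   = 0.075,    # uM/s   max IP3 production rate (PLC; calibrated, see above)
    k2   = 0.2,      # 1/s    IP3 degradation rate
    Kc   = 2.5,      # uM     ATP half-saturation of PLC activation
    K1   = 0.5,      # uM     Ca2+ half-saturation of PLC feedback
    ## --- store release (CICR) / restore / leak ---------------------------
    k3   = 6.64,     # 1/s    max store release rate
    KCICR = 0.5,     # uM     CICR sensitivity of the stores
    K2   = 0.2,      # uM     IP3 half-saturation of the release gate
    k4   = 5.0,      # uM/s   max restore (SERCA) rate
    K3   = 0.15,     # uM     SERCA half-saturation
    k5   = 1e-4,     # 1/(uM s)  store leak rate (leak = k5 * Cs^2)
    ## --- efflux and buffering --------------------------------------------
    k8   = 0.6,      # uM/s   max efflux (PMCA/NCX clearance)
    K4   = 0.15,     # uM     clearance half-saturation
    k6   = 0.1,      # 1/(uM s)  buffering on-rate
    k7   = 0.3,      # 1/s    debuffering off-rate
    BT   = 120,      # uM     total buffer site concentration
    ## --- compartments and driving gradients ------------------------------
    Vc_over_Vs = 3.5,  # cytosol-to-store volume ratio
    Cex  = 1500,     # uM     extracellular Ca2+
    C0   = 0.1,      # uM     resting cytosolic Ca2+
    ## --- P2X4 ATP-gated influx -------------------------------------------
    kp2x4 = 3e-4,    # 1/s    P2X4 flux rate (calibrated)
    Kp2x4 = 17.4,    # uM     ATP half-saturation of P2X4
    ## --- mechanosensitive TRP influx and gating ---------------------------
    qmax = 2.0e-6,   # 1/(uM s)  max TRP inflow rate (calibrated)
    qin_pass = NULL, # uM/s   passive influx; NULL = calibrated so the
                     #        unstimulated resting state is an equilibrium
    alpha = 3,       # -      no-load gating constant; open prob. 1/(1+alpha)
    fe   = 0.3,      # -      fraction of membrane energy gating the channels
    gating_scale = 8,# -      denominator factor of the gating exponent
    kB   = 1.380649e-23,  # J/K Boltzmann constant
    Temp = 310,      # K      temperature
    N    = 3e10,     # 1/m^2  mechanosensitive channel density
    eps_m = 0.1,     # -      fraction of the applied load borne by the membrane
    l_cell = 3e-5,   # m      cell length in the flow direction
    delta_m = 1e-4,  # N/m    membrane shear modulus
    a1   = 4,        # -      IP3 gate gain
    b1   = 0.1,      # -      IP3 gate baseline
    Ki   = 0.064,    # uM^3   half-saturation of the cubic IP3 gate
    c1   = 0.1,      # -      Ca2+ gate floor
    c2   = 0.9,      # -      Ca2+ gate span
    c3   = 5         # 1/uM   Ca2+ gate decay constant
  )
}

#' Calcium model parameters
#'
#' Assembles the parameter set of the intracellular Ca2+ dynamics model.
#' The shipped `"default"` profile is drawn from the antecedent endothelial
#' Ca2+ modeling literature (store release/restore, clearance and buffering
#' after Plank-type models; shear gating via membrane strain energy after
#' Wiesner-type models; P2X4 influx with Hill coefficient 3); see the
#' commented table in the package source for per-parameter provenance.
#' Any value can be overridden through `...`.
#'
#' Derived quantities are computed after overrides: the resting store level
#' `Cs_rest` from the restore/leak balance at `C0`, the resting buffer load
#' `Cb_rest` from the buffering equilibrium, and (unless supplied) the
#' passive influx `qin_pass` that makes the unstimulated resting state an
#' exact equilibrium of the full system (`qin_pass = q_out(C0)`; at rest all
#' other fluxes vanish by construction).
#'
#' @param ... named overrides of any entry of the default table
#' @param profile profile name; `"default"` is the shipped set
#' @return an object of class `calcium_params`
#' @export
#' @examples
#' p <- calcium_params()
#' p$Cs_rest   # resting store Ca2+ implied by the restore/leak balance
#' q_out(p$C0, p) - p$qin_pass   # 0: resting equilibrium calibration
calcium_params <- function(..., profile = "default") {
  profile <- match.arg(profile)
  p <- calcium_default_table()
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown calcium parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  with(p, {
    if (any(unlist(p[c("k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8")]) < 0))
      stop("rate constants must be nonnegative")
    if (fe < 0 || fe > 1) stop("fe must lie in [0, 1]")
    if (eps_m < 0 || eps_m > 1) stop("eps_m must lie in [0, 1]")
    if (!(Cex > C0) || C0 <= 0) stop("need Cex > C0 > 0")
  })
  p$profile <- profile
  p$Cs_rest <- sqrt(p$k4 / p$k5) * p$C0 / (p$K3 + p$C0)
  p$Cb_rest <- p$k6 * p$C0 * p$BT / (p$k7 + p$k6 * p$C0)
  if (is.null(p$qin_pass)) p$qin_pass <- p$k8 * p$C0 / (p$K4 + p$C0)
  class(p) <- "calcium_params"
  p
}

#' @export
print.calcium_params <- function(x, ...) {
  cat(sprintf("calcium model parameters (profile '%s')\n", x$profile))
  cat(sprintf("  resting state: C0 = %g uM, Cs = %.4g uM, Cb = %.4g uM, i = 0\n",
              x$C0, x$Cs_rest, x$Cb_rest))
  cat(sprintf("  qin_pass (resting-equilibrium calibration) = %.4g uM/s\n",
              x$qin_pass))
  invisible(x)
}

#' Write / read a parameter profile
#'
#' Flat `key = value` text serialization of a [calcium_params()] set (one
#' parameter per line, `#` comments allowed), so profiles can be stored
#' alongside run outputs and reloaded.
#'
#' @param p a `calcium_params` object
#' @param path file path
#' @return `write_calcium_params()` returns the path invisibly;
#'   `read_calcium_params()` returns a `calcium_params` object
#' @export
write_calcium_params <- function(p, path) {
  stopifnot(inherits(p, "calcium_params"))
  keys <- names(calcium_default_table())
  lines <- c(sprintf("# calcium parameter profile '%s'", p$profile),
             vapply(keys, function(k)
               sprintf("%s = %.17g", k, p[[k]]), character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calcium_params
#' @export
read_calcium_params <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) as.numeric(trimws(x[2L]))),
                          vapply(kv, function(x) trimws(x[1L]), character(1L)))
  do.call(calcium_params, vals)
}
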