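#' Channel geometry
#'
#' Dimensions of the main (cell-culture) channel of the Y-shaped microfluidic
#' chip.  `L` is the axial length (flow direction, coordinate `z`), `H` the
#' height (the depth-averaged direction, `y`), and `W` the transverse width
#' (`x`, the direction of the inlet concentration gradient and of the
#' observation points).
#'
#' Defaults are the chip's published dimensions.  Note that those print
#' `H = 1e-3` m and `W = 5e-5` m, i.e. a channel 20x deeper than wide; a
#' Hele-Shaw (wide, shallow) channel with the two values swapped is the
#' geometry under which the documented transport behaviour (near-linear
#' transverse gradient preserved to the outlet, ~4 s fill-in) is obtained.
#' Use [wide_channel_geometry()] for that assignment; both are fully
#' configurable here.
#'
#' @param L channel length (m)
#' @param H channel height (m); velocity profile and Taylor-Aris dispersion
#'   are set by this dimension
#' @param W channel width (m); the inlet ATP gradient spans `0 <= x <= W`
#' @return an object of class `channel_geometry`
#' @seealso [wide_channel_geometry()]
#' @export
#' @examples
#' channel_geometry()
#' wide_channel_geometry()
channel_geometry <- function(L = 1e-2, H = 1e-3, W = 5e-5) {
  stopifnot(is.numeric(L), is.numeric(H), is.numeric(W),
            length(L) == 1L, length(H) == 1L, length(W) == 1L)
  if (!all(is.finite(c(L, H, W))) || any(c(L, H, W) <= 0))
    stop("channel dimensions L, H, W must be strictly positive and finite")
  structure(list(L = L, H = H, W = W), class = "channel_geometry")
}

#' @rdname channel_geometry
#' @export
wide_channel_geometry <- function(L = 1e-2, H = 5e-5, W = 1e-3) {
  channel_geometry(L = L, H = H, W = W)
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("channel geometry: L = %g m, H = %g m, W = %g m\n",
              x$L, x$H, x$W))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Waveforms: Q2(t) specifications

#' Inlet flow waveforms
#'
#' Constructors for the perfusion-inlet flow-rate waveform `Q2(t)`.
#' `flow_steady()` is a constant; `flow_sinusoidal()` is
#' `mean * (1 + delta * sin(2*pi*freq*t + phase))`; `flow_sampled()` replays
#' an arbitrary sampled waveform with linear interpolation between samples
#' (the rule a pressure-driven pump replaying a drawn waveform follows).
#'
#' @param value constant flow rate (m^3/s)
#' @param mean mean flow rate (m^3/s)
#' @param delta pulsatile amplitude fraction, `0 <= delta <= 1` (so that
#'   `Q2(t) >= 0`)
#' @param freq pulsatile frequency (Hz)
#' @param phase phase offset (rad), default 0
#' @param times,values samples of the waveform; `times` (s) strictly
#'   increasing, `values` (m^3/s) nonnegative
#' @return an object of class `flow_waveform`
#' @export
#' @examples
#' w <- flow_sinusoidal(1.5e-10, delta = 0.5, freq = 0.1)
#' eval_waveform(w, c(0, 2.5, 5))
flow_steady <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (value < 0) stop("flow rate must be nonnegative")
  structure(list(kind = "steady", value = value), class = "flow_waveform")
}

#' @rdname flow_steady
#' @export
flow_sinusoidal <- function(mean, delta, freq, phase = 0) {
  stopifnot(is.numeric(mean), is.numeric(delta), is.numeric(freq),
            length(mean) == 1L, length(delta) == 1L, length(freq) == 1L)
  if (mean < 0) stop("mean flow rate must be nonnegative")
  if (delta < 0 || delta > 1)
    stop("pulsatile amplitude fraction delta must lie in [0, 1] so Q2(t) >= 0")
  if (freq <= 0) stop("pulsatile frequency must be positive")
  structure(list(kind = "sinusoidal", mean = mean, delta = delta,
                 freq = freq, phase = phase),
            class = "flow_waveform")
}

#' @rdname flow_steady
#' @export
flow_sampled <- function(times, values) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("sampled waveform times must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("sampled waveform values must be finite and nonnegative")
  structure(list(kind = "sampled", times = as.numeric(times),
                 values = as.numeric(values)),
            class = "flow_waveform")
}

#' @rdname flow_steady
#' @param w a `flow_waveform`
#' @param t time or vector of times (s)
#' @export
eval_waveform <- function(w, t) {
  stopifnot(inherits(w, "flow_waveform"), is.numeric(t))
  switch(w$kind,
    steady = rep_len(w$value, length(t)),
    sinusoidal = w$mean * (1 + w$delta * sin(2 * pi * w$freq * t + w$phase)),
    sampled = {
      if (any(t < w$times[1L] - 1e-12) || any(t > w$times[length(w$times)] + 1e-12))
        stop("sampled waveform queried outside its time span [",
             w$times[1L], ", ", w$times[length(w$times)], "] s")
      stats::approx(w$times, w$values, xout = t, rule = 2)$y
    },
    stop("unknown waveform kind"))
}

as_waveform <- function(x) {
  if (inherits(x, "flow_waveform")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(flow_steady(x))
  stop("Q2 must be a flow_waveform or a single numeric flow rate")
}

## ---------------------------------------------------------------------------
## Flow program: Q1 constant + Q2(t)

#' Two-inlet flow program
#'
#' Pairs the constant ATP-stream inlet flow rate `Q1` with the (possibly
#' pulsatile) perfusion-inlet waveform `Q2(t)`.  Because the two laminar
#' streams occupy widths proportional to their flow rates, the ATP stream
#' fills the fraction `eps(t) = Q1 / (Q1 + Q2(t))` of the channel width.
#'
#' @param Q1 constant flow rate of the ATP-stream inlet (m^3/s)
#' @param Q2 perfusion-inlet waveform: a `flow_waveform` (see
#'   [flow_steady()]) or a single number (treated as steady)
#' @return an object of class `flow_program`
#' @export
#' @examples
#' prog <- flow_program(1.5e-10, flow_sinusoidal(1.5e-10, 0.5, 0.1))
#' total_flow(prog, 0)      # 3e-10 m^3/s
#' flow_fraction(prog, 0)   # 0.5
flow_program <- function(Q1, Q2) {
  stopifnot(is.numeric(Q1), length(Q1) == 1L, is.finite(Q1))
  if (Q1 < 0) stop("Q1 must be nonnegative")
  structure(list(Q1 = Q1, Q2 = as_waveform(Q2)), class = "flow_program")
}

#' Derived flow quantities
#'
#' `total_flow()` is `Q(t) = Q1 + Q2(t)`.  `flow_fraction()` is the ATP
#' stream-width fraction `eps(t) = Q1 / (Q1 + Q2(t))`, so the ATP solution
#' occupies `0 <= x <= eps(t) * W`.  `wall_shear_stress()` is the
#' quasi-steady plane-Poiseuille wall value
#' `tau_w(t) = 6 * eta * Q(t) / (W * H^2)`, uniform over the channel floor.
#'
#' @param prog a [flow_program()]
#' @param t time or vector of times (s)
#' @param geom a [channel_geometry()]
#' @param eta fluid viscosity (Pa s)
#' @return numeric vector the length of `t`
#' @export
total_flow <- function(prog, t) {
  stopifnot(inherits(prog, "flow_program"))
  prog$Q1 + eval_waveform(prog$Q2, t)
}

#' @rdname total_flow
#' @export
flow_fraction <- function(prog, t) {
  q <- total_flow(prog, t)
  if (any(q <= 0))
    stop("degenerate flow: Q1 + Q2(t) must be positive to define the stream-width fraction")
  prog$Q1 / q
}

#' @rdname total_flow
#' @export
wall_shear_stress <- function(prog, geom, eta = 1e-3, t) {
  stopifnot(inherits(geom, "channel_geometry"), is.numeric(eta), eta > 0)
  6 * eta * total_flow(prog, t) / (geom$W * geom$H^2)
}

## ---------------------------------------------------------------------------
## Time-series metrics

#' Peak detection with prominence
#'
#' Local maxima of a sampled series whose topographic prominence (height
#' above the higher of the two bounding bases, where a base is the minimum
#' between the peak and the nearest sample exceeding it, or the record end)
#' is at least `prominence`.
#'
#' @param v numeric vector
#' @param prominence minimum prominence (same units as `v`)
#' @return integer vector of peak indices (possibly empty)
#' @export
find_peaks <- function(v, prominence = 0) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  idx <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  keep <- vapply(idx, function(i) {
    lo <- i; while (lo > 1L && v[lo - 1L] <= v[i]) lo <- lo - 1L
    hi <- i; while (hi < n && v[hi + 1L] <= v[i]) hi <- hi + 1L
    left_base <- min(v[lo:i]); right_base <- min(v[i:hi])
    (v[i] - max(left_base, right_base)) >= prominence
  }, logical(1L))
  idx[keep]
}

#' Summary metrics of a uniformly sampled time series
#'
#' Computes the time average, the peak-to-peak excursion, the dominant
#' nonzero frequency (periodogram of the mean-removed series) and the time
#' of the first prominent local maximum.  The mean, peak-to-peak and
#' dominant frequency are evaluated on an analysis window that excludes the
#' initial transient (`transient_frac` of the record by default; traces from
#' a filling channel or a resting cell carry an initial transient before the
#' periodic regime).  The first-peak time is evaluated on the full record,
#' since the transient peak is itself the feature of interest.
#'
#' @param t sample times (s), uniformly spaced
#' @param v values
#' @param transient_frac fraction of the record discarded (from the start)
#'   before computing mean / peak-to-peak / dominant frequency; default 0.25
#' @param prominence_frac first-peak prominence threshold as a fraction of
#'   the full-record range; default 0.1
#' @return a list with elements `mean`, `peak_to_peak`,
#'   `dominant_frequency` (Hz; `NA` for a constant series) and
#'   `first_peak_time` (s; `NA` if no prominent peak)
#' @export
#' @examples
#' t <- seq(0, 60, by = 0.05)
#' m <- signal_metrics(t, 2 + 0.5 * sin(2 * pi * 0.1 * t))
#' unlist(m[c("mean", "peak_to_peak", "dominant_frequency")])
signal_metrics <- function(t, v, transient_frac = 0.25, prominence_frac = 0.1) {
  stopifnot(is.numeric(t), is.numeric(v), length(t) == length(v),
            length(t) >= 2L)
  dt <- diff(t)
  if (any(abs(dt - dt[1L]) > 1e-6 * max(abs(dt[1L]), 1e-300)))
    stop("signal_metrics requires a uniform time grid")
  dt <- dt[1L]
  i0 <- max(1L, floor(length(t) * transient_frac) + 1L)
  vw <- v[i0:length(v)]
  rng <- diff(range(v))
  out <- list(
    mean = mean(vw),
    peak_to_peak = diff(range(vw)),
    dominant_frequency = dominant_frequency(vw, dt),
    first_peak_time = NA_real_
  )
  pk <- find_peaks(v, prominence = prominence_frac * rng)
  if (length(pk)) out$first_peak_time <- t[pk[1L]]
  out
}

## periodogram of the linearly detrended series (a decaying plateau would
## otherwise dominate the low-frequency end); NA when there is no power
## above numerical noise (constant series)
dominant_frequency <- function(v, dt) {
  n <- length(v)
  if (n < 4L) return(NA_real_)
  x <- stats::residuals(stats::lm.fit(cbind(1, seq_len(n)), v))
  if (max(abs(x)) <= 1e-10 * max(abs(v), 1e-300)) return(NA_real_)
  p <- Mod(stats::fft(x))^2
  k <- 2:(n %/% 2L + 1L)            # positive nonzero frequencies
  (which.max(p[k])) / (n * dt)
}
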