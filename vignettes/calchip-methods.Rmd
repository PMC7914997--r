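---
title: "Methods: coupled ATP transport and endothelial calcium dynamics in a microfluidic signal generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled ATP transport and endothelial calcium dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calchip)
```

`calchip` simulates a Y-junction microfluidic generator of paired
biochemical and biomechanical stimuli: an ATP-laden stream and a pulsatile
ATP-free perfusion stream co-flow down a shallow culture channel, so cells
adhering to the channel floor experience a position-dependent combination
of dynamic ATP concentration and wall shear stress.  A four-state
intracellular Ca²⁺ model driven by that wall stimulus closes the chain
from pump program to cytosolic Ca²⁺ trace.  This vignette records the
model equations, the numerical choices, the parameter provenance, and the
package's validation protocols.

## 1. Extracellular ATP transport

### Geometry and flow

The culture channel is a rectangular duct of length $L$ (flow direction
$z$), height $H$ (the direction averaged over) and width $W$ (the
transverse direction $x$ carrying the concentration gradient).  Two
laminar inlet streams merge at $z = 0$: the ATP stream at constant flow
rate $Q_1$ and the perfusion stream at a programmable rate $Q_2(t)$
(`flow_steady()`, `flow_sinusoidal()`, `flow_sampled()`).  Because the
streams remain laminar, the ATP stream occupies the width fraction

$$\varepsilon(t) = \frac{Q_1}{Q_1 + Q_2(t)},$$

and an upstream gradient-generator network delivers a linear profile
across it, so the inlet condition is

$$\bar\varphi(x, 0, t) = \varphi_0\left(1 - \frac{x}{\varepsilon(t) W}\right)
  \quad (0 \le x \le \varepsilon W), \qquad 0 \text{ otherwise.}$$

The flow is quasi-steady plane Poiseuille: mean velocity
$\bar u(t) = Q(t)/(HW)$ with $Q = Q_1 + Q_2(t)$, and floor shear stress
$\tau_w(t) = 6\eta Q(t)/(W H^2)$, uniform over the floor
(`wall_shear_stress()`).

### A note on the published channel dimensions

The chip's published dimension table prints $H = 10^{-3}$ m and
$W = 5\times10^{-5}$ m — a channel 20× deeper than wide — while the device
drawings and the transport behaviour it reports (a near-linear transverse
gradient that survives to the outlet, a fill-in time of about 4 s)
describe a shallow, wide (Hele-Shaw) channel.  The two assignments differ
sharply: with the printed values the transverse diffusion number
$D\,t_{\mathrm{res}}/W^2 \approx 0.3$ smears the gradient within the
transit time and the Taylor–Aris dispersion mixes the channel axially in
under a second, whereas the swapped assignment
($H = 5\times10^{-5}$ m, $W = 10^{-3}$ m) reproduces both observations.
`channel_geometry()` defaults to the printed values;
`wide_channel_geometry()` provides the swapped assignment, which the
pipeline and all validation protocols use.  Both are fully configurable.

### Depth-averaged transport equation

Averaging over the height gives a 2-D equation for the depth-averaged
concentration $\bar\varphi(x, z, t)$:

$$\frac{\partial\bar\varphi}{\partial t}
 + \bar u(t)\frac{\partial\bar\varphi}{\partial z}
 = D\frac{\partial^2\bar\varphi}{\partial x^2}
 + D_{\mathrm{eff}}(t)\frac{\partial^2\bar\varphi}{\partial z^2},$$

where the axial dispersion coefficient follows Taylor and Aris: shear
along the averaged dimension disperses the depth-averaged solute axially,

$$D_{\mathrm{eff}} = D\left(1 + \frac{\mathrm{Pe}^2}{210}
   \left(\frac{H}{W}\right)^2\right), \qquad \mathrm{Pe} = \frac{\bar u W}{D}.$$

The width factors cancel algebraically — the expression equals
$D(1 + \mathrm{Pe}_H^2/210)$ with $\mathrm{Pe}_H = \bar u H / D$ — so the
dispersion is governed by the averaging dimension alone, as it must be.
The classic parallel-plate coefficient $D(1 + 2\,\mathrm{Pe}_H^2/105)$ is
available as the `"plane_poiseuille"` variant and `"molecular"` disables
the enhancement; the default keeps the $1/210$ form.  Dispersion is
evaluated quasi-statically from the instantaneous $\bar u(t)$, valid when
the drive period far exceeds the cross-channel diffusion time
$H^2/D \approx 5$ s for the default geometry.

Boundary conditions: Dirichlet inlet profile at $z = 0$ re-evaluated every
step from $\varepsilon(t)$; no-flux side walls at $x = 0, W$;
zero-gradient outflow at $z = L$.  The channel starts ATP-free.

### Discretization

`simulate_transport()` uses an explicit scheme: first-order upwind for
axial convection and second-order central differences for both diffusion
terms.  This combination is sign-preserving, so the discrete solution
honors the maximum principle ($0 \le \bar\varphi \le \varphi_0$
everywhere, which the solver verifies by tracking the field extrema), at
the cost of some numerical axial diffusion — acceptable here because
physical Taylor–Aris dispersion already dominates the axial term.  The
time step obeys

$$\Delta t \le \left(\frac{u_{\max}}{\Delta z}
   + \frac{2D}{\Delta x^2}
   + \frac{2D_{\mathrm{eff},\max}}{\Delta z^2}\right)^{-1},$$

chosen automatically with a safety factor of 0.9; a user-supplied step
that violates the bound is refused with the computed bound in the error
message.  The inner loop is compiled (Rcpp); a 64 × 256 grid advances
about 300 simulated seconds per half minute on one CPU.  At the default
64 × 256 resolution the steady emerging-ATP value differs from a 32 × 128
run by well under 1 %.

The per-second maximum field change is recorded as a settling monitor;
`settling_time()` reports the first time it drops below 0.1 % of
$\varphi_0$ per second.

## 2. Wall stimulus and signal metrics

`sample_wall_stimulus()` extracts the paired $\{\varphi(t), \tau_w(t)\}$
series a cell at floor position $(x, z)$ experiences (bilinear
interpolation of the depth-averaged field; the floor shear is uniform).
`signal_metrics()` summarizes any uniformly sampled series with its time
average, peak-to-peak excursion and dominant frequency, all evaluated on
an analysis window that excludes the first 25 % of the record (the
fill-in or cell-activation transient), plus the time of the first
prominent peak on the full record (topographic prominence of at least
10 % of the range, `find_peaks()`).  The dominant frequency is the
periodogram maximum of the *linearly detrended* window; without
detrending, a decaying plateau dominates the low-frequency end of the
spectrum and masks genuine oscillations.

## 3. Intracellular calcium dynamics

### States and fluxes

Four states, all in µM: cytosolic free Ca²⁺ $C$, store Ca²⁺ $C_s$,
buffered Ca²⁺ $C_b$, and IP₃ $i$:

$$\frac{dC}{dt} = q_{\mathrm{rel}} - q_{\mathrm{res}} + q_{\mathrm{in}}
   - q_{\mathrm{out}} - q_{\mathrm{buf}}, \qquad
  \frac{dC_s}{dt} = \frac{V_c}{V_s}(q_{\mathrm{res}} - q_{\mathrm{rel}}),$$
$$\frac{dC_b}{dt} = q_{\mathrm{buf}}, \qquad
  \frac{di}{dt} = k_1\frac{\varphi}{K_c + \varphi}\frac{C}{K_1 + C} - k_2 i,$$

with CICR store release
$q_{\mathrm{rel}} = k_3\,\frac{C}{K_{\mathrm{CICR}}+C}\,
 \left(\frac{i}{i+K_2}\right)^{3} C_s$,
SERCA restore against a quadratic leak
$q_{\mathrm{res}} = k_4 \left(\frac{C}{K_3+C}\right)^2 - k_5 C_s^2$,
saturable clearance $q_{\mathrm{out}} = k_8 C/(K_4+C)$, and mass-action
buffering $q_{\mathrm{buf}} = k_6 C (B_T - C_b) - k_7 C_b$.  Influx
$q_{\mathrm{in}}$ has three parts: a P2X4-type ATP-gated channel with
Hill coefficient 3,
$q_{\mathrm{P2X4}} = k_{\mathrm{P2X4}}
 \left(\frac{\varphi}{K_{\mathrm{P2X4}}+\varphi}\right)^3 (C_{ex} - C)$;
a mechanosensitive TRP-type channel
$q_{\mathrm{TRP}} = q_{\max}\, p_1 p_2 p_3\,(C_{s,0} - C_s)(C_{ex} - C)$
with store feedback through the depletion $C_{s,0} - C_s$; and a constant
passive leak $q_{\mathrm{pass}}$.

The shear gate follows the membrane strain-energy formulation of Wiesner,
Berk and Nerem (Ann. Biomed. Eng. 1996; PNAS 1997):

$$p_1 = \frac{1}{1 + \alpha\,
   e^{-f_e W(\tau_w) / (8\, k_B T N)}}, \qquad
  W(\tau_w) = \frac{(A + B - 4\delta_m)^2}{A + B},$$

with $A = \epsilon_m \tau_w l$, $B = \sqrt{16\delta_m^2 + A^2}$; $W(0)=0$
and $W$ grows monotonically with the load magnitude.  The factor 8 in the
gating denominator differs between published variants and is exposed as
`gating_scale`.  The companion gates are $p_2 = b_1(1 + a_1
i^3/(K_i + i^3))$ and $p_3 = c_1 + c_2 e^{-c_3 C}$.

### Resting state as exact equilibrium

The initial condition is the unstimulated rest state: $C = C_0$, the
store at its restore/leak balance
$C_{s,0} = \sqrt{k_4/k_5}\;C_0/(K_3 + C_0)$, the buffer at binding
equilibrium, and $i = 0$.  The passive leak is then calibrated at
construction so rest is an *exact* equilibrium of the assembled
right-hand side: at rest every other flux vanishes by construction, so
$q_{\mathrm{pass}} = q_{\mathrm{out}}(C_0)$.  The test suite asserts a
residual below the solver's absolute tolerance and the return to rest
after ±10 % perturbations.

A structural consequence worth noting: because the TRP influx carries the
store-feedback factor $(C_{s,0} - C_s)$, the rest state remains an exact
equilibrium under pure shear — with no ATP anywhere, shear alone provokes
no Ca²⁺ response.  At stations of the chip where the ATP concentration is
essentially zero the model therefore predicts a flat trace, and the
oscillatory regime requires at least a small pulsatile ATP component.

### Parameter provenance and calibration

The model prints no single canonical constant set; the shipped `"default"`
profile is assembled from the antecedent endothelial Ca²⁺ modeling
literature (store, clearance and buffering constants of the Plank–Wall–
David family of models, J. Theor. Biol. 2006; shear gating constants from
the Wiesner-type models; P2X4 constants from purinergic-receptor models),
with per-parameter provenance comments in `R/calcium_params.R`.  Within
those literature ranges exactly three constants were calibrated —
$k_1$ (IP₃ production), $q_{\max}$ (TRP scale) and $k_{\mathrm{P2X4}}$
(P2X4 scale) — against two qualitative targets of the device's published
behaviour: (a) the validation protocol (sinusoidal ATP peaking at 10 µM
at 0.1 Hz with constant 0.3 Pa shear) must produce its first cytosolic
peak near 25 s with a post-transient ripple entrained at the drive
frequency, and (b) the coupled chip run must reproduce the two observed
response regimes — an acute unimodal transient at the high-mean-ATP
station and sustained entrained oscillations at the low-ATP pulsatile
stations.  The first-peak time is an ignition delay set almost entirely
by $k_1$ (IP₃ must accumulate until CICR fires); larger influx scales
produced a slow (~170 s period) store-refill relaxation cycle at the
high-ATP station instead of the observed single transient, which fixed
$q_{\max}$ and $k_{\mathrm{P2X4}}$ at the low end of their ranges.
All other constants are used as cited, and every value is overridable.

### Integration

`simulate_calcium()` integrates with `deSolve::lsoda` (rtol $10^{-6}$,
atol $10^{-9}$); the stimulus series enter the right-hand side by linear
interpolation.  The bookkeeping identity

$$\frac{dC}{dt} + \frac{dC_b}{dt} + \frac{V_s}{V_c}\frac{dC_s}{dt}
  = q_{\mathrm{in}} - q_{\mathrm{out}}$$

holds algebraically and is asserted to machine precision along driven
trajectories.

## 4. The coupled pipeline

`run_chip_experiment()` solves transport once, samples the wall stimulus
at each observation station (default $x = W\{1,2,3,4\}/5$ at the outlet),
and integrates the Ca²⁺ model per station — one-way coupling; the cells
do not release ATP back into the channel.  With an output directory set,
every series is written as CSV along with the parameter profile, a
metrics summary and a JSON manifest listing each file with its MD5
checksum; the pipeline is deterministic, so identical configurations
reproduce identical bytes.

`classify_response()` labels a trajectory *oscillatory* when the
post-transient peak-to-peak excursion of $C$ exceeds 10 % of the
trajectory's global range *and* a dominant frequency is detected, else
*unimodal*; both thresholds are configurable and recorded in the output.
Classification should be run on records long enough that the analysis
window clears the acute transient: the high-ATP surge decays over roughly
150 s, so the reference protocols use 600 s records, giving a 450 s
window (45 drive periods at 0.1 Hz, frequency resolution 0.0022 Hz).

`frequency_sweep()` characterizes the channel as a chemical-signal
filter: for each pulsatile frequency and amplitude it runs transport to
the periodic steady state (certified by the last drive period repeating
the preceding one within 0.1 % of $\varphi_0$) and records the
peak-to-peak of the emerging ATP.  The channel is low-pass: amplitude
transmission falls with frequency and grows with the drive amplitude.

## 5. Validation protocols and reference values

Four headline numbers, recomputed by `scripts/acceptance.R` and asserted
(with the stated tolerances) in `tests/testthat/test-acceptance.R`:

1. **Fill-in settling time.**  Equal steady flows
   $Q_1 = Q_2 = 1.5\times10^{-10}$ m³/s, wide-channel assignment,
   64 × 256 grid: the field settles (per-second change below 0.1 % of
   $\varphi_0$) at **3.79 s**, matching the device's ≈ 4 s.
2. **Mean emerging ATP.**  Sinusoidal perfusion (mean
   $1.5\times10^{-10}$ m³/s, $\delta = 0.5$, $f_Q = 0.1$ Hz): the
   time-averaged ATP at $(x = W/5, z = L)$ over three full drive periods
   is **5.93 µM**, within 10 % of the device's reported ≈ 6.2 µM.
3. **Calcium first peak.**  Validation stimulus (sinusoidal ATP peaking
   at 10 µM at 0.1 Hz, constant 0.3 Pa shear): first prominent peak at
   **26.1 s** (reference ≈ 25 s; ±40 % tolerance, as the rate constants
   come from cited antecedents rather than measurements).
4. **Entrainment.**  The same trace's post-transient dominant frequency
   is **0.0999 Hz** — the drive frequency to within one frequency bin.

A compact property suite backs these numbers: maximum principle, grid
convergence, low-pass monotonicity in $f_Q$ and monotonicity in
$\delta$, resting equilibrium and return to rest, nonnegativity and
buffer-cap invariants, the flux bookkeeping identity, gate bounds,
smaller Ca²⁺ oscillation amplitude at 0.5 Hz than at 0.1 Hz, and the
two-regime classification of the coupled run.

```{r validation, eval = FALSE}
# the validation protocol, verbatim (runtime ~2 s)
stim <- sinusoidal_stimulus(mean_atp = 5, delta = 1, freq = 0.1,
                            shear = 0.3, t_end = 600)
traj <- simulate_calcium(calcium_params(), stim)
classify_response(traj)[c("first_peak_time", "dominant_frequency")]
#> $first_peak_time
#> [1] 26.1
#> $dominant_frequency
#> [1] 0.09997778
```

## 6. Limitations

* The transport model is depth-averaged; vertical concentration structure
  and the cells' own boundary layer are not resolved.
* Dispersion is quasi-steady, so drive frequencies approaching
  $D/H^2 \approx 0.2$ Hz begin to strain the Taylor–Aris assumption; the
  low-pass trend remains correct but the dispersion magnitude becomes
  approximate.
* One-way coupling: no cellular ATP release or degradation feeds back
  into the channel.
* Pure shear stimulation cannot perturb the rest state (see §3); the
  minimal oscillations sometimes reported at zero-ATP stations are not
  reproduced — the model needs a nonzero pulsatile ATP component there.
* The Ca²⁺ constants are literature-assembled, not fitted to a specific
  cell line; quantitative peak amplitudes should be read as
  order-of-magnitude.
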