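---
title: "The firing-clamp method: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The firing-clamp method: model, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the idea

Synaptic input to a neuron with voltage-independent receptor channels acts
on the membrane through exactly two scalar signals: the total synaptic
conductance $G(t)$ (the coefficient of the voltage-dependent term in the
current-balance equation) and the total synaptic current at rest
$I(t)$ (the voltage-independent term).  For two input populations with
reversal potentials $V_E$ and $V_I$,

$$G(t) = G_E(t) + G_I(t), \qquad
  I(t) = G_E(t)\,(V_E - V_0) + G_I(t)\,(V_I - V_0),$$

with $V_0$ the resting potential.  If $(I, G)$ can be measured and
$V_E, V_I$ are known, the system inverts cycle by cycle:

$$G_{E} = \frac{I - G\,(V_I - V_0)}{V_E - V_I}, \qquad G_{I} = G - G_{E}.$$

The firing clamp measures $(I, G)$ from **probe spikes** evoked at a fixed
rate (200 Hz) by a meander-shaped current: a +600 pA pulse of fixed 0.81 ms
duration, then a −400 pA pulse held until the recorded voltage crosses a
−75 mV reset, then zero current until the next cycle.  The
voltage-dependent termination makes this a dynamic-clamp rather than a
current-clamp protocol, and the imposed reset re-standardises the fast
channel states every 5 ms.  Two characteristics are read from each cycle:

* **V_subthr** — the mean potential over the zero-current tail of the
  cycle, mainly sensitive to $I$;
* **V_pulse** — the probe-spike response to the positive pulse, mainly
  sensitive to $G$ through shunting of the sodium-driven depolarisation.

A calibration session injects known $(I, G)$ through the dynamic-clamp law
$I_{inj}(t) = I(t) - G(t)\,(V(t) - V_0)$ and fits each feature as a
quadratic polynomial surface over the $(I, G)$ plane; estimation inverts
the fitted pair of surfaces for each recorded cycle.

## The model neuron

No closed-loop method can be validated without ground truth, so the
package ships a single-compartment conductance-based cell built to operate
the protocol the way the original recordings describe: resting near
−77 mV with 1.5 nS input conductance, one probe spike per meander cycle,
negative-pulse termination within ~1.5 ms.  The membrane equation, in the
package-wide unit system (mV, ms, nS, pA, pF, so nS·mV = pA),

$$C_m \dot V = -G_L (V - V_L) - \bar g_{Na} m^3 h (V - E_{Na})
  - (\bar g_K n^4 + \bar g_{AHP} w)(V - E_K) + I_{inj},$$

with defaults $C_m = 12$ pF, $G_L = 1.5$ nS, $V_L = -77$ mV,
$\bar g_{Na} = 350$ nS, $\bar g_K = 100$ nS, $\bar g_{AHP} = 5$ nS,
$E_{Na} = 55$ mV, $E_K = -90$ mV.  Gating (rates in 1/ms, $x' = (x_\infty - x)/\tau_x$):

* $m$: $\alpha = 0.5\,\frac{V + 44}{1 - e^{-(V+44)/10}}$,
  $\beta = 20\,e^{-(V+60)/18}$ — fast activation, half-activation near
  −42 mV.
* $h$: $h_\infty = 0.007 + 0.993/(1 + e^{(V+55)/10})$,
  $\tau_h = 0.2 + 2.5/(1 + e^{(V+65)/12})$ — steep inactivation, well
  separated from $m$ activation so that no persistent window current can
  latch the cell depolarised, with recovery fast enough at the −75 mV
  reset to de-inactivate fully between 200 Hz cycles.  The small
  incomplete-inactivation floor keeps the spike top graded rather than
  all-or-none.
* $n$: $\alpha = 0.04\,\frac{V + 34}{1 - e^{-(V+34)/10}}$,
  $\beta = 0.5\,e^{-(V+44)/80}$.
* $w$ (slow adaptation): $w_\infty = 1/(1 + e^{-(V+25)/5})$,
  $\tau_w = 30$ ms.  The gate activates only during the spike, so its
  steady state is set by the clamped firing rate — precisely the class of
  slow channel the fixed-rate protocol is designed to hold constant.  A
  subthreshold-activating adaptation conductance would instead act as a
  slowly drifting hidden input invisible to the calibration.

These kinetics are a design outcome, not a fit to any particular cell:
candidate models with conventional fast spikes put the pulse-end voltage
sample on a near-vertical spike flank, where sub-millisecond latency
jitter across the $(I,G)$ domain translates into tens of millivolts of
feature scatter and an unusable calibration surface.  The graded,
room-temperature-like probe spike (peak ≈ +28 mV from a −77 mV rest at
quiescence) varies smoothly with both inputs.

### Integration

Fixed-step closed loop at $\Delta t = 0.03$ ms, matching a 30 µs
dynamic-clamp tick.  Gates advance by exact exponential relaxation at
frozen voltage; the voltage then advances by exact exponential relaxation
of the gate-frozen linear membrane equation.  This replaces forward Euler
on $V$ because the total conductance during the spike (tens of nS on
12 pF) puts the voltage time constant near the step size, where forward
stepping is unstable; the exponential update is unconditionally stable
and exact for the passive cell, which the test suite checks against the
closed-form RC response.  The controller is sample-and-hold: every
current computed for a step uses the voltage recorded at the step start,
and can never see the future.

## Protocol engine

`meander_config()` holds the probe parameters (200 Hz, +600/−400 pA,
τ⁺ = 0.81 ms, reset −75 mV); the worked-example variant
(400/−300 pA, reset −80 mV) is available as `preset = "figure1"`.
Termination is detected as the first sample at or below the reset value —
the natural reading of a crossing on a discrete 30 µs loop.  A 3 ms
safety cap bounds the negative phase so a strong excitatory input cannot
lock the cycle; cap-terminated cycles are flagged.  Cycle bookkeeping is
integer (sample indices), so the cycle count is exactly
$\lfloor \mathrm{duration} \cdot \mathrm{rate} / 1000 \rfloor$ and cycles
never overlap.  Each run may be preceded by a discarded warm-up
(default 200 ms, whole cycles) so recordings start on the settled
periodic attractor.

## Feature extraction

`V_subthr` is the mean voltage from 0.5 ms after the negative-pulse end
(a settle margin over the unspecified window) to the cycle end, with
samples above the spike criterion censored; a cycle is flagged when the
window is empty or more than 30 % censored (spontaneous spikes, cf. the
behaviour of depolarised real cells).

`V_pulse` defaults to the **probe-spike amplitude**: the maximum voltage
from the pulse onset to 1 ms past the pulse end (`pulse_feature =
"peak"`).  The published description of this feature is ambiguous — it is
introduced as the "spike amplitude", plotted as the "positive pulse
response amplitude", and defined in one place as the voltage difference
across the positive pulse.  The strict pulse-edge readings
(`"difference"`, `"absolute"`) are provided as switches and are
internally consistent because calibration and inversion always share one
convention; on the simulated neuron they are far noisier, for the
latency-jitter reason above, and the peak is the default.  The spike
criterion for quality control is −20 mV (configurable; needed only for
flagging, never for estimation).

## Calibration

The default calibration steps through a 6 × 5 lattice of constant
$(I, G)$ injections covering $I \in [0, 50]$ pA, $G \in [0, 4]$ nS
(120 ms per point, first 8 cycles discarded, the quiescent point held 8×
longer).  Two departures from the classic slow-sinusoid procedure (which
remains available as `stimulus = "sinusoid"`, periods 40 and 70 ms) are
deliberate:

* **Stepped, settled points.**  Under time-varying injection the features
  of a cycle depend not only on that cycle's mean $(I, G)$ but on the
  recent history (the previous cycle's current sets the pulse-start
  voltage).  Fitting settled constant segments removes this systematic
  mismatch from the surface; the scenario recordings still carry it as
  honest per-cycle noise.
* **Domain.**  With $V_E = 0$ and $V_I = -74$ mV both above
  $V_0 = -77$ mV, every excitatory/inhibitory mixture composes to
  $I \ge 0$, so negative currents are never visited; and above
  ≈ 55 pA this cell's probe response saturates sharply (the partial spike
  becomes full), a regime no quadratic surface can represent, while the
  depolarised baseline also begins to fire spontaneously between probes.
  The calibrated domain is therefore the physiologically useful one for
  this cell; scenario excitation is sized to stay inside it
  (peak $G_E \lesssim 0.65$ nS), while inhibition, being nearly
  shunting-silent ($V_I - V_0 = 3$ mV), spans the full conductance range.

Surfaces are ordinary least squares in the bilinear basis
$a_{IG} IG + a_I I + a_G G + a_0$ or (default) the full quadratic with
$a_{II} I^2 + a_{GG} G^2$.  The printed worked-example polynomials
contain exactly the four bilinear terms, and refitting data generated
from them recovers all eight coefficients to better than six significant
digits; the full quadratic is the default for live calibrations because
the sampled surfaces carry measurable curvature.  Fits store the residual
RMS per feature and the domain; rank-deficient designs (collinear
calibration points) are an explicit error.

## Inversion and decomposition

For bilinear surfaces the two-feature system reduces in closed form to a
scalar quadratic in $G$ (eliminating
$I = (V^{subthr} - a_G G - a_0)/(a_{IG} G + a_I)$); for quadratic
surfaces a damped Newton iteration is seeded from the bilinear solution
of the four leading terms, the previous cycle's estimate, and the domain
centre.  Root selection: admissible roots lie within the calibration
domain expanded by 50 % of its span; among admissible roots the one
closer to the previous cycle's estimate wins (temporal continuity), else
the one closer to the domain centre.  No admissible root → the cycle is
reported `failed` with absent values, never silently extrapolated.
Estimated conductances are reported as-is, including negative excursions:
clipping would hide exactly the dispersion the method is known for.
Per-cycle estimates are stamped at the centre of the subthreshold
averaging window.

A drifting inhibitory reversal (as under prolonged agonist application)
is supported as a per-cycle $V_I$ sequence in `reversal_spec()`; the
drift's functional form is the user's to supply, with a linear ramp
available in the scenario generator.

## Synthetic scenarios

`scenario_spec()` composes per-channel components: sinusoids (gamma
default 40 Hz, theta default 6 Hz), Poisson trains of
instantaneous-rise/mono-exponential-decay events, smoothed agonist
application steps, and linear chirps for bandwidth probing, plus
additive Gaussian noise clipped at zero conductance and the optional
$V_I$ drift.  Scenario amplitudes default to peak conductances of
0.5–2 nS around the 1.5 nS resting conductance (excitation at the lower
end, for the domain reason above; event decay constants 5–50 ms).
Generators are bit-reproducible from the spec's own seed and restore the
global RNG state.  `cycle_average()` exports the ground truth at probe
resolution — one mean per 5 ms cycle — which is the best any per-cycle
estimator can resolve, and is the reference all recovery statistics use.

What passing these synthetic tests does *not* show: the generator has no
electrode artifacts, no recording noise, no NMDA-type voltage-dependent
conductances (out of scope by design), and the model cell is one fixed
biophysics; real recordings add all of these.

## Reference estimators

The multi-trial continuous method records the same input scenario at two
or more holding currents and solves, per time point, the passive membrane
equation
$C_m \dot V_k = I_{hold,k} + I(t) - (G_L + G(t))(V_k(t) - V_{rest})$
for $(I, G)$ by least squares across trials (central-difference
derivative, zero-phase 2nd-order Butterworth low-pass at 50 Hz by
default, spiking or near-coincident time points flagged and bridged by
interpolation).  On noiseless passive simulations it recovers step inputs
to better than 2 %, which is the package's validation of the re-derived
equations.  The hyperpolarizing pulse-probe estimator reads the total
conductance from steady-state voltage deflections via Ohm's law; its
sampling is limited by the membrane time constant (40 ms pulses here,
12.5 Hz), against the firing clamp's 200 Hz — the analytic bandwidth
ratio of one estimate per 5 ms cycle against the ~100 ms stationarity
window of noise-statistics methods is ≥ 20, and a 1→40 Hz conductance
chirp shows the pulse probe losing the fast half of the sweep while the
per-cycle estimates keep tracking.

## Sizes, tolerances, degenerate inputs

Default problem sizes (also used by the test suite and the acceptance
script, as the package's own choices): 4.2 s of simulated protocol for a
calibration (648 usable cycles), 2–4 s per scenario recording, 0.03 ms
control step throughout.  Numerical tolerances: fixed-point residual
< 1e−6 mV/ms for the resting state; inversion residual < 1e−6 mV;
compose/decompose are exact algebra.  Degenerate inputs fail loudly:
non-finite states name the offending variable, |V_E − V_I| < 1 mV is
rejected as ill-conditioned, nonpositive total conductance stops the
voltage reconstruction, rank-deficient calibration designs and
uncovered control signals are errors.

## Known limitations

* The inhibitory conductance is measured almost purely through shunting
  (3 mV driving force), so its per-cycle estimates are an order of
  magnitude noisier than the excitatory ones; they are faithful for
  theta-band and slower signals but visibly dispersed when the
  excitatory channel fluctuates in the gamma band — the same asymmetry
  the method shows in its original setting.
* Excitatory amplitudes above ≈ 0.65 nS push the composed current out of
  this cell's calibrated domain; estimates there extrapolate and degrade.
* The calibration surface is only as good as its quadratic form; residual
  structure of ~0.2 mV maps to ~0.1–0.2 nS of systematic conductance
  error along scenario trajectories.
* One compartment, two conductances, voltage-independent synapses —
  multi-compartment cells and NMDA-type input are outside the model by
  construction.

## A minimal session

```{r example}
library(firingclamp)

params <- neuron_params()
cfg <- meander_config()
rev <- reversal_spec(V_0_mV = params$V_rest_mV)

surface <- calibrate_firing_clamp(params, cfg)

scenario <- scenario_spec(E = sc_sinusoid(40, 0.3), I = sc_sinusoid(6, 1.5),
                          seed = 1)
gen <- generate_scenario(scenario, duration_ms = 2000)
run <- run_firing_clamp(params, cfg, to_control_signals(gen, rev), 2000)
est <- estimate_pipeline(run$trace, run$markers, surface, rev)

ok <- est$status == "ok"
cor(est$GE_nS[ok], cycle_average(gen$G_E_nS, run$markers)[ok])
```
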