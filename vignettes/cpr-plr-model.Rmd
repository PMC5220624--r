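---
title: "A lumped-parameter model of CPR hemodynamics with passive leg raising"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of CPR hemodynamics with passive leg raising}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

During cardiac arrest, chest compressions are the only source of blood
flow. Passive leg raising (PLR) — elevating the legs above the horizontal —
shifts venous blood from the lower limbs toward the central circulation and
has been proposed as a cost-free adjunct to compression-only CPR. Whether
and how much it helps plausibly depends on the *compression mechanism*: a
"cardiac pump" (the sternum directly squeezes the ventricles) responds to
preload differently than a "thoracic pump" (a global rise of intrathoracic
pressure drives flow). `cprplr` implements a deterministic, closed-loop,
lumped-parameter model designed to interrogate exactly this interaction.

## Model structure

The circulation is fourteen RC compartments (C1–C14) in a closed loop:
right atrium and great veins (C1), right ventricle (C2), pulmonary arteries
(C3, C4), pulmonary veins (C5), pulmonary veins/left atrium (C6), left
ventricle (C7), thoracic aorta (C8), carotid arteries (C9), jugular veins
(C10), abdominal aorta (C11), femoral arteries (C12), femoral veins (C13)
and inferior vena cava (C14). Each compartment stores volume on a linear
capacitance `C_i` (L/mmHg) and discharges through an outflow resistance
(mmHg·s/L); five peripheral beds (head `Rh`, coronary `Rht`, splanchnic
`Rs`, legs `Rl`, pulmonary capillaries `Rpc`) connect the arterial and
venous sides. Six ideal diodes (tricuspid, pulmonary, mitral, aortic,
jugular and femoral-venous valves) enforce one-way flow; inertia is
neglected, appropriate for the low velocities of CPR. Total blood volume is
4.36 L, distributed over the compartments in the cardiac-arrest state.

Compartment pressure is the closed form

\[ P_i = P_0 + \frac{V_i - V_{0,i}}{C_i} + \ell_i P_{lung} + m_i P_M + s_i P_{PLR}, \]

with couplings \(\ell_i\) (1 on chest compartments C1–C8), \(m_i\) (1 on
the ventricles, the thoracic pump factor \(f_{tp}\) on the remaining chest
compartments except the peripheral pulmonary vessels C4/C5, which are
shielded deep in the lung parenchyma) and \(s_i\) (1 on the femoral
compartments C12/C13). Flows are \(\Delta P/R\), clipped at zero on valve
edges. The state integrated through time is the volume vector only; the
pressure is always computed algebraically from it. This is exactly
equivalent to co-integrating incremental pressure updates
\(\Delta P_i = \Delta V_i/C_i + \ldots\) from the arrest equilibrium, but
cannot drift.

Where the published parameterisation lists a zero outflow resistance for
the atria (C1, C6) — atrioventricular filling is nearly unresisted — a
small `epsilon_R` (default 1 mmHg·s/L, configurable) is substituted so the
valve flows stay finite at millisecond steps.

Inter-compartment flow from X to Y uses X's outflow resistance throughout.
The printed equations of the source model family use the upstream
resistance in nine of ten cases; the single downstream exception (the
femoral-artery inflow) is treated as a typographical inconsistency and the
upstream convention applied globally. Either reading leaves one printed
resistance unused, and the series path into each limb bed is dominated by
the much larger bed resistance (`Rl` = 8520, `Rh` = 5520 mmHg·s/L), so the
choice is numerically inconsequential.

The coronary bed is not drawn explicitly in the source topology; it is
connected from the thoracic aorta (C8) to the right atrium (C1) through
`Rht`, the standard arrangement in this model family, which also makes the
coronary perfusion pressure (aortic minus right-atrial) the driving
pressure of the coronary edge. During the compression phase the coronary
bed is pinched shut (`Rht` effectively infinite, zero flow); it conducts
only in the restoring phase. The gate is the instantaneous force exceeding
a threshold of `1e-9` N, i.e. "any compression at all", which with a 50%
duty cycle reproduces the compression/restoring phase split.

## Forcing

Chest compressions are non-overlapping half-sinusoids: amplitude 400 N,
rate 100/min, 50% duty cycle (0.3 s compression, 0.3 s release per 0.6 s
cycle). Force maps linearly to two pressure sources: the intrathoracic
pressure `P_lung = k_lung · F` acting on every chest compartment and the
mediastinal pressure `P_M = k_med · F` acting through \(m_i\). The
coefficients are not identifiable from the network parameters; they are
fixed once by `calibrate_force_coupling()`, a one-dimensional root search
(monotone in the common scale, bisected on the log scale) that makes the
steady-state cardiac output at \(f_{tp} = 0.75\), no PLR, equal the
published 1.30 L/min. The calibrated value, `k_lung = k_med =
0.0545444539` mmHg/N, ships as the package default.

The split `k_med/k_lung` is not identifiable from the single flow anchor
and is exposed in the configuration (default ratio 1.0). We examined
ratios 1–10, each re-calibrated to the same anchor: the absolute baseline
flows across pump factors match the published reference table best at
ratio 1 (e.g. CO 2.09/1.56/1.05 L/min at \(f_{tp}\) = 0/0.5/1 against the
reference 2.0/1.5/1.1), and the PLR response turns out to be essentially
invariant to the ratio, so nothing else constrains it. Ratio 1.0 is
therefore the default.

Leg raising adds the hydrostatic pressure of the elevated blood column,
\(P_{PLR} = \rho g (l/2) \sin\alpha\) (blood density 1060 kg/m³, g =
9.8 N/kg, leg length l = 0.79 m, centre of gravity at the column
mid-point), converted at 133.322 Pa/mmHg — 30.78 mmHg at 90°. The same
pressure applies to the femoral arterial and venous compartments, as a
step at 20 s by default; a linear ramp is available for sensitivity
checks but the reference protocol is the instantaneous step.

## Solver and numerical choices

Classic fixed-step fourth-order Runge–Kutta at `dt` = 1 ms over 40 s, the
reference solver configuration of this model family. The diode
discontinuities are evaluated directly inside the RK4 stages with no event
location; at 1 ms steps the valve-switching error is far below the
reported precision, which the test suite confirms by agreement (within 2%
on cycle-averaged cardiac output) with the explicit incremental-update
(Euler) scheme, and by an independent integration of the same right-hand
side with `deSolve`. The integrator itself is validated against the
closed-form relaxation of a two-RC-compartment loop (time constant
\(RC_1C_2/(C_1+C_2)\), matched within 1%).

Uniform initial pressure `P0` (default 7 mmHg, the mean circulatory
filling pressure of the arrest state) makes the initial condition an exact
equilibrium: with zero forcing the state is preserved to better than
1e−9 L over 5 s. Because every flow depends only on pressure differences,
`P0` shifts reported absolute pressures (relevant to the pulmonary-oedema
check) but not flows. Volume conservation is exact by construction — each
directed edge appears once as inflow and once as outflow — and is asserted
to 1e−6 L on every trace.

## Metrics and windows

`summarize_window()` reduces a trace over a window that should span whole
0.6 s cycles and lie beyond the initial transient: cardiac output (mean
aortic-valve flow, L/min), coronary perfusion pressure (mean aortic minus
right-atrial pressure over restoring-phase samples — the standard CPR
definition; the source material never defines its CPP formula), coronary
and head-bed flows (mL/s), regional leg/abdominal volumes (mL), and mean
peripheral pulmonary venous pressure (the pulmonary-capillary surrogate
screened against the 25–30 mmHg plasma colloid osmotic band, conservative
end as default threshold). `compare_plr()` uses windows \[10, 20\] s
(pre-PLR; the model is periodic to within 0.5% per cycle after 8 s) and
\[30, 40\] s (post-PLR), symmetric 10 s windows around the 20 s maneuver.
Head and coronary flows are reported in mL/s and cardiac output in L/min;
the reference table's units are unprinted, and this mixed reading is the
one that makes its magnitudes physiologically coherent.

## What the model does and does not reproduce

Everything quantitative below is computed by the test suite and the
acceptance script; problem sizes are the reference ones (40 s at 1 ms;
12 s runs for pure property checks).

Reproduced well:

* the calibrated baseline (CO 1.30 L/min at \(f_{tp} = 0.75\)) and the
  decline of baseline flow with the thoracic pump factor — absolute CO and
  coronary flow across \(f_{tp} \in \{0, 0.5, 1\}\) land within 15% of the
  published reference values, head flow within 25%;
* the direction of every PLR effect: blood leaves the legs, abdominal and
  thoracic volumes rise, cerebral flow increases at every pump factor;
* transfer volume growing with elevation angle at a diminishing marginal
  rate, and the post-PLR abdominal volume (within 2% of the reference
  2186 mL);
* pulmonary safety: mean peripheral pulmonary venous pressure stays below
  25 mmHg over the whole pump-factor × angle grid.

Not reproduced — and, as far as we can determine, not reproducible from
the printed equations:

* the magnitude of the PLR volume shift: the hydrostatic formula moves
  \(\approx (C_{12}+C_{13}) \cdot P_{PLR} \approx 143\) mL at 90°
  (34% of leg volume) against the reference 205 mL (49%). The reference
  run displays applied femoral pressures of 109/43 mmHg — 3.5× and 1.4×
  its own hydrostatic formula; injecting those values reproduces the
  reference volumes almost exactly, but they are inconsistent with the
  stated formula and are not used;
* the reference percent *flow* changes (+9% CO, +9–15% head flow, +17%
  coronary flow at mid pump factor). In this network the shifted volume
  raises all compartment pressures nearly uniformly (≈ +2 mmHg), uniform
  offsets cancel in every pressure gradient, and the simulated flow
  changes are below 1% — for every pump factor, every coupling ratio, and
  even with the larger injected femoral pressures. Reproducing
  preload-sensitive flow would require a nonlinearity absent from the
  printed equations (e.g. pressure-dependent compliances, venous
  collapse, or volume-limited ventricular emptying).

The corresponding acceptance checks are left failing rather than fitted;
the package reports what the stated model actually predicts.

## Using the package

```{r}
library(cprplr)

params <- cpr_parameters(tpf = 0.75)
protocol <- cpr_protocol(plr_angle_deg = 90)  # PLR at 20 s

cmp <- compare_plr(params, protocol)
cmp
leg_volume_transfer(cmp)

sw <- tpf_sweep(c(0, 0.25, 0.5, 0.75, 1), angle_deg = 90)
plot(sw)

grid <- edema_grid(tpfs = c(0, 0.5, 1), angles_deg = c(0, 45, 90))
attr(grid, "max_p_ppv")
```

Runs are configured either programmatically or through a YAML file
(`load_config()`, `save_config()`); the bundled
`inst/extdata/default-config.yaml` reproduces the reference
parameterisation exactly. A thin command-line front end with subcommands
`simulate`, `compare`, `sweep-tpf`, `sweep-angle`, `edema-grid`, `table3`
and `calibrate` is installed at
`system.file("cli", "cprplr", package = "cprplr")`.

## Known limitations

No respiratory system or gas exchange (the end-tidal CO₂ link is the
external linear bridge `petco2_from_co_change()`, nothing more), no
baroreflex, no venous collapse or other pressure-dependent compliances, no
compression-depth model (force is the input), and a single "average adult"
anthropometry. The model is deterministic: there is no randomness anywhere
in the artifact, and repeated runs are bit-identical.
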