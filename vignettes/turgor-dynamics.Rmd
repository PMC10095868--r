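---
title: "Guard-cell turgor dynamics from prescribed water influx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guard-cell turgor dynamics from prescribed water influx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guardcellsim)
```

## The question the model answers

Stomatal pores open when their flanking guard cells swell. The textbook
narrative makes turgor pressure the driver: solutes accumulate, water
follows, turgor rises, and the pressurized cell deforms its wall. But
turgor, volume and water content are linked by an elementary constraint —
the bulk-modulus relation of the intracellular liquid — under which a cell
that *expands* should, if anything, *lose* pressure unless more water keeps
arriving. `guardcellsim` takes the complementary view: the cumulative
osmotic water influx $W(t)$ is prescribed as the driving input, and turgor
is an emergent output of the interaction between the compressible fluid and
the mechanical response of the wall. The package simulates that interaction
for four wall rheologies (soft, rigid, linear elastic, viscoelastic) and two
influx shape families, and summarizes the resulting turgor/volume
trajectories.

## Governing relations

**Fluid.** A water volume $V_0 + W(t)$ (initial lumen volume plus cumulative
influx), confined at pressure $p$, occupies
$(V_0 + W)\,(1 - p/K)$, with $K$ the bulk modulus of the intracellular
liquid (default $K = 2{,}200$ MPa, liquid water near 20 °C).

**Wall.** The lumen is a thin-walled cylinder, internal diameter $d$, wall
thickness $t_w$. For a homogeneous, isotropic, linear elastic wall the
volumetric compliance — fractional lumen-volume gain per unit internal
pressure — is

$$C \;=\; \frac{d\,(5 - 4\nu)}{4\,t_w\,E} \qquad [\mathrm{MPa}^{-1}],$$

the thin-cylinder result combining hoop and axial strains. A rigid wall is
the limit $E \to \infty$ ($C = 0$); a soft wall is the limit $E \to 0$, in
which the cell simply takes the volume of its contents and $p \equiv 0$.

**Viscoelastic wall.** Plant cell walls — stiff cellulose microfibrils in a
hydrated pectin/hemicellulose matrix — creep. We use a standard linear
solid: an instantaneous elastic response with modulus $E_\mathrm{inst}$ in
series with a Kelvin (spring ∥ dashpot) branch, so the delayed volumetric
strain $\varepsilon_c$ relaxes toward $C_\mathrm{delay}\,p$ with retardation
time $\tau$:

$$\varepsilon_c(t) \;=\; C_\mathrm{delay}\,p\,\bigl(1 - e^{-t/\tau}\bigr)
\quad\text{(constant } p\text{)}, \qquad
C_\mathrm{delay} = C_\mathrm{eq} - C_\mathrm{inst},$$

where $C_\mathrm{inst}$ and $C_\mathrm{eq}$ are the compliances evaluated at
$E_\mathrm{inst}$ and the equilibrium modulus $E_\mathrm{eq}$. We chose the
standard linear solid over a pure Kelvin–Voigt element because measured
guard-cell walls resist instantaneous deformation with a finite (large)
modulus and relax toward a much smaller equilibrium modulus; a pure
Kelvin–Voigt wall is recovered by making $E_\mathrm{inst}$ effectively
infinite.

**Mass balance.** At every instant the pressurized water fits exactly into
the deformed lumen:

$$(V_0 + W)\left(1 - \frac{p}{K}\right)
 \;=\; V_0\,\bigl(1 + C_\mathrm{now}\,p + \varepsilon_c\bigr),$$

with $C_\mathrm{now}$ the elastic (or instantaneous-branch) compliance. The
closed-form solution used at each step is

$$p \;=\; \frac{(V_0 + W) - V_0\,(1 + \varepsilon_c)}
               {(V_0 + W)/K + V_0\,C_\mathrm{now}},$$

floored at zero. Note that the fluid is compressed at its *current* total
volume $(V_0+W)$ rather than via a first-order $pV_0/K$ term; the difference
is second order in $p/K$. Pressures are gauge pressures relative to the
closed state (the initial turgor of the closed cell is not modelled); an
additive baseline `baseline_p0_MPa` (default 0) can shift the reported
values.

## Influx schedules

Two families are motivated by osmotic physiology, plus a utility third:

* `mb_cdf` — CDF of the Maxwell–Boltzmann speed density
  ($\propto x^2 e^{-x^2/2}$): cubic onset, then rapid rise, then
  saturation. This is the "diffusive" S-curve with an initial lag.
* `sat_exp` — $1 - e^{-t/a}$: maximal rate at $t=0$, no lag
  ("logarithmic-growth" pattern).
* `logistic` — symmetric sigmoid, for sensitivity studies.

Each raw curve is min–max normalized on $[0, T_\mathrm{influx}]$ and clamped
afterwards, so $W(0) = 0$ and $W(t \ge T_\mathrm{influx}) = \Delta V$ hold
*exactly*. The default scale constants ($T/6$, $T/5$, $T/10$) put ≥ 99 % of
the raw curve inside the window, keeping normalization a small correction.
The clamp makes $W$ continuous but not differentiable at
$T_\mathrm{influx}$; `influx_rate()` returns the left-hand derivative there
and 0 beyond, and trapezoid integration of the rate reproduces the
cumulative curve to better than $10^{-6}$ relative on $[0, T_\mathrm{influx}]$.

```{r influx}
s <- influx_schedule("mb_cdf", dv_total = 912, t_influx = 3600)
cumulative_volume(s, c(0, 180, 1800, 3600, 10000))
```

## Parameters, defaults and provenance

| key | default | units | meaning |
|---|---|---|---|
| `sim.v0_um3` | 3,691 | µm³ | closed-state lumen volume (3-D confocal measurement of *Arabidopsis* guard cells) |
| `influx.dv_total_um3` | 912 | µm³ | open − closed volume (4,603 − 3,691) |
| `influx.t_influx_s` | 3,600 | s | time to approach maximal stomatal conductance |
| `sim.dt_s` | 1 | s | step small enough that influx, deformation and pressure change are effectively simultaneous |
| `fluid.K_MPa` | 2,200 | MPa | bulk modulus of water near 20 °C |
| `wall.d_um`, `wall.t_w_um` | 10, 0.5 | µm | cylinder geometry (order of guard-cell dimensions) |
| `wall.nu` | 0.3 | — | Poisson's ratio of the wall composite |
| `wall.E_MPa` | 100 | MPa | elastic modulus; with the geometry above, calibrated so the coupled final turgor is ≈ 1.3 MPa, the order of probe-measured guard-cell turgor |
| `wall.E_eq_MPa` | 77 | MPa | equilibrium modulus; gives a relaxed turgor ≈ 1 MPa |
| `wall.E_inst_MPa` | 10,000 | MPa | instantaneous modulus, see below |
| `wall.tau_s` | 6,000 | s | retardation time, 100 min — the timescale over which stomatal opening completes |
| `sim.t_total_s` | 7,200 / 18,000 | s | horizon; the longer value (viscoelastic default) lets relaxation with τ = 100 min visibly complete |

Geometry and moduli are *calibrated, not measured*: they are chosen so the
model reproduces turgor levels of the right order, and every one of them is
a config key.

**The instantaneous modulus and the peak-turgor ceiling.** One might hope to
calibrate $E_\mathrm{inst}$ against a very large transient turgor peak.
Under a pressure-driven creep law this is impossible beyond a ceiling: once
the delayed strain couples to pressure, the gap
$C_\mathrm{delay}p - \varepsilon_c$ relaxes with the *effective* time
constant $\tau_\mathrm{eff} = \tau D / (D + C_\mathrm{delay} V_0)$, where
$D = (V_0+W)/K + V_0 C_\mathrm{inst}$, which is two orders of magnitude
shorter than $\tau$ for realistic parameters. The quasi-steady peak is then
bounded near

$$p_\mathrm{peak} \;\lesssim\; p_\mathrm{eq} +
  \frac{\dot W_\mathrm{max}\,\tau}{C_\mathrm{delay}\,V_0},$$

which is independent of $E_\mathrm{inst}$ once $E_\mathrm{inst}$ is large
(the $D$ factors cancel) — about 8–9 MPa under the default influx
conditions. `calibrate_modulus()` therefore reports a bracketing error for
peak targets above this ceiling rather than returning a spurious modulus.
The default $E_\mathrm{inst} = 10$ GPa is the upper end of the physically
plausible 1–10 GPa range for instantaneous wall stiffness, where the
simulated peak comes closest to large reported transients while leaving all
long-time behaviour governed by $E_\mathrm{eq}$. Reproducing transient peaks
of several tens of MPa would instead require a *clock-driven* creep law,
$\varepsilon(t) = \varepsilon_\infty (1 - e^{-t/\tau})$ with
$\varepsilon_\infty$ fixed by the full opening volume — a prescribed-strain
wall rather than a pressure-driven one; that variant is deliberately out of
scope because it decouples wall strain from the load.

## Numerical choices

* **Per-step solve.** The mass balance is affine in $p$, so the closed form
  is exact (`solver = "closed_form"`, default; residual at machine
  precision). The alternative `fixed_point` solver performs relaxed
  successive substitution on
  $p \leftarrow K\,[W - V_0 (C_\mathrm{now} p + \varepsilon_c)]/(V_0+W)$
  with relaxation $\omega = 1/(1+\lambda)$,
  $\lambda = K V_0 C_\mathrm{now}/(V_0+W)$. The undamped substitution
  diverges whenever $\lambda > 1$ (it is ≈ 335 for the default elastic
  parameters); with this $\omega$ the affine iteration lands on the root in
  one step and the loop certifies convergence to `sim.tol` (default
  $10^{-9}$). Tests assert the two solvers agree to $10^{-9}$.
* **Creep integration.** Substituting the pressure solve into the creep law
  gives a scalar linear ODE
  $\dot\varepsilon_c = (u(t) - m\,\varepsilon_c)/\tau$ with
  $u = C_\mathrm{delay} W/D$ and $m = 1 + C_\mathrm{delay}V_0/D$.
  `run_simulation()` advances it with the exponential integrator that is
  *exact for influx varying linearly across the step* (exponential-kernel
  weighting of the forcing). Consequences verified by tests: halving `dt`
  moves the default viscoelastic trajectory by ~$10^{-5}$ relative
  (sup-norm), and the $\tau \to 0$ limit reproduces the elastic run at
  $E_\mathrm{eq}$ to $<10^{-3}$ MPa at `dt = 1`. The exported
  `creep_step()` keeps the frozen-pressure exponential update, which is the
  exact constant-load solution (one step of length τ covers $1 - e^{-1}$ of
  the gap; two half-steps equal one full step exactly).
* **The τ → ∞ limit is approached at rate 1/τ.** Over a horizon $T$ a
  finite τ accumulates $\varepsilon_c(T) \approx
  (C_\mathrm{delay}/\tau)\int p\,\mathrm dt$, so the sup-norm deviation
  from the elastic-at-$E_\mathrm{inst}$ trajectory is $\mathcal O(1/\tau)$ —
  about $6\times10^{-2}$ MPa at $\tau = 10^9$ s and $6\times10^{-5}$ MPa at
  $\tau = 10^{12}$ s for the 7,200-s default horizon. Tests assert the
  $1/\tau$ scaling and the $\tau = 10^{12}$ agreement.
* **Degenerate inputs and tie-breaks.** Pressure is floored at 0 (monotone
  influx never produces suction; the floor guards pathological
  configurations). The peak time `t_peak` is the *first* attainment of the
  maximum, so an elastic run under a clamped schedule reports
  `t_peak = t_influx`, where the plateau begins. The soft wall bypasses all
  compliance arithmetic (its compliance is a documented `Inf` sentinel;
  callers branch on the model, never on the numeric value).
* **Step ordering.** Within each step: evaluate $W$, solve the quasi-static
  pressure with the current $\varepsilon_c$, record, then advance the creep
  over `dt`. Because the creep advance integrates the coupled system, the
  ordering has no first-order effect — which the `dt`-refinement test
  confirms.

## What the schedules emulate — and what they do not

The influx schedules are the package's synthetic driving data. They emulate
the two qualitative influx patterns osmosis can plausibly produce (lagged
S-curve vs immediate saturating uptake) at the measured total volume gain
and a realistic opening duration. They do **not** emulate: osmotic feedback
(influx responding to the evolving pressure — here $W(t)$ is strictly
prescribed), solute transport and aquaporin kinetics, water efflux and
closure, or cell-to-cell water exchange. Passing tests therefore
demonstrate the mechanical consequences of a *given* influx, not a
prediction of influx itself.

Other structural limitations: the wall is isotropic and spatially lumped (no
anisotropic, finite-element wall), moduli are constant in time, the pore
aperture is not modelled (outputs are turgor and volume, not pore size), and
the closed-state absolute turgor enters only as an optional additive
baseline.

## The eight canonical scenarios

```{r presets}
sc <- load_config(overrides = preset_overrides("fig1d")) # elastic, S-curve
tr <- run_simulation(sc$cfg, sc$schedule, sc$wall, sc$fluid)
summarize_trajectory(tr)
```

Soft and rigid walls bracket the behaviour: the soft wall converts all
influx into volume (final volume exactly 4,603 µm³, turgor flat), the rigid
wall converts it all into pressure (hundreds of MPa — two to three orders
of magnitude above measured turgor). The elastic wall lands at ≈ 1.3 MPa,
the measured order, *independently of the influx shape* (the closed form
has no history dependence). The viscoelastic wall is the only one producing
a non-monotonic trace: an early peak whose height depends on the early
influx rate, then relaxation toward the equilibrium-modulus endpoint
≈ 1 MPa. Simulation horizons are 7,200 s (soft/rigid/elastic) and 18,000 s
(viscoelastic), sizes chosen so every scenario completes in well under a
second at `dt = 1` while the slowest relaxation visibly finishes.
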