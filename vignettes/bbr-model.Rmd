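---
title: "The deterministic polyvalent burnt-bridge ratchet model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The deterministic polyvalent burnt-bridge ratchet model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A burnt-bridge ratchet (BBR) is a motor that rectifies thermal
fluctuations by consuming its own track: it binds substrate "bridges",
destroys them, and is biased forward by the asymmetric substrate
landscape left in its wake.  `bbrmotor` models a *polyvalent* BBR — a hub
with many simultaneous attachment sites, such as a bead coated with
enzymes moving over a lawn of surface-tethered substrate — in one
dimension, deterministically, through three coupled equations.

Substrate exists in three pools: surface-bound at line concentration
$A_s(X)$, hub-bound complex $A_c(X)$, and free in a well-mixed buffer.
Each bound complex tethers the hub through the entropic elasticity of the
surface polymer, a linear spring of stiffness $k = k_BT/\sigma^2$ where
$\sigma$ is the tether's rms fluctuation length.  In the overdamped
regime the drag force balances the total elastic force:

$$\gamma \frac{dX_h}{dt} = -\int k\,(X_h - X)\, A_c(X)\, dX.$$

A tether at distance $X - X_h$ must fluctuate across the elastic energy
$\tfrac{1}{2}k(X-X_h)^2$ to reach the hub, so complex forms with
Arrhenius-suppressed rate $r\,e^{-\beta k (X-X_h)^2/2} A_s$.  Bound
substrate is burned (destroyed and released to the buffer) at rate $\nu$,
and may also dissociate back to the surface at a force-dependent
Bell rate $\omega\, e^{\beta k |X_h - X| \Delta}$, where $\Delta$ is the
distance between the bound and unbound states along the unbinding
coordinate.  The surface pool exchanges with the buffer (unbinding rate
$k_\mathrm{off}$, rebinding rate $k_\mathrm{on}$); because the buffer is
well mixed and large, its rebinding flux is the constant
$k_\mathrm{off} A_\mathrm{tot} / (1 + K)$ with
$K = k_\mathrm{off}/k_\mathrm{on}$.

Non-dimensionalizing by the length $\sigma$, the time $1/r$, and the
reference concentration $a_0 = \gamma r \sigma / k_BT$ gives the system
the package integrates:

$$\frac{dx_h}{d\tau} = -\int (x_h - x)\, a_c(x)\, dx,$$
$$\frac{da_c}{d\tau} = e^{-(x - x_h)^2/2} a_s - \nu' a_c
  - \omega' e^{\delta |x_h - x|} a_c,$$
$$\frac{da_s}{d\tau} = \frac{k_\mathrm{off}' a_\mathrm{tot}}{1 + K}
  - k_\mathrm{off}' a_s - e^{-(x - x_h)^2/2} a_s
  + \omega' e^{\delta |x_h - x|} a_c.$$

Four dimensionless control parameters govern the motion: the substrate
concentration $a_\mathrm{tot}$, the burn rate $\nu'$, and the turnover
pair $(k_\mathrm{off}', K)$; the unbinding pair $(\omega', \delta)$ and
the free energy per burned substrate $\Delta g$ complete the set.
`to_dimensionless()` and `from_dimensionless()` convert between this
parameterization and dimensional quantities (pN, nm, s, µm⁻¹; SI
internally), and are exact inverses.  With the default
$k_\mathrm{on} = r$, $K = k_\mathrm{off}'$.

The Stokes efficiency compares the power dissipated against drag with
the rate of chemical free-energy consumption,

$$\eta = \frac{\gamma V^2}{B} = \frac{v^2}{\Delta g\, b},
\qquad b = \nu' \int a_c(x)\, dx,$$

where $b$ is the dimensionless substrate consumption rate.  A stalled hub
($v = 0$) has $\eta = 0$ by definition even though it keeps burning
substrate through surface turnover.

## Parameters that matter

| Parameter | Meaning | Units | Default | Why |
|---|---|---|---|---|
| `atot` | total substrate | $a_0$ | 1 | order-one coverage; $a_0 \approx 10\,\mu m^{-1}$ for a 1 µm bead at $r = 20\,s^{-1}$, $\sigma \approx 100$ nm |
| `nu_p` | burn rate | $r$ | 1 | enzymatic burning comparable to binding ($\nu \sim r \sim 20\,s^{-1}$) |
| `koff_p`, `K` | surface turnover | $r$, — | 0.01 | slow turnover: tether exchange ~100× slower than binding |
| `omega_p` | complex dissociation | $r$ | 0 | irreversible binding unless studied |
| `delta` | Bell distance | $\sigma$ | 0 | force-independent unbinding unless studied |
| `dg` | energy per substrate | $k_BT$ | 15 | hydrolysis-scale free energy |

## Numerical scheme

**Method of lines.**  The fields are discretized on a fixed uniform grid
with spacing $0.1\sigma$, which resolves the unit-width Gaussian kernel;
the hub position is a continuous coordinate, never snapped to the grid.
The coupled ODE system is integrated with an adaptive
Dormand–Prince 4(5) pair (`deSolve::ode`, method `"ode45"`) with
per-step error control at `rel_tol = 1e-6`, `abs_tol = 1e-9` by default.
The right-hand side is evaluated in compiled C in the `deSolve`
compiled-model convention; a pure-R `rhs()` is the reference
implementation, and the test suite integrates both through the same
solver and requires matching trajectories.

**Quadrature.**  Force and consumption integrals use the rectangle rule
at the grid spacing (trapezoid optional).  The integrands decay like the
Gaussian kernel, so low-order quadrature at $\Delta x = 0.1\sigma$ is
spectrally accurate in practice: the stalled consumption computed on the
grid agrees with adaptive quadrature of the closed form to machine
precision.

**Exact symmetry preservation.**  The uniform stalled state is a genuine
*unstable equilibrium*: any asymmetry grows into spontaneous motion.
Naive floating-point summation of the force integral seeds this
instability at round-off and a long stall run eventually takes off on its
own.  The package therefore builds grid nodes as exact mirror pairs about
the domain centre and accumulates the force integral over mirror pairs,
so an exactly symmetric state yields exactly zero force and a hub started
at the centre of a symmetric state remains stationary for all time.  This
matters for stalled-consumption measurements, which need ~600–800 τ of
relaxation (the surface field equilibrates on the slow turnover timescale
$1/k_\mathrm{off}' = 100$ τ); those runs also use tighter solver
tolerances (`rel_tol = 1e-8`) because at the defaults the sampled
consumption wanders by ~$10^{-3}$ relative around the fixed point.

**Bounding the Bell-term stiffness.**  With $\omega' > 0$ and
$\delta > 0$ the unbinding rate $\omega' e^{\delta |x_h - x|}$ grows
without limit far from the hub, while the complex held there is
kernel-suppressed to negligible mass (the formation rate falls like
$e^{-d^2/2}$).  Those far nodes sit at tiny quasi-equilibria with
arbitrarily fast relaxation rates — stiffness that serves no purpose but
stalls an explicit solver.  The force-amplified rate is therefore capped
at a ceiling (`bell_rate_cap`, default 500 in formation-rate units,
i.e. $10^4\,s^{-1}$ at $r = 20\,s^{-1}$ — instantaneous relative to every
other process in the model).  The cap only binds where
$\delta|x_h - x| > \ln(500/\omega')$, where the kernel factor has already
suppressed the complex by many orders of magnitude; its relative effect
on steady-state observables at the defaults is below $10^{-5}$, and runs
agree with an implicit-solver cross-check to solver tolerance.  Users
studying $\delta \gtrsim 2$ should verify insensitivity by doubling the
cap.

**Domain and boundaries.**  No boundary condition is imposed: the fields
relax exponentially to their bulk values away from the hub, so a long
fixed domain (default $50\sigma$ behind, $300\sigma$ ahead, at least
$40\sigma$ total) makes edge effects negligible.  The run aborts with a
flag if the hub comes within `boundary_margin` (default $10\sigma$) of
either edge; `run_single()` then retries with a doubled forward domain.

**Symmetry breaking.**  Motion is initiated by a triangular (V-shaped)
notch in the surface field behind the hub — default width $10\sigma$,
reaching zero at its centre — emulating a patch of consumed track.
Steady-state results are insensitive to the notch shape (halving its
width changes $v_{ss}$ by well under 1%), so only its symmetry-breaking
role matters.

**Steady-state detection.**  The run proceeds in windows of 50 τ; it is
converged when the windowed means of $v$ and $b$ change by less than
$10^{-3}$ relative between consecutive windows (with an absolute floor of
the stall tolerance, $10^{-4}\,\sigma/\tau$, so stalls compare on an
absolute scale).  A converged run with $|v_{ss}|$ below the stall
tolerance is stalled; a run still decaying at the horizon is reported
`converged = FALSE` and never extrapolated — in sweeps such rows are
flagged and excluded from summaries unless their final velocity already
sits below the stall tolerance.

## What the sweeps emulate — and what they do not

The sweep drivers reproduce the model's characteristic phenomenology at
desk scale: the transient velocity spike and plateau of a single run; the
interior optimum of $v_{ss}$ over $\nu'$ at fixed $a_\mathrm{tot}$
(too-slow burning never builds a gradient, too-fast burning strips
complex); saturation of $v_{ss}$ in $a_\mathrm{tot}$ as the growing wake
pulls back; $b \approx \mathrm{slope}\cdot v + b_\mathrm{stall}$
linearity, which makes $\eta \sim v$ so velocity and efficiency peak at
the same $\nu'$; the interior efficiency optimum in the
$(\nu', a_\mathrm{tot})$ plane, whose height falls and whose position
moves outward as turnover $k_\mathrm{off}'$ grows; and the efficiency
benefit of moderate complex unbinding at high substrate but not at low.
Default sweep resolutions are coarse (6–9 points per log axis) with the
axis ranges chosen so these features are strictly interior where the
theory says they are; the resolution is a flag away from denser grids.

This is a deterministic mean-field description.  It does not capture
discrete-substrate stochasticity (important at low $a_\mathrm{tot}$ and
$\nu'$, where fluctuations favour diffusive rather than directed motion),
near-wall hydrodynamic corrections to the constant drag coefficient,
two- or three-dimensional geometry, or explicit buffer dynamics (the
buffer is folded into the constant rebinding source).  Passing tests
therefore validate the deterministic model's behaviour, not those
regimes of real BBRs.

## Problem sizes

The test-suite and acceptance computations use: single runs on a
$[-50, 300]\,\sigma$ domain at $\Delta x = 0.1\sigma$ (3501 nodes) to at
most 500 τ with early exit at the plateau (typically 150–250 τ); stalled
runs on a symmetric $[-30, 30]\,\sigma$ domain to 600–800 τ; a 9-point
$\nu'$ scan; a $6 \times 6$ log-spaced $(\nu', a_\mathrm{tot})$
efficiency map per turnover rate; and a 6-point $\omega'$ scan at two
substrate concentrations.  On one CPU the whole suite runs in about
three minutes.

## A worked run

```{r example}
library(bbrmotor)

params <- dimensionless_params(atot = 1, nu_p = 1, koff_p = 0.01)
row <- run_single(params, keep_trajectory = TRUE)
row[, c("v_ss", "b_ss", "eta", "converged")]

traj <- attr(row, "trajectory")
plot_velocity_trace(traj)

# compare the stalled branch against the closed-form oracle
oracle <- stalled_consumption_oracle(params)
stall <- run_single(params, well_depth_fraction = 0,
                    domain_behind = 30, domain_ahead = 30,
                    settings = integration_settings(tau_end = 800,
                                                    rel_tol = 1e-8,
                                                    abs_tol = 1e-11,
                                                    steady_rel_tol = 1e-6))
c(simulated = stall$b_ss, oracle = oracle)
```
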