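---
title: "A reduced-order model of the calf muscle venous pump"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of the calf muscle venous pump}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venapump)
```

## The physiological problem

In the upright posture, venous blood in the lower leg must climb roughly
130 cm against gravity. Two mechanisms drive it: the residual pulsatile
push of arterial pressure transmitted through the capillary bed, and the
calf muscle pump — rhythmic compression of the deep veins (typically the
posterior tibial vein) during walking, rectified into heart-ward flow by
one-way venous valves. When those valves become incompetent (fail to
close), part of each stroke refluxes back down during muscle relaxation
and the pump loses efficiency; the ejection fraction of the calf venous
compartment is the standard clinical index of that loss.

`venapump` models this system as a reduced-order (transmission-line)
hydraulic network: a single artery descending from the heart, a porous
(Darcy) interface standing in for arterioles and capillaries, and a single
deep vein ascending back, with a 30 cm prescribed-motion calf trunk guarded
by two ball check valves. All reported observables — cross-section
integrated flows, point pressures, per-cycle volumes, ejection fraction —
are one-dimensional quantities, which is why the 1-D idealization can stand
in for a full 3-D simulation of the same circuit.

## Circuit geometry and friction calibration

The loop has two 130 cm arms. The aorta occupies the top 10 cm of the
arterial arm (0.04 cm lumen), the arterial segment the remaining 120 cm
(0.08 cm); the venous arm is 0.5 cm throughout, split into a foot vein
(0–10 cm), the deformable calf trunk (10–40 cm) and the upper vein
(40–130 cm). The diameters are deliberately non-physiological scale-model
values chosen by the continuity equation `A v = const` so that each vessel
type carries its textbook mean velocity at a common volumetric flow; the
reference flow is the venous value

```{r}
q_ref <- pi * 0.25^2 * 0.25   # lumen area x 0.25 cm/s
q_ref
```

Fully developed Poiseuille friction is inconsistent with those diameters:
a 120 cm tube of 0.08 cm lumen would by itself drop several hundred mmHg
at `q_ref`, while the resting pressure table the model must reproduce
assigns the whole arterial arm only 5 mmHg (100 mmHg at the aortic inlet,
95 mmHg in the arteries at the feet). The canonical circuit therefore
treats the clinostatic pressure table as the calibration surface: segment
resistances are scaled so that, at `q_ref`, the arterial arm drops 5 mmHg
(Poiseuille weighting preserved between aorta and artery), the porous
interface drops 80 mmHg (95 → 15), and the venous arm drains its 15 mmHg.
The calf and upper vein keep their analytic Poiseuille values (so that calf
friction responds to wall motion) and the remainder of the venous drop is
lumped into the foot vein, where the microvenous drainage of the foot
physically sits. `poiseuille_resistance()` remains the default closure for
uncalibrated circuits.

Probe stations follow the observation points of the circuit: I aortic
inlet, II artery at the feet, III vein at the feet (elevation 0), IV
upstream of the distal valve at the ankle (10 cm), V downstream of the
proximal valve at the knee (40 cm), VI the vena-cava outlet. Placing III
at the feet and the calibrated venous resistance below the ankle makes the
same configuration reproduce both the clinostatic feet-level venous
pressure (~15 mmHg) and the orthostatic ankle pressure (~91 mmHg printed;
the model gives ~94 mmHg = 120 cm of blood column plus the drainage drop).
An alternative layout with III at the ankle and the venous resistance
spread along the whole venous arm reproduces the feet-level value but puts
the ankle pressure near 107 mmHg, and it also throttles the calf's upward
stroke; the adopted layout is both more faithful to the probe definitions
and hydraulically neutral for the pump.

## Forcing

The aortic inlet imposes `p(t) = 100 + 20 sin(2 pi t / T)` mmHg with
`T = 1` s (80/120 diastolic/systolic); the outlet is held at 0 mmHg (vena
cava). Gravity enters through the piezometric head `p + rho g z`, so in a
rigid loop it cancels around the circuit — which is why resting flows are
identical lying and standing, and why the solver treats posture purely
through the reported pressures.

Walking is a prescribed radial wall velocity on the calf trunk,
`v_r(z, t) = a pi sin(pi (z - z0)/L) * sin(2 pi t / T0) / T0`, positive
inward during the first half-cycle (muscle systole under weight-bearing),
outward during the second (relaxation and refill). The axial half-sine
vanishes at the valve housings; the net wall displacement over a full cycle
is zero. The swept volume per systole has the closed form `4 R a L`.

The one genuinely ambiguous constant is the motion amplitude: the source
model prints a bare `2.2e-5` with no resolvable unit, and no unit choice
reproduces the published stroke output. The law is therefore
reparameterized by the physically meaningful peak radial displacement `a`
at the segment mid-point, and the canonical value is calibrated once:
`a = 5e-3` cm (50 µm) makes the swept volume per systole

```{r}
swept_volume_half_cycle(wall_motion_law(5e-3, 10, 30, 1), radius_cm = 0.25)
```

which together with the resting arterial throughput of ~0.05 mL/cycle was
intended to compose the published healthy walking output of 0.2 mL/cycle.
How much of that composition survives strict mass conservation is
discussed below.

## Ball valve model

Each valve is a 0.52 cm rigid sphere in a 0.50 cm seat. The ball travels
0.5 cm between a cage stop (fully open; effective orifice = seat lumen
area, the limiting section) and a seat stop. The seat stop leaves a
residual gap: 0.016 cm for a competent valve, ~0.2 cm when travel is
restricted to model incompetence. Severity grades: `healthy` (both gaps
0.016 cm), `severe` (both 0.2 cm), `partial` (distal 0.2 cm, proximal
competent).

Seated at the competent gap the valve still leaks through ~1% of its open
area; the leak area scales linearly with the gap (12.5% at 0.2 cm, capped
at 100%). Two loss terms act on the valve edge:

* a quadratic orifice loss `(rho/2) (Q/A_eff)^2`, the standard inertial
  orifice closure — dominant when the valve is moving or partly open;
* a seat sealing resistance `kappa (1/A_eff - 1/A_full)`, a linear viscous
  leak law inversely proportional to the leak area, which vanishes when
  fully open.

The second term is a deliberate model decision. At this circuit's flows
(tenths of mL/s) and leak areas (thousandths of cm²), a quadratic orifice
alone drops only ~1 mmHg at 0.1 mL/s — it cannot seal a valve against the
several-hundred-mmHg heads that a rigid incompressible network develops
during refill, and no leak-area fraction in a plausible range changes
that. A seated ball is sealed by thin-film viscous resistance in the
residual gap, which is a linear (creeping-flow) law; taking it inversely
proportional to the leak area makes the competent/incompetent resistance
ratio equal to the gap ratio (12.5), one calibration constant for the
whole grading. `kappa = 135.7` mmHg·s·cm²/mL is fixed by requiring the
severe walking scenario to net 0.140 mL/cycle, the published dysfunction
operating point; the competent valve is then effectively sealed (reflux
~0.004 mL/cycle) with no further tuning for the partial grade.

Ball dynamics default to first-order relaxation toward the stop selected
by the net force sign (pressure difference across the ball cross-section,
Stokes drag, submerged weight), with time constant 5 ms integrated by the
exact exponential update — unconditionally stable even at the 10 ms
resting time step. A full inertial mode (`ball_dynamics = "inertial"`)
exists for cross-checks; both converge to the same cycle metrics. The ball
is neutrally buoyant by default: in quiet standing the forces on the balls
then balance and the valves rest open, which is the observed orthostatic
state.

## Solver

The circuit is discretized into a chain of edges (default spacing 2.5 cm)
carrying inertance `rho l / A`, linear resistance and, on valve edges, the
orifice terms; the porous interface and the valves are zero-length edges.
Each step solves the nodal mass balances — with the calf wall's swept
volume entering as per-node sources, integrated analytically over each
cell — implicitly for the piezometric head via a tridiagonal (Thomas)
solve, with edge momentum semi-implicit: friction and the linearized
orifice loss at the new time level, coefficients frozen at the previous
flow. Mass is conserved node-by-node to solver precision (the suite checks
the per-step volume defect against 1e-9 mL). An `explicit` mode evaluates
the losses of inertial edges at the old time level; it is used as a
cross-check at reduced steps, since its stability bound on the stiff
calibrated edges is ~2.7e-4 s.

Two time steps are used: 1e-2 s for the resting scenarios and 2e-4 s when
the pump is active. At the pump-active step and the default grid the
Courant number `v dt / dx` at the 0.35 m/s reference velocity is ~0.003;
`run_simulation()` refuses configurations with `C > 1`. Runs default to 8
forcing cycles; per-cycle metrics discard at least 2 transient cycles and
further until consecutive per-cycle net volumes agree within 1%, then
average the rest. Because the rigid network stores no volume, the system
reaches its periodic state within a few inertial time constants (~0.2 s)
and the convergence check — halving both dx and dt — moves the healthy
walking net volume by ~1e-5 relative.

Convective acceleration is neglected on plain edges (velocities ≤ 0.35 m/s
in a resistance-dominated laminar regime) and is represented only inside
the valve orifice loss. Junction nodes are incompressible and solved
algebraically; a regularization compliance per node is available
(`compliance_ml_mmhg`, default 0) for stiff experimental configurations.

## What the simulations show — and what they cannot

The five canonical scenarios reproduce the published operating points as
follows (all numbers recomputed by `scripts/acceptance.R` and the test
suite):

* Lying and standing at rest the loop carries 0.049 mL per cardiac cycle —
  the mean venous velocity at the ankle is 0.25 cm/s — with a visible but
  attenuated pulsation at the cardiac period, and the resting probe
  pressures match the reference tables within 10%.
* Healthy walking nets ~0.174 mL/cycle at both probes; reflux through the
  competent valves is ~0.004 mL/cycle; the ejection fraction over the
  5.9 mL calf cylinder is ~3.0%.
* Severe incompetence (both valves) nets 0.140 mL/cycle with an
  order-of-magnitude larger diastolic reflux at the knee and unchanged
  systolic output; restricting only the distal valve leaves the output
  essentially at the healthy value — the proximal valve is the critical
  one.

One structural property of the model deserves emphasis, because it bounds
the healthy stroke volume below the published 0.2 mL. In a rigid,
incompressible series circuit the per-cycle net volume at every
cross-section equals the per-cycle inlet throughput. During muscle
relaxation the proximal valve is shut, so the inlet can supply exactly the
0.15 mL refill demand — no more: the diastolic share of the resting
arterial throughput (~0.02 mL) is absorbed into the refill rather than
added on top of it. The model's ceiling for the healthy stroke is
therefore the swept volume plus only the *systolic* share of the resting
throughput, ~0.178 mL, and the simulated 0.174 mL sits just under it.
Recovering strict additivity (0.15 + 0.05) would require venous
compliance or a parallel (perforating-vein) path, both deliberately outside
this model — the same absence the source analysis itself invokes to explain
its non-physiological calf pressures. Those pressures appear here too:
during valve closure the calf node reaches hundreds of mmHg (positive in
systole with a sealed distal path, strongly negative during suction); they
are reported untouched, never clamped.

## What the generator emulates, and does not

The canonical configuration generator emits the five scenario files with
every constant above. It emulates the study conditions: scale-model
geometry, sinusoidal cardiac and gait forcing at 1 s period, two valve
grades of incompetence. It does not emulate real tibial-vein data: no
collapsible vein mechanics, no perforating or superficial network, no
measured gait waveforms, no flow-dependent valve geometry, and blood is
Newtonian. Passing tests therefore demonstrate internal consistency with
the idealized circuit and its published operating points, not predictive
accuracy for patient hemodynamics.

## Worked example

```{r}
orth <- run_scenario("orthostatism")
walk <- run_scenario("walking_healthy")
sev <- run_scenario("walking_severe")
compare_scenarios(list(orthostatism = orth, walking_healthy = walk,
                       walking_severe = sev))
```

## Known limitations

* The healthy walking stroke is capped ~13% below the published value for
  the structural reason above; the ejection fraction follows it.
* The valve seal law is phenomenological: thin-film sealing calibrated at
  one anchor, linear in leak area. A geometric lubrication model of the
  ball–seat gap would change the grade-to-grade scaling exponent.
* Calf pressures during valve closure are far outside physiology (the
  price of a rigid, perforator-free venous arm) and should be read as
  model diagnostics, not predictions.
* The resting velocity table is honoured at a single reference flow;
  pressures at intermediate stations (e.g. the feet-level artery in
  orthostatism) are reproduced only to within ~6%.
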