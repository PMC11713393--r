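---
title: "Synchrotron delivery-time and plan-quality modelling for proton arc therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchrotron delivery-time and plan-quality modelling for proton arc therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Spot-scanning proton arc therapy (SPArc) spreads the delivery of scanned
pencil-beam spots over many control points along a rotating gantry arc,
keeping one energy layer per control point. On cyclotron-driven systems the
approach improves dose conformity at modest delivery-time cost. On a
synchrotron with single energy extraction the calculus is different: every
energy change requires a fresh acceleration cycle (about 2 s), the charge
extracted per cycle is bounded, and the ring can hold charge stably only
for a limited time. Because an arc plan has far more energy layers than a
few-field IMPT plan, the cycling overhead threatens to dominate. This
package provides the models needed to quantify that trade-off on synthetic
cases: a static delivery-time simulator, a dynamic (gantry-coupled)
simulator, the control-point restructuring that produces arc plans, and a
plan-quality/robustness metric suite, all exercised end to end by
`run_case()`.

## Static beam delivery time

For a plan with layers $i = 1 \dots N$, the static beam delivery time is

$$
T_{BDT} \;=\; \sum_i t_{LSw,i}\,(1 + m_{EX,i} + m_{MU,i})
\;+\; \sum_i \frac{MU_i}{\dot P_i}
\;+\; \sum_i \sum_{j=1}^{N_{spot,i}-1}
\left( \frac{|x_{i,j+1}-x_{i,j}|}{V_{x,i}}
     + \frac{|y_{i,j+1}-y_{i,j}|}{V_{y,i}} + t_{SMag} \right),
$$

the three sums being the energy-layer switch time, the spill time, and the
spot-switch time. $m_{EX,i}$ counts extra acceleration cycles needed when
the layer charge $MU_i \cdot q_{MU}$ exceeds the per-cycle charge budget
$q_{max}$, and $m_{MU,i}$ counts extra cycles needed when the spill time
$MU_i/\dot P_i$ exceeds the stable hold time $T_{hold}$; both are
`ceiling(x) - 1` of the respective ratio, floored at zero. Modelling
choices worth stating explicitly:

* the spot sum charges $N_{spot}-1$ moves, each with one magnet
  verification time; the first spot's positioning is absorbed in the layer
  switch, and a single-spot layer has zero spot-switch time;
* extra cycles multiply only the switch dead time, per the factorization
  above; the spill itself is not re-split across cycles;
* spot delivery order is the stored order — timing is order-sensitive and
  the package never re-sorts spots.

The default machine model (`default_machine_model()`, also shipped as
`inst/extdata/machine_default.yaml`) has 97 energies evenly spanning
71.3–228.8 MeV, a 2 s layer switch, 2 ms magnet verification, spill rate
8–10 MU/s, 2 nC per cycle, 8 s hold time, and scanning speeds 5–7 m/s (x)
and 17–22 m/s (y). Parameters specified as ranges are interpolated
linearly across the energy list (low value at the lowest energy); this is
a deterministic default, fully overridable through the configuration file.
The charge-per-MU conversion is not part of the machine description;
the default 0.01 nC/MU keeps typical clinical layers within one charge
cycle, and the value is exposed in the configuration.

## Dynamic delivery time

The dynamic simulator couples irradiation to gantry rotation under the
kinematic limits: maximum speed 6 deg/s, acceleration 0.6 deg/s², and
deceleration 0.5 deg/s². The primitive is the time-optimal rest-to-rest
move (`rest_to_rest_time()`): trapezoidal above the 66° threshold at the
default limits (e.g. 71.0 s for 360°, 41.0 s for 180°), triangular below.

For an arc, segment $i$ spans control points $i \to i+1$ and must last at
least the irradiation time of control point $i$ (the "floor"). Boundary
speeds between segments start from the nominal per-segment speed
$\min(v_{max}, \Delta\theta_i / t_{floor,i})$ and are clipped by a forward
pass under the acceleration limit and a backward pass under the
deceleration limit, with rest at both ends; each segment then takes the
larger of its floor and the time-optimal traversal given its entry/exit
speeds. With all floors zero this envelope reproduces the closed-form
rest-to-rest time exactly, independent of how finely the arc is
discretized — a property the tests verify at 10, 144 and 1000 segments.
The final control point is delivered at rest after arrival; this
asymmetry is deliberate (there is no following segment).

Two declared model boundaries: irradiation of control point $i$ is
attributed to segment $i$ as a duration floor, abstracting the beam
controller's spill gating; consequently, inserting an extra zero-MU
control point leaves the total unchanged in the kinematics-limited regime
but can lengthen delivery when a floor binds, since the floor is then
confined to the first child segment. Whether real arc controllers permit
irradiation to continue across a control-point boundary is not modelled.

IMPT plans use a step-and-shoot model: the gantry stops while irradiating,
and consecutive fields are connected by rest-to-rest rotations along the
shortest angular path. Couch changes contribute a configurable constant
(default 0 s); data transfer, room switching and beam-request overheads
are out of scope.

## SPArc restructuring

`sparc_restructure()` converts a coarse 20°-sampled arc into a deliverable
2.5° sequence in two stages.

**Control-point splitting.** Each halving of the sampling inserts the
sector midpoints: a full (cyclic) arc of $n$ control points becomes $2n$
(the duplicate 360° endpoint stays excluded), a partial arc of $n$ becomes
$2n-1$ (both endpoints retained). Three halvings take 20° to 2.5°,
producing 144 slots on a full arc and 73 on a 180° partial arc. At each
halving the parent's layers are ranked by descending energy and
interleaved: odd ranks to the first child in rotation order, even ranks to
the second; the terminal endpoint of a partial arc keeps a single child.
After the last halving, any control point still holding more than one
layer (the partial-arc endpoint chain, or slots inside an excluded sector)
sheds the surplus to the nearest empty grid slot (angular distance,
lower-index tie-break), and empty control points are deleted. Excluded
angular sectors are honoured the same way: their slots are treated as
unavailable and their layers relocated to the nearest allowed slot.

**Low-weight filtration.** Layers whose total MU falls below a threshold
$\theta$ (default 0.1) times the mean layer MU are removed — never the
heaviest layer — and the surviving spot weights are rescaled by one global
factor so the plan's total MU is conserved exactly. Clinical arc-generation procedures interleave filtration with
re-optimization and remove layers only when plan quality is preserved; without an optimizer in scope, a
single post-split MU-threshold pass is the declared deterministic
stand-in, and $\theta$ is a free parameter rather than a fitted one.

## Plan-quality metrics and robustness

The DVH is the cumulative curve $V(d)$ = fraction of structure voxels with
dose $\ge d$, evaluated at the sorted unique voxel doses plus zero.
$D_q$ uses the max-dose-covering-$q$-volume convention on the discrete
curve (no interpolation by default; a linear-interpolation flag exists for
smooth grids). Two V-metrics coexist deliberately: `V95` in the
robustness tables means volume at or above 95% of prescription, while
absolute thresholds (V5Gy, V20Gy) are plain `dvh_query(..., "V", dose)`
calls — keeping the two explicit avoids unit confusion. The conformity
index is the body volume receiving 95% of prescription divided by the CTV
volume; the integral dose is mean body dose times body volume in Gy·L.

The worst-case evaluation uses exactly 20 scenarios: the Cartesian product
of 7 setup shifts (±uncertainty along each axis, plus zero) and 3 range
scalings (±uncertainty, zero), minus the nominal pair. The 20-scenario convention fixes this composition; the enumeration order (axis, sign, scaling)
is a package convention. Setup shifts translate the dose grid by the shift
vector at nearest-voxel resolution — exact in the homogeneous phantom —
while range scalings recompute the toy dose with every layer's range
scaled by $1+s$ under the nominal normalization factor, so perturbed
metrics genuinely move. Tables report each CTV metric (mean, D95, V95, as
% of prescription) as `nominal (min∼max)` over the evaluation set.

## The synthetic cases and the toy dose engine

No patient data ships with the package; five presets emulate the scale and
geometry of representative disease sites:

| preset | CTV (cc) | dose (cGy) / fx | fields (gantry) | arc | setup (mm) | depth (cm) |
|---|---|---|---|---|---|---|
| hn | 129.07 | 7000 / 35 | 70, 75, 180 | 0–180 | 3 | 8 |
| lung | 93.88 | 6000 / 30 | 0, 160, 186 | 180–360 | 5 | 8 |
| liver | 175.93 | 6750 / 15 | 130, 186 | 180–360 | 5 | 10 |
| chordoma | 34.15 | 5040 / 28 | 0, 130, 230 | 0–360 | 2 | 8 |
| prostate | 41.42 | 3800 / 5 | 90, 270 | 0–360 | 3 | 12 |

CTV volumes, prescriptions, fractionation, beam angles and arc ranges
follow representative clinical case inventories; CTV depths and per-site setup
uncertainties (within the clinically typical 2–5 mm span) are fixed package
choices. The phantom is a water sphere whose radius equals the CTV depth,
so the water-equivalent depth to the CTV centre is the same from every
gantry angle — the property that makes a single energy band valid for all
control points; the CTV is a centred sphere with radius from the case
volume, and one 2 cm box OAR sits 3 cm distal to the CTV centre along each
field axis. Couch angles are carried in the plan metadata but ignored by
the dose engine (coplanar geometry).

Energies map to range through the Bragg–Kleeman water power law
$R = 0.0022\,E^{1.77}$ cm (4.2–33 cm over the machine span). IMPT fields
take every second machine energy whose range falls in the CTV depth band —
the stride emulates a planning system's energy-layer spacing choice and
keeps static-field layer counts below the arc's control-point count, the
relationship clinical plan inventories show. Spots sit on a 5 mm lattice
covering the CTV cross-section at each layer's depth plus a 5 mm margin,
in serpentine delivery order. Spot MU is uniform in [0.5, 1.5] (seeded),
then scaled so the plan total equals 100 MU per Gy of *fraction* dose:
delivery, and hence the timing comparison, is per fraction, and this
normalization keeps layers out of the extra-cycle regime, which the
machine description says clinical plans rarely enter. The coarse arc that
seeds restructuring fills each 20° control point to its descendant-slot
capacity (8 energies; 1 for the terminal endpoint of a partial arc),
subsampled evenly from the same band.

The toy dose kernel is per spot
$\;mu \times B(z;R) \times \exp(-r^2/2\sigma(z)^2)$ with
$B(z;R) = 0.3 + 0.7\,e^{-(z-R)^2/2\sigma_z^2}$ for $z \le R + 2\sigma_z$
(zero beyond), $\sigma_z = 0.02R$, and lateral spread
$\sigma(z) = 3\,\text{mm} + 0.02z$; the summed dose is normalized so the
CTV mean equals the prescription. It reproduces the features the metrics
need — a Bragg-peak-like depth profile, depth-broadening penumbra,
superposition, range sensitivity — and nothing else: no heterogeneity, no
nuclear halo, no optimizer-quality conformity. Passing tests therefore
demonstrate the *pipeline's* correctness and the directional
IMPT-vs-SPArc comparison, not clinical dosimetry; absolute metric values
on these phantoms do not correspond to patient plans, whose magnitudes the
package deliberately does not target.

## Numerical choices

* Layer energies must match a machine energy within 0.05 MeV — the list is
  discrete and the tolerance absorbs float formatting.
* Plan files are canonical JSON: alphabetically sorted keys, fixed
  6-decimal floats, so write–parse round-trips are byte-identical and
  fixtures diff cleanly. Gantry angles are stored unwrapped and strictly
  monotone along the arc direction (a full arc is 0→360), removing modular
  ambiguity.
* Dose grids and masks travel as ascii-encoded NRRD — plain text, adequate
  for the grid sizes used here.
* The velocity envelope guards the peak-speed formula against floating
  point at the boundary (`v_peak >= max(v_in, v_out)`), and segment
  durations compare floors and kinematic times with `max`, so dwelling at
  rest makes any floor feasible.
* The surplus-layer cleanup walks offending control points in delivery
  order and resolves angular-distance ties toward the lower index;
  deterministic by construction.
* Degenerate inputs fail loudly: empty structures, zero spill rates,
  non-monotone arcs, energies off the machine list, both uncertainties
  zero.

## Problem sizes

`run_case()` defaults to a 4 mm isotropic grid (phantoms of roughly
45³–65³ voxels), 5 mm spot lattices, and the 20°→2.5° restructuring
cascade; a five-preset comparison, including both delivery-time
simulations and the 20-scenario robustness evaluation for both
modalities, runs in a few minutes on one core. The robustness evaluation
computes three doses per plan (nominal and the two range scalings) and
derives all 21 evaluation points from them, since setup shifts are exact
grid translations in the homogeneous phantom. Property tests use smaller
phantoms (a 4 cm "toy" case) and grids of at most a thousand voxels for
brute-force DVH oracles.

## Known limitations

* The restructuring operates on fixed spot weights; no dose-based
  re-optimization between iterations, so arc plan quality is bounded by
  the quality of the replicated-and-filtered weights.
* The dynamic model attributes each control point's irradiation to its
  outgoing segment; controllers that irradiate across boundaries or hover
  within an angular tolerance would be faster in the floor-bound regime.
* Multi-energy extraction, line scanning, beam-current structure within a
  spill, and dose-rate effects are out of scope.
* The homogeneous spherical phantom removes all angle-dependence of
  radiological depth; real anatomy would couple energy selection to
  gantry angle, which the plan model supports but the generator does not
  exercise.
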