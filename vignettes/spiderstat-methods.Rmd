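---
title: "Methods: cord characterisation, static reduction, and planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cord characterisation, static reduction, and planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiderstat)
```

This vignette is the package's own account of its model: what is assumed,
what is calibrated, which numerical choices were open and how they were
settled, and what the tests do and do not demonstrate.

## The physical setting

A patient stands inside a rigid cage wearing a carrying belt at waist
level. Elastic cords run from anchor points on the cage to the belt. A
cord anchored above the belt pulls partly upward and *unloads* the
patient; anchored below, it *loads*. The model works in a right-handed
anatomical frame: Z vertical (up positive), X anterior, Y mediolateral
(subject's left positive), origin on the floor midway between the feet.
The belt is taken as a single point per cord at the height of the body's
centre of gravity (COG), so the COG height above the floor is the one
anthropometric input the statics needs; it can be measured directly or
estimated as 0.56 × stature for adults and 0.58 × stature for young
children (`estimate_cog_height()`).

Modelling assumptions, stated once: the body is a single rigid segment;
all cord action routes through the belt at COG level (zero belt radius);
contacts are unilateral points at the two feet; the analysis is static —
no inertia, no centre-of-pressure trajectories, no muscle forces.

## Cord tension model

A cord's tension at elongation $x$ (percent of rest length) is modelled
as a three-term sum of sines,

$$T(x) = \sum_{k=1}^{3} a_k \sin(b_k x + c_k), \qquad x \in [0, 100],$$

with amplitudes $a_k$ in newtons, frequencies $b_k$ in radians per
elongation percent, phases $c_k$ in radians. Three terms are enough to
track the three ranges real expanders exhibit (compliant toe,
quasi-linear rise, saturation) while remaining smooth. Two constraints
are imposed on evaluation rather than on the coefficients:

* **tension floor** — the evaluated sum is floored at 0 N, since a cord
  cannot push;
* **domain** — the model is never extrapolated above 100 % elongation
  (that is an error); negative elongation means a slack cord and
  evaluates to 0 N with a warning.

The desirable operating band is 20–80 % elongation; `working_range()`
returns the sub-interval of that band on which the fitted curve is
strictly increasing (scanned at 0.1 % steps), which is also the bracket
the planner solves over.

### Fitting

`fit_sum_of_sines()` minimises the residual sum of squares with
Levenberg–Marquardt (`minpack.lm::nls.lm`). The objective is multimodal
in the frequencies, so the fit is multi-start: 20 restarts by default,
with initial amplitudes drawn uniformly on $(0, 2\,\max F]$, frequencies
on $(0, \pi/50]$ per percent (at most one full period across the
domain), and phases on $[-\pi, \pi]$. All draws come from one seeded
stream, so a fixed seed gives bit-identical coefficients; the caller's
RNG state is left untouched. Fit quality is reported as
$R^2 = 1 - SS_{res}/SS_{tot}$ about the observed mean. Preconditions: at
least 10 measurements spanning at least 50 percentage points; constant
forces are refused as degenerate.

Bench tables are plain CSV (`elongation_pct,force_N`). The bench
protocol stretches a cord in fixed absolute steps (e.g. every 0.05 m)
from its measured rest length, but the reader accepts any single-pass
grid; whether forces were taken on loading or unloading is not modelled
(no hysteresis — a stated non-goal).

## Synthetic bench data and the calibrated fixtures

`synthetic_cord()` defines a smooth, strictly increasing, saturating
ground truth
$F(x) = F_{max}\,(1 - e^{-(x/x_0)^p})$ — a Weibull-CDF shape with toe
exponent $p$, scale $x_0$ (elongation at 63 % of saturation) and
saturation force $F_{max}$. `generate_bench()` samples it on a grid (21
points every 5 % by default) and applies multiplicative Gaussian noise
$F(1+\varepsilon)$, $\varepsilon \sim N(0, cv)$, floored at 0, from a
seeded stream.

The two packaged characteristics are **calibrated, not measured**. No
public coefficient values exist for the physical cords, so the package
anchors its fixtures to the two documented worked cases instead:

* *adult case*: 75 kg, four cords at 45°, stretched 250 mm, ≈ 15 %
  unweighting — per-cord tension
  $0.15 \cdot 75 g / (4 \sin 45^\circ) = 39.0$ N at 40.49 % elongation;
* *child case*: 12 kg, four cords at 10°, stretched 100 mm, ≈ 16 %
  unweighting — per-cord tension
  $0.16 \cdot 12 g / (4 \sin 10^\circ) = 27.1$ N at 15.69 % elongation.

Millimetre stretches convert to percent via mid-range rest lengths
(0.6175 m thick, 0.6375 m thin), since only length *ranges* are known
(thick 0.605–0.630 m, thin 0.620–0.655 m). $F_{max}$ is solved from the
anchor; the shapes ($p = 1.6, x_0 = 55$ thick; $p = 1.2, x_0 = 40$ thin)
were chosen once as realistic elastomer profiles and are not tuned. Each
fixture is the sum-of-sines fit (seed 1234, 40 restarts, noiseless 1 %
grid) to its ground truth, stored as JSON with 17 significant digits so
`inst/scripts/regenerate-fixtures.R` reproduces the files bit-exactly;
the script asserts strict monotonicity on 5–95 % before writing. The
child-case anchor implies a "thin" cord that is stiff at small
elongations; the fixture names encode the thick/thin assumption of the
worked cases, and the fixtures claim no fidelity to any physical cord's
absolute stiffness.

What passing tests on synthetic data show — and what they do not: the
generator emulates a smooth monotone saturating cord with multiplicative
dynamometer noise. Real expanders additionally show hysteresis, creep
and temperature drift, none of which is generated, so fit-quality
results here bound only the noise-and-model-mismatch part of real bench
error.

## Static reduction

`resolve_cog()` sums $\mathbf F = \sum_i T_i \,\mathbf d_i$ over the
cord states and reports the unweighting fraction
$u = F_z / (m g)$ with $g = 9.81$ m/s² (configurable argument). Positive
$u$ relieves the body, negative adds load; $u$ is exactly linear in the
tension vector, which is what makes the 10–20 % tension-perturbation
adjustments of `perturb_tension()` act linearly on unweighting.

`foot_reactions()` distributes the remaining load. With two feet at
floor positions and the COG on the vertical through the origin, the
vertical loads $(V_L, V_R)$ are the unique solution of

$$V_L + V_R = mg - F_z, \qquad y_L V_L + y_R V_R = h\,F_y,$$

i.e. vertical force balance plus lateral moment balance about the COG's
vertical projection ($h$ = COG height). The closed-form solution is
written symmetrically so that mirroring a scenario through the sagittal
plane swaps the feet bit-exactly. The fore–aft moment $h F_x$ has no
counterpart in a two-point model; physically it is absorbed by
centre-of-pressure shift within the feet, which is out of scope. The net
horizontal cord force is reacted as friction split in proportion to each
foot's vertical load — the minimal rule that preserves componentwise
equilibrium and symmetry. If the cords carry the full weight or more,
both reactions are zero and a lift-off flag is raised (the ground cannot
pull), rather than reporting negative reactions.

Heel/toe classification operates on the **cord-imposed** force at each
foot, defined as the baseline (no-cord) reaction minus the actual
reaction; the two cord-imposed forces sum exactly to the COG resultant.
Positive Z unweights the heel, negative loads it; positive Y moves load
toward the toe mound, negative away. Note that an exactly symmetric
four-cord setup leaves ~1e-14 N of lateral summation residue, so a
"neutral" classification is only reported when a component is exactly
zero.

## The planner

`solve_configuration()` inverts the forward map with one free variable:
a shared elongation for all cords (the default, matching how setups are
specified per group), or a common anchor height with each cord keeping
its horizontal radius and azimuth. The bracket is $[0, e_{hi}]$ with
$e_{hi}$ the top of the cords' common working range (or the anchor-height
interval keeping every cord inside its range). Before solving, the
forward map is checked for monotonicity on 41 bracket points — a
non-monotone map (possible when saturating unloading cords oppose
near-linear loading cords) is refused rather than silently returning one
of several roots. The root itself is found by Brent's method
(`stats::uniroot`, tolerance 1e-9 on the free variable) and the solution
is verified by forward simulation to within 1e-6 of body weight. An
out-of-bracket target errors with the achievable interval. A target of
exactly zero returns zero elongation directly: a slack cord transmits no
force regardless of the fitted model's (sub-newton) residual at
$x = 0$.

## Scenario files and outputs

Scenarios are YAML or JSON with unit-suffixed keys (`mass_kg`,
`elongation_mm`, `azimuth_deg`, ...); unknown keys are rejected by name
so typos fail loudly. Cords are given in polar form (COG-level angle,
azimuth, elongation) — the natural way setups are described — or as
Cartesian anchors. Default azimuths in the packaged four-cord scenarios
are {45°, 135°, 225°, 315°}, a declared symmetric convention (no
published anchor coordinates exist). `write_force_table()` emits a
stable-column CSV/JSON table of per-cord forces, the COG resultant,
unweighting percent, reactions and classifications.

## Problem sizes and test design

The property suites run on generated cases under fixed seeds: 1000
random two-foot scenarios for equilibrium closure (1e-9 relative), 200
against an independently coded moment-balance solve (1e-9), 100 mirrored
scenarios (bit-exact), 100 random achievable planner targets (1e-6), and
100 polar/Cartesian round-trips (1e-9). Fits use 21-point benches with
20 restarts. These sizes make the whole suite run in seconds while
keeping the property checks dense enough to catch sign and partition
errors; the oracles (naive summation loop, `solve()` on the 2×2 moment
system, bisection, dense grid scans) are coded independently of the
implementation paths they check.

## Known limitations

Single-segment statics only; no belt torque or belt radius (a parameter
exists conceptually but the belt is a point); no cord–cord interaction;
no dynamics, EMG or balance control; cords acting on limbs directly
(rather than through the belt) are approximated as belt-routed. The
device limits are enforced as data validation: mass above 110 kg is an
error, outside the 70–80 kg adult utility range an advisory message.
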