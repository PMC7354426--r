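# spiderstat

Static force modelling for cage-and-elastic-cord body-weight support
devices used in rehabilitation ("verticalization" therapy). A patient
stands inside a rigid cage wearing a waist belt; elastic cords (expanders)
run from cage anchor points to the belt. Cords anchored above the belt
unload the patient, cords anchored below add load. `spiderstat` answers,
in numbers, the questions a physiotherapist otherwise answers by feel: how
much of the body weight do the cords carry, how is the remainder shared
between the feet, and what cord setup achieves a prescribed unweighting.

The package is aimed at rehabilitation engineers and movement scientists
who need reproducible, inspectable force numbers for cord-suspension
setups.

## The model

**Cord characteristic.** The tension of a cord at elongation *x* (percent
of rest length, valid on 0–100 %) is a three-term sum of sines,

T(x) = Σₖ aₖ sin(bₖ x + cₖ),  k = 1…3,

fitted to bench force–elongation measurements by multi-start
Levenberg–Marquardt least squares (`fit_sum_of_sines()`), with fit quality
reported as R² = 1 − SSres/SStot. Evaluated tension is floored at 0 N.
The practically useful elongation band is 20–80 %; `working_range()`
returns the strictly increasing part of that band.

**Statics.** All belt-routed cord forces are reduced to the body's centre
of gravity (COG). With per-cord tension Tᵢ and unit direction dᵢ (belt →
anchor), the COG resultant is F = Σ Tᵢ dᵢ and the unweighting fraction is
u = F_z / (m g), g = 9.81 m/s². The ground reaction is partitioned
between the two foot–ground contacts by vertical force balance plus
lateral moment balance about the COG's vertical projection; the net
horizontal cord force is reacted at the feet in proportion to each foot's
vertical load. Per foot, the cord-imposed force classifies the heel
(positive Z unweights, negative loads) and the toe mound (positive Y
moves load toward it, negative away).

**Planner.** `solve_configuration()` inverts the monotone forward map by
Brent root-finding: given a target unweighting (negative = loading), it
returns the shared cord elongation — or common anchor height — that
reproduces it to within 1e-6 of body weight.

## Worked example

A 75 kg adult suspended on four thick cords, each stretched 250 mm at a
45° cord–COG-level angle (the packaged `scenario_adult_symmetric.yaml`):

```r
library(spiderstat)
path <- system.file("extdata", "scenario_adult_symmetric.yaml",
                    package = "spiderstat")
simulate_scenario(path)
#> <load_summary>
#>   subject: 75.0 kg (weight 735.8 N)
#>   COG cord resultant [N]: X -0.00  Y +0.00  Z +110.44
#>   unweighting: 15.01% of body weight
#>   left  foot reaction [N]: X +0.00  Y -0.00  Z +312.65  (heel unweighted, toe load_toward)
#>   right foot reaction [N]: X +0.00  Y -0.00  Z +312.65  (heel unweighted, toe load_toward)
```

The cords carry 110.4 N (15 % of the 735.8 N body weight); the remaining
625.3 N splits equally, 312.65 N under each foot, and the positive
vertical cord-imposed force at each foot means both heels are relieved.
The inverse question — what elongation yields exactly 15 % — is answered
by the planner:

```r
ch <- reference_characteristic("reference_adult_thick")
sol <- solve_configuration(subject(75, 1.75), rep(list(ch), 4),
                           angles_deg = rep(45, 4),
                           target_unweighting = 0.15)
sol$elongation_pct
#> [1] 40.46137
```

i.e. ≈ 250 mm on a 0.6175 m cord. A command-line interface wrapping the
same functions ships at
`system.file("cli", "spiderstat.R", package = "spiderstat")` with
`simulate`, `fit`, `plan` and `synth` subcommands.

The two packaged reference characteristics are *calibrated*, not
measured: each is a sum-of-sines fit to a synthetic saturating
ground-truth curve anchored so the packaged adult and child scenarios
reproduce their documented unweighting levels (≈ 15 % and ≈ 16 %). See
`?reference_characteristic` and the methods vignette
(`vignettes/spiderstat-methods.Rmd`).

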