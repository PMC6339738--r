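# gripangle

Measurement of finger joint flexion angles during cylinder gripping from
three-dimensional bone-model landmarks, with a synthetic kinematic hand
standing in for CT data, and the repeated-measures statistics to go with it.

## The problem

When a hand power-grips a cylinder, each finger joint — the
metacarpophalangeal (MP), proximal interphalangeal (PIP) and distal
interphalangeal (DIP) joints of the index, middle, ring and small fingers —
flexes by an amount that depends on the cylinder diameter.  Skin-mounted
markers and sensor gloves measure these angles only indirectly; bone models
segmented from CT of the gripping hand allow a direct skeletal measurement:

- eight surface points are picked at roughly 45° intervals around the outer
  circumference of each bone end (the head and base of every phalanx and
  metacarpal);
- the end **center** is the centroid of its eight points;
- the **bone axis** is the direction vector from the base center to the head
  center;
- the **flexion angle** of a joint is the angle between the axes of its two
  bones, `acos(u · v)`, unsigned in `[0°, 180°]`;
- the **coupling ratio** (CR) of a finger is the per-subject ratio
  `DIP / PIP` of flexion angles, a measure of how synchronously the two
  interphalangeal joints close.

Angle tables over subjects × diameters (10, 60, 120 mm) × fingers × joints
are analyzed with a balanced three-way repeated-measures ANOVA (Type III SS,
each effect tested against its own effect×subject error term), Mauchly's
sphericity test with Greenhouse–Geisser correction, simple main effects, and
Bonferroni-corrected paired comparisons; the CR gets the analogous two-way
analysis.

Because per-subject CT data of this kind are not publicly available, the
package ships a fully synthetic substitute: capsule bone meshes, a
forward-kinematic finger chain, a deterministic cylinder-wrap grip solver,
a landmark noise model, and a cohort simulator parameterized by published
per-cell means and SDs.  Every stage of the measurement pipeline is
therefore testable against known ground truth.

## Worked example

```r
library(gripangle)

specs <- default_hand_specs()                      # 185.8 mm hand
pose  <- solve_grip_pose(specs$middle, grip_scenario(60))
as.data.frame(pose)
#>   finger joint angle_deg
#> 1 middle    MP  60.27036
#> 2 middle   PIP  54.82313
#> 3 middle   DIP  33.66289
```

The middle finger wrapping a 60 mm cylinder flexes ~60° at the MP, ~55° at
the PIP and ~34° at the DIP; solving at 10 mm instead saturates the joints
near their range-of-motion caps, and at 120 mm all three angles drop — the
diameter effect the statistics below quantify.

```r
co  <- simulate_cohort(cohort_spec(10, seed = 1)) # 10 subjects x 3 x 4 x 3
head(summarize_angles(co), 3)
#>   diameter_mm finger joint      mean        sd  n
#> 1          10  index   DIP  51.43787 16.354490 10
#> 2          10  index   PIP 104.88364  8.306653 10
#> 3          10  index    MP  68.43450  6.930294 10

rm_anova(co, "angle_deg", c("diameter_mm", "finger", "joint"))
#> Repeated-measures ANOVA (within-subject, balanced)
#>                    source df error_df         SS         MS        F       p
#>               diameter_mm  2       18 219758.273 109879.136 1246.827 <0.0005
#>                    finger  3       27   3253.576   1084.525   15.558 <0.0005
#>                     joint  2       18  21118.485  10559.243  167.260 <0.0005
#>        diameter_mm:finger  6       54   3085.962    514.327    5.469 <0.0005
#>         diameter_mm:joint  4       36  16506.431   4126.608   47.165 <0.0005
#>              finger:joint  6       54   2990.326    498.388    7.296 <0.0005
#>  diameter_mm:finger:joint 12      108   3205.421    267.118    2.937   0.001
```

All main effects and interactions are significant on this simulated cohort,
so one would proceed to `simple_main_effects()` and `pairwise_table()` for
the per-combination Bonferroni comparisons.  Coupling ratios:

```r
render_markdown(summarize_cr(cr_records(co)))
#> | Diameter | index | middle | ring | small | All |
#> | 10 mm | 0.49 (0.16) | 0.63 (0.18) | 0.58 (0.09) | 0.78 (0.11) | 0.62 (0.17) |
#> ...
#> | All | 0.71 (0.27) | 0.76 (0.34) | 0.60 (0.24) | 0.90 (0.30) | 0.74 (0.30) |
```

The whole chain — write posed bone meshes as PLY, re-read them, pick
landmark rings off the surfaces, re-measure every joint, analyze — runs as
three pipeline calls:

```r
cfg <- pipeline_config(output_dir = "out", seed = 1)
grip_simulate(cfg)                     # meshes + ground truth + cohort CSV
grip_measure("out", cfg)               # landmark picking -> angle records
grip_analyze(file.path("out", "cohort.csv"), "out/tables")
```

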