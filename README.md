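# canalaccess

Anatomical feasibility analysis of minimally invasive (keyhole) drill access
to the three semicircular canals of the inner ear, as needed for vestibular
implantation.

Restoring vestibular function with an implant requires advancing an
electrode into each semicircular canal (superior, lateral, posterior)
through a drilled tunnel from the mastoid surface. Whether that is possible
in a given ear is a geometric question: each trajectory must clear the
facial nerve, chorda tympani, ear canal, sigmoid sinus, lateral skull base
and the other two canals by a safety margin; it must meet the canal at a
favourable *SCC entry angle* α — the angle between the drill axis and the
canal-centreline tangent at the fenestration site (0° tangential, α ≥ 80°
risks retrograde electrode insertion); and all three entry points must fit
inside one 15 mm cortical mastoidectomy. `canalaccess` answers it
quantitatively for surface-model inputs (or for its own seeded synthetic
temporal-bone phantoms):

* **safety margin** of a trajectory: min over path samples and obstacles of
  (interpolated signed distance − local drill radius), for a stepped drill
  (0.5 mm tip, 0.6 mm from 4 mm, 1.25 mm from 14 mm behind the tip), on
  exact signed-distance fields (0.125 mm grid);
* **accessibility** of a canal: the percentage of entry points in a
  30 × 30 mm (+10 × 10 mm extension) retroauricular region whose trajectory
  has margin > threshold and α < 80°;
* **mutually optimized plan**: over accessible entry triples (one per
  canal) with pairwise distances < 12.5 mm, the exact discrete minimizer of
  Σᵢ (αᵢ − 30°)², with the 15 mm mastoidectomy verified by the minimal
  enclosing circle;
* **fenestration-site sweeps** along the canal and an idealized
  **exposed-lumen-area** model A(α) that motivates the 30° ideal angle.

The package is tidyverse-shaped: maps and reports are tibbles, results have
`tidy()`/`glance()` methods, and `autoplot()`/`plot_*()` functions draw the
entry-region maps, exposure curve and sweeps.

## Worked example

```r
library(canalaccess)

case <- generate_case(anatomy_params(seed = 1))   # synthetic right ear
#> <anatomy_case: right ear, 7 structures, seed 1>

cfg <- pipeline_config(field_spacing = 0.5, sample_step = 0.5,
                       n_entry_points = 200, target_face_area = 2,
                       sigmoid_n_dirs = 96, sigmoid_grid_pitch = 1)
report <- run_case(case, cfg)
report
#> <case_report case: feasible>
#> # A tibble: 3 x 12
#>   canal accessibility_0.5 accessibility_1 accessibility_2 lowest_accessible_an…
#> 1 supe…                13             7.5             2.5                   71.8
#> 2 late…                53            35.5             3.5                   30.9
#> 3 post…                15             3.5             0                     74.1

glance(attr(report, "plan"))
#> # A tibble: 1 x 5
#>   feasible objective max_pairwise_distance enclosing_circle_diameter ideal_angle
#> 1 TRUE         4441.                  11.7                      11.7          30
```

Reading the output: at a 1 mm safety margin, 35.5% of candidate entry
points reach the lateral canal, 7.5% the superior and 3.5% the posterior
canal of this phantom; the lowest achievable entry angle is near-ideal for
the lateral canal (30.9°) and steep for the superior canal (71.8°, its
plane being roughly sagittal). The mutual plan is feasible: three
trajectories whose entry points span an 11.7 mm circle — inside the 15 mm
mastoidectomy — at the printed entry angles and margins. (This example
runs the pipeline at reduced resolution; `pipeline_config()` defaults hold
the full-resolution values.)

The idealized exposed-lumen area shrinks as the approach steepens,
the trade-off behind the 30° ideal:

```r
exposed_area_curve(c(10, 30, 60, 90))
#> # A tibble: 4 x 2
#>   theta  area
#> 1    10 4.06
#> 2    30 1.83
#> 3    60 1.06
#> 4    90 0.917
```

Cohorts: `generate_cohort(n, seed = ...)` draws seeded anatomical variation
(±10% size, ±10° canal orientation, ±3 mm sigmoid position, alternating
sides); `run_cohort()` isolates per-case failures and returns a
median/IQR/range summary table across every per-canal metric.

A thin command-line front end over the same functions lives at
`inst/scripts/canalaccess-cli.R` (subcommands `simulate`, `plan`, `cohort`,
`sweep`, `exposure`).

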