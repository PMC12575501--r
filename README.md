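# renalrod

Desk-scale digital-twin analysis of respiration-induced renal artery
deformation before and after fenestrated endovascular aneurysm repair
(fEVAR), for vascular-biomechanics researchers and simulation engineers who
want to study how bridging stent-graft (SG) sizing changes renal artery
motion without patient imaging or a shell finite-element solver.

In fEVAR, a fenestrated aortic endograft is bridged into each renal artery
by a short balloon-expandable covered stent. During breathing the kidneys
drag the renal arteries mainly cranio-caudally; a stiff bridging device
changes how the artery accommodates that motion, and device *length* is a
choice the surgeon makes. `renalrod` reproduces this analysis end to end
with synthetic patients:

* **synthetic vasculature** — seeded, reproducible aorta + two renal
  branches (5–7 mm lumens, near-perpendicular take-offs, anterior hooks)
  with breathing displacement boundary conditions dominated by the
  cranio-caudal component;
* **stent model** — the catalog of twelve study devices (18–28 mm × 5–7 mm),
  Co–Cr/ePTFE material constants, an effective bending rigidity for the
  stented artery segment, a three-point-bending linear-regime harness, and
  geometric deployment with aortic protrusion;
* **breathing rod** — a discrete elastic rod (stretch + curvature-binormal
  bending with transported rest curvature) brought to static equilibrium
  under the breathing displacement, with the stented span stiffened and
  straightened:

  `E = Σ ks/(2h) (|e_i| − l̄_i)² + Σ kb/(2h) |κb_i − P_i(κb̄_i)|²`
* **morphometrics** — Menger curvature every 1 mm with maximum extraction,
  branching angle (aorta tangent vs renal centerline direction, 90° =
  perpendicular), end-stent angle at the device's distal end, and absolute
  inspiration→expiration deltas;
* **registration & validation** — centroid + ICP rigid registration
  (Kabsch, proper rotations only), corresponding-point centerline distances,
  the SG Placement Accuracy Score (% of points under a 3 mm threshold), and
  the protrusion-length criterion (3.4–4.3 mm band, 3.88 mm reference);
* **pipeline** — a six-stage, artifacts-on-disk study runner
  (`run_study()`, CLI in `inst/cli/renalrod`) producing the placement,
  protrusion and breathing-delta tables.

## Worked example

Draw a patient, deploy the nominal 23 × 7 mm device in the right renal
artery, and compare breathing with and without it:

```r
library(renalrod)

p <- synthetic_patient(seed = 42)
p
#> <synthetic patient, seed 42>
#>   aorta      : <centerline: 201 points, arc length 200.64 mm, radius 10.00-10.00 mm>
#>   renal left : <centerline: 46 points, arc length 44.77 mm, radius 2.97-2.97 mm>
#>   renal right: <centerline: 48 points, arc length 46.05 mm, radius 3.05-3.05 mm>
#> <breathing displacement BC (mm, lr/ap/cc); aorta ends fixed>
#>   left : (  1.01,   2.16,  10.11)
#>   right: ( -1.03,   2.16,  10.60)

dep <- deploy_geometric(p$renal_right, sg_lookup(1, "RRA", "nominal"), 3.95, 8)
dep
#> <deployed SG 23 x 7 mm (nominal): arc [-3.95, 19.05] mm, protrusion 3.95 mm, flare 8.0 mm>

sim_pre <- simulate_breathing(p)
sim_sg  <- simulate_breathing(p, deployed = list(right = dep))

breathing_deltas(
  morpho_metrics(p$aorta, sim_pre$right$inspiration, label = "pre-EVAR"),
  morpho_metrics(p$aorta, sim_pre$right$expiration,  label = "pre-EVAR"))
#> <breathing deltas [pre-EVAR]>
#>   |d branching| = 12.85 deg
#>   |d end-stent| = n/a
#>   |d max curv | = 0.0580 1/mm

breathing_deltas(
  morpho_metrics(p$aorta, sim_sg$right$inspiration, dep, label = "nominal SG"),
  morpho_metrics(p$aorta, sim_sg$right$expiration,  dep, label = "nominal SG"))
#> <breathing deltas [nominal SG]>
#>   |d branching| = 11.85 deg
#>   |d end-stent| = 10.09 deg
#>   |d max curv | = 0.0652 1/mm
```

The stented artery swings less at the ostium during a breath (branching-angle
delta 11.85° vs 12.85° pre-EVAR) but develops a 10° end-stent angulation at
the device's distal edge — the trade-off that worsens with longer devices and
motivates the study. The full three-size comparison, placement scoring and
protrusion table come from the pipeline:

```r
rep <- run_study(study_config(n_patients = 2, seed = 1, out_dir = "study_out"))
rep          # placement scores, protrusion band check, breathing-delta table
```

or from the shell, stage by stage:

```sh
inst/cli/renalrod generate --seed 42 --out study_out --n-patients 2
inst/cli/renalrod deploy   --out study_out
inst/cli/renalrod breathe  --out study_out
inst/cli/renalrod metrics  --out study_out
inst/cli/renalrod validate --out study_out
inst/cli/renalrod report   --out study_out
```

See `vignettes/breathing-stent-study.Rmd` for the model, its assumptions,
parameter defaults and limitations.

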