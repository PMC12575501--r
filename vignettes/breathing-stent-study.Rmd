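---
title: "Respiratory motion of stented renal arteries: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory motion of stented renal arteries: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
```

`renalrod` is a desk-scale digital twin of a clinical question in fenestrated
endovascular aneurysm repair (fEVAR): how does a bridging stent-graft (SG),
placed through an aortic-graft fenestration into a renal artery, change the
way that artery moves and bends during breathing — and how does the *length*
of the chosen device modulate that change? The package replaces the two
patient-specific ingredients that cannot be shipped (CT-derived vascular
geometry, and a shell finite-element model of the artery wall) with a
synthetic vasculature generator and a reduced-order elastic-rod model, while
implementing the morphometric and validation toolchain — branching angle,
end-stent angle, discrete curvature, rigid registration, centerline-distance
scoring, protrusion criterion — exactly as used in clinical placement studies.

```{r setup}
library(renalrod)
```

## The synthetic patient

A patient is an abdominal aorta (a gently tortuous tube of ~10 mm radius
running along the cranio-caudal axis) with two renal branches. The frame is
right-handed with x = left-right, y = antero-posterior, z = cranio-caudal
(superior positive); units are mm and N throughout.

```{r patient}
p <- synthetic_patient(seed = 1)
p
```

Branch geometry is sampled once per patient from ranges chosen to be
anatomically plausible *and* to put the model in the mechanical regime the
breathing analysis assumes:

* **take-off angle U(78, 100) degrees** — renal arteries branch roughly
  perpendicular to the aorta. Strongly cranially-tilted take-offs would point
  the vessel along the dominant (cranio-caudal) breathing displacement, which
  a rod then absorbs axially rather than in bending;
* **arc length U(40, 52) mm**, long enough to host the longest catalog device
  (28 mm) plus the distal window of the end-stent metric;
* **lumen radius U(2.5, 3.5) mm**, i.e. diameters in the 5-7 mm renal range
  matching the 5-7 mm device catalog;
* **constant curvature U(0.025, 0.035) / mm bending anteriorly** (a hook
  towards the kidney, radius of curvature 29-40 mm). The branch plane stays
  near-horizontal, so cranio-caudal motion of the distal end loads the vessel
  transversely. An optional out-of-plane sinusoidal perturbation
  (`wobble_amp_mm`) is available for rougher geometry; its default is 0
  because it adds noise of a degree or two to the 5-mm-window angle metrics,
  which is the scale of the effects under study.

The breathing boundary condition displaces the distal end of each branch
while both aortic ends stay fixed. Default magnitudes are (cranio-caudal,
antero-posterior, left-right) = (10, 2, 1) mm with 10% per-branch jitter;
patient-specific measured values are not publicly available, so these are
configurable stand-ins with the cranio-caudal component dominant by
construction, as respiratory organ motion requires. All randomness flows
from one master seed through fixed per-site substreams, so stage order can
never change a result.

## The rod model

The artery is a discrete elastic rod: nodes at ~1 mm spacing along the rest
centerline with energy

$$E = \sum_i \frac{k_s}{2h}\,(|e_i| - \bar l_i)^2 \;+\;
      \sum_i \frac{k_b}{2h}\,\left|\kappa b_i - P_i(\overline{\kappa b}_i)\right|^2,$$

where $e_i$ are the segment vectors with rest lengths $\bar l_i$,
$\kappa b_i = 2\,t_{i-1}\times t_i / (1 + t_{i-1}\cdot t_i)$ is the discrete
curvature binormal at interior node $i$, and $P_i$ parallel-transports the
rest curvature binormal to the current inboard tangent (minimal rotation).
This is the standard discrete-elastic-rod bending energy for an isotropic
cross-section without an independent twist field. For in-plane bending it
reduces to the familiar turning-angle form $k_b/h\,(1 - \cos(\varphi -
\varphi_0))$ to second order; unlike that scalar form it also resists
rotation of the bending plane of a curved rod ("writhe"). That resistance is
essential: with a scalar turning-angle energy, a curved rod can satisfy the
displaced-end boundary condition by rotating bending planes at zero cost,
the equilibrium becomes degenerate, and the stented segment's rigidity stops
influencing the solution.

Stiffness parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `artery_rigidity` | $E \pi r^3 t \approx 85$ N mm$^2$ ($E$ = 2 MPa, $r$ = 3 mm, $t$ = 0.5 mm) | thin-walled-tube bending rigidity of the bare wall |
| `stretch_stiffness` | $E \cdot 2\pi r t \approx 19$ N | physiological axial stiffness $EA$; arteries are extensible, so along-vessel displacement components are absorbed by moderate strain rather than forbidden |
| `rigidity_ratio` | from `effective_bending_rigidity()` | stented/unstented stiffening, applied to bending and stretch on the stented interval |

The composite rigidity of the stented segment adds, to the artery wall, the
graft as a thin-walled tube of its longitudinal modulus
($E_1 \pi r^3 t$, $E_1$ = 1.2 GPa, $t$ = 0.2 mm) and `struts_per_ring`
(default 6) rectangular Co-Cr struts (0.115 mm x 0.145 mm, $E$ = 268 GPa)
tied to the tube wall, hence carrying both their own-axis inertia
$wh^3/12$ and the parallel-axis term $A r^2/2$. The resulting ratios
(roughly $10^3$ for 5-7 mm devices) make the stented span effectively rigid
— the behaviour of a balloon-expandable covered stent. Without the
parallel-axis term the span is soft enough to pivot at the ostium clamp,
which launders the device-length dependence out of the junction mechanics.
The strut count is a free design knob; only the order of magnitude of the
ratio matters for the trends.

Boundary conditions follow the imaging protocol: the ostium end is clamped
in position and tangent (the aorta is far stiffer than the renal artery and
its ends are fixed), the distal node is displaced by the breathing vector
with free orientation. The distal orientation is unconstrained by
assumption; whether the real kidney end carries a moment is unknown.

### Deployment

Balloon deployment is represented geometrically: the device occupies the
ostium-anchored arc interval $[-p, L_{SG} - p]$, where $p$ is the protrusion
into the aortic lumen (flared to the fenestration diameter), and the
*post-EVAR rest shape* straightens the stented span along the take-off
direction, with the unstented remainder rigidly reattached
(`stented_rest_shape()`). Arc lengths are preserved exactly. Contact,
crimping and plasticity are out of scope. In the study pipeline one
protrusion target per artery (drawn from [3.5, 4.3] mm) is shared by all
three size classes, so the three deployments differ only in device length
and the breathing comparison isolates the length effect.

### Solver

Equilibria are found by minimising the energy over the free node
coordinates: displacement continuation in ~1.5 mm increments, each solved by
a damped Newton (Levenberg-Marquardt) iteration with rotation-based warm
starts and a colored finite-difference Hessian (the energy couples only
nodes within three hops, so 21 gradient evaluations suffice per Hessian
regardless of rod length). The solve is deterministic; convergence is
declared at an energy-gradient infinity norm below $10^{-8}$ N. For heavily
stiffened rods (stented bending rigidities around $10^5$ N mm$^2$) that
tolerance sits close to the double-precision gradient floor, so near-misses
within a factor of ten are reported in the solution object without a
warning. The node grid is aligned so that one node falls exactly on the
stent end: otherwise the effective stented extent jumps by a whole grid step
as the protrusion varies.

```{r simulate, fig.alt = "Inspiration and expiration centerlines"}
sim <- simulate_breathing(p)
plot(sim)
```

## Morphometrics

All metrics run on centerlines resampled at 1 mm of arc length:

* **curvature**: Menger curvature (reciprocal circumradius of consecutive
  point triples), exact on circles, parameter-free; the per-branch summary
  is the maximum over interior points.
* **branching angle**: angle between the aortic tangent at the point nearest
  the ostium and the least-squares direction of the renal centerline
  (90 degrees = perpendicular). By default the *whole* branch enters the
  direction fit, reading the measurement as the angle between the two
  centerlines as lines. A short proximal window is available
  (`fit_window_mm`), but with the window inside the stiff stented span a
  deployed device would suppress the breathing delta almost entirely,
  which contradicts the partial (roughly half) reduction the stented
  deltas are known to show; the whole-centerline reading reproduces that
  partial reduction.
* **end-stent angle**: angle between the least-squares directions of the
  last 5 mm of stented and the first 5 mm of unstented centerline, with a
  1-mm guard zone on each side of the stent end so both fits stay clear of
  the discrete stiffness transition. `NA` when insufficient artery remains
  distal to the device.
* **breathing deltas**: absolute inspiration-to-expiration differences per
  metric, computed under identical boundary conditions with and without the
  device so pre/post comparisons isolate the stent effect.

## Registration and validation

The validation chain mirrors a simulation-vs-imaging comparison. Because no
imaging exists for synthetic patients, the study pipeline manufactures an
imaging surrogate: the simulated post-EVAR expiration centerline observed in
a different (randomly drawn, known) scanner frame with Gaussian segmentation
noise (default sd 0.5 mm). The surrogate is registered back by ICP — centroid
pre-alignment, then alternating closest-point correspondence and Kabsch
alignment. Correspondence is point-to-nearest-point *on the target
polyline*, and the rigid fit uses interior correspondences only: plain
vertex-to-vertex pairing slides along smooth centerlines and stalls short of
convergence, and end-clamped projections bias the rotation. The proper
rotation branch (det = +1) is always selected in the Kabsch step. Note that
registration of a planar circular arc rotated in its own plane is
intrinsically ill-posed (a near self-symmetry); test geometries therefore
carry genuine 3-D character.

Distances are then measured between corresponding points (both curves
resampled to 100 arc-length-proportional points, orientation auto-corrected
by an endpoint-pairing test) and summarised as mean, standard deviation and
maximum. The **placement accuracy score** is the percentage of points
strictly below the 3 mm threshold (2 mm imaging + 1 mm segmentation error
budget); ties at exactly 3.000 mm count as failures, a deliberate reading of
"below". The **protrusion criterion** checks each deployment's protrusion
against the 3.4-4.3 mm band and reports the mean; the package ships the
twelve reported device protrusions
(`system.file("extdata", "protrusion_lengths.csv", package = "renalrod")`)
whose mean is 3.95 mm against a 3.88 mm clinical reference.

```{r validate}
tab <- read.csv(system.file("extdata", "protrusion_lengths.csv",
                            package = "renalrod"))
check_protrusions(tab$protrusion_mm)[c("mean_mm", "all_pass")]
```

## The study pipeline

`run_study()` executes six stages (generate, deploy, breathe, metrics,
validate, report) that communicate through CSV/JSON artifacts in the output
directory; each stage is independently runnable (also from the shell via
`inst/cli/renalrod`) and stage-wise execution is byte-identical to the
monolithic run. The default study uses 2 patients; the acceptance analysis
uses 5 (40 equilibrium solves, a few minutes on one CPU).

```{r study, eval = FALSE}
rep <- run_study(study_config(n_patients = 2, seed = 1,
                              out_dir = tempfile("study")))
rep
```

The report mirrors the three tables of a placement study: distance
statistics and placement scores per artery; protrusion lengths per
deployment with the band check; and breathing deltas with one pre-EVAR row
and one row per deployed size class (shorter / nominal / longer) for every
artery. The directional expectations for the deltas are: the branching-angle
delta decreases from pre-EVAR through shorter, nominal and longer devices
(the stiff span progressively immobilises the vessel), while the end-stent
angle delta increases with device length (a longer rigid span leaves a
shorter compliant segment to absorb the same distal motion, concentrating
angulation at the device end).

## What the synthetic study does and does not show

The generator reproduces the *structure* of the clinical analysis — tube-like
vessels of the right calibre, near-perpendicular branching, curvature of the
right magnitude, cranio-caudally dominated distal displacement, and catalog
devices at clinically observed protrusions — so passing tests demonstrate
that the pipeline's mechanics, metrics and validation logic behave correctly
and that the device-length trends emerge from the mechanical model. They do
not demonstrate patient-specific accuracy: real arteries are anisotropic
hyperelastic shells with surrounding tissue, real aortas deform, real
breathing displacement vectors are patient-specific, and deployment involves
contact and plasticity. Pre-EVAR branching-angle deltas come out at roughly
11-15 degrees under the default displacement magnitudes, somewhat above the
8.5-11 degrees reported for the two clinical patients; shrinking them by
lengthening the branches would halve the margin that separates the shorter
and nominal devices, and ordering fidelity was preferred over matching the
delta magnitude. Centerline-level validation is likewise a synthetic
closed loop (known transform + known noise), not an imaging comparison.

## Known limitations

* One rod per branch; the aorta is rigid at the ostium (clamped tangent).
* No twist degree of freedom in the rod; torsional response enters only
  through the transported-curvature bending penalty.
* Geometric deployment: no balloon, contact or plastic strain; flaring is a
  recorded diameter.
* Two quasi-static states (breath-hold inspiration/expiration); no transient
  breathing.
* The stented span straightens fully on deployment; a partially conforming
  device would lie between this model and the undeformed geometry.
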