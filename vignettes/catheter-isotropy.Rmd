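---
title: "Catheter isotropy scoring of transseptal puncture sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catheter isotropy scoring of transseptal puncture sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fossagii)
```

## The problem

Transseptal puncture (TSP) crosses the interatrial septum through the fossa
ovalis (FO), the only safe crossing window, to reach the left atrium (LA).
The choice of crossing point constrains every subsequent catheter maneuver:
a poorly placed puncture can leave pulmonary veins or the posterior wall
effectively out of reach. `fossagii` turns this into a computable
criterion: every vertex of an FO surface mesh is treated as a candidate
pivot for a steerable catheter, and scored by how isotropically the
catheter tip can move throughout the LA cavity from there.

## Catheter model

The inserted segment is modelled as a single circular arc of arc length
$\ell$ and curvature $\kappa$ launched tangent to the inward FO normal at
the pivot — the standard constant-curvature approximation for
continuum/catheter kinematics. (A piecewise or Frenet–Serret shaft model is
deliberately out of scope.) The controls are

* $\varphi \in [-\pi, \pi]$ — bending-plane angle about the insertion axis
  (rad),
* $\theta = \kappa\ell \in [0, \theta_{\max}]$ — total bend angle (rad),
* $s = \ell/\ell_{\max} \in (0, 1]$ — dimensionless insertion.

The tip sits at
$\ell\,(\cos\varphi\,\tfrac{1-\cos\theta}{\theta},\,
\sin\varphi\,\tfrac{1-\cos\theta}{\theta},\, \tfrac{\sin\theta}{\theta})$
in pivot-frame coordinates, with the continuous straight limit
$(0,0,\ell)$ as $\theta \to 0$ (Taylor series below $\theta = 10^{-6}$ rad;
the two branches agree to $10^{-9}$ mm at the switch). Inverse kinematics
is closed-form: the arc through the pivot tangent to the axis and through
the target has $\kappa = 2r/(r^2+z^2)$, from which $\theta$, $\ell$ and
$\varphi$ follow. Targets behind the pivot plane are unreachable by
construction under $\theta \le \pi$ and a tangent launch.

**Why a dimensionless insertion control?** The isotropy index below
compares singular values of the Jacobian
$J = \partial \mathbf{x} / \partial \mathbf{u}$, which only makes sense if
all three columns share units. With $u = (\varphi, \theta, s)$ every
column is in mm per unit control. The raw $(\varphi, \kappa, \ell)$
parameterization is available for sensitivity checks
(`catheter_jacobian(..., parameterization = "phi-kappa-ell")`), but mixes
mm/rad, mm$^2$ and dimensionless columns and is not used for scoring.

## The global isotropy index

For a single configuration,
$\mathrm{GII} = \sigma_{\min}(J)/\sigma_{\max}(J) \in [0,1]$: the ratio of
the smallest to the largest singular value of the catheter Jacobian; 1
means the tip moves equally well in all directions, 0 means a direction of
motion is lost. The package exposes two aggregations over a pivot's
workspace, because a single-configuration ratio and a "global" index over
the whole LA are both defensible readings of the method:

* **global** (default): over all LA sample points reachable from the
  pivot, $\min_c \sigma_{\min}(J(c)) / \max_c \sigma_{\max}(J(c))$, with
  $c$ the closed-form inverse-kinematics solutions. This is a worst-case
  whole-workspace index; it is systematically small because workspaces
  containing near-axis targets (where the $\varphi$-column degenerates)
  pull $\sigma_{\min}$ toward zero.
* **local**: Eq. ratio applied to the single Jacobian at the configuration
  reaching the LA centroid.

Reports always name the mode. Pivots with an empty reachable workspace
score 0 rather than missing — the worst maneuverability, keeping the
argmax well defined. The per-candidate score array is deterministic and
the field is invariant (to $10^{-6}$) under rigid motion of the whole
scene, which the test suite verifies against an independent `svd()` route;
the production path computes the extreme singular values in closed form
from the $1{\times}1 + 2{\times}2$ block structure of $J^\top J$ (the
bending-plane columns are orthogonal to the $\varphi$-column), avoiding
per-point SVDs.

## Geometry handling

Meshes are millimetre STL (ASCII or binary, auto-detected; metre exports
convert with `units = "m"`). The LA cavity is represented by an
axis-aligned grid of strictly interior points (`sample_la_interior()`),
with a ray-parity inside test along a fixed oblique direction; the grid
was chosen over rejection sampling for determinism. The FO centroid
follows the anatomical convention of the *thinnest* point of the fossa
(argmin of the per-vertex thickness map, lowest index on ties), not the
geometric barycentre. Normals orient toward a supplied LA-side reference
point (the RA-to-LA puncture direction); anatomical quadrants (SP/IP/SA/IA)
come from the signs of in-plane offsets along explicitly supplied
superior/posterior axes, because image axes do not map to anatomical axes
without patient-specific information. Zero offsets resolve toward superior
and posterior.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| LA grid spacing | 2.5 | mm | resolves a 40–60 mm cavity with ~4k points; halving it multiplies cost ×8 |
| $\theta_{\max}$ | $\pi$ | rad | "no looping" constraint |
| $\ell$ range | 5–100 | mm | insertion depths plausible from a septal crossing |
| $\kappa_{\max}$ | 0.1 | mm$^{-1}$ | 10 mm minimum bend radius, typical steerable ablation catheter |
| reachability tol | 1.0 | mm | order of EM-tracking / clinical placement precision |
| histogram bin width | 0.01 | — | two-decimal modal scores |

All of these surface in the pipeline configuration
(`default_pipeline_config()`), so sensitivity runs need no code changes.

## Reachability

`map_reachability()` classifies each LA sample from a pivot (by default
the maximum-GII site). A target is reachable when a configuration within
the limits places the tip within the tolerance: the exact inverse
solution when admissible, else its projection onto the limit box — which
admits targets within the tolerance of the reachable-set boundary and
makes the classification agree with an exhaustive
$1°{\times}1°{\times}0.5$ mm configuration-grid search except inside the
grid's own resolution band (verified in the tests). Reachability is
**tip-only**: no shaft–wall collision test is made, because no collision
criterion is part of the method; treat unreachable regions as necessary,
not sufficient.

## Performance statistics

* **Distance metrics** — chordal 3D Euclidean distances (not geodesic on
  the fossa; the straight-line convention) from each puncture to the
  maximum-GII point and the FO centroid, summarized per participant as
  mean ± sample SD (0 for a single trial).
* **Correlations** — Pearson r with a two-sided $t$ test ($n-2$ df) via
  `cor.test`; because "time" may reasonably live on a log scale in this
  setting, both raw-time and log-time correlations are always computed and
  reported side by side.
* **Bland–Altman** — differences STL − physical; bias = mean, limits of
  agreement bias ± 1.96·SD with the *sample* SD (the standard convention),
  percent-within counted on the same pairs.
* **Kruskal–Wallis** — tie-corrected rank test via `kruskal.test`;
  the degenerate all-identical input returns $H = 0$, $p = 1$.
* **Likert** — per-question mean ± SD with the *population* SD by default
  (under which a 4/5 split summarizes as 4.50 ± 0.50, matching the
  reporting style of small-panel face-validity tables); switchable to the
  sample convention.
* No multiple-testing correction is applied; raw p-values are reported.

## The synthetic study

The generator (`synth_config()` and `make_*()`) replaces patient geometry
and participant recordings with a parametric scene of known ground truth:

* **Geometry** — an LA ellipsoid (semi-axes 30/25/22 mm, a dilated atrium
  at atrial-fibrillation scale) with a circular FO disc of 18.46 mm
  diameter (circularity 1.0) tangent to its wall, thickness rising
  parabolically from 0.65 mm at the centre to 1.75 mm at the rim — so the
  thinnest-point centroid is the disc centre by construction.
* **Cohort** — five operators: a trainee (coded 0 years) and cardiologists
  with 10, 10, 14 and 25 years of experience, each contributing 4 recorded
  punctures (the middle of the 3–5 protocol). Punctures are isotropic
  Gaussian scatter in the FO tangent plane, centred halfway between the
  centroid and the maximum-GII site, rejected outside the rim (punctures
  are physically on the septum), with per-operator SDs 6.0 / 2.5 / 2.5 /
  2.0 / 1.5 mm: the trainee's scatter spans the fossa while experts
  cluster within a few millimetres, reproducing the qualitative
  experience–accuracy relationship.
* **Times** — `time = intercept + β_g·GII + β_d·dist + noise` with
  intercept 180 s and noise SD 30 s. The coefficients are *calibrated*,
  not copied: given the Monte-Carlo moments of (GII, centroid distance)
  under the scatter mixture, the linear system
  $\Sigma\beta = \sigma_t v$, $\sigma_t = s/\sqrt{1 - v^\top\Sigma^{-1}v}$
  (with $v$ the target correlation × SD vector) makes the *population*
  correlations of time with GII and with centroid distance equal the
  configured targets 0.656 and 0.566. The moment stream uses a fixed
  internal seed, so calibration is a reusable population property
  independent of the cohort seed.
* **Measurements** — 3 researchers × 50 paired features, uniform truth
  over 2–80 mm, physical = truth − 0.03 mm + N(0, 0.2 mm): the
  Bland–Altman stage recovers the +0.03 mm STL-minus-physical bias.
* **Likert** — scores drawn from the two-point floor/ceiling distribution
  matching each question's target mean in expectation, panel of 5.

Every table draws from its own sub-stream of the master seed, so adding a
table never perturbs the others, and all outputs are bitwise reproducible
under a fixed seed.

**What passing recovery tests do and do not show.** The generator emulates
dispersion structure, correlation structure and systematic bias — not real
anatomy: no pulmonary veins or appendage, a flat circular fossa, no
EM-registration error, Gaussian scatter (the real scatter law is unknown),
and an exactly linear time model. Parameter recovery on this scene
validates the estimators and the pipeline plumbing; it does not validate
the anatomical claims of any particular patient geometry.

## Numerical choices and tie-breaks

Vertex indices are 1-based in R (the CSV thickness interface is 0-based,
as exported by mesh tools); all argmin/argmax ties resolve to the lowest
index; quadrant ties resolve toward S and P; the histogram is left-closed
with scores of exactly 1 in the last bin, so counts always conserve the
candidate total; inverse kinematics treats curvature below $10^{-9}$
mm$^{-1}$ as straight. Problem sizes at the defaults — 197 FO candidates
× ~4.4k LA samples, 1000-seed recovery loops — were chosen so a full suite
plus an end-to-end run completes in well under a minute on a single core,
while keeping the volume-ratio and coverage oracles statistically sharp.

## Known limitations

Tip-only reachability; single-arc kinematics (no sheath/dilator
interaction, no contact forces); inputs assumed pre-registered into the
mesh frame; the workspace-aggregated GII is sensitive to the LA
discretization density near the pivot axis; and the modal GII bin depends
on the (unstated-by-nature) discretization and binning conventions, which
is why the histogram bin width is configuration-exposed rather than fixed.
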