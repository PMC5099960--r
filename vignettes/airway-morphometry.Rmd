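---
title: "Synthetic monopodial airway trees and their morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic monopodial airway trees and their morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaymorph)
```

## The system being modelled

The bronchial tree of the domestic pig differs from the human airway in
three conspicuous ways. First, a *tracheal bronchus* leaves the trachea
before the main carina and feeds the right upper lobe. Second, the two
mainstem bronchi are *monopodial*: at each branching the larger (major)
daughter continues in nearly the parent's direction while the smaller
(minor) daughter leaves laterally at a large angle, so a mainstem pathway
runs on for many generations. Third, the plane in which a parent splits —
the *bifurcating plane* — alternates in a regular pattern relative to the
plane of the trachea and the two mainstem bronchi: one in-plane
bifurcation is typically followed by two out-of-plane ones rotated about
+90° and −90°.

`airwaymorph` packages this anatomy as a generative model plus the
measurement procedures used on segmented airway casts, so that every
morphometric statistic of interest — diameter ratios and bifurcation
angles per planarity class, plane-rotation series, and the piecewise
log-linear decay of diameter with generation — can be recomputed end to
end from synthetic data, including through a CT-like voxelization and
centreline-extraction stage.

## The generator

`generate_tree()` grows a strictly binary tree under
`generator_params()`. The defaults encode the measured pig geometry:

| quantity | default | notes |
|---|---|---|
| trachea diameter | `10^1.3094` ≈ 20.39 mm | generation-0 value of the steep diameter model |
| trachea length | 120 mm | not a measured quantity; configurable |
| d1/D (major), in / out of plane | 0.88 / 0.86 | sd 0.03 |
| d2/D (minor), in / out of plane | 0.57 / 0.35 | sd 0.05; the bimodality is the monopodial signature |
| angle 1 (parent–major), in / out | 14.34° / 0° | sd 5° |
| angle 2 (parent–minor), in / out | 41.44° / 41.37° | sd 7° |
| plane schedule | 0, +90, −90 | applied cyclically along every pathway |
| branch length, generations 1–4 | 40 → 15 mm linear; generation 2 overridden to 12 mm | the "short" second generation |
| branch length, generations ≥ 5 | uniform 5–12 mm | no trend with generation |
| termination | 24 generations or 1 mm diameter | |
| transition zone | 15–40 % of parent length | distal, elliptical flare |
| aspect ratio outside the zone | 0.90–0.98 | Dmin/Dmax |
| flow-divider edge radius | 0.5–1.5 mm | carinal rounding |
| left mainstem curvature | 45 mm radius arc | all other branches straight |

Class-conditional draws are truncated normals (ratios in (0, 1), angles
in \[0°, 90°\]), rejection-sampled so the major daughter is never thinner
than the minor. All draws come from one seeded stream in a documented
order, so a tree is a pure function of its parameter set and seed.
`sd_scale = 0` gives the noise-free limit in which every bifurcation
reproduces the class means exactly — useful as an oracle in tests.

Two structural choices deserve comment:

* **The trachea is two stacked generation-0 segments.** The
  tracheal-bronchus origin and the main carina are then both ordinary
  binary events and every algorithm can assume a bifurcating tree. At the
  tracheal-bronchus event the trachea continues undiminished (d1/D = 1,
  angle 1 = 0); because that is a feature of this special structure and
  not of airway bifurcations, `summarize_morphometry()` excludes it by
  default.
* **Branches never interpenetrate.** A candidate daughter whose capsule
  would come within 1.2 mm of any non-ancestor branch terminates its
  pathway instead. Without this rule, neighbouring subtrees fuse when
  voxelized and centreline extraction finds loops that no real airway
  contains. A consequence is that the breadth of the deep tree emerges
  from available space as much as from the termination rules; default
  trees carry roughly 45–75 bifurcations.

The planarity mixture is structural: with the 0/+90/−90 schedule, one
third of bifurcations are in-plane and two thirds out-of-plane, which
makes the pooled major ratio (0.88 + 2·0.86)/3 ≈ 0.867 ≈ 0.87.

What the generator does *not* emulate: lobar anatomy beyond the role
tags, airway walls (the lumen is the object), CT intensities, noise or
beam hardening (masks are binary), respiratory deformation, and branch
curvature other than the left mainstem arc. Real plane rotations scatter
around 0/±90°; the generator places them exactly on the schedule, so a
passing rotation-series test shows the measurement chain is faithful, not
that real pigs are this tidy.

## Voxelization and meshes

`voxelize_tree()` rasterizes the lumen solid with a voxel-centre-inside
rule (no partial volume), which makes masks bit-reproducible. The solid
is the union of per-branch tubes: semi-minor axis equal to the nominal
radius everywhere, semi-major axis inflated by the reciprocal aspect
ratio, with the aspect falling linearly across the transition zone so the
lumen flares into its daughters; branch ends are rounded so parent and
daughters join without gaps, and the crotch between the daughters carries
a fillet at the flow-divider radius. The representative `diameter_mm` of
a branch is therefore the *minimum* caliper of its cross-section, and the
distance transform — an inscribed-sphere measure — recovers exactly that
quantity. Default spacing is the CT geometry (0.8 mm in-plane, 1 mm
axial); the validation pipeline uses 0.4 mm isotropic.

`surface_mesh()`/`export_mesh()` triangulate the same solid as one closed
ring-strip component per branch and write binary STL; the writer refuses
surfaces whose directed edges do not pair up exactly.

## Extraction: from mask back to tree

`skeletonize_mask()` thins the mask to a one-voxel-wide 26-connected
curve skeleton by distance-ordered homotopic thinning: boundary voxels
are peeled in increasing distance-transform order, only *simple* points
(removal preserves both foreground 26-topology and background
6-topology) are deleted, and curve endpoints are preserved. The exact
Euclidean distance transform is computed by the separable lower-envelope
algorithm with anisotropic spacing; both live in compiled code.

The raw skeleton of a fat junction is not a clean Y: the medial surface
of the fused region thins to extra fibres. The condensed graph is
therefore cleaned deterministically:

* leaf paths that fail to reach beyond the junction's inscribed radius
  plus the prune length (default 2 mm, below the 5 mm minimum branch
  length) are spurs and removed; so are short fat leaves whose distal
  half never approaches a wall;
* junction–junction paths shorter than half the junction radius are
  contracted (one bifurcation, split cluster);
* a terminal branch as wide as its parent and shorter than the parent
  diameter is a medial remnant and dropped.

`build_measured_tree()` roots the graph at the endpoint nearest a hint
inside the trachea. Each path becomes a branch: length is the arc length
of the smoothed centreline (moving average, window 3); diameter is the
median, over the middle 60 % of the branch and outside the junction
fusion regions, of twice a sub-voxel radius estimate. That estimate
samples the distance transform at ±h and ±2h along several perpendicular
directions and applies a slope-corrected tent formula; it is exact on the
ridge for both circular and elliptical sections, where plain
interpolation at a skeleton voxel is biased low by up to half a voxel.
Junctions with more than two outgoing paths are resolved into a chain of
binary events through short *virtual* stubs — the same device as the
stacked trachea; `compute_bifurcations()` skips records touching them.

Directions on measured trees need care. The skeleton junction of a
bifurcation with a large minor daughter sits up to one parent radius
*downstream* of the anatomical branch point, and the first stretch of the
daughter's path crosses the parent lumen. Daughter directions are
therefore fitted to the first locally straight window (straightness =
agreement of the window's two half-fits) beyond the point where the
centreline has left the parent's radius, and the window is then extended
to average out the voxel staircase.

## Morphometry

* `assign_generations()` reproduces the diameter-sorting rule: trachea
  = 0; remaining branches sorted descending and grouped greedily, a group
  absorbing every branch within the tolerance (default 0.3 mm, the
  diameter-measurement uncertainty) of its leader; finally generations
  are clamped to be monotone from the root. The rule is deterministic and
  permutation-invariant, and coarsening the tolerance can only merge
  groups.
* `compute_bifurcations()` defines the major daughter by diameter (ties
  broken by id), measures both angles against the parent's distal
  direction, and takes the bifurcating-plane normal as parent × minor so
  that the *sign* of the rotation distinguishes the two out-of-plane
  senses; rotations are folded to \[−90°, +90°\] (planes are defined
  modulo 180°). The planarity threshold is 45°: observed rotations
  cluster near 0 and ±90, so any threshold in a wide band classifies
  identically.
* `fit_loglinear_segments()` regresses log10 diameter on generation by
  OLS independently within generations 0–11, 12–20 and ≥ 21 ("up to
  generation 11" read as inclusive). The segments are fitted without a
  continuity constraint because the three printed equations are mutually
  inconsistent at the breakpoints. Intervals are Student-t at 95 %.
* `transition_zone_fraction()` measures the contiguous distal run of a
  diameter profile whose aspect ratio stays below 0.9.

## Numerical conventions

Coordinates are mm in a right-handed frame, trachea initially along −z,
reference plane x–z. Serialization uses 17 significant digits, so JSON
round trips reproduce doubles bit-identically. Ties in major-daughter
selection go to the smaller branch id. Folding at exactly ±90° keeps the
sign (a tolerance guards the boundary against rounding). Degenerate
events whose minor is parallel to the parent have no defined bifurcating
plane and are reported with `NA` rotation and excluded from summaries.

## Problem sizes and what the tests show

The test-suite ensembles are sized for single-CPU runs: the
morphology-statistics ensemble pools 12 default trees (over 500
bifurcations); the full measurement round trip voxelizes six trees at
0.4 mm grown to the 2 mm diameter floor — the floor at which
automatic segmentation of airway CT data typically stops resolving lumens,
and 1 mm lumens are only 2.5 voxels wide. Class-stratified *ratio*
statistics are compared on parents of at least 5 mm: below that, minor
daughters drawn under the 1 mm growth floor are censored (the bifurcation
never forms), which would bias observed ratios upward relative to the
generative means; angle draws are independent of the censoring and are
pooled in full.

## Known limitations

* **Proximal junction complexes.** The measured length model makes
  generation-2 branches shorter (12 mm) than they are wide (~17 mm), so
  grandparent and grandchild lumens overlap and the skeleton junctions of
  the proximal tree fuse and displace. Automated direction estimates
  there are heavy-tailed: the full pipeline recovers all class ratio
  means within ±0.03 and the in-plane angle-2 mean within 3°, but the
  in-plane angle-1 and out-of-plane angle-2 means carry several degrees
  of bias from this subpopulation. Cast measurements of this kind are made
  interactively on 3-D models, where a human picks the clean straight
  sections; an automated skeleton cannot fully reproduce that judgement
  at these length-to-diameter ratios.
* **Generation-count stability.** On real cast measurements, widening
  the grouping tolerance from 0.3 to 0.4 mm lowers the deepest generation
  by only 1–2. A synthetic tree is a *complete census* of branches down
  to 1 mm whose small-diameter tail is a dense continuum, so group counts
  there scale like span/tolerance and the deepest generation drops by
  around 5. This is a property of exhaustive sampling, not of the
  grouping rule.
* **Terminal branch lengths.** A medial curve skeleton ends about one
  radius short of a flat or rounded tip, and junction vertices sit inside
  the parent; measured lengths of terminal and junction-adjacent branches
  inherit those offsets. Tube phantoms, whose axes have no junctions,
  measure to within a fraction of a voxel in diameter and about one
  radius per end in length.
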