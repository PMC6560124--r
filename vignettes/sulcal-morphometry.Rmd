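---
title: "Measuring sulcal width and depth from FreeSurfer surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sulcal width and depth from FreeSurfer surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulcmorph)
```

## The measurement model

A sulcus, as FreeSurfer's Destrieux parcellation delivers it, is a set of
labelled vertices on the pial surface mesh.  `sulcmorph` turns that label
into two real-world quantities:

**Width.**  The faces whose three vertices all carry the sulcus label form
a submesh; the edges incident to exactly one submesh face form its
boundary, the contour that runs mid-way between the crowns of the
adjacent gyri.  When that boundary chains into a single closed loop, each
loop vertex searches for the nearest loop vertex *in 3D space* that is
not its neighbour along the loop — by intent, a vertex on the opposite
bank, so the connecting segment bridges the open mouth of the sulcus.
Because the initially nearest vertex need not be the locally optimal one
on the far bank, an exhaustive walk examines every loop position within
`walk_steps` (default 4) cyclic steps of it and keeps the minimum.  The
sulcal width is the **median** of all bridge lengths; the end walls of a
sulcus contribute a minority of short bridges, and the median is the
single aggregation rule that absorbs them.

**Depth.**  The fundus is approximated by the `n_fundus` (default 100)
region vertices with the most extreme sulcal-map (`?h.sulc`) values; each
gets its exact Euclidean point-to-triangle distance to the smoothed
enclosing surface that the gyrification analysis produces
(`?h.pial-outer-smoothed`), and the depth is the median of those
distances.  A straight line from fundus to hull necessarily underestimates
the along-wall depth of a curved sulcus; that bias is inherent to the
definition, is reproduced faithfully by the package, and is verified
against curved synthetic fixtures whose geodesic fundus depth is known.

**Failure semantics.**  A parcellation whose label splits into two or more
edge-disconnected patches, or whose boundary forms several loops (an
annular region) or pinches through a vertex with more than two boundary
edges, cannot be measured as a single loop.  These outcomes are *values*
(`discontinuous-region`, `multiple-loops`, `non-manifold-boundary`)
carried per measure through the cohort table, never exceptions: the batch
layer counts them, and any sulcus failing in strictly more than 10% of
attempted measurements is flagged unsupported for that cohort.  The
superior/inferior temporal and intraparietal sulci are shipped behind an
`experimental` flag because their parcellations fail this way at an
unacceptable rate.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `walk_steps` | 4 | loop edges | local refinement radius around the initial nearest vertex (at most 9 candidates) |
| `exclusion_window` | 5 | loop positions | formalises "not neighbouring in the loop" |
| `min_loop_size` | `2*window + 2` | vertices | smallest loop worth estimating |
| `n_fundus` | 100 | vertices | fundus size; smaller regions use all vertices and flag the shortfall |
| `fundus_direction` | `"low"` | — | which overlay extreme marks the fundus |
| `distance_mode` | point-to-triangle | — | exact surface distance vs vertex-only |

The exclusion window deserves the most care.  "Not neighbouring" must be
wide enough that the nearest admissible candidate cannot lie on the *same*
bank: along a locally straight boundary the candidate at `window + 1`
positions sits roughly `(window + 1) × spacing` mm away along the bank, so
the excluded arc `window × spacing` must exceed the widest sulcus you
expect to measure.  At the ~1 mm spacing of FreeSurfer meshes the default
of 5 excludes ~5 mm, comfortably above typical sulcal widths; our
validation meshes use 0.5 mm spacing and widths up to 6 mm, so the
recovery studies set `exclusion_window = 15` by the same rule.  This is a
resolution calibration, not a tuning knob: choose it once from mesh
spacing and plausible anatomy.

The fundus direction exists because overlay sign conventions differ
between toolchain versions.  As a guard against a silently inverted
overlay, `compute_depth()` checks that the selected fundus lies farther
from the outer surface, on average, than the rest of the region, and
warns when it does not.

## Numerical choices

* Ties in the nearest-vertex search break toward the smaller cyclic
  loop-distance, then the smaller vertex index; loop chaining starts at
  the smallest boundary vertex and prefers the smaller-index neighbour.
  Every estimate is therefore deterministic and orientation-independent.
* Median with an even count is the midpoint of the central pair.
* Point-to-triangle distance classifies the barycentric projection into
  vertex/edge/interior regions and is exact to machine precision; it is
  validated against an independent constrained-projection oracle at
  1e-9 mm.  The vertex-only mode (always an overestimate on coarse outer
  hulls) is retained for comparison with implementations that used it.
* Degenerate inputs have defined outcomes: an absent label is an `absent`
  region, not an error; a loop shorter than `min_loop_size` or an
  exhausted candidate set is a width failure value; zero total variance
  makes ICC undefined (`NA`), not 1; a variable fully explained by the
  partial-correlation controls yields r = 0.
* Vertex indices are 1-based throughout the R API (file encodings keep
  their native 0-based convention at the byte level); coordinates stay in
  the surface's native RAS frame, since all measures are relative
  distances in mm.

## Design decisions on genuinely open points

* **Face membership** uses the conservative all-three-vertices rule, which
  places the region boundary between labels rather than across them.
* **The walk moves along the loop**, not across arbitrary mesh edges: the
  candidate set for a bridge endpoint is the gyral–sulcal contour by
  construction.
* **Pinched boundaries fail** rather than being heuristically repaired; a
  non-loopable boundary is evidence about the parcellation, and repairing
  it silently would change what is being measured.  An opt-in
  `allow_largest_component` measures the dominant patch and flags the
  measure `largest-component` in the output.
* **Depth is still computed when the width loop fails** (the
  fundus-to-hull distance needs no loop); `strict = TRUE` fails both
  together for users who want a per-sulcus exclusion policy.
* **Per-subject mean width/depth** requires all requested sulci present by
  default (the 16-measure bilateral mean); an option averages over the
  available measures and records how many contributed.
* **ICC(1,1)** takes its mean squares from a one-way ANOVA
  (`stats::aov`) and uses the standard F-based single-measurement
  interval: `F = MSB/MSW` with `(n−1, n(k−1))` df, bounds mapped through
  `(F* − 1)/(F* + k − 1)`.  Correlations are reported raw, with no
  multiple-testing correction, and missing data are handled pairwise for
  correlations, listwise within an ICC.

## What the synthetic generator emulates — and what it does not

`make_box_sulcus()` embeds a U-shaped fold in a flat plate: two walls
separated by `true_width`, descending `true_depth`, swept along
`length` at `mesh_spacing`, with optional wall tilt, a circular-arc wall
profile (`fundus_curvature`, making the geodesic fundus depth exceed the
vertical drop), and Gaussian vertex jitter.  Labels are assigned by
construction, so the interior face set, the boundary loop, the deepest-100
list, and both depth notions are recorded exactly; the outer smoothed
surface is the plate's plane, which is precisely what the gyrification
hull is for a single open fold.  Everything is emitted through the
package's own FreeSurfer writers and read back through its readers, and
generation is byte-deterministic given the seed.

`make_cohort()` layers a linear age model on top: uniform ages, per-subject
true width/depth with between-subject noise, per-session within-subject
noise, plus age-related nuisance covariates (thickness, ventricle volume)
for partial-correlation exercises.  The default effect model is calibrated
so the generating age–width correlation is +0.5 and age–depth −0.5
(`slope × sd(age) = sd(other) / √3`).

What the plate does **not** emulate: closed brain-like topology, curved
gyral crowns, label noise at the parcellation boundary, spatially
correlated mesh distortions, or partial-volume effects of reconstruction.
Passing the recovery studies therefore demonstrates that the estimator is
correct *given* FreeSurfer-style inputs whose labels and geometry are
consistent; it does not validate FreeSurfer's parcellation itself, and
cohort-level correlations on real data remain subject to reconstruction
error that the generator does not model.

## Validation problem sizes

The recovery studies use folds of 60 mm length at 0.5 mm spacing (about
8–16k vertices each) for widths 1–6 mm and depths 5–25 mm, recovered
exactly (well within the one-mesh-spacing tolerance) and strictly
monotone.  Loop extraction is cross-checked against the
incident-to-exactly-one-face boundary oracle on 100+ randomised patch
regions; width against exhaustive brute-force enumeration on loops of up
to 40 vertices; surface distances against a per-face constrained
projection oracle on 400-face meshes.  The end-to-end cohort study
measures 150 generated subjects (24 mm folds at 1 mm spacing) and
recovers the generating ±0.5 age correlations within the Fisher-z 99%
band; the ICC study uses 50 replicates of 30 subjects × 2 sessions at a
9:1 variance ratio, whose mean lands within 0.05 of the expected 0.9.
These sizes were chosen to make each property sharply testable at
interactive runtimes.

## Known limitations

* Width is a single scalar per sulcus — no profile along the sulcus length
  and no geodesic (along-surface) width.
* Depth relies on the outer smoothed surface as produced upstream; the
  package never reconstructs the hull itself for real data.
* The Euclidean depth underestimates curved sulci by construction (verified
  property, not a bug).
* The exclusion window is a global count of loop positions; on meshes with
  very uneven edge lengths a distance-based window would be preferable.
* Supported-sulci validation follows the eight-name registry; other
  Destrieux sulci can be measured but carry no validation claim.
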