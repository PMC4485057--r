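---
title: "From traced neurons to printable objects: methods and design"
author: "neuroprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From traced neurons to printable objects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroprint)
```

## The problem

A traced neuronal reconstruction is a tree of sample points: 3D coordinates
with diameters, in microns, grouped into typed sections (soma, axon, basal
and apical dendrites).  That representation is ideal for morphometric
analysis and cable-model simulation, but it is not an object: to print a
neuron, the point-and-diameter skeleton must become a closed, consistently
oriented triangle surface, scaled to printer units, with every wirey
structure thick enough to survive fabrication and handling.

`neuroprint` implements that conversion end to end:

1. import (SWC, restricted Neurolucida ASC) and repair,
2. diameter adjustment and soma rescaling,
3. watertight surface tessellation of the frustum union,
4. optional triangle-to-segment color mapping,
5. scaling to print units, thickness validation, STL/WRL export with
   printed-volume and bounding-box metadata.

## Geometry model

Each section is an ordered polyline of points with diameters.  Between
consecutive points the neurite is a **frustum** (truncated cone); a
single-point soma is a sphere.  The solid to be printed is the union of all
frusta and spheres of all cells in the scene.

Two properties of this union matter for printing. First, the surface must
be **watertight**: every edge shared by exactly two faces, orientation
globally consistent, so that the enclosed volume (the amount of material,
hence much of the cost) is well defined and slicers accept the file.
Second, the construction must tolerate **interpenetrating neurites**:
dendrites passing close to each other — within one cell or across cells
of a microcircuit — must merge into a single unified surface rather than
produce self-intersecting shells.

### Signed-distance tessellation

Both properties are obtained by construction.  The exact signed distance
to a capped cone (negative inside, caps count as boundary) is evaluated
per primitive, and the union's field is the pointwise minimum.  The field
is sampled on a regular grid and the zero isosurface is extracted by
marching tetrahedra over the Kuhn 6-tetrahedron decomposition of each
grid cube.  Because the decomposition matches across cube faces and each
tetrahedron contributes a fixed, combinatorially oriented triangle
configuration (orientation is the permutation parity of the
inside/outside vertex partition times the tetrahedron's geometric
orientation — no per-triangle geometric test), the result is closed and
consistently oriented whenever the surface stays inside the padded grid,
which the bound computation guarantees.  Union semantics are inherited
from the `min`; interpenetration costs nothing because the algorithm is
local.

Numerical details, all chosen once and fixed:

* **Grid pitch (`spatialStep`)** — default one sixth of the smallest
  neurite radius.  Marching tetrahedra with linear interpolation
  underestimates convex volumes with an O(h²) bias; measured on analytic
  references the bias is about −6% (cylinder) and −13% (sphere) at half
  the radius, and −0.7% / −1.4% at one sixth.  The default keeps
  single-primitive volumes well within 2% of the analytic values while
  leaving triangle counts workable; any pitch up to the thinnest radius
  can be requested explicitly, and a coarser-than-radius pitch is refused
  with an error naming the offending radius.
* **Joint spheres.** Flat-capped frusta meeting at an angle leave a thin
  wedge sliver at the cap edge; below grid resolution such slivers pinch
  off into isolated bubbles.  An inscribed sphere at every interior joint
  (and at each child section's attachment point) rounds the elbows and
  removes the slivers.  Terminal tips keep their flat caps, so cylinder
  and frustum reference volumes are unaffected.
* **Padding** of two grid cells beyond every primitive's radius-expanded
  bounding box keeps the isosurface strictly interior.
* **Exact zeros** in the sampled field are nudged outward by 10⁻⁷·pitch so
  no tetrahedron vertex sits on the surface.
* Field values are stored as 32-bit floats (sign decisions and vertex
  interpolation are insensitive at the achievable geometric accuracy);
  distances are computed in doubles.

Volume is computed from the divergence theorem (signed tetrahedra against
the origin), surface area as the triangle-area sum, and connected
components by face-adjacency traversal across shared edges.  Volume
requests on non-watertight meshes are refused rather than silently
reported.

Rigid motions of the input rotate the mesh but also re-align the sampling
grid, so volumes agree only to the discretization accuracy (about 1% at
typical pitches), not to machine precision — an inherent property of
grid-sampled isosurfaces.

## Import, repair, morphometrics

SWC nodes (id, type, x, y, z, radius, parent) are grouped into maximal
unbranched same-type runs; radii are doubled to diameters.  A non-soma
section whose first point continues a non-soma parent carries a copy of
the parent's attachment point, so every consecutive point pair is real
cable; writing SWC reverses this exactly, making read → write → read a
fixed point at the printed precision (six decimals).  A single soma node
is a sphere; the three-row soma used by many archives (root plus two soma
children) is merged into one cylinder-chain section.

**Detached dendrites** — roots with parent −1 that are not soma, or
parents that do not exist — are flagged at load and repaired by
prepending a straight run at the root's own first diameter from the soma
volume centroid to its first measured point.  Measured coordinates are
treated as canonical and never moved.  The soma centroid is the
volume-weighted center of mass of the soma solid (analytic per-frustum
volumes and centroids; the sphere's center for a spherical soma), which
is well defined even when the archive reduced the soma to one sphere.

Morphometrics use the convention that reproduces public archive counts
for bifurcating trees: branch points are non-soma topological nodes with
at least two children; stems are neurite sections attached directly to
the soma (detached roots count as stems until repaired); branches are
maximal unbranched neurite paths between soma, branch points and
terminations, so stems are branches and
`nBranches = 2 * nBranchPoints + nStems` whenever every branch point is a
bifurcation — e.g. 370 = 2·181 + 8 for a motor-neuron-scale tree with
181 bifurcations on 8 stems.

The ASC reader intentionally covers only the common core of the
Neurolucida format: a `("CellBody" ...)` contour and parenthesized trees
of `(x y z d)` points with `|` separators under Axon/Dendrite/Apical
headers.  Unknown blocks are skipped with a warning; the full grammar is
out of scope.  A contour populates `somaOutline` and yields a
single-point soma at the contour centroid with the mean-radius-equivalent
diameter.

## Making a model printable

Printers bound the minimum thickness of wirey structures; at realistic
magnifications biological dendrite diameters print far below that bound,
so diameters must be adjusted — deliberately distorting the morphology to
make it printable.

* **Diameter policies** (`fixed`, `scale`, `floor`, or per-kind maps such
  as axon 6 µm / dendrites 9 µm) transform non-soma diameters only and
  never move coordinates, so lengths are exactly preserved.
* **Soma rescaling** multiplies soma positions and diameters by a factor
  and repositions the result so its volume-weighted center of mass is
  unchanged.  Dendrite attachment points are *not* re-anchored to the
  scaled soma surface — measured coordinates stay canonical and the
  union tessellation absorbs any overlap.
* **Scaling to print units** multiplies coordinates by the
  `coordinateScale`; with microns in and millimeters out the reported
  magnification is `coordinateScale × 1000` (0.2 → 200×).

Thickness is validated on the *logical skeleton*, not on the mesh: the
tessellated surface can be marginally thinner than the logical structure
describes, and skeleton checks are resolution-independent.  Printed
diameter per non-soma point is `diameter × coordinateScale`; points below
`minThickness` (default 1.0 mm) are violations, points below
`recommendedThickness` (default 1.2 mm — aiming for the bare minimum
invites rejections, so the pipeline targets the recommendation) are
advisories.  Threshold comparisons carry a 10⁻⁹ mm slack so
exactly-at-boundary diameters — in particular the output of
`suggestDiameter()`, which inverts the rule — are not flagged through
floating-point rounding.  The soma is exempt (it is not wirey) but its
extent is included in the bounding box.  Structural risks (a heavy soma
atop a long neurite, long unbranched spans) are reported as advisories
with no pass/fail claim: print outcomes give examples of such failures
but no quantitative criterion.

## Color

The tessellation discards logical structure, so coloring by region or by
a scalar (a conductance, a membrane potential) requires mapping each
triangle back to a frustum.  A face centroid is assigned to the frustum
that contains it *by the least amount* — formalised as the smallest
distance from the centroid to that frustum's boundary (lateral surface or
caps, whichever is nearer), restricted to containing frusta; centroids
contained by no frustum (e.g. on a rounded elbow) go to the frustum with
the nearest surface.  Distances equal within 10⁻⁹ µm are ties, resolved
deterministically to the lowest section id then lowest point index.
Whether the original formulation measured interior depth radially or by
nearest boundary is not specified anywhere we could verify; the
nearest-boundary reading is this package's documented choice.

Colors are then per *face* (not per vertex), matching the mapping
granularity: flat kind-based colors, per-section-name colors, or linear
interpolation of a per-section scalar across colormap stops over the
scalar's observed range.  WRL/VRML97 output carries per-face color
(`colorPerVertex FALSE`); STL cannot carry color, so colored meshes are
written geometry-only with a warning.

## Pipeline order and determinism

`runPipeline()` executes read → reattach → (optional) axon removal →
diameter policy → soma scale → thickness validation → tessellation →
(optional) color → scale to print units → measurement → export.  Repair
precedes diameter adjustment so reattachment rays use measured diameters;
the order is configurable in code but this default is the one the tests
exercise.  Thickness violations abort before the (more expensive) meshing
unless `force = TRUE`, mirroring the fact that print services enforce
their rules regardless.

Everything except `PrintableVersion` unique ids is deterministic:
identical configuration and inputs give byte-identical STL/WRL outputs.
Unique ids must differ between runs by design (they identify catalogue
entries), so they are excluded from the manifest's configuration hash.

## The synthetic generator

`genTree()` grows a soma sphere with `nStems` stems and exactly
`nBifurcations` bifurcations at randomly chosen open tips: segment
lengths uniform in `segmentLengthRange` (default 8–15 µm), branch
directions uniform in a cone about the parent direction, per-order
diameter taper, all from one seeded generator so fixed seeds give
byte-identical SWC across platforms.  Ground truth (cable length, summed
analytic frustum volume, soma volume, topology counts) is recorded in the
morphology metadata.  Defect injectors reproduce the tracing artefacts
the repair stage exists for: a detached stem, a zero-diameter point, and
slab amputation with flattening (the signature of slice preparations).
`genCluster()` arranges cells on a ring with apical dendrites that pass
through a shared convergence point, guaranteeing overlap — the printable
analogue of mitral cells converging on one glomerulus.

What the generator does *not* emulate: biologically realistic branching
statistics, dendritic spines (absent from printable models in any case),
diameter noise along sections, or real tracing error distributions.
Passing tests therefore demonstrate correctness of the geometry and
bookkeeping on known-truth inputs, not fidelity to any particular
species or cell type.

Test problem sizes are deliberately modest — single primitives at default
resolution, trees of ≤ 12 bifurcations at 0.25–0.5 µm pitch, one
181-bifurcation tree for the counting convention, 10⁶-sample Monte-Carlo
oracles — chosen to probe every code path with exact or tight oracles
while keeping the full suite in well under a minute.

## Known limitations

* Volumes converge O(h²) from below; at coarse explicit pitches thin
  near-tangential unions can still pinch off small satellite shells
  (each one itself watertight).  The default pitch avoids this on all
  shipped fixtures.
* The ASC dialect is restricted (no markers, spines, or metadata blocks).
* Thickness validation models printability as a per-point diameter rule;
  it does not simulate mechanical stability.
* `soma_outline` contours inform the soma position and equivalent
  diameter but are not yet revolved into a contoured soma surface; the
  spherical/cylinder-chain soma is used instead.
* Triangle counts are not budgeted or decimated; choose the pitch to
  taste.
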