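---
title: "Quantifying branching canal networks from micro-CT volumes"
author: "canalmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying branching canal networks from micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canalmorph)
```

## The problem

Rhizostome jellyfish such as *Rhizostoma pulmo* lack a single mouth: their
gastrovascular system is a network of branching canals running through the
umbrella, the scapulae and the eight oral arms, ending in hundreds of tiny
openings on the arm margins.  Resin endocasts of this system can be imaged
by X-ray micro-computed tomography (the scale this package defaults to is
an isotropic 62.0 um voxel), and the biology then turns into a
quantitative image-analysis problem: how many canals are there, how long
and how tortuous are they, how thick, how many openings does each
substructure carry, and what do those numbers extrapolate to for the whole
animal?

`canalmorph` implements that analysis chain as a reusable pipeline:

1. **Segmentation** -- Otsu thresholding of the full-volume 256-bin gray
   histogram; foreground is strictly above the threshold.
2. **Local thickness (LT)** -- for every foreground voxel, the radius of
   the largest sphere fully inside the foreground that contains the voxel.
3. **Connectivity-preserving smoothing** -- isotropic Gaussian blur
   (5-voxel window) re-thresholded at the highest level that preserves the
   26-connected component count.
4. **Skeletonization** -- homotopy-preserving 3D thinning to a
   one-voxel-wide medial axis, followed by two 4-voxel pruning cycles.
5. **Graph statistics** -- branches, junctions, endpoints; per-branch
   length, end-to-end Euclidean distance (ED), tortuosity ED/L, and the
   LT label along the medial axis.
6. **Morphometry** -- per-substructure volumes (cm^3), opening counts
   (skeleton endpoints), whole-organism extrapolation, and the scalar
   body measures (apparent diameter AD = 2 RD / pi of a hemispherical
   umbrella; adherence ratio of the paired hemi-canals).

Because real scans of this kind are not publicly deposited, the package
ships a synthetic phantom generator that renders branching-tube networks
with exact analytic ground truth; every stage is validated against it.

## Conventions that matter

**Axes and units.** Grids are `dim = (z, y, x)` with z the slice index;
`spacing` and `origin` follow the same order, in micrometres.  A voxel's
physical centre is `origin + (index - 1) * spacing`.  Anisotropic spacing
is supported throughout: all distances are computed in physical units, so
spheres become ellipsoids in index space.

**Local thickness is a radius.** `localThickness()` reports the radius of
the maximal inscribed sphere (a `--diameter` style switch,
`convention = "diameter"`, doubles the values for interoperability with
tools that report diameters).  The discrete definition is:

* the Euclidean distance transform (EDT) measures from each foreground
  voxel centre to the nearest *background voxel centre*, with positions
  outside the grid counting as background;
* the inscribed-sphere radius at a voxel is `EDT - h`, with
  `h = min(spacing)/2`, i.e. radii run to the voxel boundary -- an
  isolated voxel has thickness `spacing/2`, not `spacing`;
* a sphere *contains* a voxel when it reaches within `h` of the voxel's
  centre.  Without this half-voxel allowance the surface shell of a
  digital ball would be counted as thin as a lone voxel, which is an
  artifact of sampling, not geometry.

The transform is computed exactly by sphere propagation over descending
radius levels (a voxel gets thickness at level `r` iff its distance to
the set of voxels with inscribed radius at least `r` is at most `r + h`),
not approximated by the EDT alone.  The test suite checks it against a
brute-force all-pairs maximal-sphere search on random small masks; the
two agree to within one voxel (exactly, when the level ladder is not
thinned -- thinning only engages beyond `maxLevels = 96` distinct radii
and bounds the error by the largest gap between retained levels).

**LT is measured before smoothing.** The thickness field is computed on
the raw binarized volume; the smoothed volume feeds only the
skeletonization.  Smoothing exists to suppress spurious skeleton branches
caused by surface roughness, but it also thins fine tubes -- at radii of
2-3 voxels by several tenths of a voxel -- which would bias every calibre
statistic downward if the LT were taken afterwards.

**Estimated tube radius.** A medial-axis LT label systematically
understates the tube radius by about half a voxel (the boundary-versus
centre convention above).  The branch table therefore carries both the
raw `medianLtUm` and `radiusUm = medianLtUm + min(spacing)/2`; the latter
is the estimator to use when comparing against physical radii, and it is
what the distribution-recovery checks use.

## Segmentation details

`otsuThreshold()` maximizes the between-class variance over all 255 cuts
of a 256-bin histogram; ties break toward the lowest maximizing index so
the result is deterministic.  8-bit volumes get one bin per gray level;
wider ranges are rebinned over the observed range.  A histogram with all
mass in one bin has no threshold and is an error, not a guess.

"Smoothing that preserves connectivity" is operationalized as: blur the
0/1 mask with an isotropic Gaussian of window `kernelSizeVx = 5` and
sigma `kernelSizeVx/4` voxels, then re-threshold at the highest level of
the descending ladder 0.50, 0.45, ..., 0.05 for which the number of
26-connected foreground components equals that of the input.  If no level
preserves the count the 0.5 level is used and a warning says so.  The
window-to-sigma ratio follows common image-suite defaults; both the
window and the ladder are exposed in `pipelineConfig()`.

Foreground connectivity is 26 and background 6 throughout -- the standard
complementary pair under which 3D thinning is topologically sound.

## Skeletonization, pruning and the graph

The thinning is sequential border thinning over six directional
sub-iterations (z-, z+, y-, y+, x-, x+): a border voxel is deleted only
if it is a (26,6) *simple point* -- its deletion changes neither the
foreground 26-topology nor the background 6-topology, checked directly on
the 3x3x3 neighbourhood -- and is not a curve endpoint (at most one
foreground 26-neighbour).  Simplicity is re-checked at deletion time, so
every deletion is individually homotopic and the component and tunnel
counts of the mask are preserved by construction; the fixed scan order
makes the output deterministic.  The tests verify topology preservation
through the cubical-complex Euler characteristic on ball, cylinder and
torus phantoms.

**Pruning** deletes, per cycle, every terminal branch whose voxel count
(slab voxels plus the endpoint voxel, the junction voxel excluded) is at
most `pruneVx = 4`, and repeats for `pruneCycles = 2` -- the protocol's
parameters.  Pruning is measured in voxels along the path, not physical
length.  Branches connecting two junctions, isolated endpoint-to-endpoint
paths and closed loops are never deleted, so no component disappears.
When a deleted twig demotes its junction to degree two, the flanking
branches merge and their lengths sum, which keeps the tree identity
`B = E + J - 1` on loop-free structures.

**Graph construction** classifies skeleton voxels by 26-degree (endpoint
1, slab 2, junction >= 3), merges adjacent junction voxels into junction
nodes, and traces slab paths between nodes.  Two consolidation rules
remove discretization artifacts rather than anatomy:

* junction nodes joined by a branch shorter than the sum of their local
  inscribed-sphere radii are merged -- two branch points inside one
  maximal sphere are one physical junction.  Thinning occasionally
  resolves a single bifurcation as two nearby clusters; the merge radius
  scales with the local canal calibre rather than a fixed voxel count.
* a "junction" cluster left with fewer than three incident branches (a
  locked clump of mutually adjacent voxels on an otherwise ordinary path,
  or at a tip) is dissolved into the branch, or reclassified as an
  endpoint.

Both rules need the LT labelling and can be disabled
(`mergeJunctions = FALSE`).

**Branch length** is measured on the voxel polyline after Gaussian
smoothing of the coordinates (sigma 2 voxels, terminal points clamped so
the path still spans its endpoints).  Raw sums of face/edge/vertex steps
overestimate oblique digital paths by up to ~8%, which would visibly
corrupt tortuosity; the smoothed estimator removes the staircase bias
while `lengthMethod = "steps"` retains the plain sum for comparison with
plugin-style tools.  Because the smoothed path still starts and ends at
the branch's terminal points, `ED <= L` and tortuosity stays in (0, 1];
it equals 1 exactly for collinear branches.  Branches ending at a
junction are extended to the junction-node centroid so lengths run branch
point to branch point.  Closed loops on a single node get ED = 0 and are
flagged and excluded from tortuosity averages.

## The phantom generator

`sampleTreeSpec()` draws a full binary tree of tube segments in physical
units, then `voxelize()` renders it at any requested spacing -- this
split is what makes spacing-convergence tests possible.  What the
defaults emulate, and why:

* **branch lengths**: lognormal with median 2.36 mm (the average branch
  length reported for oral-arm canal systems at this scale) and log-sd
  0.25;
* **radii**: lognormal with median 200 um and log-sd 0.2, floored at
  130 um so every tube stays resolvable (>~2 voxels) at the 62 um scan
  scale; canal-thickness distributions in real endocasts follow an
  almost perfect lognormal, dominated by thin distal canals.  Radii are
  drawn i.i.d. for the whole tree and then assigned in level order
  (thickest proximal): the pooled distribution is exactly the declared
  lognormal while junctions taper realistically -- strongly mismatched
  sibling radii would genuinely split the medial bifurcation point, and
  real canal trees taper distally anyway;
* **tortuosity**: every branch is a circular arc with chord/arc ratio
  0.8, matching the slightly-curved canals of the real system; arcs (not
  splines) keep the ground-truth tortuosity analytic;
* **branching**: children leave the parent's end tangent at 45 degrees
  (plus or minus 5 of jitter) on opposite azimuths;
* **rendering**: foreground 200, background 30 on an 8-bit scale with
  additive Gaussian noise of sigma 10, seeded from the spec.

Placement is rejection-sampled: a segment is redrawn (with a widening
direction cone) until every non-adjacent tube clears every other by the
sum of their radii plus 250 um, and whole trees are redrawn from a
seed-derived stream in the rare case a segment cannot be placed.  The
clearance is deliberately larger than anything the 5-voxel smoothing can
bridge, so the voxelized topology equals the declared tree -- that is the
property that makes exact branch/junction/endpoint recovery a fair test.

Voxelization marks a voxel foreground when its centre lies within the
local tube radius of the centreline.  Slab pieces are flat-capped;
inscribed spheres are added at interior polyline joints and shared
junction points, which fills the wedge gaps between consecutive slabs
(those gaps otherwise open pinhole tunnels through curved tubes) without
adding any volume outside the true tube; free ends stay flat so the
analytic cylinder volume pi r^2 L is the right reference.  The grid
origin is snapped to the lattice through the bounding-box corner so
axis-aligned fixtures are sampled symmetrically.

The ground truth carries, per branch, the analytic arc length, chord,
tortuosity and radius, plus an *expected medial-axis length*
(`axisLengthUm`): a curve skeleton of a capped tube genuinely ends about
one tube radius inside each free tip, so terminal branches are discounted
by their radius at free ends.  Recovered branch lengths are compared
against this quantity.

`makeArmPhantom()` builds a stylized labelled oral arm -- a central canal
with lateral branchlets and three wing "combs" of terminal tubes -- whose
per-label opening counts are exact by construction; the canal's proximal
opening counts toward its total, as the canal opens to the stomach.  If
the requested counts exceed the voxel budget the spacing doubles with a
warning.

What the phantoms deliberately do **not** emulate: beam hardening,
cone-beam artifacts, partial-volume gray ramps, incompletely filled
canals (beyond what noise does), anastomoses, or contact between
neighbouring structures.  Passing these tests therefore shows the
geometry pipeline is correct on clean tubular networks; it does not show
robustness to acquisition artifacts, which on real scans must still be
judged by inspection of the intermediate masks.

## Validation suite and problem sizes

The test-suite and the `scripts/acceptance.R` script recompute, from
scratch, on sizes chosen to keep a desktop run in minutes:

* Otsu vs an exhaustive oracle on 200 random histograms;
* local thickness vs brute-force maximal spheres on random blob masks up
  to 20^3 voxels, agreement within one voxel;
* topology preservation on ball/cylinder/torus; 2 endpoints for the
  cylinder, 0 for the torus;
* pruning fixtures at the 4-voxel boundary;
* exact B/J/E recovery and the tree identity on 50 random tree phantoms
  (3-15 branches each) through the full pipeline, with mean branch
  length within 10% of the expected medial-axis length;
* tortuosity exactly 1 on straight paths and within 3% of
  `2 sqrt(2)/pi ~ 0.9003` on a fine quarter-circle tube;
* calibre within one voxel on cylinders of radius 3, 5 and 8 voxels, and
  lognormal (mu, sigma) of radii recovered within 10% on >= 500 pooled
  branches;
* voxelized cylinder volume within 3% of pi r^2 L at 62 um, the error at
  least halving after two spacing halvings (62 -> 15.5 um; a single
  halving is not asserted because the digital-disk area error oscillates
  with how the radius falls on the lattice);
* bitwise-identical reports on repeated runs of the arm-phantom preset.

## A worked example

```{r example, eval = FALSE}
library(canalmorph)

ph <- makeArmPhantom(c(12, 7, 7), 4, seed = 1)
report <- runPipeline(pipelineConfig(input = ph$volume,
                                     labels = ph$labels))
report
extrapolateOpenings(234, c(129, 128), 81, 8)
```

## Known limitations

* The junction-consolidation radius assumes canals meet at angles well
  away from tangency; nearly-parallel merging vessels can legitimately
  have two close branch points that the rule would merge.
* Opening counts equal pruned-skeleton endpoints; apertures narrower than
  a voxel, or canals the casting resin never filled, are invisible to the
  method by construction.
* The thinning is sequential, so the skeleton is deterministic but can be
  off-centre by a voxel on even-diameter tubes; all accuracy statements
  above carry that one-voxel granularity.
* `smoothPreservingConnectivity()` preserves the component count, not
  every component's identity: in pathological masks a component could
  vanish while another splits.  The warning path covers the count; the
  tests cover tubular geometry only.
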