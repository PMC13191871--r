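---
title: "Overlap-based multi-object and lineage tracking: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap-based multi-object and lineage tracking: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moltrack)
```

## The tracking problem

`moltrack` solves the association stage of tracking-by-detection: given a
per-frame instance segmentation of a 2D or 3D time series, decide which
instances in different frames are the same physical object, reconstruct the
lineage forest (splits, merges, emergence, disappearance, reappearance),
and emit temporally consistent identifiers. It is training-free and purely
overlap-based: no intensity features, no motion models, no learned
association. That makes it applicable wherever a segmentation exists but
annotated tracking ground truth does not — the typical situation in
longitudinal biomedical imaging.

Two data regimes are distinguished by a single configuration switch:

* **S1** — objects are (near-)static relative to each other while the whole
  field of view moves between acquisitions: protein accumulations in
  deformable tissue, lesions across scan sessions. Every frame is
  registered to one reference frame and a *single global union map* links
  instances across the entire series.
* **S2** — objects move independently but the sampling is dense enough that
  per-step displacements are small: cells in in-vitro videos. Each frame is
  registered to its predecessor and *pairwise union maps* chain instances
  frame to frame. The pairwise transforms are deliberately never composed
  into a global frame: under independent motion, different objects may
  occupy the same location at different times, and a global union would
  identify them.

## Model and assumptions

Let `i_{t,k}` be instance `k` of frame `t` with voxel mask `Mask(i_{t,k})`.
After registration (nearest-neighbor resampling of labels — the only
interpolation that cannot invent label values), the union map is the
voxelwise OR of the aligned masks, relabeled by connected components
(8-connectivity in 2D, 26 in 3D) into union IDs `u_m`. The central
assumption is that *aligned overlap implies identity*: instances from
different frames that fall into the same union component observed the same
physical object. This fails exactly when registration fails, which is why
the paper-level accuracy of the method is bounded by registration quality.

The mapping from initial IDs to union IDs forms a bipartite graph. Ideally
each instance touches one union component; nearest-neighbor resampling,
however, can break thin structures into fragments that touch several
components — a conflict. Conflict resolution maps every connected group of
the bipartite graph to one lineage ID `L_q`. This one operation repairs
fragmentation, merges interacting families, and in S2 collapses the
frame-by-frame chains.

Per lineage, the morphogenetic graph orders member instances by timepoint
and connects consecutive occupied timepoints with IoU-weighted edges. In S1
"consecutive occupied" skips frames where the lineage was undetected — the
global union acts as a gap-closing mechanism with no maximum gap length
imposed. In S2 edges connect only adjacent frames; a missing detection
therefore breaks the chain (one extra lineage and tracked ID per gap), a
documented limitation of the pairwise regime; n-frame gap closing is out of
scope here.

Tracked IDs are maximal event-free path segments of the morphogenetic
graphs: propagation starts at each root and a fresh ID (with a parent
link) starts at every split and merge. When the biology forbids fusion
(`allow_merges = FALSE`), each merge child keeps only its maximal-IoU
incoming edge; the severed branches terminate, and the child still starts
a new track carrying the surviving parent link, so parent links always
form a forest. Finally, IDs are projected onto the original unregistered
frames, preserving the native geometry exactly.

## Branching resolution and tie-breaks

When several instances at `t` face several at `t'`, every child keeps its
maximal-IoU incoming edge and every parent left unmatched keeps its
maximal-IoU outgoing edge. This guarantees no node is stranded, yields
exactly the parent-to-both-children edges at a split and both
parent-to-child edges at a merge, and drops weak cross edges in ambiguous
2-vs-2 situations. IoU ties break toward the larger absolute intersection,
then toward the smaller instance label — fully deterministic, and logged
nowhere else than in the edge table itself. A simultaneous split-and-merge
with exactly equal IoUs is resolved by the same rule; it is deterministic
but arbitrary, which we consider acceptable because exact ties have
measure zero off synthetic grids.

Lineage IDs are numbered by the earliest `(timepoint, label)` of any
member, tracked IDs in traversal order of the lineages, so repeated runs
are bit-identical.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `scenario` | — | S1 (reference registration, global union) or S2 (pairwise). |
| `connectivity` | 8 (2D) / 26 (3D) | Voxel adjacency for all component analyses. |
| `reference` | 1 | S1 reference frame. Configurable because objects may be absent from the first frame. |
| `min_overlap` | 1 voxel | Minimum aligned overlap for a conflict-graph edge. 1 means any intersection counts; raise it only to suppress salt-and-pepper contacts in noisy segmentations. |
| `allow_merges` | `TRUE` | `FALSE` enforces strict cell-style lineage (no fusion events in the output). |
| `registration` | translation backend | See below. |

Registration is pluggable behind one contract: `reg_identity()` for
pre-aligned data; `reg_translation()`, an FFT cross-correlation estimator
that recovers integer shifts exactly and needs no external software;
`reg_supplied()` for transforms computed elsewhere (including ground truth
in simulations); and `reg_external()`, an adapter that shells out to any
affine registration executable working on raw images and parses a
plain-text homogeneous matrix. Transforms use the pull (resampling)
convention — fixed-frame voxel coordinate to moving-frame coordinate,
0-based, column-major axis order — stated explicitly because conventions
differ across tools. A backend failure on a frame pair degrades to the
identity transform with a warning rather than aborting the series.

Voxels are treated isotropically; anisotropic spacing influences neither
connectivity nor IoU and is the caller's responsibility (e.g. resample
before tracking).

## Evaluation metrics

**LNR.** Ground truth and prediction partition the same instances into
lineages. Lineages are matched one-to-one by the Hungarian algorithm with
cost `1 - IoU` of their instance sets (dummy padding for unequal counts;
zero-IoU pairings are discarded as unmatched rather than credited). Then

`LNR = max(0, 1 - (N_unmatched + N_misassigned) / (|L_gt| + N_instances))`

where `N_unmatched` counts unmatched lineages on both sides,
`N_misassigned` counts instances whose predicted lineage is not their
ground-truth lineage's match (instances of entirely unmatched lineages
included), and the denominator is the maximal number of corrections needed
to rebuild the reference from scratch. The linear assignment solver is an
in-package O(n³) Kuhn–Munkres implementation, cross-checked in the test
suite against exhaustive enumeration.

**TRA / AOGM.** Both tracking results are acyclic oriented graphs: one
node per detection, link edges inside a track, parent edges across events.
Detections correspond by the majority rule (a predicted node matches a
reference node it covers by more than half; each absorption beyond the
first costs a node-split operation). The transformation cost AOGM sums
weighted operations — NS=5, FN=10, FP=1, ED=1, EA=1.5, EC=1 by default,
the Cell Tracking Challenge convention, configurable — and
`TRA = 1 - min(AOGM, AOGM_0)/AOGM_0` with `AOGM_0` the cost of building
the reference from an empty prediction. A detection-fixed variant
(`variant = "edges"`) scoring only edge operations is selectable; the full
AOGM is the default.

Lineage-IoU is computed on node sets. An edge-aware lineage IoU was
considered and rejected: with a shared node universe the node-set IoU
already determines the matching, and edge-aware costs would double-count
the structure that TRA measures.

## The synthetic scenario generator

`simulate_scenario()` renders axis-aligned ellipsoid blobs with per-frame
radius jitter (≤10%, emulating growth and shrinkage without topology
change) and replays a scheduled event system — split, merge, appear,
vanish, gap — into label frames plus complete ground truth (lineage
partition, track table, tracking graph, true affines). One global seed
drives a single RNG stream, so every scenario is bit-reproducible.

Design choices that matter for interpreting test results:

* **Spacing is a guarantee, not a tendency.** Placement enforces surface
  clearance (`min_spacing`, default 4 voxels) including the *future* reach
  of scheduled events: split children are displaced beyond the parent
  footprint and fused blobs bulge past their smaller partner, so
  event-scheduled objects reserve extra clearance. Rendering asserts that
  no two blobs ever share or touch voxels; distinct families can therefore
  never fuse by construction, and a reported lineage fusion is always a
  tracker error, not a rendering accident. Sequential packing restarts
  from scratch when it dead-ends, keeping determinism.
* **Merge partners differ in size** (radii drawn from the lower vs upper
  third of the radius range). A fusion of near-identical partners has no
  well-defined dominant parent; distinct sizes give the max-IoU parent
  decision a stable margin, so ground truth and prediction agree on it
  even under resampling noise.
* **Splits halve volume**: children radii are scaled by `2^(-1/d)` and
  displaced along a random axis so both children overlap the parent
  footprint — keeping IoU-based branch resolution nontrivial.
* **S1 jitter** applies a per-frame random affine (bounded translation,
  rotation, scale) about the image center, redrawing until every blob
  keeps at least 80% of its voxels in-field; the exact inverse transforms
  are stored for the passthrough backend. **S2 motion** is a per-object
  Gaussian random walk with collision redraws; divisions re-anchor the
  children to the parent's walked position.
* **At most one scheduled event per seed object.** This keeps the
  scheduled event counts identical to the event tags the classifier should
  produce (a vanish on an object whose lineage continues elsewhere, for
  instance, would legitimately not be tagged).
* `corrupt_series()` emulates upstream segmentation errors: independent
  per-detection dropout and random boundary erosion/dilation, with
  dilation barred from bridging two labels.

What the generator does **not** emulate: photorealistic microscopy (PSF,
photobleaching, intensity statistics), deformable (non-affine) tissue
motion, densely touching objects, and segmentation label noise other than
the corruption model above. Perfect scores on clean synthetic scenes
therefore demonstrate the correctness of the association logic, not
robustness to real-world registration or segmentation failure — on real
data the dominant error source is registration accuracy, which enters here
only through the backend.

## Numerical choices and degenerate inputs

* Connected components are numbered by the array scan order (ascending
  column-major index) of their first voxel; all outputs inherit this
  determinism.
* Instance inputs with more than one positive label skip the
  per-frame component analysis; a label whose support is disconnected is
  kept as one instance with a warning, never re-split.
* Instances whose registered mask is empty (objects pushed out of the
  field) become warned singleton lineages/tracks during back-projection,
  so foreground support is always conserved.
* Empty frames, empty series stages and single-frame series are valid
  inputs throughout; a single-frame S2 series degenerates to a
  self-spanning union map.
* The translation backend falls back to the identity (with a warning) on
  empty frames, where cross-correlation is undefined.

## Problem sizes

The shipped tests and the acceptance script use a 3D 64×64×64 series with
8 frames and 20 objects (3 splits, 2 merges, 1 gap) as the reference
scene, 2D 64–96 px scenes for scenario-level properties, ≥200 random
bipartite graphs (up to ~500 nodes) for the union-find equivalence, and
the full cross-product of instance partitions (up to 6 instances, 3
lineages) for the exhaustive LNR check. These sizes exercise every code
path while keeping a full run in minutes on one core; the algorithms scale
to the hundreds of objects per frame reported for real data, the dominant
costs being the component labeling (linear in foreground voxels) and the
per-lineage IoU tables.

## Known limitations

* S2 cannot re-identify objects across missing detections (by design of
  the pairwise union; the S1/S2 contrast under a one-frame dropout is part
  of the acceptance suite).
* Association is purely spatial; two objects that genuinely swap positions
  between sparse acquisitions in S2 are indistinguishable to any
  overlap-based method.
* Only affine misalignment is compensated; non-rigid deformation must be
  handled upstream or accepted as overlap noise.
* The external-tool registration adapter is a contract (executable lookup,
  matrix parsing); no specific third-party registration tool is bundled.
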