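---
title: "Interval-coded spatial domains: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-coded spatial domains: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intervox)
```

## The problem

Embryo atlas resources curate thousands of gene-expression assays by
*mapping* each assay onto a stage-matched 3D reference model of the embryo,
so that expression domains from different genes, labs and imaging modalities
live on one voxel grid and become comparable as sets. Everything downstream
— "which genes are expressed here?", "which patterns look like this one?",
"which genes form a syn-expression group?" — is then set algebra over binary
spatial domains, plus a viewer that can cut the annotated volume along any
plane. This package implements that computational core: the compressed
domain representation, its set and morphological algebra, similarity search
and clustering, the 2D curation (landmark warp + colour thresholding), and
arbitrary-plane virtual sectioning.

## Interval coding

A binary 2D/3D region is stored as, per grid line, an ordered list of
maximal half-open column intervals `[start, end)` (run-length coding). Two
representation rules make the coding *canonical*: intervals on a line are
sorted and separated by strict gaps (touching intervals are merged at
construction), and empty lines are simply absent. Canonicality means two
domains cover the same voxel set **iff** their interval tables are
structurally identical, so equality testing is `identical()` on an integer
matrix and needs no voxel expansion.

Coordinates are 0-based and intervals half-open. The classical
implementation of this idea uses 1-offset inclusive intervals; the
half-open 0-based convention was chosen here because it composes cleanly
(`end - start` is the length, concatenation needs no `±1`) and it is stated
explicitly in the `.ivd` serialization header so the choice can never be
silently misread.

Union, intersection and difference are per-interval sweeps implemented in
C++ (`src/ivcore.cpp`): cost is proportional to the number of intervals,
which for compact biological shapes scales with one dimension fewer than
the voxel count — linearly in the diameter for 2D regions, quadratically
for 3D. The package asserts this operationally: quadrupling the radius of a
disc must grow its interval count by < 6x while its area grows > 12x. The
n-ary union is the canonicalization of a concatenated interval table, which
is what makes dilation (below) cheap.

Domains optionally carry a *reference frame* (model id + grid shape).
Binary operations refuse to combine domains from different frames rather
than resampling: overlap scores between patterns mapped to different models
are not meaningful, and a silent resample would hide exactly the error the
frame id exists to prevent.

## Morphology

Dilation and erosion use flat city-block (diamond/octahedron; connectivity
4/6) or chessboard (square/cube; 8/26) structuring elements. Radius `r`
means the `r`-fold Minkowski sum of the unit element, so
`dilate(A, r1 + r2) == dilate(dilate(A, r1), r2)` exactly. Dilation is a
union of row-shifted, x-expanded copies of the interval table; erosion is
computed by duality (dilate the complement within the bounding box grown by
`r + 1`, subtract). Outside the grid counts as background for erosion; when
a domain carries a frame, dilation is clipped to the frame so behaviour
near the model boundary is reproducible. No Euclidean structuring elements
are provided — nothing downstream needs them, and integer grid balls keep
every result exactly representable.

The distance transform returns integer grid distances (city-block default)
computed by successive unit dilations — the `d`-th dilation ring *is* the
set at distance `d`, so the transform inherits the interval algebra's
correctness. Connected-component labelling runs union–find over the
interval table directly (an interval is adjacent to intervals on
neighbouring lines whose column ranges overlap, widened by one voxel for
the diagonal connectivities); components are returned sorted by size
descending with bounding-box tie-breaks so output order is deterministic.

## Similarity search

The global score is the Jaccard index `|A∩B| / |A∪B|`, computed from
interval sizes without materialising the union. A query identical to a
database entry scores exactly 1, which is the acceptance desk-check: a
"find similar" query over a database containing the query's own entry must
return that entry first at score 1.

The *local* score used for painted region-of-interest queries is

```
lossst(q, e; r) = |q ∩ e| / |q ∪ (e ∩ dilate(q, r))|
```

i.e. a Jaccard index in which expression farther than `r` dilation steps
from the query is ignored rather than penalised. This is built from exactly
the four primitives the interval engine accelerates (intersect, union,
dilation, difference). The production search tool's published weighting is
not reproduced in the sources available to this package; the form above is
a documented stand-in with the same intent, pinned against an independent
dense-array evaluation in the test-suite, and satisfies
`lossst(q, e, r) >= jaccard(q, e)` for every pair (the local denominator
never exceeds the global union). The dilation radius defaults to `r = 2`
voxels with 8/26-connectivity; both are exposed because no published value
fixes them.

Ranked queries score the `detected` strength level by default (the level
every curated entry must carry), drop zero-scoring patterns, sort by
descending score and break ties by entry id, so rankings are deterministic.
2D whole-mount query regions and 3D section-painted regions go through the
same code path — a domain is a domain.

## Syn-expression clustering and occupancy

Clustering follows the two-step signature construction: every pattern is
compared with every other pattern pairwise (Jaccard on the chosen level),
and the *rows* of that matrix — each pattern's similarity profile against
the whole set — are the feature vectors. Agglomerative clustering uses
Euclidean distance between signature rows and average linkage (UPGMA).
Neither choice is prescribed by the method's description; Euclidean/UPGMA
were fixed as defaults because they are the standard robust pairing for
profile vectors, and both are arguments (`sig_distance`, `linkage`), with a
`mode = "direct"` alternative that clusters on `1 − Jaccard` itself for
comparison. Signature clustering deliberately differs from direct overlap
clustering: two patterns that never touch can still cluster together if
they overlap the *same* third patterns — that is what makes it a discovery
tool rather than a co-location test.

Identical signatures merge at height 0; `cut_tree(tree, k)` removes the
`k − 1` highest merges. No default `k` is asserted anywhere: the method's
description gives no stopping rule, so choosing the cut is left to the
user, and the tests only claim recovery at the *true* `k` of planted
fixtures.

Per-node heatmaps and standalone occupancy maps count, per voxel, how many
member domains contain it (`sum(counts) == sum(domain sizes)` always —
a conservation law the tests assert). Counts are binned for display into
four classes — 0, 1, 2, ≥3 patterns — rendered blue, green, yellow and red
respectively. Analysis outputs carry raw counts; colour is applied only by
`render_heatmap()`, keeping the analysis colour-space-free.

## Mapping assay images into the model frame

`map_entry()` reproduces the curation step in two parts.

**Signal extraction** thresholds the RGB image in HSV space, one band (hue
range, minimum saturation, value range) per strength level. HSV was chosen
because chromogenic ISH signal (BCIP/NBT purple) separates from pale
counterstain mainly in hue and saturation; the bands live in a config
object/JSON file, never in code. The four-level vocabulary
`detected ⊇ weak ⊇ moderate ⊇ strong` is enforced at config load: each
stricter band must be contained in the laxer one (hue containment is
checked wrap-around-safely on a 0.125° grid), so level nesting holds by
construction and survives warping. Gradient-valued signal capture beyond
discrete levels is out of scope. Trapping artefacts (stain pooled in
cavities) are handled the way a curator would: an explicit exclusion
domain subtracted from every level.

**The warp** Delaunay-triangulates the source landmarks (via `deldir`) and
maps each triangle affinely onto its target triangle: continuous across
edges, exact at every landmark, and exactly reproducing any generating
affine map (the test probes 1,000 interior points against a closed-form
affine oracle). Warped domains are rasterized by *inverse* mapping — each
target pixel centre is pulled back and tested against the source domain's
nearest pixel — which cannot leave holes. Pixels outside the landmark hull
cannot be mapped and are dropped with a warning. The production system's
constrained-distance-transform warp is deliberately not imitated; the warp
sits behind `build_warp()`/`apply_warp()` precisely so a different engine
could be slotted in without touching extraction or pattern assembly.

## Virtual sectioning

A section is parameterized by pitch/yaw/roll (degrees), a distance along
the view normal, a fixed rotation centre, scale and viewport. The rotation
convention is fixed and test-pinned: base axes rotated by yaw about z, then
pitch about the rotated x axis, then roll about the resulting view normal —
equivalently `Rz(yaw) %*% Rx(pitch) %*% Rz(roll)`. The angle *names* do not
by themselves determine an order, so the convention is covered by a
sequential axis-angle oracle test that will catch any accidental change.
Coordinates are right-handed with x = column, y = row, z = plane, and the
section's v axis points down to match image convention.

Sampling happens in physical space: voxel coordinates are scaled by the
voxel spacing before rotation, so oblique sections through anisotropic
reconstructions are geometrically correct; with unit spacing, distances are
voxel units. Grey sections offer nearest and trilinear interpolation;
out-of-volume pixels take a configurable background (default 0). With zero
angles and integer distance the nearest-neighbour section is *exactly* the
stored plane — asserted for every plane of a phantom.

Domain layers are cut by nearest-voxel membership — binary in, binary out,
so section-plane domains remain interval-codable; no partial-volume alpha
is introduced. Overlays composite back-to-front with source-over blending
(`out = α·colour + (1−α)·under`), and overlapping layers are explicitly
legal — the whole point of the compound-object representation is to avoid
the index-image restriction that no two patterns may share a voxel.
Flattening to an index volume is still available for interchange, but
overlap there is a hard error by default (`policy = "error"`), making the
lossiness of that format an enforced contract instead of silent data loss;
`policy = "priority"` lets later layers win and reports the overridden
voxel count. Tiles default to 256 px and mosaic exactly back to the full
composited section.

## Serialization

The `.ivd` domain format is JSON — versioned, with the coding convention
named in the header, the optional frame, and per-plane/per-row interval
lists. JSON was chosen over a binary layout for inspectability; `.ivdz`
adds a gzip wrapper for bulk sets. The writer is byte-deterministic. The
reader *validates rather than repairs*: unsorted, overlapping or adjacent
intervals, malformed JSON, and out-of-frame intervals are three distinct
error classes (`ivd_canonical_error`, `ivd_parse_error`,
`ivd_bounds_error`). Repairing on read would mask corrupted upstream
writers. Dense 3D exchange uses NIfTI (axis order permuted between the
on-disk x-fastest convention and the in-memory `[y, x, z]` arrays; spacing
maps to pixdim); 2D masks use PNG. Pattern databases are a TSV manifest
(`entry_id, gene, stage, level, path`) plus one `.ivd`/`.ivdz` per level.

## Synthetic fixtures and what the tests do (and do not) show

All tests run on seeded synthetic data; the generators are pure functions
of their seed.

* `make_phantom_volume()` — a smooth ellipsoidal grey phantom whose
  intensity decays to exactly 0 at its surface (so sections never see an
  artificial jump at the volume boundary), with three nested anatomy
  layers. The spherical variant is rotation-invariant by construction,
  giving the sectioning code a symmetry oracle: the mean intensity of any
  central section must be constant to within 1%.
* `make_expression_set()` — planted syn-expression groups: per group one
  template ellipsoid, members derived by toggling a `jitter` fraction of
  voxels *preferentially at the morphological boundary* (removals from the
  inner shell, additions from the outer shell). Boundary-biased jitter
  mimics how real mapped domains differ — curators disagree at edges, not
  in random interior holes — and keeps within-group overlap provably above
  between-group overlap, which the tests sweep over seeds 0–19. The default
  frame is a 100 × 120 × 80 voxel grid: large enough that interval
  compression matters, small enough for seconds-scale tests.
* `make_assay_case()` — a purple signal ellipse (dark core, lighter
  annulus) drawn on pale tissue background in an image that is a known mild
  affine deformation of the model frame, with landmarks sampled from that
  deformation and ground truth rasterized from the closed-form map. The
  end-to-end mapping test requires Jaccard ≥ 0.95 against truth over 20
  seeds; observed values are ≈ 0.98, the residual being boundary-pixel
  rasterization.

Problem sizes used by the shipped checks: oracle-equivalence sweeps run
≥ 200 seeded instances per operation on small grids (where dense
brute-force oracles are exact and fast); clustering recovery runs 20 seeds
of 3 × 5 patterns on the full default frame; the scale check ranks one
query against 1,000 generated patterns on the default frame, which
completes in a few seconds.

These fixtures validate the *algebra and the pipeline*, not biology: they
contain no realistic embryo morphology, no staining chemistry, no imaging
noise, no stage variation, and affine-only deformations. Passing them shows
the machinery is correct and fast, not that any particular biological
conclusion follows from real curated data.

## Known limitations

* The local similarity formula is a declared stand-in (see above), not the
  production tool's published weighting.
* The landmark warp is piecewise-affine; strongly non-affine deformations
  are only as good as the landmark density, and regions outside the
  landmark hull are dropped.
* Grey values are never attached to intervals — only binary domains carry
  the compressed representation; grey volumes stay dense arrays.
* Erosion's outside-is-background rule means domains touching the frame
  boundary erode there; callers wanting reflective or periodic boundaries
  must pad first.
* No HTTP tile serving, multi-resolution pyramids, or interactive viewers:
  the sectioning/tiling code computes what such a server would serve.
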