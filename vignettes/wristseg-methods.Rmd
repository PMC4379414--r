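---
title: "Atlas-guided watershed segmentation of the wrist bones: models, parameters and design choices"
author: "wristseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-guided watershed segmentation of the wrist bones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science inside `wristseg`: the segmentation
model and its assumptions, every tunable parameter with its unit and
default, what the synthetic phantom emulates (and does not), the numerical
choices that make the pipeline deterministic, and the known limitations.

## The problem and the model

Low-field (0.2T) T1-weighted wrist MR shows each bone as a bright marrow
interior wrapped in a thin dark cortical shell, embedded in soft tissue
whose intensity — especially skin — overlaps the marrow band. Plain
thresholds therefore cannot isolate bone. The pipeline instead treats the
gradient magnitude of the (lightly blurred) image as a topographic relief:
every cortical surface produces a ridge, and a watershed flooded from one
marker per bone plus one background marker partitions the volume into
catchment basins whose boundaries follow those ridges. The entire problem
then reduces to *finding one reliable marker inside each of the 15 bones*,
which is what the atlas machinery does. Because full-volume 3D registration
is expensive and the wrist anatomy is elongated, the problem is split into
three stages — distal radius/ulna, metacarpal bases, carpals — each with its
own marker construction, and the three partial label maps are merged.

Assumptions worth stating explicitly:

* marrow is brighter than the immediately surrounding soft tissue, so a
  buffered global threshold can separate bone clusters (`TH_ME + 200`);
* the cortical shell is about one voxel thick (0.7 mm), so the watershed
  basin captures marrow and a single unit-diamond dilation recovers the
  shell;
* the axial slice index grows from the fingers (distal) toward the elbow
  (proximal); all direction-dependent rules (growth direction, cluster
  coordinates) use this convention.

## Stage parameters

All defaults live in `wrist_config()` and are logged whenever overridden.

| parameter | default | unit | role |
|---|---|---|---|
| `i_low`, `i_high` | 200, 500 | intensity | search range for the hand-mask threshold (the histogram valley always falls there on this protocol) |
| `smooth_box` | 11 | gray levels | running-average width for the histogram before the valley search |
| `box` | 5 | pixels | half-size of the per-slice closing; the full 11 px (~8 mm) bridges cortical bone and tendons; the final erosion uses `box %/% 2` = 2 px (~1.5 mm, thinner than skin) |
| `min_rel_depth` | 0.10 | — | required relative depth `(max−min)/(0.5(max+min))` of the distal dip next to the radioulnar profile maximum |
| `max_dist_frac` | 0.15 | fraction of axial extent | maximal dip-to-peak distance for the radioulnar slice classifier |
| `depth_slices` | 10 | slices (~7 mm) | stopping distance of marker growth; close to the radioulnar joint extent |
| `buffer` | 200 | intensity | added to the Kapur threshold so that clusters of different bones separate |
| `n_keep`, `x_th_frac` | 10, 0.35 | —, fraction | cluster filter: keep at most 10 largest-extent clusters with `x_min > 0.35 L` |
| marker thresholds | 1, 1, 240 | gray (of 255) | binarization of propagated markers per stage |
| component caps | 2, 5, 8 | — | candidate components kept per stage |
| `dilation_half` | 1 | voxel | cortical-compensation dilation (diamond) |

Registration settings (`register_images()`): mean-squares metric with
linear interpolation; stages rigid → affine → coarse FFD (4 control points
per axis) → fine FFD (8 per axis, initialized by upsampling the coarse
grid); per-stage iteration cap 200 and relative metric tolerance `1e-4`;
the 3D stage uses a 2-level resolution pyramid for the rigid/affine parts
and evaluates the metric on a stride-2 subsample of the fixed voxels (the
optimum is unchanged at these image sizes, the cost drops eightfold).
The free-form deformation interpolates control displacements multilinearly
— the simplest grid-based deformation consistent with "coarse grid plus
2× refined fine grid" — and is optimized by regular-step gradient descent
with an analytic metric gradient (step halves on failure, stops below 0.01
voxel).

## The metrics

For ground truth `G` and segmentation `S` (per bone, one-vs-rest):

* **AUC** — area under the three-point ROC polyline
  `{(0,0), (FPR,TPR), (1,1)}`, i.e. `FPR·TPR/2 + (1−FPR)(1+TPR)/2`. True
  negatives are counted inside the bounding box of `G ∪ S` padded by one
  voxel: without the restriction the huge empty background dominates and
  every segmentation looks perfect; without the pad a perfect segmentation
  has no negatives and the rate is undefined.
* **MS** — Jaccard index `|G∩S| / |G∪S|`.
* **MAD** — the size-weighted mean of the granulometric pattern spectrum of
  `G XOR S`: `PS(n) = |Φ_{n−1}| − |Φ_n|` with `Φ_n` the opening by the
  size-`n` diamond (n-fold unit diamond). `MAD = Σ n·PS(n) / Σ PS(n)`,
  defined as 0 for an empty XOR. One subtlety is worth knowing: a band of
  width `w` around the boundary is removed at the first opening of size
  `⌈w/2⌉`, so MAD measures roughly *half* the XOR band width plus one —
  a uniform 1-voxel band gives exactly 1, but a uniform 2-voxel band
  *also* gives values near 1 (only corner wedges survive the first
  opening). MAD = 1 therefore means "boundaries disagree by about one
  voxel", but MAD does not grow linearly with larger uniform offsets.
* 3D masks use the 6-connected octahedron; `per_slice = TRUE` computes 2D
  spectra per axial slice and pools them, for users who prefer the
  slice-wise reading. The 3D form is the default because the XOR volumes
  are intrinsically 3D.
* AUC aggregation averages per-bone values within each group
  (radius/ulna, metacarpals, carpals) rather than pooling voxels across
  bones; pooling would let the large radius dominate the group.

## What the phantom emulates

`generate_phantom()` produces the study conditions used throughout the test
suite: a 16-bit volume (default 160×160×120 voxels at 0.75×0.75×0.7 mm;
the regression corpus uses 96×96×72 to keep a 20-phantom end-to-end run in
minutes on one core, with bone sizes that are anatomically sensible at that
grid's effective ~1 mm/voxel scale) containing

* a dark air background (mean 100), an elliptic soft-tissue hand (450)
  wrapped in a 3-voxel bright skin shell (880),
* 15 bones: two proximal rods with ellipsoidal caps and a mild taper
  (radius/ulna, in-plane radii 0.105/0.093 of the grid — large enough that
  the radioulnar profile dip passes the 10% depth rule), five distal bars
  (radius 0.048, slightly flaring toward the base), and eight carpal
  ellipsoids in two in-plane rows (semi-axes ~0.052–0.058 in x, with the
  outer columns smaller and closer in, like the pisiform/trapezium, so the
  carpus stays medial to the lateral tangent planes),
* per bone, a bright marrow core (900) and a cortical shell (250) built as
  the core's unit-diamond dilation ring — exactly one voxel thick in the
  city-block metric, matching the dilation that compensates it,
* Gaussian noise per tissue class (sd 25–45) and 16-bit quantization.

Deliberate design points: skin and marrow share an intensity band, which is
the central difficulty of low-field wrist MR and defeats naive
thresholding; the radiocarpal gap spans about 10 slices, matching the
growth depth `D`; every carpal's proximal tip crosses 0.65 of the axial
extent, so the cluster filter's `x_min > 0.35 L` rule removes all carpals
(the anatomical origin at the styloid apex is approximated by the
field-of-view edge — the offset is absorbed into the fractional rule). The
intensity means were calibrated once so the histogram valley falls inside
[200, 500] and `TH_ME + 200` separates soft tissue from marrow, as the
pipeline requires of real acquisitions.

What the phantom does **not** emulate: true anatomical shapes (bones are
rods and ellipsoids), bone erosions and edema, intensity inhomogeneity
(bias fields), partial-volume anisotropy, and inter-subject pose variation
beyond small jitter plus the atlas warp. Passing the phantom suite
therefore shows the pipeline's logic and numerics are sound under the
stated intensity model; it does not certify performance on clinical data.

`derive_atlas()` stands in for the expert-selected atlas of a clinical
deployment: it warps an independent phantom with a smooth random control
grid displacement field (5×5×5 nodes, default amplitude 2 voxels; folding
warps — non-positive Jacobian — are rejected), adds an intensity gain
jitter, and extracts the radioulnar and metacarpal slices at the maximal
bone cross-sectional area, the 3D carpal region, and marker images eroded
from the warped ground truth at foreground 255 (so the carpal gray
threshold of 240 selects near-full-support voxels).

## Numerical and tie-break choices

Determinism is a design requirement; every ordering ambiguity is fixed:

* *Watershed*: priority queue ordered by (relief value, insertion
  counter); neighbours scanned in the fixed order −x,+x,−y,+y,−z,+z; a
  voxel takes the label of its first queue entry popped. Watershed lines
  are not emitted by default (the dilation and the metrics need total
  labelings); `lines = TRUE` labels contested voxels 0 instead.
* *Marker growth*: best-first by decreasing intensity, FIFO among equal
  intensities (breadth-first among ties); each voxel enqueued once by its
  first expanded neighbour, which becomes its path predecessor; growth is
  restricted to slices on the chosen side of the seed, seed slice
  included.
* *Morphology*: diamond = city-block ball (4/6-connectivity), square =
  Chebyshev ball; size-n elements via n unit iterations (the equivalent
  direct kernels are kept as a cross-checked second path); outside the
  grid counts as background, with a foreground-padding variant for exact
  erosion/dilation duality at borders.
* *Connected components*: labelled in order of each component's smallest
  linear index; size ties in `keep_largest()` break toward the smaller
  label.
* *Thresholds*: the Kapur criterion and the histogram-valley search both
  resolve ties toward the lowest intensity.
* *Cluster filter*: extent ties break toward the smaller component label;
  the slice score tie breaks toward the most distal slice.
* *Support planes*: the convex-hull edge of the projected body union that
  bridges the two bodies with the region centroid on the body side — the
  *outer* common tangent. (The inner tangent would cut carpals out of the
  region whenever the carpus is wider than the radius–metacarpal corridor.)
* *Envelopes*: columns without bone take the value of the nearest
  (city-block, FIFO) column that has bone.
* *Marker naming*: candidate components are matched to atlas markers by
  greatest propagated-gray overlap, greedily; this keeps bone identities
  stable even when the threshold/cap step reshuffles components.
* *Merging*: a voxel claimed by several stages goes to the earlier stage
  (radius/ulna over metacarpals over carpals), logged.
* Degenerate inputs fail loudly: empty markers name the bone, a carpal
  marker count below eight aborts the stage with the count, constant
  images refuse to register, raw files with inconsistent geometry refuse
  to load.

The mask threshold selection scans the smoothed histogram only inside
[`i_low`, `i_high`]; the radioulnar classifier detects extrema on a box-3
smoothed profile (single-slice noise would otherwise create spurious
maxima) and, failing to find a qualifying maximum, the pipeline falls back
to the global profile maximum with a log entry.

## Known limitations

* The watershed basin boundary sits on the steepest ring of the blurred
  cortical edge, which for small bones (carpals) is a fraction of a voxel
  inside the marrow surface; after the one-voxel dilation the label is
  accurate to about one voxel (MAD ≈ 1), which is also what the metric
  reports on clinical-style data. Sub-voxel accuracy is out of scope.
* Bones that touch the volume edge are handled (the shell closes at the
  boundary), but markers whose growth would leave the volume are truncated
  with a warning.
* The pipeline assumes one wrist per volume, the standard coronal
  acquisition axis convention, and — like the underlying method — degrades
  when large erosions destroy the marrow/cortex layering.
* The registration stack is intentionally small (mean squares only;
  other metrics performed worse on this modality) and is not a general
  registration tool.
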