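# wristseg

Automated segmentation of the fifteen wrist bones — distal radius and ulna,
the eight carpals, and the five metacarpal bases — in low-field (0.2T)
T1-weighted MR volumes of the wrist, for image-analysis work on rheumatoid
arthritis where the bones must be delineated before marrow, joint-space or
erosion measures can be computed. Low-field wrist MR is hard to segment
directly: skin and bone marrow share the same intensity band, so
intensity thresholds alone cannot isolate bone.

The package is a full R implementation of an atlas-guided
watershed-from-markers pipeline:

1. **Hand mask.** The intensity histogram is smoothed with an 11-gray-level
   running average and thresholded at the valley right of the background
   mode (searched in [200, 500]); every axial slice is then closed
   (square element, half-size 5), hole-filled and eroded (half-size 2).
   The one-voxel surface of this mask is the soft-tissue (background)
   marker.
2. **Radius/ulna.** A representative axial slice is selected from the
   mask-restricted mean-intensity profile (first maximum from the proximal
   end with a ≥10% relative dip within 15% of the axial extent on its
   distal side). An atlas cross section is registered to it
   (rigid → affine → coarse/fine free-form deformation, mean-squares
   metric, linear interpolation) and the atlas markers are resampled,
   thresholded at 1, capped at the 2 largest components, and extended 3D-wards
   by intensity-ordered region growing (10 slices proximally). A 3D
   watershed on the Prewitt gradient-magnitude relief, followed by a unit
   diamond dilation compensating the dark cortical shell, yields the two
   bone labels.
3. **Metacarpal bases.** The representative slice comes from a
   maximum-entropy threshold (Kapur) plus a 200-unit buffer and a cluster
   filter (at most 10 clusters with the largest axial extent whose distal
   coordinate `x_min` exceeds 0.35 of the axial field of view); markers are
   reduced to central pixels and grown 10 slices distally; watershed and
   dilation as above give the five bases.
4. **Carpals.** The region between the distal envelope of radius/ulna and
   the proximal envelope of the metacarpals, clipped by two lateral planes
   tangent to ulna+M5 and radius+M1, is registered in 3D against an atlas
   carpal volume. Propagated markers are thresholded at 240 (of 255),
   intensity-filtered at the buffered maximum-entropy threshold, closed and
   hole-filled per slice, and capped at the eight largest components; the
   watershed restricted to the carpal region yields the eight carpal
   labels.

Segmentation quality is quantified with the three-point ROC area
`AUC = FPR·TPR/2 + (1−FPR)(1+TPR)/2`, the Jaccard mean similarity
`MS = |G ∩ S| / |G ∪ S|`, and the granulometric mean absolute distance
`MAD = Σ n·PS(n) / Σ PS(n)` where `PS` is the pattern spectrum of the
symmetric difference under successive unit-diamond openings. A
majority-vote consensus over segmentations is also provided.

Because no public low-field wrist MR data exist, the package ships a
synthetic wrist-phantom generator (`generate_phantom()`) producing volumes
with ground-truth 15-bone label maps and warped atlas bundles
(`derive_atlas()`), which the test suite uses to validate the pipeline
end-to-end.

## Worked example

```r
library(wristseg)

# a synthetic wrist volume with ground truth, and an atlas from another
# (warped) phantom
case  <- generate_phantom(phantom_spec(shape = c(96, 96, 72), seed = 1))
atlas <- derive_atlas(generate_phantom(phantom_spec(shape = c(96, 96, 72),
                                                    seed = 100)),
                      warp_amplitude = 2, seed = 101)

seg <- wrist_segment(case$volume, atlas)
seg
#> <wrist_segmentation> 96x96x72 voxels; 15/15 bones: R U M1 M2 M3 M4 M5 A B C D E F G H

rep <- evaluate_labels(case$labels, seg$labels)
attr(rep, "aggregate")
#>        group  n auc_mean  auc_sd ms_mean   ms_sd mad_mean mad_sd
#>  radius_ulna  2    0.962 0.00222   0.924 0.00443        1      0
#>  metacarpals  5    0.914 0.00441   0.828 0.00881        1      0
#>      carpals  8    0.906 0.01457   0.811 0.02913        1      0
#>      overall 15    0.916 0.02184   0.832 0.04369        1      0
```

All fifteen bones are detected; the mean similarity is highest for the large
radius/ulna and lowest for the small carpals, and the granulometric MAD of 1
voxel says the automated boundary sits about one voxel from the ground-truth
boundary — the behaviour expected from a watershed on a gradient relief with
a one-voxel cortical shell. `summary(seg)` lists per-bone voxel counts and
`seg$log` the full provenance (thresholds, selected slices, registration
metrics).

A thin command-line front end is installed at `inst/cli/wristseg.R`
(`phantom`, `run`, `evaluate` subcommands) for use from a shell.

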