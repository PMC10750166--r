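---
title: "Segmenting C. elegans germline nuclei in 3D: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting C. elegans germline nuclei in 3D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germseg)
```

## The segmentation problem

Nuclei in the distal *C. elegans* germline are round, about 3.5 µm across,
and densely packed. Chromatin staining (DAPI) or synaptonemal-complex
markers label them *discontinuously*: in meiotic prophase the partially
condensed, paired chromosomes appear as bright threads, so a nucleus is a
cluster of filaments inside a round envelope rather than a filled ball.
Confocal z-stacks sample this anisotropically — a typical acquisition has
0.117 µm lateral pixels but a 0.3 µm z-step (anisotropy ≈ 2.6).

`germseg` composes the stages around a pluggable 3D instance-segmentation
backend so that the whole chain — preprocessing in physical units,
segmentation, border/shape filtering, instance-matched evaluation, and
ground-truth preparation — is a single reproducible pipeline.

## The pipeline

Given a stack with pixel size $p$ (µm/px) and expected nucleus diameter $d$
(µm), `run_pipeline()` executes:

1. **Rescale.** $s = 30\,p/d$, applied laterally with bilinear
   interpolation. After rescaling, one nucleus spans 30 px (pixel size
   $d/30$; for $d = 3.5$ µm that is 0.1167 µm/px, matching the 0.117 µm/px
   the ground-truth collection was standardised to). 30 px is the object
   scale most generalist nucleus models are tuned for, which is why the
   pixel grid is moved to the model rather than the other way round. z is
   never resampled; the residual axial coarseness is passed on as the
   anisotropy $a = z_\mathrm{step} / (d/30)$.
2. **Blur.** A Gaussian of standard deviation `blurfactor` px laterally and
   `blurfactor`$/a$ px axially — i.e. physically isotropic. Blurring merges
   the discontinuous chromatin threads into a filled envelope, which is the
   geometrically meaningful object. Default 2.5 for chromatin staining;
   3.5 for deconvolved or synaptonemal-complex images, whose structures are
   sharper and sparser. `blurfactor = 0` is exactly the identity.
3. **Segment.** The backend receives the preprocessed grid, $a$, and
   `cellprob_threshold` (default 0.0) and returns a label volume of the
   same shape with 6-connected instances.
4. **Map back.** Labels are resampled to the acquisition grid by nearest
   neighbour, so downstream quantification happens in the user's original
   coordinate frame. (The interface is silent on the output frame; staying
   in acquisition coordinates makes the result composable with any other
   measurement on the raw stack.)
5. **Post-filter.** `clean_borders()` then `filter_masks()`, both of which
   only ever *delete* instances — surviving voxel sets are bit-identical,
   there is no relabelling or morphology.

## The classical baseline backend

The published approach uses a retrained Cellpose-style network; its weights
are an external artifact. To make the pipeline testable — and usable — with
no trained model, `baseline_segment()` implements a deterministic classical
detector tuned to the same 30-px regime:

- foreground by Otsu's threshold on a lightly smoothed volume
  (σ = 2 px lateral, 2/$a$ axial);
- a difference-of-Gaussians blob response at σ = $30/(2\sqrt3) \approx 8.7$
  px lateral (the scale-space optimum for a 30-px ball), anisotropy-scaled
  axially, approximating the Laplacian of Gaussian;
- seeds = response maxima inside the foreground above a percentile cut;
- instances grown from the seeds by a marker-controlled watershed
  (priority flood, ascending inverted intensity, 6-connectivity,
  FIFO tie-breaking) restricted to the foreground mask.

`cellprob_threshold` has a precise meaning only for flow-based networks;
the baseline maps it monotonically to the seed-response percentile
`plogis(cellprob_threshold)`, so 0.0 cuts at the median foreground response
and raising the threshold is stricter in both worlds. The Cellpose adapter
(`cellpose_adapter()`) forwards `anisotropy` and `cellprob_threshold`
verbatim (inspectable via `cellpose_call()`); in the absence of the
optional Python dependency it raises a capability error rather than
silently substituting a different backend. Whether that backend should run
in true-3D or stitched-2D mode is exposed as an option (`do_3D`) without a
claimed default.

## Border cleaning and shape filters

`clean_borders()` implements the literal rule used to remove incomplete
nuclei: delete an instance iff it has a voxel on the first or last z slice,
*or* within 2 px of the lateral edges (0-based index `< 2` or
`>= dim − 2`). The asymmetry between z ("touch") and xy ("within 2 pixels")
is preserved deliberately. The rule is idempotent and tested on all six
faces.

`filter_masks()` measures, per instance:

- **size** — voxel count;
- **solidity** — voxel count / lattice voxels inside the instance's 3D
  convex hull. No 3D hull library is assumed: the hull is evaluated by an
  exact plane sweep (per-slice 2D hull vertices as a candidate superset,
  cross-slice segment interpolation at each integer z, then a 2D
  half-plane lattice count). Tests cross-check the count against an
  independent Delaunay-based oracle;
- **elongation** — ratio of largest to smallest principal-axis length from
  the voxel covariance *in physical µm* (z scaled by the z-step), so
  anisotropy cannot masquerade as shape. The voxel's own second moment
  ($\mathrm{size}^2/12$ per axis) is added to the covariance diagonal so
  flat instances get a finite, physically sensible value;
- **z-thickness** — number of distinct z slices occupied.

Single-voxel instances are defined to have solidity 1 and elongation 1.
Whether such measurements should be 3D or per-slice is not fixed by the
interface; per-instance 3D measurement is used because the filters target
whole-nucleus geometry.

## Evaluation: instance-matched Jaccard

Segmentation quality is summarised as $J = TP/(TP+FP+FN)$ where TP counts
ground-truth/prediction pairs matched one-to-one at voxel IoU strictly
above a threshold (default 0.5, the metric's standard operating point,
overridable). `iou_matrix()` uses a sparse joint histogram, never all-pairs
voxel scans. `match_instances()` is maximum-cardinality (sorted-greedy by
descending IoU with id tie-breaks, completed by augmenting paths); above
threshold 0.5 a voxel set can exceed the threshold with at most one
partner, so greedy and optimal coincide — the optimal matcher matters only
for exploratory low thresholds, and is verified against exhaustive
enumeration in the tests. Per-image scores with mean/sd/median/IQR come
from `evaluate_dataset()`; 2D views ride along as single-slice volumes.
Empty-vs-empty scores 1 by convention.

## Ground-truth preparation and augmentation

Annotating full stacks is prohibitively slow; annotating 2D orthogonal
views is the economical protocol. `extract_ortho_view()` passes xy slices
through untouched and resamples xz/yz views along z by the anisotropy
factor (linear for intensity, nearest for labels — which therefore can
never invent ids) so annotators see isotropic geometry.
`split_train_test()` reproduces the canonical 120 → 108/12 split at a 10%
test fraction.

`augment_pair()` applies, per draw: optional horizontal/vertical mirroring,
a rotation uniform in 0–90°, additive Gaussian noise (σ relative to the
image sd), multiplicative intensity rescaling with min–max renormalisation,
and Gaussian blurring with a factor in 0–3.5. Geometric transforms hit
image and mask identically (bilinear vs nearest); photometric ones touch
the image only. Rotation uses reflective padding with a shape-preserving
crop; mask fragments below 9 px created at rotated edges are dropped,
mirroring the minimum-mask-size convention of the training stage. The
noise/intensity parameter ranges are package defaults, recorded per-draw in
the manifest, not claimed as anyone's training values.
`build_training_set()` derives per-view RNG substreams from
`(seed, view index)`, writes Cellpose-convention `_img`/`_masks` TIFF
pairs, a CSV manifest of every sampled parameter, and the frozen training
hyperparameters (`training_config_record()`: 500 epochs, momentum 0.9,
weight decay 1e-5, learning rate 0.05, min 2 training masks, normalise and
rescale on) — recorded for provenance; network training itself is out of
scope.

## The synthetic scene generator

`generate_scene()` emulates exactly the regime the pipeline targets:

- spheres with diameters $\mathcal N(3.5, 0.25^2)$ µm (truncated to
  ±40%), dart-thrown with a hard-core gap of 0.25 µm, fully inside a
  64×256×256 voxel volume at 0.117 µm/px and 0.3 µm z-step;
- ground-truth labels are the *full spheres* rasterised on the anisotropic
  grid — matching how annotators outline whole nuclei, not the sparse
  chromatin;
- intensity = 25 chromatin blobs of 0.9 µm per nucleus (discontinuous
  texture) over a 0.45 nucleoplasm level, blurred by a 0.15 µm isotropic
  PSF, plus 0.08 background, Poisson shot noise (scale 400) and Gaussian
  read noise (sd 0.02);
- everything deterministic given the seed; placement failure raises an
  explicit density error.

What it does **not** emulate: real chromosome/synaptonemal-complex
geometry, the gonad-scale gradient of meiotic stages, nuclei truncated by
the imaging volume, intensity attenuation with depth, or the correlated
noise of deconvolution. Passing tests on these scenes therefore establish
the pipeline's *mechanics* (units, composition, matching, filters), and
that the classical baseline solves the idealised task — they do not certify
any accuracy level on real micrographs, which depends on the trained
backend. The published accuracy figures for real test images were produced
with the authors' microscopy data and network weights and are deliberately
not reproduced here.

`corrupt_labels()` manufactures predictions with *known* error counts for
evaluation tests: dropping $k$ of $N$ instances gives
$J = (N-k)/N$ exactly; splitting one instance through its centroid gives
one FN and two FPs. A plane through the centroid of an odd-sized voxel set
necessarily leaves one half larger than 50% of the parent — which would
still match at threshold 0.5 — so the splitter removes the single
rank-median voxel in that case, guaranteeing both fragments stay at or
below half. With $N = 10$: drop 2 → $J = 0.8$; split 1 → $J = 9/12 = 0.75$.

## Numerical choices

- `blurfactor` is interpreted as a Gaussian *standard deviation* in
  rescaled pixels (the plugin phrase "blurred by a factor" does not fix the
  parameterisation); the axial σ is divided by the anisotropy so blurring
  is one physical operation, and the blur is truly 3D rather than
  per-slice.
- Resampling: bilinear for intensities, nearest for labels, pixel-centre
  alignment (`(i+0.5)·n_src/n_out − 0.5`); constants are exactly invariant;
  reflective boundaries for all convolutions, so total intensity is
  conserved.
- Rescaled lateral dimensions below 4 px are refused rather than produced.
- Connectivity is fixed at 6-neighbourhood in 3D (conservative; avoids
  diagonal mergers of touching nuclei).
- Watershed flooding resolves priority ties by insertion order, making the
  baseline bit-reproducible.
- TIFF I/O: integer data round-trips exactly (16-bit); float data is
  normalised with the scale stored in the YAML sidecar. Plausible TIFF
  resolution tags (0.01–10 µm/px) take precedence over sidecar pixel
  sizes; non-square pixels are an error, never silently averaged. Axis
  order is (z, y, x) with TIFF pages as z throughout; a stack transposed
  on disk is generally undetectable from shape alone and is the user's
  responsibility.
- 8- and 16-bit inputs are both accepted; nothing in the pipeline assumes
  a specific bit depth.

## Problem sizes

The test-suite and acceptance scenes are sized for a desk run: the default
scene is 64×256×256 voxels (~4M), segmented in a few seconds; the
known-answer corruption scenes use 10 nuclei in 40×192×192; unit fixtures
use 1.8–2 µm nuclei in smaller volumes where full-size nuclei would not
pack. The evaluation matcher is exercised against exhaustive enumeration on
≤ 6×6 instance sets over hundreds of seeded trials.

## Known limitations

- The baseline assumes roughly spherical, similarly sized objects; it is a
  reference implementation of the pipeline contract, not a competitor to a
  trained network on real data.
- Solidity's plane-sweep hull is exact but $O(V^2)$ per z-slice in the
  candidate vertex count; for very large or very irregular instances it is
  the slowest measurement (it is only computed when a solidity criterion
  is active).
- Label ids are limited to 65535 by the 16-bit TIFF writer.
- `cellprob_threshold` equivalence between the baseline and flow-based
  backends is monotone, not calibrated.
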