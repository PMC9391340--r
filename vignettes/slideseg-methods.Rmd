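---
title: "slideseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slideseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`slideseg` implements the computational core of patch-based whole-slide
image (WSI) segmentation: streaming class-balanced training patches out of
a pyramidal slide, stitching overlapping patch predictions back into a
slide-level map, converting between raster and polygon annotation
representations, and scoring the result. This vignette records the model
assumptions, the parameters that matter, and the design decisions taken
where the problem was genuinely open.

## Coordinate and raster conventions

All public APIs use 0-based, half-open pixel coordinates at base (level-0)
resolution, with `x` indexing columns and `y` rows; pixel `(x0, y0)` covers
`[x0, x0+1) x [y0, y0+1)` and has its center at `(x0+0.5, y0+0.5)`. RGB
rasters are `[h, w, 3]` arrays in `[0, 1]`; label rasters are integer
matrices with 0 as background. A *downsample factor* `d` is the ratio of
base resolution to working resolution; region reads at downsample `d`
return `floor(w/d) x floor(h/d)` pixels, rendered from the finest pyramid
level whose factor divides `d` and block-mean averaged down, so reads at
different downsamples agree up to interpolation. Reads beyond the slide
bounds are padded with white rather than raising an error: edge patches of
the inference grid must stay full-size, and white is the empty-slide color
of a brightfield scan. Integer downsample factors cover every scale the
tool uses (1–4 for training, 2 for prediction, 32 for tissue masking).

## Tissue masking

Stained tissue is never pure white, so tissue is located by color
thresholding a low-resolution rendition (downsample 32 by default): after
Gaussian smoothing with `smooth_sigma = 1` mask-scale pixels, a pixel is
tissue when `min(R, G, B) < 228/255`, and connected components smaller
than 100 mask-scale pixels are removed as speckle. The threshold value and
morphology are a documented default of this package, chosen to be robust
for white-background brightfield slides and fully specified so the mask is
testable; they are not a reproduction of any published recipe. Masks are
cached as PNG files keyed by a hash of the slide identity and parameters,
and a second call reloads the cached mask bit-exactly. An all-background
slide yields an empty mask, which downstream produces an empty inference
plan rather than an error.

## Training-patch sampling

`sample_patch()` draws, per patch:

1. a downsample factor, uniform over `downsample_list` (default `1:4`) —
   multi-resolution extraction that exposes the model to varied scales;
2. with probability `background_prob` (default 0.1) a *background-eligible*
   location, uniform over the whole slide, which may contain no tissue —
   occasional background patches help a trainer generalize its
   normalization statistics;
3. otherwise, when balancing is on, a target class uniform over the classes
   that have at least one polygon, a polygon uniform within that class, and
   a patch center at the polygon centroid plus uniform jitter up to half a
   patch per axis.

Balancing is probabilistic rather than a per-step quota: each draw is
independent, which keeps the stream stateless and restartable from a seed.
The half-patch jitter bound guarantees the targeted polygon's centroid
stays inside the patch, so every balanced draw contains at least one pixel
of its target class (the synthetic objects are star-convex, so the
centroid is interior). Patch locations are clamped to slide bounds. Pixels
inside layers named by `ignore_layers` receive `ignore_label` (default
255) and are excluded from training loss; they are also never the target
of a balanced draw. With balancing off, patch centers are uniform over
tissue-mask foreground. A `pixels = FALSE` mode returns draw provenance
only (location, class, downsample, background flag), which makes auditing
sampling statistics over tens of thousands of draws cheap; the test suite
uses 10,000-draw audits for the background fraction (binomial 3-sigma
band), the 50/50 class balance under a 90:10 polygon imbalance, and the
uniform downsample cycling.

## The patch-segmenter contract and the reference model

Tiled inference is agnostic to the model: anything that maps an RGB patch
`[H, W, 3]` to logits `[H/stride, W/stride, n_classes]` (background first)
can be plugged in via `patch_segmenter()`. The decoder output stride
(default 4) reflects how semantic-segmentation decoders emit predictions
at reduced resolution; `slideseg` never up-samples predictions — contour
and heatmap coordinates are up-sampled at export instead, which keeps
memory flat in slide size.

The built-in reference model is deliberately tiny so the whole pipeline
trains in seconds on one CPU: a fixed bank of Gaussian smoothing
convolutions over the RGB channels (scales 2 and 4 px) provides local
context, inputs are rescaled to `[-1, 1]`, and a learned 1×1 convolution
(multinomial logistic layer) maps each stride-grid feature vector to class
logits. It segments whatever is color-separable, which is exactly what the
synthetic fixture provides, and it makes no attempt to match a deep
network's capacity — reproducing a full encoder-decoder architecture is an
explicit non-goal. Training uses the optimizer configuration standard for
segmentation networks: momentum SGD (momentum 0.9) with base learning rate
1e-3 under polynomial decay `lr(s) = base_lr * (1 - s/steps)^0.9` ending
at zero (decay power and end rate follow the reference implementation
convention of that schedule). The loss is softmax cross-entropy with
ignore-label pixels dropped. Two choices matter at desk scale:

- **In-batch class weighting** (`class_balance = TRUE`): small structures
  occupy few pixels even in patches centered on them, and at 500-step
  budgets an unweighted loss leaves rare classes far from convergence.
  Per-pixel weights proportional to inverse in-batch class frequency fix
  this without touching the optimizer settings; it is the standard
  imbalanced-segmentation practice.
- **Reference defaults** `steps = 500`, `batch_size = 2`, `patch_size =
  512` (tests use 64–128 px patches): large-scale trainings of deep models
  use the same schedule with 50,000–400,000 steps and batch 12; the
  reference model's linear decoder needs far less.

Checkpoints store weights plus architecture metadata and can initialize
further training (`init =`), the transfer-learning path: in the test
suite, a model initialized from a trained checkpoint reaches the 0.9
holdout-accuracy threshold in strictly fewer steps than random
initialization.

## Tiled inference and logit stitching

Prediction runs at `prediction_downsample` (default 2, a speed/accuracy
compromise) on an overlapping grid: origins on a `stride` lattice (default
1000 px at prediction scale) with `patch_size` 2000 px, the final
row/column clamped so the grid covers the full extent. Origins are kept on
multiples of the decoder stride so all patch logit grids align; the final
patch may overhang into white padding instead of misaligning. Patches that
do not intersect the tissue mask are skipped — that is where tissue
masking buys its speed — and the plan asserts that every tissue pixel
remains covered.

Each output pixel of the stitched logit volume is the *unweighted mean* of
all contributing patch logits. Before accumulation a `border_trim` rim
(default 100 px in patch coordinates, floored to whole logit pixels) of
each patch prediction is discarded to suppress edge artifacts — except
along sides where the patch abuts the slide boundary, where trimming would
leave a rim of tissue with no prediction at all. Logit averaging is used
in both contour and heatmap modes. The implementation accumulates
per-pixel sums and counts; a brute-force per-pixel accumulator reproduces
it to numerical exactness in the tests. With the defaults the volume lives
at `prediction_downsample x stride = 8`, one-eighth of base resolution per
side.

`volume_to_mask()` takes the per-pixel argmax; exact ties break toward the
lower class index for determinism, and pixels never covered by a patch are
background. `export_heatmap()` converts one class's logits to softmax
probabilities and stores the sparse entries above a threshold (default
0.05) — heatmaps communicate confidence for structures with poorly defined
boundaries, such as IFTA, better than binary contours do.

## Annotation model and interchange

Annotations are named layers of closed polygons in base coordinates; the
layer is the class. Rasterization uses an even-odd scanline fill at pixel
centers with half-open crossing intervals, so shared edges between
adjacent polygons never double-fill; the rule is deterministic and
verified against a per-pixel point-in-polygon oracle. Where polygons of
different layers overlap, later layers win: no canonical precedence rule
exists for this situation, so it is resolved by document order, matching
how training layers are listed. Each polygon carries its bounding box; rasterization
skips polygons whose box misses the requested region, an index that can
only affect speed, never output (tested by equivalence).

Vectorization (`mask_to_annotations()`) traces one polygon per connected
component per class and pushes vertices 0.5 px outward from the component
centroid: tracing through boundary-pixel centers alone loses the boundary
ring on re-rasterization, while the outward offset makes the round trip
exact on blob-like (star-convex) components and ≥ 0.98 IoU is asserted on
the generated fixtures. Heavily concave shapes may round trip less
tightly; for them the raster, not the polygon, is the authoritative form.

The XML dialect is the ImageScope-compatible
`Annotations/Annotation/Regions/Region/Vertices/Vertex` structure with
`X`/`Y` vertex attributes and bounding boxes as `Region` attributes;
coordinates are printed with 17 significant digits so write-then-read is
the identity. The JSON schema is self-defined and versioned
(`slideseg-annotation` / `slideseg-heatmap`, version 1); heatmap point
coordinates are up-sampled to base resolution in the JSON so viewers need
no knowledge of the prediction scale.

## Features and percent IFTA

`extract_object_features()` computes a fixed, versioned set (~20 shape and
intensity features) rather than a sprawling catalogue; the exact formulas
are in its help page. Perimeter uses chain-code steps with
Vossepoel–Smeulders weights (0.980 axial, 1.406 diagonal, −0.091 per
corner), an unbiased estimator of smooth boundary length — a raw staircase
count would bias circularity for round objects; on an axis-aligned square
it underestimates by ~3%, the price of calibrating for smooth boundaries.
Circularity and solidity are capped at 1 against discretization noise.
Stain separation uses the standard published H&E optical-density vectors
with a fixed deconvolution matrix. Areas are reported in px² always and
µm² when the slide's microns-per-pixel is known (typical scanner
resolutions are 0.13–0.25 µm/px); without `mpp` the µm² column is NA.
Degenerate polygons that rasterize to zero pixels are dropped with a
warning. Percent IFTA is pure pixel counting at a rasterization scale
chosen to keep the raster under ~2048 px per side:
`100 * |IFTA ∩ cortex| / |cortex|`, with an error on zero cortex area.

## Evaluation

Pixel metrics are one-vs-rest per class from the 2×2 confusion table;
degenerate denominators yield 0 with an explicit flag rather than NaN.
ROC sweeps run on softmax probabilities (any monotone transform of the
logits leaves AUC unchanged) via the pROC package, and the tests pin AUC
to the normalized Mann–Whitney statistic on enumerable instances. ICC(2,1)
— two-way random effects, absolute agreement, single rater — is computed
from the two-way ANOVA mean squares, with the F test of r = 0 vs r > 0;
it is verified against an independent `aov()` decomposition. The
separability analysis embeds the feature table into two dimensions with
UMAP and cross-validates a KNN classifier on the embedding, reporting
Cohen's kappa per neighborhood size over a default grid of odd k from 1 to
25 and the maximum over the grid; the fold count is a parameter (default
10) because the field's usage varies between five- and ten-fold for this
analysis. Runs are deterministic given the seed (single-threaded UMAP).

## The synthetic fixture: what it shows and what it does not

The generator emulates the geometry of the problem — white background,
irregular stained-tissue blobs, star-convex target objects of two classes
placed fully inside tissue without mutual overlap, a three-level pyramid —
with bit-reproducible output per seed, object colors chosen
color-separable, and ground-truth polygons that are exactly the drawn
shapes. Defaults are a 1024-px slide, three tissue blobs (radius 15–25% of
the slide side), twelve 40–80 px "glomerulus" objects and eight 24–50 px
"artery" objects. It does **not** emulate stain variability, texture,
focus blur, scanner differences, touching or overlapping structures, or
ambiguous boundaries. Passing tests therefore demonstrate that the
*machinery* — sampling statistics, stitching arithmetic, coordinate
transforms, interchange fidelity, metric formulas — is correct, and that
the pipeline composes end to end; they say nothing about biological
segmentation accuracy on real slides, which is a property of the plugged-in
model and its training data.

## Problem sizes and numerical choices

The test suite and the acceptance script run on 384–1500 px synthetic
slides, 10,000-draw sampling audits, 500-step reference trainings at
128-px patches, and 200×315 separability problems — sizes chosen so the
full suite completes in a few minutes on one CPU while every assertion
still has statistical or numerical teeth. Other fixed choices: argmax ties
to the lower index; `log` clamped at 1e-12 in the cross-entropy; optical
density clamped at 1/255; heatmap sparsification strictly above the
threshold, so threshold 0 keeps exactly the covered pixels; tissue-mask
idempotence is bit-exact via the PNG cache.
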