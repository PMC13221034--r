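---
title: "Measuring shape vs. texture bias with and without 3D shading cues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring shape vs. texture bias with and without 3D shading cues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cueconflict3d)
```

## The problem

Humans classify objects mainly by shape; deep networks lean more on
surface texture. The standard probe is the *cue-conflict* stimulus: an
image whose shape comes from one category and whose texture from
another, so shape-based and texture-based classification disagree. Most
cue-conflict stimuli carry shape only in the external contour. But real
images also convey shape through *shading* (smooth luminance variation
with surface orientation) and *attached shadows* (shadows one part of an
object casts onto another part of the same object). This package
implements a complete, desk-scale pipeline for asking how those 3D cues
change the shape/texture balance: stimulus synthesis, classifier
evaluation, bias statistics, behavioral simulation and analysis, and a
finetuning protocol.

Everything runs on procedural stand-ins — parametric part-based meshes
and procedural textures — so the pipeline is fully reproducible with no
model zoo, photographs, or downloads. Real classifier outputs can be
plugged in as probability matrices over a label vocabulary.

## Stimulus model

**Shapes.** Each of ten entry-level categories (five biological, five
non-biological names: fish, elephant, butterfly, bird, bear, helmet,
mailbox, bathtub, mug, phone) is bound to a distinct part-based family
assembled from closed primitives (spheres, boxes, cylinders, cones,
tori). Models within a category share the family's part topology and
differ in part dimensions jittered ±15% per model, all drawn
deterministically from the seed. Meshes are normalized to unit
bounding-sphere radius (so camera framing is family-independent), use at
most ~400 triangles per model (well under the 2,000-triangle ceiling
chosen for desk-scale shadow ray casting), carry a unit front axis (+x),
and are validated for outward orientation by the signed-volume test.
These families are deliberately *not* miniature elephants or mugs — the
point is ten visually distinct shape classes with known structure, not
biological realism. A fixed JSON registry pins the category-to-family
binding.

**Textures.** Each category is likewise bound to a procedural pattern
family (checks, stripes at several orientations, dots, gratings,
periodic noise, weave, zigzag) with a base hue fixed per category and
evenly spaced around the color circle; frequency, phase and the
secondary color vary per texture instance. Patterns are evaluated on
unit coordinates with integer frequencies, so opposite edges match
exactly (tolerance 1e-6) and tiling is seamless. Every pixel is pattern
content; there are no background pixels to leak silhouette information.

**Rendering.** A software rasterizer (perspective projection, depth
buffer, barycentric interpolation of smooth vertex normals) renders each
model white-on-black from a 12-camera orbit in 30° steps. Shading is
Lambertian with a small ambient term: off-figure pixels are 0 and
on-figure pixels take
`ambient + (1 - ambient) * max(0, n·(-l)) * visibility`,
where visibility is decided per pixel by casting a shadow ray toward the
directional light against the full triangle set (vectorized
Möller–Trumbore). Visibility-0 pixels whose surface faces the light form
the attached-shadow mask; back-facing points get the ambient term only
and are not counted as attached shadow (that term is reserved for cast
occlusion). The light is a single directional source offset 30°/30° in
azimuth/elevation from the camera axis by default, with ambient 0.1 —
the simplest configuration that produces both smooth shading and
attached shadows; all of it is explicit configuration, since no lighting
or renderer choice is canonical for this problem.

**Texture substitution.** The 3D operator multiplies the grayscale
shaded render pixelwise with the RGB texture (tiled over the frame in
image space, not UV-mapped — matching the pixelwise-product definition
of the stimuli); the 2D operator does the same with the binary
silhouette. Because both share one rasterization, matched 3D/2D stimuli
have *pixel-identical* figure masks and differ only in shading and
attached-shadow cues inside the silhouette. Two invariants follow by
construction and are tested: shading can only darken (3D ≤ 2D pointwise)
and never below the ambient floor (3D ≥ ambient × 2D inside the mask).

**Canonicality.** Views are labeled canonical when the camera azimuth is
within a tolerance of the model's front direction or of either profile
(±90°), and noncanonical otherwise (backside views). The original
datasets hand-coded this per image; an angular rule makes it
reproducible while matching the verbal criteria ("facing toward the
viewer or in profile"). The default tolerance of 31° lets each
front/profile direction capture its adjacent 30° orbit neighbors, giving
9 canonical and 3 noncanonical views per 12-view orbit; the tolerance is
configurable because the per-model canonical/noncanonical composition of
the original datasets is not published (only an aggregate 80,400/39,600
split, i.e. 67% canonical; the default rule gives 75%).

At full scale the design reproduces the published combinatorics exactly:
100 models × 12 views = 1,200 base renders, each crossed with 100
textures = 120,000 records per condition. Congruent records (shape and
texture from the same category) are generated — the full cross includes
them — but flagged, and excluded from bias metrics by default since
"texture-correct" and "shape-correct" coincide there.

## Evaluation model

Classifiers emit probability vectors over their own label vocabulary
(e.g. 1,000 fine-grained labels). Scores are aggregated to the ten
entry-level categories by summing the probabilities of all mapped
subcategories (the package ships the subcategory-to-entry-level mapping
as a CSV fixture); the decision is the argmax of the summed scores, with
lexicographic tie-breaking (flagged; ties have measure zero for real
softmax outputs). A decision counts as shape-correct or texture-correct
by comparison with the stimulus's two source categories.

The bias statistic is
`texture_bias = texture_correct / (texture_correct + shape_correct)`,
with shape bias its complement; values above 50% indicate texture bias.
It is undefined (reported `NA`) when no decision followed either cue,
and invariant to the number of `other` outcomes. Percentages are
rounded half-away-from-zero when printed. Condition metrics stratify by
(condition × canonicality) and compute the 3D gain — shape accuracy 3D
minus 2D — on matched stimulus pairs; both the stratified and pooled
reductions are available, since it is unspecified whether published
cross-network averages pooled raw trials or strata.

Oracle classifiers (shape oracle, texture oracle, mixtures, uniform
random) serve as calibrated test doubles: a mixture answering by shape
with probability p has expected texture bias 1 − p, which the pipeline
recovers within binomial error.

## Behavioral machinery

Trial builders reproduce both experimental designs: a 160-trial shape
block (8 stimuli × 10 categories × 2 conditions) plus a symmetric
texture block, with shape ≠ texture category enforced on every trial;
and an 80-trial 2×2 schedule (20 per condition × canonicality cell),
randomly interleaved, with flagged practice trials (10 and 16
respectively) excluded from analysis. Simulated observers respond
correctly with a per-cell accuracy probability (else a uniformly wrong
category, plus an optional uniform lapse), with log-normal response
times per cell. The default accuracy pattern is the reported human
Experiment-2 pattern: canonical 95/95, noncanonical 94/85 (3D/2D).

The 2×2 repeated-measures ANOVA is computed from the within-subject
sums-of-squares decomposition, each 1-df effect tested against its own
subject-by-effect stratum; partial eta squared is
SS_effect/(SS_effect + SS_error), and paired contrasts report the mean
difference, t(S−1) and Cohen's d (mean difference over the SD of the
paired differences). Accuracy is analyzed on per-subject cell
proportions — the same reduction as the published analysis — rather
than a binomial mixed model. Sphericity is not an issue for 2×2
within-subject designs (all effects have 1 df). The implementation is
checked to 1e-8 against an independent textbook sums-of-squares oracle
and against `aov()` error strata, and a power property holds by
simulation: at the default accuracy pattern, 129 observers with 20
trials per cell yield a significant condition × canonicality interaction
at α = .001 in ≥95% of replicates.

## Finetuning protocol

Four curricula cross an image filter (all viewpoints vs canonical-only)
with a freeze policy (all weights vs decision head only): learning rate
2e-5 for the unfrozen curricula (1 and 3) and 1e-3 for the head-only
curricula (2 and 4), batch size 96. Training is restricted to 3D
stimuli; the filter applies before the 80/20 train/validation split,
which is stratified by shape category and deterministic under the seed.
Training runs whole epochs in shuffled batches (reshuffled each epoch
from the run seed, last partial batch kept), evaluates validation error
once per epoch — the epoch is the natural granularity given that the
published runs reached criterion in 1–2 epochs — stops at the first
validation-error increase, and adopts the minimum-validation-error
checkpoint. The optimizer is plain gradient descent (the original
optimizer is unreported; this is the least-assumption default and is
configurable).

The trainable model is pluggable via three generics (`model_predict`,
`model_update`, `model_supports_freeze`). The shipped reference
classifier is a small two-stage network — a tanh hidden layer standing
in for a pretrained backbone, plus a softmax decision head — so the
curriculum, early-stopping, freezing and purity logic is exercised for
real at desk scale. Under `head_only` its backbone parameters are left
bit-identical, verified exactly. Note one honest difference from a
pretrained transformer: the reference backbone is *random*, so its
frozen features are a genuine bottleneck and head-only runs plateau
well below unfrozen runs; with a pretrained backbone the frozen/unfrozen
gap is smaller. The published accuracies of the finetuned transformer
(97–99%) are out of scope by design — they require the real pretrained
weights and the original dataset — and are not reproduced or asserted
anywhere.

## Numerical choices

- Rasterization interpolates attributes affinely in screen space
  (adequate at the package's triangle densities and fields of view);
  depth test uses camera-space depth with a 1e-9 tie guard.
- Shadow rays start 5e-3 units toward the light to avoid self-hits
  ("shadow acne") and use inclusive barycentric bounds (±1e-9) so rays
  through shared triangle edges register a hit regardless of
  floating-point evaluation order; the shadow test is verified
  pixel-for-pixel against an independently coded scalar ray-triangle
  loop.
- Degenerate inputs: meshes with no front-facing triangles render as an
  empty mask with a warning; all-zero aggregated scores yield decision
  `"none"`; empty bias denominators yield `NA` rather than 0.
- All generators route randomness through an internal seed derivation
  so every artifact is a pure function of its arguments, and the
  caller's RNG stream is never disturbed.

## What the synthetic data does and does not show

The generators emulate the *structure* of the original study —
category counts, orbit geometry, matched 3D/2D pairs, canonicality
labels, entry-level label granularity — with category signal verified
by construction (a fixed nearest-centroid classifier separates texture
categories at >90% and shape categories from silhouettes at >70%).
They do not emulate natural image statistics, ShapeNet geometry,
photographic texture, or pretrained-network behavior. Passing tests
therefore certify the pipeline's correctness (formulas, invariants,
protocols, statistics) — not that any particular network will show a
particular bias on real images. The published headline numbers that
depend only on printed values and formulas (the 44% average 2D texture
bias; the 56% → 70% shape-bias shift with 3D cues) are reproduced
exactly from those values through the package's own statistic.

## Problem sizes used in tests and scripts

Tests run at 64×64 resolution (the default stimulus resolution is
224×224) with 2–4 models and 2–6 textures per category; the full-size
manifest checks run lazily without rendering. The acceptance script
evaluates the bias statistic on 10,000-trial outcome sets; the ANOVA
power property uses 200 replicates of 129 simulated observers; finetune
demonstrations train on a few hundred rendered stimuli. These sizes were
chosen so the whole suite exercises every code path in well under a
minute per module.

## Known limitations

- Image-space texturing means texture does not foreshorten with the
  surface; this matches the pixelwise-product stimulus definition but is
  not a physical surface texture model.
- Affine (not perspective-correct) attribute interpolation and smooth
  normals everywhere (including intentionally sharp edges) introduce
  small shading errors at the package's scales.
- The canonicality rule is purely azimuthal; elevation is accepted but
  unused, which is faithful to orbit-style datasets at a fixed modest
  elevation only.
- No cast shadows on a ground plane, no global illumination, no
  specularities — the background is pure black by design.
- The reference classifier is a protocol vehicle, not a model of any
  published network's representations.
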