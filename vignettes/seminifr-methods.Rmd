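---
title: "Methods: automated staging and morphometrics of seminiferous tubule images"
author: "SeminifR maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated staging and morphometrics of seminiferous tubule images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mouse spermatogenesis proceeds inside seminiferous tubules as a cyclic
sequence of twelve cellular associations (stages I--XII, with XII
adjacent to I). A cross-section stained for DNA (Hoechst), peritubular
smooth-muscle actin (Acta2) and the acrosomal protein Acrv1 shows, for
every tubule, concentric layers of germ cells at characteristic
positions: spermatogonia (SPG) and Sertoli cells at the basal edge,
primary and secondary spermatocytes (SPC, SPCII) in the middle layers,
and round, intermediate and elongated spermatids (rSPD, iSPD, eSPD)
apically, around the central lumen. SeminifR automates the analysis of
such images: it segments nuclei and tubules, classifies each nucleus
into one of the seven types and each tubule into one of the twelve
stages with residual convolutional networks, filters low-confidence
calls, and derives the spatial statistics a reproductive biologist
reads off such sections -- apical--basal positions, nuclear
orientations, nearest-neighbour structure, the spermatogenic index,
and tubule and lumen radii -- with a quantile-normalization step to
suppress batch effects between image sources.

Because annotated fluorescence sections are large and rare, the
package ships a seeded synthetic-section generator with exact ground
truth; every stage of the pipeline is tested against it.

# Image processing model

**Coordinates and orientation.** All images are numeric matrices
indexed (row, col), 1-based, at a physical scale of `umPerPx`
micrometres per pixel (default 0.17, a 40x slide-scanner objective).
An object's orientation is the angle of its major axis measured from
the +col axis toward +row, folded into [-90, 90) degrees; only the
undirected axis is meaningful, and every derived quantity (relative
orientation) is invariant under a 180-degree flip.

**Intensity normalization.** `normalizeIntensity()` applies a white
top-hat: the image minus its grayscale opening with a disk of radius
100 px. Features smaller than the disk pass through; smooth background
shading is removed; a constant image maps to zero. The operation
commutes with positive scaling, which the implementation exploits to
work in the [0, 1] range its morphology backend expects.

**Nucleus segmentation.** The builtin backend is a classical
threshold-plus-watershed chain: Otsu threshold of the normalized
Hoechst channel; filling of enclosed holes up to `diameter^2` px
(larger enclosed spaces, e.g. a lumen encircled by touching nuclei,
are deliberately left open); Euclidean distance transform; seeds at
local maxima of the distance map with a minimum separation of half the
expected nucleus diameter (30 px default, i.e. 5 um). Tied distance
maxima along the ridge of an elongated nucleus are handled twice: a
half-pixel plateau tolerance keeps ridge plateaus connected, and any
remaining candidate peaks closer than the minimum separation are
single-linkage merged into one seed. Foreground components whose peak
was suppressed by a taller neighbour receive their own label rather
than silently vanishing. Objects smaller than
`(pi/4) * (diameter/3)^2` px are discarded. The `backend = "external"`
slot exists for a generalist learned segmenter; in its absence the
call falls back to the builtin backend with a warning.

**Tubule segmentation.** From the Acta2 channel: Otsu threshold;
binary dilation by `tubuleDilationPx` (default 5) to bridge gaps in
imperfect peritubular rings; hole filling; binary opening by
`tubuleOpeningPx` (default 15) to detach interstitial slivers; erosion
by the dilation radius to revert the ring thickening; connected-
component labelling. Neither radius is dictated by the staining
chemistry -- they are declared defaults chosen to bridge gaps of
roughly 10 px without merging adjacent tubules at the default
magnification, and both are exposed in `PipelineConfig`. Labels are
whole tubule interiors including the lumen, which the lumen-radius
computation later needs. Objects are then filtered to areas in
[5e5, 3e6] px (equivalent radii ~68--166 um at 0.17 um/px) and
circularity strictly greater than 0.5, discarding mis-segmented or
longitudinally cut tubules; the filter is idempotent and fully
accounted in a `SegmentationReport`.

**Perimeter and circularity.** Circularity is `4 pi A / P^2`, exactly
1 for a continuous disk. On rasters the perimeter is estimated by a
four-direction Cauchy--Crofton formula (axis plus diagonal intercept
counts, `P = pi/4 (T0 + T90 + (T45 + T135)/sqrt(2))`). The estimator
is within ~0.1% on large disks but can let circularity slightly exceed
1 on rasters, so the filter compares with `>` rather than clamping.

# Classifiers

Both classifiers are residual convolutional networks implemented in
the package itself (no external deep-learning runtime is required): a
7x7 stride-2 stem, 3x3 stride-2 max pooling, four stages of residual
blocks with identity shortcuts (basic two-convolution blocks at depth
18; the standard bottleneck arrangement 3-4-6-3 at depth 50), global
average pooling and a softmax head. Convolutions are evaluated as
im2col matrix products against BLAS; batch normalization uses batch
statistics during optimization and exactly recalibrated running
statistics at inference (recomputed by averaging batch moments over
the training set after each epoch, which matters for the short
training schedules used at desk scale).

* The **cell-type classifier** consumes a 64 x 64 px patch of the
  top-hat-normalized Hoechst channel centered on the nucleus centroid,
  rescaled to [0, 1] by the source-image maximum, zero-padded at image
  borders; 7 outputs.
* The **tubule-stage classifier** consumes a 2000 x 2000 px crop
  centered on the tubule centroid, area-average downsampled (500 px
  standard), with ten channels: Hoechst, Acta2, Acrv1 and seven
  layers in which each detected nucleus's mask footprint is filled
  with its class probability; 12 outputs. Two construction details
  matter and are deliberate design choices. First, the crop is
  *masked to the tubule object* (interior plus its actin ring) in
  both training and inference: at tissue packing density a 2000 px
  window otherwise contains large fragments of neighbouring tubules
  and interstitial cells, and a classifier trained on isolated
  tubules does not transfer to such crops. Second, the three image
  channels enter at their native calibrated scale with no per-image
  maximum rescaling, because the *absolute* Acrv1 amplitude tracks
  acrosome maturation and is itself a stage cue; rescaling each
  training image by its own maximum would erase it. For the same
  domain-matching reason the probability layers use one encoding on
  both sides: training layers carry the ground-truth class one-hot,
  rendered on footprints produced by the builtin nucleus segmentation
  of the training canvas, and at inference the layers carry the
  *called* class (probabilities hardened to the argmax) on the
  segmented footprints. Soft probability vectors would leak
  stage-specific mass everywhere -- the classifier assigns a little
  iSPD probability to every round spermatid, and iSPD presence is
  a stage IX--X signature -- and truth-ellipse footprints carry about
  twice the pixel mass of thresholded segmentation footprints, both of
  which measurably break the transfer from synthetic training patches
  to pipeline crops. Two further robustness measures: a small fraction
  (8%) of the rendered training classes is flipped to a
  developmentally confusable neighbour (rSPD/iSPD/eSPD, SPC/SPCII,
  Sertoli/SPG), emulating the cell classifier's realistic error
  structure so staging tolerates it; and at inference the stage
  probabilities are averaged over the four axis-flip orientations of
  the patch -- tubules have no preferred orientation, so the flip
  ensemble is exact augmentation-consistent smoothing.

Training uses cross-entropy, SGD with momentum 0.9 and weight decay
1e-4, batch 64, learning rate 1e-3 stepped down tenfold at two thirds
of 20 epochs, flip and 90-degree-rotation augmentation, and a
stratified 90/10 train/validation split, all seeded. Argmax ties break
toward the lowest enumeration index; the label order is fixed by
`cellTypes()` / `stageLabels()` and persisted in saved models, so a
reloaded model can never permute its probability columns.

**Desk-scale configuration.** The networks were designed so the whole
pipeline trains and runs on one CPU in minutes: the test suite and the
worked examples use depth 18 with base width 8 and, for the tubule
task, the 2000 px crop downsampled to 100 px. These are the package's
own reduced settings -- depth 50, width 64 and 500 px input remain the
defaults of `classifierSpec()` -- and nothing in the architecture
changes other than size. With the default learning rate the reduced
tubule network converges slowly; the desk-scale runs use 3e-3.

**Confidence filtering (LCF).** Calls with confidence below 0.80 are
removed (exactly 0.80 is retained); the retention fraction is
reported. Per-tubule statistics are computed over retained
intratubular nuclei by default (switchable), while the probability
layers fed to the stage classifier use all detected nuclei.

**Evaluation.** `evaluateClassification()` reports the confusion
matrix (rows annotated, columns predicted), overall accuracy,
per-class true/false positive rates and positive predictive values,
a confidence histogram in left-closed 5% bins (1.0 included in the
last bin), and -- for stages -- the within-one cyclic accuracy, where
stage s accepts predictions in {s-1, s, s+1} modulo 12, so I matches
XII and II.

# Morphometrics

**Apical--basal position.** The two measurable distances are the
nucleus centroid to the nearest tubule edge (`d_edge`) and to the
tubule centroid (`d_center`). They are combined as
`ABP = d_edge / (d_edge + d_center)`, which is bounded in [0, 1], 0 at
the basal edge, 1 at the centroid, equals `1 - r/R` for a circular
tubule, and is monotone along any ray of a convex tubule. Pixel
distances to the edge are taken as `distmap - 1` so a boundary pixel
scores 0.

**Relative orientation.** The acute angle between the undirected
nuclear major axis and the radial vector to the tubule centroid,
folded into [0, 90]: 0 is radial (apical--basal), 90 circumferential.

**Nearest neighbours.** Within one tubule, each nucleus (reference)
is connected to the Euclidean-nearest nucleus of every *other* type
present (centroid-to-centroid); absent types yield no edge, recorded
as missing rather than zero. Each edge carries the signed radial
displacement `ABP(target) - ABP(reference)`, positive when the target
is more apical; this is the package's fixed sign convention.
`neighborSummary()` pools edges into 7x7 reference-by-target matrices:
single-nearest pair counts normalized by the number of contributing
tubules, mean distances and mean signed radial displacements.

**Spermatogenic index.** `eSPD / SPG` per tubule; missing when the
tubule has no SPG. Under the ideal meiotic yield (one SPG lineage
producing four spermatids) the value is 4.

**Lumen radius.** On the map of distances to the nearest nucleus
pixel *or* tubule edge, the lumen region is the connected component
above half the map maximum that contains the deepest point. The lumen
radius is that maximal distance -- the radius of the largest
nucleus-free disk. We deliberately do not report the equivalent
radius of the half-maximum region itself: for an annular arrangement
leaving a free central disk of radius `R_l` that region has radius
close to `R_l / 2`, and for an empty tubule close to `R / 2`, both
half the quantity of interest; the maximal distance estimates `R_l`
(and, for an empty tubule, the tubule radius, giving a
lumen-to-tubule ratio near 1) directly. The half-maximum fraction is
configurable.

**Improbable-class filtering.** For genotypes in which some classes
cannot occur (a meiotic-arrest mutant has no post-meiotic cells),
records called as a disallowed class are dropped and the remaining
records' probability vectors are zeroed on the disallowed components
and renormalized, with call and confidence recomputed.

# Batch-effect normalization and tests

Observations (for example nuclear areas) are organized as a tensor of
features x samples x observations, with features the cell types and
samples the image sources; 10 000 observations per cell is the
standard depth, subsampled without replacement when a group is large
enough and with replacement (flagged in metadata) otherwise.
`quantileNormalize3D()` first sorts every z-vector, then applies
classic rank-mean quantile normalization (midranks for ties,
interpolated reference) independently to every features x samples
frame; after the operation all samples of a frame hold identical value
multisets.

Two properties often quoted for quantile normalization -- idempotence
and equality of per-feature means across samples -- hold here exactly
in the *stable-rank regime*, i.e. when feature scales are separated
enough that within-frame ranks do not change along z. That is the
regime the method is designed for (cell-type features differ
systematically by an order of magnitude more than their within-type
spread); for strongly interleaved features the frame ranks fluctuate
and neither property is guaranteed. The test suite asserts both
properties in the separated regime and exact agreement with an
independent brute-force implementation (and with the classic 2D
method applied frame by frame) on small tensors.

`compareFeatures()` extracts one two-sided p-value per feature
between two samples: a paired t-test on the z-aligned values or a
Mann--Whitney U-test. No multiple-testing correction is applied by
default (per-feature raw p-values are the primary output); a
Bonferroni option exists. Features whose aligned values agree exactly
-- possible after normalization -- report p = 1. Significance labels
use `p <= 0.01`, with additional tiers at 1e-3 and 1e-5. Under the
null (two samples from one distribution) the sort-and-normalize
pipeline makes both tests conservative, which the acceptance suite
verifies as a type-I error well below the nominal level.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
conditions every downstream test assumes.

A section is a jittered grid of circular tubules (~120 per whole
section by default; radii 420--470 px, inside the area-filter
bracket). Pure rejection sampling of tubule positions cannot terminate
at tissue-like packing densities, so placement is grid-plus-jitter
with an explicit overlap guard and a bounded-retry error. Each tubule
carries an Acta2 ring (Gaussian radial profile, 12 px thick), nuclei,
and Acrv1 signal; interstitial nuclei (truth type `extratubular`) are
scattered between tubules.

Nuclei are rendered as anisotropic super-Gaussian blobs
(`exp(-0.5 rho^4)` in the normalized elliptical radius): flat-topped
with a sharp fall-off, like a stained nucleus, so neighbours do not
fuse through Gaussian tails. Per-type size, aspect ratio and
brightness make the seven classes separable in (area, eccentricity,
intensity) -- spermatocytes largest and bright, Sertoli large and dim
with a bright nucleolus, spermatids small, eSPD strongly elongated and
condensed -- which is the generator's declared design goal: it gives
the classifier learnable, honest signal without imitating real
chromatin texture. Placement bands in apical--basal position encode
the tissue's architecture (SPG/Sertoli basal, SPC mid, spermatids
apical), with the documented stage dependences: rSPD drift apically
as spermiogenesis progresses, eSPD move into the lumen at stages
VI--VII, Sertoli drop sharply basal at VIII, SPG shift apically from
VIII. Spermatids are radially oriented (+-8 degrees); other types are
uniform. A minimum centroid separation (footprint-touching distance,
floor 18 px) is enforced by bounded rejection sampling; an
over-packed request errors out rather than degrading.

Composition per stage encodes the ideal meiotic yield -- every stage
holds exactly four eSPD per SPG -- plus the stage-specific types:
rSPD through spermiogenesis steps I--VIII, iSPD at the round-to-
elongated transition (IX--X), SPCII only at the meiotic divisions
(XII). The `meiotic_arrest` genotype removes SPCII and all spermatids,
so arrest tubules hold fewer nuclei than wildtype, the qualitative
analogue of mutant atrophy. The tubule-stage signal available to the
classifier is therefore: composition (which types are present),
geometry (the apical drift of the spermatid layers) and the Acrv1
channel, whose per-cell amplitude grows with acrosome maturation
across I--VIII -- the monotone cue that distinguishes
developmentally adjacent early stages, mirroring the role of the
acrosomal stain in manual staging.

Imaging noise is Poisson shot noise at a camera gain of 400 with a
small baseline and Gaussian read noise, clamped to [0, 1] and
quantized to the 16-bit integer grid of typical scanner exports --
which also makes the TIFF round-trip of generated stacks bit-exact.

**What the generator does not emulate:** real chromatin texture,
staining heterogeneity and antibody background, partial-volume and
focus effects, non-circular or longitudinally cut tubules, touching
or overlapping nuclei beyond the separation floor, and biological
variability of composition beyond the fixed per-stage table. Passing
tests therefore demonstrate that the pipeline's machinery is correct
and self-consistent under realistic geometry and noise, not that the
shipped reduced networks would reach any particular accuracy on real
micrographs.

# Numerical choices and degenerate inputs

* Probability vectors must sum to 1 within 1e-6; confidence equals the
  maximum; argmax ties break toward the lowest enumeration index.
* Record CSV round-trips are exact to at least 1e-9 (15 significant
  digits written).
* An empty image yields an empty mask, not an error; an empty record
  list yields a header-only file; an empty (feature, sample) group is
  an error.
* Confidence histogram bins are left-closed at 5% steps with 1.0 in
  the last bin.
* The seed governs every stochastic step (generator, subsampling,
  training shuffles and augmentation); training is deterministic given
  the seed and a fixed BLAS configuration up to last-digit jitter,
  which the determinism test bounds at 0.02 in final-epoch accuracy.

# Problem sizes used in the tests

The shipped tests run the full pipeline at desk scale: a 12-tubule
wild-type section (~2500 intratubular nuclei plus interstitials, a
~3000 x 4000 px image), classifiers at depth 18 / width 8 trained on
64 Hoechst patches per cell type and 10 tubule patches per stage
(2000 px crops downsampled to 100 px), and 200-replicate calibration
loops for the statistical tests. Unit tests use smaller constructed
fixtures (4-tubule sections, two-class separable patch sets, 2x2x3
tensors). The whole-section default (120 tubules) is the generator's
statement of the real study conditions and is not exercised inside the
test suite.

# Known limitations

* The builtin nucleus backend is a classical watershed: it
  under-segments heavily overlapping nuclei and its centroid accuracy
  degrades for strongly concave clumps; the external-backend slot is
  the intended upgrade path.
* The stage classifier's reduced configuration is tuned for the
  generator's signal; real sections need the full-size configuration
  and real annotations.
* Quantile normalization assumes comparable observation depth per
  sample; groups far smaller than `nObs` are resampled with
  replacement and flagged, but their quantiles are correspondingly
  noisy.
* Tubules are modelled as circles; strongly elliptical tubules pass
  the circularity filter down to 0.5 but their ABP is compressed along
  the minor axis (the formula, not the tissue, defines the scale).
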