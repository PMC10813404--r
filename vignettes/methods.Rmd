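---
title: "Methods: hypertensive retinopathy grading with fundusHR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hypertensive retinopathy grading with fundusHR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusHR)
```

## The problem

Hypertensive retinopathy (HR) is retinal microvascular damage caused by
systemic hypertension. Graders sort fundus photographs into five classes —
normal, mild, moderate, severe, malignant — by findings that progress from
arteriolar narrowing (mild), through narrowing with focal constriction
(moderate) and hemorrhages with diffuse narrowing (severe), to hard
exudates and optic-disc edema (malignant). fundusHR implements an
automated pipeline for this grading task: contrast enhancement tuned to
retinal vasculature, vessel segmentation with a lightweight attention
network, optic-disc removal, a 24-feature descriptor, and boosted SVM/KNN
grade classifiers with k-fold cross-validation.

Because the public HR datasets the task is usually studied on cannot be
bundled, the package ships a synthetic fundus generator that renders the
same grade-dependent findings with pixel-accurate ground truth, so every
stage is testable end to end.

## Enhancement chain

`preprocessFundus()` runs four deterministic stages in order.

**Gaussian contrast gain.** Per RGB channel, with mean `m` and population
standard deviation `s`, the response
`G(x,y) = exp(-(o-m)^2/s) / (2*pi*s)` is largest where intensity sits at
the channel mean. The per-pixel gain is `1 + f/g` with `g = 1 + G/lambda`
(`lambda = 0.2` by default, the sampling parameter) and
`f = mean(p * (1 - o))`, where `p` is each pixel's 256-bin histogram
probability. Note two deliberate choices. First, `G` keeps the
first-power denominators of the chain's defining form rather than the
textbook normal density (`textbookGaussian = TRUE` switches to the
standard form). Second, `f` is the *mean* of the summand `p*(1-o)`, not
its raw sum: the raw sum grows linearly with pixel count, which would
drive the gain into saturation on any realistically sized image; the
normalized form is bounded in `[0,1]`, keeps `gain >= 1`, and makes the
enhancement independent of image size. The gain multiplies the channel
and the result is clipped to `[0,1]`.

**HSV transform.** Channels are first reduced to chromaticities
`beta_r = r/(r+g+b)` (summing to 1 on lit pixels). Saturation is
`(max-min)/max` of the chromaticities, value is their maximum (so a gray
pixel has value 1/3), and hue is the arccos form on chromaticities, in
radians in `[0, pi]`. Achromatic pixels, where the hue denominator
vanishes, receive the sentinel hue 0 and are flagged.

**Doane normalization.** Each plane is passed through
`psi = 1 + log2(beta) + log2(k)` where `k` is the plane's skewness from
population central moments (`E[(x-m)^3]/s^3`; a symmetric plane has
`k = 0` exactly). Guards: both logarithm arguments are clamped below at
1e-12 and `k` enters as `|k|`. The raster is then rescaled to `[0,1]` by
a *robust* min–max over the 0.5–99.5 percentile range. The robustness is
load-bearing: sentinel-hue pixels have `log2(1e-12) ≈ -40`, and a plain
min–max over a plane containing even one of them compresses all real
signal into a few percent of the output range. Clipping the rescale at
the percentile envelope preserves the plane's dynamic range while the
guards keep every value finite.

**Channel selection.** With `f(.)` the per-pixel histogram probability of
each normalized plane and `mp` their per-pixel mean, the cascade picks
hue where `f(beta_h) < mp`, else saturation where `f(beta_s) < mp`, else
value (on `<=`). The value branch always accepts when reached — at least
one of three numbers is `<=` their mean — so the choice map is total, and
ties fall through to value. The output is a per-pixel mosaic of the three
planes plus the choice map and per-channel provenance.

**Which plane feeds what.** The selected mosaic plane is the *analysis*
plane: texture features (GLCM, LBP) are computed on it, and its
construction — preferring locally rare intensities — highlights lesioned
tissue. It is, however, a poor input for a convolutional segmenter: the
pixel-wise stitching of unrelated planes has almost no spatial coherence,
and measured vessel-to-background contrast on it is on the order of 0.01.
The segmentation network therefore consumes the contrast-gain-enhanced
*green* channel (`segmentationPlane()`), the channel with the strongest
vessel contrast in fundus photography. Both planes come from the same
`preprocessFundus()` call.

## Attention block and segmentation network

The spatial-convolution attention block (`scmBlock()`) composes two
gates. *Channel attention*: the feature map (C×H×W) is reduced by
spatial pyramid pooling — each level `L` partitions the plane into L×L
bins with half-open `floor` boundaries; each bin is average- and
max-pooled; the descriptor length `2*sum(L^2)` per channel is independent
of H and W (default levels 1, 2, 4 standalone; 1, 2 inside the network).
Both branch descriptors pass through a shared two-layer network
(`W1 act(W0 x)`, hidden size `max(1, floor(C/e))`, ReLU by default with a
Gaussian-RBF unit available) and are combined by element-wise summation
before the sigmoid. *Spatial attention*: the channel-axis mean and max
maps are convolved with a 9×9 kernel (zero-padded, same size) and passed
through the sigmoid. The default arrangement is sequential —
`M' = DC(M) ⊗ M`, then `M'' = DS(M') ⊗ M'` — with a parallel averaging
arrangement available behind the config. Because both gates lie in
(0,1), the block can only attenuate; output shape equals input shape.

The segmentation network is a small U-shaped encoder–decoder: each
encoder stage is 3×3 convolution + ReLU, an attention block, then 2×2
max pooling; the decoder mirrors with nearest-neighbor upsampling, skip
connections and 3×3 convolutions; a 1×1 sigmoid head emits per-pixel
vessel probabilities. The bottleneck is summarized by a pyramid-pooled
descriptor whose length is independent of input size, so the same
weights process any image geometry in a single pass. All layers,
including the attention block, are implemented with hand-derived
backpropagation and verified against central finite differences in the
test suite (agreement to ~1e-10 on random instances). Training minimizes
Dice + binary cross-entropy with Adam; everything is deterministic under
the config seed.

Defaults and why: depth 3 and 16 base channels as the general-purpose
configuration; threshold 0.5 on the probability raster; learning rate
1e-2 (Adam), which on the synthetic corpus converges in tens of epochs
where 3e-3 needs hundreds; Dice+BCE because vessel pixels are a small
minority (~10% of the field of view) and plain BCE stalls in the
background class. The sigmoid head's bias is initialized at -2, the
logit of the vessel-class prior, rather than 0: starting the output
near the class prior removes the early epochs otherwise spent
un-learning the background and makes convergence insensitive to the
weight-initialization seed.

## Optic-disc removal and the vessel graph

`removeOpticDisc()` clusters FOV pixels on (intensity, blurred intensity)
with k-means (k = 3, centers seeded deterministically along the intensity
range). The brightest cluster is accepted only if its mean brightness
exceeds the FOV mean — otherwise a no-disc flag is returned and the image
passes through unmodified. The accepted cluster's largest connected
component is morphologically closed and hole-filled into the disc mask;
disc pixels are zeroed and removed from the vessel mask (removal can
only shrink it).

`skeletonizeVessels()` thins the mask to one-pixel centerlines
(Zhang–Suen), estimates caliber as twice the distance transform along the
centerline, and splits segments at junctions. Skeletal pixels with three
8-connected neighbors are bifurcation candidates, four or more a
crossover; candidates are merged over 3×3 clusters and typed by the
number of skeleton branches leaving the cluster neighborhood. Crossover
neighborhoods (radius 3 px) are eroded from the working mask before
per-segment features so that arteriovenous crossings do not contaminate
either vessel.

Artery/vein labels come from per-segment features — median green-plane
centerline intensity, caliber, central-reflex contrast (centerline minus
flank intensity at half-caliber offset), hue variability — fed to a
trained classifier when one is supplied, else to a threshold fallback:
brighter, thinner, reflex-positive segments are arteries. Degenerate
inputs (all segments identical) collapse to one class with a warning.

## The 24-feature descriptor

The four groups (order fixed in `hrFeatureNames()`):

* texture (8): GLCM contrast, correlation, energy, homogeneity, entropy
  of the analysis plane (distance 1, four symmetric angles averaged, 32
  gray levels), plus mean/variance/skewness of the 8-neighbor radius-1
  LBP code distribution;
* color (6): mean and population sd of hue, saturation, value inside the
  vessel mask;
* disc (4): disc area fraction of the FOV, disc mean brightness, boundary
  blur (mean gradient magnitude on the boundary ring), disc obscuration
  (vessel pixels inside the disc over disc area);
* vascular (6): vessel density in the FOV, mean and sd of segment
  calibers, mean arc/chord tortuosity (≥ 1 by construction), junction
  density per centerline pixel, artery-to-vein mean-caliber ratio (AVR
  proxy; 1 when either class is absent).

The grading literature names these four groups without enumerating the
members; this list is the package's canonical interpretation, chosen to
cover every cue the grading ladder uses (narrowing/AVR, obscuration,
color and texture change), and is versioned with the package.

## Classifiers

**Boosted SVM** (`trainImprovedSVM()`): each round fits one-vs-rest
linear hinge scorers on the current sample weights by full-batch
subgradient descent (L2-regularized, `lambda = 1/(C n)`), evaluates the
multiclass hinge loss, and up-weights samples with positive loss
(`w <- w * exp(min(loss, 2))`, renormalized). Round weights follow the
weighted error, `log((1-err)/err) + log(K-1)` floored at 1e-3, and
prediction averages round score vectors under these weights. One round
with uniform weights is exactly the plain one-vs-rest linear SVM.

**Boosted KNN** (`trainImprovedKNN()`): boosting-by-resampling over weak
KNN learners, each drawing a weighted bootstrap, a random third of the
features, and k from {1,3,5}; weighted error sets the vote weight and
the reweighting; the lowest-error learner is recorded as best and the
variance of learner errors is logged. KNN itself is brute force
(exact distances; Euclidean or cosine, optional inverse-distance votes) —
at the package's problem sizes an index structure would be overhead.

The comparison variants are thin specs over `e1071::svm` (polynomial
degrees 1–3 with offset 1; Gaussian kernels with gamma 4/24, 1/24,
0.25/24 so fine < medium < coarse bandwidth) and over the brute-force
KNN (k = 1, 10, 100; cosine; distance-weighted). Cross-validation is
stratified (plain randomization is used, with a warning, when a class
has fewer members than folds); each fold is tested exactly once and the
aggregate is the mean of per-fold macro metrics. The 80:20 split rounds
the test share per class, so the reference class distribution
(200 normal / 400 mild / 200 moderate / 200 severe / 200 malignant)
yields exactly 960 training and 240 test images.

## Metrics

`metricSuite()` evaluates accuracy, precision, recall, F1, Dice and
Jaccard from one-vs-rest confusion counts, per class, macro-averaged and
pooled (micro). Two non-standard forms from the pipeline's original formulation are
preserved deliberately: the default Dice omits the FP term (`2TP/(2TP+FN)`;
`standardDice = TRUE` restores `2TP/(2TP+FP+FN)`) and the halved-sum F1
variant is reported alongside as `f1_paper` (it equals the standard
macro-F1 only in the single-class case). Pixel-mask segmentation quality
(`maskOverlap()`) always uses the standard Dice — the two-term form would
reward over-segmentation. Zero denominators yield 0 with a warning.

## Synthetic generator: what it emulates, and what it does not

`generateFundus()` renders: a dark circular field of view with radial
vignetting; a bright elliptical optic disc; two vein and two artery
arcades grown by recursive midpoint-displacement branching from the disc
(widths halve per generation; arteries are thinner by the artery:vein
ratio and carry a central reflex stripe); grade presets 0.75 / 0.62 /
0.50 / 0.40 / 0.40 for that ratio (monotone non-increasing, the
narrowing axis of the grading ladder); focal constrictions (40%-caliber
notches) on arteries from moderate up; six dark hemorrhage blobs from
severe up; five bright hard-exudate blobs, placed clear of vessels and
of each other, plus an enlarged blurred disc for malignant; additive
Gaussian noise (sd 0.02 by default) applied last, then clipping. The
default canvas is 300×250, the pipeline's working size; the minimum is
64×64, which the scaled-down studies use. Identical specs render
bit-identical samples, and the sample records what was actually drawn
(bifurcation and lesion counts) for bookkeeping tests.

The generator is a *fixture*, not a vascular model: no camera optics, no
illumination field, no inter-eye anatomical variation, no pathology
beyond the five-grade ladder. Tests passing on it demonstrate that the
pipeline's machinery is correct and self-consistent, not that it reaches
clinical performance on real fundus photographs — the study-scale
accuracies on public HR datasets are out of this package's reach by
construction.

`generateFeatureTable()` plants a known class structure in feature space:
unit-variance Gaussians whose class means are `class_shift` standard
deviations apart along grade-relevant axes, with the mean-width and AVR
features decreasing monotonically in severity. At `class_shift = 0` the
classes are indistinguishable, so classifier accuracy must fall to
chance (0.2) — the parameter-recovery tests assert both ends.

## Numerical choices and degenerate inputs

* Constant channels (zero variance) signal a typed degenerate-channel
  condition; the pipeline substitutes an identity gain with a warning.
* Histogram probabilities quantize to 256 levels with the top bin closed.
* Attention hidden size floors at 1; pyramid levels must not exceed the
  smaller image side (bin-degeneracy error).
* Max pooling drops odd trailing rows/columns; decoder paths crop or
  zero-pad to the skip's size, so odd geometries (e.g. 300×250) flow
  through the network.
* Ties: pooling argmax takes the first maximum; KNN votes break toward
  the smaller class index; the channel-selection cascade resolves ties
  into the value plane. All randomness passes through a seed-scoped RNG
  that restores the caller's state.

## Scaled-down study sizes

The test suite and the acceptance script run the package's own studies
at desk scale, chosen as the smallest sizes at which each property is
meaningful: segmentation trains on twenty 64×64 synthetic pairs for 30
epochs (depth 2, 8 base channels, Adam 1e-2) and is scored on five
held-out images — reaching ~0.96 training and ~0.94 held-out Dice —
and classifier recovery uses 100 samples per class with 10-fold CV. The
metric, attention and pooling oracles run on dozens of random small
instances each.

## Known limitations

* The enhancement chain is faithful to its defining formulas, including
  their non-standard denominators; it is not a general-purpose contrast
  enhancer and is not benchmarked against CLAHE-class methods.
* Artery/vein fallback labeling relies on rendering conventions
  (brighter/thinner arteries with reflex); on real images a trained
  classifier should be supplied instead.
* The segmentation network is intentionally small; it is sized for the
  synthetic corpus, not for state-of-the-art benchmark performance.
* `f1_paper` and the two-term Dice reproduce the pipeline's original
  formulation, kept for comparability; prefer the standard metrics for
  new work.
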