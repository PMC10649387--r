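---
title: "melascan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{melascan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melascan)
```

melascan is a toolkit for the classical melanoma-screening pipeline on
dermoscopy-like images: denoise, segment the lesion by maximum-entropy
thresholding, extract first-order/GLCM/GLSZM/geometric features, classify
benign vs malignant with an RBF-kernel SVM, and — on the deep-learning side —
verify and train a small convolutional network with Grad-CAM
interpretability. Every stage is exercisable end to end on seeded synthetic
lesions, so the package's behaviour is fully testable without any image
downloads. This vignette records the models, the tunable parameters, the
numerical conventions, and the design decisions, in that order of interest
to a methods reader.

## Image representation

Images are plain R matrices (grayscale) or H × W × 3 arrays (RGB) on the
8-bit scale [0, 255], row 1 at the top, indexed (row, column). Grayscale
conversion uses the ITU-R BT.601 luma weights (0.299, 0.587, 0.114),
rounded to integer levels — the de-facto standard for this conversion.
Resizing is bilinear; downscaling first applies a Gaussian blur matched to
the scale factor (σ = ½·√(s² − 1) for scale factor s) so that
high-frequency content does not alias.

## Denoising and image quality

Five filters are provided, all constant-preserving and range-safe:

| filter | default parameters | character |
|---|---|---|
| `median` | 3 × 3 window | impulse noise, edge-preserving |
| `gaussian` | σ = 1 | fast smoothing, blurs edges |
| `bilateral` | σ_spatial = 2, σ_range = 25, radius 3 | edge-preserving smoothing |
| `nlm` | h = 10, 3 × 3 patches, 7 × 7 search | patch self-similarity |
| `bm3d` | σ = 10, 8 × 8 blocks, groups ≤ 16, threshold 2.7σ | collaborative filtering |

The BM3D-style filter is the single-stage hard-threshold variant: groups of
similar 8 × 8 blocks are stacked, transformed with separable DCTs in all
three dimensions, hard-thresholded at 2.7σ (always keeping the DC
coefficient), inverted, and aggregated with weights inversely proportional
to the number of retained coefficients. A second Wiener stage would improve
it further and is out of scope.

Filter choice is scored against a reference image with four standard
metrics. MSE is the mean squared intensity error. PSNR is
10·log₁₀(255²/MSE) dB, infinite for identical images. SSIM is the
Wang–Bovik structural similarity with the standard constants
C₁ = (0.01·255)², C₂ = (0.03·255)² and an 11 × 11 Gaussian window
(σ = 1.5), mean-pooled; for identical inputs it is exactly 1 by
construction. UQI is the constant-free Q index averaged over 8 × 8 sliding
windows; windows with a zero denominator carry no correlatable structure
and are excluded from the average, and two constant images — where the
formula is 0/0 everywhere — are assigned 0.

Hair removal is DullRazor-style: a morphological black-hat (closing minus
image) under linear structuring elements of length 9 at four orientations,
computed on a 3 × 3-median-smoothed copy so pixel noise does not fire the
detector; responses above 10 intensity levels are flagged. Because hair is
at most a few pixels wide, flagged components that survive a 3 × 3 erosion
are too thick to be hair and are dropped — this keeps lesion-boundary
concavities (which the directional closings also fill) out of the hair
mask. The surviving mask is dilated by one pixel and restored by diffusion
inpainting (iterative 3 × 3 averaging of masked pixels, seeded from the
unmasked mean, to a 10⁻³ tolerance). On hair-free images the mean absolute
change is below one intensity level.

## Maximum-entropy segmentation

The lesion threshold maximises the Kapur two-class criterion: for a
candidate threshold t, the histogram is split into levels ≤ t and > t, each
class histogram is renormalised, and the criterion is the sum of the two
Shannon entropies (base 2, with 0·log 0 ≡ 0). All 256 candidates are
scanned; only candidates with two nonempty classes are admissible, and ties
are broken towards the smallest t. Constant images have no threshold and
raise an error.

Binarisation takes the *darker* side (levels ≤ t) as foreground, because
pigmented lesions are darker than the surrounding skin; of the two classes
this side necessarily has the lower mean intensity. Bright components
touching an image corner are removed (8-connectivity), as corner structures
in a dark-side mask are vignetting, not lesion. Morphological refinement
removes components below `min_area` (default 64 px, sized for 256 × 256
images), fills interior holes, and closes with a 5 × 5 disc; hole-filling
and closing are extensive, so refinement never erodes a retained component.

A known fragility, visible in the synthetic studies: when the background
histogram is wide and smooth, the Kapur criterion can prefer splitting the
background's bright tail over the lesion/skin valley (the mixture class
earns a between-mode entropy bonus). The downstream corner cleanup then
empties the mask. The pipeline flags and excludes such images rather than
failing; on the synthetic study conditions below this affects a minority of
seeds, and the median recovery remains high.

## Features

All features are computed over the masked lesion only.

* First-order: min/max gray level, mean, median, *population* standard
  deviation (the histogram-weighted variance form), coefficient of
  variation σ/µ (NaN sentinel when µ = 0), and histogram width — the 90th
  minus 10th percentile with linear interpolation (type-7 quantiles).
* GLCM: intensities are uniformly re-binned from [0, 255] to 32 levels
  (configurable); pairs at distance 1 along 0°, 45°, 90° and 135° are
  accumulated into one symmetric matrix (each pair counted in both
  directions), with both endpoints required in-mask. Features: inverse
  difference moment Σ p(i,j)/(1 + (i − j)²); sum average Σ k·p_{x+y}(k)
  with 1-based level indexing so k runs over 2..2N; difference entropy
  −Σ p_{x−y}(k)·log₂ p_{x−y}(k).
* GLSZM: zones are 8-connected components of equal binned level inside the
  mask; cell (i, j) counts zones of level i and size j, so
  Σ_{i,j} j·P(i,j) equals the masked pixel count — a conservation law the
  tests enforce. Features: gray-level variance Σ p·(i − µ)² with
  µ = Σ p·i, and zone-size entropy −Σ p·log₂(p + ε) with ε = 10⁻¹². The
  matrix is orientation-free, so these features are invariant to 90°
  rotations.
* Geometry: area is the pixel count of the largest 8-connected component.
  Perimeter is the length of the half-level contour polygon
  (marching-squares style) of that component after hole filling; the
  indicator is lightly smoothed (3 × 3 box) first so the contour
  interpolates the sub-pixel edge position. A hard 0/1 field puts every
  contour vertex at a pixel-edge midpoint and overestimates a disc's
  circumference by about 7%, while counting boundary pixel edges
  overestimates it by about 27%; the smoothed contour is accurate to about
  1% for disc radii ≥ 5.

The 13-feature schema (`feature_schema()`) carries per-class Gaussian
parameters (mean, sd) for benign and malignant lesions, used by the
synthetic feature generator and as a magnitude sanity check. Two caveats
are recorded here deliberately. First, the schema's zone-size entropy and
difference entropy constants are *negative*, while the definitions above
are nonnegative; the generator samples the constants as given, so for these
two features generated tables and extracted features are not directly
comparable in sign. Second, the schema lists marginal statistics only, so
the generator draws features independently; real lesion features are
correlated (area with perimeter, most obviously), and classifiers trained
on generated tables see an easier problem than real data.

## Classification and evaluation

The split is stratified per class, `round(0.7·n)` training rows per class,
reproducible under a seed. Features are z-scored with parameters fitted on
the training rows only (constant features get sd 1), then fit with an
RBF-kernel SVM at library defaults — deliberately no kernel or
hyperparameter search, matching the protocol the package models. Labels
are `benign`/`malignant`, with malignant as the positive class for
confusion counts.

Evaluation reports accuracy, sensitivity TP/(TP+FN), specificity
TN/(TN+FP), precision TP/(TP+FP) — all as percentages — and the F-measure
2·P·R/(P+R). Zero denominators return 0 with a warning. The per-class
report gives precision/recall/F1/support with each class in turn as
positive, stored at full precision and rounded to two decimals for display.

## CNN architectures and training

Architectures are declarative layer lists from which every intermediate
shape and parameter count is derived analytically: `same` convolutions
produce ⌈n/stride⌉, `valid` produce ⌊(n − k)/stride⌋ + 1, conv parameters
are k_h·k_w·C_in·C_out + C_out and dense parameters n_in·units + units.
The designed network is

rescale(1/255) → conv 3×3×32, stride 4, same → ReLU → maxpool 2 →
conv 5×5×64, stride 2, valid → ReLU → maxpool 2 → flatten →
dense 38 (ReLU) → dropout 0.2 → dense 3 (softmax),

which at a 224 × 224 × 3 input yields shapes 56×56×32 → 28×28×32 →
12×12×64 → 6×6×64 → 2304 → 38 → 3 and parameter counts 896, 51,264,
87,590, 117 (139,867 total). The two kernel/stride settings are the unique
small-integer configuration consistent with all of those shapes and counts
simultaneously, solved analytically before implementation. The reference
AlexNet, LeNet-5, and VGG-16 specs follow their canonical published
configurations with the classifier head replaced by three classes.

The training engine is authored in R for the modest networks this package
trains: im2col-based convolution with exact backpropagation (verified
against finite differences to ~10⁻⁹ relative error), max-pooling with
argmax routing, inverted-scaling dropout, softmax cross-entropy, and Adam
(β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸). The training recipe defaults to batch
size 32 and learning rate 10⁻⁴. All randomness — initialisation (He
normal), shuffling, dropout, augmentation — derives from one seed, making
runs bit-reproducible. Augmentation (optional, training split only)
applies random horizontal/vertical flips, integer translations up to 4 px,
and rotations up to ±15°. Gradients for Grad-CAM are taken on the target
class's *logit* (pre-softmax), pooled spatially into per-channel weights
over the last convolutional layer's post-ReLU activation maps; the heatmap
is the ReLU of the weighted sum, max-normalised unless identically zero.
Because the gradient is of a logit, adding a constant to all class scores
leaves the map unchanged.

## The synthetic generator

`make_lesion()` emulates a dermoscopic field at 256 × 256: a bright skin
background (mean 180, smooth low-frequency variation of sd 8) with an
embedded darker lesion — mean intensity 68 (benign) or 76 (malignant) — on
an ellipse whose radius is perturbed by a random sinusoidal series (modes
3–8; total relative amplitude 0.03 benign, 0.12 malignant), plus smooth
intra-lesion texture (sd 10), optional dark curved hair strokes, and
additive Gaussian pixel noise (sd 4). Lesion areas are drawn from the
schema's class statistics (benign 6727 ± 3150 px, malignant
13,010 ± 6649 px, clamped to the frame), with aspect ratios 0.85–1
(benign, rounder) and 0.55–0.9 (malignant, more eccentric). The `normal`
class is background only. Everything is reproducible per seed.

What the generator does *not* model: colour, vignetting, immersion-gel
bubbles and ruler artifacts, pigment networks, or realistic lesion texture.
Passing the recovery and separability tests therefore shows the pipeline's
machinery is correct and well-calibrated on idealised inputs; it does not
certify accuracy on real dermoscopy.

`make_feature_table()` samples the schema's class-conditional Gaussians
independently per feature. Only hard physical bounds are clipped — gray
levels to [0, 255], area and perimeter to be positive. The coefficient of
variation, gray-level variance and the two entropies are left unclipped:
the malignant coefficient-of-variation statistics (0.00204 ± 0.016354)
place substantial mass below zero, and clipping would shift the sample
means off the schema parameters that the sampling tests verify (means
within 3 standard errors at n = 1000).

## Study conditions used by the test suite

The property suite runs at sizes chosen to finish in minutes on one CPU
while keeping the statistics meaningful, and these sizes are the package's
documented study conditions: the Kapur threshold is checked against an
exhaustive 256-candidate oracle on 100 random 16 × 16 images; the GLCM and
GLSZM builders against brute-force pair-enumeration and flood-fill oracles
on 200 random instances up to 6 × 6 with up to 4 levels; segmentation
recovery on 50 seeded hairless lesions at 256 × 256 (median IoU ≥ 0.8);
SVM separability on 20 seeded tables of 100 rows per class (mean held-out
accuracy ≥ 0.75); and CNN learnability on 180 synthetic images (60 per
class, 5 epochs, batch 32, learning rate 10⁻⁴), requiring training
accuracy strictly above the 1/3 chance level.

## Known limitations

* Kapur thresholding can lock onto the background's bright tail on images
  with a wide, smooth background histogram (discussed above).
* The BM3D variant is single-stage; no Wiener refinement.
* Feature sampling ignores correlations; synthetic separability overstates
  real-world separability.
* The CNN engine is single-threaded R and intended for small networks and
  datasets; the reference VGG-16/AlexNet specs are for architecture
  arithmetic, not training at scale.
* The per-image threshold/entropy table, the class feature statistics, and
  published training accuracies of the reference corpus cannot be
  reproduced without that corpus; the test suite substitutes the seeded
  synthetic studies above.
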