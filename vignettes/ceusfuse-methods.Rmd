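---
title: "Multimodal ultrasound fusion for HCC recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal ultrasound fusion for HCC recognition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Hepatocellular carcinoma (HCC) typically develops on cirrhotic liver
parenchyma (PAR) and can be difficult to distinguish from it by eye in
ultrasound. Two co-registered modalities carry complementary information:
B-mode grayscale imaging reflects tissue echogenicity and texture (HCC tends
to be heterogeneous, with interleaving necrosis, fibrosis and actively
growing tissue), while contrast-enhanced ultrasound (CEUS) highlights
vascularity — HCC is hyper-enhanced during the arterial phase. `ceusfuse`
implements a complete, testable pipeline for 2-class HCC-vs-PAR patch
classification from such image pairs, with the two modalities combined at
three different points of the processing chain:

* **feature-level fusion** — the two images are combined pixelwise
  (arithmetic mean, CEUS-weighted mean $(2c + b)/3$, or rescaled
  multiplication) and a single CNN classifies the fused patch;
* **classifier-level fusion** — two CNN branches are trained separately per
  modality, their tap-layer feature vectors are fused (concatenation,
  elementwise means/product after PCA dimension matching, or concatenation
  followed by kernel PCA) and a shared supervised head (softmax,
  feedforward network, or SVM) classifies the fused vector;
* **decision-level fusion** — two fully separate classifiers emit class
  probabilities which are combined by an arithmetic or CEUS-weighted mean.

A conventional baseline computes a 41-feature texture descriptor per patch,
selects relevant features (CFS with best-first search, gain-ratio ranking
with a 0.15 cutoff, union rule) and feeds them to standard classifiers
(polynomial SVM, MLP, AdaBoost over trees, random forest).

Everything is driven by a seeded synthetic generator of paired patches and
annotated frames, so the pipeline runs and is tested end to end without any
patient data.

# Patch preparation

Tumors are delineated by closed polygons in VIA-style JSON annotations.
`extract_patches()` centers a 250×250 search window on the polygon's vertex
centroid and tiles it with non-overlapping 51×51 candidates (stride 51,
anchored at the window's top-left corner). A candidate's *intersection* is
the number of its pixel centers inside the polygon (ray casting; points on
an edge count as inside). The labeling rule is strict: intersection
$= 51^2 = 2601$ → HCC; intersection $= 0$ → PAR; anything in between is
discarded. Discarding partial candidates keeps both classes pure; the rule
defines only the two extreme cases, and mixed patches would dilute either
class. The search window is clipped at frame borders and only fully
in-bounds candidates are kept. Offline augmentation adds the three quarter
turns of every patch (labels preserved; a group-aware splitting option
keeps rotated copies on one side of a train/test split). Train-time
augmentation applies random horizontal/vertical flips and integer
translations of up to 5 px with reflected padding, identically to both
channels.

# Texture descriptor (41 features per channel)

The descriptor concatenates, per channel:

| block | count |
|---|---|
| Haralick statistics of the order-2 co-occurrence matrix | 6 |
| Haralick statistics of the order-3 generalized co-occurrence matrix | 6 |
| edge frequency, edge contrast, edge orientation variability | 3 |
| autocorrelation index (lag-1) | 1 |
| Hurst fractal index | 1 |
| Haar wavelet detail entropies (2 levels) | 2 |
| Laws texture-energy statistics (11 mask classes × density, frequency) | 22 |

The generalized co-occurrence matrix (GCM) counts pixel $n$-tuples in fixed
spatial configurations over quantized gray levels. Order 2 uses 256 levels
and the eight unit displacements at 45° multiples; order 3 uses 64 levels
(sparse accumulation — a dense 256³ cube would be memory-prohibitive) with
four collinear configurations (current pixel central) and four right-angle
configurations (current pixel at the vertex). For every configuration both
the displacement set and its point reflection are counted, which makes each
matrix symmetric under tuple reversal; a literal reading of the sign
constraints would also admit degenerate tuples with coincident pixels,
which we exclude. Haralick features (energy, entropy, contrast, local
homogeneity, correlation, variance) are computed per configuration on the
probability-normalized matrix and arithmetically averaged over the family,
which makes the order-2 block exactly invariant under quarter-turn
rotations. Order-3 generalizations use pairwise index differences:
contrast $\sum p\,[(f_1-f_2)^2 + (f_2-f_3)^2]/2$, local homogeneity
$\sum p / (1 + [(f_1-f_2)^2+(f_2-f_3)^2]/2)$, correlation as the mean of
the three two-index correlations, and variance around the grand marginal
mean. When a marginal standard deviation vanishes the correlation term is 0
by convention; a constant patch therefore yields energy 1, entropy 0,
contrast 0, homogeneity 1.

The classical block: Sobel gradients with reflected borders define edge
pixels (magnitude above the patch mean magnitude); edge orientation
variability is the circular variance of gradient angles over edge pixels,
and an edge-free patch returns zeros. Laws maps use the standard L5/E5/S5/
W5/R5 outer-product masks; we retain the 11 zero-sum classes E5E5, S5S5,
R5R5, W5W5, L5E5, L5S5, L5R5, L5W5, E5S5, E5R5, E5W5 (symmetric pairs
averaged in absolute response) and report per class the *density* (fraction
of pixels with energy above the map mean) and *frequency* (mean energy);
dropping L5L5 (not zero-sum) and the three highest-order cross terms gives
the documented 41-feature total. The Hurst index is the log-log slope of
mean absolute intensity increments over lags 1–8 (a fractional-Brownian-
surface estimator), clipped to [0, 1] with 0 for constant patches. Wavelet
entropies are Shannon entropies of the energy-normalized pooled detail
subbands of an orthonormal 2-level Haar transform (odd trailing rows/
columns cropped per level). The autocorrelation index averages the
normalized lag-(1,0) and lag-(0,1) autocorrelations and returns 1 for
constant patches. The exact composition of the 41 features, the Laws
statistics, the edge-threshold rule and the Hurst estimator are design
choices of this package (documented defaults, configurable); no global
illumination normalization is applied.

# Dimensionality reduction

`fit_kpca()` eigen-decomposes the double-centered kernel matrix and scales
eigenvectors so that projections are $y_k(x) = \sum_j \alpha_{kj}
\tilde K(x, x_j)$ with training-score variance $\lambda_k/n$. Double
centering is essential: without feature-space mean removal the linear
kernel would *not* reproduce classical PCA, which is both a correctness
check and a contract (the linear case must equal PCA scores up to
per-component sign). Out-of-sample rows are centered with the training
terms; negative numerical eigenvalue residue is clipped at zero and those
components dropped. Kernels: linear, polynomial $(x\cdot y + 1)^3$, and
Gaussian with the median-pairwise-distance bandwidth heuristic. The
eigenproblem is always the $n \times n$ kernel matrix (training size),
never the feature dimension, so concatenated CNN feature vectors of several
thousand dimensions are unproblematic. PCA dimension matching for
elementwise vector fusion is fitted on training features only and applied
unchanged to validation/test features to avoid leakage. The retained KPCA
dimension at classifier-level fusion defaults to 128 (a round figure
comfortably below typical desk-scale training sizes; configurable).

# CNN branches

The package contains a compact CNN engine (im2col convolution via BLAS,
max/average pooling with optional ceil-mode asymmetric padding, global
average pooling, fully connected layers, channel concatenation, elementwise
addition, softmax) with full backpropagation and SGD-with-momentum, plus
shape-faithful builders for SqueezeNet (v1.1 layout), GoogLeNet, a
GoogLeNet variant with residual shortcuts past the last three inception
modules, ResNet-18, VGG-16 and DenseNet-201, and a 3-block `tiny` network
(conv 5×5×8 → pool → conv 3×3×16 → pool → conv 3×3×64 → global average
pool → fc) with native input 51 and a 64-length tap. Batch normalization is
omitted (it does not affect layer shapes, and the engine trains only
desk-scale networks); dropout layers are identity at inference, so the
VGG-16 `drop7` tap is the second 4096-wide fully connected output. Tap
lengths are contractual and tested: 392/394 (SqueezeNet single/dual tap),
1024 (GoogLeNet), 528 (variant), 512 (ResNet-18), 4096 (VGG-16), 1920
(DenseNet-201), 64 (tiny). 51×51 grayscale patches are bilinearly resized
to each architecture's native input (227 or 224) and replicated to three
channels; inputs are scaled to $[-0.5, 0.5]$ by a fixed affine map so that
per-patch gain differences (a class cue) survive.

The GoogLeNet variant deserves a note: its published description is loose,
so the concrete wiring here — tap after the 528-wide inception module, the
three subsequent inception outputs each global-average-pooled, linearly
mapped to the 2-class width and summed with the main classifier output —
is flagged experimental.

`train_config()` defaults to the fine-tuning schedule appropriate for
pretrained backbones: SGDM with learning rate 0.0002, momentum 0.1,
minibatch 25, 70 epochs, train-time augmentation on. Pretrained ImageNet
weights are not bundled (no download is performed; `pretrained = TRUE`
errors), so the package's own experiments train the `tiny` backbone from
random He initialization, for which that learning rate is far too small;
the desk-scale schedule used throughout the tests is learning rate 0.02,
momentum 0.1, minibatch 25, 40 epochs. Training is deterministic given the
seed on a fixed platform (single-threaded BLAS assumed; cross-platform
bitwise identity is not promised).

# Evaluation

Splits are stratified to within one patch: 60/15/25
(train/validation/test) for CNN experiments and 75/25 for the conventional
baseline, with an optional group constraint that keeps a source patch and
its augmented copies together (augmented copies always follow their source
patch). The positive class is HCC everywhere; accuracy, sensitivity and
specificity come from the confusion matrix, the decision threshold is 0.5
with exact ties assigned to HCC, and the ROC sweeps thresholds over the
unique scores with trapezoidal AUC (equal to the tie-corrected normalized
Mann–Whitney U, and cross-checked against an independent implementation in
the tests). `run_experiment_grid()` shares one split and one set of trained
branches across all requested configurations, so decision-level fusion
reuses the two single-modality branches rather than retraining them.

# The synthetic generator

The generator emulates the statistical structure the pipeline assumes,
not ultrasound physics. Each patch pair is built from smoothed Gaussian
random fields: white noise convolved with an L2-normalized separable
Gaussian kernel whose bandwidth is the class correlation length, scaled by
the class field standard deviation around the class mean. The kernel
normalization (rather than per-patch restandardization) keeps natural
sampling variability in the patch statistics. The CEUS field correlates
with the B-mode field at `cross_channel_rho`; the HCC CEUS channel adds a
constant arterial-phase enhancement offset; HCC pairs receive, with
probability `necrosis_fraction`, a union of 2–4 dark disks (radius
U(3, 8) px, 60 gray levels below the class mean, both channels). Each
channel of each pair is multiplied by an independent per-patch gain
$1 + N(0, \sigma_g)$ — the synthetic counterpart of between-acquisition
gain/TGC variation, and the mechanism that keeps the two classes
overlapping: without it, patch-mean statistics over 2601 pixels concentrate
so tightly that any classifier saturates. Everything is clipped to 8-bit
gray levels at the end.

Defaults (frozen after calibrating single-modality `tiny` accuracy into the
intended 0.8–0.9 band, leaving headroom for fusion): B-mode means 130 (HCC)
/ 100 (PAR), CEUS offset +25, correlation lengths 3.5 / 1.8 px, field
standard deviations 20 / 12, necrosis fraction 0.3, cross-channel
correlation 0.6, gain standard deviations 0.13 (B-mode) / 0.15 (CEUS).
The two channels then disagree on different patches (independent gains),
which is exactly the complementarity that decision- and classifier-level
fusion exploit. Whole annotated frames place a star-shaped 12-vertex tumor
polygon (radius roughly 80–110 px) of HCC texture on a PAR background.

What the generator does *not* model — speckle statistics, attenuation with
depth, contrast-agent kinetics over time, anatomical context, annotation
error — bounds what passing tests show: they demonstrate that the
pipeline's machinery is correct and that its qualitative orderings hold
under the stated generative assumptions, not that any accuracy level
transfers to clinical data.

# Numerical choices and degenerate inputs

* 8-bit clipping after every image-level operation; image fusion rounds to
  integers, vector fusion stays in floating point.
* Multiplication fusion rescales by the fixed factor 255
  (`round(b·c/255)`) rather than per-image min–max: deterministic,
  monotone, and well defined for constant images.
* Quantization is `floor(v · n_levels / 256)`; patches smaller than a
  displacement extent yield an empty GCM (total 0), which is an error only
  when features are requested from it.
* Equal-frequency 10-bin discretization precedes all entropy-based
  selection; CFS uses symmetric uncertainty; all ties break toward the
  lowest feature index; best-first search stops after 5 expansions without
  improvement.
* Degenerate min–max normalization in `activation_map()` maps constant
  vectors to the all-zero image; zero-variance patches give Hurst 0 and
  autocorrelation 1 by convention.
* Seeds: every stochastic step (generation, splitting, shuffling,
  augmentation, head fitting) takes an explicit seed and restores the
  caller's RNG state.

# Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen for a single-CPU
desk run: fusion-ordering experiments use 100 patches per class over 5
seeds with the 40-epoch tiny schedule; null-calibration runs use 120–150
patches per class with shuffled labels (10 selection-side, 5 CNN-side
repetitions); oracle equivalences use 100 random 8×8 patches; feature
fuzzing uses 40 heterogeneous patches. The backbone registry check builds
all seven architectures and runs one forward pass each.

# Known limitations

* The CNN engine is deliberately minimal: no batch normalization, no
  dropout at train time, no GPU; fine-tuning the large backbones is
  possible in principle but not practical at this scale, and pretrained
  weights are not available offline.
* The 41-feature composition is this package's documented reconstruction
  of a conventional descriptor; other enumerations of the same families
  are plausible.
* The MLP baseline trains by the optimizer of its underlying
  implementation (BFGS) rather than momentum SGD; epoch count is honored,
  momentum/learning-rate settings are recorded but not applicable.
* Synthetic calibration targets qualitative orderings; absolute accuracies
  on the generator say nothing about clinical performance.
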