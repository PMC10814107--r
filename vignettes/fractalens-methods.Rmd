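---
title: "Multiscale fractal quantification and ensemble classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale fractal quantification and ensemble classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalens)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical conventions adopted where the
underlying formulations leave room, and what the synthetic test bed does and
does not demonstrate.

## The gliding-box probability matrix

All handcrafted features derive from one primitive: an r×r box slides one
pixel at a time across the RGB image (box sides odd, so a central pixel
exists). A pixel *p* in the box is a *pore* when its Chebyshev distance to
the central pixel, taken over the 5-dimensional representation
(x, y, R, G, B), is at most *r*. Spatial offsets within the box never exceed
(r−1)/2 < r, so the criterion reduces to max(|ΔR|, |ΔG|, |ΔB|) ≤ r with
channels in native 0–255 units. Color tolerance therefore grows with scale —
deliberate: coarse scales should merge mild stain variation, fine scales
should not. The pore count *m* per box position defines N(m, r), normalized
by the number of box positions n_r = (width−r+1)(height−r+1) into P(m, r).

The central pixel always satisfies d = 0, so m ≥ 1 in every box; this pins
the invariants FD(r) ≤ 1 and C(r) ≥ 1 below.

**Scale ladder.** r runs over 3, 5, …, 41 (20 scales). Images must be at
least 41×41; smaller inputs are rejected naming the limiting scale.
Grayscale inputs are promoted to RGB by channel replication.

## Curves and descriptors

Per scale the package computes:

- **Fractal dimension** FD(r) = Σ_m P(m, r)/m, the expected number of boxes
  needed to cover the image (Voss box-count estimator). The mass-moment
  variant Σ_m P(m, r)·m is available as `fd_variant = "mass"`; the box-count
  reading is the default because FD is defined as a covering estimate, which
  only the 1/m form yields (a delta distribution at full occupancy then
  gives FD = 1/r², the covering intuition).
- **Lacunarity** L(r) = (μ₂ − μ²)/μ², the normalized variance of the box
  mass distribution. L = 0 exactly when the distribution is degenerate;
  μ = 0 cannot occur since m ≥ 1.
- **Percolation curves** from Hoshen–Kopelman union-find labeling of each
  box's pore mask: C(r) the mean cluster count per box; Q(r) the mean
  largest-cluster size, normalized by r² to a coverage ratio; P(r) the
  fraction of boxes whose pore fraction Ω/r² reaches the site-percolation
  threshold 0.59275.

Q(r) is reported as a coverage ratio (scale-free, comparable across r) by
default; the absolute-pixel variant is available as
`q_normalization = "absolute"` since the raw-average formulation is equally
defensible. Cluster connectivity defaults to 4-neighbor adjacency (the
classical Hoshen–Kopelman setting) and can be set to 8.

Each of the L, C, Q, P curves is reduced to four scalars over the interval
(a, b) = (1, 20):

- area A(a,b) = (b−a)/(2N) Σ (f(xₙ) + f(xₙ₊₁)), a trapezoid sum;
- skewness, the standardized third moment of the curve values, with the 0/0
  case of a constant curve defined as 0;
- area ratio R = A(⌊b/2⌋+1, b) / A(a, ⌊b/2⌋); a zero denominator is encoded
  as 0 and flagged `r_defined = FALSE`;
- the curve maximum (one value per curve — the value f(x), not its
  argument, so the descriptor block stays at 16 = 4 curves × 4 scalars).

The FD curve contributes no scalar descriptors. The fixed 116-value layout
is: FD (1–20), L (21–40), C (41–60), Q (61–80), P (81–100), then
(L, C, Q, P) × (area, skewness, area ratio, max) (101–116).

## Explanation representations

Grad-CAM and LIME images are quantified with the same 116-feature extractor,
so each backend contributes two extra 116-value sources.

**Grad-CAM** reads activations and gradients of the backend's last exposed
convolutional layer for the *predicted* class (not the true label), weights
each channel map by its mean gradient, sums, applies ReLU, upsamples
bilinearly to the image size and min-max scales to [0, 1]. A constant map is
valid: an everywhere-nonpositive sum renders as colormap(0). The quantified
image is the bare heatmap through a fixed perceptual colormap (inferno);
an alpha overlay is available by configuration, and the rendering choice is
recorded in the representation's provenance.

**LIME** segments the image with quick-shift (mode seeking on joint
color/position features; defaults ratio 1, kernel size 2, max link distance
6 — chosen to yield on the order of tens of superpixels on 64×64 textures,
and recorded per run), draws 1000 seeded on/off perturbations of the
superpixels, fudges hidden superpixels to their mean color for model input,
and fits a ridge (λ = 1) linear surrogate weighted by exp(−d²/0.25²) with
*d* the cosine distance from the unperturbed mask. The five top-scoring
superpixels keep their original pixels; everything else is black in the
output representation. The perturbation seed is mandatory — an unseeded
explanation would silently break feature-table reproducibility downstream.

## Deep embeddings and fine-tuning

Five architectures contribute embeddings: DenseNet-121 (normalization layer
after the last dense block, 1024), EfficientNet-b2 / Inception-V3 /
ResNet-50 (final average pooling, 1408 / 2048 / 2048) and VGG-19 (last
fully connected layer before the output, 4096). No pretrained weights ship
with the package; a weightless real backend raises "backend unavailable"
rather than silently using random weights, and the deterministic mock
backend stands in for all tests and examples.

Fine-tuning is transfer learning on the embedding: the output head is
replaced to match the dataset's classes and trained with full-batch SGD
(momentum 0.9) under cross-entropy for 10 epochs, learning rate
0.01 · 0.75^⌊e/2⌋ with 0-based epochs (decays at epochs 2, 4, …). Training
runs per fold of a 10-fold plan and the head with the highest held-out
accuracy is kept, ties to the earliest fold.

## Selection, classification, comparison

ReliefF (all instances; 10 nearest hits/misses per class, clamped to class
size; Manhattan distance on range-normalized features; miss terms weighted
by P(c)/(1−P(class))) ranks features *inside each training fold only* — the
leakage test in the suite verifies that corrupting held-out labels never
changes a fold's selected subsets. Subset sizes 5, 10, 15, 20, 25 are
evaluated; ties in the ranking break to the lower feature index.

The classifier ensemble averages per-class probabilities of four algorithms
run at library defaults — SVM (RBF, Platt-calibrated probabilities), naive
Bayes, random forest (100 trees), 5-nearest neighbors — and assigns the
argmax, ties to the lowest class index. Accuracy is (TP+TN)/total, F1 is
macro-averaged. Solutions rank by mean accuracy, then fewest descriptors,
then name.

Categories of compositions are compared with the Friedman test on the
categories × datasets accuracy matrix: within-dataset ranks (1 = best,
mid-ranks on ties), average rank per category, chi-square statistic with
k−1 degrees of freedom. The package computes ranks and statistic directly;
the suite cross-checks against `stats::friedman.test`. No pairwise post-hoc
is run by default since post-hoc conventions vary; the omnibus statistic
and average ranks are the verifiable quantities.

## Synthetic test bed

`texture_spec()` defaults define the study conditions: two classes of
64×64 images, thresholded Gaussian-smoothed noise fields in an H&E-like
palette (bluish-purple blobs on a pinkish base), differing in blob
correlation length (1.5 vs 4 px) and density (0.35 vs 0.45), channel noise
sd 12. Blob fields were chosen because their lacunarity and percolation
curves vary monotonically with correlation length, so the fractal features
are class-informative by construction. The mock backend produces embeddings
of each architecture's exact dimension as a seeded random projection of a
pooled image summary scaled by a `separation` effect size plus image-keyed
pseudo-noise; at separation 0 the embeddings carry no class information.

What passing tests show: the implementation computes the documented
quantities exactly (closed forms, oracles), keeps folds leak-free, and
recovers planted signal while staying at chance on null signal. What they
do not show: performance on real H&E images — real stain statistics, nuclei
morphology and inter-patient variation are outside the generator's scope,
and published accuracies on external histology collections depend on
GPU-fine-tuned CNN embeddings that the mock does not emulate.

## Numerical choices and problem sizes

- Probability mass is validated to 1e-9 per scale; ensemble probability
  rows are renormalized before averaging and validated to 1e-6 on input.
- The permutation benchmark in the acceptance script uses 30 images per
  class, one subset size (5) and 99 label permutations — sizes at which the
  null's 99th percentile is stable yet the whole run stays within a few
  minutes on one CPU.
- Chance-level controls run at 200 samples: the mean CV accuracy of a
  null pipeline has slightly super-binomial spread (CV predictions within a
  fold share one trained model and one selected subset), and at 200 samples
  the measured design effect is small enough for the 99% binomial band to
  cover comfortably.
- Zero-variance training columns are dropped before classifier fitting — a
  selected subset can be entirely constant under label permutation, where
  ReliefF's zero weight for constants outranks the negative weights of real
  features; in that fully degenerate case the ensemble returns the training
  class priors.
- Box sides must be odd and ≥ 3; even `r` is rejected rather than rounded.
- Curve-descriptor intervals use integer halves (1–10 / 11–20 at N = 20).

## Known limitations

- No real CNN backend ships; plugging one in requires implementing the
  backend protocol (`embed`, `predict_probabilities`,
  `layer_activations_and_gradients`).
- The gliding-box scan is exhaustive (every box position); large slides are
  quantified in O(area · r² · #scales) time. Tiling is the practical route
  for whole-slide images.
- Multiclass operation is implemented throughout (n-class-safe soft voting
  and macro F1) but exercised only up to the two-class designs described
  here.
- ReliefF assumes numeric features; categorical descriptors would need a
  different diff function.
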