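---
title: "Methods: the CNN-SVM cascade for brain tumor segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CNN-SVM cascade for brain tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadeSeg)
```

## The problem and the model

Gliomas are imaged with four MRI sequences (T1, post-contrast T1, T2,
FLAIR) whose contrasts highlight different tumor tissues: FLAIR is bright
over peritumoral edema, T1CE over the enhancing tumor core. `cascadeSeg`
segments the *whole tumor* (the union of the edema, necrotic/non-enhancing
core and enhancing core labels) as a single foreground class, pixel by
pixel, with a three-stage cascade:

1. **Presegmentation.** A small LeNet-style convolutional network
   classifies the square intensity patch centered on every pixel
   (alternating valid convolutions and 2×2 downsampling, one fully
   connected layer, softmax output; ReLU $f(x)=\max(0,x)$ or softplus
   $f(x)=\log(1+e^x)$ activations).
2. **ROI-restricted SVM refinement.** The current segmentation is dilated
   by a Euclidean disc into a region of interest (ROI). Inside it, a
   bagged ensemble of RBF-kernel support vector machines re-classifies
   each pixel from a compact feature vector: per modality the pixel's
   grayscale value, the mean and the median of its $w \times w$
   neighborhood, plus the current segmentation label at the pixel. The
   kernel is $k(u,v) = \exp(-\lVert u-v \rVert^2 / 2\sigma^2)$ with
   penalty $C$; binary members aggregate by the sign of the mean decision
   value (an exact zero counts as tumor).
3. **Iteration.** The network then re-scores the ROI and its argmax
   overrides the SVM label wherever its maximum class probability reaches
   a confidence threshold; pixels outside the ROI are never modified. The
   ROI-SVM-CNN pass repeats until the fraction of pixels changing falls
   below a tolerance or an iteration cap is reached.

Quality is measured with the standard pixel-overlap indices derived from
TP/FP/TN/FN tallies: $DSC = 2TP/(FP + 2TP + FN)$,
$Sens = TP/(TP+FN)$, $Spec = TN/(TN+FP)$, averaged unweighted over cases,
and method comparisons are summarized as relative percent change
($100\,(new-baseline)/baseline$, one decimal).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `feature@window` | 5 px | side of the square neighborhood for the mean/median features (odd) |
| `svm@sigma` | 0.1 | RBF kernel width on the [0, 1]-rescaled feature scale |
| `svm@C` | 1000 | soft-margin penalty |
| `svm@nMembers` | 5 | bagged ensemble size |
| `svm@subsample` | 0.5 | per-member bootstrap fraction (1 = use every row once) |
| `svm@maxTrainPixels` | 5000 | per-member row cap (kernel fits are quadratic in rows) |
| `cnn@patchSize` | 17 px | patch side seen by the network |
| `cnn@convChannels` | 8, 16 | channels of the two 3×3 convolution layers |
| `cnn@epochs` / `batchSize` / `learningRate` | 6 / 128 / 0.01 | SGD budget (momentum 0.9) |
| `roiDilation` | 3 px | Euclidean-disc radius of the refinement ROI |
| `maxIterations` | 2 | refinement passes |
| `convergenceTol` | 0.001 | whole-image pixel-change fraction that stops iterating |
| `cnnVetoThreshold` | 0.9 | CNN confidence needed to override the SVM inside the ROI |

## Design choices where the design was open

* **What the CNN consumes.** The network sees raw multimodal intensity
  patches rather than the 3-feature vector: convolving a per-pixel scalar
  triplet is vacuous, while the compact triplet-plus-label vector is
  exactly what a kernel SVM handles well. The triplet is therefore
  reserved for the refinement stage.
* **"Integrated" SVM = bagging.** The ensemble is read as bagged members
  over bootstrap pixel subsamples aggregated by mean decision value — the
  minimal interpretation that also keeps $\sigma = 0.1$, $C = 1000$
  kernel fits tractable on subsampled pixel sets. With one member and a
  full sample the ensemble provably collapses to a single SVM fit.
* **SVM feature scale.** Each feature column is rescaled to $[0, 1]$
  (min-max) before the kernel, and the transform is stored with the model
  and replayed at prediction. A width of $\sigma = 0.1$ is only a
  meaningful bandwidth on such a compact scale; on z-scored columns the
  squared distances concentrate around twice the dimension, every kernel
  value vanishes and the decision degenerates to its intercept.
* **Where the SVM trains.** Refinement rows are drawn from the dilated
  presegmentation ROI of the training cases — the distribution the stage
  sees at test time — pooled over cases and capped, with ground truth as
  the target. The ensemble is trained once on the training split (a
  per-test-image retrain is not used).
* **Fusion rule.** Within the ROI the SVM label overwrites the map, then
  the network's argmax overrides only where its maximum class probability
  is at least 0.9. The confidence-gated veto is explicit, testable and
  configurable.
* **Intensity standardization** z-scores the nonzero (brain) pixels with
  the population standard deviation, so a two-valued image maps exactly to
  $-1/+1$; exact zeros (the stripped background) stay zero. The operation
  is idempotent.
* **Borders** use reflect padding with the edge sample duplicated, both
  for the window features and for patch extraction, so no artificial
  zeros leak into edge features. The median of an even count (impossible
  with odd windows, kept for generality) is the lower middle order
  statistic.
* **Ties** in the softmax argmax break toward the lower class index;
  3-D volumes are processed slice by slice (the common desk-scale
  baseline) and restacked; convergence is measured on whole-image maps.

## The phantom generator

Real multimodal cohorts with expert truth are large and access-controlled,
so the package generates seeded synthetic gliomas: a concentric-ellipsoid
tumor (necrotic core ⊂ enhancing core ⊂ non-enhancing core ⊂ edema,
strictly nested semi-axes) inside a smooth brain ellipse, rendered per
modality from a tissue-mean table on a unit background scale (background
1.0; e.g. edema 1.8 on FLAIR, enhancing core 1.8 on T1CE, necrotic core
0.5 on T1CE), then multiplied by a smooth bias field
($1 + a\,e^{-d^2/2}$, a seeded broad Gaussian bump with peak relative
deviation $a$) and degraded with additive Gaussian noise inside the brain.
Voxels outside the brain ellipse are exactly zero, as in skull-stripped
MRI. Cohorts jitter the tumor center (±10% of the grid) and the
subregion semi-axes (×[0.85, 1.2], resampled if nesting would break).

The phantom emulates the label semantics, the modality-dependent contrast,
noise and intensity inhomogeneity of clinical data. It does **not**
emulate anatomy, Rician noise physics, tumor mass effect, or
inter-scanner variability — so passing phantom tests demonstrates that the
pipeline's mechanics and learning behavior are correct at desk scale, not
that clinical accuracy transfers.

## Problem sizes and numerical notes

The packaged experiments use 64×64 2-D four-modality cases: an
eight-case cohort with noise sd 0.4 and bias amplitude 0.2, six cases for
training and two held out; the full cascade trains and evaluates in well
under a minute on one CPU. Unit tests exercise mechanics on a 32×32
fixture. All randomness (phantom sampling, pixel subsampling, weight
initialization, minibatch shuffling, fold assignment) flows from explicit
integer seeds, and two runs with one seed are bitwise identical. Degenerate
inputs are defined, not accidental: empty prediction and truth give DSC 1;
sensitivity/specificity with an empty denominator are reported `NA` and
excluded (with a log) from cohort means; a constant nonzero image is
centered but not scaled, with a warning.

## Known limitations

* Whole-tumor (binary) segmentation is the validated path; multi-class
  subregion labels are supported mechanically but not tuned.
* The slice-wise processing unit ignores through-plane context.
* The network is intentionally small; it is a pixel-patch classifier, not
  an encoder-decoder, and inference cost grows with the pixel count.
* Registration, skull stripping and bias-field *correction* are out of
  scope; the phantom's bias field is used to stress robustness instead.
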