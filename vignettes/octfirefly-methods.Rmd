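---
title: "Methods: hybrid OCT classification with binary firefly feature selection"
author: "octfirefly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid OCT classification with binary firefly feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The pipeline

`octfirefly` classifies retinal disease in grayscale OCT B-scans with a
hybrid of classic image analysis and machine learning, organised as five
stages:

1. **Retinal-layer masking** — bilateral filter, CLAHE, Otsu threshold,
   morphological opening-then-closing, and multiplication of the resulting
   binary mask with the *original* image. The filtered and equalized image
   exists only to build the mask; classification features always come from
   masked original intensities.
2. **Hybrid feature extraction** — gray-level co-occurrence (GLCM)
   statistics, a histogram-of-oriented-gradients (HOG) descriptor, and
   headless convolutional embeddings, concatenated with per-feature
   provenance names (`glcm:`, `hog:`, backbone name).
3. **Wrapper feature selection** — a binary firefly algorithm scored by the
   accuracy of a K-nearest-neighbour classifier on the candidate subset.
4. **Hierarchical binary classification** — abnormal vs normal, then AMD vs
   DME among the abnormal, then CNV vs DRUSEN among the AMD cases, each
   stage with its own selection, standardization and binary classifier.
5. **Reporting** — per-stage confusion matrices, accuracy, class-by-class
   precision/recall/F1, their unweighted mean across stages, and an
   optional composed-cascade leaf accuracy.

Every quantity in this document is computed by the package's tests or by
`scripts/acceptance.R`; nothing here is an external benchmark claim.

## The phantom generator

Real OCT datasets are large external downloads, so the package ships a
seeded generator of OCT-like phantoms that drive every test. A phantom is
built on the 8-bit scale as:

* a dark background (mean 10) standing in for the vitreous and the
  sub-choroidal space;
* a banded bright region spanning rows 30 %–78 % of the image height, with
  `n_layers` horizontal bands; inner bands alternate between intensities
  110 and 160 and the bottom band — the RPE analogue — is brightest at 200.
  The inner-band spread is deliberately small relative to the
  background-to-retina gap so that the dominant bimodality an automatic
  threshold sees is background vs retina, not band vs band;
* class-specific lesions:
  * **DRUSEN**: 2–4 narrow smooth Gaussian bumps (width 3–6 px, amplitude
    5–10 px) lifting the RPE top boundary, the "little bump" morphology of
    drusen deposits;
  * **CNV**: one broad dome-like RPE elevation (width 10–16 px) plus 2–3
    small dark pockets hugging the RPE from above, emulating a neovascular
    membrane with sub-retinal fluid;
  * **DME**: 1–2 large round dark pockets (semi-axes 6–14 px) in the middle
    of the band region, emulating intraretinal cystoid fluid;
  * **NORMAL**: undeformed bands;
* additive i.i.d. Gaussian noise of standard deviation `noise_sigma`
  (default 5), clipped to [0, 255].

Pocket interiors sit at intensity 30 — dark relative to the bands but above
the background mean — so the ground-truth retina mask (every pixel whose
noiseless intensity exceeds the background level) remains the full band
region regardless of lesions. Lesion draws consume the RNG before the noise
draw and band geometry is deterministic, so a NORMAL and a DRUSEN phantom
generated from the same seed differ only inside the lesion bounding boxes
(a tested invariant).

Per-sample seeds are derived by hashing (base seed, split, class, index),
so a dataset can be extended with more samples without changing the ones
already generated.

**What the phantoms do not emulate:** multiplicative speckle statistics
(noise here is additive Gaussian), anatomically correct layer counts and
curvature, vitreomacular traction, scanner artefacts, or inter-patient
variability. Passing the phantom study therefore demonstrates that the
pipeline's machinery is correct and discriminates the modelled lesion
morphologies at the stated noise level — not that it reaches any particular
accuracy on clinical data.

The synthetic feature tables (`make_feature_table`) are the selector's
substrate: two balanced classes, `n_informative` randomly placed columns
with a between-class mean gap of `class_sep` (within-class SD 1), the rest
standard normal noise. Labels alternate A/B so prefix splits stay
stratified.

## Preprocessing conventions

The parameters of the five masking steps are exposed in
`preprocess_config()`; the defaults are the widely used ones: bilateral
diameter 9 with both sigmas 75, CLAHE clip limit 2 on an 8×8 tile grid, and
a 5×5 elliptical structuring element.

Numerical choices that matter:

* **Borders** are reflect-padded for the bilateral filter and for CLAHE's
  tile padding. Morphology uses the adjoint pair on the finite frame —
  dilation pads with 0, erosion with 1 — which makes the open-then-close
  filter exactly idempotent (tested on random masks).
* **Otsu** maximizes the between-class variance over all 256 candidate
  cuts with the mask defined as `pixel >= threshold`; ties are broken by
  the smallest threshold for determinism. A constant image is flagged
  degenerate and returns an all-zero mask. Equivalence with an exhaustive
  search oracle is asserted on random images.
* **CLAHE** clips each tile histogram at `clip_limit` times the uniform
  bin height, redistributes the excess uniformly over all 256 bins, and
  maps through the equalization cdf
  `m(v) = round((cdf(v) - cdf_min) / (n - cdf_min) * 255)`; pixel values
  are bilinearly interpolated between the four nearest tile mappings. A
  tile whose clipped histogram occupies a single bin maps identically
  (keeps constant images constant). With a 1×1 grid and a clip limit too
  high to bite, the operation reduces exactly to plain histogram
  equalization (tested against an independent cdf oracle).
* **Color inputs** are converted with Rec. 601 luminance weights on load;
  all arithmetic is on the 8-bit scale.

## Feature extraction choices

* **GLCM** quantizes to 32 gray levels by default: on small working images
  a 256-level matrix is almost empty and its statistics are dominated by
  sampling noise, while 32 levels keep the matrix well populated without
  flattening texture contrast. Distances {1, 2} and all four axis/diagonal
  angles give 32 features. The matrix is unsymmetric and normalized;
  degenerate correlation (zero marginal variance) is defined as 1.
* **HOG** uses 8×8-pixel cells, 9 unsigned orientation bins over
  [0°, 180°), 2×2-cell blocks at stride 1, and plain L2 block
  normalization. Voting is hard assignment of the full gradient magnitude
  to the bin containing the angle — matching the worked description the
  descriptor follows here — with bilinear splitting available as the
  standard alternative. Gradients are centred `[-1, 0, 1]` differences
  with replicate borders; zero-norm blocks are left as zeros so constant
  images give the zero vector.
* **Backbones** are a pluggable interface. No pretrained weights ship with
  the package: requesting `weights_source = "pretrained"` is an explicit
  error, never a silent fallback. The built-in trunk is a small bias-free
  seeded random-weight CNN (3×3 convolutions, ReLU, 2×2 average pooling,
  two stages, global average pooling by default). Random convolutional
  projections still produce stable, discriminative texture summaries, and
  a seeded stub keeps the full pipeline — including the CNN slot of the
  feature vector — testable offline. Images are bilinearly resized to the
  backbone's input size and the gray channel is replicated to three.
* The assembled layout is a pure function of the configuration (canonical
  order GLCM, HOG, then backbones), never of image content. The default
  working size for the phantom study is 64×64, giving 32 GLCM + 1764 HOG +
  16 stub features = 1812 columns; the per-group counts are logged per run
  rather than matched to any external total, which cannot be decomposed
  without the original image geometry.

## The binary firefly selector

Each firefly is a bitstring over the features (1 = selected) with fitness

```
fit(C) = w * acc(C) + (1 - w) * size_term(C)
```

where `acc` is the KNN accuracy of the subset (fit split standardized to
zero mean / unit SD, Euclidean distance over selected columns, k = 5,
deterministic tie-breaks: equidistant neighbours by smallest fit-row index,
vote ties by smallest class label). Two polarities of the size term are
implemented because the printed form of the objective rewards *large*
subsets (`selected/total`) while the stated goal is the fewest features:

* `parsimony_mode = "penalize"` (default): `size_term = 1 - selected/total`;
* `parsimony_mode = "literal"`: `size_term = selected/total`, kept for
  fidelity experiments.

A dim firefly `i` moves towards every brighter `j`:

```
r     = Hamming(C_i, C_j) / (2N - |C_i| - |C_j|)
beta  = beta0 * exp(-gamma * r)
X_new = [X_i +] beta * (X_j - X_i) + alpha * (R - 0.5)    (R ~ U[0,1) per coordinate)
bits  = tanh(X_new) >= 0.5
```

The bracketed incumbent term is the `movement_variant` switch. The printed
update omits `X_i`; under that literal form two agreeing set bits propose
`beta * 0 = 0` and collapse to unselected whenever the random kick is below
`atanh(0.5) ≈ 0.549`, which destroys consensus features. The default
`"standard"` variant adds the incumbent, the canonical firefly move; the
literal form stays available behind the flag and both are unit-tested. The
distance's denominator form is one documented parsing of an ambiguously
typeset original; both all-ones strings (denominator 0) define `r = 0`.

Further conventions:

* Positions collapse to their binarized bits after every move, so the
  update always sees 0/1 incumbent coordinates (positions are defined as
  bit vectors throughout).
* The comparison loop is doubly nested with asynchronous updates: firefly
  `i` is moved, binarized, repaired and re-scored after *each* comparison,
  including against itself (where the not-brighter branch triggers a random
  move `X_i + alpha*(R - 0.5)`). End-of-sweep ranking is reporting-only;
  it does not reorder the population seen by the next sweep.
* An all-zero selection is repaired by setting one uniformly random bit
  (the accuracy of an empty subset is undefined).
* Elitism: the best (selection, fitness) over all evaluations, including
  initialization, is returned; the recorded history is therefore monotone.
* One seeded RNG stream drives initialization, every move and every repair
  in a fixed documented order, so runs are bit-reproducible.
* Hyperparameter defaults — 20 fireflies, 30 sweeps, `w = 0.9`,
  `alpha = 0.5` constant (no decay schedule is assumed), `beta0 = 1`,
  `gamma = 1`, `k = 5` — are common values in the binary-firefly
  literature; all are exposed in `firefly_params()`.
* **Fitness splits:** by default the fitness KNN fits on the *training*
  split and scores on the *validation* split. The alternative protocol of
  fitting on validation and scoring on the *test* split is available as
  `fit_on_validation = TRUE` for replication studies, but it leaks the
  test set into selection and is not the default.
* Selection runs independently per hierarchy stage, since each binary
  problem has its own informative features.

## Hierarchical classification

Stage datasets relabel leaf classes into the stage's positive/negative
groups and drop the rest. Classifier defaults (hyperparameters are
overridable and echoed into reports): SVM with RBF kernel and cost 1
(`e1071`), logistic regression as a ridge-penalized fit with
`lambda = 1/(n*C)`, `C = 1` (`glmnet`; a plain maximum-likelihood fit would
not converge on linearly separable stages), and random forest with 100
trees (`randomForest`, seeded). Features are standardized per stage on its
training split; the stage model bundles classifier, selection and
standardization so prediction is a pure function of bundle and input.

Metrics follow the confusion-matrix identities (accuracy, precision,
recall, F1 as the harmonic mean), computed class by class with each stage
class in turn treated as positive. Zero-denominator cases are defined as 0
and flagged rather than crashing on degenerate classifiers. The headline
number is the unweighted mean of stage accuracies. Cascade evaluation —
routing each test sample abnormal → AMD → CNV/DRUSEN to a single leaf — is
an additional report beyond the per-stage protocol and is labelled as such.

## Problem sizes and runtime

The default study — chosen as the package's own desk-scale conditions — is
50 training, 15 validation and 15 test phantoms per class at 128×128 with
noise sigma 5, analysed at a 64×64 working size (1812 features). The
per-stage selector inside the pipeline run uses 10 fireflies × 3 sweeps,
which already halves the feature set; the full default selector
(20 fireflies × 30 sweeps) is exercised on the 100-feature synthetic
tables, where its planted-feature recovery is measured. The complete test
suite and the acceptance script each run in minutes on one CPU.

## Known limitations

* Phantom realism as above; accuracies on phantoms do not transfer to
  clinical scans.
* The bundled backbone is a random-weight stub; plugging in a pretrained
  trunk requires the user to supply weights through the `backbone_spec`
  interface.
* The selector's objective uses a single KNN evaluation per subset; no
  cross-validation is performed inside the fitness, so very small
  validation splits make selection noisy.
* The hierarchy resolves leaves only when terminal groups are single
  classes; multi-class terminal groups are rejected rather than guessed.
* The CLAHE excess-redistribution is the simple uniform single-pass
  variant; mass pushed above the clip by redistribution is not re-clipped.
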