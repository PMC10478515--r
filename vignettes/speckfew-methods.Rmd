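---
title: "Methods: simulating and classifying X-ray speckle patterns with few labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying X-ray speckle patterns with few labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In X-ray single-particle imaging (SPI), a free-electron laser pulse hits a
stream of injected particles and a pixel detector records one coherent
diffraction ("speckle") pattern per pulse. Most pulses are not useful:
only *single hits* — exactly one particle in the beam — feed the downstream
3-D reconstruction, while *multi-hits* (two or more particles scattering
coherently) and *non-sample hits* (parasitic scattering from apertures or
injector debris) must be vetoed. At modern repetition rates this triage has
to run with almost no labeled examples of the current sample, which rules
out conventional per-class classifier training.

`speckfew` approaches the problem with metric learning. A small
convolutional network $f$ maps a pattern $x$ to an embedding
$f(x) \in \mathbb{R}^{d}$ with $\lVert f(x)\rVert_2 = 1$, so every pattern
lands on the unit hypersphere and similarity is measured by (squared)
Euclidean distance. Classification is then *N-way X-shot*: a query is
embedded, its plain Euclidean distance to each of $X$ labeled support
examples per class is computed, distances are averaged per class, and the
nearest class wins. Changing samples, or even label sets, requires only a
new handful of supports — not retraining.

## Triplet loss and semi-hard mining

Training uses triplets $(x^a, x^p, x^n)$: anchor and positive share a
label, the negative does not. With squared distances
$d_{ap} = \lVert f(x^a) - f(x^p)\rVert_2^2$ and
$d_{an} = \lVert f(x^a) - f(x^n)\rVert_2^2$, the loss per triplet is the
hinge

$$\mathcal{L} = \max(0,\; d_{ap} - d_{an} + \alpha),$$

which is zero once the negative is farther from the anchor than the
positive by at least the margin $\alpha$. Because embeddings are unit
vectors, $d \in [0, 4]$ and the largest meaningful margin is $\alpha = 4$;
the package enforces $\alpha \in (0, 4]$ and defaults to $\alpha = 0.2$
(the margin value is a free parameter of the method; 0.2 on the squared-L2
scale keeps a usable semi-hard band on the sphere without saturating it).

Triplets come in three kinds: *easy* ($d_{an} > d_{ap} + \alpha$, zero
loss and zero gradient), *hard* ($d_{an} < d_{ap}$, prone to bad local
minima when over-weighted), and *semi-hard* (the band in between).
`select_semihard_triplets()` mines semi-hard triplets at the mini-batch
level: it repeatedly draws an anchor/positive pair — under the
*multi-sample rule*, both must come from the same sample as well as the
same class, so the loss never tries to collapse two different particles'
patterns onto each other — and then samples a negative from another class
inside the band $d_{ap} \le d_{an} \le d_{ap} + \alpha$. Two conventions
were open and are fixed as follows:

* **Boundary ties** ($d_{an} = d_{ap}$ or $d_{an} = d_{ap} + \alpha$)
  count as semi-hard, i.e. the band is closed. Ties are measure-zero in
  practice; a closed band keeps the selector's accepted set exactly
  complementary to the easy and hard sets.
* **Fallback**: if a drawn pair has no semi-hard negative in the batch,
  the selector takes the *easiest hard* negative (largest $d_{an}$ among
  $d_{an} < d_{ap}$), else a uniformly random valid-label negative, and
  flags the triplet. This keeps the optimizer moving when a batch is
  fully separated (or fully collapsed) without over-weighting the hardest
  examples.

Selection embeddings are computed with the current model in inference
mode; the subsequent gradient step re-embeds the batch in training mode
(batch-norm batch statistics). Validation loss uses *random* triplets, not
mined ones, so it is a selector-independent measure; the checkpoint with
the best validation loss is the fitted model.

## The embedding network

The backbone is deliberately small: two valid 5×5 convolutions with
stride 1 and no padding, each followed by ReLU, then batch normalization,
then 2×2 max pooling with stride 2; two fully connected layers
(512-wide hidden, ReLU) produce the embedding, which is divided by its L2
norm. For 96×96 inputs the spatial chain is 96 → 92 → 46 → 42 → 21; the
minimum input size is 16. Both convolution widths default to 32 channels
and the hidden width to 512 — the kernel sizes, strides, pooling, the
128-dimensional embedding and the normalization are fixed by the design,
while these widths are free architecture parameters exposed in
`model_config()`. Weights initialize i.i.d. $N(0, 0.2^2)$ (biases zero,
batch-norm at identity) and training uses Adam at learning rate $10^{-3}$.
The final L2 normalization makes the head scale-invariant, so the wide
initialization is numerically harmless, and Adam's per-parameter scaling
absorbs the resulting gradient magnitudes.

The network, its backward pass and Adam are implemented in the package
itself (R orchestration over BLAS matrix products, with the hot loops —
patch extraction, pooling, the fused training workspace — in compiled
code under `src/`). A plain-R reference implementation of the same
network is kept alongside and the test suite checks the two agree to
~1e-12 and match finite-difference gradients; the compiled path
pre-allocates every large buffer once per training run, which matters on
the memory-bandwidth-bound machines this is designed to run on.

The comparison baseline (`build_binary_baseline()`) couples the same
backbone to fully connected layers ending in a sigmoid that outputs
P(single-hit), thresholded at 0.9 by convention — the classical CNN hit
finder this package's method is measured against.

## The speckle simulator

The simulator is a deliberately simplified forward model whose purpose is
to generate *labeled, statistically structured* training and test data,
not to reproduce an instrument:

* **Diffraction**: far-field, flat-Ewald (small-angle) point-scatterer
  model, $I(q) = s\,\lvert\sum_{\text{copies}}\sum_{\text{atoms}}
  w\,e^{i q\cdot(Rr + t)}\rvert^2$ with per-pixel transverse
  $q = (2\pi/\lambda)\,(\Delta x, \Delta y)/D$. Unit form factors, no
  Ewald curvature, no polarization or solid-angle corrections. Copies sum
  coherently, so multi-hits carry interference fringes — the feature that
  makes them distinguishable. Under this model a real-valued scatterer
  gives exactly centrosymmetric intensities (Friedel symmetry), and $k$
  in-phase scatterers give $k^2$ the central intensity; both are tested.
* **Geometry**: 172×172 pixels, beam energy 1.66 keV
  (λ ≈ 7.47 Å), 10¹² photons per pulse, 0.5 µm beam radius. Pixel size
  (0.2 mm) and detector distance (20 mm) are *not* instrument values;
  they were chosen once so a ~100 Å toy particle yields speckle fringes
  of roughly 3–10 pixel period on this grid, which is the regime the
  classifier has to work in.
* **Intensity scale**: the overall factor defaults to
  `photons_per_pulse * 3e-14`, calibrated once so a default 100-atom toy
  single-hit integrates to ~10⁵ detected photons before jitter — enough
  that Poisson noise is realistic rather than dominant. It is a plain
  argument for other regimes.
* **Noise chain and its order**: noise-free diffraction → fluence-jitter
  multiplier → Poisson shot noise → beam-stop (6×8) and panel-gap
  (172×4) masks → 96×96 center crop → per-image standardization →
  additive Gaussian noise (σ = 0.15). Two conventions here were open:
  masks are applied after the Poisson draw (they zero whatever the
  detector cannot see), and the σ = 0.15 Gaussian read-out noise is added
  on the *standardized* scale, where an O(0.1) σ is meaningful; on raw
  photon counts it would be invisible. The crop window starts at
  `floor((n - size)/2) + 1`, fixed so results are bit-reproducible.
* **Fluence jitter**: a log-normal multiplier with median 1
  (`sdlog = 0.6`, mean `exp(0.18)` ≈ 1.20) stands in for an experimental
  pulse-energy histogram — right-skewed with occasional bright shots. An
  empirical sample vector can be plugged in instead.
* **Non-sample hits**: parasitic scattering has no generative model here;
  the proxy is 1–3 broad anisotropic Gaussian streaks (long axis 30–80 px,
  short 5–15 px, random orientation) scaled to a comparable total
  intensity. It is smooth and low-frequency where particle speckle is
  grainy, which is the property the tests assert and the classifier uses.
* **Multi-hits** draw 2–4 copies with equal probability (double, triple
  and quadruple hits pooled under one `multi_hit` label), displaced
  uniformly in a ball of three particle extents — close enough that
  fringes fall within the resolvable band.

What the generator does *not* emulate: water/background scattering,
element-specific form factors, detector gain maps, real pulse-energy
distributions, or the full diversity of protein shapes (toy particles are
uniform balls of point atoms). Passing the package's tests therefore
demonstrates that the method works as specified on data with this
statistical structure; it does not certify performance on any real
instrument's data.

## Augmentation and the leakage rule

Four augmentations expand a labeled set: in-plane rotation (bilinear,
with exact lattice rotations at multiples of 90°), rectangular masking,
center zoom, and shift — all shape-preserving, filling exposed pixels
with 0 to match masked-detector semantics. The essential discipline is
*split before augmenting*: `split_then_augment()` partitions source
patterns first and augmented copies inherit their source's partition, so
a test set can never contain a rotated copy of a training pattern.
`audit_split()` re-checks this invariant and is run inside the builder,
in the tests, and as a CLI subcommand.

## Benchmarks the package ships

Two protocols fix the package's study conditions (both are ordinary
exported functions; `scripts/acceptance.R` and the test suite run them):

* `protocol_fewshot_learning()` — two classes of single-hit patterns from
  toy particles of radius 22 Å vs 60 Å ("distinct fringe spacings"),
  4 particles per class, 200 patterns per class at 96×96, split
  60/20/20, 5 epochs. Reports held-out 1/5/20-shot accuracy with
  bootstrap errors on the consecutive differences, and a 5-shot cell at
  1% fluence, the signal-starved end of the scan (how far accuracy falls
  there depends on how gross the class difference is; the tests assert
  only that it falls).
* `protocol_detector_robustness()` — the single-sample (online) setting:
  three hit classes from one 100-atom particle, 80 sources per class
  split 50/25/25 (40 training / 20 validation sources per class, the
  label-starved regime), expanded ×3 by rotation+masking augmentation,
  4 epochs. The 5-shot embedding classifier and the threshold baseline
  are then evaluated on identical inputs with the full crop and with only
  the top-left 48×48 quadrant (25% area) available on every query *and*
  support. The quantity of interest is the paired accuracy drop.

Problem sizes were set so each protocol trains in minutes on one CPU
core; they are desk-scale versions of the corresponding experiments, not
attempts to reproduce any published number.

## Other fixed conventions

* Few-shot distances are *plain* Euclidean (squared distances, used by
  the loss, can rank class averages differently); a `distance = "squared"`
  switch exposes the alternative. Ties break toward the
  lexicographically smallest label.
* F-1 aggregation is the unweighted macro average; per-class values are
  always returned so any other aggregation is recomputable.
* The 25%-area ablation keeps the top-left quadrant by default (losing
  contiguous panels, as modular detectors do); a random-corner mode
  exists.
* Every stochastic operation takes a seed; one master seed fans out to
  per-purpose streams through a string-keyed hash (`derive_seed()`), so
  datasets, training runs and evaluations are pure functions of
  (configuration, seed) and artifacts embed the seed and a configuration
  hash.
* Batch norm uses ε = 1e-5 and momentum 0.1 on running statistics;
  pooling ties route gradients to the first maximum; a constant image
  standardizes to all zeros rather than dividing by zero.
* Datasets and checkpoints are stored as single-file R serializations
  (with the label map, configuration JSON and seed embedded).

## Known limitations

The flat-Ewald, unit-form-factor physics limits realism at wide angles
and for heavy-atom contrast; the non-sample-hit proxy is statistical, not
physical; t-SNE export is an exact O(N²) implementation intended for a
few hundred points; and the compiled training workspace holds one
pre-sized buffer set, so the batch size is fixed per training run.
Transfer from simulated to real detector data is out of scope: nothing
here addresses the domain gap beyond the augmentations described.
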