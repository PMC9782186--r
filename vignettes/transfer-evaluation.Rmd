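---
title: "Evaluating how image feature extractors transfer: methods and design"
author: "transferscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating how image feature extractors transfer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transferscope)
```

## The problem

Pretrained image backbones — supervised or self-supervised — are routinely
reused as frozen feature extractors on new classification tasks, notably in
medical imaging where labeled data are scarce and class signal often
consists of minute local texture differences rather than global object
structure. Judging whether a given extractor transfers well to such a task
requires more than one number: few-shot behavior, many-shot behavior, where
in the image the features are sensitive, and which transformations the
features are invariant to can all disagree.

`transferscope` packages those four measurements behind one extractor
contract, together with a synthetic image generator that plants a known
class signal, so that every stage of the analysis can be validated against
analytic ground truth without external datasets or pretrained weights.

## The extractor contract and preprocessing

An extractor is a pure function $f_\phi$ from a preprocessed image to a
fixed-length feature vector of dimension $d$, plus a preprocessing
specification. The default preprocessing mirrors the common evaluation
convention: single-channel images are replicated to three identical
channels; the shorter side is resampled to 224 pixels with a bicubic
(Catmull–Rom, $a = -0.5$) kernel, preserving aspect ratio; a 224×224 center
crop is taken; finally per-channel standardization with ImageNet statistics
(mean 0.485/0.456/0.406, sd 0.229/0.224/0.225) is applied. Histogram
equalization (to uniform on $[0,1]$ via midpoint-adjusted ranks) is
available for backbones that expect it, and `"none"` disables
normalization.

Two conventions here were genuinely open and are fixed as follows. The
resize is aspect-preserving with the *shorter* side mapped to the target
(the square-resize alternative is used only inside the saliency module,
whose working size is explicitly square). Output coordinates are
center-aligned (`src = (i + 0.5) * scale - 0.5`), which makes the resize an
exact identity when sizes match — that gives the preprocessing its
idempotence property on already-conforming input.

Four toy extractors with provable properties support testing: a seeded
random projection of the flattened pixels; the same restricted to a pixel
region (all other pixels provably ignored); a flip-invariant map (the image
is symmetrized with its horizontal mirror before projection, so invariance
holds exactly in floating point); and a small trainable network (3×3
convolution, ReLU, global average pooling) for the finetuning protocol.

## Few-shot evaluation (prototypical networks)

A K-way N-shot *episode* samples K classes, then per class N support and
$N_Q$ query images without replacement (support and query disjoint). Class
prototypes are support centroids,

$$c_k = \frac{1}{N} \sum_{(x_i, y_i) \in S_k} f_\phi(x_i),$$

and each query is assigned the class of the nearest prototype. Distance is
squared Euclidean (argmin-equivalent to Euclidean); exact ties break toward
the lowest class id, making the classifier fully deterministic. No feature
re-normalization is applied before the distance computation.

By default 600 episodes are sampled with $N_Q = 15$ and the mean accuracy
is reported with a normal-approximation 95% confidence half-width,
$1.96\,\mathrm{sd}/\sqrt{n_{\text{episodes}}}$ — the CI is over episodes,
which we consider the natural reading when none is stated. Episode $e$
draws from a child seed derived from `(seed, e)`, so results are
reproducible and a longer run extends a shorter one without changing its
episodes.

```{r fewshot-example, eval = FALSE}
feats <- matrix(rnorm(400 * 16), 400)   # label-independent features
labs <- rep(0:1, each = 200)
evaluateFewshot(feats, labs, K = 2, N = 20, NQ = 15,
                nEpisodes = 600, seed = 1)
#> EpisodicResult: 2-way 20-shot, 600 episodes
#>   accuracy 0.4878 +/- 0.0120 (95% CI)
```

## Many-shot evaluation

**Linear probe.** A multinomial logistic regression
$P(y = c_i \mid x) \propto e^{w_i \cdot x}$ is fitted on frozen features
with an $\ell_2$ penalty for each of 45 logarithmically spaced
regularization constants between $10^{-6}$ and $10^{5}$ (`l2Grid()`). The
constant maximizing validation accuracy is selected — ties resolve to the
smallest constant, a deterministic and documented choice — the model is
refitted on train + validation at that constant, and top-1 test accuracy is
reported. The convex fits are delegated to glmnet (ridge,
`standardize = FALSE`, convergence threshold $10^{-10}$); features enter
the regression as given, without re-standardization, since nothing in the
protocol prescribes it. glmnet normalizes the log-likelihood per
observation, so duplicating every training point leaves the fit at a given
constant unchanged — a property the tests assert.

**Finetuning.** For trainable extractors, all parameters plus an attached
linear head are refitted by SGD with Nesterov momentum 0.9, learning rate
$10^{-2}$, weight decay $10^{-8}$, batch size 64, for at most 5000 steps,
with random-resized-crop and horizontal-flip augmentation. Validation
accuracy is checked every 200 steps; training halts after 3 consecutive
non-improving checks and the best-validation checkpoint is evaluated on
test. The first check always registers as an improvement over the initial
$-\infty$ baseline, so a never-improving trace halts at step
$(1 + 3) \times 200 = 800$. `maxSteps = 0` evaluates the initial model with
an empty log. The head is initialized at small scale from a fixed child
seed for reproducibility.

## Occlusion saliency and attentive diffusion

The image is resized (square, bicubic) to 242×242, normalized per the
extractor's spec, and embedded once. A 10×10 occluding patch slides with
stride 1 over every fully-inside position — $(242 - 10 + 1)^2 = 54{,}289$
of them. For each position the root relative squared error

$$\mathrm{RRSE}(f_{\text{orig}}, f_{\text{occ}}) =
\sqrt{\frac{\sum_j (f_{\text{occ},j} - f_{\text{orig},j})^2}
           {\sum_j (f_{\text{orig},j} - \bar f_{\text{orig}})^2}}$$

is added to the attention accumulator of every occluded pixel; accumulators
are divided by per-pixel occlusion counts, and the map is center-cropped to
224×224, inside which every pixel was occluded exactly $10^2 = 100$ times.
The crop arithmetic generalizes: counts are uniform whenever
`cropTo <= resizeTo - 2 * (maskSize - 1)`, which the implementation
enforces.

Design choices needing fixing here: occluded pixels are set to 0 *in
normalized space* (the least informative fill under the normalization); the
RRSE denominator averages over the components of the single original
feature vector (the definition is isolated in `rrse()` so it can be
swapped); a constant original feature makes the statistic undefined and
raises a degenerate-extractor error rather than returning anything.

The *attentive diffusion* of a map is the fraction of pixels strictly above
the map mean — near 1 means broad focus, near 0 concentrated focus.
"Strictly" makes the constant map well-defined (diffusion 0).

For extractors that are linear in the pixels, the per-position feature
change is computed in closed form with 2-D box filters (implemented by
shift-and-add so that windows of exact zeros stay exactly zero); the
result is identical to embedding every masked copy, which a test asserts,
and a full-geometry map takes a fraction of a second instead of minutes.

## Transformation invariance

Given a dataset, the feature mean $\bar f_\phi$ and covariance $\Sigma$ are
estimated from at most 1000 sampled images (the whole dataset if smaller).
Features are whitened and compared across a transformation family
$T_\Theta = \{t_\theta\}$ by the mean cosine similarity

$$L_f^{T_\Theta}(D) = \frac{1}{|D||\Theta|}
\sum_{x, \theta} \frac{z \cdot z_{t_\theta}}{\lVert z\rVert\,
\lVert z_{t_\theta}\rVert},$$

averaged in practice over 100 sampled images. The whitener is derived from
the Cholesky factorization $\Sigma^{-1} = L L^\top$ with $L$ lower
triangular; the whitened vector is computed as
$z = L^\top(\bar f_\phi - f_\phi(x))$. The orientation matters: with
$L^\top$, $\lVert z \rVert^2$ equals the Mahalanobis form
$(\bar f - f)^\top \Sigma^{-1} (\bar f - f)$ and the resulting score is
invariant under any invertible linear reparameterization of the feature
space (with moments re-estimated) — with $L$ it would be neither. Both
properties are asserted in the tests, and we read the conventional
shorthand "$z = L(\bar f - f)$" accordingly. If $\Sigma$ is singular the
smallest ridge $\varepsilon \in \{0, 10^{-8}, 10^{-6}, \dots\}$ making the
factorization succeed is added, and the result records it.

Built-in families are horizontal flip, exact grid rotations (90°/180°/270°
— chosen over arbitrary angles to avoid interpolation artifacts in the
oracle checks), and hue rotation (computed numerically, not through
quantized color strings; a no-op on stacked-grayscale images, which the
result flags). Identity transforms, which contribute a constant cosine of
1, are excluded by default; `includeIdentity = TRUE` restores the literal
flip-family reading with $\theta \in \{\text{False}, \text{True}\}$.

*Multi-view* invariance replaces $t_\theta(x)$ by a second image of the
same object: the score is the mean whitened cosine across view pairs
(groups without exactly two views are excluded with a warning). Zero-norm
whitened features — a feature exactly at the dataset mean — are skipped
with a warning and the average adjusted.

## Label-conversion rules

Real medical manifests arrive as multi-label records, free text, or graded
categories. The adapters implement the standard conversions: many-to-one
binarization against a caller-supplied target pathology (positive iff the
target indicator is set, everything else including "no finding" negative);
abnormal-vs-normal text binarization (labels are trimmed and case-folded
first — real manifests are messy); explicit class merging; ordinal encoding
by position in an ordered category list; and filtering multi-label records
to those with exactly one positive indicator for multiclass use (the drop
count is logged; this is the only adapter that removes rows). The target
pathology is never auto-detected — determinism and explicitness are worth
one extra argument.

## The synthetic generator: what it does and does not emulate

`generateDataset()` plants, per class $k$, a sinusoidal grating oriented at
$k \cdot 180^\circ / K$ with fixed spatial frequency (0.15 cycles/pixel —
a short period, so the signal reads as local texture), amplitude 0.5 by
default, confined to a configurable region (default: centered square of a
quarter of the image side), over a smooth per-object polynomial background,
plus Gaussian pixel noise (sd 0.05 by default) added after the signal and
clipped to $[0,1]$ — clipping after noise slightly breaks Gaussianity at
the boundaries, which is documented rather than avoided. Background and
grating phase derive from per-object child seeds that are class-independent,
so with zero noise the class-mean images agree *exactly* outside the signal
region; per-image child seeds also mean that generating more images never
perturbs existing ones. Multi-view pairs render one object on a padded
canvas (noise included, as part of the object) and crop two views whose
relative translation is at most `multiviewShift` pixels per axis; with zero
shift the views are pixel-identical.

This emulates the *statistical structure* the analysis assumes — class
signal as a localized texture perturbation, grayscale radiograph-like
channels, paired views of one object, multi-label records with independent
Bernoulli indicators — and nothing more. Passing tests on it demonstrates
that the evaluation machinery measures what it claims (oracle equivalence,
chance-level calibration, locality, invariance algebra). It does not
demonstrate that any particular backbone transfers well to real medical
images: real pathology is not a stationary grating, real backgrounds are
anatomy rather than polynomials, and label noise, class imbalance and
acquisition shifts are all absent by construction.

Note also that the planted signal is deliberately hard for *linear*
extractors: the grating phase is randomized per object, so class means in
any linear feature space coincide and random-projection features sit at
chance. Texture-sensitive (rectifying) extractors such as the toy CNN
separate the classes easily in the many-shot regime. The demo includes both
on purpose — and shows a third effect worth knowing about: the same CNN
features that probe at accuracy 1.0 stay near chance under nearest-prototype
few-shot evaluation, because nuisance (background) variance dominates
Euclidean distances that the linear probe can simply project away.

## Problem sizes and numerical choices

The test suite and demo use reduced problem sizes chosen as the smallest
that still exercise every code path with clear margins: 32–64 px synthetic
images, feature dimensions 2–32, 600 episodes for the calibration checks
and 100–200 elsewhere, the full 242/10/224 saliency geometry where the
occlusion arithmetic itself is under test and 30–50 px geometries
elsewhere. The ordering statistics the analysis relies on (focused <
global diffusion; flip-invariant > generic invariance) hold with wide
margins at these sizes. Remaining numerical conventions: min–max scaling
across models maps a constant column to 0.5 (flagged as degenerate);
reduced $\chi^2$ is reported only when per-point uncertainties are
supplied, never assumed; Pearson's $p$ value is two-sided from the $t$
distribution with $n - 2$ degrees of freedom.

## Limitations

Checkpoint loading for real backbones is out of scope — any function
satisfying the extractor contract can be registered, but nothing is
downloaded or bundled. The finetuning protocol is implemented for the
package's trainable toy architecture; wiring a real deep network through
`TrainableExtractor` would require its own gradient machinery. Saliency for
non-linear extractors uses the generic embed-every-mask path, which at the
full 54,289-position geometry is slow in pure R; use a reduced geometry or
a linear surrogate there. The generator's gratings-and-polynomials world is
a validation harness, not a simulator of clinical images.
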