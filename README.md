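# transferscope

Evaluate how well a frozen image feature extractor transfers to a labeled
image classification task — the question behind every "should I reuse this
pretrained backbone on my (medical) images?" decision. The package measures
four complementary things about an extractor `f_φ`:

1. **Few-shot transfer** — episodic K-way N-shot evaluation with
   prototypical networks: class prototypes are support centroids,
   `c_k = (1/N) Σ_{(x_i,y_i)∈S_k} f_φ(x_i)`, queries go to the nearest
   prototype, and mean accuracy over 600 episodes is reported with a 95%
   CI.
2. **Many-shot transfer** — a multinomial logistic-regression linear probe
   `P(y = c_i | x) ∝ exp(w_i·x)` on frozen features, with the ℓ2 constant
   selected on validation from 45 log-spaced values in `[1e-6, 1e5]`; plus
   an SGD finetuning protocol (Nesterov momentum 0.9, lr 1e-2, weight decay
   1e-8, max 5000 steps, early stopping with patience 3 checked every 200
   steps) for trainable extractors.
3. **Occlusion saliency** — a 10×10 mask slides over the 242×242 image
   (54,289 positions); the root relative squared error (RRSE) between
   original and occluded features accumulates into per-pixel attention,
   averaged over the 100 occlusions each retained pixel receives after the
   224×224 crop. The *attentive diffusion* of a map — the fraction of
   pixels strictly above its mean — summarizes broad vs. concentrated
   focus.
4. **Transformation invariance** — whitened cosine similarity
   `mean cos(z, z_tθ)` with `z = Lᵀ(f̄ − f_φ(x))` and `Σ⁻¹ = LLᵀ`, over
   flip / rotation / hue families, plus a multi-view variant comparing two
   images of the same object.

A synthetic image generator plants a class-specific texture grating inside
a configurable "pathology" region over smooth backgrounds and noise, with
multi-view pairs and multi-label records, so every stage is testable
against analytic ground truth — no external datasets or pretrained weights
required. Dataset adapters implement the standard medical-imaging label
conversions (many-to-one binarization, abnormal-vs-normal, class merging,
ordinal encoding, single-pathology filtering) for real manifests.

## Worked example

The built-in demo generates a two-class synthetic dataset (64×64 px,
texture signal in a central 16×16 region) and runs three toy extractors —
a global random projection, a region-restricted projection, and a small
untrained CNN — through every stage:

```r
library(transferscope)
res <- runDemo("demo_out", seed = 42)

res$fewshot
#>      global     focused texture_cnn
#>   0.4548333   0.4708333   0.4813333
res$linear
#>      global     focused texture_cnn
#>   0.3333333   0.2500000   1.0000000
res$diffusion
#>     global    focused
#> 0.47505682 0.04416947
res$invariance
#>     global     focused texture_cnn
#> 0.04955255  0.08902597  0.46309490
```

Three observations worth reading off these numbers. The linear extractors
sit at chance everywhere: the planted texture has a random phase per
object, so class means coincide in any linear feature space — accuracy
alone would say "nothing transfers". The untrained CNN probes at accuracy
1.0 (rectified texture energy is linearly separable) yet stays at chance in
the few-shot column, because background variance dominates the Euclidean
distances that prototypical networks use while the probe projects it away:
the two evaluation regimes genuinely measure different things. And the
saliency column shows the region-restricted extractor with attentive
diffusion 0.044 against 0.475 for the global one — a concentrated vs. broad
focus, measured without reference to any task.

Every stage writes a JSON result (tagged with seed, config hash and package
version) into `demo_out/`, and the report stage aggregates them into
per-metric model × task score tables with min–max cross-model scaling and
group means (`scaledGroupMeans()`), plus `pearsonFit()` for
correlation/linear-fit summaries with optional reduced χ².

A shell entry point with the same stages is installed at
`inst/cli/transferscope.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/transferscope.R", package = "transferscope"))')" \
  demo --out demo_out --seed 42
```

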