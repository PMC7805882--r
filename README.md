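# beetag

Synthesis of realistic, automatically labeled images of the circular
12-bit markers used to identify honeybees in hive monitoring — and a
decoder network trained on that synthetic data.

## The problem

Tracking individually marked bees requires decoding a binary marker
(12 code cells in an outer ring, $2^{12} = 4096$ ids; two inner
semicircles give the orientation) from small, noisy grayscale crops.
Labeling crops by hand takes about a minute each — 10 examples per id is
over 680 hours of work — so supervised training data must be generated.
A parametric 3D model renders a clean binary marker for any code and
pose, but networks trained on such idealistic renders do not generalize
to real imagery.

`beetag` closes that gap with a generative-adversarial approach in which
the generator cannot change the label: instead of synthesizing pixels
freely, it parameterizes a fixed renderer plus a chain of differentiable
image augmentations (blur, lighting, background, detail) whose parameter
ranges are restricted so the code bits cannot flip,

$$x \;=\; \phi_{detail} \circ \phi_{bg} \circ \phi_{light} \circ
\phi_{blur}(\text{render}(\text{bits}, \text{pose})),$$

with, e.g., $\phi_{light}(x) = x\,b(s_w)W(x) + x\,b(s_b)(1-W(x)) + b(t)$
and $s_w, s_b \in [0.10, 1]$ so black cells stay darker than white ones.
Ranges are enforced during learning by clip layers with an L1 activity
penalty ($\gamma = 15$).  Trained adversarially against unlabeled
imagery, the generator adds realistic nuisance structure while the bits
fed to the renderer remain the ground truth of every generated image.
A 34-layer residual decoder (16 base feature maps, one sigmoid per bit)
is then trained on the generated data and evaluated on the mean Hamming
distance (MHD) — the expected number of wrongly decoded bits; chance
level is 6.

Everything runs self-contained: hand-designed augmentation samplers
double as the "real" image distribution at desk scale, so no external
data is required.

## Worked example

```r
library(beetag)

# render the marker for a chosen id, decode it back
p <- tag_params(as.integer(strsplit("100110100010", "")[[1]]),
                yaw = 0.6, pitch = 0.2, roll = -0.1,
                center_row = 31.5, center_col = 31.5, radius = 24)
r <- render_tag(p, resolution = 64)
paste(reference_decode(r$image, p), collapse = "")
#> [1] "100110100010"

# label-preserving augmentation: random in-range parameters, same decode
a <- sample_augmentation_params(64, seed = 7)
x <- compose_augmentations(r, a)
paste(reference_decode(x, p), collapse = "")
#> [1] "100110100010"

# the clip layer that enforces the ranges during learning
clip_with_penalty(-0.9, clip_spec(0.10, 1, gamma = 15))
#> $value
#> [1] 0.1
#>
#> $penalty
#> [1] 15
```

The rendered marker is exactly binary (`r$image` is $\pm 1$); the
augmented image `x` shows blur, shading and background while the decoded
id is unchanged — that invariance, audited over random draws
(`audit_labels()`), is the package's core guarantee.

A scaled-down training pipeline:

```r
real <- hm_corpus(10000, 32, handmade_config(32), seed = 1)   # stand-in corpus
cfg  <- gan_config(resolution = 32, batch_size = 8,
                   epochs = 4, batches_per_epoch = 500, seed = 2)
ck   <- train_rendergan(cfg, real)
gen  <- generate_labeled_dataset(ck, 10000, discard_fraction = 0.05, seed = 3)
audit_labels(gen)                       # fraction of exact label matches
fit  <- train_decoder(decoder_train_config(epochs = 2, batches_per_epoch = 70,
                                           batch_size = 16, seed = 4),
                      gen, hm_corpus(400, 32, handmade_config(32), seed = 5))
evaluate_decoder(fit$decoder, hm_corpus(1500, 32, handmade_config(32), seed = 6))$mhd
```

A thin command-line wrapper (`exec/beetag`) exposes the same steps as
`render`, `make-hm-dataset`, `train-gan`, `generate`, `train-decoder` and
`evaluate` subcommands.

## Package layout

* `R/tag-model.R` — parametric marker renderer, pose sampling, reference
  decoder (the label-preservation oracle)
* `R/augment.R`, `R/blur.R` — differentiable augmentation stages, their
  backward passes, clip-with-penalty layer
* `R/gan.R`, `R/nn-core.R`, `src/` — generator/discriminator, renderer
  emulator, adversarial training loop; minimal conv-net core (im2col +
  BLAS) with Rcpp kernels
* `R/handmade.R` — hand-designed augmentation baselines and the
  desk-scale "real" corpus
* `R/datasets.R`, `R/generate.R` — labeled-dataset container, lossless
  on-disk format, dataset generation with score filtering
* `R/decoder.R` — residual decoder, training protocol, MHD evaluation
* `vignettes/marker-synthesis.Rmd` — model, assumptions, parameter
  choices, limitations
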