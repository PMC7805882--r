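---
title: "Label-preserving adversarial synthesis of honeybee marker images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-preserving adversarial synthesis of honeybee marker images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hive-monitoring systems identify individual honeybees by a curved circular
marker glued to the thorax: an outer ring of 12 binary cells encodes one of
$2^{12} = 4096$ ids, and two inner semicircles encode the orientation.
Decoding these markers from real camera crops is a supervised learning
problem, but labeling crops by hand takes about a minute per image —
covering every id with even 10 examples is months of work.  The way out is
to *generate* labeled training data: a parametric model renders a clean
marker for any code and pose, and a learned chain of image augmentations
makes the render look like a real crop *without being able to change the
code*.  The labels of the generated images are then known by construction,
and a convolutional decoder can be trained on millions of them.

`beetag` implements that pipeline end to end: the parametric renderer, the
differentiable label-preserving augmentation stages, their adversarial
training against an unlabeled corpus, dataset generation with
discriminator-score filtering, hand-designed augmentation baselines, and a
residual-network decoder evaluated on the mean Hamming distance (MHD).

## The marker model

`render_tag()` models the marker as a flat disc (curvature is deliberately
omitted; see *Limitations*): the outer annulus is divided into twelve
30-degree sectors, the inner disc (half the radius) into a white and a
black semicircle.  The disc is rotated in 3D — yaw about the view axis,
then pitch, then roll — and projected orthographically.  Conventions, fixed
once and used consistently by the renderer and the reference decoder:

* pixel coordinates are 0-based, origin top-left, rows increase downward;
* yaw 0 points the marker's north toward row 0; cell 0 starts at north and
  cells proceed clockwise; the white semicircle is the eastern half;
* white = $+1$, black = $-1$, background constant $-1$;
* pitch and roll are limited to $\pm 60^\circ$ so the code stays visible.

Rasterization supersamples $4\times$ and thresholds, so the idealistic
image is exactly binary; softness is the blur stage's job.  The renderer
also returns the background mask $B$ (1 off the marker surface) and a depth
map normalized to $(0, 1]$ on the surface, 0 on background.

`reference_decode()` inverts the model when the pose is known: it averages
the image over each projected code cell and over the two projected
semicircles, and calls a cell white when its mean is closer to the
white-semicircle mean than to the black one.  Because both references are
taken from the same image, the decision is invariant to smooth intensity
shifts and positive scalings — and, in fact, to any affine intensity map,
including negation.  This decoder is the package's label-preservation
oracle: every augmentation and every generated dataset is audited with it.

## The augmentation stages

Four differentiable stages, applied in a fixed order, each restricted so
that the code cannot flip:

1. **Blur** $\phi_{blur}(x, \alpha) = (1-\alpha)(x - b_\sigma(x)) +
   b_\sigma(x)$ with $b_\sigma$ a Gaussian blur, $\alpha \in [0,1]$ per
   image.  The bounded kernel scale ($\sigma = 2$ at 64 px) limits the
   blur; the construction mirrors one level of a Laplacian pyramid.
2. **Lighting** $\phi_{light}(x) = x\, b(s_w) W(x) + x\, b(s_b)(1 - W(x)) +
   b(t)$: smooth multiplicative scalings of the white and black parts plus
   a smooth shift.  $W(x)$ thresholds at 0 (the midpoint of the $\pm 1$
   convention).  Restricting $s_w, s_b \in [0.10, 1]$ keeps black cells
   darker than white cells pointwise.
3. **Background** $\phi_{bg}(x) = x (1 - B) + d\, B$: background pixels are
   replaced wholesale, foreground pixels pass through bit-identically.
4. **Detail** $\phi_{detail}(x) = x + \mathrm{highpass}(d)$ with $d \in
   [-2, 2]$ and a high-pass filter built as image minus blurred image
   ($\sigma = 3.5$), iterated three times to sharpen the cutoff.  The
   filter removes everything at the spatial scale of a code cell and
   larger; the bound on $d$ prevents overwhelming it.  The $[-2,2]$ range
   lets details turn black pixels white, which spotlight reflections need.

Each stage has a hand-derived backward companion (`*_vjp`), so the chain
can sit inside a generator trained by backpropagation.  $W(x)$ is treated
as locally constant by the backward passes (its true derivative is a
measure-zero impulse at the threshold).

**Range enforcement during learning** uses a clip layer: hard clipping to
$[a, b]$ in the forward pass plus an L1 activity penalty $\gamma \lvert x -
a\rvert$ (below) or $\gamma \lvert x - b \rvert$ (above), $\gamma = 15$.
Saturating activations (tanh, sigmoid) at these bounds starve the upstream
network of gradients; the clip passes gradients unchanged inside the
interval while the penalty supplies the corrective gradient outside.  The
penalty is continuous (zero) at both boundaries.

A detail the stage definitions leave open: the smoothing blur $b(\cdot)$
inside the lighting stage reuses the blur-stage kernel ($\sigma_{blur}$;
same kernel family, one fewer tunable).  The spatial resolution at which
the generator predicts the lighting fields, and the treatment of the
shift field $t$ (which the black-darker-than-white argument does not
bound), are adversarial-training concerns discussed below.

**Kernel scales follow the resolution.**  $\sigma = 2$ and $\sigma = 3.5$
are sized for 64-pixel crops, where a code cell is roughly 6 px across.
At 32 px a cell is 3 px and a $\sigma = 2$ blur merges neighboring cells —
empirically the label-preservation rate collapses.  `blur_spec_for()`
therefore scales both sigmas proportionally to the working resolution;
scaled-down runs in this package use it throughout.

## Adversarial training

The generator maps a 64-dimensional standard-normal latent vector to (a)
the marker pose, via a small dense head (`gan_config(pose_source =
"sampled")` alternatively draws the pose uniformly from the configured
ranges), and (b) the augmentation
parameter fields, via a dense–reshape–upsample–convolution trunk.  The
code bits are *not* predicted — they are sampled uniformly and fed to the
renderer, which is what makes every generated image labeled by
construction.  The renderer's depth map is merged into the trunk features
(lighting depends strongly on the marker's orientation in space); the blur
amount is an intermediate feature map reduced to one scalar; the lighting
branch is separate; the background branch sees the trunk features, the
lighting-stage output and the model image; the detail branch sees the
trunk features and the background-stage output.  Every range-bound output
passes through its clip layer, and the summed penalties join the generator
loss.

The rasterizer is piecewise constant in the pose, so its gradient is zero
almost everywhere.  Following the renderer-emulation approach, a small
upsampling network is pretrained to reproduce the renders from (pose,
bits) and then frozen.  During adversarial training the renderer is used
straight-through: the augmentation chain composes on the *exact* render
(so the discriminator always sees exactly the images that generation
later produces), while the frozen emulator supplies the backward path
that carries discriminator gradients into the pose head.  An earlier
variant that composed on the emulator's image during training taught the
generator to compensate for the emulator's residual blur with extra
detail noise — noise that then corrupted the exact-render images at
generation time; the straight-through form removes that train/generate
mismatch.  Emulator pretraining targets a pixelwise mean absolute error
of 0.05 within a configurable step budget (desk-scale budgets typically
stop above it, which only degrades the pose-gradient quality).  The
depth map and background mask are non-differentiable context, and in the
alternative `renderer_mode = "direct"` no emulator is trained at all,
leaving the pose head driven only by the clip penalties.  In all modes
`final_image = compose_augmentations(rendered, aug_params)` holds
exactly at generation time.

Two further desk-scale design choices protect the label guarantee where
a weakly supervised discriminator cannot.  First, the lighting fields
are predicted at quarter resolution and upsampled, so they cannot paint
cell-sized structure that would redraw the code (the field resolution is
deliberately coarse; real lighting varies smoothly).  Second, the shift
field $t$ — for which, unlike $s_w$ and $s_b$, no range restriction can
be derived from the black-darker-than-white invariant — is passed
through its own clip layer (default $[-0.5, 0.5]$, `gan_config(t_clip =
NULL)` restores the unrestricted form).  Realistic lighting shifts are
well inside that bound; without it, a desk-scale run drifts into
in-range-but-undecodable lighting configurations long before the
discriminator learns to reject them.

The discriminator is a DCGAN-family convolutional classifier with the
convolutional depth doubled (a stride-1 layer before every stride-2 layer)
and an extra dense layer before the scalar score — but *without* batch
normalization: with small mixed real/fake batches, train-mode batch
statistics let the discriminator separate the sources from the batch
composition alone, its per-image gradients stop reflecting realism, and
the generator drifts freely (observed as near-zero discriminator loss at
100% accuracy together with a collapsing label audit).  Training is the
standard alternating binary-crossentropy game with Adam
($\beta_1 = 0.5$), starting learning rate 0.0002, decayed by 0.25 in
epochs 200, 250 and 300 (`scheduled_lr()` reproduces this schedule
exactly; desk-scale runs simply never reach the decay epochs).  One
generator forward pass per step serves both updates: the generator
update runs first against the current discriminator, then the
discriminator trains on a balanced batch containing the same fakes.
Training aborts with a diagnostic if either loss turns non-finite.

After training, generated samples are scored by the discriminator and the
lowest-scoring fraction (default 5%) is discarded
(`filter_by_discriminator()`); the generator's occasional high-frequency
failure modes receive reliably low scores, and exactly $\lceil n (1 - f)
\rceil$ samples are retained with ties broken by stable input order.

## Hand-made baselines and the desk-scale "real" corpus

The hand-designed counterparts of the learned effects — sampled blur,
smooth random lighting fields, a random image pyramid background (sums of
nearest-neighbour-upsampled uniform-noise grids), additive radially
decaying spotlights, and Gaussian sensor noise — serve two purposes.
First, the classic baseline comparison: `make_baseline_dataset()` builds
the three stage combinations (all effects hand-made; learned blur+lighting
with hand-made rest; learned background with hand-made rest), so that the
union of applied effects is always the same five.  Second, at desk scale
the hand-made sampler *is* the "real" image distribution
(`hm_corpus()`): no external imagery is needed anywhere in the test
suite.

The exact amplitude distributions of the original hand-made effects are
not published.  The defaults here were chosen once by two requirements:
plausible appearance at 64 px, and a reference-decoder recovery rate of at
least 90%, which `handmade_config()` verifies by Monte-Carlo at
construction time (cached per configuration; a config that fails is
rejected).  Chosen values: lighting fields are blurred white noise with
correlation length $0.25 \cdot$ resolution and amplitude `field_sd` 0.35
squashed into $[0.10, 1]$, shifts up to 0.3, pyramid level scales (0.6,
0.3, 0.15, 0.1), noise $\sigma \in [0.02, 0.08]$, up to two spotlights of
radius 0.12–0.25 and amplitude 0.2–0.5 relative to the tag radius.  A
zero-scale effect is an exact identity, so neutral configurations
reproduce the idealistic render.

What the hand-made corpus does *not* emulate about real hive imagery:
curved marker geometry, perspective, motion blur, occlusion by other bees,
compression artifacts, and correlated illumination across frames.  Tests
passing against this corpus show the machinery is correct and the
label-preservation guarantee holds; they do not certify accuracy on real
hive data.

## Datasets and the decoder

`labeled_dataset` objects pair images with bits and pose; provenance
(source, config hash, seed) is always attached.  On disk (the package's
own compact format — no HDF5 reader exists in this R stack): a magic
string, a JSON header with every array's shape, then raw little-endian
arrays.  Doubles are stored at full 64-bit width, so write–read round
trips are bit-exact; a plain-text JSON variant carries the small shipped
fixture.  Orientation is stored even though the decoder does not use it —
generated data has it for free while real ground truth typically lacks it.

`build_decoder()` is a 34-layer residual network (3-4-6-3 basic blocks)
that starts at 16 feature maps — a quarter of the usual width — with one
sigmoid output per bit and binary crossentropy on the logits.  Training
(`train_decoder()`) follows the epoch structure of 1,000 batches of 128 at
full scale (both configurable); generated data is used as-is (it is
abundant and needs no further augmentation), real data is augmented on the
fly with translation ($\le 4$ px), rotation ($\le 10^\circ$), shear
($\le 5^\circ$), histogram scaling ($\pm 20\%$) and noise
($\sigma \le 0.08$) — bounds chosen as standard mild values since the
original ones are unpublished; a mixed regime interleaves both sources
50:50 within each batch.  Early stopping keeps the weights of the best
validation epoch.  Validation uses a held-out split by default; the
original protocol's reuse of the test set for real-data validation is not
reproduced.  `mhd()` thresholds predictions at 0.5 (a tie counts as a set
bit) and averages the per-tag Hamming distance; chance level for 12
independent bits is 6.

## Numerical choices

* Gaussian kernels are truncated at $3\sigma$ with reflect-padded borders,
  implemented as explicit 1-D blur matrices; their transposes give exact
  adjoints for the backward passes.
* The idealistic render thresholds the supersampled average at 0; a pixel
  is background when more than half its subsamples are.
* Degenerate poses (disc viewed edge-on) are rejected; the pose limit of
  $60^\circ$ keeps the projection well-conditioned.
* Decoder probabilities are clamped into the open interval at machine
  precision: an untrained deep network's eval-mode batchnorm statistics
  can saturate the sigmoid exactly.
* Seeded operations save and restore the caller's RNG state, so library
  calls do not perturb user-level reproducibility.

## Problem sizes used by the tests

The packaged test-suite and acceptance runs use desk-scale sizes, chosen
as the smallest runs that still exercise every mechanism: 32-pixel crops,
a 10,000-image hand-made corpus, 2,000 adversarial steps at batch 8 with a
1,000-step emulator pretrain, 10,000 generated samples (5% discarded), and
brief decoder training (tens of batches at batch 16).  At these sizes the
qualitative results reproduce: generated samples pass the label audit, the
discriminator separates real from generated imperfectly, and a decoder
trained on generated data beats one trained on idealistic renders on a
held-out hand-made test set by a wide MHD margin.  Published full-scale
results (MHD around 0.4 on real imagery) require the real 2.4M-image
corpus and GPU-scale training and are out of scope here.

## Known limitations

* Flat-disc geometry: real markers are curved; the pose-conditional
  appearance differs systematically at large tilts.
* The reference decoder's local-reference trick assumes lighting varies
  smoothly across the tag; adversarially chosen (rather than smooth
  random) in-range fields could defeat it.  The audit is therefore a
  statistical, not adversarial, guarantee.
* Pose gradients flow only through the emulator image; pose-dependent
  effects entering via the depth map and mask are invisible to the pose
  head during training.
* The NN core is deliberately minimal (plain Adam, batchnorm, no
  augmentation-free tricks) and CPU-bound; it is sized for desk-scale
  experiments, not production training.
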