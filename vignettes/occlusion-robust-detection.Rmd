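---
title: "Occlusion-robust pest detection and streaming test-time adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occlusion-robust pest detection and streaming test-time adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestwatch)
```

## The problem

Field images of crop pests are rarely clean: insects hide behind leaves and
each other, and the same detector that works at noon in dry weather is asked
to work in fog, rain, low light, or through a lossy transmission channel.
`pestwatch` implements two complementary answers for small-object detectors:

* a **dual-branch training framework** that teaches a detector to find
  partially hidden objects without paying anything at inference time, and
* a **streaming test-time adaptation (TTA) strategy** that lets a deployed
  detector track changing imaging conditions from unlabeled images alone,
  while protecting itself against catastrophic forgetting.

Both are built around a compact four-stage convolutional detector implemented
from first principles in this package (forward passes and all gradients are
hand-derived and verified against finite differences in the test suite).

## Dual-branch training with gated feature exchange

During training two detector branches with identical architecture run side by
side. The **main** branch receives the clean image; the **auxiliary** branch
receives the same image with 1-3 random rectangles (each covering 10-30% of
the image, gray or noise fill) painted over it. Ground-truth boxes are never
clipped to the occluder: the network is asked to recover the *full* object.

Features are exchanged four times per forward pass, once after each backbone
stage. An exchange sends the sender features `f_x` through a learned gate

```
alpha = Sigmoid(M f_x + a)
f_out = alpha * GELU(N f_x + b) + f_receiver
```

where `M`, `N` are 1x1 channel-mixing convolutions, `*` and `+` are
elementwise, and GELU uses the exact Gaussian-CDF form. Because `alpha` lies
strictly in (0, 1) per channel and position, the gate can smoothly interpolate
between "ignore the other branch" (a plain skip connection) and "trust its
message". The exchanges after stages 1 and 3 are unidirectional (auxiliary to
main only) so that the main branch sees *damaged* features before any
restoration; the exchanges after stages 2 and 4 are bidirectional, computed
from the pre-exchange features of both branches simultaneously.

The auxiliary branch additionally passes its stage-1 and stage-3 features
through a **convolutional autoencoder** (two stride-2 convolutions halving
the channel count to a code with 1/64 of the input volume, mirrored by two
transposed convolutions). The bottleneck forces the branch to re-synthesize
feature content that the occluder destroyed. No explicit reconstruction loss
is attached: the autoencoders train end to end through the detection loss,
and `train_cae()` exists separately as a diagnostic that verifies the block
can learn feature inpainting in isolation.

One SGD step updates all four parameter groups (main, auxiliary,
autoencoders, gates) from the combined loss `L_t = L_main + gamma * L_aux`,
both terms being the detection loss against the shared ground truth. After
training, everything except the main detector is discarded, so test-time cost
is exactly that of a plain detector - the test suite asserts the retained
parameter tree and forward pass are bit-identical to a never-dual-trained
detector carrying the same weights.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.5 | auxiliary-loss weight; 0.5 keeps the main task dominant while still training the auxiliary path |
| `lr0`, `lrf` | 0.015, 0.01 | cosine learning-rate schedule from `lr0` down to `lr0 * lrf` |
| `epochs`, `batch_size` | 50, 16 | training protocol defaults |
| occlusion | 1-3 rects, 10-30% each | the damage distribution the auxiliary branch sees |
| `lambda_cls`, `lambda_bb`, `lambda_conf` | 1, 5, 1 | detection-loss weights; the box term is up-weighted as is common for IoU-based regression |

Fresh occlusion masks are drawn every epoch, so over 30-50 epochs each image
is seen under many damage patterns. Gate biases start at 0 (half-open).

## Streaming adaptation with parameter partitioning

At deployment the trained detector is duplicated into a **teacher** and a
**student**. For every unlabeled stream image:

1. The teacher predicts on the original image (*proxy labels*) and on `X = 8`
   augmented views (flips, rotations up to 10 degrees, scale 0.9-1.1, small
   translations, brightness/contrast jitter, mild blur). View boxes are
   mapped back into original coordinates; for each proxy box the highest-IoU
   view box is matched (IoU > 0.1, else the proxy's own values substitute).
2. Per-detection **certainty matrices** summarize cross-view agreement:
   `Mu[i,j] = exp(-1/(X-1) * sum_x (p~ - p_bar)^2)` over the four box corners
   (coordinates normalized by the image size so the exponent is scale-free)
   and `Mc[i,n] = exp(-1/X * sum_x (-c_bar * log c~))` over the classes,
   concatenated into `M`. A value of 1 means perfect agreement (for the class
   block, exactly 1 only for one-hot probabilities). Detections whose mean
   certainty falls below 0.5 are dropped from the pseudo-label set.
3. The student takes one gradient step of size `eta = 0.001` on the detection
   loss against the surviving pseudo-labels, with the gradient multiplied
   elementwise by a binary mask `b`: only *domain-sensitive* coordinates
   move. The emitted detections come from the updated student.
4. The teacher receives an **isolated EMA** update with momentum `mu = 0.85`:
   masked (domain-sensitive) coordinates keep their value exactly, the rest
   take the classical EMA toward the student.

The mask comes from a diagonal Fisher-information approximation: per-image
squared gradients of the detection loss under teacher pseudo-labels are
averaged over a 64-image window, normalized onto [0, 1], and thresholded at
`tau = 0.3` (strictly greater). The mask starts as all zeros, so the first
window behaves exactly like the frozen model, and is refreshed every 64
images.

### Why quantile-rank normalization

The thresholding rule needs the importances on a scale where 0.3 means
something. Averaged squared detection gradients span roughly ten orders of
magnitude, so a plain min-max map sends all but a handful of coordinates to
values near 0: at `tau = 0.3` the "domain-sensitive" set then contains a few
dozen out of ~80,000 coordinates and the whole adaptation machinery is
vacuously idle. The default here is therefore the **quantile rank**
`K_hat = (rank(K) - min rank) / (max rank - min rank)`, which spreads the
importance distribution evenly over [0, 1]; `tau = 0.3` then marks the top
70% of coordinates by Fisher importance as domain-sensitive. Plain min-max
remains available via `normalization = "minmax"`. For a two-parameter model
the two conventions coincide.

Two structural consequences of the literal update rules are worth noting.
First, because the student only moves masked coordinates and the teacher's
EMA only moves unmasked ones, the teacher changes *only when the mask
changes* between refresh windows - without refresh it would be a global fixed
point. Second, substituting proxy coordinates for unmatched views gives those
views *zero* deviation, i.e. maximal certainty; an optional
`unmatched = "penalty"` mode inverts this, but the literal substitution rule
is the default.

Two further numerical choices: student gradients get the same global-norm
clip (10) as the training loops, since single-image detection gradients are
an order of magnitude larger than batch-averaged ones and `eta` is calibrated
for the clipped scale; and the detector carries no batch-normalization state,
so the masked gradient and EMA updates are the *only* mutable state - the
isolation invariants are checked bitwise over 100-step streams in the tests.

## The synthetic scene generator

Real pest imagery cannot ship with a package, so all experiments run on
generated scenes: textured green-brown backgrounds (bilinear-interpolated
coarse noise) with 2-5 elliptical pest-like sprites per 96 px image, each
class carrying a distinct color and mottled texture, with tight boxes from
the drawn mask. Sprite centers keep a minimum distance of 18 px, roughly one
head cell, so center-cell target assignment stays well posed. Nine
environmental corruptions are implemented with a five-level severity ladder:
fog (convex blend toward white), rain and snow (seeded streak/flake
stamping), brightness and darkness (multiplicative gain; gain 1 is the exact
identity), additive Gaussian noise, salt-and-pepper pixel flips, linear-kernel
motion blur, and a real JPEG encode/decode round trip. The ladders were
calibrated once so that severity 3 visibly degrades but does not obliterate a
trained detector (fog's blend coefficient was softened for this reason); the
severities are generator properties, not tuned experiment knobs.

What the generator does *not* emulate: natural occlusion by foliage (its
occluders are rectangles), object scale variation beyond ~2x, class
imbalance, background clutter resembling pests, and label noise. Passing the
package's directional experiments therefore demonstrates that the training
framework and adaptation loop behave as designed on controlled scenes - not
that they reach any particular accuracy on real field imagery.

## Desk-scale study conditions

The two built-in experiments (`experiment_maf_gain()`, `experiment_saodl()`)
use 400 training scenes at 96 px for 30 epochs, 100 occluded test scenes, and
nine sequential corruption regimes of 50 images each, with a detector of
about 78k parameters - sizes chosen so a complete run takes minutes on one
CPU core while keeping several hundred objects in every evaluation. The
detector head works on a single 6x6 grid (stride 16), which suffices for
sprites of 7-22 px; `decode()` uses class-agnostic greedy NMS, and
evaluation decodes at a 0.05 confidence floor so average precision sees the
full ranking while the reported precision/recall point uses 0.25.

## Known limitations

* The detector is deliberately small and single-scale; crowded scenes with
  more than one object per 16 px cell lose assignments.
* `1 - IoU` box regression has zero gradient for disjoint boxes; the head's
  box-size prior keeps early boxes large enough to overlap their targets.
* The dual-branch occlusion benefit is regime-dependent on these synthetic
  scenes: when training is under-converged the dual-branch model consistently
  outperforms the plain baseline on occluded tests, but once the momentum
  optimizer drives training to convergence the gap falls within seed noise
  (the acceptance experiments report both arms so this can be inspected
  directly). The tutoring channel is indirect - occlusion pressure reaches
  the retained main weights only through the gated exchanges and the shared
  loss - and the easy, fully converged synthetic task leaves it little to
  add.
* Adaptation gains at this scale are small; with the literal isolated
  student/teacher updates the teacher changes only through mask churn, so
  pseudo-label quality is fixed at source level and 50-image regimes at
  `eta = 0.001` mostly demonstrate stability (no material degradation,
  bitwise isolation) rather than accuracy recovery. The relative ordering of
  regimes - larger adaptation deltas on the noise/blur corruptions than on
  the photometric ones - does reproduce.
* The class-certainty term is a cross-entropy, so it equals 1 only for
  one-hot agreement; well-calibrated soft predictions always carry a small
  apparent uncertainty.

## A minimal session

```{r, eval = FALSE}
scenes <- generate_scenes(64, image_size = 96, classes = 3, seed = 1)
cfg <- maf_config(epochs = 10, seed = 1)
fit <- train_maf(scenes, cfg)

test <- lapply(generate_scenes(32, 96, 3, seed = 2), occlude,
               spec = occlusion_spec(seed = 3))
evaluate(fit$detector, test)

stream <- lapply(generate_scenes(40, 96, 3, seed = 4), corrupt,
                 kind = "gaussian_noise", severity = 3)
adapted <- adapt_stream(fit$detector, stream, adapt_config(seed = 5))
plot_adaptation_log(adapted$log)
```
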