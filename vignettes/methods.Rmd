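---
title: "Automatic augmentation-policy search for cavity segmentation: models, search, and phantom design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic augmentation-policy search for cavity segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(autoaugseg)
```

## The problem

Fluid-filled schisis cavities in retinal OCT B-scans are the segmentation
target in X-linked juvenile retinoschisis (XLRS). Their area is a disease
marker, but their appearance varies strongly across patients, devices and
acquisition settings, and cohorts are small (a rare disease). Data
augmentation is therefore not a garnish here but a first-order modelling
decision: which image transformations, at which strength, with which
probability?

`autoaugseg` treats that decision as a search problem. A recurrent policy
controller proposes *augmentation strategies* — five *sub-strategies*, each
a pair of image operations with a discretized magnitude and application
probability — a *child* segmentation network is trained under the proposed
strategy, and the child's loss on held-out validation patients, negated, is
the controller's reward. The controller is updated by proximal policy
optimization (PPO). After the search, the sub-strategies of the five
highest-reward strategies are concatenated into one 25-sub-strategy policy
used to train the final models.

Formally the search solves a bilevel problem: the outer level picks the
strategy $F$, the inner level trains model parameters $\omega$ on the
augmented training set,

$$F^* = \arg\min_{F} \; L\!\big(\arg\min_{\omega} L(M_\omega, F(D_{train})),\; D_{valid}\big),
\qquad D_{train} \cap D_{valid} = \emptyset ,$$

with the disjointness enforced at the *patient* level.

## The search space

Sixteen operations make up the space (`op_table()`): ShearX/Y, TranslateX/Y,
Rotate, Horizontal/Vertical Flip (geometric — they move pixels, so the mask
is transformed with identical parameters), and Color, Posterize, Solarize,
Contrast, Sharpness, Brightness, AutoContrast, Equalize, Invert
(photometric — intensity-only, the mask is returned bit-exact). Each
operation's magnitude range is divided into **ten** equally spaced levels and
its application probability into **eleven** levels ($\phi \in \{0, 0.1,
\dots, 1\}$). One sub-strategy therefore lives in a space of
$(16 \times 10 \times 11)^2 = 3{,}097{,}600$ configurations, and a
five-sub-strategy strategy in $(16\times10\times11)^{10} > 10^{32}$.

Choices the operation table leaves open, and what this package does:

* **Signed ranges** (shear $[-0.3, 0.3]$, translate $[-150, 150]$ px, rotate
  $[-30, 30]^\circ$) are mapped linearly across the full signed range
  (level 0 = minimum, level 9 = maximum); there is no random sign flip.
* **Enhancement factors.** Contrast, Brightness, Sharpness and Color use the
  PIL convention (factor 0 = fully degenerate, 1 = identity) with the level
  mapped directly into the printed $[0, 0.9]$ range. Note this makes these
  ops strictly "weakening" at every level — the printed upper bound is 0.9,
  not $1\pm m$.
* **Grayscale Color.** A saturation blend is mathematically the identity on
  a single-channel image. The operation is retained for fidelity to the
  16-operation space; selecting it is equivalent to a no-op.
* **Solarize** threshold is the magnitude itself in $[0, 256]$; **Posterize**
  keeps an integer-rounded number of bits in $[4, 8]$.
* **Geometric fill** is intensity 0 / background class (OCT backgrounds are
  dark); masks are warped with nearest-neighbour sampling and re-binarized
  at 0.5, so they stay strictly binary.
* **Translate units** are pixels at the native 512 px scan width and scale
  proportionally when images are resized for desk-scale runs.
* **Equalize** uses the classic CDF-based histogram-equalization LUT;
  **AutoContrast** stretches the full observed range (0% cutoff).
* A serialized policy may carry a `null` magnitude for a magnitude-bearing
  operation (this occurs in published policy tables); it resolves to the
  midpoint of the operation's range at application time.

## Segmentation models

Four encoder–decoder architectures are provided (`build_seg_model()`):
plain U-Net, U-Net++ (nested dense skip connections), Attention U-Net
(additive attention gates on the skips), and Residual U-Net (residual
blocks whose shortcut bypasses the two convolutions). All are fully
convolutional: a 1-channel $H\times W$ image in $[0,1]$ maps to 2-channel
class scores at the same resolution; input sides must be divisible by
$2^{depth}$.

Because no deep-learning framework is available to R here, the models run on
a compact reverse-mode autodiff tape implemented in the package
(`R/autodiff.R`): im2col convolutions via BLAS matrix products, 2×2 max
pooling, 2×2 stride-2 transposed convolutions, instance normalization,
attention gating, and a fused softmax + hybrid-loss node with an analytic
gradient. Every operator's gradient is verified against central finite
differences in the test suite.

Design choices:

* Blocks are two 3×3 convolutions, each followed by normalization and ReLU
  (He-style initialization, deterministic under the build seed).
* Normalization is a knob: `"instance"` (default) or `"none"`. True
  cross-batch batch normalization is not implemented because mini-batches
  are processed sample-by-sample on the tape; instance normalization is the
  per-sample analogue. **Caveat that matters for the search:** instance
  normalization makes the network almost invariant to global affine
  intensity changes, which *removes the very signal a photometric
  augmentation search feeds on*. The desk-scale search preset therefore
  uses `norm = "none"`, which mirrors the shift sensitivity of full-scale
  batch-norm models evaluated with training-set running statistics.
* U-Net++ deep supervision is off; the head reads the topmost, rightmost
  node.
* The attention gate computes
  $\sigma(\psi\,\mathrm{ReLU}(W_x x + W_g g))$ with the gating signal $g$
  taken from the upsampled decoder feature at the skip's resolution.
* Default full-scale geometry is depth 4 / 32 base channels (for 512 px
  scans); the desk preset is depth 2 / 8 channels at 64 px.

## Loss and metrics

Training minimizes the hybrid loss
$L = \tfrac12 L_{CE} + \tfrac12 L_{Dice}$ with
$L_{CE} = -\frac1N \sum_{i}\sum_{j} p_{ji} \log q_{ji}$ over classes $i$
and pixels $j$, and
$L_{Dice} = 1 - \frac{2\sum y\hat y + \alpha}{\sum y + \sum\hat y + \alpha}$
computed on the foreground channel only. $\alpha$ (default 1, configurable)
keeps the Dice term defined in the all-empty edge case, where the loss is
exactly 0. Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ inside the
logarithm.

Evaluation (`compute_metrics()`) reports precision, recall (sensitivity),
specificity, Dice $= 2TP/(2TP+FP+FN)$, Jaccard $= TP/(TP+FP+FN)$ (so
$J = D/(2-D)$ identically), and **two accuracy variants**: overall pixel
accuracy $(TP+TN)/N$ — the headline value — and the class-average form
$\frac12(TP/(TP{+}FN) + TN/(TN{+}FP))$. Both are kept because the printed
class-average definition cannot reach the accuracy magnitudes commonly
reported alongside recall values near 0.85, which indicates overall pixel
accuracy is what such tables actually show; the package asserts neither
interpretation and reports both. Zero-denominator metrics resolve to 1 when
the corresponding error count is zero (else 0) and the record is flagged
`degenerate`.

Cross-validated comparisons (`compare_runs()`) use a two-sided **Welch**
two-sample t-test per metric. The equal-variance flavour is deliberately
avoided: the two runs are independently trained model families and there is
no reason to assume a common variance. Identical zero-variance samples are
reported as $p = 1$ and flagged.

## The controller and its update

The controller is a single-layer LSTM with 100 hidden units; parameters are
initialized uniformly in $(-0.1, 0.1)$. A strategy is 30 categorical
decisions in a fixed cycle — operation (16-way), magnitude level (10-way),
probability level (11-way), repeated for the 10 operation slots. Each
step's chosen token is embedded, summed with a vocabulary-type embedding
(so the three vocabularies do not collide), and fed as the next LSTM input.
Prediction heads are a shared fully connected trunk followed by a per-vocabulary
output layer — two fully connected layers per prediction.

The update is PPO-clip on the joint 30-step log-probability: ratio
$r = \exp(\log\pi_\theta(a) - \log\pi_{old}(a))$, objective
$\min(rA, \mathrm{clip}(r, 1\pm0.2)A)$ plus an entropy bonus (weight
$10^{-5}$), three epochs per update over a buffer of the last 10
(strategy, reward) pairs, one new pair per search iteration. The advantage
$A$ is the reward minus an exponential moving-average baseline (decay
0.95), then standardized within the update batch — the usual PPO
normalization, which makes the update size independent of the reward's
units (validation losses move in hundredths here, and un-normalized
advantages of that size would leave the controller effectively static over
a short horizon). The clip value, epoch count, buffer size, baseline and
normalization are package defaults, disclosed in `controller_config()` —
the source protocol names PPO but none of these constants. A plain REINFORCE mode exists solely as
the reference implementation for the analytic gradient checks in the test
suite.

Learning rates: the full-scale default is $4\times10^{-4}$, tied to a
1000-iteration horizon. The desk preset (`desk_controller_config()`) uses
0.02 for 30-iteration searches — with 30 updates instead of 1000, a
proportionally larger step is needed for the controller to move at all; the
value was fixed when the preset was designed.

## The search loop

Per iteration: sample a strategy; **freshly initialize** the child (the
bilevel objective evaluates a strategy by what a model trained under it
achieves, not by what a warm-started model drifts to); train for E epochs,
drawing one sub-strategy uniformly per mini-batch and applying it to the
whole batch; compute the hybrid validation loss (the "evaluation loss" is
not named in the source protocol; the training loss function is the natural
choice); set reward = −loss; PPO-update. The trace (iteration, strategy,
reward, validation loss) is persisted incrementally when a path is given.

Child initialization and training use **common random numbers**: every
iteration re-initializes and trains the child under the same derived RNG
stream (fresh parameters each time, common seed). At desk scale the spread
of validation losses across child initializations is comparable to the
effect of the augmentation strategy itself; evaluating all strategies under
a common stream removes that nuisance variance from the reward, which both
the PPO update and the top-5 consolidation depend on. The controller's own
sampling stream is kept separate and is not affected.

"Top five strategies" for consolidation is read as top-5 by reward over the
whole trace (not the last five), with ties broken toward the earlier
iteration.

The full-scale budget (T = 1000, E = 200) is GPU-scale arithmetic; the
package keeps those values as documented defaults of `search_config()` and
provides `desk_search_config()` — T = 30, a depth-2/8-channel child, E =
10, batch 4, Adam $3\times10^{-3}$, 64 px phantoms — which completes a full
search in roughly ten CPU-minutes. These are the problem sizes used by the
package's own end-to-end tests and by `scripts/acceptance.R`.

## The phantom generator

`generate_phantom()` emulates the *structure* of the clinical cohort: 30
patients × 2 eyes × 25 consecutive B-scans (1500 images) by default. Each
eye draws latent geometry — a smoothly curved stack of alternating bright
and dark tissue bands on a dark background — and 1–4 elliptical
hypo-reflective cavities placed inside one designated band (emulating the
strong predilection of cavities for particular retinal layers). Cavity
size follows a smooth envelope across the scan index and the center drifts
slowly, so cavities appear in consecutive scans (adjacent-scan mask Dice ≥
0.5 on average — the package's measurable proxy for cross-scan coherence).
On top: multiplicative gamma speckle (mean 1, SD = `speckle`), occasional
dark vertical vessel shadows, and per-eye brightness/contrast factors
emulating acquisition variability. A `geometry_jitter` knob scales how much
the band geometry varies across eyes: at 1 (default) every eye draws its
own retina position, thickness, curvature and band widths; at 0 all eyes
share one band geometry (cavities still vary per eye). The domain-shift
experiments set it low (0.2) so that the train/validation gap is carried
almost entirely by the photometric factors, which is the condition the
qualitative photometric-dominance finding speaks to.

What the phantom does **not** emulate: real retinal texture and
layer-specific reflectivity, device-specific speckle statistics, motion
artifacts, pathology other than cavities, annotation ambiguity. Passing
tests on phantoms therefore demonstrates that the pipeline's mechanics —
mask-consistent augmentation, patient-level isolation, reward bookkeeping,
policy learning — are correct, not that the clinical performance figures
transfer.

A deliberately constructed *photometric domain shift* (training eyes at
nominal brightness/contrast, validation eyes darker and flatter) is the
test bed for the search's qualitative behaviour: under such a shift the
highest-reward strategies are dominated by photometric operations, echoing
the finding that geometric transformations are rarely selected for OCT,
where inter-acquisition variability is photometric rather than geometric.

## Numerical choices and degenerate inputs

* Probability draws: `apply_op` consumes the R RNG only when
  $\phi > 0$; level 0 returns the input bit-exact without advancing the
  stream's transformation state (the identity strategy is exactly
  augmentation-off).
* Warping uses inverse mapping with bilinear sampling for images (exact for
  integer translations and flips) and nearest-neighbour for masks.
* Max-pool gradient ties route to the first position in the 2×2 window.
* Validation-loss rewards must be finite; `NaN` rewards reject the update.
* `make_splits` rounds the validation patient count to the nearest integer
  (minimum 1); both eyes of a patient always share every assignment because
  assignment is by patient id.
* Child training aborts with a diagnostic on a non-finite training loss.

## Known limitations

* Pure-R training is ~3 orders of magnitude slower than a GPU framework;
  the full-scale preset is documentation, not a practical budget here.
* Instance normalization vs. true batch normalization (above) is the one
  architectural place where the package deviates from common full-scale
  practice, with a documented consequence for photometric search signal.
* TransUNet-style ViT hybrids and published third-party baselines are out
  of scope; the comparison machinery (`compare_runs`) is general, the
  reference models are not bundled.
* The phantom's realism knobs are calibrated qualitatively (they are
  measurable — e.g. heavier speckle demonstrably lowers test Dice — but not
  fitted to any real dataset).
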