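---
title: "Sprint convolutional segmentation of blastocyst components: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sprint convolutional segmentation of blastocyst components: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sssnet)
```

## The problem

Day-5 human embryos (blastocysts) are graded before in vitro fertilization
transfer by the morphology of four components: the zona pellucida (ZP), the
outer glycoprotein ring whose thickness correlates with implantation
success; the trophectoderm (TE), the cell band lining the ZP that will form
the placenta; the blastocoel (BL), the fluid cavity whose formation marks
the blastocyst stage; and the inner cell mass (ICM), the cell cluster on
one side of the cavity that becomes the fetus.  Hoffman Modulation Contrast
microscopy renders these components at low contrast under non-uniform
illumination, and TE and ICM in particular occupy nearly the same gray
range, so multi-class pixel-wise segmentation is the natural computational
formulation: given an RGB micrograph, assign each pixel one of five classes
(background, ZP, TE, BL, ICM).

This package implements a complete, self-contained train/evaluate loop for
that task: a compact encoder--decoder convolutional network built from
*sprint convolutional blocks*, a Tversky training objective for
class-imbalanced masks, a pooled multiclass Jaccard evaluation protocol,
the paired augmentation pipeline, error-overlay rendering and mask
morphometrics, plus a synthetic blastocyst phantom generator that provides
images with exact ground truth so everything is testable without any
external dataset.  The convolutional core (convolutions, transposed
convolutions, batch normalisation, Adam, and reverse-mode differentiation
through the whole graph) is implemented inside the package in
C++/RcppArmadillo; all heavy arithmetic is BLAS.

## The network

### Sprint convolutional blocks

A sprint convolutional block (SCB) with input $I_i$ computes five branches:

* $G_i = \mathrm{Conv}_{1\times 1}(I_i)$, a point-wise feature shared by
  three spatial branches;
* $K_{iA} = \mathrm{Conv}_{1\times 3}(G_i)$ and
  $K_{iB} = \mathrm{Conv}_{3\times 1}(G_i)$, the asymmetric-kernel pair,
  concatenated into $DA_i = K_{iA} \,\|\, K_{iB}$ and passed through batch
  norm and ReLU to give $DA_i'$;
* $L_i = \mathrm{Conv}_{3\times 3}(G_i)$, batch norm + ReLU giving $L_i'$;
* $F_i = \mathrm{ConvSep}(I_i)$, a depth-wise $3\times 3$ convolution
  followed by a point-wise $1\times 1$ (the standard separable
  factorisation), batch norm + ReLU giving $F_i'$.

The second-stage concatenation $DB_i = DA_i' \,\|\, L_i' \,\|\, F_i'$ is
compressed by an end $1\times 1$ bottleneck, batch norm and ReLU into the
block output.  Factorising $3\times 3$ kernels into $1\times 3$ + $3\times
1$ pairs and using the separable branch for spatial information imported
directly from the block input is what keeps the parameter count low while
aggregating features of several receptive fields.

All convolutions use same-padding, so an SCB never changes spatial size.
Convolutions feeding a batch-norm layer carry no bias (it would be absorbed
by the shift parameter); the point-wise $G$ convolution and the final
classification head, which are not normalised, do carry biases.  This bias
policy is part of the parameter accounting below.

### Encoder, bridge, decoder

The encoder stacks four SCBs with three strided $3\times 3$ convolutions
(stride 2) between them, placing the bottleneck at 1/8 of the input
resolution; learned strided downsampling is used instead of pooling to
avoid discarding spatial detail.  A bridge of four $3\times 3$
convolutions deepens the bottleneck features.  The decoder is deliberately
shallow: three transposed convolutions (kernel $4\times 4$, stride 2 --
chosen over $3\times 3$/stride 2 to avoid checkerboard artifacts) restore
the input resolution, and after each upsampling the decoder feature is
merged with the encoder feature of matching resolution (the feature
entering each strided convolution):

* **residual** variant: the upsampled feature passes a $1\times 1$
  convolution, the skip feature passes a $1\times 1$ projection + batch
  norm, and the two are added element-wise before the ReLU;
* **dense** variant: the upsampled and skip features are concatenated
  depth-wise and projected back to the stage width by a single $1\times 1$
  convolution + batch norm.

The two merges span the same linear family and are sized so that the
variants have *identical* trainable parameter totals; they differ in where
normalisation is applied and therefore in training dynamics.  (In the
residual merge the batch norm sits on the skip projection only -- the
upsampled operand is already normalised -- which is the one deliberate
deviation from the "batch norm after every convolution" rule; it is what
makes the parameter totals of the two variants agree exactly.)

A final $1\times 1$ convolution with one filter per class plus a per-pixel
softmax produces the five-channel probability mask; the arg-max (ties
broken toward the lowest class index, deterministically) gives the label
map, and binarising the arg-max gives the five one-hot masks.

### Width schedule and parameter budget

The per-stage channel widths are not uniquely determined by the
architecture's printed aggregate (4.04 million trainable parameters), so
the package fixes a single *reference schedule*, found by a scripted search
over monotone width schedules to land on that aggregate exactly: SCB inner
widths 40/68/84/108 (each SCB's output is twice its inner width),
channel-preserving strided convolutions, a 216-channel bridge, and decoder
widths 168/136/80 mirroring the encoder.  `referenceNetworkSpec()` builds
it; `countTrainableParameters()` sums every kernel, bias and batch-norm
scale/shift over the instantiated arrays:

```{r}
net <- buildNetwork(referenceNetworkSpec("dense"), seed = 1)
countTrainableParameters(net)
```

Both variants count 4,039,980 parameters, i.e. 4.04 M at two decimals.  A
FLOP estimate (one multiply--add counted as two operations, convolutions
only) is available via `countTrainableParameters(net, inputSize = c(H, W))`;
it is reported for transparency but not asserted against any published
figure, because published FLOP counts rarely state the input resolution or
the multiply--add convention.

`compactNetworkSpec()` is the same topology at inner widths 8/12/16/24
(175,380 parameters).  It exists because a 4-million-parameter network is
needlessly slow for CPU-scale demonstrations and tests; all structural
properties (shape contracts, variant parameter equality, gradient flow)
hold for any schedule, and the package's training demonstrations and tests
use the compact schedule at 128 x 128 pixels.

## The training objective

Class frequencies are heavily imbalanced (background dominates; ICM is
small), so training minimises a Tversky loss rather than cross-entropy.
For class $c$ with predicted probabilities $p_{ic}$ and binary ground truth
$g_{ic}$,

$$T_c = \frac{\sum_i p_{ic} g_{ic} + \omega}
  {\sum_i p_{ic} g_{ic} + \omega
   + \alpha \sum_i (1 - p_{ic}) g_{ic}
   + \beta \sum_i p_{ic} (1 - g_{ic}) + \omega},$$

and the loss is $1 - \frac{1}{5}\sum_c T_c$.  The printed form of this
objective in the source literature is the index itself (equal to 1 at a
perfect prediction); a quantity to be *minimised* must be its complement,
which is what the package implements.  $\alpha$ weights false negatives
and $\beta$ false positives, with $\alpha + \beta = 1$ enforced; the
defaults $\alpha = 0.7, \beta = 0.3$ push the network to recall small
structures (ICM) at the cost of some precision.  At $\alpha = \beta = 0.5$
and binary predictions the index reduces to the Dice coefficient, which the
test suite uses as an independent closed form.  The smoothing constant
$\omega$ guards empty masks; its magnitude is not prescribed anywhere, so
the package uses $10^{-6}$, small enough not to bias any mask larger than a
few pixels.  The index is aggregated per class over all pixels of the batch
and averaged over classes *before* the complement; the per-class-then-mean
order matters for imbalance and is the package's reading of an objective
written for a single foreground.

Optimisation follows the reference protocol: Adam with constant learning
rate $10^{-4}$ and $\epsilon = 10^{-6}$, mini-batches of 20 images, 11,200
iterations at full scale (with 3,200 training pairs that is exactly 70
epochs of 160 iterations), and gradient clipping. The clipping phrase in
the protocol ("global L2 normalisation") names the threshold family but no
value; the package clips the global L2 norm of the full gradient at 1.0.
No learning-rate schedule is applied ("initial learning rate" with no decay
stated).  Batch order is a fresh permutation per epoch under the
configuration seed, making runs bit-reproducible on a given BLAS.

## Evaluation protocol

At test time the per-class Jaccard index is computed from pixel confusion
counts, $JI_c = TP_c / (TP_c + FP_c + FN_c)$, and the mean JI is the
unweighted mean over the five classes.  (The printed formula in the source
carries an evident typo -- the denominator lists FP twice -- and the
surrounding definitions of FN and FP make the intended intersection-over-
union unambiguous.)  Two conventions are fixed here: confusion counts are
**pooled over all test pixels** before the ratio (not averaged per image),
because the definition is stated in pixel counts; and a class absent from
both prediction and ground truth scores $JI_c = 1$ with an `absent` flag in
the report, so that correctly-empty classes are not penalised.  Validation
monitoring during training is carved from the training split (or supplied
explicitly) -- never from the test set.

## The phantom generator

`generatePhantom()` draws a blastocyst-like scene with exact ground truth:
a bright ZP annulus (optionally elliptic) around a TE band textured as a
ring of overlapping cell-like discs, the BL cavity inside, and an ICM disc
carved out of the cavity so that it touches the TE band at a configurable
angle.  The image is the per-class base gray level plus a planar
illumination ramp of configurable amplitude and direction, plus Gaussian
noise, clipped to [0, 255] and replicated to RGB with small per-channel
offsets (HMC images are near-gray; this keeps the three-channel input
contract).  The ground truth is computed from the geometry *before* noise,
so it is exact by construction.

Default appearance parameters (background 95, ZP 185, TE 130, BL 70 on the
0--255 scale, ICM = TE + 6, illumination amplitude 20, noise sd 8) were
chosen once to reproduce the qualitative difficulties of the real imagery
-- low contrast, a TE/ICM pair separated by less than the noise amplitude,
and an illumination ramp comparable to class contrasts -- and are not tuned
thereafter.  `generateDataset()` samples geometry uniformly from
documented relative ranges under per-item derived seeds and records every
draw in a manifest.

What the phantoms deliberately do **not** model: optical shear shadows of
HMC, out-of-focus TE cells, debris and fragmentation, ZP thinning
asymmetry, and the texture statistics of real cytoplasm.  Passing the
training property on phantoms therefore demonstrates that the
implementation can fit and generalise on a structurally faithful task; it
does not certify performance on real blastocyst imagery.

## Augmentation

The augmentation plan is a fixed list of 16 paired transforms -- three
flips, six small rotations ($\pm 5^\circ, \pm 10^\circ, \pm 15^\circ$),
six translations ($\pm 10$ px axis-aligned and two diagonals), and one
flip+rotation combination -- so 200 source pairs yield exactly 3,200
transformed pairs; the originals are not included in the count.  The
transformed copies replace nothing: the choice that 3,200 = 200 x 16
consists purely of transformed copies is the package's reading of an
augmentation whose exact recipe is cited to an unavailable external
reference; only the operation families (flip, translate, rotate) and the
totals are fixed by the protocol.  Images are resampled bilinearly with
clamp-to-edge; label maps use nearest-neighbour sampling (labels are never
interpolated into new classes) with exposed borders filled with the
background class, and every output records its source index and transform
name as provenance.

## Morphometrics and error overlays

From a predicted label map the package computes the quantities an
embryologist reads off the masks: per-class pixel areas and image
fractions, ZP thickness, blastocoel presence, and per-class centroids (the
package's neutral reading of component "position").  ZP thickness is
estimated as twice the mean distance-to-boundary along the medial axis of
the ZP region -- the ridge of the Euclidean distance transform, with a half-
pixel correction for the pixel-centre-to-boundary offset -- plus a
per-angle radial-extent profile; the estimator is validated on analytic
annuli to within one pixel.  Blastocoel "presence" is a thresholded area
fraction (default 1% of the image), a tool parameter rather than a
clinical criterion.

The error overlay follows the established convention: agreeing pixels wear
their class color (ZP green, TE red, BL yellow, ICM blue, background
black); disagreeing pixels over ground-truth foreground are pink (a false
negative for that component); disagreeing pixels over ground-truth
background are black (a false positive).  Black doubles as the background
class color, an ambiguity inherited from the convention itself; false
positives are therefore only distinguishable over ground-truth background,
which is exactly where they are defined.

## Numerical choices and degenerate inputs

* Batch norm: statistics over (H, W, batch) per channel, $\epsilon =
  10^{-5}$, running statistics updated with momentum 0.1 and used at
  inference.
* Initialisation: He-uniform for all convolution kernels (fan-in of the
  forward operation), batch-norm scale 1 / shift 0, zero biases, all under
  a single seed; two builds with the same seed are identical.
* Arg-max ties in prediction and one-hot decoding resolve to the lowest
  class index and are flagged when the input was not strictly one-hot.
* Inputs whose height or width is not divisible by 8 are rejected with an
  error naming the divisor; the library never resizes silently (the
  command-line tool may resize explicitly and records the original size).
* Ground-truth color decoding uses nearest palette color with a Euclidean
  tolerance (default 10 of 255, absorbing anti-aliased edges); any pixel
  beyond tolerance is an error listing offending coordinates and colors.
* Non-finite scores or losses abort with a diagnostic naming the batch.

## Scale of the shipped demonstrations

The test suite and the acceptance script run entirely on synthetic
phantoms at desk scale, sized so the whole suite completes in minutes on a
single CPU: structural checks use a four-level toy schedule; the learning
demonstration trains the compact schedule on 64 phantoms of 128 x 128
pixels with the reference optimiser configuration for 300 iterations
(far below the full protocol's 11,200), evaluating on 16 held-out
phantoms.  The compact width was picked over an even narrower one because
it reaches a given held-out accuracy in several-fold fewer optimisation
steps, which more than repays its higher per-step cost on a CPU.  Full-scale training (the
reference 4.04 M-parameter schedule, 3,200 augmented pairs, 11,200
iterations) uses exactly the same code path via `trainConfig()` defaults
and the command-line tool, but is a multi-hour CPU run and is not exercised
by the tests.  Published Jaccard scores on the real 235-image blastocyst
dataset are not reproducible here -- they require the external dataset and
GPU-scale training -- and are replaced throughout by the phantom learning
property.

## Known limitations

* The engine is CPU-only and double-precision; throughput is adequate for
  the compact schedule and desk-scale experiments, not for full-scale
  training runs, which remain possible but slow.
* The exact per-layer widths of the original architecture are not public;
  the reference schedule reproduces the printed parameter total, not
  necessarily the original layer-by-layer allocation.
* The skip-connection endpoints (one per resolution level, from the
  feature entering each strided convolution) are the standard reading of a
  coarse architecture diagram, not a published table.
* Phantoms are statistical stand-ins; see the generator section for the
  real-data features they do not emulate.
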