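---
title: "Sparse residual networks for multi-label OCT classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse residual networks for multi-label OCT classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A retinal OCT B-scan can show several pathologies at once: drusen deposits
(age-related macular degeneration, AMD), a thin scar-tissue membrane on the
inner retinal surface (epiretinal membrane, ERM), and intraretinal fluid
cavities (macular edema, ME). Clinically useful automation therefore has to
be *multi-label*: each image receives a binary mark per disease, plus an
explicit Normal output that is 1 exactly when no disease is present. `octsrn`
implements a compact convolutional family for this task — the sparse residual
network (SRN) and its dual-branch multi-scale variant (MS-SRN) — together
with the training loop, diagnostic metrics, Grad-CAM interpretation, and a
synthetic phantom generator that makes the whole pipeline testable without
clinical data.

## The SRN family

An SRN is six convolutional blocks with channel widths
32/32/64/128/256/512. The stem block is a single 7×7 convolution; every
other convolution is 3×3 (larger kernels are "factorized" away: one 5×5 is
replaced by two stacked 3×3 layers with the same receptive field, shrinking
that unit's weights by 18/25 and its per-position multiply–accumulate cost
by the same factor; `substitute_kernels()` applies the rule in either
direction). Each convolution carries a bias and is followed by a rectifier;
each block is followed by a 2×2 stride-2 max-pool (floor mode, so sides such
as 224 → 112 → … → 3 work); the final map is global-average-pooled into a
512-feature ahead of a fully connected sigmoid head. The three variants
differ only in per-block layer counts:

| variant  | layers per block | parameters |
|----------|------------------|-----------:|
| 8-layer  | 1/2/2/1/1/1      | 1,804,932 (1.80 M) |
| 10-layer | 1/3/2/2/1/1      | 1,961,764 (1.96 M) |
| 12-layer | 1/3/3/2/2/1      | 2,588,772 (2.59 M) |

With the residual switch on, every post-stem block adds a skip from its
input to the output of its last convolution — identity when channels are
unchanged, a 1×1 convolution (with bias) at the four channel transitions —
with the addition placed before the pool and the rectifier after the
addition. The skip granularity is one per block: that is what the
projection-parameter delta (174,080 weights + 960 biases between the
12-layer residual and plain networks) pins down, and "residual blocks" is
the natural reading; pairwise within-block skips would give the same delta
but are not what block-level skip wiring means here.

Several conventions are forced by the reference parameter totals above and are
treated as part of the architecture definition:

* **Input channels = 3** (grayscale replicated): the stem count
  7·7·3·32 = 4,704 is the only choice consistent with every total.
* **No normalization layers, biases everywhere** (convolutions, projections,
  head): normalization pairs would push the 8-layer count to 1.81 M. The
  configuration carries a `normalization` flag for completeness, but only
  the off setting — the actual SRN definition — is buildable.
* **Stem stride 1**, with the block's own max-pool doing the 224 → 112
  reduction; counts are stride-independent, and this honors "every block is
  followed by a pool".
* **Global average pooling** generalizes the classifier's fixed 3×3 pooling:
  identical at 224 input, and well-defined for the 448 branch.
* Input sides of at least 64 px are accepted. Divisibility by 64 is *not*
  required: the canonical sizes 112, 224 and 448 themselves rely on
  floor-mode pooling (224/64 = 3.5).

The MS-SRN runs one independent SRN trunk per scale (by default a local
448 px branch and a global 224 px branch — weight sharing would break the
5.18 M total), discards the trunks' own heads, concatenates the per-branch
512-features and applies a single fully connected sigmoid head:
2 × 2,586,720 + (1024·4 + 4) = 5,177,540 parameters.

`count_macs()` reports multiply–accumulate operations
(kernel² × C_in × C_out × output positions, plus the head). Reported "FLOPs"
figures for such networks follow unstated conventions (MACs vs 2×MACs,
pooling/activation accounting), so the package documents its counter's
semantics and asserts only convention-free *ratios* (25/9 = 2.78,
25/18 = 1.39) and closed-form single-layer values.

## Training

The loss is the multi-label sigmoid cross-entropy
$L(\hat y, y) = -\tfrac1C \sum_{i=1}^{C} y_i \log \hat y_i + (1-y_i)\log(1-\hat y_i)$,
averaged over the batch, with probabilities clamped to $[\varepsilon,
1-\varepsilon]$, $\varepsilon = 10^{-7}$, so the value is always finite
(the gradient uses the standard unclamped $\hat y - y$ form). Optimization
is plain SGD with momentum 0.9 and weight decay $10^{-4}$ applied to every
parameter; reference settings are batch 64, learning rate 0.003 (constant —
no schedule is specified for this family), 200 epochs, five seeds reported
as mean ± std. Weights start from seeded Kaiming fan-in normal draws
(uniform for the head, zero biases). Splits are 80/20 by image with exact
label-combination stratification (largest-remainder rounding; floor on the
test side); a `by_patient` switch moves whole patients to one side, the
leakage-safe option for frame-correlated data. Augmentation is a random
rotation within ±10° plus independent horizontal/vertical flips at
probability 0.5 each — magnitudes are not pinned down externally, so ±10°
was chosen as a typical small anatomical tilt, and vertical flips are kept
despite their anatomical implausibility because the protocol lists them.
The same draw is applied to every branch of a multi-scale network so the
branches stay geometrically consistent. Binarization for metrics uses 0.5
on the sigmoid outputs. Training retains the checkpoint with the best test
micro-average accuracy, logs per-epoch loss and test metrics, aborts on
non-finite loss, and is bit-reproducible given (seed, config, manifest).

The network engine itself is compiled code inside the package: stride-1
same-padding convolutions as im2col + single-precision BLAS matrix
products, with analytically verified backpropagation (the test suite checks
the update against hand-computed head gradients and directional finite
differences). Single precision bounds forward/backward agreement with
double-precision references at about $10^{-5}$ relative, which is why
structural tests use tolerances of that order.

## Metrics

Per class: Acc = (TP+TN)/(TP+FP+TN+FN), Sen = TP/(TP+FN), Spe = TN/(TN+FP).
Micro-averages pool the four classes' counts first and apply the same
formulas once. A ratio with zero denominator is reported as `NA` (absent),
never coerced to 0 or 1. Patient-level accuracy is exact-match (subset)
accuracy: an image counts only if its entire predicted vector equals the
truth — detecting two of three co-occurring diseases is wrong. Whether that
quantity should be aggregated per image or per patient is ambiguous in
common usage; both are implemented (`patient` grouping argument, a patient
being correct only if all its frames are), per-image being the default.
Across-seed comparisons use an unpaired two-sided equal-variance Student
t-test with significance at p ≤ 0.05 inclusive; with zero variance in both
groups the statistic degenerates and p is set to 1 for equal means (0
otherwise). The t statistic is computed from the pooled-variance closed
form so that `stats::t.test` can serve as an independent reference in the
tests.

## Grad-CAM

For a chosen class, the gradient of that class's logit is taken with
respect to a target block's output map (post-rectifier, pre-pool; default
block 6, the deepest — the layer is not externally specified, so the
standard highest-level choice is used), channel-averaged into weights, and
the rectified weighted activation sum is bilinearly upsampled to the input
and max-normalized (an identically zero map stays zero). For the MS-SRN the
gradient flows from the shared fused logit through the concatenation, so
each branch yields its own map against the same prediction. Max
normalization makes maps invariant to positive rescaling of the class head
weights, which the suite asserts.

## The phantom generator

The clinical dataset the family was designed for is private, so the package
ships a generator of OCT-like B-scans with known ground truth: a curved
bright multi-layer band (bright nerve-fiber-layer line, banded interior,
bright RPE floor, fading choroid, a foveal dip) over dark background,
multiplied by unit-mean gamma speckle. Three lesion types are injected
independently per image with configurable probabilities — defaults
0.2207/0.2813/0.1091 for AMD/ERM/ME match the marginal prevalences of a
large multi-label OCT cohort (7,273/9,272/3,597 of ≈33,000 images), so
multi-disease images arise naturally:

* **AMD**: 2–4 bright dome-shaped drusen bumps deforming the outer band;
* **ERM**: a thin bright membrane (1–3 px at 512) hovering above the inner
  surface with a hypo-reflective slit beneath it;
* **ME**: 2–5 dark elliptical cavities inside the band.

Geometry is specified in side-fractions, so the image side is a resolution
knob rather than a difficulty knob (one exception: the membrane line is
always drawn at least one pixel wide, so rendering directly at a coarse
side is slightly kinder to ERM than downsampling a 512 px render). The
membrane's sub-pixel thickness at coarse scales is deliberate: it gives
multi-scale learning a mechanism to act on, since ERM evidence visible at
448 px largely vanishes at 224 px. Labels and bounding boxes are recorded
at generation time and are consistent with the rendered lesions by
construction; the acceptance suite re-derives labels from boxes on 10,000
samples and checks prevalences against 3 binomial standard errors.
Datasets assign consecutive frames to synthetic patients (6 per patient)
that share jittered anatomy; lesion presence is drawn per frame — like a
scan sweeping through the macula, lesions appear in some frames of an eye
and not others — which keeps image-level prevalences exactly binomial.
Generator defaults were calibrated once, at design time, so that the
smallest variant separates the classes quickly (large, high-contrast
lesions; speckle contrast 0.18); harder regimes are a matter of turning
the exposed knobs (speckle, lesion size/contrast ranges). The phantoms
emulate none of the optics of real OCT (A-scan acquisition, shadowing,
vendor post-processing), so passing tests demonstrate that the pipeline
learns and localizes *separable structure of this geometry*, not clinical
performance.

## Problem sizes in the test suite

The suite's learning check trains the 8-layer SRN on 700 phantoms rendered
at 128 px (split 80/20), mini-batch 16, learning rate 0.003, 10 epochs,
three seeds, and requires test micro-average accuracy ≥ 0.85 on every seed
— a deliberately desk-sized counterpart of the full protocol (tens of
thousands of 224/448 px images for 200 epochs). Two of the scaled choices
matter and were made once: the 128 px side keeps the six-block topology
and its pooling ladder intact while shrinking convolution cost
quadratically, and mini-batch 16 restores a sensible number of SGD updates
(350) for a 560-image training split at the reference learning rate —
batch 64 at this dataset size leaves so few updates that no variant escapes
the label-prior solution. The accuracy bar itself is unchanged. The
localization check then asks the trained model's Grad-CAM maps to put more
mean heat inside the generator's lesion boxes than outside for the matching
class on at least 70% of 100 lesioned phantoms.

## Known limitations

* The engine is single-threaded CPU code tuned for desk-scale experiments;
  it is faithful, not fast, at the full 33,000-image, 200-epoch protocol.
* Batch-normalized SRN variants are intentionally out of the buildable
  space (see above); the flag exists so configurations can state the
  convention explicitly.
* The "non-factorized" large-kernel counterpart of the 12-layer network is
  not reconstructable from its parameter count alone under any natural
  3×3 → 5×5 merging, so no such builder is offered;
  `substitute_kernels()` exposes the general mechanism instead.
* Externally reported FLOPs figures are not asserted against; only MAC ratios and
  closed forms are.
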