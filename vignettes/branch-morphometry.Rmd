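---
title: "Measuring branch length and inclination from segmented tree images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring branch length and inclination from segmented tree images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchmorph)
```

# The problem

Monitoring the health of tall trees in the field calls for automated
measurement of branch phenotypes: when a branch breaks or sags, its
apparent length and inclination angle change. `branchmorph` implements a
two-stage pipeline for RGB images of trees:

1. **Semantic segmentation** of every pixel into background (0), trunk
   (1) or branch (2), with an attention-augmented UNet.
2. **Skeleton-based morphometry**: each trunk/branch instance is reduced
   to its one-pixel-wide skeleton; the number of skeleton pixels is the
   length, and a total-least-squares line fit through the skeleton gives
   the inclination angle.

A synthetic scene generator with exact ground truth closes the loop: it
renders tree-like scenes from known stroke parameters, so every stage can
be validated quantitatively without any proprietary imagery.

# The segmentation model

The network is a UNet with a VGG16-style encoder: 13 convolutional layers
(3×3, stride 1, zero padding) in blocks of [2, 2, 3, 3, 3] with channel
widths [64, 128, 256, 512, 512], and four 2×2 max-pools between the first
four blocks. The decoder mirrors the encoder with four 2×2 transpose-conv
upsampling stages, each followed by concatenation with the matching
encoder feature map (skip connection) and a two-convolution block. The
head is a 1×1 convolution with a per-pixel softmax over the three
classes, so the output has the same height and width as the input.

Two attention mechanisms are embedded:

**Squeeze-and-excitation (SE).** For a feature map $u$ with $c_2$
channels of size $h \times w$, the squeeze step pools each channel to a
scalar, $z_m = \frac{1}{wh}\sum_{i}\sum_{j} u_m(i,j)$; the excitation
step passes $z$ through a two-layer bottleneck,
$s = \sigma\!\left(w_2\,\mathrm{ReLU}(w_1 z)\right)$ with $\sigma$ the
sigmoid and $w_1 \in \mathbb{R}^{c_2/r \times c_2}$,
$w_2 \in \mathbb{R}^{c_2 \times c_2/r}$; and the scale step multiplies
channel $m$ by the gate $s_m$. The reduction ratio defaults to $r = 16$,
the standard value in the channel-attention literature; it must divide
the channel count at every SE site. SE modules sit before each of the
four max-pools and at five decoding-path sites — the bottleneck plus each
of the four skip concatenations, the reading of "five upsampling sites"
that makes the counts come out exactly.

**Residual attention module (RAM).** After one convolution + ReLU of the
input, a channel-attention branch computes one scalar per channel by
*variance pooling* (the per-channel population variance over spatial
positions — the second central moment, which responds to texture detail
where average pooling does not), while a spatial-attention branch applies
a depthwise 3×3 convolution. The two maps are fused by broadcast addition
(channel gains of shape $c{\times}1{\times}1$ added to a
$c{\times}h{\times}w$ map — the only shape-consistent fusion), passed
through a sigmoid, multiplied with a second convolution of the same
features, and added back to the input. With all module weights zero the
RAM is exactly the identity, a property the test suite checks; the two
convolutions do not share weights. The RAM sits directly after the first
SE module, before the first downsampling.

The implementation is a self-contained CPU engine (im2col convolutions
through RcppArmadillo GEMM, hand-derived backward passes verified against
numerical differentiation). Encoder weights use He initialization — the
builder runs fully offline, so no pretrained VGG16 weights are bundled.
Inputs whose sides are not multiples of $2^{\text{depth}}$ are
reflect-padded and the output cropped back.

## Training recipe

`train_config()` defaults: Adam, pixel-wise cross-entropy, batch size 4,
300 epochs, initial learning rate $10^{-4}$ with cosine decay
$\mathrm{lr}(t) = \mathrm{lr}_0 \cdot \tfrac12\,(1 + \cos(\pi t/T))$,
and a two-phase schedule in which the encoder (backbone) convolution
weights are frozen for the first 150 epochs — only the attention modules,
decoder and head adapt — and then released. Freezing refers to the
feature-extraction backbone; SE/RAM parameters always train. Training is
deterministic given the config seed (all randomness flows through R's
RNG, and the loss history is bitwise reproducible on the same machine).

The package's own tests necessarily run at desk scale: a reduced
architecture (channel widths [8, 16, 32], one convolution per block,
$r=4$) trained on 8–10 rendered scenes of 96–128 px for 50–100 epochs,
which overfits the training scenes to ≥ 0.9 pixel accuracy in a few
minutes on one CPU. The full-size architecture is exercised for its
forward-pass contracts (shape, softmax normalization). These sizes are
the package's choice of a convergent small-scale experiment, not a limit
of the implementation.

# Skeleton thinning

Thinning uses the classic two-subiteration parallel algorithm on the
binary mask of one instance. For a foreground pixel $P_1$, its eight
neighbors $P_2,\dots,P_9$ are read clockwise starting from the pixel
directly above. With $N(P_1)$ the number of foreground neighbors and
$S(P_1)$ the number of $0{\to}1$ transitions in the cyclic sequence
$P_2, P_3, \dots, P_9, P_2$:

* Sub-iteration 1 deletes every pixel with $2 \le N(P_1) \le 6$,
  $S(P_1) = 1$, $P_2 P_4 P_6 = 0$ and $P_4 P_6 P_8 = 0$.
* Sub-iteration 2 replaces the products with $P_2 P_4 P_8 = 0$ and
  $P_2 P_6 P_8 = 0$.

Deletion within a sub-iteration is simultaneous (mark, then delete) — the
parallel formulation — and rounds repeat until nothing changes. Pixels
outside the image count as background. The test suite checks the
implementation against an independently written whole-image
implementation on thousands of random grids and against hand-coded truth
tables of all 256 neighbor configurations.

# Morphometry

`measure_all()` runs the full measurement pipeline on a class mask:

1. **Instance separation.** Each class is binarized and decomposed into
   8-connected components (8-connectivity, so thin diagonal branches do
   not fragment). Components smaller than `min_area` pixels (default 50)
   are discarded as segmentation fragments; survivors are renumbered in
   (class, top-left pixel) order. Overlapping branches that merge into
   one component are deliberately kept as a single instance — a 2-D image
   cannot disambiguate them.
2. **Length.** The instance is thinned and the skeleton pixels are
   counted; that count is the length in pixels. No metric calibration is
   attempted — the measurement is defined in image pixels.
3. **Inclination.** A line is fitted through the skeleton pixels by total
   least squares: the line through the centroid along the principal axis
   of the coordinate scatter, which minimizes the sum of squared
   orthogonal (Euclidean) distances. (An orthogonal L1 fit has no closed
   form; the principal-axis solution is unique and direct.) The angle is
   $\operatorname{atan2}(\Delta y, \Delta x)$ with $y$ measured upward
   (image rows flipped), mapped into $[0°, 180°)$ from the horizontal
   image axis: 0° is horizontal, 90° vertical, values above 90° lean the
   other way. The convention distinguishes left- from right-leaning
   branches while keeping one value per undirected axis. A perfectly
   vertical skeleton is handled by a vertical flag rather than an
   infinite slope; an isotropic pixel set (no unique axis, e.g. a
   symmetric cross) is flagged degenerate and surfaces as a flagged
   record with `NA` angle rather than an error, so one bad instance never
   aborts a batch run.

# Evaluation metrics

From the pixel confusion matrix (rows = truth, columns = prediction),
with per-class $TP$, $FP$, $FN$:

$$\mathrm{MIoU} = \frac{1}{K+1} \sum_{i=0}^{K} \frac{TP_i}{TP_i + FP_i + FN_i},$$

and precision $TP/(TP+FP)$, recall $TP/(TP+FN)$ averaged over the $K+1$
classes (macro, the default; frequency-weighted averaging is also
exposed since both conventions appear in practice). The reported F1 is
the harmonic mean of the reported precision and recall. A class that is
absent from both masks would make a ratio 0/0; such classes contribute 0
with a warning instead of propagating NaN.

Measurement agreement between manual values $t_i$ and estimates $m_i$
uses $R^2 = 1 - \sum (t_i - m_i)^2 / \sum (t_i - \bar t)^2$ and
$\mathrm{RMSE} = \sqrt{\tfrac1n \sum (t_i - m_i)^2}$; $R^2$ is undefined
(NA, with a warning) when $t$ is constant.

# The synthetic scene generator

`render_scene()` rasterizes tree-like scenes: one or more thick trunk
strokes (class 1) plus thinner branch strokes (class 2) at known angles
and lengths, over a condition-dependent background with optional clutter
blobs and Gaussian RGB noise. A stroke is a Bresenham line of chessboard
length `length_px` dilated by a disk of radius $(w-1)/2$ — anti-alias
free, so the ground-truth axis pixel count is exact. Ground truth records
the realized axis pixel count and the angle; photometric perturbations
(condition tags *sunny*, *rainy*, *night*, *snowy*, plus *foggy* mapped
to contrast compression and *typhoon* mapped to horizontal motion blur —
documented emulations, since no image statistics exist for them) change
only the RGB image, never the class mask. `random_scene_spec()` places a
near-vertical trunk and branches that are rejected if they would touch
the trunk or each other, so the stroke count in the truth table equals
the component count in the mask. Defaults (256×256 scenes, trunk width
8–14, branch widths 2–8, lengths 40–300 px, angles 5–175°, noise sd
0.02) were fixed once as a plausible desk-scale stand-in for field
imagery.

What the generator does *not* emulate: photorealistic bark texture,
foliage occlusion, perspective foreshortening, annotation noise, or
branches that genuinely attach to (and overlap) the trunk. Trunk and
branch also receive slightly different bark tones, giving the segmenter a
photometric cue that real same-species imagery would not provide so
cleanly. Passing tests on these scenes therefore validates the
*geometry* of the pipeline (thinning, counting, fitting, filtering) and
the *mechanics* of training, not field-grade segmentation accuracy.

# Numerical choices

* Mask files are 8-bit grayscale PNG whose integer gray level **is** the
  class id; they are read back by level, never by color. (Palette-indexed
  PNG cannot be written by the available PNG writer; the gray-level
  encoding carries identical information.)
* Line-fit degeneracy: the scatter matrix is isotropic when
  $S_{xx} = S_{yy}$ and $S_{xy} = 0$ (tolerance $10^{-12}$); vertical
  when the principal direction's $x$-component is below $10^{-9}$.
* Softmax is computed with the usual max-shift for stability; training
  clamps probabilities at $10^{-12}$ inside the log.
* The Adam step uses the standard bias correction with
  $\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$.
* max-pool ties resolve to the first maximum in (row, col) scan order,
  deterministically.

# Known limitations

* **Staircase effect of the thinning scheme.** On strokes that are
  neither axis-aligned nor at 45°, the literal two-subiteration algorithm
  can converge to a 4-connected staircase path: a staircase corner has
  $S(P_1) = 2$ and is protected, so the staircase is a fixpoint. The
  skeleton then counts roughly $|\Delta x| + |\Delta y|$ pixels instead
  of $\max(|\Delta x|, |\Delta y|)$ — up to ~41% length inflation,
  dependent on stroke width and parity (width 4 is typically clean, width
  3 typically staircases). Later lookup-table thinning variants (e.g.
  what `scikit-image` ships under the same name) add staircase-removing
  conditions and do not show this; the package deliberately implements
  the classic parallel formulation. Angle estimates are unaffected (the
  staircase follows the same axis, and the total-least-squares fit is
  robust to it). Users who need tighter length fidelity on oblique
  branches should treat the pixel count as an upper bound or
  post-process staircases.
* **Small-structure deletion.** The parallel scheme deletes an isolated
  2×2 square entirely (all four pixels satisfy the conditions
  simultaneously), and a compact component whose erosion passes through
  an exact 2×2 remnant can vanish altogether (about 0.3% of components
  in the random-blob test fixtures). Components are never split or
  merged. In the measurement pipeline this is harmless in practice: the
  contour-area filter removes components of that size class first.
* Lengths are reported in pixels only; no camera calibration.
* Overlapping branches are measured as one instance (2-D limitation).
* Trunk length uses the same skeleton-pixel-count rule as branches.
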