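---
title: "From paper to signal: the models and numerics behind ecgdigitizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From paper to signal: the models and numerics behind ecgdigitizer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ecgdigitizer` turns raster images of printed electrocardiograms into
calibrated multi-lead voltage series. This vignette explains the models the
package implements, the assumptions they rest on, the tunable parameters
and their defaults, and the numerical choices made where the design was
genuinely open. It states no empirical result beyond what the package's own
tests and acceptance script compute.

## The synthetic data generator

All development and testing rests on a built-in generator, because paper
archives cannot ship with a package.

**Waveforms.** `simulate_ecg()` models each beat as a sum of five Gaussian
waves (P, Q, R, S, T) with per-lead amplitude profiles; beat positions
follow a heart-rate parameter (default 60 bpm) with mild RR jitter
(relative s.d. 0.02) and per-beat amplitude jitter (0.05). Lead I and II
are generative; the remaining limb leads are derived, so III = II − I,
aVR = −(I+II)/2, aVL = I − II/2 and aVF = II − I/2 hold exactly — a
property downstream consistency checks exploit. V1–V6 get their own
profiles emulating R-wave progression. Optional baseline wander and white
noise are off by default: the generator's defaults describe a clean
recording, and degradations are applied as explicit augmentations.

**Paper rendering.** `render_paper()` draws minor grid rulings every 1 mm
(≈0.1 mm wide) and heavier major rulings every 5 mm (≈0.25 mm), places each
lead's time window into its layout panel at the configured speed (mm/s) and
gain (mm/mV), prints lead names with a built-in 5×7 bitmap font, and
records pixel-accurate masks: a 4-class mask (background, grid, signal,
text), a 13-class lead-text mask, and a *subpixel coverage plane* for the
signal class — the fraction of each pixel covered by the continuous ink
band. The coverage plane is what an ideal segmentation network would
output, and it is the soft ground truth used by the oracle round-trip
tests; the binary class mask remains available. The trace pen width
defaults to 0.2 mm at the render resolution. `apply_perspective()` warps
image and masks by a random corner-jitter homography (recorded in the
sample) and composites a procedural background (gradient, noise, or a
table-like texture); real photo backgrounds cannot be bundled, and the
procedural ones exercise the same failure mode — non-paper pixels that the
segmentation must suppress. `apply_fading()` adds a smooth brightness field
emulating thermal-paper fading. What the generator does *not* emulate:
lens blur, wrinkled (non-planar) paper, handwriting, and real printer
artifacts — passing tests therefore show geometric and numeric
correctness, not robustness to every clinical degradation.

## The segmentation networks

The main network is a residual U-Net with encoder widths
(32, 64, 128, 256, 320, 320, 320, 320). Each encoder block applies two
bias-free conv3×3–InstanceNorm–LeakyReLU stages inside a residual shortcut
and is followed by a width-preserving 2×2 stride-2 convolution (with
InstanceNorm and LeakyReLU) for downsampling; one residual block forms the
bottleneck; each decoder block upsamples bilinearly by 2, concatenates the
skip connection and applies a single conv3×3–InstanceNorm–LeakyReLU stage;
a final 3×3 convolution (the only biased layer) projects to the four
classes. Residual shortcuts use a bias-free 3×3 projection convolution when
the channel count changes and the identity otherwise. Standard
descriptions of this family leave the shortcut and bottleneck details open;
this package fixes them by requiring the default network to land on the
reference 22.6 M trainable-parameter budget, which the recipe above does
exactly (22,611,780). The lead-text network shares the recipe with widths
(32, 64, 128, 256, 256), one input channel and 13 outputs.

Because no deep-learning framework is available to R here, the forward and
backward passes are implemented in the package itself on Rcpp kernels
(im2col + GEMM convolutions, bilinear resampling); gradients are verified
against finite differences in the test suite. Inputs of any size are
zero-padded to a multiple of $2^{\text{depth}}$ and cropped back. Images
larger than the tile budget (default 1024 px, 128 px overlap) are processed
as overlapping tiles blended with a cosine-ramp window.

**Loss.** Soft Dice (1 − mean per-class Dice on softmax probabilities,
smoothing $10^{-5}$) plus focal loss $-(1-p)^\gamma \log p$ with
$\gamma = 2$ and no class weights by default — both suit the extreme class
imbalance of thin traces on large paper.

**Optimization.** Convolution kernels are updated by Muon: momentum 0.95
buffers reshaped to (fan-in × fan-out) matrices and orthogonalized by five
quintic Newton–Schulz iterations (coefficients 3.4445, −4.775, 2.0315),
scaled by $\sqrt{\max(1, \text{out}/\text{in})}$; InstanceNorm affines and
the head bias use AdamW (betas 0.9/0.999). Decoupled weight decay 0.001
applies to both. The learning rate decays by cosine from 0.0037 to 0.00037
over 20,000 batches and stays constant afterwards. A pure-AdamW fallback is
available (`optimizer = "adamw"`). Desk-scale tests train reduced-width
networks (8–48 channels, 64 px crops, a few hundred steps); the full-scale
recipe (batch 12, 1024 px patches, 45 epochs) is expressed by the defaults
of `train_config()` but is not exercised by the tests.

## Perspective correction

Grid pixels vote their probability into the angle–radius (Hough) domain,
$\rho = x\cos\theta + y\sin\theta$ with the origin at the top-left pixel
center, $x$ the column and $y$ the row. Under perspective, a family of
parallel grid lines becomes a *line* in that domain; the angle–angle
transform assigns to $(\theta_i, \theta_j)$ the variance of accumulator
samples along the segment from $(\theta_i, \rho_{\min})$ to
$(\theta_j, \rho_{\max})$ (one bilinear sample per ρ bin), so each family
becomes a point. Implementation choices that proved load-bearing:

- **Accumulator sharpening.** Any line through a dense grid collects large,
  slowly varying mass, so raw angle-angle maps have weak contrast. A
  running-mean high-pass along ρ (window 25 bins, clamped at zero) removes
  this background and makes family maxima orders of magnitude more
  prominent; degenerate inputs are rejected when the best peak is less than
  50× the median over admissible pairs.
- **Occupied-band restriction.** Variance segments are evaluated only over
  the ρ band that actually holds line mass (bins above 20% of the peak
  column sum); outside it the segments are unconstrained and the maxima
  smear into ridges.
- **Spread limit.** Pairs with $|\theta_i - \theta_j| > 25°$ are excluded —
  no plausible perspective bends a grid family that far, and such segments
  are artifact-prone.
- **Coarse-to-fine.** A 0.5° pass over $[-\pi/4, 3\pi/4]$ locates the two
  maxima (the second is searched within ±15° of the orthogonal direction);
  a 0.2° pass over each family's window with its own occupied band refines
  them; a 0.02° pass pins the final angles.

The two families' extreme lines intersect in the two vanishing points; the
homography sends the vanishing line to infinity, maps the family directions
to the image axes, forbids flips, preserves unit scale at the image center,
and finally rescales the vertical axis so both grid spacings agree (the
affine ambiguity left by vanishing-point rectification is not determined by
the geometry; equal physical grid spacing on both axes is the natural gauge
and is fixed by feedback from the spacing estimator). Cropping keeps the
bounding box of signal probability above 0.5 plus a 10 mm margin. Maps
whose long side exceeds 2048 px are max-pooled first — angles are scale
invariant. When family detection fails (blank or structureless maps), the
pipeline falls back to a pure rotation estimate, then to the identity.

Probability maps travel through the warp with bilinear interpolation by
default (right for soft network outputs, and preserving subpixel trace
positions); `map_interp = "nearest"` is available for crisp label-derived
maps.

## Grid calibration

Each axis profile (column or row sums of the rectified grid map, used as
soft probabilities without thresholding) yields the exact autocorrelation
$R[m] = \sum_n x[n]\,x[n+m]$ (no wrap-around). A comb template — Gaussian
bumps at multiples of the candidate spacing $d$, amplified (×1.5) at
multiples of $5d$, damped by the triangular envelope $(1 - m/n)$ of an
$n$-sample autocorrelation — is compared with the moving-average-detrended
autocorrelation by Pearson correlation. Two template details guard against
harmonic confusion: the bump width follows σ = d/12 but is capped at
1.2 px, because autocorrelation peak widths are set by the ruling line
width rather than the spacing, and the major-line amplification is kept
mild — with a heavy 5d weight the $d/5$ subharmonic (whose amplified bumps
land exactly on the true peaks) can outscore the true spacing. The search over
$d \in [3, 80]$ px runs at a 0.25 px step and refines in four rounds that
shrink the step by 0.2 (final step < 0.01 px). Crucially the score is
evaluated over *few* comb periods early (10) and more later (25, 62, 156,
then all): the template decorrelates after roughly $m/d$ periods of
mismatch, so a long window makes the coarse score a needle the coarse step
would miss, while a short window gives a broad, step-robust peak.
A best score below 0.2 raises a calibration failure; the pipeline then
assumes the signal spans the full recording to guess a spacing, with a
warning. The spacing (pixels per 1 mm minor square) and the paper constants
give seconds and millivolts per pixel. Speed and gain themselves are taken
from configuration, as on real archives.

## Layout identification

Lead-name markers are the weighted centroids of segmented text blobs:
per-lead probability above 0.5, blobs under 5 units of mass discarded,
fragments of one label (blobs closer than 5% of the image size) merged with
the heaviest fragment's centroid kept. Distant repeats of the same lead
name — a rhythm strip's label — remain separate markers; this is the only
evidence distinguishing a 3×4 layout from 3×4 with a rhythm lead, so
collapsing them globally would make those layouts indistinguishable.

Each candidate template contributes nominal marker positions in
$[0,1]^2$. Matching pairs detected and template markers of the same lead
identity (nearest-distance assignment when either side has multiples), fits
an independent scale and translation per axis by least squares (≥ 2
distinct coordinates required for a scale, else 1), and scores

$$\text{cost} = \frac{1}{|G|}\Big(\lambda\,(|M_{\text{miss}}| + |P_{\text{extra}}|) + \sum \lVert p' - g\rVert\Big), \qquad \lambda = 0.5,$$

with Euclidean distances in template coordinates. Penalizing unmatched
*detections* ($P_{\text{extra}}$) alongside missing template markers is a
deliberate extension: without it, a layout that is a subset of another
(3×4 inside 3×4+rhythm) can never lose. The lowest cost wins; ties keep
candidate order; if nothing matches, or fewer than 4 markers were detected
(too few to fit a meaningful transform), the configured default template is
used with a warning.

## Trace extraction

Components of the thresholded signal map (default 0.5; speck mass below 10
discarded) are 8-connected. A component is deemed to contain merged leads
when its row extent exceeds one lead band or more than 20% of its columns
hold two or more disjoint vertical runs; such components are snipped along
a left-to-right path of least accumulated probability found greedily with
one-step lookahead over the moves right, right-up, right-down, up, down
(no immediate vertical reversals; at most 20 consecutive vertical moves,
then a rightward move is forced, guaranteeing progress). Detection and
snipping iterate to convergence (≤ 10 rounds).

Fragments are chained by a dense Jonker–Volgenant assignment from right
endpoints to left endpoints. Plausible continuations cost the weighted
Manhattan distance $|\Delta c| + 2\,|\Delta r|$, doubled when the
connection runs backward in time; strongly backward connections — including
a component wrapping onto itself — carry a constant wrap cost (defaulting
to twice the components' row span). The constant matters: if wrap edges
paid a distance cost, closing any chain would always be dearer than
splitting it into self-matched fragments, and no chain would ever form.
Cycles of the optimal permutation are opened by dropping their most
expensive edge; singleton cycles (self-connections) are rejected as noise.

The waveform sample at a column lies where that column's vertical ink run
meets the next column's run, so the per-column value is the
probability-weighted mean row restricted to that overlap, including
sub-threshold soft mass within two rows — this recovers subpixel positions
and undoes the bias that plain column averaging inflicts on steep slopes.
Rows convert to millivolts (up positive), the per-lead median is removed as
baseline, and traces are resampled to the target rate (default 1000 Hz) by
linear interpolation over finite runs. NA runs no longer than 20 ms are
bridged first: at desk-scale resolutions a single missing pixel column
spans several output samples, and without bridging, isolated dropouts —
not genuine failures — would dominate the output. Longer gaps stay NA: no
image is rejected, failure is always expressed per sample. A lead printed
both in the grid and as a rhythm strip takes the rhythm version, which
covers the full record.

## Evaluation harness

Reconstruction and truth are zero-centred and aligned by the integer-sample
shift within ±100 ms (1 ms steps at 1000 Hz) that maximizes SNR, re-centring
per candidate overlap window. $\text{SNR} = 10\log_{10}(\sum y^2 / \sum (y-\hat y)^2)$,
with +∞ as the sentinel for exact recovery (excluded from aggregate means,
with a count) and NaN for zero-power truth. NA samples in the
reconstruction score as zeros on the centred scale by default — an all-NA
lead therefore scores exactly 0 dB, the same convention that makes an
all-zero reconstruction the natural baseline — and a strict mode excludes
them instead. RMSE is reported in µV, correlation is Pearson's. Because
most layouts print each lead for only part of the record, per-lead
evaluation can be restricted to the span where the reconstruction has
observations (`span = "observed"`); the package's round-trip checks use
this mode.

## Problem sizes, limitations, open choices

The test suite runs entirely on CPU with renders of roughly 550 × 1050 px
(25 mm/s at ~3.9 px/mm) for training and end-to-end checks and
1400 × 5200 px (50 mm/s at 10 px/mm) for the oracle round trip; reduced
U-Nets of 8–48 channels train for 200–600 steps. These sizes are the
package's own choice of desk-scale study conditions. Known limitations:
non-planar (wrinkled, curved) paper violates the single-homography
assumption; lead-name identification by glyph shape requires a network of
realistic capacity — the tiny desk-scale text nets do not learn it, and the
pipeline then falls back to the configured default layout, which is also
the honest behaviour on label-free papers; limb-lead linear dependence is
deliberately not exploited to impute missing segments. Random number use is
always funnelled through explicit seeds, so every sample, warp, crop and
training run in the package is reproducible bit for bit.
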