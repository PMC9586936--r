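---
title: "Models and methods behind flimcoreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flimcoreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimcoreg)
```

`flimcoreg` aligns full-spectral fluorescence lifetime microscopy
(FS-FLIM) tiles with H&E histology through an unpaired image
translation stage and a photometric homography regression. This
vignette explains the models each stage implements, the parameters
that matter and why their defaults are what they are, what the
synthetic phantoms emulate, and the numerical choices that were made
where the design was genuinely open. Nothing here reports an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Lifetime reconstruction

A hypercube stores non-negative photon counts indexed by `(x, y, s,
t)`. Per pixel and band the decay is modelled as mono-exponential
without additive background,

$$y_t = A\, e^{-t/\tau},$$

fitted by nonlinear least squares on the raw counts. The fitter is a
vectorised Gauss–Newton iteration over all pixels of a band at once
(`fit_monoexp`), initialised by an intensity-weighted log-linear
regression; steps that would drive the decay rate or amplitude
non-positive are halved. Times are taken at the left edge of each bin,
consistently with the synthetic decay sampler, so noiseless decays are
recovered to solver tolerance (1e-6 relative) for any τ in the working
range 0.5–5 ns. Pixels whose total count falls below the
fit-feasibility floor (`min_counts = 25`) get lifetime 0: below ~25
photons the two-parameter fit is dominated by shot noise and a
confident lifetime cannot be reported. The independent cross-check in
the test suite fits the same histograms with `minpack.lm::nlsLM`.

Weighted least squares on Poisson data is a pragmatic choice, not a
maximum-likelihood one; at the photon counts the filter passes
(hundreds and up) the difference is well below the 5% recovery
tolerance the tests enforce.

**Spectral moving mean.** Low-count bands at the spectral edges are
smoothed by a centred moving mean over `width` bands (default 8). The
window is truncated — shrunk, not padded — at the spectral edges, so
no counts are invented; for even widths the window extends one band
further to the long-wavelength side.

**Photon filter.** With $\hat N$ the mean of the measured fluorescence
concentration, every pixel with $i^I_{x,y,s} \le \sqrt{\hat N}$ has
both its intensity and lifetime set to zero; the inequality is
inclusive, so a pixel exactly at the threshold is removed. The scope
of $\hat N$ is configurable: the default computes it per spectral band
(each band's own mean intensity), `scope = "stack"` uses one mean for
the whole stack. The per-band default reflects that photon statistics
vary strongly across the emission spectrum, so a single stack-wide
threshold would over-filter bright bands and under-filter dim ones.
The filter recomputes $\hat N$ from its input by default; passing the
recorded `nhat` back in freezes the threshold and makes the operation
idempotent. $\hat N$ is computed on whatever the filter receives — in
the standard pipeline that is the reconstruction of the
spectrally-smoothed cube, i.e. after the moving mean.

**Global normalisation** rescales intensities of all stacks from one
microarray by the single global maximum, to [0, 1]. Lifetimes are
never rescaled: lifetime is a physical quantity in ns and its display
window is a rendering decision (below). A per-band option exists for
exploratory use.

## Rendering

Lifetime displays clamp τ to a fixed window — [1 ns, 3 ns] by default,
the window used for whole-sample visualisation so that lifetime
differences are comparable across wavelengths — and map it linearly
through the standard Jet palette; pixels with zero (filtered)
intensity render black, the conventional dark background.
Intensity-weighted displays multiply the palette colour by the
normalised intensity (HSV value scaling). An alternative
`weight_channel = "saturation"` desaturates towards white instead; the
value-channel default is what matches brightness-scaled third-row
displays in practice. Histogram equalisation is global, operates on a
configurable number of grey levels (256 by default) and returns
constant images unchanged.

## Histology background masking

Histology uses a bright background where FLIM uses a dark one, so
before translation training the slide background is removed with:
greyscale (luma weights 0.299/0.587/0.114, the standard choice where
none is specified) → colour inversion → global histogram equalisation
→ Otsu binarisation → pixel-wise multiplication with the original
image. Equalisation runs on the inverted image, per the stated
pipeline order; the Otsu step maximises between-class variance by
exhaustive search over 256 levels (ties broken towards the smallest
level). No morphological cleanup is applied by default — the pipeline
as specified has none — and equalisation is global rather than
tile-adaptive.

## Unpaired translation

The translation stage is a cycle-consistent adversarial model with two
generators and two patch discriminators and the overall objective

$$L(G_{FH}, G_{HF}, D_{FH}, D_{HF}) =
  L_{FH} + L_{HF} + \lambda\, L_{cyc},$$

with least-squares adversarial terms (real → 1, fake → 0) and an L1
cycle term in both directions. The least-squares variant and
$\lambda = 10$ follow the original recipe's defaults, which the
pipeline otherwise retains; the published training configuration —
batch size 16, 50 epochs, Adam at 2e-4 with $\beta_1 = 0.5$ — is the
package default (`translate_config()`).

The networks themselves are deliberately small 3 × 3 convolutional
stacks (two hidden generator layers, sigmoid output in [0, 1]; one
hidden discriminator layer with linear patch outputs) whose channel
width scales with the config, with forward and backward passes written
out explicitly. This keeps desk-scale training on a single CPU in
seconds while preserving the training dynamics the tests probe
(adversarial seesaw plus cycle-driven convergence). Toy smoke
configurations in the tests (16 × 16 images, width 4, two epochs, 8
images per domain) raise the learning rate to 2e-3: with eight Adam
updates at the full-scale rate such a toy model moves by ~1e-3 and the
loss trend would be measurement noise; the step is scaled once to the
toy problem and the package default is untouched.

Histology inputs are background-masked by default before training
(`mask_histology = TRUE`), and each patch is cropped at a random
position and size — from the model input size up to the full patch —
then resized to the input size, mirroring how whole-slide crops of
varying physical scale are consumed. FLIM inputs are shuffled without
regard to wavelength, which is what makes a single model serve
arbitrary emission bands.

At inference, `translate_image` optionally multiplies the output by an
intensity mask: renderings without a dark background can hallucinate
background texture, and masking with the (binary) intensity image
suppresses it. Downstream code depends only on the translator
interface `f(image) -> image` (`as_translator`), so the identity and
contrast-boost translators stand in for the trained model in every
registration test; translation fidelity on patient data is explicitly
out of scope.

## Homography regression

The homography acts on homogeneous pixel coordinates, `x` = column and
`y` = row, 0-based, and is exposed normalised to $h_{33} = 1$. Warping
is inverse-mapped: each output pixel samples the input at the
$H^{-1}$-transformed position with bilinear interpolation and zero
fill outside the source. The loss is the masked mean absolute
difference on a [0, 1] scale; the PPM mask keeps the centred
`w × w` window (default 200 on 256² inputs, i.e. a 28-pixel excluded
frame) because the cropped histology patch's larger field of view
contaminates the border. The mask lives in the fixed-image frame,
where that contamination occurs. For colour inputs the L1 average runs
over channels after the per-channel differences.

Several open details were resolved as follows:

- **Loss normalisation.** The loss is the *mean* over masked pixels
  (and channels), not a sum or a side-length normalisation; this makes
  learning rates transfer across window sizes.
- **Parameterisation.** All nine entries of `H` are optimised,
  initialised to the identity. Internally coordinates are normalised
  to [−1, 1] so that translation, rotation/scale and perspective
  entries live on comparable scales; the conversion matrices are exact
  similarity transforms and round-trip to machine precision.
- **Optimiser.** Plain gradient descent without momentum, 200 epochs,
  learning rate 0.01 multiplied by 0.1 at epoch 100 — the reference
  schedule used for all comparison experiments. The reported matrix is
  the *best-loss* iterate, not the last: with a contaminated window
  the loss along the trajectory is not monotone, and best-loss
  reporting is what gives the window-size experiment its observed
  behaviour.
- **Gradients.** The gradient of the masked loss with respect to `H`
  is analytic: the L1 subgradient (0 at 0) chains through the bilinear
  interpolation weights, the projective division, and
  $\partial H^{-1}/\partial H = -H^{-1} E_{ij} H^{-1}$. Out-of-bounds
  samples contribute zero value and zero gradient. The tests require
  agreement with central finite differences to a relative error of
  1e-3; the achieved agreement is ~1e-5.

The basin of attraction of this purely local optimisation is set by
the image's spatial correlation length. The synthetic registration
phantoms are Gaussian random fields smoothed with σ = 6 px, a
correlation length comparable to the broad tissue structures that
drive the photometric loss on real data; under the reference schedule
the recovery suite (translations ≤ 10 px, rotations ≤ 5°, scale
0.95–1.05, perspective ≤ 1e-4, noise σ = 0.02) converges to well under
a pixel of corner error. Transforms far outside those ranges (e.g.
scale changes beyond ~15%) exceed the basin and are out of scope —
multi-scale schemes are deliberately not implemented.

## The window-size / patch-size experiment

Two phantom constructions (`make_fov_pair`) reproduce the interaction
between the PPM window and the cropped patch's field of view:

- **Smaller-FOV patch** (true scale 1.12): the tissue is homogeneous
  in the centre with informative structure near the tile periphery. A
  196 window sees almost constant intensity, receives no usable
  gradient and stalls at the identity (corner error ≈ the planted
  transform); a 246 window captures the peripheral structure and
  converges.
- **Larger-FOV patch** (true scale 0.88): the fixed patch shows bright
  unmasked slide background beyond the moving tile's footprint, and
  the tile itself sits at a tissue edge with a bright border band. A
  246 window includes background pixels whose large constant penalty
  grows as the moving image shrinks towards the true pose, so the
  best-loss iterate stays near the start; a 196 window lies inside the
  warped tile's footprint at the true pose and converges cleanly.

Both failure mechanisms mirror what is observed on real data —
failures cluster at tissue-edge tiles and contaminated windows — but
they are *constructed*: the phantoms plant exactly the pathology the
experiment is about, and passing shows the optimiser responds to it as
described, not that real croppings always behave this way.

## Stitching and cell profiles

"Averaging the patch positions" is interpreted as: compute the mean
horizontal and vertical displacement between grid-adjacent tiles, then
snap every tile to the regular grid those means define, anchored at
the mean origin. A pass-through mode keeps the raw positions (used
e.g. to verify exact reassembly of a jittered cut). Overlaps compose
by unweighted mean, except that zero-valued (filtered) pixels are
excluded so the dark background of one tile cannot dim tissue in
another; a background image composites beneath with configurable
alpha. Cell profiles are the plain mean lifetime over the centred
5 × 5 pixel neighbourhood per wavelength — cells span several pixels,
so the neighbourhood mean is reported as the cell's absolute lifetime.

## Similarity metrics

MSE, Pearson cross-correlation and normalised mutual information
(`2 I(A;B)/(H(A)+H(B))`, 64 equal-width bins, computed on luma for
colour inputs) are provided for context. They are documented — not
asserted — as unreliable rankings for strongly multi-modal pairs; on
synthetic data the corner reprojection error against the known
homography is the authoritative signal, and it is what the acceptance
checks use.

## What the synthetic data does and does not show

The generator produces Poisson mono-exponential decays with
region-wise lifetimes (defaults: 1.5 ns vs 3.0 ns, the printed
tumour/alveoli contrast; 10⁴ expected photons per pixel and band), a
linear spectral sensitivity roll-off towards long wavelengths
(emulating the low-SNR regime there), H&E-like pseudo-histology
sharing the region geometry, and Gaussian-random-field textures for
registration. Everything is a pure function of its spec and seed.

Deliberately absent: instrument response convolution, multi-exponential
decays, detector afterpulsing, stain variation, sectioning distortion
and non-rigid tissue deformation. Passing tests therefore demonstrate
the correctness of the algorithms under their stated models — exact
filters, calibrated fits, convergent registration within the basin —
not end-to-end performance on patient material, which additionally
depends on translation fidelity and tissue-specific texture.

## Problem sizes

Desk-scale defaults keep every experiment on one CPU: hypercubes of
64 × 64 × 16 × 32 (the full 256 × 256 × 512 × 32 geometry is supported
but not the default), registration at 256² with the 200-epoch
schedule (a few seconds per case), translation smoke models at 16²
with width 4. The acceptance script's 20-case recovery suite is the
longest single experiment at roughly two minutes.
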