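# flimcoreg

Co-registration of full-spectral autofluorescence lifetime microscopy
(FS-FLIM) images with H&E-stained histology.

## The problem

FS-FLIM measures, per pixel, a fluorescence decay histogram resolved
over hundreds of emission bands — a 4-D hypercube `(x, y, s, t)` of
photon counts (typically 256 × 256 × 512 × 32 per tile). Lifetime
images derived from it are diagnostically rich but visually flat and
statistically unlike the H&E histology that pathologists read, so
conventional intensity- or feature-based registration between the two
modalities fails. `flimcoreg` implements a pipeline that makes this
registration tractable and testable:

1. **Reconstruction** (`reconstruct`): per band, intensity is the time
   sum and lifetime τ comes from a per-pixel nonlinear least-squares
   fit of the mono-exponential decay `A·exp(−t/τ)`, after an optional
   spectral moving mean (`spectral_moving_mean`) that tames low-count
   bands. A photon filter (`photon_filter`) zeroes intensity and
   lifetime wherever `i ≤ √N̂`, with `N̂` the mean measured fluorescence
   concentration, and `global_normalise` puts all tiles of a microarray
   on one intensity scale.
2. **Rendering** (`render_lifetime`, `intensity_weighted`, `equalise`):
   Jet false colour over a fixed lifetime window (default [1 ns, 3 ns]),
   intensity-weighted lifetime displays, histogram equalisation for
   contrast enhancement.
3. **Histology preparation** (`background_mask`, `apply_mask`,
   `crop_patch`): grey → invert → equalise → Otsu, then pixel-wise
   masking, so the bright slide background becomes black like the FLIM
   background; patch cropping with recorded provenance.
4. **Unpaired translation** (`train_translation`, `translate_image`):
   a cycle-consistent adversarial model
   `L = L_FH + L_HF + λ·L_cyc`
   with two generator/discriminator pairs turns FLIM renderings into
   "false histology" images that share the photometric statistics of
   real histology. Any translator can stand in through `as_translator`
   (identity, contrast boost, trained model).
5. **Homography regression** (`register_homography`): starting from the
   identity, the 3 × 3 homography `H` acting on `[x, y, 1]ᵀ` is
   optimised by plain gradient descent on the partial photometric (PPM)
   L1 loss — the mean absolute difference inside a centred window
   (`ppm_mask`), which excludes the border frame contaminated by the
   larger field of view of the cropped patch. The warp
   (`warp_homography`) is differentiable and gradients with respect to
   all nine entries of `H` are analytic.
6. **Stitching and profiling** (`average_layout`, `compose_mosaic`,
   `cell_profile`): registered tiles are snapped to a regular grid by
   averaging adjacent displacements, composed with overlap averaging,
   and spectral lifetime profiles of annotated cells are read out as
   5 × 5 neighbourhood means.
7. **Metrics** (`similarity`, `corner_error`): MSE, normalised mutual
   information and normalised cross-correlation for context, plus
   corner reprojection error against known homographies — the
   authoritative recovery signal on synthetic data.

A synthetic module (`make_phantom`, `poisson_decay`,
`make_warped_pair`, `make_tile_grid`, `make_fov_pair`) generates
Poisson mono-exponential hypercubes with region-wise lifetimes,
pseudo-histology textures, warped pairs with known homographies and
jittered tile grids, so every stage is validated against ground truth
without any acquired data.

## Worked example

```r
library(flimcoreg)

## 1. simulate a two-region tissue phantom (tumour 1.5 ns | alveoli 3.0 ns)
ph <- make_phantom(phantom_spec(size = 64, S = 16, tau_ns = c(1.5, 3.0),
                                counts_per_pixel = 1e4, seed = 42))

## 2. reconstruct lifetime images, filter, normalise
stack <- reconstruct(spectral_moving_mean(ph$cube, 4))
stack <- global_normalise(list(photon_filter(stack)))[[1]]
print(stack)
#> Spectral stack: 64 x 64 px, 16 bands (500-780 nm)
#>   mean intensity (N-hat): 8042; lifetime range (nonzero): 1.38-3.28 ns
cat(sprintf("region means at 527 nm: %.2f ns | %.2f ns\n",
            mean(stack$lifetime[, 1:32, 2]), mean(stack$lifetime[, 33:64, 2])))
#> region means at 527 nm: 1.50 ns | 3.00 ns

## 3. register a moving image against a warped, noisy observation
moving <- textured_phantom(256, seed = 1, sigma = 6)
H_true <- random_homography(256, seed = 2)
pair   <- make_warped_pair(moving, H_true, noise_sd = 0.02, seed = 3)
fit <- register_homography(pair$moving, pair$fixed, regression_config())
print(fit)
#> Homography registration (PPM L1 gradient descent)
#>   image side: 256 px, window: 200 px, epochs: 200
#>   initial loss: 0.09867, best loss: 0.01609 (improved)
#> Homography (pixel coordinates, h33 = 1):
#>            [,1]        [,2]    [,3]
#> [1,] 9.9990e-01 -1.2794e-03 -3.3991
#> [2,] 2.4045e-02  1.0004e+00  3.9261
#> [3,] 8.7113e-05  9.1057e-05  1.0000
cat(sprintf("corner reprojection error: %.3f px\n",
            corner_error(fit$H, H_true, 256)))
#> corner reprojection error: 0.079 px
```

The regression recovers the planted transform (translation, rotation,
scale and perspective terms) to well under a pixel of mean corner
displacement; the reconstructed region lifetimes reproduce the planted
tumour/alveoli contrast to 0.01 ns.

A command-line front end for the same operations ships at
`inst/cli/flimcoreg.R` (subcommands `simulate`, `reconstruct`,
`render`, `mask-histology`, `crop`, `translate`, `register`,
`evaluate`, `stitch`).

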