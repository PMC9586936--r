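## Synthetic phantom generators: every stage of the pipeline is testable
## against known ground truth without any acquired data.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Sample a Poisson mono-exponential decay histogram
#'
#' Expected counts proportional to `exp(-t / tau)` at the left edge of
#' each time bin, scaled to `total_counts` in expectation, then
#' Poisson-sampled.
#'
#' @param tau lifetime (ns), > 0.
#' @param total_counts expected total photon count.
#' @param T number of time bins (>= 3).
#' @param bin_width bin width (ns).
#' @param seed optional integer; fixes the sample.
#' @return integer vector of length `T`.
#' @export
poisson_decay <- function(tau, total_counts, T = 32L, bin_width = 0.4,
                          seed = NULL) {
  if (tau <= 0) stop_invalid("tau must be positive")
  if (T < 3) stop_invalid("need at least 3 time bins")
  t <- (seq_len(T) - 1) * bin_width
  lambda <- exp(-t / tau)
  lambda <- lambda / sum(lambda) * total_counts
  with_seed(seed, stats::rpois(T, lambda))
}

#' Phantom specification
#'
#' Describes a synthetic FS-FLIM acquisition: a label image assigning
#' each pixel to a region, per-region lifetimes and amplitudes, the time
#' and spectral axes, and a spectral roll-off that dims long-wavelength
#' bands (emulating the weak emission and poor SNR beyond ~650 nm).
#'
#' @param size spatial side in pixels.
#' @param region_map integer matrix `size x size` of region labels
#'   (default: left/right split into regions 1 and 2).
#' @param tau_ns named or positional per-region lifetimes (ns); default
#'   `c(1.5, 3.0)`, the printed tumour vs. healthy-alveoli contrast.
#' @param counts_per_pixel expected total photons per pixel per band at
#'   full spectral sensitivity.
#' @param T,bin_width_ns time axis (32 bins of 0.4 ns by default).
#' @param S spectral bands, wavelengths spread over
#'   `wavelength_range_nm`.
#' @param wavelength_range_nm emission range, default 500-780 nm.
#' @param rolloff_start fraction of the band axis after which intensity
#'   decays linearly to `rolloff_floor`.
#' @param rolloff_floor relative intensity of the last band.
#' @param seed integer fixing all randomness.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 64L, region_map = NULL,
                         tau_ns = c(1.5, 3.0), counts_per_pixel = 1e4,
                         T = 32L, bin_width_ns = 0.4, S = 16L,
                         wavelength_range_nm = c(500, 780),
                         rolloff_start = 0.6, rolloff_floor = 0.2,
                         seed = 1L) {
  if (any(tau_ns <= 0)) stop_invalid("all region lifetimes must be > 0")
  if (is.null(region_map)) {
    region_map <- matrix(1L, size, size)
    region_map[, seq_len(size) > size / 2] <- 2L
  }
  if (!all(dim(region_map) == size))
    stop_invalid("region_map must be size x size")
  if (!all(unique(as.vector(region_map)) %in% seq_along(tau_ns)))
    stop_invalid("region_map contains labels without a lifetime")
  structure(list(size = as.integer(size), region_map = region_map,
                 tau_ns = tau_ns, counts_per_pixel = counts_per_pixel,
                 T = as.integer(T), bin_width_ns = bin_width_ns,
                 S = as.integer(S),
                 wavelength_range_nm = wavelength_range_nm,
                 rolloff_start = rolloff_start,
                 rolloff_floor = rolloff_floor,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## per-band relative sensitivity implied by a phantom spec
band_scaling <- function(spec) {
  s <- seq(0, 1, length.out = spec$S)
  ifelse(s <= spec$rolloff_start, 1,
         1 + (spec$rolloff_floor - 1) *
           (s - spec$rolloff_start) / (1 - spec$rolloff_start))
}

#' Generate a synthetic FS-FLIM phantom
#'
#' Builds a Poisson mono-exponential hypercube whose per-pixel lifetime
#' follows the region map, the ground-truth lifetime map, and a
#' pseudo-histology rendering of the same geometry in H&E-like colours
#' (purple nuclei speckle on pink tissue). FLIM and pseudo-histology
#' share structure but differ completely in appearance — the statistical
#' situation the registration faces.
#'
#' @param spec [phantom_spec].
#' @return list with elements `cube` ([flim_hypercube]), `tau_map`
#'   (matrix, ns), `histology` (RGB array).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    M <- spec$size; S <- spec$S; T <- spec$T
    t <- (seq_len(T) - 1) * spec$bin_width_ns
    tau_map <- matrix(spec$tau_ns[spec$region_map], M, M)
    scal <- band_scaling(spec)
    counts <- array(0, dim = c(M, M, S, T))
    tau_vec <- as.vector(tau_map)
    decay <- exp(-outer(1 / tau_vec, t))            # (M^2, T)
    decay <- decay / rowSums(decay)
    for (s in seq_len(S)) {
      lam <- decay * (spec$counts_per_pixel * scal[s])
      counts[, , s, ] <- array(stats::rpois(length(lam), lam), dim = c(M, M, T))
    }
    wl <- seq(spec$wavelength_range_nm[1], spec$wavelength_range_nm[2],
              length.out = S)
    cube <- flim_hypercube(counts, wl, spec$bin_width_ns, fov_um = 600)

    # H&E-like rendering of the same region geometry
    base <- list(c(0.91, 0.55, 0.75),   # region 1: eosin pink
                 c(0.55, 0.35, 0.70))   # region 2: haematoxylin purple
    extra <- replicate(max(0, length(spec$tau_ns) - 2),
                       stats::runif(3, 0.3, 0.9), simplify = FALSE)
    pal <- c(base, extra)
    histology <- array(0, dim = c(M, M, 3))
    for (ch in 1:3) {
      col_map <- matrix(vapply(as.vector(spec$region_map),
                               function(r) pal[[r]][ch], numeric(1)), M, M)
      histology[, , ch] <- col_map
    }
    # nuclei speckle: dark blobs shared across channels
    speck <- gaussian_blur(matrix(stats::rnorm(M * M), M, M), 1.5)
    speck <- (speck - min(speck)) / (max(speck) - min(speck))
    nuclei <- speck < stats::quantile(speck, 0.15)
    for (ch in 1:3) {
      v <- histology[, , ch]
      v[nuclei] <- v[nuclei] * 0.35
      histology[, , ch] <- clamp(v, 0, 1)
    }
    list(cube = cube, tau_map = tau_map, histology = histology)
  })
}

#' Textured phantom image for registration experiments
#'
#' A smoothed Gaussian random field rescaled to `[0, 1]`, with spatial
#' correlation length set by `sigma`; emulates the broad tissue texture
#' that drives the photometric loss basin. Optionally tinted to an
#' H&E-like RGB image.
#'
#' @param N image side in pixels.
#' @param seed integer seed.
#' @param sigma blur radius (pixels) controlling feature size.
#' @param rgb return an H&E-tinted RGB array instead of a grey matrix.
#' @return matrix or RGB array in `[0, 1]`.
#' @export
textured_phantom <- function(N = 256L, seed = 1L, sigma = 6, rgb = FALSE) {
  with_seed(seed, {
    g <- gaussian_blur(matrix(stats::rnorm(N * N), N, N), sigma)
    g <- (g - min(g)) / (max(g) - min(g))
    if (!rgb) return(g)
    out <- array(0, dim = c(N, N, 3))
    out[, , 1] <- 0.55 + 0.40 * g
    out[, , 2] <- 0.30 + 0.35 * g
    out[, , 3] <- 0.55 + 0.30 * g
    clamp(out, 0, 1)
  })
}

#' Build a registration test pair with known homography
#'
#' Warps `image` by the ground-truth homography and adds clipped
#' Gaussian noise, returning the moving image, the fixed (warped, noisy)
#' image and the truth.
#'
#' @param image grey matrix or RGB array in `[0, 1]`.
#' @param H_true [homography].
#' @param noise_sd standard deviation of the additive noise.
#' @param seed optional integer.
#' @return list `(moving, fixed, H_true)`.
#' @export
make_warped_pair <- function(image, H_true, noise_sd = 0, seed = NULL) {
  H_true <- homography(H_true)
  fixed <- warp_homography(image, H_true)
  if (noise_sd > 0) {
    fixed <- with_seed(seed,
      clamp(fixed + stats::rnorm(length(fixed), 0, noise_sd), 0, 1))
    if (is_rgb(image)) dim(fixed) <- dim(image)
  }
  list(moving = image, fixed = fixed, H_true = H_true)
}

#' Random small homography
#'
#' Draws a homography within the perturbation ranges used by the
#' recovery experiments: translation, rotation, isotropic scale about
#' the image centre, plus small perspective terms.
#'
#' @param N image side (pixels); rotation/scale are about the centre.
#' @param max_shift_px,max_rot_deg,scale_range,max_perspective ranges.
#' @param seed optional integer.
#' @return [homography].
#' @export
random_homography <- function(N = 256L, max_shift_px = 10, max_rot_deg = 5,
                              scale_range = c(0.95, 1.05),
                              max_perspective = 1e-4, seed = NULL) {
  with_seed(seed, {
    tx <- stats::runif(1, -max_shift_px, max_shift_px)
    ty <- stats::runif(1, -max_shift_px, max_shift_px)
    th <- stats::runif(1, -max_rot_deg, max_rot_deg) * pi / 180
    sc <- stats::runif(1, scale_range[1], scale_range[2])
    px <- stats::runif(1, -max_perspective, max_perspective)
    py <- stats::runif(1, -max_perspective, max_perspective)
    c0 <- (N - 1) / 2
    C <- matrix(c(1, 0, 0, 0, 1, 0, -c0, -c0, 1), 3, 3)
    R <- matrix(c(sc * cos(th), sc * sin(th), px,
                  -sc * sin(th), sc * cos(th), py,
                  tx, ty, 1), 3, 3)
    homography(solve(C) %*% R %*% C)
  })
}

#' Cut a mosaic into an overlapping, jittered tile grid
#'
#' Emulates sequential tile acquisition across a microarray: a regular
#' `rows x cols` grid with `overlap_px` overlap between neighbours, each
#' tile's cut position jittered uniformly by up to `jitter_px`. Returns
#' the tiles, their true cut offsets and grid indices.
#'
#' @param mosaic grey matrix or RGB array.
#' @param rows,cols grid shape.
#' @param overlap_px nominal overlap between adjacent tiles (>= 0).
#' @param jitter_px maximum absolute jitter applied per tile and axis.
#' @param seed optional integer.
#' @return list `(tiles, offsets, grid, tile_size)`; offsets are 0-based
#'   `(x, y)` pixel positions in the mosaic, `grid` the (row, col) index
#'   of each tile.
#' @export
make_tile_grid <- function(mosaic, rows, cols, overlap_px = 8L,
                           jitter_px = 0L, seed = NULL) {
  d <- if (is_rgb(mosaic)) dim(mosaic)[1:2] else dim(mosaic)
  if (overlap_px < 0) stop_invalid("overlap must be >= 0")
  # tile size from the grid geometry: cols tiles spanning the width with
  # the given overlap
  tw <- floor((d[2] + (cols - 1) * overlap_px) / cols)
  th <- floor((d[1] + (rows - 1) * overlap_px) / rows)
  if (tw <= overlap_px || th <= overlap_px)
    stop_invalid("grid geometry infeasible for this mosaic size")
  with_seed(seed, {
    tiles <- list(); offsets <- NULL; grid <- NULL
    k <- 0L
    for (i in seq_len(rows)) {
      for (j in seq_len(cols)) {
        k <- k + 1L
        x0 <- (j - 1L) * (tw - overlap_px)
        y0 <- (i - 1L) * (th - overlap_px)
        if (jitter_px > 0) {
          x0 <- x0 + sample(-jitter_px:jitter_px, 1)
          y0 <- y0 + sample(-jitter_px:jitter_px, 1)
        }
        x0 <- clamp(x0, 0, d[2] - tw); y0 <- clamp(y0, 0, d[1] - th)
        tiles[[k]] <- if (is_rgb(mosaic))
          mosaic[y0 + seq_len(th), x0 + seq_len(tw), , drop = FALSE]
        else mosaic[y0 + seq_len(th), x0 + seq_len(tw), drop = FALSE]
        offsets <- rbind(offsets, c(x = x0, y = y0))
        grid <- rbind(grid, c(row = i, col = j))
      }
    }
    list(tiles = tiles, offsets = offsets, grid = grid,
         tile_size = c(h = th, w = tw))
  })
}

#' Registration pair with a mismatched field of view
#'
#' Builds moving/fixed pairs emulating the two problematic patch
#' croppings met in practice, for studying how the PPM window size
#' interacts with the patch field of view (FOV).
#'
#' `patch = "small"`: the fixed patch covers a smaller area than the
#' moving tile (true scale > 1) and the tissue is homogeneous in the
#' centre with informative structure near the tile periphery — a small
#' window then sees almost no photometric signal, while a large window
#' captures the peripheral structure.
#'
#' `patch = "large"`: the fixed patch covers a larger area (true scale
#' < 1) and shows bright unmasked slide background beyond the moving
#' tile's FOV; the moving tile sits at a tissue edge with a bright
#' border band. A window wider than the warped tile then includes
#' background pixels that corrupt the loss, while a window inside the
#' tile's footprint stays clean.
#'
#' @param N image side in pixels.
#' @param patch `"small"` or `"large"` fixed-patch FOV.
#' @param seed integer seed.
#' @param shift_px,rot_deg true translation and rotation.
#' @return list `(moving, fixed, H_true)`.
#' @export
make_fov_pair <- function(N = 256L, patch = c("small", "large"), seed = 1L,
                          shift_px = c(6, -5), rot_deg = 2) {
  patch <- match.arg(patch)
  g <- textured_phantom(N, seed = seed, sigma = 6)
  c0 <- (N - 1) / 2
  cheb <- pmax(abs(col(g) - 1 - c0), abs(row(g) - 1 - c0))
  if (patch == "small") {
    m <- g
    m[cheb <= round(0.39 * N)] <- mean(g)   # homogeneous tissue centre
    m <- gaussian_blur(m, 2)
    sc <- 1.12
  } else {
    m <- 0.15 + 0.6 * g
    m[cheb > round(0.4375 * N)] <- 0.95     # bright slide edge band
    m <- gaussian_blur(m, 1.5)
    sc <- 0.88
  }
  th <- rot_deg * pi / 180
  C <- matrix(c(1, 0, 0, 0, 1, 0, -c0, -c0, 1), 3, 3)
  R <- matrix(c(sc * cos(th), sc * sin(th), 0,
                -sc * sin(th), sc * cos(th), 0,
                shift_px[1], shift_px[2], 1), 3, 3)
  H_true <- homography(solve(C) %*% R %*% C)
  fixed <- warp_homography(m, H_true)
  if (patch == "large") {
    cov <- warp_homography(matrix(1, N, N), H_true)
    fixed <- fixed * cov + 1.0 * (1 - cov)  # white background beyond the tile
  }
  fixed <- with_seed(seed + 9000L,
    clamp(fixed + stats::rnorm(length(fixed), 0, 0.01), 0, 1))
  dim(fixed) <- dim(m)
  list(moving = m, fixed = fixed, H_true = H_true)
}
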