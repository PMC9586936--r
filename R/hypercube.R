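#' FS-FLIM hypercube container
#'
#' A raw full-spectral FLIM measurement: photon counts indexed by two
#' spatial dimensions, emission band and time channel, as acquired by a
#' time-resolved spectral detector (e.g. 256 x 256 x 512 x 32 per tile).
#'
#' @param counts 4-D non-negative array `(M, M, S, T)`.
#' @param wavelengths_nm strictly increasing emission wavelengths, length
#'   `S` (nm).
#' @param time_bin_ns width of one time channel (ns).
#' @param fov_um field of view of the tile (micrometres), optional.
#' @return object of class `flim_hypercube`.
#' @export
flim_hypercube <- function(counts, wavelengths_nm, time_bin_ns, fov_um = NA_real_) {
  d <- dim(counts)
  if (length(d) != 4L) stop_invalid("counts must be a 4-D (x, y, s, t) array")
  if (d[1] != d[2]) stop_invalid("spatial extents must be equal (M x M)")
  if (any(!is.finite(counts))) stop_invalid("counts contain non-finite values")
  if (any(counts < 0)) stop_invalid("photon counts must be non-negative")
  if (length(wavelengths_nm) != d[3])
    stop_invalid("wavelengths length (%d) != spectral extent (%d)",
                 length(wavelengths_nm), d[3])
  if (any(diff(wavelengths_nm) <= 0))
    stop_invalid("wavelengths must be strictly increasing")
  if (time_bin_ns <= 0) stop_invalid("time_bin_ns must be positive")
  structure(list(counts = counts,
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 time_bin_ns = as.numeric(time_bin_ns),
                 fov_um = as.numeric(fov_um)),
            class = "flim_hypercube")
}

#' @export
print.flim_hypercube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("FS-FLIM hypercube: %d x %d px, %d bands (%.0f-%.0f nm), %d time channels (%.3g ns each)\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
              d[4], x$time_bin_ns))
  cat(sprintf("  total photons: %.4g; FOV: %s um\n", sum(x$counts),
              if (is.na(x$fov_um)) "unknown" else format(x$fov_um)))
  invisible(x)
}

#' Spectral stack of paired intensity and lifetime images
#'
#' Per-band photon-count intensity and fitted lifetime (ns) images
#' derived from one hypercube.
#'
#' @param intensity,lifetime arrays `(M, M, S)`; lifetime must be 0
#'   wherever intensity is 0.
#' @param wavelengths_nm per-band wavelengths (nm).
#' @param intensity_mean mean measured fluorescence concentration of the
#'   stack (computed if missing).
#' @return object of class `spectral_stack`.
#' @export
spectral_stack <- function(intensity, lifetime, wavelengths_nm,
                           intensity_mean = mean(intensity)) {
  if (!identical(dim(intensity), dim(lifetime)))
    stop_invalid("intensity and lifetime shapes differ")
  if (length(dim(intensity)) != 3L)
    stop_invalid("stack arrays must be (x, y, s)")
  if (any(intensity < 0) || any(lifetime < 0))
    stop_invalid("intensity and lifetime must be non-negative")
  if (length(wavelengths_nm) != dim(intensity)[3])
    stop_invalid("wavelengths length mismatch")
  structure(list(intensity = intensity, lifetime = lifetime,
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 intensity_mean = intensity_mean),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  d <- dim(x$intensity)
  nz <- x$lifetime[x$intensity > 0]
  cat(sprintf("Spectral stack: %d x %d px, %d bands (%.0f-%.0f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm)))
  cat(sprintf("  mean intensity (N-hat): %.4g; lifetime range (nonzero): %s ns\n",
              x$intensity_mean,
              if (length(nz)) sprintf("%.2f-%.2f", min(nz), max(nz)) else "none"))
  invisible(x)
}

#' Spectral moving mean
#'
#' Replaces each emission band by the mean of a centred window of `width`
#' bands, truncated (shrunk) at the spectral edges; used to tame the low
#' photon counts at the edges of the emission spectrum before lifetime
#' estimation. Spatial and time dimensions are untouched.
#'
#' @param cube [flim_hypercube].
#' @param width window width in bands (default 8, ~4.5 nm on a 512-band
#'   500-780 nm grid).
#' @return smoothed [flim_hypercube] (counts become non-integer means).
#' @export
spectral_moving_mean <- function(cube, width = 8L) {
  stopifnot(inherits(cube, "flim_hypercube"))
  S <- dim(cube$counts)[3]
  if (width < 1 || width > S)
    stop_invalid("width must be in [1, %d]", S)
  if (width == 1) return(cube)
  d <- dim(cube$counts)
  # cumulative sum along the spectral axis; window sums by subtraction
  cs <- array(0, dim = c(d[1], d[2], S + 1L, d[4]))
  for (s in seq_len(S))
    cs[, , s + 1L, ] <- cs[, , s, ] + cube$counts[, , s, ]
  half_lo <- floor((width - 1) / 2)
  half_hi <- width - 1L - half_lo
  out <- array(0, dim = d)
  for (s in seq_len(S)) {
    lo <- max(1L, s - half_lo); hi <- min(S, s + half_hi)
    out[, , s, ] <- (cs[, , hi + 1L, ] - cs[, , lo, ]) / (hi - lo + 1L)
  }
  flim_hypercube(out, cube$wavelengths_nm, cube$time_bin_ns, cube$fov_um)
}

## Vectorised Gauss-Newton fit of y_t ~ A exp(-t/tau) across many decay
## histograms at once. `Y` is (n, T); `t` the time at each bin (ns).
## Returns tau (ns); rows that fail to converge to a positive rate get 0.
fit_monoexp <- function(Y, t, max_iter = 50L, tol = 1e-10) {
  n <- nrow(Y)
  if (n == 0) return(numeric(0))
  tot <- rowSums(Y)
  # initial decay rate from an intensity-weighted log-linear regression,
  # robust to Poisson noise in the tail
  eps <- 1e-12
  L <- log(pmax(Y, eps))
  w <- Y
  sw <- rowSums(w); swt <- as.vector(w %*% t); swt2 <- as.vector(w %*% t^2)
  swl <- rowSums(w * L); swtl <- as.vector(rowSums(w * sweep(L, 2, t, `*`)))
  denom <- sw * swt2 - swt^2
  b <- -(sw * swtl - swt * swl) / pmax(denom, eps)   # decay rate 1/tau
  b <- clamp(b, 1e-3, 1e3)
  A <- tot / pmax(rowSums(exp(-outer(b, t))), eps)
  active <- rep(TRUE, n)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    bi <- b[active]; Ai <- A[active]
    E <- exp(-outer(bi, t))            # (na, T)
    M <- Ai * E                        # model
    R <- M - Y[active, , drop = FALSE]
    # Jacobian columns: dM/dA = E ; dM/db = -A t E
    Jb <- -M * rep(t, each = length(bi))
    saa <- rowSums(E * E); sab <- rowSums(E * Jb); sbb <- rowSums(Jb * Jb)
    ra <- rowSums(R * E); rb <- rowSums(R * Jb)
    det <- saa * sbb - sab * sab
    det[det < 1e-300] <- 1e-300
    dA <- (sbb * ra - sab * rb) / det
    db <- (saa * rb - sab * ra) / det
    # damped step: keep the rate positive
    newb <- bi - db
    bad <- newb <= 0
    newb[bad] <- bi[bad] / 2
    newA <- Ai - dA
    newA[newA <= 0] <- Ai[newA <= 0] / 2
    step <- pmax(abs(db) / pmax(bi, eps), abs(dA) / pmax(Ai, eps))
    b[active] <- newb; A[active] <- newA
    done <- step < tol
    active[active] <- !done
  }
  tau <- 1 / b
  tau[!is.finite(tau) | tau <= 0] <- 0
  tau
}

#' Reconstruct intensity and lifetime images from a hypercube
#'
#' Per band, intensity is the sum of the time-channel counts; lifetime is
#' the decay constant of a per-pixel nonlinear least-squares fit of the
#' mono-exponential model `A exp(-t / tau)` to the raw time histogram.
#' Pixels whose total count is below `min_counts` cannot support a
#' meaningful fit and get lifetime 0.
#'
#' @param cube [flim_hypercube].
#' @param min_counts fit-feasibility floor on the per-(pixel, band) total
#'   photon count (default 25).
#' @return [spectral_stack].
#' @export
reconstruct <- function(cube, min_counts = 25) {
  stopifnot(inherits(cube, "flim_hypercube"))
  d <- dim(cube$counts)
  if (d[4] < 3L) stop_invalid("at least 3 time channels are required")
  t <- (seq_len(d[4]) - 1) * cube$time_bin_ns
  M2 <- d[1] * d[2]
  intensity <- array(0, dim = d[1:3])
  lifetime <- array(0, dim = d[1:3])
  for (s in seq_len(d[3])) {
    Y <- matrix(cube$counts[, , s, ], M2, d[4])
    tot <- rowSums(Y)
    intensity[, , s] <- matrix(tot, d[1], d[2])
    sel <- tot >= min_counts
    if (any(sel)) {
      tau <- fit_monoexp(Y[sel, , drop = FALSE], t)
      lt <- numeric(M2); lt[sel] <- tau
      lifetime[, , s] <- matrix(lt, d[1], d[2])
    }
  }
  spectral_stack(intensity, lifetime, cube$wavelengths_nm)
}

#' Photon-count threshold filter
#'
#' Zeroes both intensity and lifetime wherever the per-band intensity is
#' at or below `sqrt(N-hat)`, with `N-hat` the mean measured fluorescence
#' concentration; suppresses photon quantum noise in low-count pixels.
#' By default `N-hat` is the mean of the intensity image of each spectral
#' band; `scope = "stack"` uses one mean over the whole stack.
#'
#' @param stack [spectral_stack].
#' @param scope `"band"` (default) or `"stack"`.
#' @param nhat optional frozen `N-hat` (scalar, or length-S vector for
#'   band scope), e.g. from a previous application; when supplied it is
#'   used instead of being recomputed, making the filter idempotent.
#' @return filtered [spectral_stack] with attribute `nhat` recording the
#'   threshold basis used.
#' @export
photon_filter <- function(stack, scope = c("band", "stack"), nhat = NULL) {
  stopifnot(inherits(stack, "spectral_stack"))
  scope <- match.arg(scope)
  S <- dim(stack$intensity)[3]
  if (is.null(nhat)) {
    nhat <- if (scope == "band") {
      apply(stack$intensity, 3, mean)
    } else {
      mean(stack$intensity)
    }
  }
  thr <- sqrt(nhat)
  intensity <- stack$intensity
  lifetime <- stack$lifetime
  if (length(thr) == 1L) thr <- rep(thr, S)
  for (s in seq_len(S)) {
    kill <- intensity[, , s] <= thr[s]
    i <- intensity[, , s]; l <- lifetime[, , s]
    i[kill] <- 0; l[kill] <- 0
    intensity[, , s] <- i; lifetime[, , s] <- l
  }
  out <- spectral_stack(intensity, lifetime, stack$wavelengths_nm,
                        stack$intensity_mean)
  attr(out, "nhat") <- nhat
  out
}

#' Global intensity normalisation across a microarray
#'
#' Rescales the intensities of all stacks acquired on one microarray by a
#' single shared factor (the global maximum) to `[0, 1]`, so relative
#' brightness is comparable across tiles and wavelengths. Lifetimes are
#' left untouched (their display range is a rendering concern).
#'
#' @param stacks list of [spectral_stack] on identical wavelength grids.
#' @param per_band normalise each band by its own global-across-stacks
#'   maximum instead of one overall factor.
#' @return list of normalised stacks.
#' @export
global_normalise <- function(stacks, per_band = FALSE) {
  if (length(stacks) < 1) stop_invalid("need at least one stack")
  wl <- stacks[[1]]$wavelengths_nm
  for (s in stacks) {
    stopifnot(inherits(s, "spectral_stack"))
    if (!isTRUE(all.equal(s$wavelengths_nm, wl)))
      stop_invalid("stacks must share one wavelength grid")
  }
  if (per_band) {
    S <- length(wl)
    mx <- rep(0, S)
    for (s in stacks)
      mx <- pmax(mx, apply(s$intensity, 3, max))
    if (all(mx == 0)) {
      warning("all-zero intensity collection; returned unchanged")
      return(stacks)
    }
    mx[mx == 0] <- 1
    lapply(stacks, function(s) {
      spectral_stack(sweep(s$intensity, 3, mx, `/`), s$lifetime,
                     s$wavelengths_nm, s$intensity_mean)
    })
  } else {
    mx <- max(vapply(stacks, function(s) max(s$intensity), numeric(1)))
    if (mx == 0) {
      warning("all-zero intensity collection; returned unchanged")
      return(stacks)
    }
    lapply(stacks, function(s) {
      spectral_stack(s$intensity / mx, s$lifetime, s$wavelengths_nm,
                     s$intensity_mean)
    })
  }
}

#' Read / write hypercubes and stacks
#'
#' Serialisation of the pipeline containers to single files (R's native
#' RDS format), preserving counts/intensity/lifetime together with the
#' wavelength grid, time-bin width and field of view.
#'
#' @param path file path.
#' @param x object to write.
#' @return the object (readers), or `path` invisibly (writers).
#' @export
read_flim_hypercube <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "flim_hypercube")) stop_invalid("not a hypercube file")
  x
}

#' @rdname read_flim_hypercube
#' @export
write_flim_hypercube <- function(x, path) {
  stopifnot(inherits(x, "flim_hypercube"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname read_flim_hypercube
#' @export
read_spectral_stack <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "spectral_stack")) stop_invalid("not a spectral stack file")
  x
}

#' @rdname read_flim_hypercube
#' @export
write_spectral_stack <- function(x, path) {
  stopifnot(inherits(x, "spectral_stack"))
  saveRDS(x, path)
  invisible(path)
}
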