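#' Rendering specification
#'
#' How to turn one spectral band of a stack into a display image: the
#' band, the fixed lifetime display window, the palette and the
#' intensity weighting.
#'
#' @param band spectral index, or a wavelength in nm (matched to the
#'   nearest band when `wavelength = TRUE`).
#' @param lifetime_range display window `(lo, hi)` in ns; values outside
#'   are clamped. Default `c(1, 3)`, the fixed range used for
#'   whole-sample visualisation.
#' @param colormap `"jet"` or `"grey"`.
#' @param weighting `"none"` or `"intensity"`.
#' @param weight_channel `"value"` or `"saturation"`: whether intensity
#'   scales the HSV value (brightness) or saturation channel.
#' @return list of class `render_spec`.
#' @export
render_spec <- function(band = 1L, lifetime_range = c(1, 3),
                        colormap = c("jet", "grey"),
                        weighting = c("none", "intensity"),
                        weight_channel = c("value", "saturation")) {
  if (lifetime_range[1] >= lifetime_range[2])
    stop_invalid("lifetime_range must satisfy lo < hi")
  structure(list(band = band, lifetime_range = lifetime_range,
                 colormap = match.arg(colormap),
                 weighting = match.arg(weighting),
                 weight_channel = match.arg(weight_channel)),
            class = "render_spec")
}

## resolve a render_spec band against a wavelength grid: values within
## 1..S are spectral indices, anything larger is matched as nm
resolve_band <- function(band, wavelengths_nm) {
  S <- length(wavelengths_nm)
  if (band > S) {
    if (band < min(wavelengths_nm) - 50 || band > max(wavelengths_nm) + 50)
      stop_invalid("band %s outside the spectral grid", band)
    return(which.min(abs(wavelengths_nm - band)))
  }
  if (band < 1)
    stop_invalid("band %s outside the spectral grid (1..%d)", band, S)
  as.integer(band)
}

## standard Jet palette: blue -> cyan -> yellow -> red over [0, 1]
jet_colors <- function(x) {
  x <- clamp(x, 0, 1)
  r <- clamp(1.5 - abs(4 * x - 3), 0, 1)
  g <- clamp(1.5 - abs(4 * x - 2), 0, 1)
  b <- clamp(1.5 - abs(4 * x - 1), 0, 1)
  cbind(r, g, b)
}

#' Render a lifetime image in false colour
#'
#' Clamps lifetime to the display window, maps it linearly through the
#' palette and renders pixels with zero (filtered) intensity black, the
#' conventional dark background of FLIM displays.
#'
#' @param stack [spectral_stack].
#' @param spec [render_spec].
#' @return RGB array in `[0, 1]` (grey matrix for `colormap = "grey"`).
#' @export
render_lifetime <- function(stack, spec = render_spec()) {
  stopifnot(inherits(stack, "spectral_stack"))
  s <- resolve_band(spec$band, stack$wavelengths_nm)
  lt <- stack$lifetime[, , s]
  inten <- stack$intensity[, , s]
  lo <- spec$lifetime_range[1]; hi <- spec$lifetime_range[2]
  u <- (clamp(lt, lo, hi) - lo) / (hi - lo)
  if (spec$colormap == "grey") {
    out <- u
    out[inten == 0] <- 0
    return(out)
  }
  cols <- jet_colors(as.vector(u))
  d <- dim(lt)
  out <- array(0, dim = c(d, 3L))
  for (ch in 1:3) {
    m <- matrix(cols[, ch], d[1], d[2])
    m[inten == 0] <- 0
    out[, , ch] <- m
  }
  out
}

#' Intensity-weighted lifetime rendering
#'
#' Scales the palette colour of each pixel by its normalised intensity,
#' so bright (photon-rich) pixels dominate and structure from the
#' intensity image carries into the lifetime display. With
#' `weight_channel = "value"` the RGB triple is multiplied by intensity
#' (brightness scaling); with `"saturation"` the colour is desaturated
#' towards white at low intensity.
#'
#' @param stack [spectral_stack] with intensities normalised to `[0, 1]`
#'   (see [global_normalise()]).
#' @param spec [render_spec].
#' @return RGB array in `[0, 1]`.
#' @export
intensity_weighted <- function(stack, spec = render_spec()) {
  stopifnot(inherits(stack, "spectral_stack"))
  s <- resolve_band(spec$band, stack$wavelengths_nm)
  if (max(stack$intensity) > 1 + 1e-9)
    stop_invalid("intensities must be normalised to [0, 1] before weighting")
  base <- render_lifetime(stack, render_spec(spec$band, spec$lifetime_range,
                                             "jet"))
  w <- stack$intensity[, , s]
  out <- base
  if (spec$weight_channel == "value") {
    for (ch in 1:3) out[, , ch] <- base[, , ch] * w
  } else {
    for (ch in 1:3) out[, , ch] <- 1 - (1 - base[, , ch]) * w
    # zero-intensity pixels stay black, not white
    for (ch in 1:3) { m <- out[, , ch]; m[w == 0] <- 0; out[, , ch] <- m }
  }
  out
}

#' Histogram equalisation of a grey image
#'
#' Standard global histogram equalisation on `levels` grey levels; a
#' monotone remapping that spreads the empirical CDF towards uniform,
#' used to enhance lifetime-image contrast before registration.
#' Constant images are returned unchanged.
#'
#' @param image grey matrix in `[0, 1]`.
#' @param levels number of grey levels (default 256).
#' @return equalised grey matrix in `[0, 1]`.
#' @export
equalise <- function(image, levels = 256L) {
  if (is_rgb(image)) stop_invalid("equalise expects a single-channel image")
  rng <- range(image)
  if (rng[1] == rng[2]) return(image)
  q <- pmin(floor(image * levels), levels - 1L)   # quantise to levels
  h <- tabulate(q + 1L, nbins = levels)
  cdf <- cumsum(h)
  cdf_min <- cdf[which(h > 0)[1]]
  lut <- (cdf - cdf_min) / (sum(h) - cdf_min)     # maps to [0, 1]
  lut[cdf < cdf_min] <- 0
  matrix(lut[q + 1L], nrow(image), ncol(image))
}
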