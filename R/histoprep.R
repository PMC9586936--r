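#' Otsu threshold
#'
#' Exhaustively maximises the between-class variance of the grey-level
#' histogram over all candidate levels and returns the level at the
#' maximum (the smallest level in case of ties).
#'
#' @param image grey matrix in `[0, 1]`.
#' @param levels number of grey levels used for the histogram (256).
#' @return threshold on the `[0, 1]` scale; pixels `> threshold` are
#'   foreground when the foreground is bright.
#' @export
otsu_threshold <- function(image, levels = 256L) {
  if (is_rgb(image)) image <- rgb_to_grey(image)
  q <- pmin(floor(image * levels), levels - 1L)
  h <- tabulate(q + 1L, nbins = levels)
  if (sum(h > 0) < 2L)
    stop_invalid("Otsu threshold is undefined for a constant image")
  p <- h / sum(h)
  lev <- 0:(levels - 1L)
  omega <- cumsum(p)                 # class-0 weight for threshold = lev
  mu <- cumsum(p * lev)
  mu_t <- mu[levels]
  # between-class variance for threshold t: pixels <= t in class 0
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  t_star <- lev[which.max(sigma_b)]
  t_star / levels
}

#' Histology background mask
#'
#' Marks tissue (1) against the bright slide background (0) with the
#' pipeline: greyscale conversion, colour inversion, histogram
#' equalisation, Otsu binarisation. On an inverted image tissue is
#' bright, so pixels above the Otsu level are tissue.
#'
#' @param rgb RGB histology image in `[0, 1]` (grey accepted).
#' @return binary matrix (0/1), 1 = tissue.
#' @export
background_mask <- function(rgb) {
  g <- rgb_to_grey(rgb)
  if (diff(range(g)) == 0) {
    warning("constant image: returning an all-zero mask")
    return(matrix(0, nrow(g), ncol(g)))
  }
  inv <- 1 - g
  eq <- equalise(inv)
  thr <- otsu_threshold(eq)
  (eq > thr) * 1
}

#' Apply a binary mask to an image
#'
#' Pixel-wise multiplication of the mask with every channel; background
#' becomes black.
#'
#' @param rgb image (grey or RGB).
#' @param mask binary matrix of matching spatial shape.
#' @return masked image.
#' @export
apply_mask <- function(rgb, mask) {
  d <- if (is_rgb(rgb)) dim(rgb)[1:2] else dim(rgb)
  if (!identical(d, dim(mask))) stop_invalid("mask shape mismatch")
  if (is_rgb(rgb)) {
    for (ch in seq_len(dim(rgb)[3])) rgb[, , ch] <- rgb[, , ch] * mask
    rgb
  } else rgb * mask
}

#' Crop a patch from a whole-slide image
#'
#' Exact sub-image copy with its provenance recorded; replaces the
#' interactive cropping step. Coordinates are 0-based, top-left origin,
#' x = column, y = row, half-open rectangles `[x, x+w) x [y, y+h)`.
#'
#' @param wsi image (grey or RGB).
#' @param origin `c(x, y)` pixel offset.
#' @param size `c(w, h)` in pixels.
#' @param mpp microns per pixel, if known.
#' @return object of class `histology_patch`: list `(rgb, origin, size,
#'   mpp)`.
#' @export
crop_patch <- function(wsi, origin, size, mpp = NA_real_) {
  d <- if (is_rgb(wsi)) dim(wsi)[1:2] else dim(wsi)
  x <- origin[1]; y <- origin[2]; w <- size[1]; h <- size[2]
  if (w < 1 || h < 1 || x < 0 || y < 0 || x + w > d[2] || y + h > d[1])
    stop_invalid("crop rectangle [%d, %d) x [%d, %d) outside WSI %d x %d",
                 x, x + w, y, y + h, d[2], d[1])
  rgb <- if (is_rgb(wsi)) wsi[y + seq_len(h), x + seq_len(w), , drop = FALSE]
  else wsi[y + seq_len(h), x + seq_len(w), drop = FALSE]
  structure(list(rgb = rgb, origin = c(x = x, y = y),
                 size = c(w = w, h = h), mpp = mpp),
            class = "histology_patch")
}

#' @export
print.histology_patch <- function(x, ...) {
  cat(sprintf("Histology patch %d x %d at (%d, %d)%s\n",
              x$size["w"], x$size["h"], x$origin["x"], x$origin["y"],
              if (is.na(x$mpp)) "" else sprintf(", %.3f um/px", x$mpp)))
  invisible(x)
}

#' Read / write images
#'
#' PNG and TIFF readers/writers for patches and rendered results;
#' images are numeric in `[0, 1]`, RGBA alpha is dropped on read.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param img image to write (grey matrix or RGB array in `[0, 1]`).
#' @return the image (reader) or `path` invisibly (writer).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop_invalid("unsupported image format: .%s", ext))
  if (is_rgb(img) && dim(img)[3] == 4L) img <- img[, , 1:3]
  img
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  img <- clamp(img, 0, 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path),
         stop_invalid("unsupported image format: .%s", ext))
  invisible(path)
}

#' Patch metadata JSON
#'
#' @param patch [crop_patch()] result.
#' @param path JSON file path.
#' @return `path` (writer) / named list (reader).
#' @export
write_patch_meta <- function(patch, path) {
  jsonlite::write_json(list(origin = unname(patch$origin),
                            size = unname(patch$size),
                            mpp = patch$mpp),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_patch_meta
#' @export
read_patch_meta <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
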