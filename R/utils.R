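#' @keywords internal
"_PACKAGE"

## Internal image helpers shared across modules. Images are numeric matrices
## (grey, values in [0,1] unless stated) or H x W x 3 arrays (RGB).

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_rgb <- function(img) is.array(img) && length(dim(img)) == 3L

n_channels <- function(img) if (is_rgb(img)) dim(img)[3] else 1L

## ITU-R BT.601 luma weights; standard choice when a paper leaves the
## grey conversion unstated.
rgb_to_grey <- function(img) {
  if (!is_rgb(img)) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

grey_to_rgb <- function(img) {
  if (is_rgb(img)) return(img)
  array(rep(img, 3L), dim = c(dim(img), 3L))
}

## Bilinear sampling of a single-channel matrix at fractional (row, col)
## positions (1-based). Out-of-bounds samples return `fill`.
bilinear_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  inb <- r >= 1 & c >= 1 & r <= nr & c <= nc
  # clamp cell indices so the gather is always legal (and boundary
  # samples fall in the last cell with fraction 1), then mask
  r0c <- clamp(floor(r), 1, nr - 1); c0c <- clamp(floor(c), 1, nc - 1)
  fr <- r - r0c; fc <- c - c0c
  i00 <- img[cbind(r0c, c0c)]
  i10 <- img[cbind(r0c + 1, c0c)]
  i01 <- img[cbind(r0c, c0c + 1)]
  i11 <- img[cbind(r0c + 1, c0c + 1)]
  out <- (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
  out[!inb] <- fill
  out
}

#' Bilinear image resize
#'
#' Resizes a grey matrix or RGB array to a target size by bilinear
#' interpolation, aligning the corner pixel centres of source and target.
#'
#' @param img grey matrix or H x W x 3 array.
#' @param out_h,out_w output size in pixels.
#' @return resized image of the same kind as the input.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  stopifnot(out_h >= 1, out_w >= 1)
  resize1 <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    r <- if (out_h == 1) rep(1, out_h) else seq(1, nr, length.out = out_h)
    c <- if (out_w == 1) rep(1, out_w) else seq(1, nc, length.out = out_w)
    rr <- matrix(rep(r, out_w), out_h, out_w)
    cc <- matrix(rep(c, each = out_h), out_h, out_w)
    matrix(bilinear_sample(m, as.vector(rr), as.vector(cc)), out_h, out_w)
  }
  if (is_rgb(img)) {
    out <- array(0, dim = c(out_h, out_w, dim(img)[3]))
    for (k in seq_len(dim(img)[3])) out[, , k] <- resize1(img[, , k])
    out
  } else resize1(img)
}

## Separable Gaussian blur with reflected edges; used by the phantom
## generator to shape texture correlation length.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) {
    conv_rows <- function(mm) {
      n <- nrow(mm)
      # reflected padding via index folding (robust for tiny images)
      idx <- (1 - half):(n + half)
      idx <- ifelse(idx < 1, 2 - idx, idx)
      idx <- ifelse(idx > n, 2 * n - idx, idx)
      idx <- pmin(pmax(idx, 1L), n)
      p <- mm[idx, , drop = FALSE]
      out <- matrix(0, n, ncol(mm))
      for (i in seq_along(k)) {
        out <- out + k[i] * p[seq_len(n) + i - 1L, , drop = FALSE]
      }
      out
    }
    t(conv_rows(t(conv_rows(m))))
  }
  if (is_rgb(img)) {
    for (ch in seq_len(dim(img)[3])) img[, , ch] <- blur1(img[, , ch])
    img
  } else blur1(img)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
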