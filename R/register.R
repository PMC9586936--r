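#' Homography container
#'
#' Creates a 3x3 projective transform acting on homogeneous pixel
#' coordinates `[x, y, 1]'` (0-based, x = column, y = row). The matrix is
#' normalised so the bottom-right entry is 1.
#'
#' @param H 3x3 invertible numeric matrix.
#' @return object of class `homography`.
#' @export
homography <- function(H = diag(3)) {
  H <- as.matrix(H)
  if (!all(dim(H) == c(3L, 3L)) || any(!is.finite(H)))
    stop_invalid("a homography must be a finite 3x3 matrix")
  if (abs(det(H)) < .Machine$double.eps)
    stop_invalid("homography matrix is singular")
  H <- H / H[3, 3]
  structure(H, class = c("homography", "matrix"))
}

#' @export
print.homography <- function(x, ...) {
  cat("Homography (pixel coordinates, h33 = 1):\n")
  print(unclass(x), digits = 5)
  invisible(x)
}

## pixel -> [-1, 1] normalised coordinate transform for an N x N frame.
## Normalised coordinates condition the gradient-descent updates: all nine
## entries of H then live on comparable scales.
norm_transform <- function(N) {
  s <- 2 / (N - 1)
  matrix(c(s, 0, 0, 0, s, 0, -1, -1, 1), 3, 3)
}

to_normalised <- function(H, N) {
  T <- norm_transform(N)
  Hn <- T %*% H %*% solve(T)
  Hn / Hn[3, 3]
}

from_normalised <- function(Hn, N) {
  T <- norm_transform(N)
  H <- solve(T) %*% Hn %*% T
  H / H[3, 3]
}

#' Warp an image by a homography
#'
#' Inverse-mapped resampling: each output pixel at 0-based position
#' `(x, y)` samples the input at the `solve(H)`-transformed position with
#' bilinear interpolation, so image content moves forward by `H`.
#' Samples falling outside the source are zero.
#'
#' @param img grey matrix or RGB array, values on any scale.
#' @param H [homography] (or plain 3x3 matrix) in pixel coordinates.
#' @param out_size optional `c(rows, cols)` of the output (default: input
#'   size).
#' @return warped image, same kind as input.
#' @export
warp_homography <- function(img, H, out_size = NULL) {
  H <- homography(H)
  d <- if (is_rgb(img)) dim(img)[1:2] else dim(img)
  if (is.null(out_size)) out_size <- d
  nr <- out_size[1]; nc <- out_size[2]
  A <- solve(H)
  x <- rep(0:(nc - 1), each = nr)    # column-major grid, 0-based
  y <- rep(0:(nr - 1), times = nc)
  den <- A[3, 1] * x + A[3, 2] * y + A[3, 3]
  u <- (A[1, 1] * x + A[1, 2] * y + A[1, 3]) / den  # source x (col)
  v <- (A[2, 1] * x + A[2, 2] * y + A[2, 3]) / den  # source y (row)
  warp1 <- function(m) matrix(bilinear_sample(m, v + 1, u + 1), nr, nc)
  if (is_rgb(img)) {
    out <- array(0, dim = c(nr, nc, dim(img)[3]))
    for (k in seq_len(dim(img)[3])) out[, , k] <- warp1(img[, , k])
    out
  } else warp1(img)
}

#' Partial-photometric (PPM) window mask
#'
#' Binary mask that keeps the centred `w` x `w` square of an `N` x `N`
#' frame and zeroes the surrounding border frame (the "hollow rectangle"
#' of pixels contaminated by the fixed patch's larger field of view).
#'
#' @param N image side in pixels.
#' @param w window side in pixels, `0 < w <= N`.
#' @return `N` x `N` matrix of 0/1.
#' @export
ppm_mask <- function(N, w) {
  if (w < 1 || w > N) stop_invalid("PPM window w must satisfy 1 <= w <= N")
  m <- matrix(0, N, N)
  lo <- floor((N - w) / 2) + 1
  m[lo:(lo + w - 1), lo:(lo + w - 1)] <- 1
  m
}

#' Masked photometric L1 loss
#'
#' Mean absolute difference over masked pixels (and channels) between two
#' images on a `[0, 1]` scale.
#'
#' @param warped,target images of identical shape.
#' @param mask binary matrix matching the spatial shape.
#' @return scalar loss.
#' @export
ppm_l1 <- function(warped, target, mask) {
  if (!identical(n_channels(warped), n_channels(target)) ||
      !identical(dim(warped)[1:2], dim(target)[1:2]))
    stop_invalid("image shapes differ")
  if (sum(mask) == 0) stop_invalid("PPM mask is empty")
  idx <- mask > 0
  if (is_rgb(warped)) {
    tot <- 0
    for (k in seq_len(dim(warped)[3]))
      tot <- tot + sum(abs(warped[, , k][idx] - target[, , k][idx]))
    tot / (sum(idx) * dim(warped)[3])
  } else {
    mean(abs(warped[idx] - target[idx]))
  }
}

## Loss and analytic gradient of ppm_l1(warp(moving, H), fixed) with
## respect to the nine entries of H (pixel coordinates). The chain runs
## through A = H^{-1} (dA/dH = -A E A), the projective division and the
## bilinear interpolation weights. Returns list(loss, grad, warped).
ppm_loss_grad <- function(moving, fixed, H, mask) {
  H <- unclass(homography(H))
  d <- if (is_rgb(moving)) dim(moving)[1:2] else dim(moving)
  nr <- d[1]; nc <- d[2]
  A <- solve(H)
  x <- rep(0:(nc - 1), each = nr)
  y <- rep(0:(nr - 1), times = nc)
  den <- A[3, 1] * x + A[3, 2] * y + A[3, 3]
  u <- (A[1, 1] * x + A[1, 2] * y + A[1, 3]) / den
  v <- (A[2, 1] * x + A[2, 2] * y + A[2, 3]) / den

  r <- v + 1; c <- u + 1
  inb <- r >= 1 & c >= 1 & r <= nr & c <= nc
  r0c <- clamp(floor(r), 1, nr - 1); c0c <- clamp(floor(c), 1, nc - 1)
  fr <- r - r0c; fc <- c - c0c

  midx <- as.vector(mask > 0)
  count <- sum(midx)
  if (count == 0) stop_invalid("PPM mask is empty")
  chans <- n_channels(moving)

  loss <- 0
  gu <- numeric(nr * nc)  # d loss / d u, accumulated over channels
  gv <- numeric(nr * nc)
  warped <- if (chans > 1L) array(0, dim = c(nr, nc, chans)) else NULL
  for (k in seq_len(chans)) {
    m <- if (chans > 1L) moving[, , k] else moving
    f <- if (chans > 1L) fixed[, , k] else fixed
    i00 <- m[cbind(r0c, c0c)]; i10 <- m[cbind(r0c + 1, c0c)]
    i01 <- m[cbind(r0c, c0c + 1)]; i11 <- m[cbind(r0c + 1, c0c + 1)]
    w <- (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
      (1 - fr) * fc * i01 + fr * fc * i11
    w[!inb] <- 0
    diffs <- w - as.vector(f)
    loss <- loss + sum(abs(diffs[midx]))
    s <- sign(diffs) / (count * chans)
    s[!midx | !inb] <- 0
    dIdc <- (1 - fr) * (i01 - i00) + fr * (i11 - i10)
    dIdr <- (1 - fc) * (i10 - i00) + fc * (i11 - i01)
    gu <- gu + s * dIdc
    gv <- gv + s * dIdr
    if (chans > 1L) warped[, , k] <- matrix(w, nr, nc) else warped <- matrix(w, nr, nc)
  }
  loss <- loss / (count * chans)

  # gradient w.r.t. A, then pull back to H via dA/dH_ij = -A E_ij A
  gw <- -(gu * u + gv * v)          # d loss / d A[3,] factor before p_l / den
  P <- cbind(x, y, 1)
  GA <- rbind(colSums(P * (gu / den)),
              colSums(P * (gv / den)),
              colSums(P * (gw / den)))
  GH <- -t(A) %*% GA %*% t(A)
  list(loss = loss, grad = GH, warped = warped)
}

#' Estimate a homography by gradient descent on the PPM L1 loss
#'
#' Iteratively aligns a moving (false-)histology image to a fixed
#' histology patch. Starting from the identity, each epoch warps the
#' moving image by the current homography, evaluates the windowed partial
#' photometric L1 loss against the fixed image, and updates all nine
#' matrix entries by plain gradient descent; the learning rate is
#' multiplied by `decay_factor` at `decay_epoch`. Internally the matrix
#' is optimised in `[-1, 1]`-normalised coordinates for conditioning and
#' reported in pixel coordinates. The returned homography is the one with
#' the lowest loss seen, not the last iterate.
#'
#' @param moving,fixed images on a `[0, 1]` scale, grey matrices or RGB
#'   arrays; resized to `config$image_side` square if needed.
#' @param config list from [regression_config()].
#' @return object of class `flim_registration` with elements `H`
#'   ([homography]), `loss_trace`, `warped`, `converged`, `config`.
#' @export
register_homography <- function(moving, fixed, config = regression_config()) {
  N <- config$image_side
  fit1 <- function(img) {
    d <- if (is_rgb(img)) dim(img)[1:2] else dim(img)
    if (!all(d == N)) resize_bilinear(img, N, N) else img
  }
  moving <- fit1(moving); fixed <- fit1(fixed)
  if (n_channels(moving) != n_channels(fixed))
    stop_invalid("moving and fixed images must share the channel count")
  mask <- ppm_mask(N, config$window)
  Tn <- norm_transform(N); Tni <- solve(Tn)

  Hn <- diag(3)
  lr <- config$learning_rate
  best <- list(loss = Inf, Hn = Hn)
  trace <- numeric(config$epochs)
  for (e in seq_len(config$epochs)) {
    if (e == config$decay_epoch) lr <- lr * config$decay_factor
    Hp <- Tni %*% Hn %*% Tn
    Hp <- Hp / Hp[3, 3]
    lg <- ppm_loss_grad(moving, fixed, Hp, mask)
    if (!is.finite(lg$loss))
      stop_invalid("PPM loss became non-finite at epoch %d", e)
    trace[e] <- lg$loss
    if (lg$loss < best$loss) best <- list(loss = lg$loss, Hn = Hn)
    Gn <- t(Tni) %*% lg$grad %*% t(Tn)   # chain rule H = Tn^-1 Hn Tn
    Hn <- Hn - lr * Gn
  }
  H <- homography(Tni %*% best$Hn %*% Tn)
  structure(
    list(H = H,
         loss_trace = trace,
         warped = warp_homography(moving, H),
         moving = moving, fixed = fixed,
         converged = best$loss <= trace[1],
         best_loss = best$loss,
         config = config),
    class = "flim_registration")
}

#' Regression schedule for homography estimation
#'
#' Defaults follow the fixed schedule used throughout the comparison
#' experiments: 200 epochs, learning rate 0.01 decayed by 10 at epoch
#' 100, PPM window 200 on 256 x 256 inputs.
#'
#' @param epochs number of gradient-descent epochs.
#' @param learning_rate initial step size (normalised-coordinate scale).
#' @param decay_factor multiplier applied to the learning rate once.
#' @param decay_epoch epoch at which the decay is applied.
#' @param window PPM window side in pixels.
#' @param image_side side length N both images are resized to.
#' @param seed unused by the (deterministic) regression; recorded for
#'   provenance.
#' @return list of class `regression_config`.
#' @export
regression_config <- function(epochs = 200, learning_rate = 0.01,
                              decay_factor = 0.1, decay_epoch = 100,
                              window = 200, image_side = 256, seed = 1L) {
  if (epochs < 1) stop_invalid("epochs must be >= 1")
  if (learning_rate <= 0) stop_invalid("learning_rate must be > 0")
  if (decay_factor <= 0 || decay_factor > 1)
    stop_invalid("decay_factor must be in (0, 1]")
  if (window < 1 || window > image_side)
    stop_invalid("window must be in [1, image_side]")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 decay_factor = decay_factor,
                 decay_epoch = as.integer(decay_epoch),
                 window = as.integer(window),
                 image_side = as.integer(image_side),
                 seed = as.integer(seed)),
            class = "regression_config")
}

#' @export
print.flim_registration <- function(x, ...) {
  cat("Homography registration (PPM L1 gradient descent)\n")
  cat(sprintf("  image side: %d px, window: %d px, epochs: %d\n",
              x$config$image_side, x$config$window, x$config$epochs))
  cat(sprintf("  initial loss: %.5f, best loss: %.5f (%s)\n",
              x$loss_trace[1], x$best_loss,
              if (x$converged) "improved" else "no improvement"))
  print(x$H)
  invisible(x)
}

#' @export
summary.flim_registration <- function(object, ...) {
  cat("Loss trace summary:\n")
  print(summary(object$loss_trace))
  print(object)
  invisible(object)
}

#' @export
coef.flim_registration <- function(object, ...) unclass(object$H)

#' @rdname register_homography
#' @param x a `flim_registration` object.
#' @param ... ignored.
#' @export
plot.flim_registration <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "epoch", ylab = "PPM L1 loss",
       main = "Homography regression loss", ...)
  abline(v = x$config$decay_epoch, lty = 3)
  invisible(x)
}

#' @export
residuals.flim_registration <- function(object, ...) {
  mask <- ppm_mask(object$config$image_side, object$config$window)
  res <- (rgb_to_grey(object$warped) - rgb_to_grey(object$fixed)) * mask
  res
}

#' Blend two registered images for visual inspection
#'
#' In `"greyscale"` mode the first image is shown in green and the second
#' in magenta, so aligned structure appears grey/white. In `"colour"`
#' mode the images are alpha-composited.
#'
#' @param image_a,image_b images of identical spatial shape, `[0, 1]`.
#' @param mode `"greyscale"` or `"colour"`.
#' @param alpha weight of `image_a` in colour mode.
#' @return RGB array.
#' @export
blend_images <- function(image_a, image_b, mode = c("greyscale", "colour"),
                         alpha = 0.5) {
  mode <- match.arg(mode)
  if (!identical(dim(image_a)[1:2], dim(image_b)[1:2]))
    stop_invalid("images must share spatial shape")
  if (mode == "greyscale") {
    a <- rgb_to_grey(image_a); b <- rgb_to_grey(image_b)
    out <- array(0, dim = c(dim(a), 3L))
    out[, , 1] <- b; out[, , 2] <- a; out[, , 3] <- b
    out
  } else {
    a <- grey_to_rgb(image_a); b <- grey_to_rgb(image_b)
    alpha * a + (1 - alpha) * b
  }
}
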