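#' Registration similarity metrics
#'
#' The similarity metrics used for quantitative comparison of
#' registration outcomes: mean squared error (`"mse"`), Pearson
#' normalised cross-correlation (`"ncc"`) and normalised mutual
#' information (`"nmi"`, `2 I(A;B) / (H(A) + H(B))` on a joint
#' equal-width histogram). Colour inputs are converted to grey first.
#' These metrics are reported for context only: with strongly
#' multi-modal image pairs they do not always rank registrations
#' correctly, and the corner reprojection error against a known
#' homography is the authoritative recovery signal.
#'
#' @param image_a,image_b images of equal shape, values in `[0, 1]`.
#' @param metric `"mse"`, `"nmi"` or `"ncc"`.
#' @param bins histogram bins per axis for NMI (default 64).
#' @return scalar metric value.
#' @export
similarity <- function(image_a, image_b, metric = c("mse", "nmi", "ncc"),
                       bins = 64L) {
  metric <- match.arg(metric)
  a <- as.vector(rgb_to_grey(image_a))
  b <- as.vector(rgb_to_grey(image_b))
  if (length(a) != length(b)) stop_invalid("image shapes differ")
  if (metric == "mse") return(mean((a - b)^2))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_invalid("%s is undefined for a constant image", metric)
  if (metric == "ncc") return(stats::cor(a, b))
  # nmi on a joint equal-width histogram over [0, 1]
  qa <- pmin(floor(clamp(a, 0, 1) * bins), bins - 1L)
  qb <- pmin(floor(clamp(b, 0, 1) * bins), bins - 1L)
  joint <- table(factor(qa, levels = 0:(bins - 1L)),
                 factor(qb, levels = 0:(bins - 1L)))
  p <- joint / sum(joint)
  pa <- rowSums(p); pb <- colSums(p)
  ent <- function(x) { x <- x[x > 0]; -sum(x * log(x)) }
  ha <- ent(pa); hb <- ent(pb); hab <- ent(as.vector(p))
  mi <- ha + hb - hab
  2 * mi / (ha + hb)
}

#' Corner reprojection error between two homographies
#'
#' Mean Euclidean displacement (pixels) of the four image corners mapped
#' by the estimated versus the true homography; the standard recovery
#' diagnostic when the ground-truth transform is known.
#'
#' @param H_est,H_true [homography] (or 3x3 matrices).
#' @param N image side in pixels.
#' @return mean corner displacement in pixels.
#' @export
corner_error <- function(H_est, H_true, N) {
  H_est <- unclass(homography(H_est)); H_true <- unclass(homography(H_true))
  pts <- rbind(c(0, 0, 1), c(N - 1, 0, 1), c(0, N - 1, 1), c(N - 1, N - 1, 1))
  pe <- t(H_est %*% t(pts)); pt <- t(H_true %*% t(pts))
  pe <- pe[, 1:2] / pe[, 3]; pt <- pt[, 1:2] / pt[, 3]
  mean(sqrt(rowSums((pe - pt)^2)))
}
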