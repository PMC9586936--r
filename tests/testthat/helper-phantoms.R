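# Shared fixture builders; everything is generated in code at test time.

# noiseless mono-exponential cube: expected counts, no Poisson sampling
noiseless_cube <- function(M = 4, S = 2, T = 32, tau = 2.0, A = 1000,
                           bin_width = 0.4) {
  t <- (seq_len(T) - 1) * bin_width
  counts <- array(0, dim = c(M, M, S, T))
  for (k in seq_len(T)) counts[, , , k] <- A * exp(-t[k] / tau)
  flim_hypercube(counts, seq(500, 780, length.out = S), bin_width)
}

# synthetic H&E-ish patch: dark magenta discs on a white field, plus the
# ground-truth disc raster
disc_patch <- function(N = 96, n_discs = 6, r = 9, seed = 4) {
  set.seed(seed)
  truth <- matrix(0, N, N)
  cx <- runif(n_discs, r + 2, N - r - 2)
  cy <- runif(n_discs, r + 2, N - r - 2)
  for (i in seq_len(n_discs)) {
    d2 <- (col(truth) - cx[i])^2 + (row(truth) - cy[i])^2
    truth[d2 <= r^2] <- 1
  }
  img <- array(0, dim = c(N, N, 3))
  img[, , 1] <- ifelse(truth == 1, 0.55, 0.98)
  img[, , 2] <- ifelse(truth == 1, 0.12, 0.97)
  img[, , 3] <- ifelse(truth == 1, 0.45, 0.96)
  list(rgb = img, truth = truth)
}

expect_images_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.vector(a), as.vector(b), tolerance = tol)
}
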