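test_that("hypercube constructor enforces its invariants", {
  counts <- array(1, dim = c(4, 4, 3, 8))
  wl <- c(500, 600, 700)
  expect_s3_class(flim_hypercube(counts, wl, 0.4), "flim_hypercube")
  expect_error(flim_hypercube(counts, c(500, 600), 0.4), "spectral")
  expect_error(flim_hypercube(counts, rev(wl), 0.4), "increasing")
  expect_error(flim_hypercube(array(-1, dim = c(4, 4, 3, 8)), wl, 0.4),
               "non-negative")
  bad <- counts; bad[1] <- NA
  expect_error(flim_hypercube(bad, wl, 0.4), "non-finite")
  expect_error(flim_hypercube(array(1, dim = c(4, 5, 3, 8)), wl, 0.4),
               "spatial")
})

test_that("spectral moving mean: identity cases and parameter errors", {
  cube <- noiseless_cube(M = 4, S = 6, tau = 2)
  # spectrally constant cube is unchanged by any window
  sm <- spectral_moving_mean(cube, 4)
  expect_images_equal(sm$counts, cube$counts)
  # width 1 is the identity window
  expect_images_equal(spectral_moving_mean(cube, 1)$counts, cube$counts)
  expect_error(spectral_moving_mean(cube, 0), "width")
  expect_error(spectral_moving_mean(cube, 7), "width")
})

test_that("spectral moving mean reduces i.i.d. noise variance ~width-fold
           and conserves interior totals", {
  set.seed(42)
  S <- 24; d <- c(12, 12, S, 8)
  counts <- array(rpois(prod(d), 50), dim = d)
  cube <- flim_hypercube(counts, seq(500, 780, length.out = S), 0.4)
  sm <- spectral_moving_mean(cube, 8)
  interior <- 5:20  # full windows only
  ratio <- var(as.vector(counts[, , interior, ])) /
    var(as.vector(sm$counts[, , interior, ]))
  expect_gt(ratio, 8 * 0.8)
  expect_lt(ratio, 8 * 1.2)
  # each interior input band contributes to exactly `width` outputs
  tot_in <- sum(counts[, , 8:17, ])
  tot_out <- sum(sm$counts[, , 8:17, ])
  expect_equal(tot_out / tot_in, 1, tolerance = 0.02)
})

test_that("reconstruct recovers noiseless lifetimes exactly and sums
           intensity over time channels", {
  cube <- noiseless_cube(M = 4, S = 2, tau = 2.0, A = 1000)
  st <- reconstruct(cube)
  expect_equal(as.vector(st$lifetime), rep(2.0, 4 * 4 * 2), tolerance = 1e-6)
  expect_images_equal(st$intensity, apply(cube$counts, 1:3, sum), tol = 1e-9)
  # any tau in the working range is recovered to solver tolerance
  for (tau in c(0.5, 1.5, 3.7, 5)) {
    cu <- noiseless_cube(M = 2, S = 1, tau = tau, A = 500)
    expect_equal(as.vector(reconstruct(cu)$lifetime), rep(tau, 4),
                 tolerance = 1e-6)
  }
})

test_that("reconstruct handles degenerate input", {
  zero <- flim_hypercube(array(0, dim = c(3, 3, 2, 8)), c(500, 600), 0.4)
  st <- reconstruct(zero)
  expect_true(all(st$intensity == 0) && all(st$lifetime == 0))
  expect_error(reconstruct(flim_hypercube(array(1, dim = c(3, 3, 2, 2)),
                                          c(500, 600), 0.4)), "time channels")
})

test_that("Poisson decays are fitted within 5% RMS and match an
           independent per-pixel nls oracle", {
  skip_if_not_installed("minpack.lm")
  T <- 32; bw <- 0.4; t <- (seq_len(T) - 1) * bw
  set.seed(7)
  Y <- t(vapply(1:40, function(i) poisson_decay(2.5, 1e4, T, bw),
                numeric(T)))
  tau_hat <- flimcoreg:::fit_monoexp(Y, t)
  expect_lt(sqrt(mean((tau_hat - 2.5)^2)) / 2.5, 0.05)
  # independent oracle: minpack.lm Levenberg-Marquardt per pixel
  for (i in 1:5) {
    df <- data.frame(y = Y[i, ], t = t)
    fit <- minpack.lm::nlsLM(y ~ A * exp(-t / tau), df,
                             start = list(A = max(df$y), tau = 1))
    expect_equal(tau_hat[i], coef(fit)[["tau"]], tolerance = 1e-4)
  }
})

test_that("photon filter equals the per-pixel threshold oracle including
           the boundary case", {
  set.seed(11)
  d <- c(6, 6, 3)
  intensity <- array(sample(0:30, prod(d), replace = TRUE), dim = d)
  lifetime <- array(runif(prod(d), 0.5, 4), dim = d)
  lifetime[intensity == 0] <- 0
  st <- spectral_stack(intensity, lifetime, c(500, 600, 700))
  # force an exact boundary hit: N-hat = 100 in band 1, one pixel at 10
  st$intensity[1, 1, 1] <- 10; st$lifetime[1, 1, 1] <- 2.1
  st$intensity[2, 1, 1] <- 11; st$lifetime[2, 1, 1] <- 2.1
  nhat <- c(100, 64, 25)
  out <- photon_filter(st, nhat = nhat)
  # brute-force elementwise oracle
  for (s in 1:3) for (x in 1:6) for (y in 1:6) {
    if (st$intensity[x, y, s] <= sqrt(nhat[s])) {
      expect_identical(out$intensity[x, y, s], 0)
      expect_identical(out$lifetime[x, y, s], 0)
    } else {
      expect_identical(out$intensity[x, y, s], st$intensity[x, y, s])
      expect_identical(out$lifetime[x, y, s], st$lifetime[x, y, s])
    }
  }
  # i = sqrt(N-hat) is zeroed (inequality is <=), i just above passes
  expect_identical(out$intensity[1, 1, 1], 0)
  expect_identical(out$lifetime[1, 1, 1], 0)
  expect_identical(out$intensity[2, 1, 1], 11)
  expect_identical(out$lifetime[2, 1, 1], 2.1)
})

test_that("photon filter is idempotent with a frozen N-hat and never
           leaves lifetime without intensity", {
  ph <- make_phantom(phantom_spec(size = 16, S = 3, counts_per_pixel = 800,
                                  seed = 5))
  st <- reconstruct(ph$cube)
  f1 <- photon_filter(st)
  f2 <- photon_filter(f1, nhat = attr(f1, "nhat"))
  expect_images_equal(f1$intensity, f2$intensity)
  expect_images_equal(f1$lifetime, f2$lifetime)
  expect_true(all(f1$intensity[f1$lifetime > 0] > 0))
})

test_that("global normalisation shares one factor and preserves order", {
  mk <- function(mx) {
    i <- array(runif(4 * 4 * 2, 0, mx), dim = c(4, 4, 2))
    i[1] <- mx
    spectral_stack(i, i * 0, c(500, 600))
  }
  set.seed(3)
  s1 <- mk(500); s2 <- mk(1000)
  out1 <- global_normalise(list(s1))
  expect_equal(max(out1[[1]]$intensity), 1.0)
  out <- global_normalise(list(s1, s2))
  expect_equal(max(out[[1]]$intensity), 0.5)
  expect_equal(max(out[[2]]$intensity), 1.0)
  expect_equal(rank(as.vector(s1$intensity)),
               rank(as.vector(out[[1]]$intensity)))
  # lifetimes untouched
  expect_images_equal(out[[2]]$lifetime, s2$lifetime)
  zero <- spectral_stack(array(0, dim = c(2, 2, 1)),
                         array(0, dim = c(2, 2, 1)), 500)
  expect_warning(global_normalise(list(zero)), "all-zero")
})

test_that("hypercube and stack serialisation round-trips", {
  cube <- noiseless_cube(M = 3, S = 2)
  p <- tempfile(fileext = ".rds")
  write_flim_hypercube(cube, p)
  expect_equal(read_flim_hypercube(p), cube)
  st <- reconstruct(cube)
  p2 <- tempfile(fileext = ".rds")
  write_spectral_stack(st, p2)
  expect_equal(read_spectral_stack(p2), st)
  expect_error(read_spectral_stack(p), "not a spectral stack")
})
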