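translation_H <- function(tx, ty) {
  H <- diag(3); H[1, 3] <- tx; H[2, 3] <- ty
  homography(H)
}

test_that("homography construction validates and normalises", {
  H <- homography(2 * diag(3))
  expect_equal(unclass(H), diag(3))
  expect_error(homography(matrix(0, 3, 3)), "singular")
  expect_error(homography(matrix(1, 2, 2)), "3x3")
  bad <- diag(3); bad[1] <- Inf
  expect_error(homography(bad), "finite")
})

test_that("warping by the identity is a no-op and integer translations
           match an array-shift oracle", {
  img <- textured_phantom(48, seed = 14, sigma = 3)
  expect_images_equal(warp_homography(img, diag(3)), img)
  w <- warp_homography(img, translation_H(5, 0))
  oracle <- matrix(0, 48, 48)
  oracle[, 6:48] <- img[, 1:43]   # content moves +5 columns, zero fill
  expect_images_equal(w, oracle, tol = 1e-9)
  w2 <- warp_homography(img, translation_H(0, -3))
  oracle2 <- matrix(0, 48, 48)
  oracle2[1:45, ] <- img[4:48, ]
  expect_images_equal(w2, oracle2, tol = 1e-9)
})

test_that("warp composition approximates the composed homography", {
  img <- textured_phantom(96, seed = 3, sigma = 6)
  H1 <- unclass(random_homography(96, 4, 2, c(0.98, 1.02), 5e-5, seed = 1))
  H2 <- unclass(random_homography(96, 4, 2, c(0.98, 1.02), 5e-5, seed = 2))
  two_step <- warp_homography(warp_homography(img, H1), H2)
  one_step <- warp_homography(img, H2 %*% H1)
  # compare away from the zero-fill borders
  core <- 15:82
  d <- abs(two_step[core, core] - one_step[core, core])
  expect_lt(mean(d), 2 / 255)
})

test_that("PPM mask is the centred window with the documented pixel
           counts", {
  expect_true(all(ppm_mask(64, 64) == 1))
  m <- ppm_mask(256, 200)
  expect_equal(sum(m), 40000)
  expect_true(all(m[1:28, ] == 0) && all(m[, 1:28] == 0))
  expect_true(all(m[29:228, 29:228] == 1))
  expect_identical(m, m[nrow(m):1, ])
  expect_identical(m, m[, ncol(m):1])
  expect_error(ppm_mask(64, 65), "window")
})

test_that("PPM L1 loss equals the brute-force masked mean", {
  set.seed(31)
  for (i in 1:10) {
    a <- matrix(runif(32 * 32), 32, 32)
    b <- matrix(runif(32 * 32), 32, 32)
    mask <- matrix(rbinom(32 * 32, 1, 0.7), 32, 32)
    if (sum(mask) == 0) mask[1, 1] <- 1
    brute <- sum(abs(a - b)[mask == 1]) / sum(mask)
    expect_equal(ppm_l1(a, b, mask), brute, tolerance = 1e-6)
  }
  expect_equal(ppm_l1(matrix(1, 4, 4), matrix(1, 4, 4), matrix(1, 4, 4)), 0)
  # single differing masked pixel on a w = 200 window
  a <- matrix(0, 256, 256); b <- a
  b[128, 128] <- 0.5
  expect_equal(ppm_l1(a, b, ppm_mask(256, 200)), 0.5 / 40000)
  expect_error(ppm_l1(a, b, a * 0), "empty")
})

test_that("analytic loss gradient matches central finite differences", {
  img <- textured_phantom(64, seed = 2, sigma = 4)
  H <- random_homography(64, 5, 3, c(0.97, 1.03), 1e-4, seed = 5)
  pair <- make_warped_pair(img, H, 0.02, seed = 9)
  mask <- ppm_mask(64, 50)
  H0 <- unclass(random_homography(64, 2, 1, c(0.99, 1.01), 5e-5, seed = 11))
  lg <- flimcoreg:::ppm_loss_grad(pair$moving, pair$fixed, H0, mask)
  fd <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    eps <- 1e-6 * max(abs(H0[i, j]), 1e-3)
    Hp <- H0; Hp[i, j] <- Hp[i, j] + eps
    Hm <- H0; Hm[i, j] <- Hm[i, j] - eps
    fd[i, j] <- (flimcoreg:::ppm_loss_grad(pair$moving, pair$fixed, Hp, mask)$loss -
                   flimcoreg:::ppm_loss_grad(pair$moving, pair$fixed, Hm, mask)$loss) /
      (2 * eps)
  }
  expect_lt(norm(lg$grad - fd, "F") / norm(fd, "F"), 1e-3)
})

test_that("self-registration stays at the identity", {
  img <- textured_phantom(128, seed = 17, sigma = 5)
  fit <- register_homography(img, img,
                             regression_config(epochs = 50, window = 100,
                                               image_side = 128))
  expect_lt(corner_error(fit$H, diag(3), 128), 0.5)
  expect_true(fit$converged)
})

test_that("a known translation is recovered on a textured phantom with
           the reference schedule", {
  img <- textured_phantom(256, seed = 23, sigma = 6)
  pair <- make_warped_pair(img, translation_H(8, -5), 0.02, seed = 24)
  fit <- register_homography(pair$moving, pair$fixed, regression_config())
  expect_lt(corner_error(fit$H, pair$H_true, 256), 2)
  # best-so-far reporting: reported loss never above the initial loss
  expect_lte(fit$best_loss, fit$loss_trace[1])
  expect_equal(length(fit$loss_trace), 200)
})

test_that("regression is deterministic and its methods are coherent", {
  img <- textured_phantom(64, seed = 30, sigma = 4)
  pair <- make_warped_pair(img, translation_H(3, 2), 0, seed = 1)
  cfg <- regression_config(epochs = 30, window = 48, image_side = 64)
  f1 <- register_homography(pair$moving, pair$fixed, cfg)
  f2 <- register_homography(pair$moving, pair$fixed, cfg)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(coef(f1), coef(f2))
  expect_equal(dim(coef(f1)), c(3, 3))
  expect_equal(coef(f1)[3, 3], 1)
  expect_equal(dim(residuals(f1)), c(64, 64))
  expect_output(print(f1), "Homography")
})

test_that("regression config validates its schedule", {
  expect_error(regression_config(epochs = 0), "epochs")
  expect_error(regression_config(learning_rate = 0), "learning_rate")
  expect_error(regression_config(decay_factor = 1.5), "decay_factor")
  expect_error(regression_config(window = 300, image_side = 256), "window")
})

test_that("blending follows the green/magenta and alpha conventions", {
  a <- matrix(0, 4, 4); b <- matrix(0.8, 4, 4)
  g <- blend_images(a, b, "greyscale")
  expect_equal(g[, , 1], b); expect_equal(g[, , 2], a); expect_equal(g[, , 3], b)
  same <- matrix(0.4, 4, 4)
  gg <- blend_images(same, same, "greyscale")
  expect_true(all(gg[, , 1] == gg[, , 2] & gg[, , 2] == gg[, , 3]))
  ca <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  cb <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  expect_images_equal(blend_images(ca, cb, "colour", alpha = 1), ca)
  expect_error(blend_images(a, matrix(0, 5, 5)), "shape")
})
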