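test_that("average layout reproduces an exact grid and passes single
           tiles through", {
  pos <- rbind(c(0, 0), c(90, 0), c(0, 80), c(90, 80))
  grid <- rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  lay <- average_layout(pos, grid, c(100, 100))
  expect_equal(unname(lay$offsets), unname(pos))
  expect_equal(unname(lay$spacing), c(90, 80))
  one <- average_layout(rbind(c(12, 7)), rbind(c(1, 1)), c(50, 50))
  expect_equal(unname(one$offsets[1, ]), c(12, 7))
})

test_that("average layout recovers jittered grid spacing within a pixel", {
  set.seed(19)
  true_sx <- 57; true_sy <- 55
  grid <- as.matrix(expand.grid(row = 1:5, col = 1:5))
  pos <- cbind((grid[, "col"] - 1) * true_sx + sample(-3:3, 25, TRUE),
               (grid[, "row"] - 1) * true_sy + sample(-3:3, 25, TRUE))
  lay <- average_layout(pos, grid, c(70, 70))
  expect_lt(abs(lay$spacing["sx"] - true_sx), 1)
  expect_lt(abs(lay$spacing["sy"] - true_sy), 1)
})

test_that("compose pastes, averages overlaps and is order-invariant", {
  # non-overlapping 2x2 grid of constant tiles -> exact block mosaic
  tiles <- lapply(c(0.2, 0.4, 0.6, 0.8), function(v) matrix(v, 10, 10))
  lay <- average_layout(rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10)),
                        rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2)),
                        c(10, 10))
  mos <- compose_mosaic(tiles, lay)
  expect_equal(mos[1:10, 1:10], matrix(0.2, 10, 10))
  expect_equal(mos[11:20, 11:20], matrix(0.8, 10, 10))
  # overlapping constant tiles compose to the same constant
  lay2 <- average_layout(rbind(c(0, 0), c(6, 0)), rbind(c(1, 1), c(1, 2)),
                         c(10, 10))
  mos2 <- compose_mosaic(list(matrix(0.5, 10, 10), matrix(0.5, 10, 10)), lay2)
  expect_true(all(mos2 == 0.5))
  # permutation invariance
  set.seed(33)
  tiles3 <- lapply(1:4, function(i) matrix(runif(100), 10, 10))
  lay3 <- average_layout(rbind(c(0, 0), c(7, 0), c(0, 7), c(7, 7)),
                         rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2)),
                         c(10, 10))
  perm <- c(3, 1, 4, 2)
  lay3p <- average_layout(rbind(c(0, 0), c(7, 0), c(0, 7), c(7, 7))[perm, ],
                          rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2))[perm, ],
                          c(10, 10))
  expect_equal(compose_mosaic(tiles3, lay3),
               compose_mosaic(tiles3[perm], lay3p))
  expect_error(compose_mosaic(tiles3, average_layout(rbind(c(50, 50)),
                                                     rbind(c(1, 1)),
                                                     c(10, 10))),
               "cover")
})

test_that("cut-and-reassemble reproduces the phantom outside seams", {
  mos <- textured_phantom(200, seed = 44, sigma = 5)
  # zero jitter: averaged layout reassembles exactly
  tg <- make_tile_grid(mos, 2, 2, overlap_px = 12, jitter_px = 0)
  lay <- average_layout(tg$offsets, tg$grid, tg$tile_size)
  out <- compose_mosaic(tg$tiles, lay)
  H <- nrow(out); W <- ncol(out)
  expect_lt(max(abs(out - mos[1:H, 1:W])), 1e-6)
  # jittered cut: recorded (raw) positions reassemble exactly
  tg2 <- make_tile_grid(mos, 3, 3, overlap_px = 14, jitter_px = 3, seed = 2)
  lay2 <- average_layout(tg2$offsets, tg2$grid, tg2$tile_size, mode = "raw")
  out2 <- compose_mosaic(tg2$tiles, lay2)
  covered <- matrix(FALSE, nrow(out2), ncol(out2))
  for (i in seq_len(nrow(tg2$offsets))) {
    covered[tg2$offsets[i, 2] + seq_len(tg2$tile_size[1]),
            tg2$offsets[i, 1] + seq_len(tg2$tile_size[2])] <- TRUE
  }
  expect_lt(max(abs((out2 - mos[1:nrow(out2), 1:ncol(out2)])[covered])), 1e-6)
})

test_that("zero (filtered) pixels do not dim overlaps and backgrounds
           composite beneath", {
  a <- matrix(0.8, 10, 10)
  b <- matrix(0, 10, 10)      # fully filtered tile
  lay <- average_layout(rbind(c(0, 0), c(0, 0)), rbind(c(1, 1), c(1, 1)),
                        c(10, 10), mode = "raw")
  mos <- compose_mosaic(list(a, b), lay)
  expect_true(all(mos == 0.8))
  bg <- matrix(0.3, 10, 10)
  mos2 <- compose_mosaic(list(a), average_layout(rbind(c(0, 0)),
                                                 rbind(c(1, 1)), c(10, 10)),
                         background = bg, alpha = 0.5)
  expect_true(all(abs(mos2 - 0.55) < 1e-12))
})

test_that("cell profiles are 5x5 neighbourhood means with border checks", {
  set.seed(55)
  lt <- array(runif(20 * 20 * 3, 1, 3), dim = c(20, 20, 3))
  st <- spectral_stack(array(1, dim = dim(lt)), lt, c(500, 590, 680))
  prof <- cell_profile(st, c(10, 8))
  for (s in 1:3)
    expect_equal(prof$lifetime_ns[s], mean(lt[7:11, 9:13, s]))
  expect_equal(prof$wavelength_nm, c(500, 590, 680))
  # constant stack: profile independent of location
  stc <- spectral_stack(array(1, dim = c(20, 20, 2)),
                        array(2.5, dim = c(20, 20, 2)), c(500, 600))
  p1 <- cell_profile(stc, c(5, 5)); p2 <- cell_profile(stc, c(14, 12))
  expect_equal(p1$lifetime_ns, p2$lifetime_ns)
  expect_true(all(p1$lifetime_ns == 2.5))
  expect_error(cell_profile(st, c(1, 10)), "border")
  expect_error(cell_profile(st, c(10, 19)), "border")
  # band-range restriction
  pr <- cell_profile(st, c(10, 8), band_range = c(500, 600))
  expect_equal(nrow(pr), 2)
})
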