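# Dark-channel haze reduction and morphological contrast enhancement.

test_that("dark channel reduces to channel/neighborhood minima", {
  expect_equal(dark_channel(flat_image(1), 3), matrix(1, 8, 8))
  expect_equal(dark_channel(flat_image(0), 3), matrix(0, 8, 8))
  # one channel zeroed everywhere forces the map to zero for any patch
  img <- rand_image(5, 5, seed = 2)
  img[, , 2] <- 0
  for (p in c(1, 3, 5)) {
    expect_equal(dark_channel(img, p), matrix(0, 5, 5))
  }
  # brute-force oracle on a random image
  img <- rand_image(6, 7, seed = 3)
  p <- 3; r <- 1
  oracle <- matrix(0, 6, 7)
  for (i in 1:6) {
    for (j in 1:7) {
      ri <- pmin(pmax((i - r):(i + r), 1), 6)
      ci <- pmin(pmax((j - r):(j + r), 1), 7)
      oracle[i, j] <- min(img[ri, ci, ])
    }
  }
  expect_equal(dark_channel(img, p), oracle)
  expect_error(dark_channel(img, 4), "odd")
})

test_that("dark channel is monotone under pixel brightening", {
  img <- rand_image(10, 10, seed = 4)
  base <- dark_channel(img, 5)
  set.seed(5)
  for (rep_i in 1:10) {
    img2 <- img
    i <- sample(10, 1); j <- sample(10, 1); c <- sample(3, 1)
    img2[i, j, c] <- min(1, img2[i, j, c] + runif(1, 0, 0.5))
    expect_true(all(dark_channel(img2, 5) >= base - 1e-12))
  }
})

test_that("atmospheric light comes from the haziest pixels", {
  img <- flat_image(0.5)
  a <- estimate_atmospheric_light(img, dark_channel(img, 3), 0.1)
  expect_equal(a, rep(0.5, 3))
  # single brightest dark-channel pixel is pure white
  img <- flat_image(0.2, 10, 10)
  img[4, 7, ] <- 1
  dark <- dark_channel(img, 1)
  a <- estimate_atmospheric_light(img, dark, light_fraction = 1 / 101)
  expect_equal(a, c(1, 1, 1))
  # all-black image is floored at eps
  img0 <- flat_image(0)
  a0 <- estimate_atmospheric_light(img0, dark_channel(img0, 3), 0.01,
                                   eps = 1e-3)
  expect_equal(a0, rep(1e-3, 3))
})

test_that("transmission obeys the attenuated dark-channel formula", {
  a <- c(0.6, 0.7, 0.8)
  img <- array(rep(a, each = 64), dim = c(8, 8, 3))
  tm <- estimate_transmission(img, a, haze_params(omega = 0.95, t0 = 0.1))
  expect_equal(tm, matrix(0.1, 8, 8))  # 1 - 0.95 clamped up to t0
  img[, , 1] <- 0
  tm <- estimate_transmission(img, a, haze_params())
  expect_equal(tm, matrix(1, 8, 8))
  img2 <- rand_image(8, 8, seed = 6)
  tm <- estimate_transmission(img2, c(1, 1, 1),
                              haze_params(omega = 1e-12))
  expect_equal(tm, matrix(1, 8, 8), tolerance = 1e-9)
  # always inside [t0, 1]
  for (s in 1:5) {
    tm <- estimate_transmission(rand_image(9, 9, seed = s), c(0.9, 0.8, 1),
                                haze_params(t0 = 0.2))
    expect_true(all(tm >= 0.2 - 1e-12) && all(tm <= 1 + 1e-12))
  }
})

test_that("radiance recovery inverts the haze model", {
  a <- c(0.9, 0.9, 0.9)
  img <- flat_image(0.9)
  expect_equal(recover_radiance(img, a, matrix(0.3, 8, 8)), img)
  # scalar hand example: (0.8 - 0.9)/0.5 + 0.9 = 0.7
  img <- flat_image(0.8, 2, 2)
  out <- recover_radiance(img, a, matrix(0.5, 2, 2), t0 = 0.1)
  expect_equal(out, flat_image(0.7, 2, 2))
  # T below t0: the divisor is exactly t0, so (0.8-0.9)/0.1+0.9 = -0.1 -> 0
  out <- recover_radiance(img, a, matrix(0.01, 2, 2), t0 = 0.1)
  expect_equal(out, array(0, c(2, 2, 3)))
  # exact algebraic inverse of the forward model
  set.seed(7)
  j <- rand_image(10, 10, seed = 8)
  tmap <- matrix(runif(100, 0.2, 1), 10, 10)
  a <- c(0.95, 0.9, 0.85)
  hazy <- array(0, dim = dim(j))
  for (c in 1:3) hazy[, , c] <- j[, , c] * tmap + a[c] * (1 - tmap)
  back <- recover_radiance(hazy, a, tmap, t0 = 0.1)
  expect_lt(max(abs(back - j)), 1e-6)
})

test_that("top/bottom-hat isolate small bright/dark structures", {
  m <- morph_params("disk", 2)
  img <- flat_image(0.4)
  expect_equal(top_hat(img, m), flat_image(0, 8, 8) * 0)
  expect_equal(bottom_hat(img, m), array(0, c(8, 8, 3)))
  # single bright pixel on black: top hat returns the spike, bottom hat 0
  img <- flat_image(0, 7, 7)
  img[4, 4, ] <- 0.8
  th <- top_hat(img, m)
  expect_equal(th, img)
  expect_equal(bottom_hat(img, m), array(0, c(7, 7, 3)))
  # single dark pixel on white: bottom hat returns the dip, top hat 0
  img <- flat_image(1, 7, 7)
  img[3, 5, ] <- 0.25
  bh <- bottom_hat(img, m)
  expect_equal(bh[3, 5, ], rep(0.75, 3))
  expect_equal(sum(bh) - sum(bh[3, 5, ]), 0)
  expect_equal(top_hat(img, m), array(0, c(7, 7, 3)))
})

test_that("underlying opening is idempotent", {
  for (s in 1:5) {
    m <- rand_image(12, 12, seed = 10 + s)[, , 1]
    for (shape in c("disk", "square")) {
      o1 <- dermalo:::.opening(m, shape, 2)
      expect_equal(dermalo:::.opening(o1, shape, 2), o1)
      c1 <- dermalo:::.closing(m, shape, 2)
      expect_equal(dermalo:::.closing(c1, shape, 2), c1)
    }
  }
})

test_that("enhance_image is deterministic and respects fixed points", {
  img <- flat_image(0.5, 16, 16)
  out <- enhance_image(img, haze_params(patch_size = 5),
                       morph_params("disk", 2))
  # constant image: morphology vanishes, output equals recovered radiance
  expect_true(max(out) - min(out) < 1e-12)
  img2 <- rand_image(16, 16, seed = 20)
  o1 <- enhance_image(img2)
  o2 <- enhance_image(img2)
  expect_identical(o1, o2)
  expect_equal(dim(o1), dim(img2))
})

test_that("enhancement dehazes and raises contrast on hazy fixtures", {
  fx <- make_hazy_images(n_classes = 2, per_class = 3, size = c(48, 48),
                         haze_strength = 1.2, noise_sigma = 0, seed = 11)
  for (img in fx$images) {
    out <- enhance_image(img)
    expect_lt(mean(dark_channel(out)), mean(dark_channel(img)))
    expect_gt(rms_contrast(out), rms_contrast(img))
  }
})
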