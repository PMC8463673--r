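testImage <- function(seed = 1, n = 96) {
  set.seed(seed)
  # double storage, matching the package's raster convention
  array(as.numeric(sample(0:255, n * n * 3, replace = TRUE)), c(n, n, 3))
}

test_that("identity configuration is a bit-exact no-op", {
  img <- testImage()
  for (seed in 1:5)
    expect_identical(enhance(img, identityAugment(), seed), img)
})

test_that("flips are involutions and shifts restore the interior", {
  img <- testImage(2)
  p <- sampleAugmentParams(identityAugment(), 1)
  for (fl in c("flip_h", "flip_v")) {
    q <- p; q[[fl]] <- TRUE
    expect_identical(applyAugment(applyAugment(img, q), q), img)
  }
  q <- p; q$dx <- 7L; q$dy <- -5L
  r <- p; r$dx <- -7L; r$dy <- 5L
  back <- applyAugment(applyAugment(img, q), r)
  interior_rows <- 10:80; interior_cols <- 10:80
  expect_identical(back[interior_rows, interior_cols, ],
                   img[interior_rows, interior_cols, ])
})

test_that("hue-only shifts leave the value channel within rounding", {
  img <- testImage(3)
  p <- sampleAugmentParams(identityAugment(), 1)
  p$hue <- 20
  out <- applyAugment(img, p)
  v0 <- pmax(img[, , 1], pmax(img[, , 2], img[, , 3]))
  v1 <- pmax(out[, , 1], pmax(out[, , 2], out[, , 3]))
  expect_lte(max(abs(v0 - v1)), 1)
})

test_that("value and contrast scaling are monotone in mean intensity", {
  img <- testImage(4)
  base <- sampleAugmentParams(identityAugment(), 1)
  means_v <- vapply(c(0.8, 0.9, 1.0, 1.1, 1.2), function(f) {
    p <- base; p$val <- f
    mean(applyAugment(img, p))
  }, numeric(1))
  expect_true(all(diff(means_v) >= 0))
  means_c <- vapply(c(0.8, 1.0, 1.2), function(f) {
    p <- base; p$contrast <- f
    mean(applyAugment(img, p))
  }, numeric(1))
  # contrast about mid-grey: monotone given this image's mean above 128
  if (mean(img) >= 128) expect_true(all(diff(means_c) >= 0)) else
    expect_true(all(diff(means_c) <= 0))
})

test_that("sampled parameters respect their ranges and replay bit-exactly", {
  cfg <- augmentConfig(hue_shift_range = c(-30, 30))
  expect_identical(sampleAugmentParams(cfg, 99), sampleAugmentParams(cfg, 99))
  hues <- vapply(1:2000, function(s) sampleAugmentParams(cfg, s)$hue, numeric(1))
  expect_gte(min(hues), -30)
  expect_lte(max(hues), 30)
  shifts <- vapply(1:500, function(s) sampleAugmentParams(cfg, s)$dx, numeric(1))
  expect_true(all(abs(shifts) <= cfg@max_shift_px))
  # replay: enhance == applyAugment(sampleAugmentParams)
  for (s in 1:20) {
    img <- testImage(s, 48)
    expect_identical(enhance(img, cfg, s),
                     applyAugment(img, sampleAugmentParams(cfg, s)))
  }
})

test_that("geometric parameters co-transform annotation coordinates exactly", {
  img <- array(255, c(64, 64, 3))
  pts <- cbind(c(10, 50), c(20, 40))
  p <- sampleAugmentParams(identityAugment(), 1)
  p$flip_h <- TRUE; p$dx <- 3L; p$dy <- -2L
  out <- transformPoints(p, pts, 64, 64)
  expect_equal(out[1, ], c(63 - 10 + 3, 20 - 2))
  expect_equal(out[2, ], c(63 - 50 + 3, 40 - 2))
  # photometric-only records do not move points
  q <- sampleAugmentParams(identityAugment(), 1)
  q$hue <- 15; q$val <- 0.9
  expect_equal(transformPoints(q, pts, 64, 64), pts)
  # the flip really relocates planted content to the transformed coordinate
  img[21, 11, ] <- 0
  fl <- sampleAugmentParams(identityAugment(), 1); fl$flip_h <- TRUE
  moved <- applyAugment(img, fl)
  tp <- transformPoints(fl, cbind(10, 20), 64, 64)
  expect_equal(unname(moved[tp[2] + 1, tp[1] + 1, 1]), 0)
})

test_that("non-RGB input is rejected", {
  expect_error(enhance(matrix(0, 4, 4), augmentConfig(), 1), "RGB")
})
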