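test_that("resolution normalisation scales dimensions and is idempotent", {
  s <- new("CytoSlide", slide_id = "s", mpp = 0.486,
           pixels = array(runif(64 * 64 * 3) * 255, c(64, 64, 3)))
  n <- normalizeResolution(s, 0.243)
  expect_equal(slideMpp(n), 0.243)
  expect_equal(c(slideWidth(n), slideHeight(n)), c(128, 128))
  # already at target: identity, no resampling
  expect_identical(normalizeResolution(n, 0.243), n)
  # scanner at 0.180 um/px: 1000 px -> round(1000 * 0.180 / 0.243) = 741
  s2 <- new("CytoSlide", slide_id = "s2", mpp = 0.180,
            pixels = array(255, c(1000, 1000, 3)))
  n2 <- normalizeResolution(s2, 0.243)
  expect_equal(slideWidth(n2), round(1000 * 0.180 / 0.243))
  expect_equal(slideWidth(n2), 741)
})

test_that("slides without scale metadata are refused", {
  path <- file.path(tempdir(), "nompp.tif")
  tiff::writeTIFF(array(1, c(16, 16, 3)), path)
  expect_error(readSlide(path), "mpp")
  expect_silent(readSlide(path, mpp = 0.243))
})

test_that("tile planning clamps the last row/column and covers the slide", {
  mk <- function(w, h, mpp = 0.486)
    new("CytoSlide", slide_id = "t", mpp = mpp, pixels = array(255, c(h, w, 3)))
  g <- planTiles(mk(1024, 1024), 512, 0.486, overlap_px = 0)
  expect_equal(nTiles(g), 4)
  expect_setequal(apply(g@origins, 1, paste, collapse = ","),
                  c("0,0", "512,0", "0,512", "512,512"))
  # clamping rule on a 1300-wide slide with stride 384
  g2 <- planTiles(mk(1300, 512), 512, 0.486, overlap_px = 128)
  expect_equal(sort(unique(g2@origins[, 1])), c(0, 384, 768, 788))
  # degenerate: slide smaller than a tile
  g3 <- planTiles(mk(100, 100), 512, 0.486)
  expect_equal(nTiles(g3), 1)
  expect_equal(g3@origins[1, ], c(x = 0, y = 0))
  expect_error(planTiles(mk(1024, 1024), 512, 0.486, overlap_px = 512), "overlap")
})

test_that("tile grids cover every pixel (brute-force rasterised check)", {
  for (dims in list(c(700, 300), c(512, 512), c(513, 900), c(100, 40))) {
    s <- new("CytoSlide", slide_id = "c", mpp = 0.486,
             pixels = array(0, c(dims[2], dims[1], 3)))
    g <- planTiles(s, 256, 0.486, overlap_px = 64)
    cov <- matrix(0L, dims[2], dims[1])
    for (i in seq_len(nTiles(g))) {
      o <- g@origins[i, ]
      ys <- (o[2] + 1):min(o[2] + 256, dims[2])
      xs <- (o[1] + 1):min(o[1] + 256, dims[1])
      cov[ys, xs] <- cov[ys, xs] + 1L
    }
    expect_true(all(cov >= 1L))
  }
})

test_that("tile reads pad out-of-bounds area with the glass colour", {
  px <- array(0, c(200, 200, 3))  # black slide
  s <- new("CytoSlide", slide_id = "t", mpp = 0.486, pixels = px)
  g <- planTiles(s, 128, 0.486, overlap_px = 0)
  # interior tile is an exact sub-array
  t1 <- readTile(s, g, 1)
  expect_identical(t1, px[1:128, 1:128, , drop = FALSE])
  # the clamped last tile contains no pad; a manual off-grid read does
  reg <- readRegion(s, 190, 0, 128, 128)
  expect_true(all(reg[, 11:128, ] == 255))  # 10 slide columns, 118 pad
  expect_true(all(reg[, 1:10, ] == 0))
  expect_error(readTile(s, g, 99), "out of range")
})

test_that("crops centre the requested coordinate and pad borders", {
  s <- greySlide(256, 256)
  full <- cropAt(s, c(128, 128), 256)
  expect_identical(full, s@pixels)
  # planted blob round trip: centroid lands at the crop centre +- 1 px
  px <- array(255, c(512, 512, 3))
  for (ch in 1:3) px[301:311, 201:211, ch] <- 0  # 11x11 blob centred (205,305)
  s2 <- new("CytoSlide", slide_id = "b", mpp = 0.243, pixels = px)
  cr <- cropAt(s2, c(205, 305), 64)
  dark <- which(cr[, , 1] < 128, arr.ind = TRUE)
  expect_equal(mean(dark[, 1]) - 1, 32, tolerance = 1)
  expect_equal(mean(dark[, 2]) - 1, 32, tolerance = 1)
  # far off-slide centre: pure pad, no error
  expect_true(all(cropAt(s2, c(-500, -500), 64) == 255))
})

test_that("LR-tile coordinates round trip to base level within a pixel", {
  # plant one blob, detect it in a LR tile frame, map back to base
  px <- array(255, c(1024, 1024, 3))
  for (ch in 1:3) px[641:661, 385:405, ch] <- 0  # centre (394, 650) base
  s <- new("CytoSlide", slide_id = "rt", mpp = 0.243, pixels = px)
  lr <- normalizeResolution(s, 0.486)
  g <- planTiles(lr, 256, 0.486, overlap_px = 0)
  # tile containing the blob at LR coords (197, 325) -> tile 2 origin (0,256)
  tile <- readTile(lr, g, which(g@origins[, 1] == 0 & g@origins[, 2] == 256))
  dark <- which(tile[, , 1] < 200, arr.ind = TRUE)
  tx <- mean(dark[, 2]) - 1; ty <- mean(dark[, 1]) - 1
  base <- c(tx + 0, ty + 256) * 0.486 / 0.243
  expect_lt(abs(base[1] - 394), 1.5)
  expect_lt(abs(base[2] - 650), 1.5)
})
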