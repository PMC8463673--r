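mkLrOutput <- function(heatmap, prob, stride = 8) {
  list(lesion_prob = prob, heatmap = heatmap, heat_stride = stride,
       tile_px = 512, tile_mpp = 0.486)
}

test_that("the probability gate empties the mask regardless of the heatmap", {
  hot <- matrix(1, 64, 64)
  m <- heatmapToMask(mkLrOutput(hot, 0.4))
  expect_equal(nrow(m@components), 0)
  expect_true(all(m@mask == 0))
  # exactly at the gate is still closed (strict "higher than 0.5")
  expect_equal(nrow(heatmapToMask(mkLrOutput(hot, 0.5))@components), 0)
  # all-zero heatmap above the gate: empty mask too
  expect_equal(nrow(heatmapToMask(mkLrOutput(matrix(0, 64, 64), 0.9))@components), 0)
})

test_that("a Gaussian blob heatmap yields one centroid at the mode", {
  xs <- matrix(0:63, 64, 64, byrow = TRUE)
  ys <- matrix(0:63, 64, 64)
  blob <- exp(-((xs - 40)^2 + (ys - 22)^2) / (2 * 3^2))
  m <- heatmapToMask(mkLrOutput(blob, 0.9), bin_threshold = 0.5,
                     tile_origin = c(0, 0))
  expect_equal(nrow(m@components), 1)
  # centroid in base px: cell (40, 22) centre * stride 8 * 2 (0.486 -> 0.243)
  expect_equal(m@components$cx, (40.5) * 8 * 2, tolerance = 16)
  expect_equal(m@components$cy, (22.5) * 8 * 2, tolerance = 16)
  # tile origin shifts the global coordinates
  m2 <- heatmapToMask(mkLrOutput(blob, 0.9), tile_origin = c(512, 0))
  expect_equal(m2@components$cx - m@components$cx, 512 * 2)
})

test_that("mask extraction is monotone in threshold and area filter", {
  set.seed(4)
  heat <- matrix(runif(64 * 64)^3, 64, 64)
  areas <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    sum(heatmapToMask(mkLrOutput(heat, 0.9), bin_threshold = th)@mask),
    numeric(1))
  expect_true(all(diff(areas) <= 0))
  ncomp <- vapply(c(1, 2, 4, 8), function(a)
    nrow(heatmapToMask(mkLrOutput(heat, 0.9), bin_threshold = 0.6,
                       min_area_px = a)@components), numeric(1))
  expect_true(all(diff(ncomp) <= 0))
})

test_that("crop proposals are area-ordered and capped", {
  # smallest block is 3x3: the 3x3 opening erases anything smaller
  heat <- matrix(0, 64, 64)
  heat[5:10, 5:10] <- 1     # area 36
  heat[40:43, 40:43] <- 1   # area 16
  heat[58:60, 20:22] <- 1   # area 9
  m <- heatmapToMask(mkLrOutput(heat, 0.9))
  expect_equal(nrow(m@components), 3)
  expect_true(all(diff(m@components$area) <= 0))
  pr <- proposeCrops(m, 10)
  expect_equal(nrow(pr), 3)
  expect_equal(nrow(proposeCrops(m, 2)), 2)
  empty <- heatmapToMask(mkLrOutput(matrix(0, 64, 64), 0.9))
  expect_equal(nrow(proposeCrops(empty)), 0)
})

test_that("backbone specs enforce their contracts", {
  expect_equal(resnet50HrSpec()@feature_dim, 2048L)
  expect_equal(resnet50LrSpec()@input_px, 512L)
  expect_true(resnet50LrSpec()@seg_branch)
  expect_false(resnet50HrSpec()@seg_branch)
  expect_equal(deskHrSpec(32)@feature_dim, 32L)
  expect_error(trainLesionModel(resnet50HrSpec(), list(1), list(1)),
               "architecture contract")
})

test_that("trained cascade models infer deterministically with shape checks", {
  models <- miniModels()
  co <- miniCohort()
  va <- co$manifest[co$manifest$split == "val", ]
  slide <- readSlide(va$path[va$label == "positive"][1])
  lr_slide <- normalizeResolution(normalizeResolution(slide, 0.243), 0.486)
  grid <- planTiles(lr_slide, 512, 0.486, 128)
  tile <- readTile(lr_slide, grid, 1)
  o1 <- lrInfer(tile, models$lr)
  o2 <- lrInfer(tile, models$lr)
  expect_identical(o1, o2)
  expect_gte(o1$lesion_prob, 0); expect_lte(o1$lesion_prob, 1)
  expect_equal(dim(o1$heatmap), c(64, 64))
  expect_true(all(o1$heatmap >= 0 & o1$heatmap <= 1))
  expect_error(lrInfer(tile[1:100, 1:100, ], models$lr), "512")
  crop <- cropAt(normalizeResolution(slide, 0.243), c(300, 300))
  h1 <- hrInfer(crop, models$hr)
  expect_identical(h1, hrInfer(crop, models$hr))
  expect_length(h1$features, deskHrSpec()@feature_dim)
  expect_true(all(is.finite(h1$features)))
  expect_error(hrInfer(tile, models$hr), "256")
  expect_error(lrInfer(crop, models$hr), "LR model")
})

test_that("desk-scale training separates lesion tiles and localises them", {
  models <- miniModels()
  expect_gte(models$lr@log$val_auc, 0.95)
  expect_gte(models$hr@log$val_auc, 0.95)
  # validation loss decreased from the first recorded epoch
  expect_lt(min(models$lr@log$val_loss), models$lr@log$val_loss[1] + 1e-9)
  co <- miniCohort()
  va <- co$manifest[co$manifest$split == "val", ]
  pos <- va[va$label == "positive", ][1, ]
  slide <- readSlide(pos$path)
  lr_slide <- normalizeResolution(normalizeResolution(slide, 0.243), 0.486)
  grid <- planTiles(lr_slide, 512, 0.486, 128)
  ann <- co$annotations[co$annotations$slide_id == pos$slide_id, ]
  out <- lrInfer(readTile(lr_slide, grid, 1), models$lr)
  expect_gt(out$lesion_prob, 0.5)
  # heatmap argmax within one heatmap cell footprint of a planted centre
  am <- which(out$heatmap == max(out$heatmap), arr.ind = TRUE)[1, ]
  ax <- (am[2] - 0.5) * 8 * 2; ay <- (am[1] - 0.5) * 8 * 2
  d <- sqrt((ann$x_px - ax)^2 + (ann$y_px - ay)^2)
  expect_lt(min(d), 32)
  # background tile on a negative slide stays under the gate
  neg <- va[va$label == "negative", ][1, ]
  nslide <- readSlide(neg$path)
  nlr <- normalizeResolution(normalizeResolution(nslide, 0.243), 0.486)
  nout <- lrInfer(readTile(nlr, planTiles(nlr, 512, 0.486, 128), 1), models$lr)
  expect_lt(nout$lesion_prob, 0.5)
})

test_that("training guards reject slide leakage and empty pools", {
  co <- miniCohort()
  tr <- co$manifest[co$manifest$split == "train", ][1:2, ]
  recs <- materializeHrSamples(tr, co$annotations, deskHrSpec(),
                               per_slide = 1, seed = 1)
  expect_error(trainLesionModel(deskHrSpec(), recs, recs), "overlap")
  expect_error(trainLesionModel(deskHrSpec(), list(), recs), "non-empty")
})

test_that("mining with proportion zero reproduces single-round training", {
  co <- miniCohort()
  tr <- co$manifest[co$manifest$split == "train", ]
  va <- co$manifest[co$manifest$split == "val", ]
  spec <- deskHrSpec(16)
  rtr <- materializeHrSamples(tr, co$annotations, spec, per_slide = 2, seed = 3)
  rva <- materializeHrSamples(va, co$annotations, spec, per_slide = 2, seed = 4)
  opt <- optimConfig(epochs = 6, seed = 11)
  m0 <- trainLesionModel(spec, rtr, rva, mining = miningConfig(0, 1), optim = opt)
  m1 <- trainLesionModel(spec, rtr, rva, mining = miningConfig(0, 2), optim = opt)
  expect_identical(m0@weights, m1@weights)
})
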