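test_that("rendering is a pure function of the plan and respects labels", {
  p_neg <- slidePlan("n1", "negative", styleLibrary()$A, 512, 512,
                     n_normal = 200, seed = 3)
  r_neg <- renderSlide(p_neg)
  expect_equal(nrow(r_neg$annotations), 0)

  p_pos <- slidePlan("p1", "positive", styleLibrary()$B, 512, 512,
                     n_normal = 30, n_lesions = 7, seed = 4)
  r_pos <- renderSlide(p_pos)
  expect_equal(nrow(r_pos$annotations), 7)
  expect_equal(r_pos$annotations$x_px, p_pos@lesion_cells$x)
  expect_equal(r_pos$annotations$y_px, p_pos@lesion_cells$y)

  # byte-identical re-render
  expect_identical(renderSlide(p_pos)$slide@pixels, r_pos$slide@pixels)
  expect_true(all(r_pos$slide@pixels >= 0 & r_pos$slide@pixels <= 255))
})

test_that("out-of-bounds lesion centres are rejected with the cell named", {
  p <- slidePlan("p1", "positive", styleLibrary()$A, 256, 256,
                 n_normal = 5, n_lesions = 2, seed = 1)
  p@lesion_cells$x[2] <- 600
  expect_error(validObject(p), "lesion cell 2")
})

test_that("lesion morphology is stochastically larger and darker than normal", {
  morph <- defaultMorphology()
  p <- slidePlan("p", "positive", styleLibrary()$A, 2048, 2048,
                 n_normal = 10, n_lesions = 15, seed = 9)
  # configured margin: every lesion nucleus exceeds the largest normal one
  expect_gt(min(p@lesion_cells$nucleus_radius), morph$normal_radius[2])
  expect_true(min(p@lesion_cells$nucleus_darkness) >=
                morph$normal_darkness[1] + morph$lesion_darkness_shift)
  # sparsity: planted nucleus area under 1% of the slide
  area <- sum(pi * p@lesion_cells$nucleus_radius^2)
  expect_lt(area / (2048 * 2048), 0.01)
})

test_that("cohort generation balances styles and records an 8:1:1 split", {
  dir <- file.path(tempdir(), "cohort_split")
  # 0 positives, 5 negatives
  m0 <- generateCohort(dir, 0, 5, styles = styleLibrary()["A"],
                       size_px = c(256, 256), n_normal = 5, seed = 1,
                       overwrite = TRUE)
  expect_equal(nrow(m0), 5)
  expect_true(all(m0$label == "negative"))
  expect_error(generateCohort(dir, 0, 5, styles = styleLibrary()["A"]),
               "already exists")
  expect_error(generateCohort(dir, 1, 1, styles = list(), overwrite = TRUE),
               "at least one")

  # style round-robin and split ratios on a 100-slide plan (tiny canvases)
  m <- generateCohort(file.path(tempdir(), "cohort_rr"), 50, 50,
                      styles = styleLibrary()[c("A", "B", "C", "D")],
                      size_px = c(256, 256), n_normal = 5,
                      lesions_per_positive = c(1, 2), seed = 2,
                      overwrite = TRUE)
  expect_equal(as.integer(table(m$style_id)), rep(25L, 4))
  expect_equal(sum(m$split == "train"), 80)
  expect_equal(sum(m$split == "val"), 10)
  expect_equal(sum(m$split == "test"), 10)
  # label consistency: positive iff annotated
  co <- readCohort(file.path(tempdir(), "cohort_rr"))
  annotated <- unique(co$annotations$slide_id)
  expect_setequal(annotated, m$slide_id[m$label == "positive"])
})

test_that("value-channel histograms normalise and order by value scale", {
  h <- valueChannelHistogram(greySlide(value = 128), bins = 32)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_equal(sum(h > 0), 1)  # all mass in one bin for a uniform image

  mk <- function(vs) {
    st <- styleSpec("t", value_scale = vs, noise_sd = 2)
    renderSlide(slidePlan("s", "negative", st, 384, 384, n_normal = 40,
                          seed = 6))$slide
  }
  lo <- valueChannelHistogram(mk(0.8), 64)
  hi <- valueChannelHistogram(mk(1.2), 64)
  expect_equal(sum(lo), 1, tolerance = 1e-12)
  centres <- (seq_len(64) - 0.5) / 64
  expect_lt(sum(lo * centres), sum(hi * centres))
})

test_that("style separation holds for value scales differing by 0.2", {
  lib <- styleLibrary()
  vmeans <- vapply(names(lib), function(nm) {
    s <- renderSlide(slidePlan("s", "negative", lib[[nm]], 256, 256,
                               n_normal = 20, seed = 10))$slide
    mean(valueChannelHistogram(s, 64) * ((seq_len(64) - 0.5) / 64)) * 64
  }, numeric(1))
  vs <- vapply(lib, function(s) s@value_scale, numeric(1))
  for (i in seq_along(lib)) for (j in seq_along(lib)) {
    if (vs[i] - vs[j] >= 0.2) expect_gt(vmeans[i], vmeans[j])
  }
})
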