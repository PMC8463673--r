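# Synthetic multi-style cytology slides with planted lesion cells and exact
# point ground truth. The generator emulates the structure screening depends
# on: sparse, small lesion cells (enlarged, deep-stained nuclei, optional
# perinuclear halo) scattered among abundant normal cells, rendered under
# several staining/imaging styles whose value-channel distributions differ.

#' Built-in style library
#'
#' Six named styles loosely spanning the staining/imaging diversity of a
#' multi-centre cohort. Styles A-D are intended as "training-site" styles;
#' E and F are held-out styles for generalisation experiments. Their
#' `value_scale` values differ by well over 0.2 between extremes, so their
#' value-channel histograms are clearly separated.
#'
#' @return Named list of [StyleSpec-class] objects.
#' @examples
#' names(styleLibrary())
#' @export
styleLibrary <- function() {
  list(
    A = styleSpec("A", hue_shift = 0,   saturation_scale = 1.00, value_scale = 1.00,
                  background_rgb = c(243, 241, 246), noise_sd = 3, blur_sigma = 0),
    B = styleSpec("B", hue_shift = -12, saturation_scale = 1.15, value_scale = 0.92,
                  background_rgb = c(236, 229, 243), noise_sd = 4, blur_sigma = 0.5),
    C = styleSpec("C", hue_shift = 18,  saturation_scale = 0.85, value_scale = 1.08,
                  background_rgb = c(248, 246, 240), noise_sd = 2, blur_sigma = 0),
    D = styleSpec("D", hue_shift = 30,  saturation_scale = 1.30, value_scale = 0.85,
                  background_rgb = c(238, 232, 230), noise_sd = 5, blur_sigma = 0.8),
    E = styleSpec("E", hue_shift = -35, saturation_scale = 0.70, value_scale = 0.75,
                  background_rgb = c(226, 229, 236), noise_sd = 6, blur_sigma = 1.0),
    F = styleSpec("F", hue_shift = 45,  saturation_scale = 1.20, value_scale = 1.12,
                  background_rgb = c(250, 244, 248), noise_sd = 3, blur_sigma = 0.3)
  )
}

# Default lesion-morphology margins: lesion nuclei are 1.8-2.5x the normal
# radius and +0.3 darker, the "large nucleus / deep-stained" cues that drive
# recognition.

#' Lesion morphology parameters
#'
#' `defaultMorphology()` gives the study margins (lesion nucleus radius
#' 1.8-2.5x normal, darkness +0.3, perinuclear halo probability 0.5).
#' `confusableMorphology()` narrows those margins (radius 1.35-1.9x,
#' darkness +0.12) to produce borderline, ASC-US-like lesion cells whose
#' recognition genuinely depends on training strategy; the ablation harness
#' uses it.
#'
#' @return named list of morphology parameters.
#' @export
defaultMorphology <- function() {
  list(
    normal_radius = c(10, 14),       # px at 0.243 um/px
    normal_darkness = c(0.25, 0.45),
    lesion_radius_scale = c(1.8, 2.5),
    lesion_darkness_shift = 0.3,
    halo_prob = 0.5,
    normal_cyto_ratio = c(2.6, 3.4), # cytoplasm radius / nucleus radius
    lesion_cyto_ratio = c(1.5, 2.0)  # high N:C ratio for lesion cells
  )
}

#' @rdname defaultMorphology
#' @export
confusableMorphology <- function() {
  m <- defaultMorphology()
  m$lesion_radius_scale <- c(1.35, 1.9)
  m$lesion_darkness_shift <- 0.12
  m$halo_prob <- 0.3
  m
}

sampleLesionCells <- function(n, width_px, height_px, morph, seed) {
  if (n == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), cell_class = character(0),
                      nucleus_radius = numeric(0), nucleus_darkness = numeric(0),
                      halo = logical(0), cyto_ratio = numeric(0)))
  }
  withSeed(seed, {
    # margins scale down on small canvases so placement stays feasible
    margin <- min(64, floor(min(width_px, height_px) / 8))
    min_sep <- min(96, floor(min(width_px, height_px) / 2.5))
    xs <- ys <- numeric(0)
    tries <- 0
    while (length(xs) < n && tries < 5000) {
      tries <- tries + 1
      x <- stats::runif(1, margin, width_px - margin)
      y <- stats::runif(1, margin, height_px - margin)
      if (length(xs) == 0 || min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_sep) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    if (length(xs) < n)
      stop("could not place ", n, " lesion cells with the configured separation")
    base_r <- mean(morph$normal_radius)
    data.frame(
      x = round(xs), y = round(ys), cell_class = "lesion",
      nucleus_radius = base_r * stats::runif(n, morph$lesion_radius_scale[1],
                                             morph$lesion_radius_scale[2]),
      nucleus_darkness = pmin(1, stats::runif(n, morph$normal_darkness[1],
                                              morph$normal_darkness[2]) +
                                   morph$lesion_darkness_shift),
      halo = stats::runif(n) < morph$halo_prob,
      cyto_ratio = stats::runif(n, morph$lesion_cyto_ratio[1],
                                morph$lesion_cyto_ratio[2])
    )
  })
}

#' Plan a synthetic slide
#'
#' Builds a [SlidePlan-class]: for positive slides, lesion-cell specs are
#' drawn from distributions stochastically larger (radius) and darker
#' (nucleus) than normal cells, with the margins of
#' `defaultMorphology()`. Normal background cells are drawn at render time
#' from the plan seed, so the plan plus seed fully determines the pixels.
#'
#' @param slide_id slide token.
#' @param label `"positive"` or `"negative"`.
#' @param style a [StyleSpec-class].
#' @param width_px,height_px canvas size at the reference 0.243 um/px level.
#' @param mpp microns per pixel of the rendered raster.
#' @param n_normal number of background normal cells.
#' @param n_lesions planted lesion count (ignored for negatives).
#' @param morph morphology parameter list, see `defaultMorphology()`.
#' @param seed integer seed.
#' @return A [SlidePlan-class].
#' @examples
#' p <- slidePlan("s1", "positive", styleLibrary()$A, 512, 512,
#'                n_normal = 20, n_lesions = 2, seed = 7)
#' nrow(p@lesion_cells)
#' @export
slidePlan <- function(slide_id, label, style, width_px = 2048, height_px = 2048,
                      mpp = 0.243, n_normal = 180, n_lesions = 0,
                      morph = defaultMorphology(), seed = 1) {
  n_les <- if (label == "positive") n_lesions else 0L
  cells <- sampleLesionCells(n_les, width_px, height_px, morph,
                             subSeed(seed, "lesions", slide_id))
  new("SlidePlan", slide_id = as.character(slide_id), label = label,
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      mpp = mpp, n_normal = as.integer(n_normal), lesion_cells = cells,
      style = style, seed = as.integer(seed))
}

# Geometry of one soft-edged cell (cytoplasm disk + nucleus + optional
# halo): returns the bounding-box rows/cols (1-based) and the blend alphas,
# or NULL when the cell lies outside the canvas. Blending happens in the
# caller so the canvas matrices are modified in place. Coordinates 0-based.
cellAlphas <- function(h, w, cx, cy, nr, cr, halo, ecc, ang) {
  x0 <- max(0, floor(cx - cr - 2)); x1 <- min(w - 1, ceiling(cx + cr + 2))
  y0 <- max(0, floor(cy - cr - 2)); y1 <- min(h - 1, ceiling(cy + cr + 2))
  if (x1 < x0 || y1 < y0) return(NULL)
  xs <- (x0:x1) - cx
  ys <- (y0:y1) - cy
  dx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  dy <- matrix(ys, length(ys), length(xs))
  # mild elliptical irregularity for the nucleus
  rx <- dx * cos(ang) + dy * sin(ang)
  ry <- -dx * sin(ang) + dy * cos(ang)
  dn <- sqrt((rx / ecc)^2 + (ry * ecc)^2)
  dc <- sqrt(dx^2 + dy^2)
  a_h <- NULL
  if (halo) {
    ring_out <- min(1.8 * nr, cr - 1)
    if (ring_out > nr + 1)
      a_h <- clamp01((dn - nr) / 1.2) * clamp01((ring_out - dn) / 1.2) * 0.85
  }
  list(rows = (y0 + 1):(y1 + 1), cols = (x0 + 1):(x1 + 1),
       a_c = clamp01((cr - dc) / 1.5) * 0.9,
       a_n = clamp01((nr - dn) / 1.2),
       a_h = a_h)
}

# Rotate the hue of a single RGB colour (exact hexcone transform).
rotateHue <- function(rgb, degrees) {
  if (degrees == 0) return(rgb)
  hsv <- grDevices::rgb2hsv(matrix(pmax(rgb, 0), 3), maxColorValue = 255)
  as.vector(hsvToRgbArr(matrix(hsv[1] * 360 + degrees, 1, 1),
                        matrix(hsv[2], 1, 1), matrix(hsv[3], 1, 1)))
}

# Photometric style transform. Hue rotation is applied to the drawing
# palette (single colours, in renderSlide); here the per-pixel part runs:
# value and saturation scaling in their exact linear per-channel form
# (V' = min(V * f, 1); channels then move toward/away from V' by the
# saturation factor, which leaves V' untouched), plus luminance noise and
# optional defocus blur.
applyStyle <- function(img, style, seed) {
  v <- pmax(img[, , 1], pmax(img[, , 2], img[, , 3]))
  vf <- pmin(style@value_scale, 255 / pmax(v, 1e-9))
  v2 <- v * vf
  out <- img
  for (ch in 1:3) {
    c2 <- img[, , ch] * vf
    out[, , ch] <- v2 + (c2 - v2) * style@saturation_scale
  }
  if (style@noise_sd > 0) {
    noise <- withSeed(seed, matrix(stats::rnorm(prod(dim(img)[1:2]),
                                                sd = style@noise_sd),
                                   dim(img)[1], dim(img)[2]))
    for (ch in 1:3) out[, , ch] <- out[, , ch] + noise
  }
  if (style@blur_sigma > 0) out <- gaussBlurRgb(out, style@blur_sigma)
  round(clamp255(out))
}

#' Nested lesion-count ladder of slide plans
#'
#' Builds plans that differ only in how many planted lesion cells they carry:
#' the largest count is planned once and each rung keeps a prefix of that
#' lesion set, so every smaller slide is pixel-identical to the larger ones
#' apart from the added cells. Used to check that slide scores do not
#' decrease when lesion cells are added.
#'
#' @param counts increasing lesion counts (0 allowed; gives a negative slide).
#' @param style a [StyleSpec-class].
#' @param width_px,height_px,mpp,n_normal,morph,seed as in [slidePlan()].
#' @return list of [SlidePlan-class], one per count.
#' @export
ladderPlans <- function(counts = c(0, 2, 5, 10), style = styleLibrary()$A,
                        width_px = 2048, height_px = 2048, mpp = 0.243,
                        n_normal = 180, morph = defaultMorphology(), seed = 1) {
  counts <- sort(counts)
  full <- slidePlan("ladder", "positive", style, width_px, height_px, mpp,
                    n_normal, max(counts), morph = morph, seed = seed)
  lapply(counts, function(n) {
    new("SlidePlan", slide_id = "ladder",
        label = if (n > 0) "positive" else "negative",
        width_px = full@width_px, height_px = full@height_px, mpp = full@mpp,
        n_normal = full@n_normal,
        lesion_cells = full@lesion_cells[seq_len(n), , drop = FALSE],
        style = full@style, seed = full@seed)
  })
}

#' Render a synthetic slide
#'
#' Pure function of the plan (including its seed): identical plans give
#' byte-identical rasters. Normal cells are Poisson-placed with overlap
#' allowed; lesion cells are drawn on top; the style transform (HSV hue/
#' saturation/value, luminance noise, blur) is applied last.
#'
#' @param plan a valid [SlidePlan-class].
#' @return list with elements `slide` (a [CytoSlide-class] at `plan@mpp`) and
#'   `annotations` (data.frame `slide_id, x_px, y_px, cell_class` in 0-based
#'   base-level pixel coordinates, one row per planted lesion cell).
#' @examples
#' p <- slidePlan("s1", "negative", styleLibrary()$A, 256, 256,
#'                n_normal = 10, seed = 3)
#' r <- renderSlide(p)
#' nrow(r$annotations)  # 0: negatives have no lesions
#' @export
renderSlide <- function(plan) {
  validObject(plan)
  sc <- 0.243 / plan@mpp   # geometry scale from reference level to raster
  h <- as.integer(round(plan@height_px * sc))
  w <- as.integer(round(plan@width_px * sc))
  style <- plan@style
  ch1 <- matrix(style@background_rgb[1], h, w)
  ch2 <- matrix(style@background_rgb[2], h, w)
  ch3 <- matrix(style@background_rgb[3], h, w)
  morph <- defaultMorphology()
  # build the draw list (deterministic from the plan seed), then blend each
  # cell into the channel matrices in place
  lc <- plan@lesion_cells
  cells <- withSeed(subSeed(plan@seed, "render", plan@slide_id), {
    n_norm <- plan@n_normal
    out <- vector("list", n_norm + nrow(lc))
    if (n_norm > 0) {
      nx <- stats::runif(n_norm, 0, w - 1)
      ny <- stats::runif(n_norm, 0, h - 1)
      nr <- stats::runif(n_norm, morph$normal_radius[1], morph$normal_radius[2]) * sc
      nd <- stats::runif(n_norm, morph$normal_darkness[1], morph$normal_darkness[2])
      ncr <- nr * stats::runif(n_norm, morph$normal_cyto_ratio[1],
                               morph$normal_cyto_ratio[2])
      for (i in seq_len(n_norm))
        out[[i]] <- list(cx = nx[i], cy = ny[i], nr = nr[i], cr = ncr[i],
                         dark = nd[i], halo = FALSE,
                         cyto = rotateHue(c(186, 168, 205) + stats::rnorm(3, sd = 8),
                                          style@hue_shift),
                         nucl = rotateHue(c(118, 82, 150) + stats::rnorm(3, sd = 6),
                                          style@hue_shift),
                         ecc = stats::runif(1, 0.9, 1.1),
                         ang = stats::runif(1, 0, pi))
    }
    for (i in seq_len(nrow(lc)))
      out[[n_norm + i]] <- list(cx = lc$x[i] * sc, cy = lc$y[i] * sc,
                                nr = lc$nucleus_radius[i] * sc,
                                cr = lc$nucleus_radius[i] * lc$cyto_ratio[i] * sc,
                                dark = lc$nucleus_darkness[i], halo = lc$halo[i],
                                cyto = rotateHue(c(186, 168, 205) +
                                                   stats::rnorm(3, sd = 8),
                                                 style@hue_shift),
                                nucl = rotateHue(c(118, 82, 150) +
                                                   stats::rnorm(3, sd = 6),
                                                 style@hue_shift),
                                ecc = stats::runif(1, 0.85, 1.15),
                                ang = stats::runif(1, 0, pi))
    out
  })
  for (cell in cells) {
    a <- cellAlphas(h, w, cell$cx, cell$cy, cell$nr, cell$cr, cell$halo,
                    cell$ecc, cell$ang)
    if (is.null(a)) next
    nuc <- cell$nucl * (1 - 0.85 * cell$dark)
    blend <- function(layer, ch) {
      layer <- layer * (1 - a$a_c) + cell$cyto[ch] * a$a_c
      if (!is.null(a$a_h))
        layer <- layer * (1 - a$a_h) + style@background_rgb[ch] * a$a_h
      layer * (1 - a$a_n) + nuc[ch] * a$a_n
    }
    ch1[a$rows, a$cols] <- blend(ch1[a$rows, a$cols], 1)
    ch2[a$rows, a$cols] <- blend(ch2[a$rows, a$cols], 2)
    ch3[a$rows, a$cols] <- blend(ch3[a$rows, a$cols], 3)
  }
  canvas <- array(0, c(h, w, 3))
  canvas[, , 1] <- ch1; canvas[, , 2] <- ch2; canvas[, , 3] <- ch3

  pixels <- applyStyle(canvas, style, subSeed(plan@seed, "noise", plan@slide_id))
  slide <- new("CytoSlide", slide_id = plan@slide_id, mpp = plan@mpp,
               pixels = pixels)
  ann <- if (nrow(plan@lesion_cells) > 0) {
    data.frame(slide_id = plan@slide_id, x_px = plan@lesion_cells$x,
               y_px = plan@lesion_cells$y, cell_class = "lesion")
  } else {
    data.frame(slide_id = character(0), x_px = numeric(0), y_px = numeric(0),
               cell_class = character(0))
  }
  list(slide = slide, annotations = ann)
}

assignSplit <- function(labels, ratios, seed) {
  split <- character(length(labels))
  for (lb in unique(labels)) {
    idx <- which(labels == lb)
    idx <- withSeed(subSeed(seed, "split", lb), sample(idx))
    n <- length(idx)
    n_tr <- floor(ratios[1] * n)
    n_va <- floor(ratios[2] * n)
    n_te <- n - n_tr - n_va
    split[idx] <- rep(c("train", "val", "test"), c(n_tr, n_va, n_te))
  }
  split
}

#' Generate a synthetic cohort on disk
#'
#' Renders `n_pos + n_neg` slides, assigning styles round-robin over the
#' manifest order and a slide-wise train/val/test split (default ratio
#' 8:1:1, stratified by label). Slides are written as 8-bit RGB TIFF with the
#' microns-per-pixel scale in a YAML sidecar; the manifest and the planted
#' lesion annotations are written as CSV.
#'
#' @param out_dir output directory (created; refuses to overwrite an existing
#'   manifest unless `overwrite = TRUE`).
#' @param n_pos,n_neg number of positive / negative slides (>= 0).
#' @param styles non-empty list of [StyleSpec-class] objects.
#' @param lesions_per_positive integer range (min, max) of planted lesions.
#' @param size_px (width, height) at the reference level.
#' @param n_normal background cells per slide.
#' @param mpp rendered microns per pixel.
#' @param morph lesion morphology parameters, see [defaultMorphology()].
#' @param split_ratios train/val/test proportions (must sum to 1).
#' @param seed cohort seed; per-slide seeds derive from it.
#' @param prefix slide-id prefix (distinguishes slides of separate cohorts).
#' @param overwrite overwrite an existing cohort.
#' @return Invisibly, the manifest data.frame
#'   (`slide_id, label, style_id, split, path, n_lesions, seed`).
#' @export
generateCohort <- function(out_dir, n_pos, n_neg,
                           styles = styleLibrary()[c("A", "B", "C", "D")],
                           lesions_per_positive = c(3, 15),
                           size_px = c(2048, 2048), n_normal = 180,
                           mpp = 0.243, morph = defaultMorphology(),
                           split_ratios = c(0.8, 0.1, 0.1),
                           seed = 1, prefix = "", overwrite = FALSE) {
  if (length(styles) == 0) stop("at least one StyleSpec is required")
  if (n_pos < 0 || n_neg < 0) stop("n_pos and n_neg must be >= 0")
  if (abs(sum(split_ratios) - 1) > 1e-9) stop("split_ratios must sum to 1")
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite)
    stop("cohort already exists at ", out_dir, " (use overwrite = TRUE)")
  dir.create(file.path(out_dir, "slides"), recursive = TRUE, showWarnings = FALSE)

  n <- n_pos + n_neg
  labels <- rep(c("positive", "negative"), c(n_pos, n_neg))
  ids <- sprintf("%s%s_%03d", prefix,
                 ifelse(labels == "positive", "pos", "neg"),
                 c(seq_len(n_pos), seq_len(n_neg)))
  style_idx <- ((seq_len(n) - 1) %% length(styles)) + 1
  n_lesions <- withSeed(subSeed(seed, "counts"), {
    ifelse(labels == "positive",
           sample(lesions_per_positive[1]:lesions_per_positive[2], n,
                  replace = TRUE), 0L)
  })
  split <- assignSplit(labels, split_ratios, seed)

  ann_all <- list()
  paths <- character(n)
  for (i in seq_len(n)) {
    st <- styles[[style_idx[i]]]
    plan <- slidePlan(ids[i], labels[i], st, size_px[1], size_px[2], mpp,
                      n_normal, n_lesions[i], morph = morph,
                      seed = subSeed(seed, "slide", i))
    r <- renderSlide(plan)
    paths[i] <- file.path(out_dir, "slides", paste0(ids[i], ".tif"))
    writeSlide(r$slide, paths[i])
    if (nrow(r$annotations) > 0) ann_all[[length(ann_all) + 1]] <- r$annotations
  }
  manifest <- data.frame(
    slide_id = ids, label = labels,
    style_id = vapply(styles[style_idx], function(s) s@style_id, character(1)),
    split = split, path = paths, n_lesions = n_lesions,
    seed = vapply(seq_len(n), function(i) subSeed(seed, "slide", i), integer(1))
  )
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  ann <- if (length(ann_all)) do.call(rbind, ann_all) else
    data.frame(slide_id = character(0), x_px = numeric(0), y_px = numeric(0),
               cell_class = character(0))
  utils::write.csv(ann, file.path(out_dir, "annotations.csv"), row.names = FALSE)
  yaml::write_yaml(list(n_pos = n_pos, n_neg = n_neg, seed = seed, mpp = mpp,
                        size_px = as.integer(size_px), n_normal = n_normal,
                        lesions_per_positive = as.integer(lesions_per_positive),
                        styles = vapply(styles, function(s) s@style_id,
                                        character(1))),
                   file.path(out_dir, "cohort.yaml"))
  invisible(manifest)
}

#' Read a cohort manifest and its annotations
#'
#' @param dir cohort directory written by [generateCohort()].
#' @return list with `manifest` and `annotations` data.frames.
#' @export
readCohort <- function(dir) {
  list(
    manifest = utils::read.csv(file.path(dir, "manifest.csv"),
                               stringsAsFactors = FALSE),
    annotations = utils::read.csv(file.path(dir, "annotations.csv"),
                                  stringsAsFactors = FALSE)
  )
}

#' Normalised value-channel histogram of a slide
#'
#' Histograms the HSV value channel (max of R, G, B, scaled to \[0, 1\]) into
#' equal-width bins; counts are normalised to sum to one. The last bin is
#' closed at 1.
#'
#' @param slide a [CytoSlide-class].
#' @param bins number of bins.
#' @return numeric vector of length `bins` summing to 1.
#' @export
valueChannelHistogram <- function(slide, bins = 32) {
  v <- valueChannel(slide@pixels)
  idx <- pmin(bins, floor(as.vector(v) * bins) + 1L)
  counts <- tabulate(idx, nbins = bins)
  counts / sum(counts)
}
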