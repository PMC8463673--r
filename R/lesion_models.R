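# The two cascade models. The LR model reads a 512 px tile at 0.486 um/px
# and emits (lesion probability, location heatmap); tiles passing the 0.5
# probability gate have their heatmaps binarised, morphologically cleaned and
# reduced to connected-component centroids that seed 256 px HR crops at
# 0.243 um/px. The HR model emits (lesion probability, penultimate feature
# vector). Both are trained with Adam (initial lr 1e-3, step decay) under
# balanced epochs and a second-round hard-sample mix.

#' Create an untrained cascade model
#'
#' @param spec a [BackboneSpec-class]; specs with a segmentation branch give
#'   an LR model, others an HR model.
#' @return A [LesionModel-class].
#' @export
lesionModel <- function(spec) {
  new("LesionModel", spec = spec, kind = if (spec@seg_branch) "lr" else "hr",
      weights = list(), norm = list(), trained = FALSE, log = list())
}

checkInput <- function(img, spec, what) {
  if (!isRgbArray(img) || dim(img)[1] != spec@input_px ||
      dim(img)[2] != spec@input_px)
    stop(what, " expects a ", spec@input_px, "x", spec@input_px,
         " RGB array, got ", paste(dim(img), collapse = "x"))
}

#' LR inference on one tile
#'
#' Deterministic: no randomness is consumed. The heatmap is spatially
#' registered to the tile at 1 cell per `heat_stride` input pixels.
#'
#' @param tile `512 x 512 x 3` array at 0.486 um/px.
#' @param model a trained LR [LesionModel-class].
#' @return list: `lesion_prob`, `heatmap` (matrix in \[0,1\]), `heat_stride`,
#'   `tile_px`, `tile_mpp`.
#' @export
lrInfer <- function(tile, model) {
  spec <- model@spec
  if (model@kind != "lr") stop("lrInfer needs an LR model")
  if (!model@trained) stop("model is untrained")
  checkInput(tile, spec, "lrInfer")
  maps <- blobMaps(tile, spec)
  cf <- cellFeatures(maps, spec)
  fv <- tileFeatureVector(cf$X)
  z <- applyStandardizer(matrix(fv, 1), model@norm$cls)
  prob <- sigmoid(as.vector(z %*% model@weights$cls$w) + model@weights$cls$b)
  zc <- applyStandardizer(cf$X, model@norm$seg)
  heat <- matrix(sigmoid(as.vector(zc %*% model@weights$seg$w) +
                           model@weights$seg$b), cf$ncy, cf$ncx)
  list(lesion_prob = prob, heatmap = heat, heat_stride = spec@heat_stride,
       tile_px = spec@input_px, tile_mpp = spec@input_mpp)
}

#' Convert an LR heatmap into a location mask
#'
#' The mask is empty whenever the tile's lesion probability is at or below
#' the gate (proposals are made only for tiles "with a probability higher
#' than 0.5"). Otherwise: binarise at `bin_threshold` (absolute), 3x3
#' closing, 3x3 opening, 8-connected components, drop components smaller
#' than `min_area_px` heatmap cells; centroids are mapped through the tile
#' origin to base-level coordinates.
#'
#' @param output result of [lrInfer()].
#' @param bin_threshold heatmap binarisation threshold.
#' @param min_area_px minimum component area (heatmap cells).
#' @param tile_origin (x, y) tile origin at `tile_mpp`.
#' @param gate probability gate (0.5; strict "higher than").
#' @return A [LocationMask-class].
#' @export
heatmapToMask <- function(output, bin_threshold = 0.5, min_area_px = 2,
                          tile_origin = c(0, 0), gate = 0.5) {
  cell_base <- output$heat_stride * output$tile_mpp / REF_MPP
  empty <- function() new("LocationMask",
                          mask = matrix(0, nrow(output$heatmap), ncol(output$heatmap)),
                          components = data.frame(cx = numeric(0), cy = numeric(0),
                                                  area = numeric(0)),
                          cell_base_px = cell_base)
  if (output$lesion_prob <= gate) return(empty())
  bin <- (output$heatmap > bin_threshold) * 1
  if (!any(bin > 0)) return(empty())
  brush <- EBImage::makeBrush(3, "box")
  eb <- EBImage::opening(EBImage::closing(EBImage::Image(t(bin)), brush), brush)
  bin <- t(EBImage::imageData(eb))
  if (!any(bin > 0)) return(empty())
  lab <- labelComponents(bin)
  nlab <- max(lab)
  comps <- lapply(seq_len(nlab), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) return(NULL)
    # 0-based cell centroids -> tile px (cell centre) -> base-level px
    cy_cell <- mean(idx[, 1]) - 1
    cx_cell <- mean(idx[, 2]) - 1
    tx <- (cx_cell + 0.5) * output$heat_stride + tile_origin[1]
    ty <- (cy_cell + 0.5) * output$heat_stride + tile_origin[2]
    data.frame(cx = tx * output$tile_mpp / REF_MPP,
               cy = ty * output$tile_mpp / REF_MPP,
               area = nrow(idx))
  })
  comps <- do.call(rbind, comps[!vapply(comps, is.null, logical(1))])
  if (is.null(comps) || nrow(comps) == 0) return(empty())
  comps <- comps[order(-comps$area, comps$cy, comps$cx), , drop = FALSE]
  rownames(comps) <- NULL
  new("LocationMask", mask = bin, components = comps, cell_base_px = cell_base)
}

#' Propose HR crop centres from a location mask
#'
#' One proposal per component centroid, largest area first, truncated at
#' `per_tile_cap`. Coordinates are base-level (global frame), so crops near
#' tile edges draw pixels from neighbouring slide regions rather than pad.
#'
#' @param mask a [LocationMask-class].
#' @param per_tile_cap maximum proposals per tile.
#' @return numeric matrix (n x 2) of (x, y) base-level centres.
#' @export
proposeCrops <- function(mask, per_tile_cap = 10) {
  comps <- mask@components
  n <- min(nrow(comps), per_tile_cap)
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  cbind(comps$cx[seq_len(n)], comps$cy[seq_len(n)])
}

#' HR inference on one crop
#'
#' Deterministic. The feature vector is the penultimate (hidden-layer)
#' activation, length `spec@feature_dim` (2,048 in the full-scale contract).
#'
#' @param crop `256 x 256 x 3` array at 0.243 um/px.
#' @param model a trained HR [LesionModel-class].
#' @return list: `lesion_prob`, `features` (length F).
#' @export
hrInfer <- function(crop, model) {
  spec <- model@spec
  if (model@kind != "hr") stop("hrInfer needs an HR model")
  if (!model@trained) stop("model is untrained")
  checkInput(crop, spec, "hrInfer")
  raw <- hrRawFeatures(crop, spec)
  z <- as.vector(applyStandardizer(matrix(raw, 1), model@norm$raw))
  h <- tanh(as.vector(model@weights$W1 %*% z) + model@weights$b1)
  prob <- sigmoid(sum(model@weights$w2 * h) + model@weights$b2)
  list(lesion_prob = prob, features = h)
}

# ---------------------------------------------------------------------------
# Sample materialisation (images -> cached head features)
# ---------------------------------------------------------------------------

# Shared record shape: list(sample_id, slide_id, group_id, category, label,
# ...payload). Pools for the sampling module are derived with recordsPool().
recordsPool <- function(records) {
  data.frame(
    sample_id = vapply(records, `[[`, character(1), "sample_id"),
    group_id = vapply(records, `[[`, character(1), "group_id"),
    category = vapply(records, `[[`, character(1), "category"),
    label = vapply(records, `[[`, character(1), "label"),
    hard = FALSE, idx = seq_along(records)
  )
}

#' Materialise LR training tiles as head features
#'
#' Reads each training slide once, plans the redundant LR tile grid, labels
#' tiles by whether a planted lesion centre falls inside (with a margin), and
#' converts a per-slide selection of tiles into cached head inputs: the
#' tile-level descriptor, and per-heatmap-cell features with disk supervision
#' targets (radius `target_radius_cells` around each lesion centre). With a
#' non-NULL augmentation config, `variants` extra augmented copies are
#' materialised per tile; geometric transforms co-transform the lesion
#' coordinates exactly.
#'
#' @param manifest cohort manifest rows to use (one slide per row).
#' @param annotations cohort annotations (base-level lesion centres).
#' @param spec LR [BackboneSpec-class].
#' @param augment an [AugmentConfig-class] or NULL for no enhancement.
#' @param variants augmented copies per tile (ignored when `augment` is NULL).
#' @param tiles_per_class tiles kept per slide and class.
#' @param overlap_px tile overlap.
#' @param target_radius_cells supervision disk radius (heatmap cells).
#' @param seed integer seed.
#' @return list of sample records.
#' @export
materializeLrSamples <- function(manifest, annotations, spec = deskLrSpec(),
                                 augment = NULL, variants = 2,
                                 tiles_per_class = 2, overlap_px = 128,
                                 target_radius_cells = 2, seed = 1) {
  records <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    slide <- readSlide(row$path)
    lr <- normalizeResolution(normalizeResolution(slide, REF_MPP), spec@input_mpp)
    grid <- planTiles(lr, spec@input_px, spec@input_mpp, overlap_px)
    ann <- annotations[annotations$slide_id == row$slide_id, , drop = FALSE]
    # lesion centres in the LR frame
    lx <- ann$x_px * REF_MPP / spec@input_mpp
    ly <- ann$y_px * REF_MPP / spec@input_mpp
    margin <- 32
    n_les <- integer(nTiles(grid))
    for (t in seq_len(nTiles(grid))) {
      o <- grid@origins[t, ]
      n_les[t] <- sum(lx >= o[1] + margin & lx < o[1] + spec@input_px - margin &
                      ly >= o[2] + margin & ly < o[2] + spec@input_px - margin)
    }
    pos_t <- order(-n_les)[seq_len(min(tiles_per_class, sum(n_les > 0)))]
    pos_t <- pos_t[n_les[pos_t] > 0]
    neg_pool <- which(n_les == 0)
    neg_t <- withSeed(subSeed(seed, "negtiles", row$slide_id),
                      neg_pool[sample.int(length(neg_pool),
                                          min(tiles_per_class, length(neg_pool)))])
    for (t in c(pos_t, neg_t)) {
      o <- grid@origins[t, ]
      img0 <- readTile(lr, grid, t)
      inside <- lx >= o[1] & lx < o[1] + spec@input_px &
                ly >= o[2] & ly < o[2] + spec@input_px
      pts0 <- cbind(lx[inside] - o[1], ly[inside] - o[2])
      n_var <- if (is.null(augment)) 1L else as.integer(variants) + 1L
      for (v in seq_len(n_var)) {
        if (v == 1L) {
          img <- img0; pts <- pts0
        } else {
          pars <- sampleAugmentParams(augment,
                                      subSeed(seed, "aug", row$slide_id, t, v))
          img <- applyAugment(img0, pars)
          pts <- transformPoints(pars, pts0, spec@input_px, spec@input_px)
          keep <- pts[, 1] >= 0 & pts[, 1] < spec@input_px &
                  pts[, 2] >= 0 & pts[, 2] < spec@input_px
          pts <- pts[keep, , drop = FALSE]
        }
        maps <- blobMaps(img, spec)
        cf <- cellFeatures(maps, spec)
        fv <- tileFeatureVector(cf$X)
        # disk targets in heatmap-cell coordinates
        tgt <- rep(0, nrow(cf$X))
        if (nrow(pts) > 0) {
          cyi <- rep(seq_len(cf$ncy) - 1, times = cf$ncx)
          cxi <- rep(seq_len(cf$ncx) - 1, each = cf$ncy)
          for (j in seq_len(nrow(pts))) {
            ccx <- pts[j, 1] / spec@heat_stride - 0.5
            ccy <- pts[j, 2] / spec@heat_stride - 0.5
            tgt[(cxi - ccx)^2 + (cyi - ccy)^2 <= target_radius_cells^2] <- 1
          }
        }
        pos_cells <- which(tgt == 1)
        neg_cells <- withSeed(subSeed(seed, "cells", row$slide_id, t, v),
                              sample(which(tgt == 0),
                                     min(40, sum(tgt == 0))))
        sel <- c(pos_cells, neg_cells)
        tile_pos <- nrow(pts) > 0 && length(pos_cells) > 0
        records[[length(records) + 1]] <- list(
          sample_id = sprintf("%s_t%d_v%d", row$slide_id, t, v),
          slide_id = row$slide_id, group_id = row$style_id,
          category = if (tile_pos) "lesion" else "normal",
          label = if (tile_pos) "positive" else "negative",
          fvec = fv, cellX = cf$X[sel, , drop = FALSE], cellY = tgt[sel]
        )
      }
    }
  }
  records
}

#' Materialise HR training crops as raw descriptors
#'
#' Positive samples are crops centred on planted lesion cells; negative
#' samples are crops at random locations at least `neg_min_dist` px from any
#' lesion (on both positive and negative slides). With augmentation enabled,
#' `variants` extra augmented copies are added (shift capped so the target
#' cell stays in the centre region).
#'
#' @inheritParams materializeLrSamples
#' @param spec HR [BackboneSpec-class].
#' @param per_slide positive and negative crops per slide.
#' @param neg_min_dist minimum negative-centre distance from lesions (px).
#' @return list of sample records (payload: `raw` descriptor).
#' @export
materializeHrSamples <- function(manifest, annotations, spec = deskHrSpec(),
                                 augment = NULL, variants = 2, per_slide = 4,
                                 neg_min_dist = 96, seed = 1) {
  if (!is.null(augment)) augment@max_shift_px <- min(augment@max_shift_px, 16L)
  records <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    slide <- normalizeResolution(readSlide(row$path), REF_MPP)
    ann <- annotations[annotations$slide_id == row$slide_id, , drop = FALSE]
    centres <- list()
    if (nrow(ann) > 0) {
      pick <- withSeed(subSeed(seed, "pos", row$slide_id),
                       sample(nrow(ann), min(per_slide, nrow(ann))))
      for (j in pick)
        centres[[length(centres) + 1]] <- list(x = ann$x_px[j], y = ann$y_px[j],
                                               label = "positive")
    }
    neg_xy <- withSeed(subSeed(seed, "neg", row$slide_id), {
      out <- NULL; tries <- 0
      while ((is.null(out) || nrow(out) < per_slide) && tries < 200) {
        tries <- tries + 1
        x <- stats::runif(1, 128, slideWidth(slide) - 128)
        y <- stats::runif(1, 128, slideHeight(slide) - 128)
        ok <- nrow(ann) == 0 ||
          min(sqrt((ann$x_px - x)^2 + (ann$y_px - y)^2)) >= neg_min_dist
        if (ok) out <- rbind(out, c(x, y))
      }
      out
    })
    for (j in seq_len(nrow(neg_xy)))
      centres[[length(centres) + 1]] <- list(x = neg_xy[j, 1], y = neg_xy[j, 2],
                                             label = "negative")
    for (ci in seq_along(centres)) {
      cc <- centres[[ci]]
      img0 <- cropAt(slide, c(cc$x, cc$y), spec@input_px)
      n_var <- if (is.null(augment)) 1L else as.integer(variants) + 1L
      for (v in seq_len(n_var)) {
        img <- if (v == 1L) img0 else
          applyAugment(img0, sampleAugmentParams(
            augment, subSeed(seed, "aug", row$slide_id, ci, v)))
        records[[length(records) + 1]] <- list(
          sample_id = sprintf("%s_c%d_v%d", row$slide_id, ci, v),
          slide_id = row$slide_id, group_id = row$style_id,
          category = if (cc$label == "positive") "lesion" else "normal",
          label = cc$label, raw = hrRawFeatures(img, spec)
        )
      }
    }
  }
  records
}

# ---------------------------------------------------------------------------
# Training
# ---------------------------------------------------------------------------

#' Mining configuration
#'
#' Defaults encode the recall/precision asymmetry of the cascade: a small
#' hard proportion (0.1) for the LR model, a large one (0.5) for the HR
#' model; `rounds = 2` adds the second-round hard-mix learning.
#' @param hard_proportion fraction of hard samples in the second round.
#' @param rounds 1 (no mining) or 2.
#' @return list.
#' @export
miningConfig <- function(hard_proportion = 0.1, rounds = 2) {
  stopifnot(hard_proportion >= 0, hard_proportion <= 1)
  list(hard_proportion = hard_proportion, rounds = rounds)
}

#' Sampling configuration
#'
#' @param quota_per_cell balanced-epoch quota per (group, category) cell;
#'   NULL sizes it from the mean cell size.
#' @return list.
#' @export
samplingConfig <- function(quota_per_cell = NULL) {
  list(quota_per_cell = quota_per_cell)
}

# Balanced-epoch + hard-mix training loop shared by both heads.
# fit: list(init(d), step(params, st, Xb, yb, lr), predict(params, X)).
trainWithStrategies <- function(X, pool, Xval, yval, fit, sampling, mining,
                                optim) {
  quota <- sampling$quota_per_cell
  if (is.null(quota)) {
    n_cells <- nrow(unique(pool[, c("group_id", "category")]))
    quota <- max(4L, as.integer(round(nrow(pool) / n_cells)))
  }
  y_all <- as.numeric(pool$label == "positive")
  params <- fit$init(ncol(X))
  st <- adamInit(params)
  log <- list(lr = numeric(0), val_loss = numeric(0), round = integer(0))
  best <- list(loss = Inf, params = params)
  epoch_pass <- function(stream_idx, lr) {
    for (b0 in seq(1, length(stream_idx), by = optim$batch)) {
      bi <- stream_idx[b0:min(length(stream_idx), b0 + optim$batch - 1)]
      up <- fit$step(params, st, X[bi, , drop = FALSE], y_all[bi], lr)
      params <<- up$params; st <<- up$state
    }
  }
  note_epoch <- function(round_id, lr) {
    vl <- bceLoss(fit$predict(params, Xval), yval)
    log$lr <<- c(log$lr, lr); log$val_loss <<- c(log$val_loss, vl)
    log$round <<- c(log$round, round_id)
    if (vl < best$loss) best <<- list(loss = vl, params = params)
  }
  for (e in seq_len(optim$epochs)) {
    lr <- optim$lr * optim$decay_factor^((e - 1) %/% optim$decay_every)
    stream <- balancedEpoch(pool, quota, seed = subSeed(optim$seed, "ep", e))
    epoch_pass(stream$idx, lr)
    note_epoch(1L, lr)
  }
  hard <- data.frame()
  if (mining$rounds >= 2) {
    pred <- ifelse(fit$predict(params, X) > 0.5, "positive", "negative")
    hard <- mineHard(data.frame(sample_id = pool$sample_id, pred_label = pred),
                     pool)
    if (nrow(hard) > 0 && mining$hard_proportion > 0) {
      epoch_size <- quota * nrow(unique(pool[, c("group_id", "category")]))
      for (e in seq_len(optim$epochs)) {
        lr <- optim$lr * optim$decay_factor^((optim$epochs + e - 1) %/%
                                               optim$decay_every)
        stream <- mixHard(pool, hard, mining$hard_proportion, epoch_size,
                          seed = subSeed(optim$seed, "mix", e))
        epoch_pass(stream$idx, lr)
        note_epoch(2L, lr)
      }
    }
  }
  list(params = best$params, final = params, log = log,
       n_hard = nrow(hard))
}

logisticFit <- function(seed) {
  list(
    init = function(d) list(w = numeric(d), b = 0),
    step = function(params, st, Xb, yb, lr) {
      p <- sigmoid(as.vector(Xb %*% params$w) + params$b)
      err <- p - yb
      g <- list(w = as.vector(crossprod(Xb, err)) / length(yb), b = mean(err))
      adamUpdate(params, g, st, lr)
    },
    predict = function(params, X) sigmoid(as.vector(X %*% params$w) + params$b)
  )
}

mlpFit <- function(hidden, seed) {
  list(
    init = function(d) withSeed(subSeed(seed, "mlpinit"), {
      list(W1 = matrix(stats::rnorm(hidden * d, sd = 1 / sqrt(d)), hidden, d),
           b1 = numeric(hidden),
           w2 = stats::rnorm(hidden, sd = 1 / sqrt(hidden)), b2 = 0)
    }),
    step = function(params, st, Xb, yb, lr) {
      A <- tanh(params$W1 %*% t(Xb) + params$b1)
      p <- sigmoid(as.vector(crossprod(A, params$w2)) + params$b2)
      dlogit <- (p - yb) / length(yb)
      dA <- outer(params$w2, dlogit) * (1 - A^2)
      g <- list(W1 = dA %*% Xb, b1 = rowSums(dA),
                w2 = as.vector(A %*% dlogit), b2 = sum(dlogit))
      adamUpdate(params, g, st, lr)
    },
    predict = function(params, X) {
      A <- tanh(params$W1 %*% t(X) + params$b1)
      sigmoid(as.vector(crossprod(A, params$w2)) + params$b2)
    }
  )
}

#' Train a cascade model
#'
#' Runs the three-strategy schedule on materialised sample records:
#' enhancement is whatever the records were materialised with; every epoch is
#' a fresh group- and category-balanced resample; with `mining$rounds >= 2`,
#' samples misclassified after round one are mixed back at the configured
#' hard proportion for a second round. The checkpoint with the lowest
#' validation loss is kept. Training slides and validation slides must not
#' overlap.
#'
#' For LR specs the tile classification head and the heatmap
#' (segmentation) head are both fitted; for HR specs a one-hidden-layer MLP
#' is fitted whose hidden activations are the candidate features.
#'
#' @param spec a [BackboneSpec-class] (desk-scale).
#' @param train_records,val_records records from [materializeLrSamples()] or
#'   [materializeHrSamples()].
#' @param sampling [samplingConfig()].
#' @param mining [miningConfig()].
#' @param optim [optimConfig()].
#' @return A trained [LesionModel-class]; `@log` records the lr schedule,
#'   per-epoch validation losses, hard-set size and validation AUC.
#' @export
trainLesionModel <- function(spec, train_records, val_records,
                             sampling = samplingConfig(),
                             mining = miningConfig(),
                             optim = optimConfig()) {
  if (spec@name != "deskblob")
    stop("only the desk-scale 'deskblob' backbone is trainable here; '",
         spec@name, "' is an architecture contract")
  if (length(train_records) == 0 || length(val_records) == 0)
    stop("train and validation pools must be non-empty")
  tr_slides <- unique(vapply(train_records, `[[`, character(1), "slide_id"))
  va_slides <- unique(vapply(val_records, `[[`, character(1), "slide_id"))
  if (length(intersect(tr_slides, va_slides)) > 0)
    stop("validation slides overlap training slides: ",
         paste(intersect(tr_slides, va_slides), collapse = ", "))
  model <- lesionModel(spec)
  pool <- recordsPool(train_records)
  if (model@kind == "lr") {
    X <- do.call(rbind, lapply(train_records, `[[`, "fvec"))
    Xval <- do.call(rbind, lapply(val_records, `[[`, "fvec"))
    yval <- as.numeric(vapply(val_records, `[[`, character(1), "label") ==
                         "positive")
    norm_cls <- standardizer(X)
    res <- trainWithStrategies(applyStandardizer(X, norm_cls), pool,
                               applyStandardizer(Xval, norm_cls), yval,
                               logisticFit(optim$seed), sampling, mining, optim)
    # heatmap head: per-cell logistic with class weighting
    cellX <- do.call(rbind, lapply(train_records, `[[`, "cellX"))
    celly <- unlist(lapply(train_records, `[[`, "cellY"))
    norm_seg <- standardizer(cellX)
    wpos <- max(1, sum(celly == 0) / max(1, sum(celly == 1)))
    seg <- adamLogistic(applyStandardizer(cellX, norm_seg), celly,
                        optimConfig(lr = optim$lr, epochs = optim$epochs,
                                    batch = 32, decay_every = optim$decay_every,
                                    decay_factor = optim$decay_factor,
                                    seed = subSeed(optim$seed, "seg")),
                        class_weights = c(1, wpos))
    val_auc <- aucFromScores(logisticFit(optim$seed)$predict(
      res$params, applyStandardizer(Xval, norm_cls)), yval)
    model@weights <- list(cls = res$params, seg = list(w = seg$w, b = seg$b))
    model@norm <- list(cls = norm_cls, seg = norm_seg)
    model@log <- c(res$log, list(n_hard = res$n_hard, val_auc = val_auc,
                                 seed = optim$seed))
  } else {
    X <- do.call(rbind, lapply(train_records, `[[`, "raw"))
    Xval <- do.call(rbind, lapply(val_records, `[[`, "raw"))
    yval <- as.numeric(vapply(val_records, `[[`, character(1), "label") ==
                         "positive")
    norm <- standardizer(X)
    res <- trainWithStrategies(applyStandardizer(X, norm), pool,
                               applyStandardizer(Xval, norm), yval,
                               mlpFit(spec@feature_dim, optim$seed),
                               sampling, mining, optim)
    val_auc <- aucFromScores(mlpFit(spec@feature_dim, optim$seed)$predict(
      res$params, applyStandardizer(Xval, norm)), yval)
    model@weights <- res$params
    model@norm <- list(raw = norm)
    model@log <- c(res$log, list(n_hard = res$n_hard, val_auc = val_auc,
                                 seed = optim$seed))
  }
  model@trained <- TRUE
  model
}

# rank-based AUC used in training logs (the evaluation module's rocAuc is
# the user-facing metric; this avoids constructing curve points per epoch)
aucFromScores <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
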