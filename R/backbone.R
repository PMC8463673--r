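# Desk-scale backbone: a fixed multi-scale blob-response filter bank over the
# HSV value/saturation channels, computed at a reduced working resolution,
# feeding trainable heads. Dark nuclei appear as peaks of the darkness
# channel and of difference-of-Gaussian responses at the matching scale;
# the heads learn which scales and statistics separate lesion from normal.
# The full-scale ResNet50 two-head contract is retained as a named spec.

#' Desk-scale LR backbone spec
#'
#' 512 px input at 0.486 um/px with a heatmap branch at 1/8 input resolution
#' (the registration factor). `feature_dim` is the length of the tile-level
#' descriptor consumed by the classification head.
#' @param heat_stride input pixels per heatmap cell.
#' @return A [BackboneSpec-class].
#' @export
deskLrSpec <- function(heat_stride = 8L) {
  new("BackboneSpec", name = "deskblob", input_px = 512L, input_mpp = LR_MPP,
      feature_dim = 24L, seg_branch = TRUE, seg_dilations = numeric(0),
      heat_stride = as.integer(heat_stride), work_scale = 2L,
      sigmas = c(2, 4, 8))
}

#' Desk-scale HR backbone spec
#'
#' 256 px input at 0.243 um/px; `feature_dim` is the width F of the
#' penultimate (hidden) layer whose activations are the candidate features.
#' @param feature_dim penultimate feature dimension (64 desk scale).
#' @return A [BackboneSpec-class].
#' @export
deskHrSpec <- function(feature_dim = 64L) {
  new("BackboneSpec", name = "deskblob", input_px = 256L, input_mpp = REF_MPP,
      feature_dim = as.integer(feature_dim), seg_branch = FALSE,
      seg_dilations = numeric(0), heat_stride = 0L, work_scale = 2L,
      sigmas = c(2, 4, 8))
}

#' Full-scale architecture contracts
#'
#' The named ResNet50 specifications used at clinical scale: modified fully
#' connected layer, 2,048-dim penultimate features, and (for LR) a
#' segmentation branch of dilated-convolution residual blocks. Retained as
#' architecture contracts; desk-scale training uses [deskLrSpec()] /
#' [deskHrSpec()].
#' @return A [BackboneSpec-class].
#' @export
resnet50LrSpec <- function() {
  new("BackboneSpec", name = "resnet50", input_px = 512L, input_mpp = LR_MPP,
      feature_dim = 2048L, seg_branch = TRUE, seg_dilations = c(2, 4, 8),
      heat_stride = 8L, work_scale = 1L, sigmas = numeric(0))
}

#' @rdname resnet50LrSpec
#' @export
resnet50HrSpec <- function() {
  new("BackboneSpec", name = "resnet50", input_px = 256L, input_mpp = REF_MPP,
      feature_dim = 2048L, seg_branch = FALSE, seg_dilations = numeric(0),
      heat_stride = 0L, work_scale = 1L, sigmas = numeric(0))
}

N_MAPS <- 4L  # darkness, fine DoG, coarse DoG, saturation

# Multi-scale response maps at working resolution. Input: RGB array at the
# spec's input size. Returns h x w x 4 array (working resolution).
blobMaps <- function(img, spec) {
  work <- spec@input_px %/% spec@work_scale
  img <- resizeRgb(img, work, work)
  d <- 1 - valueChannel(img)          # darkness: nuclei are high
  s <- saturationChannel(img)
  g1 <- gaussBlurMat(d, spec@sigmas[1])
  g2 <- gaussBlurMat(d, spec@sigmas[2])
  g3 <- gaussBlurMat(d, spec@sigmas[3])
  out <- array(0, c(work, work, N_MAPS))
  out[, , 1] <- g1            # smoothed darkness
  out[, , 2] <- g1 - g2       # fine blob response (normal-nucleus scale)
  out[, , 3] <- g2 - g3       # coarse blob response (lesion-nucleus scale)
  out[, , 4] <- gaussBlurMat(s, spec@sigmas[2])
  out
}

# Per-heatmap-cell pooled features: mean and max of each map over
# (heat_stride / work_scale)-sized blocks. Returns list(ncy, ncx,
# X = ncell x 2*N_MAPS matrix in cell-row-major order (y fastest)).
cellFeatures <- function(maps, spec) {
  bs <- spec@heat_stride %/% spec@work_scale
  ncy <- dim(maps)[1] %/% bs
  ncx <- dim(maps)[2] %/% bs
  X <- matrix(0, ncy * ncx, 2L * N_MAPS)
  for (m in seq_len(N_MAPS)) {
    p <- poolBlocks(maps[, , m], bs)
    X[, 2L * m - 1L] <- as.vector(p$mean)
    X[, 2L * m] <- as.vector(p$max)
  }
  list(ncy = ncy, ncx = ncx, X = X)
}

# Tile-level descriptor from the per-cell feature matrix: per-column mean,
# max and mean of the top 5% cells.
tileFeatureVector <- function(cellX) {
  n <- nrow(cellX)
  k <- max(1L, ceiling(0.05 * n))
  top <- apply(cellX, 2, function(col) mean(sort(col, decreasing = TRUE)[1:k]))
  c(colMeans(cellX), apply(cellX, 2, max), top)
}

# HR raw descriptor: centre-disk / annulus / whole-crop statistics of each
# map plus value-channel context. The candidate cell sits at the crop centre.
hrRawFeatures <- function(img, spec) {
  work <- spec@input_px %/% spec@work_scale
  maps <- blobMaps(img, spec)
  v <- 1 - resizeMat(valueChannel(img), work, work)
  cx <- (work - 1) / 2
  dx <- matrix(0:(work - 1), work, work, byrow = TRUE) - cx
  dy <- matrix(0:(work - 1), work, work) - cx
  r <- sqrt(dx^2 + dy^2)
  centre <- r <= work / 6          # ~21 px at work 128: nucleus region
  annulus <- r > work / 6 & r <= work / 3
  f <- numeric(0)
  for (m in seq_len(N_MAPS)) {
    mm <- maps[, , m]
    f <- c(f, mean(mm[centre]), max(mm[centre]), mean(mm[annulus]),
           mean(mm), max(mm))
  }
  c(f, mean(v[centre]), mean(v))
}

HR_RAW_DIM <- 5L * N_MAPS + 2L

# ---------------------------------------------------------------------------
# Adam optimiser over named parameter lists
# ---------------------------------------------------------------------------

adamInit <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adamUpdate <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(params)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

#' Optimiser configuration
#'
#' Adam with initial learning rate 1e-3 and step decay. Defaults:
#' `decay_factor` 0.5 every `decay_every` 20 epochs, minibatch 8.
#' @param lr initial learning rate.
#' @param epochs training epochs.
#' @param batch minibatch size.
#' @param decay_every epochs between learning-rate decays.
#' @param decay_factor multiplicative decay.
#' @param seed training seed.
#' @return list of optimiser settings.
#' @export
optimConfig <- function(lr = 1e-3, epochs = 60, batch = 8, decay_every = 20,
                        decay_factor = 0.5, seed = 1) {
  list(lr = lr, epochs = epochs, batch = batch, decay_every = decay_every,
       decay_factor = decay_factor, seed = seed)
}

bceLoss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Logistic regression fitted with Adam + BCE. X: n x d (already
# standardised), y in {0,1}. Optionally warm-started from `init`.
adamLogistic <- function(X, y, optim, init = NULL, class_weights = NULL) {
  d <- ncol(X)
  params <- if (is.null(init)) list(w = numeric(d), b = 0) else init
  st <- adamInit(params)
  n <- nrow(X)
  if (is.null(class_weights)) cw <- rep(1, n) else
    cw <- ifelse(y > 0.5, class_weights[2], class_weights[1])
  trace <- numeric(optim$epochs)
  withSeed(optim$seed, {
    for (e in seq_len(optim$epochs)) {
      lr <- optim$lr * optim$decay_factor^((e - 1) %/% optim$decay_every)
      idx <- sample(n)
      for (b0 in seq(1, n, by = optim$batch)) {
        bi <- idx[b0:min(n, b0 + optim$batch - 1)]
        Xb <- X[bi, , drop = FALSE]
        p <- sigmoid(as.vector(Xb %*% params$w) + params$b)
        err <- (p - y[bi]) * cw[bi]
        g <- list(w = as.vector(crossprod(Xb, err)) / length(bi),
                  b = mean(err))
        up <- adamUpdate(params, g, st, lr)
        params <- up$params; st <- up$state
      }
      p_all <- sigmoid(as.vector(X %*% params$w) + params$b)
      trace[e] <- bceLoss(p_all, y)
    }
  })
  list(w = params$w, b = params$b, loss = trace)
}

# One-hidden-layer MLP (tanh) with sigmoid output, fitted with Adam + BCE.
# The hidden activations are the model's penultimate features.
adamMlp <- function(X, y, hidden, optim, init = NULL) {
  d <- ncol(X)
  params <- if (!is.null(init)) init else withSeed(subSeed(optim$seed, "init"), {
    list(W1 = matrix(stats::rnorm(hidden * d, sd = 1 / sqrt(d)), hidden, d),
         b1 = numeric(hidden),
         w2 = stats::rnorm(hidden, sd = 1 / sqrt(hidden)),
         b2 = 0)
  })
  st <- adamInit(params)
  n <- nrow(X)
  trace <- numeric(optim$epochs)
  withSeed(optim$seed, {
    for (e in seq_len(optim$epochs)) {
      lr <- optim$lr * optim$decay_factor^((e - 1) %/% optim$decay_every)
      idx <- sample(n)
      for (b0 in seq(1, n, by = optim$batch)) {
        bi <- idx[b0:min(n, b0 + optim$batch - 1)]
        Xb <- X[bi, , drop = FALSE]
        A <- tanh(params$W1 %*% t(Xb) + params$b1)   # hidden x nb
        p <- sigmoid(as.vector(crossprod(A, params$w2)) + params$b2)
        dlogit <- (p - y[bi]) / length(bi)
        dA <- outer(params$w2, dlogit) * (1 - A^2)
        g <- list(W1 = dA %*% Xb, b1 = rowSums(dA),
                  w2 = as.vector(A %*% dlogit), b2 = sum(dlogit))
        up <- adamUpdate(params, g, st, lr)
        params <- up$params; st <- up$state
      }
      A <- tanh(params$W1 %*% t(X) + params$b1)
      p_all <- sigmoid(as.vector(crossprod(A, params$w2)) + params$b2)
      trace[e] <- bceLoss(p_all, y)
    }
  })
  c(params, list(loss = trace))
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-8] <- 1
  list(centre = mu, scale = sd)
}

applyStandardizer <- function(X, norm) {
  sweep(sweep(X, 2, norm$centre), 2, norm$scale, "/")
}
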