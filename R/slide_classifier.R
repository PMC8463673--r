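# Slide classification: the rank-ordered top-k HR feature sequences are read
# by single-hidden-layer recurrent networks (rank 1 fed first; vanilla tanh
# cell); six members (two per k in {10, 20, 30}, differing by seed) are
# averaged into one slide positivity score, thresholded at 0.5 (strict >).
#
# Each member reads its positivity from the time-averaged hidden state
# rather than the final one: padded sequences end in long runs of identical
# pad inputs, and a final-state readout is bistable there (the state falls
# into one of two attractors, flipping the output), whereas the mean
# accumulates the evidence of each real candidate row.

#' Forward pass of one recurrent member
#'
#' @param seq numeric k x F matrix, rank 1 first (pad rows allowed).
#' @param model a trained [RnnModel-class].
#' @return positivity probability in \[0, 1\]; deterministic.
#' @export
rnnForward <- function(seq, model) {
  seq <- as.matrix(seq)
  if (nrow(seq) != model@k || ncol(seq) != model@input_dim)
    stop("sequence shape ", nrow(seq), "x", ncol(seq), " does not match model (",
         model@k, "x", model@input_dim, ")")
  X <- applyStandardizer(seq, model@norm)
  w <- model@weights
  h <- numeric(model@hidden_units)
  hbar <- numeric(model@hidden_units)
  for (t in seq_len(model@k)) {
    h <- tanh(as.vector(w$Wxh %*% X[t, ]) + as.vector(w$Whh %*% h) + w$bh)
    hbar <- hbar + h
  }
  sigmoid(sum(w$wo * hbar / model@k) + w$bo)
}

rnnInitWeights <- function(input_dim, hidden, seed) {
  withSeed(seed, {
    list(Wxh = matrix(stats::rnorm(hidden * input_dim, sd = 1 / sqrt(input_dim)),
                      hidden, input_dim),
         Whh = matrix(stats::rnorm(hidden * hidden, sd = 0.5 / sqrt(hidden)),
                      hidden, hidden),
         bh = numeric(hidden),
         wo = stats::rnorm(hidden, sd = 1 / sqrt(hidden)),
         bo = 0)
  })
}

# full BPTT gradient for one sequence (X already standardised); output read
# from the time-averaged hidden state
rnnGrad <- function(w, X, y) {
  k <- nrow(X); H <- length(w$bh)
  hs <- matrix(0, H, k + 1)
  for (t in seq_len(k))
    hs[, t + 1] <- tanh(as.vector(w$Wxh %*% X[t, ]) +
                          as.vector(w$Whh %*% hs[, t]) + w$bh)
  hbar <- rowMeans(hs[, -1, drop = FALSE])
  p <- sigmoid(sum(w$wo * hbar) + w$bo)
  dlogit <- p - y
  g <- list(Wxh = w$Wxh * 0, Whh = w$Whh * 0, bh = numeric(H),
            wo = dlogit * hbar, bo = dlogit)
  dh <- numeric(H)
  for (t in k:1) {
    da <- (dh + dlogit * w$wo / k) * (1 - hs[, t + 1]^2)
    g$Wxh <- g$Wxh + outer(da, X[t, ])
    g$Whh <- g$Whh + outer(da, hs[, t])
    g$bh <- g$bh + da
    dh <- as.vector(crossprod(w$Whh, da))
  }
  list(g = g, p = p)
}

# global gradient-norm clipping: BPTT over 20-30 steps explodes for some
# initialisations without it
clipGrads <- function(g, max_norm = 5) {
  nrm <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
  if (nrm > max_norm) g <- lapply(g, function(x) x * max_norm / nrm)
  g
}

rnnPredictAll <- function(w, norm, feats, k) {
  vapply(feats, function(f) {
    X <- applyStandardizer(f[seq_len(k), , drop = FALSE], norm)
    H <- length(w$bh)
    h <- numeric(H); hbar <- numeric(H)
    for (t in seq_len(k)) {
      h <- tanh(as.vector(w$Wxh %*% X[t, ]) + as.vector(w$Whh %*% h) + w$bh)
      hbar <- hbar + h
    }
    sigmoid(sum(w$wo * hbar / k) + w$bo)
  }, numeric(1))
}

#' Train one recurrent member
#'
#' Adam (initial lr 1e-3, step decay), one sequence per update, full
#' backpropagation through time. Sequence augmentation: with
#' `rearrange = TRUE` the rank order of each training sequence is randomly
#' permuted per epoch; `jitter_sd > 0` adds multiplicative feature jitter
#' emulating photometric variation at the feature level. The checkpoint with
#' the lowest validation loss is kept.
#'
#' @param feats list of feature matrices (>= k rows each, rank-ordered).
#' @param labels "positive"/"negative" per sequence.
#' @param val_feats,val_labels validation sequences (no slide overlap with
#'   training; enforced by [trainRnnEnsemble()]).
#' @param k sequence length read by this member.
#' @param hidden hidden units (512 full scale; 64 desk default).
#' @param seed member seed (replicas differ only by this).
#' @param augment list(rearrange, jitter_sd).
#' @param optim [optimConfig()].
#' @return A trained [RnnModel-class].
#' @export
trainRnn <- function(feats, labels, val_feats, val_labels, k = 10, hidden = 64,
                     seed = 1, augment = list(rearrange = TRUE, jitter_sd = 0.05),
                     optim = optimConfig(epochs = 80)) {
  F_dim <- ncol(feats[[1]])
  y <- as.numeric(labels == "positive")
  yval <- as.numeric(val_labels == "positive")
  # standardise over real (non-pad) rows of the training sequences
  allrows <- do.call(rbind, lapply(feats, function(f) f[seq_len(k), , drop = FALSE]))
  real <- rowSums(abs(allrows)) > 0
  norm <- standardizer(allrows[real, , drop = FALSE])
  w <- rnnInitWeights(F_dim, hidden, subSeed(seed, "init"))
  st <- adamInit(w)
  best <- list(loss = Inf, w = w)
  n <- length(feats)
  withSeed(subSeed(seed, "train"), {
    for (e in seq_len(optim$epochs)) {
      lr <- optim$lr * optim$decay_factor^((e - 1) %/% optim$decay_every)
      for (i in sample(n)) {
        Xf <- feats[[i]][seq_len(k), , drop = FALSE]
        if (isTRUE(augment$rearrange)) Xf <- Xf[sample(k), , drop = FALSE]
        if (!is.null(augment$jitter_sd) && augment$jitter_sd > 0)
          Xf <- Xf * (1 + matrix(stats::rnorm(length(Xf), sd = augment$jitter_sd),
                                 nrow(Xf)))
        X <- applyStandardizer(Xf, norm)
        gr <- rnnGrad(w, X, y[i])
        up <- adamUpdate(w, clipGrads(gr$g), st, lr)
        w <- up$params; st <- up$state
      }
      vp <- rnnPredictAll(w, norm, val_feats, k)
      vl <- bceLoss(vp, yval)
      if (vl < best$loss) best <- list(loss = vl, w = w)
    }
  })
  new("RnnModel", input_dim = as.integer(F_dim), hidden_units = as.integer(hidden),
      k = as.integer(k), weights = best$w, norm = norm, seed = as.integer(seed))
}

#' Train the six-member recurrent ensemble
#'
#' Two members per k in `ks` (default {10, 20, 30}), trained on identical
#' folds with different seeds. Sequences must have at least `max(ks)` rows
#' (use `topK(cs, max(ks))` with padding).
#'
#' @param feats,labels,slide_ids training sequences, labels and slide tokens.
#' @param val_feats,val_labels,val_slide_ids validation fold (slide-wise
#'   disjoint from training; checked).
#' @param ks sequence lengths.
#' @param replicas_per_kind members per k.
#' @param hidden hidden units per member.
#' @param augment sequence augmentation, see [trainRnn()].
#' @param optim [optimConfig()].
#' @param seed ensemble seed.
#' @return A trained [RnnEnsemble-class].
#' @export
trainRnnEnsemble <- function(feats, labels, val_feats, val_labels,
                             slide_ids = NULL, val_slide_ids = NULL,
                             ks = c(10, 20, 30), replicas_per_kind = 2,
                             hidden = 64,
                             augment = list(rearrange = TRUE, jitter_sd = 0.05),
                             optim = optimConfig(epochs = 80), seed = 1) {
  if (!is.null(slide_ids) && !is.null(val_slide_ids) &&
      length(intersect(slide_ids, val_slide_ids)) > 0)
    stop("validation slides overlap training slides")
  if (length(unique(labels)) < 2)
    stop("RNN training needs both positive and negative slides")
  if (min(vapply(feats, nrow, integer(1))) < max(ks))
    stop("sequences must have at least max(ks) = ", max(ks), " rows")
  members <- list(); mks <- integer(0)
  for (k in ks) {
    for (r in seq_len(replicas_per_kind)) {
      members[[length(members) + 1]] <-
        trainRnn(feats, labels, val_feats, val_labels, k = k, hidden = hidden,
                 seed = subSeed(seed, "member", k, r), augment = augment,
                 optim = optim)
      mks <- c(mks, k)
    }
  }
  new("RnnEnsemble", members = members, ks = as.integer(mks))
}

#' Ensemble slide score
#'
#' Feeds each member its top-k sequence (the first k rows of the rank-ordered
#' feature matrix) and averages the member probabilities.
#'
#' @param feats rank-ordered feature matrix with at least `max(ks)` rows
#'   (padded), e.g. `topKFeatures(topK(cs, 30))`.
#' @param ensemble a trained [RnnEnsemble-class].
#' @return list: `score` (mean probability), `members` (per-member scores).
#' @export
ensembleScore <- function(feats, ensemble) {
  if (length(ensemble@members) == 0) stop("ensemble has no members")
  if (nrow(feats) < max(ensemble@ks))
    stop("feature matrix has ", nrow(feats), " rows; ensemble needs ",
         max(ensemble@ks))
  ms <- vapply(ensemble@members, function(m)
    rnnForward(feats[seq_len(m@k), , drop = FALSE], m), numeric(1))
  list(score = mean(ms), members = ms)
}

#' Classify a slide score
#'
#' Positive iff the score strictly exceeds the threshold (a score exactly at
#' the threshold is negative).
#'
#' @param score slide score in \[0, 1\].
#' @param threshold decision threshold (default 0.5).
#' @return `"positive"` or `"negative"`.
#' @export
classifySlide <- function(score, threshold = 0.5) {
  if (score < 0 || score > 1) stop("score must lie in [0, 1]")
  if (score > threshold) "positive" else "negative"
}
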