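# small synthetic feature-sequence task: positive slides have a few rows
# drawn from a shifted distribution (strong candidates), negatives only
# noise/pad rows -- the same structure the HR stage hands the ensemble.
mkSequences <- function(n, k, F, seed) {
  set.seed(seed)
  feats <- list(); labels <- character(n)
  for (i in seq_len(n)) {
    pos <- i <= n / 2
    m <- matrix(rnorm(k * F, sd = 0.3), k, F)
    if (pos) {
      n_strong <- sample(2:6, 1)
      m[seq_len(n_strong), ] <- m[seq_len(n_strong), , drop = FALSE] + 1.5
    }
    feats[[i]] <- m
    labels[i] <- if (pos) "positive" else "negative"
  }
  list(feats = feats, labels = labels)
}

trainedToyEnsemble <- function() {
  if (!is.null(.fixtures$toy_ens)) return(.fixtures$toy_ens)
  tr <- mkSequences(40, 30, 8, 1)
  va <- mkSequences(12, 30, 8, 2)
  .fixtures$toy_ens <- list(
    ens = trainRnnEnsemble(tr$feats, tr$labels, va$feats, va$labels,
                           hidden = 16, optim = optimConfig(epochs = 30),
                           seed = 5),
    tr = tr,
    te = mkSequences(20, 30, 8, 3))
  .fixtures$toy_ens
}

test_that("the recurrent forward pass is bounded, total and deterministic", {
  fix <- trainedToyEnsemble()
  m <- fix$ens@members[[1]]
  seqs <- fix$te$feats[[1]][seq_len(m@k), ]
  p <- rnnForward(seqs, m)
  expect_gte(p, 0); expect_lte(p, 1)
  expect_identical(rnnForward(seqs, m), p)
  # all-pad sequence (negative slide with zero candidates) is defined
  expect_silent(rnnForward(matrix(0, m@k, m@input_dim), m))
  expect_error(rnnForward(seqs[1:3, ], m), "does not match")
})

test_that("the ensemble is the member mean and learns the toy task", {
  fix <- trainedToyEnsemble()
  expect_length(fix$ens@members, 6)
  expect_equal(sort(unique(fix$ens@ks)), c(10, 20, 30))
  es <- ensembleScore(fix$te$feats[[1]], fix$ens)
  expect_equal(es$score, mean(es$members))
  expect_gte(es$score, min(es$members)); expect_lte(es$score, max(es$members))
  scores <- vapply(fix$te$feats, function(f) ensembleScore(f, fix$ens)$score,
                   numeric(1))
  co <- data.frame(score = scores, label = fix$te$labels)
  expect_gte(rocAuc(co)$auc, 0.9)
  expect_error(ensembleScore(fix$te$feats[[1]][1:5, ],
                             fix$ens), "needs")
})

test_that("replicas with different seeds learn different parameters", {
  fix <- trainedToyEnsemble()
  w1 <- fix$ens@members[[1]]@weights$Wxh
  w2 <- fix$ens@members[[2]]@weights$Wxh
  expect_gt(max(abs(w1 - w2)), 1e-3)
  # same k read by both
  expect_equal(fix$ens@ks[1], fix$ens@ks[2])
})

test_that("rearrangement training confers permutation robustness", {
  fix <- trainedToyEnsemble()
  m <- fix$ens@members[[1]]
  set.seed(42)
  deltas <- vapply(fix$te$feats[1:10], function(f) {
    x <- f[seq_len(m@k), ]
    abs(rnnForward(x, m) - rnnForward(x[sample(m@k), ], m))
  }, numeric(1))
  expect_lt(mean(deltas), 0.1)
})

test_that("training is reproducible under a fixed seed", {
  tr <- mkSequences(16, 12, 6, 7)
  va <- mkSequences(8, 12, 6, 8)
  fit <- function() trainRnn(tr$feats, tr$labels, va$feats, va$labels,
                             k = 10, hidden = 8, seed = 33,
                             augment = list(rearrange = FALSE, jitter_sd = 0),
                             optim = optimConfig(epochs = 10))
  m1 <- fit(); m2 <- fit()
  expect_identical(m1@weights, m2@weights)
})

test_that("slide classification uses a strict threshold", {
  expect_equal(classifySlide(0.5, 0.5), "negative")
  expect_equal(classifySlide(0.51, 0.5), "positive")
  expect_equal(classifySlide(0, 0.5), "negative")
  expect_error(classifySlide(1.2), "lie in")
  # closure with specificity-at-full-sensitivity: its threshold keeps
  # sensitivity 1.0 by construction
  set.seed(9)
  co <- data.frame(score = runif(60), label = sample(c("positive", "negative"),
                                                     60, TRUE))
  thr <- specAtFullSens(co)$threshold
  pred <- vapply(co$score, classifySlide, character(1), threshold = thr)
  expect_true(all(pred[co$label == "positive"] == "positive"))
})

test_that("leakage and class guards refuse degenerate ensembles", {
  tr <- mkSequences(8, 30, 4, 1)
  expect_error(trainRnnEnsemble(tr$feats, tr$labels, tr$feats, tr$labels,
                                slide_ids = paste0("s", 1:8),
                                val_slide_ids = paste0("s", 1:8)),
               "overlap")
  expect_error(trainRnnEnsemble(tr$feats, rep("positive", 8), tr$feats,
                                rep("positive", 8)),
               "both positive and negative")
})
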