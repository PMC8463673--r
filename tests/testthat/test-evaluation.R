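concordanceAuc <- function(cohort) {
  pos <- cohort$score[cohort$label == "positive"]
  neg <- cohort$score[cohort$label == "negative"]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

test_that("trapezoidal AUC equals the concordance statistic", {
  # worked example: 3 concordant pairs of 4, no ties
  co <- data.frame(score = c(0.9, 0.6, 0.7, 0.1),
                   label = c("positive", "positive", "negative", "negative"))
  expect_equal(concordanceAuc(co), 0.75)
  expect_equal(rocAuc(co)$auc, 0.75, tolerance = 1e-12)
  # degenerate cohorts
  sep <- data.frame(score = c(0.8, 0.9, 0.1, 0.2),
                    label = rep(c("positive", "negative"), each = 2))
  expect_equal(rocAuc(sep)$auc, 1.0)
  ties <- data.frame(score = rep(0.5, 6),
                     label = rep(c("positive", "negative"), 3))
  expect_equal(rocAuc(ties)$auc, 0.5)
  expect_error(rocAuc(data.frame(score = 0.5, label = "positive")),
               "each label")
  # random cohorts with heavy ties, n up to 500
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(c(20, 100, 500), 1)
    co <- data.frame(score = round(runif(n), sample(c(1, 2), 1)),
                     label = sample(c("positive", "negative"), n, TRUE,
                                    prob = c(0.4, 0.6)))
    if (length(unique(co$label)) < 2) next
    expect_equal(rocAuc(co)$auc, concordanceAuc(co), tolerance = 1e-9)
    # curve is monotone
    cv <- rocAuc(co)$curve
    expect_true(all(diff(cv$fpr) >= 0))
    expect_true(all(diff(cv$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  co <- data.frame(score = runif(200),
                   label = sample(c("positive", "negative"), 200, TRUE))
  ref <- as.numeric(pROC::auc(pROC::roc(co$label == "positive", co$score,
                                        quiet = TRUE, direction = "<")))
  expect_equal(rocAuc(co)$auc, ref, tolerance = 1e-9)
})

test_that("sensitivity/specificity match brute-force confusion counts", {
  co <- data.frame(score = c(0, 0.2, 0.4, 0.5, 0.5, 0.6, 0.8, 0.9, 1, 0.3),
                   label = c("negative", "negative", "positive", "positive",
                             "negative", "positive", "positive", "negative",
                             "positive", "negative"))
  brute <- function(thr) {
    tp <- sum(co$score > thr & co$label == "positive")
    fn <- sum(co$score <= thr & co$label == "positive")
    tn <- sum(co$score <= thr & co$label == "negative")
    fp <- sum(co$score > thr & co$label == "negative")
    c(tp / (tp + fn), tn / (tn + fp))
  }
  for (thr in c(0, 0.25, 0.5, 0.75, 1)) {
    got <- sensSpec(co, thr)
    expect_equal(c(got$sensitivity, got$specificity), brute(thr))
  }
  # boundary rules: strict >
  expect_equal(sensSpec(co, 1)$sensitivity, 0)
  expect_equal(sensSpec(co, 1)$specificity, 1)
  expect_equal(sensSpec(co, 0)$sensitivity, mean(co$score[co$label == "positive"] > 0))
  # monotone in threshold
  ths <- seq(0, 1, by = 0.05)
  sens <- vapply(ths, function(t) sensSpec(co, t)$sensitivity, numeric(1))
  spec <- vapply(ths, function(t) sensSpec(co, t)$specificity, numeric(1))
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("specificity at full sensitivity matches an exhaustive sweep", {
  sweep_oracle <- function(co) {
    cands <- sort(unique(c(-1e-9, co$score, co$score - 1e-9)))
    best <- c(threshold = -1, specificity = -1)
    for (t in cands) {
      s <- sensSpec(co, t)
      if (s$sensitivity == 1 && s$specificity >= best["specificity"]) {
        best <- c(threshold = t, specificity = s$specificity)
      }
    }
    best
  }
  # positives all above all negatives
  co <- data.frame(score = c(0.9, 0.8, 0.3, 0.2),
                   label = rep(c("positive", "negative"), each = 2))
  expect_equal(specAtFullSens(co)$specificity, 1)
  # a negative above the minimum positive costs specificity
  co2 <- data.frame(score = c(0.9, 0.4, 0.6, 0.1),
                    label = rep(c("positive", "negative"), each = 2))
  expect_equal(specAtFullSens(co2)$specificity, 0.5)
  for (seed in 1:5) {
    set.seed(seed)
    co3 <- data.frame(score = round(runif(100), 2),
                      label = sample(c("positive", "negative"), 100, TRUE))
    got <- specAtFullSens(co3)
    expect_equal(got$specificity, unname(sweep_oracle(co3)["specificity"]),
                 tolerance = 1e-12)
    # closure: the returned threshold reproduces sensitivity 1.0
    expect_equal(sensSpec(co3, got$threshold)$sensitivity, 1.0)
  }
})

test_that("top-k TPR performs greedy rank-ordered one-to-one matching", {
  mkTopk <- function(coords, k) {
    n <- nrow(coords)
    cs <- candidateSet("s1", coords, rep(0.5, n), seq(0.9, 0.5, length.out = n),
                       matrix(0, n, 4))
    topK(cs, k)
  }
  truth <- data.frame(slide_id = "s1",
                      x_px = c(100, 300, 500, 700, 900, 1100),
                      y_px = rep(100, 6))
  # all recommendations on planted centres
  tk <- mkTopk(cbind(truth$x_px[1:5], truth$y_px[1:5]), 5)
  r <- topkTpr(list(s1 = tk), truth, match_radius_um = 15)
  expect_equal(r$mean_tpr, 1.0)
  expect_true(r$min_hit)
  # zero candidates: all pads
  empty <- topK(candidateSet("s1", matrix(numeric(0), ncol = 2), numeric(0),
                             numeric(0), matrix(numeric(0), ncol = 4)), 10)
  r0 <- topkTpr(list(s1 = empty), truth)
  expect_equal(r0$mean_tpr, 0)
  expect_false(r0$min_hit)
  # constructed geometry: two recs chase one truth point; one-to-one matching
  # lets only the higher-ranked one count. radius 15 um ~ 61.7 px.
  recs <- rbind(c(110, 100),   # rank 1: matches truth 1
                c(120, 100),   # rank 2: truth 1 taken, truth 2 too far
                c(305, 95),    # rank 3: matches truth 2
                c(2000, 2000)) # rank 4: no match
  r2 <- topkTpr(list(s1 = mkTopk(recs, 4)), truth)
  expect_equal(r2$per_slide$hits, 2L)
  expect_equal(r2$per_slide$tpr, 0.5)
  # invariant to truth permutation and frame translation
  perm <- truth[sample(nrow(truth)), ]
  expect_equal(topkTpr(list(s1 = mkTopk(recs, 4)), perm)$per_slide$hits, 2L)
  shift <- truth; shift$x_px <- shift$x_px + 50; shift$y_px <- shift$y_px - 20
  recs_s <- cbind(recs[, 1] + 50, recs[, 2] - 20)
  expect_equal(topkTpr(list(s1 = mkTopk(recs_s, 4)), shift)$per_slide$hits, 2L)
  # negative slide (no truth) is an error
  expect_error(topkTpr(list(s2 = mkTopk(recs, 4)), truth), "positive slides")
})

test_that("score histograms follow the 0.05 binning with a closed last bin", {
  h <- scoreHistogram(rep(0, 7))
  expect_equal(nrow(h), 20)
  expect_equal(h$count[1], 7)
  h1 <- scoreHistogram(c(1, 1))
  expect_equal(h1$count[20], 2)
  grid <- scoreHistogram(seq(0.025, 0.975, by = 0.05))
  expect_true(all(grid$count == 1))
  co <- data.frame(score = runif(57), label = "negative")
  expect_equal(sum(scoreHistogram(co)$count), 57)
  expect_error(scoreHistogram(c(-0.1, 0.5)), "lie in")
})
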