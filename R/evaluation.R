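# Screening metrics: ROC/AUC, sensitivity/specificity at a threshold,
# specificity at 100% sensitivity, slide-score histograms, and the top-k
# true positive rate of recommended cells against point ground truth.
#
# A scored cohort is a data.frame with columns `score` (in [0,1]) and
# `label` ("positive"/"negative"); `slide_id` is carried when present.

assertCohort <- function(cohort, need_both = TRUE) {
  if (!is.data.frame(cohort) || !all(c("score", "label") %in% names(cohort)))
    stop("cohort must be a data.frame with columns score and label")
  if (any(cohort$score < 0 | cohort$score > 1))
    stop("scores must lie in [0, 1]")
  if (need_both && length(unique(cohort$label)) < 2)
    stop("ROC needs at least one slide of each label")
  invisible(cohort)
}

#' ROC curve and AUC
#'
#' The curve sweeps every distinct score as a strict-greater threshold; the
#' AUC is the trapezoidal integral, which equals the pairwise concordance
#' statistic (ties counted 1/2).
#'
#' @param cohort scored cohort data.frame.
#' @return list: `curve` (data.frame `threshold, fpr, tpr`, monotone) and
#'   `auc`.
#' @examples
#' co <- data.frame(score = c(0.9, 0.6, 0.7, 0.1),
#'                  label = c("positive", "positive", "negative", "negative"))
#' rocAuc(co)$auc  # 0.75: three of four pos/neg pairs are concordant
#' @export
rocAuc <- function(cohort) {
  assertCohort(cohort)
  y <- cohort$label == "positive"
  thr <- c(Inf, sort(unique(cohort$score), decreasing = TRUE))
  # point at each observed score: decision score >= t; Inf gives (0,0)
  tpr <- vapply(thr, function(t) if (is.infinite(t)) 0 else
    mean(cohort$score[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) if (is.infinite(t)) 0 else
    mean(cohort$score[!y] >= t), numeric(1))
  curve <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Sensitivity and specificity at a threshold
#'
#' Positive decision iff `score > threshold` (strict). Sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP).
#'
#' @param cohort scored cohort data.frame.
#' @param threshold decision threshold (normally in \[0, 1\]; values outside
#'   are degenerate but defined, so the full-sensitivity threshold can be fed
#'   back even when a positive slide scores exactly 0).
#' @return list(sensitivity, specificity).
#' @export
sensSpec <- function(cohort, threshold) {
  assertCohort(cohort, need_both = FALSE)
  if (!is.finite(threshold)) stop("threshold must be finite")
  y <- cohort$label == "positive"
  pred <- cohort$score > threshold
  list(sensitivity = if (any(y)) mean(pred[y]) else NA_real_,
       specificity = if (any(!y)) mean(!pred[!y]) else NA_real_)
}

#' Specificity at 100% sensitivity
#'
#' The largest threshold that still classifies every positive slide as
#' positive (under strict >), and the specificity there: the fraction of
#' negative slides that can be excluded without missing any positive. The
#' threshold depends on the lowest positive score of the cohort.
#'
#' @param cohort scored cohort with at least one positive.
#' @return list(threshold, specificity).
#' @export
specAtFullSens <- function(cohort) {
  assertCohort(cohort, need_both = FALSE)
  y <- cohort$label == "positive"
  if (!any(y)) stop("cohort has no positive slides")
  min_pos <- min(cohort$score[y])
  below <- cohort$score[cohort$score < min_pos]
  # largest threshold below every positive; may dip below 0 when a positive
  # scores exactly 0 (sensitivity 1.0 then excludes no negatives)
  thr <- if (length(below)) max(below) else min_pos - 1e-9
  list(threshold = thr,
       specificity = if (any(!y)) mean(cohort$score[!y] < min_pos) else NA_real_)
}

#' Top-k true positive rate against point ground truth
#'
#' A recommended entry is a true positive iff it lies within the match radius
#' of a not-yet-matched ground-truth point; matching is greedy in rank order
#' and one-to-one (a lesion cell cannot be claimed twice by duplicate
#' recommendations). Pads count as non-matches. Reports the per-slide TPR
#' (matches / k), its mean, the pooled TPR over all slides, and the min-hit
#' flag: whether every slide has at least one true recommendation.
#'
#' @param topks named list (by slide_id) of [TopK-class] objects for positive
#'   slides.
#' @param truth annotations data.frame (`slide_id, x_px, y_px`), non-empty for
#'   every listed slide.
#' @param match_radius_um match radius in microns (default 15, about one cell
#'   diameter), converted at 0.243 um/px.
#' @return list: `per_slide` (data.frame `slide_id, tpr, hits, k`),
#'   `mean_tpr`, `pooled_tpr`, `min_hit`.
#' @export
topkTpr <- function(topks, truth, match_radius_um = 15) {
  radius_px <- match_radius_um / REF_MPP
  rows <- lapply(names(topks), function(sid) {
    tk <- topks[[sid]]
    tr <- truth[truth$slide_id == sid, , drop = FALSE]
    if (nrow(tr) == 0)
      stop("slide '", sid, "' has no ground-truth lesions; topkTpr is ",
           "defined for positive slides only")
    used <- logical(nrow(tr))
    hits <- 0L
    for (i in seq_len(tk@k)) {
      if (tk@pad_mask[i]) next
      d <- sqrt((tr$x_px - tk@candidates@coords[i, 1])^2 +
                  (tr$y_px - tk@candidates@coords[i, 2])^2)
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= radius_px) {
        used[j] <- TRUE
        hits <- hits + 1L
      }
    }
    data.frame(slide_id = sid, tpr = hits / tk@k, hits = hits, k = tk@k)
  })
  per_slide <- do.call(rbind, rows)
  list(per_slide = per_slide,
       mean_tpr = mean(per_slide$tpr),
       pooled_tpr = sum(per_slide$hits) / sum(per_slide$k),
       min_hit = all(per_slide$hits >= 1))
}

#' Slide-score frequency histogram
#'
#' Bins scores from 0 to 1 with the given width (default 0.05, i.e. 20
#' bins); bins are half-open `[a, a + width)` except the last, which is
#' closed at 1. Counts sum to the cohort size.
#'
#' @param cohort scored cohort data.frame (or vector of scores).
#' @param bin_width bin width.
#' @return data.frame `lower, upper, count`.
#' @export
scoreHistogram <- function(cohort, bin_width = 0.05) {
  scores <- if (is.data.frame(cohort)) cohort$score else cohort
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  nb <- as.integer(round(1 / bin_width))
  idx <- pmin(nb, floor(scores / bin_width) + 1L)
  data.frame(lower = (seq_len(nb) - 1) * bin_width,
             upper = seq_len(nb) * bin_width,
             count = tabulate(idx, nbins = nb))
}
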