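# Slide-level candidate aggregation: duplicate suppression across the
# redundant tiling, deterministic top-k selection, and gallery export.

# canonical candidate order: hr_prob desc, then lr_prob desc, then y, x asc
candidateOrder <- function(cs) {
  order(-cs@hr_prob, -cs@lr_prob, cs@coords[, 2], cs@coords[, 1])
}

#' Suppress duplicate candidates
#'
#' Overlapping tiles detect the same cell more than once. Candidates are
#' visited in descending HR probability (ties broken by LR probability, then
#' y, then x ascending); a candidate is dropped iff it lies within
#' `min_dist_px` (Euclidean, base level) of an already-kept higher-ranked
#' candidate. Idempotent, and independent of the input permutation.
#'
#' @param cs a [CandidateSet-class] (single slide).
#' @param min_dist_px suppression radius, base-level px (default 64,
#'   about 15.6 um, below typical cell spacing).
#' @return the deduplicated [CandidateSet-class], in canonical order.
#' @export
dedupCandidates <- function(cs, min_dist_px = 64) {
  n <- length(cs)
  if (n <= 1) return(cs)
  ord <- candidateOrder(cs)
  xs <- cs@coords[ord, 1]; ys <- cs@coords[ord, 2]
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (i == 1) { keep[1] <- TRUE; next }
    kept <- which(keep[seq_len(i - 1)])
    d2 <- (xs[kept] - xs[i])^2 + (ys[kept] - ys[i])^2
    keep[i] <- all(d2 >= min_dist_px^2)
  }
  sel <- ord[keep]
  candidateSet(cs@slide_id, cs@coords[sel, , drop = FALSE], cs@lr_prob[sel],
               cs@hr_prob[sel], cs@features[sel, , drop = FALSE])
}

#' Rank-ordered top-k recommendation
#'
#' Sorts by HR probability descending (the confirmed lesion probability) with
#' the deterministic tie-break (LR probability descending, then y, then x
#' ascending) and keeps the first k. With `pad = TRUE` and fewer than k
#' candidates, zero-feature pad entries with probability 0 complete the
#' fixed k x F shape the recurrent classifier requires; `pad_mask` flags
#' them.
#'
#' @param cs a [CandidateSet-class] (typically deduplicated).
#' @param k list length (>= 1), default 10.
#' @param pad pad to exactly k entries.
#' @return A [TopK-class].
#' @export
topK <- function(cs, k = 10, pad = TRUE) {
  if (k < 1) stop("k must be >= 1")
  ord <- candidateOrder(cs)
  sel <- ord[seq_len(min(k, length(ord)))]
  n_real <- length(sel)
  coords <- cs@coords[sel, , drop = FALSE]
  lr <- cs@lr_prob[sel]; hr <- cs@hr_prob[sel]
  feats <- cs@features[sel, , drop = FALSE]
  pad_count <- 0L
  if (pad && n_real < k) {
    pad_count <- as.integer(k - n_real)
    coords <- rbind(coords, matrix(NA_real_, pad_count, 2))
    lr <- c(lr, rep(0, pad_count))
    hr <- c(hr, rep(0, pad_count))
    feats <- rbind(feats, matrix(0, pad_count, ncol(feats)))
  }
  cand <- new("CandidateSet", slide_id = cs@slide_id, coords = coords,
              lr_prob = lr, hr_prob = hr, features = feats)
  new("TopK", candidates = cand, k = as.integer(k), pad_count = pad_count,
      pad_mask = c(rep(FALSE, n_real), rep(TRUE, pad_count)))
}

#' @describeIn topK the k x F feature matrix of a TopK (rank 1 first).
#' @param tk a [TopK-class].
#' @export
topKFeatures <- function(tk) tk@candidates@features

#' Export a top-k gallery
#'
#' Writes one rank-ordered image strip (PNG) of crops around each entry and
#' a CSV with one row per entry (`rank, x, y, hr_prob, pad`). Pad entries
#' render as blank placeholders.
#'
#' @param tk a [TopK-class].
#' @param slide the [CytoSlide-class] (reference level).
#' @param crop_px crop side length per entry.
#' @param path_png,path_csv output paths.
#' @return invisibly, the CSV data.frame.
#' @export
exportGallery <- function(tk, slide, crop_px = 128,
                          path_png = "gallery.png", path_csv = "gallery.csv") {
  cand <- tk@candidates
  strip <- array(1, c(crop_px, crop_px * tk@k, 3))
  for (i in seq_len(tk@k)) {
    if (!tk@pad_mask[i]) {
      crop <- cropAt(slide, cand@coords[i, ], crop_px) / 255
      strip[, ((i - 1) * crop_px + 1):(i * crop_px), ] <- crop
    }
  }
  png::writePNG(strip, path_png)
  df <- data.frame(rank = seq_len(tk@k),
                   x = cand@coords[, 1], y = cand@coords[, 2],
                   hr_prob = cand@hr_prob, pad = tk@pad_mask)
  utils::write.csv(df, path_csv, row.names = FALSE)
  invisible(df)
}
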