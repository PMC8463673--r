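# Group- and category-balanced epoch construction over multi-source training
# pools, and two-round hard-sample mining. Pools are data.frames of sample
# records with columns: sample_id, group_id, category, label
# ("positive"/"negative"), hard (logical), plus any payload columns callers
# attach (paths, origins, feature indices).

assertPool <- function(pool) {
  need <- c("sample_id", "group_id", "category", "label")
  if (!is.data.frame(pool) || !all(need %in% names(pool)))
    stop("a sample pool needs columns: ", paste(need, collapse = ", "))
  if (!"hard" %in% names(pool)) pool$hard <- FALSE
  if (any(duplicated(pool$sample_id))) stop("sample_id must be unique")
  pool
}

#' Build a group- and category-balanced epoch
#'
#' Multi-source pools have unbalanced annotation counts per dataset group and
#' per category; a balanced epoch resamples every `(group_id, category)` cell
#' to exactly `quota_per_cell` records (with replacement when the cell is
#' smaller), then shuffles the order. An empty cell is a configuration error
#' unless it is listed in `exclude_cells`.
#'
#' @param pool sample-record data.frame.
#' @param quota_per_cell samples contributed by each cell (0 gives an empty
#'   epoch).
#' @param seed integer seed.
#' @param exclude_cells character vector of `"group:category"` tokens to skip.
#' @return data.frame of sampled records, one row per epoch position.
#' @export
balancedEpoch <- function(pool, quota_per_cell, seed = 1, exclude_cells = character()) {
  pool <- assertPool(pool)
  if (nrow(pool) == 0) stop("pool must be non-empty")
  if (quota_per_cell == 0) return(pool[integer(0), , drop = FALSE])
  cells <- unique(pool[, c("group_id", "category")])
  cells <- cells[order(cells$group_id, cells$category), , drop = FALSE]
  keys <- paste(cells$group_id, cells$category, sep = ":")
  keep <- !(keys %in% exclude_cells)
  cells <- cells[keep, , drop = FALSE]
  if (nrow(cells) == 0) stop("all cells excluded")
  withSeed(seed, {
    picked <- integer(0)
    for (i in seq_len(nrow(cells))) {
      idx <- which(pool$group_id == cells$group_id[i] &
                   pool$category == cells$category[i])
      if (length(idx) == 0)
        stop("empty cell ", cells$group_id[i], ":", cells$category[i],
             " (exclude it explicitly or fill it)")
      picked <- c(picked, if (length(idx) >= quota_per_cell)
        sample(idx, quota_per_cell) else
        sample(idx, quota_per_cell, replace = TRUE))
    }
    pool[sample(picked), , drop = FALSE]
  })
}

#' Mine hard samples from predictions
#'
#' The hard set is exactly the records whose predicted label differs from the
#' true label; returned flagged `hard = TRUE`. Pure: identical predictions
#' give identical sets.
#'
#' @param predictions data.frame with `sample_id` and `pred_label`
#'   (`"positive"`/`"negative"`), covering the pool.
#' @param pool sample-record data.frame.
#' @return data.frame subset of `pool` with `hard = TRUE`.
#' @export
mineHard <- function(predictions, pool) {
  pool <- assertPool(pool)
  m <- match(pool$sample_id, predictions$sample_id)
  if (anyNA(m)) {
    missing <- pool$sample_id[which(is.na(m))[1]]
    stop("missing prediction for sample '", missing, "'")
  }
  hard <- pool[predictions$pred_label[m] != pool$label, , drop = FALSE]
  if (nrow(hard) > 0) hard$hard <- TRUE
  hard
}

#' Mix hard samples into a second-round training pool
#'
#' Builds an epoch-sized pool in which the fraction of hard samples equals
#' `hard_proportion` within one sample; the remainder is drawn from the full
#' pool. A small proportion suits the recall-oriented LR model, a large one
#' the precision-oriented HR model. With an empty hard set the full pool is
#' used, with a warning.
#'
#' @param pool sample-record data.frame.
#' @param hard_set subset of `pool` (checked by `sample_id`).
#' @param hard_proportion fraction of hard samples in \[0, 1\].
#' @param epoch_size output size (default `nrow(pool)`).
#' @param seed integer seed.
#' @return data.frame of `epoch_size` records, shuffled.
#' @export
mixHard <- function(pool, hard_set, hard_proportion, epoch_size = nrow(pool),
                    seed = 1) {
  pool <- assertPool(pool)
  if (hard_proportion < 0 || hard_proportion > 1)
    stop("hard_proportion must lie in [0, 1]")
  if (!all(hard_set$sample_id %in% pool$sample_id))
    stop("hard_set must be a subset of the pool")
  if (nrow(hard_set) == 0 && hard_proportion > 0) {
    warning("hard_proportion > 0 with an empty hard set; using the full pool")
    hard_proportion <- 0
  }
  n_hard <- round(hard_proportion * epoch_size)
  n_rest <- epoch_size - n_hard
  withSeed(seed, {
    rows <- list()
    if (n_hard > 0) {
      hs <- hard_set
      hs$hard <- TRUE
      rows$hard <- hs[sample(nrow(hs), n_hard, replace = n_hard > nrow(hs)), ,
                      drop = FALSE]
    }
    if (n_rest > 0)
      rows$rest <- pool[sample(nrow(pool), n_rest, replace = n_rest > nrow(pool)), ,
                        drop = FALSE]
    out <- do.call(rbind, rows)
    out[sample(nrow(out)), , drop = FALSE]
  })
}
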