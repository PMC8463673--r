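# Pipeline orchestration: cohort simulation, three-stage training (LR, HR,
# RNN ensemble), slide screening and cohort evaluation, driven by a single
# config that defaults to the printed system parameters (512 px LR tiles at
# 0.486 um/px, 256 px HR crops at 0.243 um/px, 0.5 gate, k = {10, 20, 30},
# slide threshold 0.5) and fully determines a run together with its seed.

#' Default pipeline configuration
#'
#' Nested list of every tunable the pipeline uses. Cascade geometry and
#' thresholds default to the printed system values; desk-scale sizes (slide
#' count and size, backbone feature width, training epochs) are the package's
#' own choices for CPU-scale experiments.
#'
#' @param work_dir run directory (cohort, checkpoints and reports live here).
#' @param seed global seed; all stage seeds derive from it.
#' @return config list.
#' @export
defaultConfig <- function(work_dir = file.path(tempdir(), "cytoscreen_run"),
                          seed = 1) {
  list(
    work_dir = work_dir,
    seed = as.integer(seed),
    cohort = list(n_pos = 40, n_neg = 40, styles = c("A", "B"),
                  lesions_per_positive = c(3, 15), size_px = c(2048, 2048),
                  n_normal = 180, mpp = REF_MPP,
                  split_ratios = c(0.8, 0.1, 0.1)),
    lr = list(tile_px = 512, tile_mpp = LR_MPP, overlap_px = 128,
              gate = 0.5, bin_threshold = 0.5, min_area = 2,
              per_tile_cap = 10, target_radius_cells = 2,
              tiles_per_class = 2, hard_proportion = 0.1),
    hr = list(crop_px = 256, feature_dim = 64, per_slide = 3,
              hard_proportion = 0.5),
    augment = list(enabled = TRUE, variants = 1),
    mining = list(rounds = 2),
    rank = list(min_dist_px = 64, ks = c(10, 20, 30), k_recommend = 10),
    rnn = list(hidden = 64, replicas_per_kind = 2, epochs = 60,
               rearrange = TRUE, jitter_sd = 0.05),
    optim = list(lr = 1e-3, epochs = 40, batch = 8, decay_every = 20,
                 decay_factor = 0.5),
    evaluate = list(slide_threshold = 0.5, match_radius_um = 15,
                    localization_radius_px = 32, hist_bin = 0.05)
  )
}

#' Read a pipeline config from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#' @param path YAML file.
#' @param seed optional seed override.
#' @return config list.
#' @export
readPipelineConfig <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- modifyList(defaultConfig(), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

cohortDir <- function(config) file.path(config$work_dir, "cohort")
ckptDir <- function(config) file.path(config$work_dir, "checkpoints")
reportDir <- function(config) file.path(config$work_dir, "reports")

logEvent <- function(config, stage, ...) {
  dir.create(config$work_dir, recursive = TRUE, showWarnings = FALSE)
  line <- jsonlite::toJSON(c(list(time = format(Sys.time()), stage = stage),
                             list(...)), auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = file.path(config$work_dir, "pipeline.jsonl"),
      append = TRUE)
}

dumpEffectiveConfig <- function(config) {
  dir.create(config$work_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(config$work_dir, "effective_config.yaml"))
}

augmentFromConfig <- function(config) {
  if (isTRUE(config$augment$enabled)) augmentConfig() else NULL
}

#' Simulate a cohort under the config
#'
#' Wraps [generateCohort()]; styles are resolved by name from
#' [styleLibrary()]. The effective config is dumped into the run directory.
#'
#' @param config pipeline config.
#' @param overwrite overwrite an existing cohort.
#' @return invisibly, the manifest.
#' @export
runSimulate <- function(config, overwrite = FALSE) {
  dumpEffectiveConfig(config)
  cc <- config$cohort
  styles <- styleLibrary()[cc$styles]
  if (any(vapply(styles, is.null, logical(1))))
    stop("unknown style id(s): ",
         paste(setdiff(cc$styles, names(styleLibrary())), collapse = ", "))
  t0 <- proc.time()[3]
  manifest <- generateCohort(cohortDir(config), cc$n_pos, cc$n_neg,
                             styles = styles,
                             lesions_per_positive = cc$lesions_per_positive,
                             size_px = cc$size_px, n_normal = cc$n_normal,
                             mpp = cc$mpp, split_ratios = cc$split_ratios,
                             seed = subSeed(config$seed, "cohort"),
                             overwrite = overwrite)
  logEvent(config, "simulate", n = nrow(manifest),
           elapsed_s = round(proc.time()[3] - t0, 1))
  invisible(manifest)
}

#' Load trained checkpoints
#'
#' @param config pipeline config.
#' @param need character subset of c("lr", "hr", "rnn").
#' @return list(lr, hr, ensemble) (missing stages NULL).
#' @export
loadModels <- function(config, need = c("lr", "hr", "rnn")) {
  p <- function(f) file.path(ckptDir(config), f)
  out <- list(lr = NULL, hr = NULL, ensemble = NULL)
  if ("lr" %in% need) {
    if (!file.exists(p("lr_model.rds")))
      stop("LR checkpoint missing; run the 'lr' training stage first")
    out$lr <- readRDS(p("lr_model.rds"))
  }
  if ("hr" %in% need) {
    if (!file.exists(p("hr_model.rds")))
      stop("HR checkpoint missing; run the 'hr' training stage first")
    out$hr <- readRDS(p("hr_model.rds"))
  }
  if ("rnn" %in% need) {
    if (!file.exists(p("rnn_ensemble.rds")))
      stop("RNN checkpoint missing; run the 'rnn' training stage first")
    out$ensemble <- readRDS(p("rnn_ensemble.rds"))
  }
  out
}

#' Screen one slide through the full cascade
#'
#' Runs the progressive pipeline: redundant LR tiling, LR inference, the 0.5
#' probability gate, heatmap-to-mask proposals, HR confirmation of proposed
#' crops, duplicate suppression, top-k ranking, and (when an ensemble is
#' given) the slide score. HR inference runs only on proposals, and gated
#' tiles (LR probability <= gate) produce none; `tiles` and `n_hr_calls`
#' give the exact call accounting.
#'
#' @param slide a [CytoSlide-class] or a path readable by [readSlide()].
#' @param models list(lr, hr, ensemble) from [loadModels()] (ensemble may be
#'   NULL).
#' @param config pipeline config.
#' @return list: `slide_id`, `candidates` (deduplicated [CandidateSet-class]),
#'   `topk` ([TopK-class] at `max(ks)`, padded), `tiles` (data.frame per tile:
#'   origin, lr_prob, n_proposals), `proposals` (all pre-dedup proposal
#'   centres), `n_hr_calls`, and with an ensemble: `score`, `members`,
#'   `label`.
#' @export
screenSlide <- function(slide, models, config = defaultConfig()) {
  if (is.character(slide)) slide <- readSlide(slide)
  lrc <- config$lr
  ref <- normalizeResolution(slide, REF_MPP)
  lr_slide <- normalizeResolution(ref, lrc$tile_mpp)
  grid <- planTiles(lr_slide, lrc$tile_px, lrc$tile_mpp, lrc$overlap_px)
  tiles <- data.frame(x0 = grid@origins[, 1], y0 = grid@origins[, 2],
                      lr_prob = NA_real_, n_proposals = 0L)
  proposals <- NULL
  prop_lr <- numeric(0)
  n_hr <- 0L
  for (t in seq_len(nTiles(grid))) {
    out <- lrInfer(readTile(lr_slide, grid, t), models$lr)
    tiles$lr_prob[t] <- out$lesion_prob
    if (out$lesion_prob <= lrc$gate) next
    mask <- heatmapToMask(out, lrc$bin_threshold, lrc$min_area,
                          tile_origin = grid@origins[t, ], gate = lrc$gate)
    pr <- proposeCrops(mask, lrc$per_tile_cap)
    tiles$n_proposals[t] <- nrow(pr)
    if (nrow(pr) > 0) {
      proposals <- rbind(proposals, pr)
      prop_lr <- c(prop_lr, rep(out$lesion_prob, nrow(pr)))
    }
  }
  F_dim <- models$hr@spec@feature_dim
  if (is.null(proposals) || nrow(proposals) == 0) {
    cands <- emptyCandidateSet(slide@slide_id, F_dim)
  } else {
    hr_prob <- numeric(nrow(proposals))
    feats <- matrix(0, nrow(proposals), F_dim)
    for (i in seq_len(nrow(proposals))) {
      crop <- cropAt(ref, proposals[i, ], config$hr$crop_px)
      hr <- hrInfer(crop, models$hr)
      n_hr <- n_hr + 1L
      hr_prob[i] <- hr$lesion_prob
      feats[i, ] <- hr$features
    }
    cands <- dedupCandidates(
      candidateSet(slide@slide_id, proposals, prop_lr, hr_prob, feats),
      config$rank$min_dist_px)
  }
  tk <- topK(cands, max(config$rank$ks), pad = TRUE)
  rep <- list(slide_id = slide@slide_id, candidates = cands, topk = tk,
              tiles = tiles,
              proposals = if (is.null(proposals)) matrix(numeric(0), ncol = 2)
                          else proposals,
              n_hr_calls = n_hr)
  if (!is.null(models$ensemble)) {
    es <- ensembleScore(topKFeatures(tk), models$ensemble)
    rep$score <- es$score
    rep$members <- es$members
    rep$label <- classifySlide(es$score, config$evaluate$slide_threshold)
  }
  rep
}

#' Train the pipeline stages
#'
#' `stage` is one of `"lr"`, `"hr"`, `"rnn"`, `"all"`. The RNN stage needs
#' the LR and HR checkpoints (it screens the train and validation slides to
#' collect top-k feature sequences). Checkpoints and JSON training logs are
#' written under the run's `checkpoints/` directory.
#'
#' @param config pipeline config.
#' @param stage stage selector.
#' @param enhance override augmentation (default from config); FALSE gives
#'   the no-enhancement ablation arm.
#' @param mine override mining (FALSE gives single-round training).
#' @return invisibly, list of trained artifacts for the stages run.
#' @export
runTrain <- function(config, stage = "all", enhance = NULL, mine = NULL) {
  stage <- match.arg(stage, c("lr", "hr", "rnn", "all"))
  stages <- if (stage == "all") c("lr", "hr", "rnn") else stage
  dumpEffectiveConfig(config)
  co <- readCohort(cohortDir(config))
  manifest <- co$manifest
  ann <- co$annotations
  train_m <- manifest[manifest$split == "train", ]
  val_m <- manifest[manifest$split == "val", ]
  if (nrow(train_m) == 0 || nrow(val_m) == 0)
    stop("cohort needs non-empty train and val splits")
  aug <- if (is.null(enhance)) augmentFromConfig(config) else
    if (isTRUE(enhance)) augmentConfig() else NULL
  rounds <- if (is.null(mine)) config$mining$rounds else if (isTRUE(mine)) 2 else 1
  dir.create(ckptDir(config), recursive = TRUE, showWarnings = FALSE)
  out <- list()
  optim <- function(tag) optimConfig(lr = config$optim$lr,
                                     epochs = config$optim$epochs,
                                     batch = config$optim$batch,
                                     decay_every = config$optim$decay_every,
                                     decay_factor = config$optim$decay_factor,
                                     seed = subSeed(config$seed, tag))

  if ("lr" %in% stages) {
    t0 <- proc.time()[3]
    spec <- deskLrSpec()
    tr <- materializeLrSamples(train_m, ann, spec, augment = aug,
                               variants = config$augment$variants,
                               tiles_per_class = config$lr$tiles_per_class,
                               overlap_px = config$lr$overlap_px,
                               target_radius_cells = config$lr$target_radius_cells,
                               seed = subSeed(config$seed, "lrmat"))
    va <- materializeLrSamples(val_m, ann, spec, augment = NULL,
                               tiles_per_class = config$lr$tiles_per_class,
                               overlap_px = config$lr$overlap_px,
                               seed = subSeed(config$seed, "lrval"))
    model <- trainLesionModel(spec, tr, va,
                              mining = miningConfig(config$lr$hard_proportion,
                                                    rounds),
                              optim = optim("lr"))
    saveRDS(model, file.path(ckptDir(config), "lr_model.rds"))
    writeJson(model@log[c("val_auc", "n_hard", "seed")],
              file.path(ckptDir(config), "lr_train_log.json"))
    logEvent(config, "train_lr", n_train = length(tr), val_auc = model@log$val_auc,
             elapsed_s = round(proc.time()[3] - t0, 1))
    out$lr <- model
  }
  if ("hr" %in% stages) {
    t0 <- proc.time()[3]
    spec <- deskHrSpec(config$hr$feature_dim)
    tr <- materializeHrSamples(train_m, ann, spec, augment = aug,
                               variants = config$augment$variants,
                               per_slide = config$hr$per_slide,
                               seed = subSeed(config$seed, "hrmat"))
    va <- materializeHrSamples(val_m, ann, spec, augment = NULL,
                               per_slide = config$hr$per_slide,
                               seed = subSeed(config$seed, "hrval"))
    model <- trainLesionModel(spec, tr, va,
                              mining = miningConfig(config$hr$hard_proportion,
                                                    rounds),
                              optim = optim("hr"))
    saveRDS(model, file.path(ckptDir(config), "hr_model.rds"))
    writeJson(model@log[c("val_auc", "n_hard", "seed")],
              file.path(ckptDir(config), "hr_train_log.json"))
    logEvent(config, "train_hr", n_train = length(tr), val_auc = model@log$val_auc,
             elapsed_s = round(proc.time()[3] - t0, 1))
    out$hr <- model
  }
  if ("rnn" %in% stages) {
    t0 <- proc.time()[3]
    models <- loadModels(config, need = c("lr", "hr"))
    collect <- function(m) {
      feats <- list(); labels <- character(0)
      for (i in seq_len(nrow(m))) {
        sr <- screenSlide(m$path[i], models, config)
        feats[[m$slide_id[i]]] <- topKFeatures(sr$topk)
        labels <- c(labels, m$label[i])
      }
      list(feats = feats, labels = labels)
    }
    trd <- collect(train_m)
    vad <- collect(val_m)
    saveRDS(list(train = trd, val = vad),
            file.path(ckptDir(config), "rnn_features.rds"))
    ens <- trainRnnEnsemble(trd$feats, trd$labels, vad$feats, vad$labels,
                            slide_ids = names(trd$feats),
                            val_slide_ids = names(vad$feats),
                            ks = config$rank$ks,
                            replicas_per_kind = config$rnn$replicas_per_kind,
                            hidden = config$rnn$hidden,
                            augment = list(rearrange = config$rnn$rearrange,
                                           jitter_sd = config$rnn$jitter_sd),
                            optim = optimConfig(lr = config$optim$lr,
                                                epochs = config$rnn$epochs,
                                                decay_every = config$optim$decay_every,
                                                decay_factor = config$optim$decay_factor,
                                                seed = subSeed(config$seed, "rnn")),
                            seed = subSeed(config$seed, "rnnens"))
    saveRDS(ens, file.path(ckptDir(config), "rnn_ensemble.rds"))
    logEvent(config, "train_rnn", members = length(ens@members),
             elapsed_s = round(proc.time()[3] - t0, 1))
    out$ensemble <- ens
  }
  invisible(out)
}

#' Screen a cohort split and compute the evaluation report
#'
#' Screens every slide of the split and reports: ROC/AUC, sensitivity and
#' specificity at the slide threshold, specificity at 100% sensitivity, the
#' slide-score histogram, the top-k TPR of recommendations on positive
#' slides, localization recall of planted lesions (fraction receiving an HR
#' proposal within the configured radius), and the gate accounting. The
#' report is written as JSON under `reports/`.
#'
#' @param config pipeline config.
#' @param split `"test"`, `"val"` or `"train"`.
#' @param models optional pre-loaded models.
#' @return report list (invisible file side effect).
#' @export
runEvaluate <- function(config, split = "test", models = NULL) {
  co <- readCohort(cohortDir(config))
  m <- co$manifest[co$manifest$split == split, ]
  if (nrow(m) == 0) stop("split '", split, "' is empty")
  if (is.null(models)) models <- loadModels(config)
  t0 <- proc.time()[3]
  screens <- lapply(seq_len(nrow(m)), function(i)
    screenSlide(m$path[i], models, config))
  names(screens) <- m$slide_id
  cohort <- data.frame(slide_id = m$slide_id,
                       score = vapply(screens, `[[`, numeric(1), "score"),
                       label = m$label)
  roc <- rocAuc(cohort)
  ss <- sensSpec(cohort, config$evaluate$slide_threshold)
  sfs <- specAtFullSens(cohort)
  hist <- scoreHistogram(cohort, config$evaluate$hist_bin)
  # top-k TPR on positive slides
  pos_ids <- m$slide_id[m$label == "positive"]
  tpr <- NULL
  if (length(pos_ids) > 0) {
    topks <- lapply(screens[pos_ids], function(s)
      topK(s$candidates, config$rank$k_recommend, pad = TRUE))
    names(topks) <- pos_ids
    tpr <- topkTpr(topks, co$annotations, config$evaluate$match_radius_um)
  }
  # localization recall: planted lesions receiving a proposal within radius
  rad <- config$evaluate$localization_radius_px
  loc_hit <- loc_tot <- 0L
  for (sid in pos_ids) {
    tr <- co$annotations[co$annotations$slide_id == sid, ]
    pr <- screens[[sid]]$proposals
    for (j in seq_len(nrow(tr))) {
      loc_tot <- loc_tot + 1L
      if (nrow(pr) > 0 &&
          min((pr[, 1] - tr$x_px[j])^2 + (pr[, 2] - tr$y_px[j])^2) <= rad^2)
        loc_hit <- loc_hit + 1L
    }
  }
  gate_ok <- all(vapply(screens, function(s)
    all(s$tiles$n_proposals[s$tiles$lr_prob <= config$lr$gate] == 0L),
    logical(1)))
  report <- list(
    split = split, n_slides = nrow(m),
    auc = roc$auc, sensitivity = ss$sensitivity, specificity = ss$specificity,
    spec_at_full_sens = sfs$specificity, full_sens_threshold = sfs$threshold,
    mean_top10_tpr = if (!is.null(tpr)) tpr$mean_tpr else NA,
    pooled_top10_tpr = if (!is.null(tpr)) tpr$pooled_tpr else NA,
    min_hit = if (!is.null(tpr)) tpr$min_hit else NA,
    localization_recall = if (loc_tot > 0) loc_hit / loc_tot else NA,
    n_lesions_total = loc_tot,
    gate_clean = gate_ok,
    scores = stats::setNames(cohort$score, cohort$slide_id),
    histogram = hist
  )
  dir.create(reportDir(config), recursive = TRUE, showWarnings = FALSE)
  writeJson(report[setdiff(names(report), "histogram")],
            file.path(reportDir(config), paste0("evaluate_", split, ".json")))
  utils::write.csv(hist, file.path(reportDir(config),
                                   paste0("histogram_", split, ".csv")),
                   row.names = FALSE)
  utils::write.csv(roc$curve, file.path(reportDir(config),
                                        paste0("roc_", split, ".csv")),
                   row.names = FALSE)
  logEvent(config, "evaluate", split = split, auc = roc$auc,
           elapsed_s = round(proc.time()[3] - t0, 1))
  c(report, list(screens = screens, cohort = cohort, roc = roc))
}

#' Scaled-down training-strategy ablation
#'
#' Trains the HR model twice on single-style ("A") crops — once with
#' designed enhancement plus hard mining, once with neither — and compares
#' tile-level AUC on crops from the unseen style "E". Slide sets are small
#' and rendered at reduced size; the comparison is directional.
#'
#' @param config pipeline config (only `seed` and HR settings are used).
#' @param n_train,n_val,n_test slides per arm component.
#' @param size_px ablation slide size.
#' @return list: `auc_enhanced`, `auc_baseline`, `delta`.
#' @export
runAblation <- function(config = defaultConfig(), n_train = 14, n_val = 4,
                        n_test = 12, size_px = c(1024, 1024)) {
  seed <- subSeed(config$seed, "ablation")
  lib <- styleLibrary()
  # borderline lesion morphology: with the study margins the crop task is
  # separable under any training regime and the comparison saturates
  mk <- function(dir, n, style, seed_off, prefix) {
    generateCohort(dir, n %/% 2, n - n %/% 2, styles = lib[style],
                   lesions_per_positive = c(4, 10), size_px = size_px,
                   n_normal = 60, morph = confusableMorphology(),
                   split_ratios = c(1, 0, 0),
                   seed = subSeed(seed, seed_off), prefix = prefix,
                   overwrite = TRUE)
  }
  base <- file.path(config$work_dir, "ablation")
  tr_m <- mk(file.path(base, "train"), n_train, "A", 1, "abltr_")
  va_m <- mk(file.path(base, "val"), n_val, "A", 2, "ablva_")
  # unseen styles E and F differ between themselves as well as from A: a
  # model sensitive to absolute intensity interleaves their score scales
  te_m <- mk(file.path(base, "test"), n_test, c("E", "F"), 3, "ablte_")
  spec <- deskHrSpec(config$hr$feature_dim)
  annOf <- function(dir) readCohort(dir)$annotations
  mat <- function(m, dir, augment, tag)
    materializeHrSamples(m, annOf(dir), spec, augment = augment, variants = 2,
                         per_slide = config$hr$per_slide,
                         seed = subSeed(seed, tag))
  tr_aug <- mat(tr_m, file.path(base, "train"), augmentConfig(), "mat_aug")
  tr_plain <- mat(tr_m, file.path(base, "train"), NULL, "mat_plain")
  va <- mat(va_m, file.path(base, "val"), NULL, "mat_val")
  te <- mat(te_m, file.path(base, "test"), NULL, "mat_test")
  optim <- optimConfig(lr = config$optim$lr, epochs = config$optim$epochs,
                       batch = config$optim$batch,
                       decay_every = config$optim$decay_every,
                       decay_factor = config$optim$decay_factor,
                       seed = subSeed(seed, "fit"))
  m_full <- trainLesionModel(spec, tr_aug, va,
                             mining = miningConfig(config$hr$hard_proportion, 2),
                             optim = optim)
  m_base <- trainLesionModel(spec, tr_plain, va,
                             mining = miningConfig(0, 1), optim = optim)
  testAuc <- function(model) {
    X <- do.call(rbind, lapply(te, `[[`, "raw"))
    y <- as.numeric(vapply(te, `[[`, character(1), "label") == "positive")
    p <- mlpFit(spec@feature_dim, 0)$predict(model@weights,
                                             applyStandardizer(X, model@norm$raw))
    aucFromScores(p, y)
  }
  res <- list(auc_enhanced = testAuc(m_full), auc_baseline = testAuc(m_base))
  res$delta <- res$auc_enhanced - res$auc_baseline
  logEvent(config, "ablation", auc_enhanced = res$auc_enhanced,
           auc_baseline = res$auc_baseline)
  res
}

#' Screen one slide and write its report
#'
#' Full inference on a single slide: score, decision at the slide threshold,
#' top-10 gallery (PNG + CSV) and candidate/tile counts, written under
#' `reports/<slide_id>/`.
#'
#' @param config pipeline config.
#' @param slide_path slide image path.
#' @return report list.
#' @export
runScreen <- function(config, slide_path) {
  models <- loadModels(config)
  t0 <- proc.time()[3]
  slide <- readSlide(slide_path)
  sr <- screenSlide(slide, models, config)
  out_dir <- file.path(reportDir(config), sr$slide_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tk10 <- topK(sr$candidates, config$rank$k_recommend, pad = TRUE)
  gallery <- exportGallery(tk10, normalizeResolution(slide, REF_MPP),
                           crop_px = 128,
                           path_png = file.path(out_dir, "top10_gallery.png"),
                           path_csv = file.path(out_dir, "top10.csv"))
  report <- list(slide_id = sr$slide_id, score = sr$score, label = sr$label,
                 member_scores = sr$members,
                 n_tiles = nrow(sr$tiles),
                 n_gated_tiles = sum(sr$tiles$lr_prob <= config$lr$gate),
                 n_hr_calls = sr$n_hr_calls,
                 n_candidates = length(sr$candidates),
                 runtime_s = round(proc.time()[3] - t0, 2))
  writeJson(report, file.path(out_dir, "report.json"))
  logEvent(config, "screen", slide = sr$slide_id, score = sr$score)
  c(report, list(topk = tk10, gallery = gallery, screen = sr))
}
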