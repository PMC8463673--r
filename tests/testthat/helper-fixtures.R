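# Shared fixtures, built once per test run and cached in-session. All are
# generated programmatically; nothing is stored on disk beyond tempdir().

.fixtures <- new.env(parent = emptyenv())

# a small multi-style cohort (16 slides at 1024^2) for module-level tests
miniCohort <- function() {
  if (!is.null(.fixtures$mini)) return(.fixtures$mini)
  dir <- file.path(tempdir(), "cyto_mini")
  generateCohort(dir, 8, 8, styles = styleLibrary()[c("A", "B")],
                 lesions_per_positive = c(3, 8), size_px = c(1024, 1024),
                 n_normal = 50, split_ratios = c(0.5, 0.25, 0.25),
                 seed = 421, overwrite = TRUE)
  co <- readCohort(dir)
  co$dir <- dir
  .fixtures$mini <- co
  co
}

# desk-scale LR + HR models trained on the mini cohort's train/val splits
miniModels <- function() {
  if (!is.null(.fixtures$models)) return(.fixtures$models)
  co <- miniCohort()
  tr <- co$manifest[co$manifest$split == "train", ]
  va <- co$manifest[co$manifest$split == "val", ]
  lr_spec <- deskLrSpec()
  lrm <- trainLesionModel(
    lr_spec,
    materializeLrSamples(tr, co$annotations, lr_spec,
                         augment = augmentConfig(), variants = 1, seed = 71),
    materializeLrSamples(va, co$annotations, lr_spec, seed = 72),
    mining = miningConfig(0.1, 2), optim = optimConfig(seed = 5))
  hr_spec <- deskHrSpec()
  hrm <- trainLesionModel(
    hr_spec,
    materializeHrSamples(tr, co$annotations, hr_spec,
                         augment = augmentConfig(), variants = 1,
                         per_slide = 3, seed = 73),
    materializeHrSamples(va, co$annotations, hr_spec, per_slide = 3, seed = 74),
    mining = miningConfig(0.5, 2), optim = optimConfig(seed = 6))
  .fixtures$models <- list(lr = lrm, hr = hrm)
  .fixtures$models
}

# a flat mid-grey test slide
greySlide <- function(h = 256, w = 256, value = 128) {
  new("CytoSlide", slide_id = "grey", mpp = 0.243,
      pixels = array(value, c(h, w, 3)))
}

# random candidate set for ranking tests
randomCandidates <- function(n, seed, F = 8, extent = 2000) {
  set.seed(seed)
  candidateSet("s", cbind(runif(n, 0, extent), runif(n, 0, extent)),
               runif(n), runif(n), matrix(rnorm(n * F), n, F))
}
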