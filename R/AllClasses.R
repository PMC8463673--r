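#' @import methods
NULL

# ---------------------------------------------------------------------------
# StyleSpec: one staining/imaging style for the synthetic generator.
# ---------------------------------------------------------------------------

#' Staining/imaging style specification
#'
#' A `StyleSpec` describes one staining and imaging "style": a hue rotation,
#' saturation and value (brightness) scaling applied in HSV space, a glass
#' background colour, additive luminance noise and an optional defocus blur.
#' Rendering the same scene under styles with different `value_scale` yields
#' value-channel histograms with correspondingly shifted means, which is the
#' property the multi-centre cohorts differ most visibly in.
#'
#' @slot style_id single token naming the style.
#' @slot hue_shift hue rotation in degrees, in \[-180, 180\].
#' @slot saturation_scale multiplicative saturation factor, > 0.
#' @slot value_scale multiplicative value (brightness) factor, > 0.
#' @slot background_rgb background (glass) colour, three intensities in \[0, 255\].
#' @slot noise_sd standard deviation of additive luminance noise, intensity units.
#' @slot blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @export
setClass("StyleSpec", representation(
  style_id = "character",
  hue_shift = "numeric",
  saturation_scale = "numeric",
  value_scale = "numeric",
  background_rgb = "numeric",
  noise_sd = "numeric",
  blur_sigma = "numeric"
))

setValidity("StyleSpec", function(object) {
  msg <- character()
  if (length(object@style_id) != 1L || !nzchar(object@style_id))
    msg <- c(msg, "style_id must be a single non-empty token")
  if (abs(object@hue_shift) > 180) msg <- c(msg, "hue_shift must lie in [-180, 180]")
  if (object@saturation_scale <= 0) msg <- c(msg, "saturation_scale must be > 0")
  if (object@value_scale <= 0) msg <- c(msg, "value_scale must be > 0")
  if (length(object@background_rgb) != 3L ||
      any(object@background_rgb < 0 | object@background_rgb > 255))
    msg <- c(msg, "background_rgb must be three intensities in [0, 255]")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (object@blur_sigma < 0) msg <- c(msg, "blur_sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a StyleSpec
#'
#' @param style_id style token.
#' @param hue_shift hue rotation in degrees.
#' @param saturation_scale,value_scale multiplicative HSV factors (> 0).
#' @param background_rgb glass background colour (three values in 0..255).
#' @param noise_sd additive luminance noise SD (intensity units).
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @return A [StyleSpec-class] object.
#' @examples
#' styleSpec("demo", hue_shift = -10, value_scale = 0.9)
#' @export
styleSpec <- function(style_id, hue_shift = 0, saturation_scale = 1,
                      value_scale = 1, background_rgb = c(243, 241, 246),
                      noise_sd = 3, blur_sigma = 0) {
  new("StyleSpec", style_id = as.character(style_id), hue_shift = hue_shift,
      saturation_scale = saturation_scale, value_scale = value_scale,
      background_rgb = background_rgb, noise_sd = noise_sd,
      blur_sigma = blur_sigma)
}

setMethod("show", "StyleSpec", function(object) {
  cat(sprintf("StyleSpec '%s': hue %+g deg, sat x%g, value x%g, noise %g, blur %g\n",
              object@style_id, object@hue_shift, object@saturation_scale,
              object@value_scale, object@noise_sd, object@blur_sigma))
})

# ---------------------------------------------------------------------------
# SlidePlan: full recipe for one synthetic slide.
# ---------------------------------------------------------------------------

#' Synthetic slide plan
#'
#' A `SlidePlan` fully determines one rendered synthetic slide: canvas size
#' and resolution, the style, the number of background (normal) cells, the
#' planted lesion cells, and the seed. Cell tables have columns
#' `x`, `y` (0-based centre coordinates at the reference 0.243 um/px level),
#' `cell_class` (`"normal"`/`"lesion"`), `nucleus_radius` (px),
#' `nucleus_darkness` (0..1) and `halo` (logical, perinuclear clearing).
#'
#' @slot slide_id slide token.
#' @slot label `"positive"` or `"negative"`.
#' @slot width_px,height_px canvas size in pixels at the reference level.
#' @slot mpp microns per pixel of the rendered raster.
#' @slot n_normal number of background normal cells.
#' @slot lesion_cells data.frame of lesion cell specs (zero rows iff negative).
#' @slot style a [StyleSpec-class].
#' @slot seed integer rendering seed.
#' @export
setClass("SlidePlan", representation(
  slide_id = "character",
  label = "character",
  width_px = "integer",
  height_px = "integer",
  mpp = "numeric",
  n_normal = "integer",
  lesion_cells = "data.frame",
  style = "StyleSpec",
  seed = "integer"
))

setValidity("SlidePlan", function(object) {
  msg <- character()
  if (!object@label %in% c("positive", "negative"))
    msg <- c(msg, "label must be 'positive' or 'negative'")
  if (object@width_px < 64L || object@height_px < 64L)
    msg <- c(msg, "slide must be at least 64x64 px")
  if (object@mpp <= 0) msg <- c(msg, "mpp must be > 0")
  lc <- object@lesion_cells
  if (object@label == "negative" && nrow(lc) > 0)
    msg <- c(msg, "negative slides must contain zero lesion cells")
  if (object@label == "positive" && nrow(lc) == 0)
    msg <- c(msg, "positive slides must contain at least one lesion cell")
  if (nrow(lc) > 0) {
    need <- c("x", "y", "cell_class", "nucleus_radius", "nucleus_darkness", "halo")
    if (!all(need %in% names(lc))) {
      msg <- c(msg, paste("lesion_cells needs columns:", paste(need, collapse = ", ")))
    } else {
      bad <- which(lc$x < 0 | lc$x >= object@width_px |
                   lc$y < 0 | lc$y >= object@height_px)
      if (length(bad))
        msg <- c(msg, paste0("lesion cell ", bad[1], " centre (", lc$x[bad[1]], ",",
                             lc$y[bad[1]], ") lies outside slide bounds"))
      if (any(lc$nucleus_radius <= 0)) msg <- c(msg, "nucleus_radius must be > 0")
      if (any(lc$nucleus_darkness < 0 | lc$nucleus_darkness > 1))
        msg <- c(msg, "nucleus_darkness must lie in [0, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SlidePlan", function(object) {
  cat(sprintf("SlidePlan '%s' (%s): %dx%d px @ %.3f um/px, %d normal, %d lesion, style '%s'\n",
              object@slide_id, object@label, object@width_px, object@height_px,
              object@mpp, object@n_normal, nrow(object@lesion_cells),
              object@style@style_id))
})

# ---------------------------------------------------------------------------
# CytoSlide: in-memory raster with physical scale.
# ---------------------------------------------------------------------------

#' A slide raster with physical scale
#'
#' `CytoSlide` is the pipeline's unit of work: an RGB raster (numeric array
#' `height x width x 3`, intensities 0..255) with a microns-per-pixel scale.
#' Region reads outside the bounds are padded with the glass colour, never an
#' error.
#'
#' @slot slide_id slide token.
#' @slot mpp microns per pixel of the stored raster (> 0).
#' @slot pixels numeric array `height x width x 3` in \[0, 255\].
#' @export
setClass("CytoSlide", representation(
  slide_id = "character",
  mpp = "numeric",
  pixels = "array"
))

setValidity("CytoSlide", function(object) {
  msg <- character()
  if (length(object@mpp) != 1L || is.na(object@mpp) || object@mpp <= 0)
    msg <- c(msg, "mpp must be a single value > 0")
  if (!isRgbArray(object@pixels)) msg <- c(msg, "pixels must be h x w x 3 numeric")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CytoSlide", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CytoSlide '%s': %d x %d px @ %.3f um/px\n",
              object@slide_id, d[2], d[1], object@mpp))
})

#' @describeIn CytoSlide-class slide width in pixels.
#' @param x a `CytoSlide`.
#' @export
slideWidth <- function(x) dim(x@pixels)[2]

#' @describeIn CytoSlide-class slide height in pixels.
#' @export
slideHeight <- function(x) dim(x@pixels)[1]

#' @describeIn CytoSlide-class microns per pixel of the stored raster.
#' @export
slideMpp <- function(x) x@mpp

#' @describeIn CytoSlide-class slide identifier.
#' @export
slideId <- function(x) x@slide_id

# ---------------------------------------------------------------------------
# TileGrid: redundant (overlapping) division of a slide.
# ---------------------------------------------------------------------------

#' Redundant tile grid
#'
#' Tile origins are 0-based top-left coordinates at `tile_mpp`, with half-open
#' extents `[x, x + tile_px)`. The stride is at most the tile side, so tiles
#' overlap and their union covers the slide.
#'
#' @slot tile_px tile side length in pixels.
#' @slot tile_mpp microns per pixel at which tiles are sampled.
#' @slot stride_px step between tile origins.
#' @slot origins integer matrix (n x 2) of (x, y) origins.
#' @slot extent_px integer (width, height) of the slide at `tile_mpp`.
#' @export
setClass("TileGrid", representation(
  tile_px = "integer",
  tile_mpp = "numeric",
  stride_px = "integer",
  origins = "matrix",
  extent_px = "integer"
))

setValidity("TileGrid", function(object) {
  msg <- character()
  if (object@stride_px > object@tile_px)
    msg <- c(msg, "stride_px must be <= tile_px (redundant division)")
  if (ncol(object@origins) != 2L) msg <- c(msg, "origins must be an n x 2 matrix")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TileGrid", function(object) {
  cat(sprintf("TileGrid: %d tiles of %d px @ %.3f um/px, stride %d, extent %dx%d\n",
              nrow(object@origins), object@tile_px, object@tile_mpp,
              object@stride_px, object@extent_px[1], object@extent_px[2]))
})

#' Number of tiles in a grid
#' @param grid a [TileGrid-class].
#' @export
nTiles <- function(grid) nrow(grid@origins)

# ---------------------------------------------------------------------------
# LocationMask: binarised, cleaned heatmap with components.
# ---------------------------------------------------------------------------

#' Location mask derived from a heatmap
#'
#' Binary mask at heatmap resolution after thresholding and morphological
#' cleaning, with connected components (8-connectivity) and their centroids
#' mapped to base-level (0.243 um/px) coordinates.
#'
#' @slot mask binary matrix at heatmap resolution.
#' @slot components data.frame with columns `cx`, `cy` (base-level px) and
#'   `area` (heatmap cells), ordered by decreasing area.
#' @slot cell_base_px base-level pixels covered by one heatmap cell.
#' @export
setClass("LocationMask", representation(
  mask = "matrix",
  components = "data.frame",
  cell_base_px = "numeric"
))

setMethod("show", "LocationMask", function(object) {
  cat(sprintf("LocationMask: %dx%d cells, %d component(s)\n",
              nrow(object@mask), ncol(object@mask), nrow(object@components)))
})

# ---------------------------------------------------------------------------
# CandidateSet / TopK
# ---------------------------------------------------------------------------

#' Confirmed lesion-cell candidates on one slide
#'
#' Stores, for one slide, the HR-confirmed candidates: base-level centre
#' coordinates, LR and HR probabilities, and the HR feature matrix (one row
#' per candidate).
#'
#' @slot slide_id slide token.
#' @slot coords numeric matrix (n x 2) of (x, y) base-level centres.
#' @slot lr_prob,hr_prob numeric vectors of probabilities in \[0, 1\].
#' @slot features numeric matrix (n x F) of HR feature vectors.
#' @export
setClass("CandidateSet", representation(
  slide_id = "character",
  coords = "matrix",
  lr_prob = "numeric",
  hr_prob = "numeric",
  features = "matrix"
))

setValidity("CandidateSet", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (length(object@lr_prob) != n || length(object@hr_prob) != n ||
      nrow(object@features) != n)
    msg <- c(msg, "coords, probabilities and features must agree in length")
  if (n > 0 && (any(object@lr_prob < 0 | object@lr_prob > 1) ||
                any(object@hr_prob < 0 | object@hr_prob > 1)))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a CandidateSet
#' @param slide_id slide token.
#' @param coords n x 2 matrix of (x, y) base-level centres.
#' @param lr_prob,hr_prob probability vectors.
#' @param features n x F feature matrix.
#' @return A [CandidateSet-class].
#' @export
candidateSet <- function(slide_id, coords, lr_prob, hr_prob, features) {
  coords <- matrix(as.numeric(coords), ncol = 2)
  new("CandidateSet", slide_id = slide_id, coords = coords,
      lr_prob = as.numeric(lr_prob), hr_prob = as.numeric(hr_prob),
      features = as.matrix(features))
}

emptyCandidateSet <- function(slide_id, feature_dim) {
  new("CandidateSet", slide_id = slide_id,
      coords = matrix(numeric(0), ncol = 2), lr_prob = numeric(0),
      hr_prob = numeric(0), features = matrix(numeric(0), ncol = feature_dim))
}

setMethod("length", "CandidateSet", function(x) nrow(x@coords))

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet '%s': %d candidate(s), F = %d\n", object@slide_id,
              nrow(object@coords), ncol(object@features)))
})

#' @describeIn CandidateSet-class candidates as a data.frame
#'   (x, y, lr_prob, hr_prob).
#' @param x a `CandidateSet`.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.CandidateSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(slide_id = rep(x@slide_id, nrow(x@coords)),
             x = x@coords[, 1], y = x@coords[, 2],
             lr_prob = x@lr_prob, hr_prob = x@hr_prob)
}

#' Rank-ordered top-k recommendation
#'
#' The k highest-probability candidates of a slide, ordered by HR probability
#' (rank 1 first). When a slide yields fewer than k candidates and padding is
#' enabled, synthetic pad entries with zero features and probability 0 keep
#' the k x F shape required by the recurrent classifier; `pad_mask` flags them.
#'
#' @slot candidates a [CandidateSet-class] holding the k (possibly padded) rows.
#' @slot k requested list length.
#' @slot pad_count number of synthetic pad entries.
#' @slot pad_mask logical vector, TRUE for pad rows.
#' @export
setClass("TopK", representation(
  candidates = "CandidateSet",
  k = "integer",
  pad_count = "integer",
  pad_mask = "logical"
))

setMethod("show", "TopK", function(object) {
  cat(sprintf("TopK k=%d on '%s': %d real + %d pad\n", object@k,
              object@candidates@slide_id, object@k - object@pad_count,
              object@pad_count))
})

# ---------------------------------------------------------------------------
# Model specs and trained models
# ---------------------------------------------------------------------------

#' Backbone architecture specification
#'
#' Describes a cascade-model backbone: the named full-scale architecture is a
#' ResNet50 two-head contract (2,048-dim features, dilated-convolution
#' segmentation branch); the desk-scale backbone (`"deskblob"`) is a fixed
#' multi-scale blob-response filter bank over the HSV value channel feeding
#' trainable heads, with the same two-head contract. LR specs carry a
#' segmentation branch; HR specs do not.
#'
#' @slot name architecture token (`"deskblob"` or `"resnet50"`).
#' @slot input_px input side length (512 LR / 256 HR).
#' @slot input_mpp microns per pixel of the input (0.486 LR / 0.243 HR).
#' @slot feature_dim penultimate feature dimension F (2048 full scale).
#' @slot seg_branch TRUE for the LR model's heatmap branch.
#' @slot seg_dilations dilation rates of the segmentation branch (full scale).
#' @slot heat_stride input pixels per heatmap cell (registration factor).
#' @slot work_scale downsampling factor applied before the filter bank.
#' @slot sigmas filter-bank Gaussian scales, in working-resolution pixels.
#' @export
setClass("BackboneSpec", representation(
  name = "character",
  input_px = "integer",
  input_mpp = "numeric",
  feature_dim = "integer",
  seg_branch = "logical",
  seg_dilations = "numeric",
  heat_stride = "integer",
  work_scale = "integer",
  sigmas = "numeric"
))

setValidity("BackboneSpec", function(object) {
  msg <- character()
  if (object@feature_dim <= 0) msg <- c(msg, "feature_dim must be > 0")
  if (object@input_px <= 0) msg <- c(msg, "input_px must be > 0")
  if (object@seg_branch && object@heat_stride <= 0)
    msg <- c(msg, "seg_branch requires a positive heat_stride")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BackboneSpec", function(object) {
  cat(sprintf("BackboneSpec '%s': input %d px @ %.3f um/px, F = %d%s\n",
              object@name, object@input_px, object@input_mpp, object@feature_dim,
              if (object@seg_branch)
                sprintf(", seg branch (stride %d)", object@heat_stride) else ""))
})

#' Trained cascade model (LR or HR)
#'
#' @slot spec the [BackboneSpec-class].
#' @slot kind `"lr"` or `"hr"`.
#' @slot weights list of trained head weights.
#' @slot norm feature standardisation (centre/scale) applied before the heads.
#' @slot trained TRUE once fitted.
#' @slot log training log (seeds, lr schedule, per-epoch metrics).
#' @export
setClass("LesionModel", representation(
  spec = "BackboneSpec",
  kind = "character",
  weights = "list",
  norm = "list",
  trained = "logical",
  log = "list"
))

setMethod("show", "LesionModel", function(object) {
  cat(sprintf("LesionModel [%s] on '%s' backbone, %s\n", toupper(object@kind),
              object@spec@name,
              if (object@trained) "trained" else "untrained"))
})

#' Recurrent slide-classification member
#'
#' A vanilla recurrent network with a single hidden layer reading the
#' rank-ordered k x F feature sequence (rank 1 first) and emitting a slide
#' positivity probability from the time-averaged hidden state (robust to the
#' pad tails of slides with few candidates).
#'
#' @slot input_dim feature dimension F.
#' @slot hidden_units hidden layer width (512 at full scale).
#' @slot k sequence length this member reads.
#' @slot weights list (Wxh, Whh, bh, Wout, bout).
#' @slot norm per-dimension feature standardisation.
#' @slot seed training seed.
#' @export
setClass("RnnModel", representation(
  input_dim = "integer",
  hidden_units = "integer",
  k = "integer",
  weights = "list",
  norm = "list",
  seed = "integer"
))

setMethod("show", "RnnModel", function(object) {
  cat(sprintf("RnnModel: k=%d, F=%d, hidden=%d\n", object@k, object@input_dim,
              object@hidden_units))
})

#' Six-member recurrent ensemble
#'
#' Two members per sequence length k in {10, 20, 30}; the slide score is the
#' unweighted mean of the member probabilities.
#'
#' @slot members list of [RnnModel-class] objects.
#' @slot ks integer vector of each member's k.
#' @export
setClass("RnnEnsemble", representation(
  members = "list",
  ks = "integer"
))

setValidity("RnnEnsemble", function(object) {
  if (length(object@members) != length(object@ks))
    return("one k per member required")
  TRUE
})

setMethod("show", "RnnEnsemble", function(object) {
  cat(sprintf("RnnEnsemble: %d member(s), k = {%s}\n", length(object@members),
              paste(sort(unique(object@ks)), collapse = ", ")))
})
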