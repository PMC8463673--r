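# Designed photometric/geometric data enhancement in HSV and RGB space,
# imitating diverse staining and imaging styles during training: hue,
# saturation, brightness (value) and contrast jitter, flips, shifts, and
# blur/sharpen noise. Every transform is sampled into an explicit parameter
# record first, so any augmented image can be replayed bit-exactly.

#' Augmentation configuration
#'
#' Ranges are hard caps chosen so the cytological content stays
#' recognisable; defaults: hue +-15 degrees, saturation/value/contrast
#' x\[0.8, 1.2\], shift <= 32 px, blur sigma <= 1.5, blur/sharpen probability
#' 0.2 each. All are configurable.
#'
#' @slot hue_shift_range degrees (min, max).
#' @slot saturation_range,value_range,contrast_range ratio intervals.
#' @slot p_flip_h,p_flip_v flip probabilities.
#' @slot max_shift_px maximum absolute shift per axis.
#' @slot p_blur,p_sharpen noise-op probabilities.
#' @slot blur_sigma_range blur sigma interval (px).
#' @export
setClass("AugmentConfig", representation(
  hue_shift_range = "numeric",
  saturation_range = "numeric",
  value_range = "numeric",
  contrast_range = "numeric",
  p_flip_h = "numeric",
  p_flip_v = "numeric",
  max_shift_px = "integer",
  p_blur = "numeric",
  p_sharpen = "numeric",
  blur_sigma_range = "numeric"
))

setValidity("AugmentConfig", function(object) {
  msg <- character()
  probs <- c(object@p_flip_h, object@p_flip_v, object@p_blur, object@p_sharpen)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  for (nm in c("hue_shift_range", "saturation_range", "value_range",
               "contrast_range", "blur_sigma_range")) {
    r <- slot(object, nm)
    if (length(r) != 2L || r[1] > r[2]) msg <- c(msg, paste(nm, "must be an ordered interval"))
  }
  if (object@max_shift_px < 0) msg <- c(msg, "max_shift_px must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an AugmentConfig
#'
#' @param hue_shift_range,saturation_range,value_range,contrast_range
#'   photometric jitter intervals.
#' @param p_flip_h,p_flip_v,p_blur,p_sharpen operation probabilities.
#' @param max_shift_px maximum shift per axis (px).
#' @param blur_sigma_range blur sigma interval (px).
#' @return An [AugmentConfig-class].
#' @examples
#' identityAugment()  # strict no-op configuration
#' @export
augmentConfig <- function(hue_shift_range = c(-15, 15),
                          saturation_range = c(0.8, 1.2),
                          value_range = c(0.8, 1.2),
                          contrast_range = c(0.8, 1.2),
                          p_flip_h = 0.5, p_flip_v = 0.5,
                          max_shift_px = 32L,
                          p_blur = 0.2, p_sharpen = 0.2,
                          blur_sigma_range = c(0.5, 1.5)) {
  new("AugmentConfig", hue_shift_range = hue_shift_range,
      saturation_range = saturation_range, value_range = value_range,
      contrast_range = contrast_range, p_flip_h = p_flip_h,
      p_flip_v = p_flip_v, max_shift_px = as.integer(max_shift_px),
      p_blur = p_blur, p_sharpen = p_sharpen,
      blur_sigma_range = blur_sigma_range)
}

#' @describeIn augmentConfig a configuration under which `enhance()` is a
#'   bit-exact no-op.
#' @export
identityAugment <- function() {
  augmentConfig(hue_shift_range = c(0, 0), saturation_range = c(1, 1),
                value_range = c(1, 1), contrast_range = c(1, 1),
                p_flip_h = 0, p_flip_v = 0, max_shift_px = 0L,
                p_blur = 0, p_sharpen = 0, blur_sigma_range = c(0, 0))
}

#' Sample a concrete transform record
#'
#' Draws one realisation of every augmentation parameter from the config.
#' The record fully determines the effect of [applyAugment()]: replaying it
#' reproduces the augmented image bit-exactly.
#'
#' @param config an [AugmentConfig-class].
#' @param seed integer seed for the draw.
#' @return named list: `flip_h`, `flip_v`, `dx`, `dy`, `hue`, `sat`, `val`,
#'   `contrast`, `blur_sigma` (0 = none), `sharpen` (logical).
#' @export
sampleAugmentParams <- function(config, seed) {
  withSeed(seed, {
    blur <- stats::runif(1) < config@p_blur
    sharpen <- !blur && stats::runif(1) < config@p_sharpen
    list(
      flip_h = stats::runif(1) < config@p_flip_h,
      flip_v = stats::runif(1) < config@p_flip_v,
      dx = if (config@max_shift_px > 0)
        sample(-config@max_shift_px:config@max_shift_px, 1) else 0L,
      dy = if (config@max_shift_px > 0)
        sample(-config@max_shift_px:config@max_shift_px, 1) else 0L,
      hue = stats::runif(1, config@hue_shift_range[1], config@hue_shift_range[2]),
      sat = stats::runif(1, config@saturation_range[1], config@saturation_range[2]),
      val = stats::runif(1, config@value_range[1], config@value_range[2]),
      contrast = stats::runif(1, config@contrast_range[1], config@contrast_range[2]),
      blur_sigma = if (blur)
        stats::runif(1, config@blur_sigma_range[1], config@blur_sigma_range[2]) else 0,
      sharpen = sharpen
    )
  })
}

isIdentityParams <- function(p) {
  !p$flip_h && !p$flip_v && p$dx == 0L && p$dy == 0L && p$hue == 0 &&
    p$sat == 1 && p$val == 1 && p$contrast == 1 && p$blur_sigma == 0 &&
    !p$sharpen
}

shiftImage <- function(img, dx, dy, pad = c(255, 255, 255)) {
  if (dx == 0 && dy == 0) return(img)
  padRegion(img, -dx, -dy, dim(img)[2], dim(img)[1], pad = pad)
}

#' Apply a transform record to an image
#'
#' Operation order: horizontal/vertical flip, shift (edge padded with glass
#' white), hue/saturation/value in HSV, contrast about mid-grey, then blur or
#' sharpen. The image is rounded back to 8-bit after the photometric block
#' and after the noise op, making replay bit-exact. Geometric parameters
#' co-transform annotation coordinates via [transformPoints()]; photometric
#' ones leave geometry untouched.
#'
#' @param image 8-bit RGB array (`h x w x 3`, 0..255).
#' @param params record from [sampleAugmentParams()].
#' @return augmented array, same shape, values in \[0, 255\].
#' @export
applyAugment <- function(image, params) {
  assertRgb(image)
  if (isIdentityParams(params)) return(image)
  out <- image
  if (params$flip_h) out <- out[, dim(out)[2]:1, , drop = FALSE]
  if (params$flip_v) out <- out[dim(out)[1]:1, , , drop = FALSE]
  out <- shiftImage(out, params$dx, params$dy)
  if (params$hue != 0 || params$sat != 1 || params$val != 1) {
    hsv <- rgbToHsvArr(out)
    out <- hsvToRgbArr(hsv$h + params$hue, clamp01(hsv$s * params$sat),
                       clamp01(hsv$v * params$val))
  }
  if (params$contrast != 1) out <- (out - 128) * params$contrast + 128
  out <- round(clamp255(out))
  if (params$blur_sigma > 0) {
    out <- round(clamp255(gaussBlurRgb(out, params$blur_sigma)))
  } else if (params$sharpen) {
    blur <- gaussBlurRgb(out, 1)
    out <- round(clamp255(out + 0.7 * (out - blur)))
  }
  out
}

#' Sample and apply an augmentation
#'
#' Convenience wrapper: `applyAugment(image, sampleAugmentParams(config, seed))`.
#' All randomness comes from `seed`; the global RNG stream is untouched.
#'
#' @param image 8-bit RGB array.
#' @param config an [AugmentConfig-class].
#' @param seed integer seed.
#' @return augmented image.
#' @export
enhance <- function(image, config, seed) {
  applyAugment(image, sampleAugmentParams(config, seed))
}

#' Co-transform annotation coordinates under a transform record
#'
#' Applies exactly the geometric part (flips, then shift) of a record to
#' 0-based point coordinates; photometric parameters do not move points.
#'
#' @param params record from [sampleAugmentParams()].
#' @param pts numeric matrix (n x 2) of (x, y).
#' @param width,height image dimensions in px.
#' @return transformed n x 2 matrix (points may leave the canvas after a
#'   shift; callers decide whether to drop them).
#' @export
transformPoints <- function(params, pts, width, height) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (params$flip_h) pts[, 1] <- (width - 1) - pts[, 1]
  if (params$flip_v) pts[, 2] <- (height - 1) - pts[, 2]
  pts[, 1] <- pts[, 1] + params$dx
  pts[, 2] <- pts[, 2] + params$dy
  pts
}
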