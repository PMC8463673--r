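# Slide I/O: reading/writing rasters with physical scale, resolution
# normalisation to the 0.243 um/px reference level, redundant tile planning,
# and region access in a single coordinate frame.
#
# Coordinate convention (used everywhere): 0-based pixel indices, x rightward,
# y downward, half-open tile extents. Candidate coordinates are stored at the
# 0.243 um/px reference level.

REF_MPP <- 0.243
LR_MPP <- 0.486

#' Write a slide as TIFF with an mpp sidecar
#'
#' Writes an 8-bit RGB TIFF (LZW) and a YAML sidecar (`<path>.yaml` with the
#' `.tif` extension replaced) recording `slide_id` and `mpp`.
#'
#' @param slide a [CytoSlide-class].
#' @param path output path ending in `.tif` or `.tiff`.
#' @export
writeSlide <- function(slide, path) {
  tiff::writeTIFF(slide@pixels / 255, path, bits.per.sample = 8L,
                  compression = "LZW")
  yaml::write_yaml(list(slide_id = slide@slide_id, mpp = slide@mpp),
                   sidecarPath(path))
  invisible(path)
}

sidecarPath <- function(path) paste0(sub("\\.tiff?$", "", path), ".yaml")

#' Read a slide from TIFF or PNG
#'
#' The microns-per-pixel scale is taken from the YAML sidecar when present,
#' else from the `mpp` argument. A slide without any scale information is an
#' error: downstream geometry depends on it.
#'
#' @param path image path (`.tif`/`.tiff`/`.png`).
#' @param mpp explicit scale override (um/px).
#' @param slide_id token; defaults to the file stem.
#' @return A [CytoSlide-class].
#' @export
readSlide <- function(path, mpp = NULL, slide_id = NULL) {
  sc <- sidecarPath(path)
  meta <- if (file.exists(sc)) yaml::read_yaml(sc) else list()
  if (is.null(mpp)) mpp <- meta$mpp
  if (is.null(mpp))
    stop("slide '", path, "' has no mpp metadata; provide a sidecar YAML or ",
         "an explicit mpp override")
  if (is.null(slide_id))
    slide_id <- if (!is.null(meta$slide_id)) meta$slide_id else
      sub("\\.[^.]+$", "", basename(path))
  raw <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), c(dim(raw), 3))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  new("CytoSlide", slide_id = slide_id, mpp = mpp, pixels = raw * 255)
}

#' Read a rectangular region of a slide
#'
#' Out-of-bounds area is filled with the pad colour (default white, the glass
#' background); reads never error on geometry.
#'
#' @param slide a [CytoSlide-class].
#' @param x0,y0 0-based top-left corner, in the slide's own pixel frame.
#' @param w,h region width and height in pixels.
#' @param pad pad colour (RGB, 0..255).
#' @return numeric `h x w x 3` array.
#' @export
readRegion <- function(slide, x0, y0, w, h, pad = c(255, 255, 255)) {
  padRegion(slide@pixels, as.integer(round(x0)), as.integer(round(y0)),
            as.integer(w), as.integer(h), pad)
}

#' Normalise a slide to a target resolution
#'
#' Returns the identity when the slide is already at the target scale;
#' otherwise resamples bilinearly, scaling dimensions by `mpp / target_mpp`
#' (rounded to nearest integer). Normalisation is idempotent.
#'
#' @param slide a [CytoSlide-class] with known mpp.
#' @param target_mpp target microns per pixel (default the 0.243 reference).
#' @return A [CytoSlide-class] at `target_mpp`.
#' @export
normalizeResolution <- function(slide, target_mpp = REF_MPP) {
  if (isTRUE(all.equal(slide@mpp, target_mpp))) return(slide)
  f <- slide@mpp / target_mpp
  new_h <- as.integer(round(slideHeight(slide) * f))
  new_w <- as.integer(round(slideWidth(slide) * f))
  new("CytoSlide", slide_id = slide@slide_id, mpp = target_mpp,
      pixels = resizeRgb(slide@pixels, new_h, new_w))
}

clampedStarts <- function(extent, tile, stride) {
  if (extent <= tile) return(0L)
  s <- seq.int(0L, extent - tile, by = stride)
  if (max(s) + tile < extent) s <- c(s, extent - tile)
  as.integer(s)
}

#' Plan the redundant tile division of a slide
#'
#' Tile origins step by `tile_px - overlap_px`; the last row/column is
#' clamped inward to the boundary so every tile has the full shape and every
#' pixel is covered. A slide smaller than one tile yields a single padded
#' tile at the origin.
#'
#' @param slide a [CytoSlide-class].
#' @param tile_px tile side length (default 512).
#' @param tile_mpp sampling resolution of the tiles (default 0.486 um/px).
#' @param overlap_px overlap between adjacent tiles (default 25% of the tile).
#' @return A [TileGrid-class].
#' @examples
#' s <- new("CytoSlide", slide_id = "s", mpp = 0.486,
#'          pixels = array(255, c(1024, 1024, 3)))
#' nTiles(planTiles(s, 512, 0.486, overlap_px = 0))  # 4
#' @export
planTiles <- function(slide, tile_px = 512, tile_mpp = LR_MPP,
                      overlap_px = tile_px %/% 4) {
  if (overlap_px < 0 || overlap_px >= tile_px)
    stop("need tile_px > overlap_px >= 0")
  f <- slide@mpp / tile_mpp
  ext_w <- max(1L, as.integer(round(slideWidth(slide) * f)))
  ext_h <- max(1L, as.integer(round(slideHeight(slide) * f)))
  stride <- as.integer(tile_px - overlap_px)
  xs <- clampedStarts(ext_w, as.integer(tile_px), stride)
  ys <- clampedStarts(ext_h, as.integer(tile_px), stride)
  origins <- as.matrix(expand.grid(x = xs, y = ys))
  new("TileGrid", tile_px = as.integer(tile_px), tile_mpp = tile_mpp,
      stride_px = stride, origins = origins,
      extent_px = c(ext_w, ext_h))
}

#' Read one tile of a grid
#'
#' Returns the `tile_px` square at the indexed origin, sampled at the grid's
#' resolution. If the slide is not stored at `tile_mpp` it is resampled
#' first (callers that read many tiles should pre-normalise once with
#' [normalizeResolution()]). Out-of-bounds area is padded.
#'
#' @param slide a [CytoSlide-class].
#' @param grid a [TileGrid-class] planned on this slide.
#' @param index tile index in `1..nTiles(grid)`.
#' @param pad pad colour.
#' @return numeric `tile_px x tile_px x 3` array.
#' @export
readTile <- function(slide, grid, index, pad = c(255, 255, 255)) {
  if (index < 1 || index > nTiles(grid))
    stop("tile index ", index, " out of range for slide '", slide@slide_id, "'")
  at_level <- normalizeResolution(slide, grid@tile_mpp)
  o <- grid@origins[index, ]
  readRegion(at_level, o[1], o[2], grid@tile_px, grid@tile_px, pad = pad)
}

#' Crop a square region centred on a base-level coordinate
#'
#' The centre lands on pixel index `crop_px / 2` (0-based) of the crop.
#' Borders are padded, so any finite centre is valid.
#'
#' @param slide a [CytoSlide-class] at the 0.243 um/px reference level.
#' @param center numeric (x, y) at the reference level.
#' @param crop_px crop side length (default 256, a ~62 um field).
#' @param pad pad colour.
#' @return numeric `crop_px x crop_px x 3` array.
#' @export
cropAt <- function(slide, center, crop_px = 256, pad = c(255, 255, 255)) {
  if (any(!is.finite(center))) stop("crop centre must be finite")
  slide <- normalizeResolution(slide, REF_MPP)
  half <- crop_px %/% 2
  readRegion(slide, round(center[1]) - half, round(center[2]) - half,
             crop_px, crop_px, pad = pad)
}

# Map a tile-local coordinate at tile_mpp to the base-level frame.
tileToBase <- function(xy_tile, origin, tile_mpp, ref_mpp = REF_MPP) {
  (xy_tile + origin) * tile_mpp / ref_mpp
}
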