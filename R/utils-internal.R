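# Shared internal helpers: seeded RNG scoping, colour-space conversion and
# raster plumbing. Rasters are numeric arrays dim c(height, width, 3) holding
# 8-bit intensities in [0, 255]; pixel coordinates are 0-based, x rightward,
# y downward.

clamp01 <- function(x) pmin(pmax(x, 0), 1)
clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Evaluate `code` under a temporary RNG state seeded deterministically,
# restoring the caller's stream afterwards.
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a parent seed and string/integer tokens.
# Stays inside 32-bit integer range.
subSeed <- function(seed, ...) {
  tokens <- unlist(lapply(list(...), function(t) {
    if (is.character(t)) utf8ToInt(t) else as.integer(t)
  }))
  h <- as.double(seed) %% 2147483647
  for (t in tokens) h <- (h * 31 + (as.double(t) %% 1000003)) %% 2147483647
  as.integer(max(1, h))
}

isRgbArray <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L && is.numeric(img)
}

assertRgb <- function(img, what = "image") {
  if (!isRgbArray(img)) {
    stop(what, " must be a numeric height x width x 3 RGB array", call. = FALSE)
  }
  invisible(TRUE)
}

# RGB array [0,255] -> list(h (degrees 0..360), s, v in [0,1]), each h x w.
# Vectorised hexcone transform (equivalent to grDevices::rgb2hsv, but fast
# enough for full-slide rasters).
rgbToHsvArr <- function(img) {
  r <- img[, , 1] / 255; g <- img[, , 2] / 255; b <- img[, , 3] / 255
  v <- pmax(r, pmax(g, b))
  mn <- pmin(r, pmin(g, b))
  delta <- v - mn
  s <- delta / pmax(v, 1e-12)
  dsafe <- pmax(delta, 1e-12)
  h <- matrix(0, nrow(r), ncol(r))
  idx <- delta > 0 & v == r
  h[idx] <- ((g - b) / dsafe)[idx] %% 6
  idx <- delta > 0 & v == g & v != r
  h[idx] <- ((b - r) / dsafe)[idx] + 2
  idx <- delta > 0 & v == b & v != r & v != g
  h[idx] <- ((r - g) / dsafe)[idx] + 4
  list(h = h * 60, s = s, v = v)
}

# Inverse hexcone transform, vectorised over matrices; returns [0,255] array.
# Channel formula: c_n = v - v*s*clamp(min(k, 4-k), 0, 1), k = (n + h/60) mod 6.
hsvToRgbArr <- function(h, s, v) {
  hh <- (h / 60) %% 6
  vs <- v * s
  chan <- function(n) {
    k <- (n + hh) %% 6
    v - vs * pmin(pmax(pmin(k, 4 - k), 0), 1)
  }
  out <- array(0, c(dim(h), 3))
  out[, , 1] <- chan(5)
  out[, , 2] <- chan(3)
  out[, , 3] <- chan(1)
  out * 255
}

# Value channel (max of RGB), in [0,1].
valueChannel <- function(img) {
  pmax(img[, , 1], pmax(img[, , 2], img[, , 3])) / 255
}

saturationChannel <- function(img) {
  mx <- pmax(img[, , 1], pmax(img[, , 2], img[, , 3]))
  mn <- pmin(img[, , 1], pmin(img[, , 2], img[, , 3]))
  s <- (mx - mn) / pmax(mx, 1e-9)
  s[mx == 0] <- 0
  s
}

# EBImage bridges ---------------------------------------------------------

asEB <- function(img) {
  EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
}

fromEB <- function(eb) {
  aperm(EBImage::imageData(eb), c(2, 1, 3)) * 255
}

# Bilinear resize of an RGB array to new_h x new_w.
resizeRgb <- function(img, new_h, new_w) {
  if (dim(img)[1] == new_h && dim(img)[2] == new_w) return(img)
  out <- fromEB(EBImage::resize(asEB(img), w = new_w, h = new_h))
  clamp255(out)
}

resizeMat <- function(m, new_h, new_w) {
  if (nrow(m) == new_h && ncol(m) == new_w) return(m)
  t(EBImage::imageData(EBImage::resize(EBImage::Image(t(m)), w = new_w, h = new_h)))
}

# Gaussian blur of a matrix with replicated borders.
gaussBlurMat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  t(EBImage::imageData(EBImage::filter2(EBImage::Image(t(m)), brush,
                                        boundary = "replicate")))
}

gaussBlurRgb <- function(img, sigma) {
  if (sigma <= 0) return(img)
  d <- dim(img)
  if (prod(d[1:2]) > 1e6) {
    # full-slide defocus: blur a half-resolution pyramid level and upsample;
    # the bilinear kernels contribute the residual smoothing
    small <- resizeRgb(img, d[1] %/% 2, d[2] %/% 2)
    for (ch in 1:3) small[, , ch] <- gaussBlurMat(small[, , ch], sigma / 2)
    return(resizeRgb(small, d[1], d[2]))
  }
  for (ch in 1:3) img[, , ch] <- gaussBlurMat(img[, , ch], sigma)
  img
}

# Extract a region with constant padding. x0/y0 are 0-based top-left
# coordinates; region may extend outside the array.
padRegion <- function(img, x0, y0, w, h, pad = c(255, 255, 255)) {
  d <- dim(img)
  out <- array(0, c(h, w, 3))
  for (ch in 1:3) out[, , ch] <- pad[ch]
  # overlap with source, in 0-based coords
  sx0 <- max(x0, 0); sy0 <- max(y0, 0)
  sx1 <- min(x0 + w, d[2]); sy1 <- min(y0 + h, d[1])
  if (sx1 > sx0 && sy1 > sy0) {
    out[(sy0 - y0 + 1):(sy1 - y0), (sx0 - x0 + 1):(sx1 - x0), ] <-
      img[(sy0 + 1):sy1, (sx0 + 1):sx1, , drop = FALSE]
  }
  out
}

# 8-connected component labelling of a binary matrix. Small masks only.
labelComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nlab <- 0L
  fg <- which(mask > 0)
  if (length(fg) == 0) return(lab)
  stack <- integer(h * w)
  for (start in fg) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    sp <- 1L
    stack[1L] <- start
    lab[start] <- nlab
    while (sp > 0L) {
      cur <- stack[sp]; sp <- sp - 1L
      cy <- ((cur - 1L) %% h) + 1L
      cx <- ((cur - 1L) %/% h) + 1L
      for (dy in -1:1) for (dx in -1:1) {
        ny <- cy + dy; nx <- cx + dx
        if (ny >= 1L && ny <= h && nx >= 1L && nx <= w) {
          idx <- (nx - 1L) * h + ny
          if (mask[idx] > 0 && lab[idx] == 0L) {
            lab[idx] <- nlab
            sp <- sp + 1L
            stack[sp] <- idx
          }
        }
      }
    }
  }
  lab
}

# Pool a matrix into (nrow/bs) x (ncol/bs) blocks; returns list(mean, max).
# Matrix dimensions must be multiples of bs.
poolBlocks <- function(m, bs) {
  h <- nrow(m); w <- ncol(m)
  ncy <- h %/% bs; ncx <- w %/% bs
  x <- array(m[seq_len(ncy * bs), seq_len(ncx * bs)], c(bs, ncy, ncx * bs))
  meanY <- colMeans(x)                       # ncy x (ncx*bs)
  maxY <- x[1, , ]
  if (bs > 1) for (i in 2:bs) maxY <- pmax(maxY, x[i, , ])
  # now pool along x: reshape (ncy, bs, ncx)
  a1 <- array(t(meanY), c(bs, ncx, ncy))
  mean2 <- t(colMeans(a1))                   # ncy x ncx
  a2 <- array(t(maxY), c(bs, ncx, ncy))
  max2 <- a2[1, , ]
  if (bs > 1) for (i in 2:bs) max2 <- pmax(max2, a2[i, , ])
  list(mean = mean2, max = t(max2))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
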