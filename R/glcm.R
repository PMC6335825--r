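# GLCM texture stage: 8-bit quantization, background subtraction, the
# co-occurrence matrix within a cell mask, and the three texture
# statistics: angular second moment (ASM), inverse difference moment (IDM)
# and entropy.

#' Quantize a raster to 8-bit gray levels
#'
#' Maps gray value v to \code{floor(255 * (clip(v, lo, hi) - lo) / (hi - lo))}
#' so \code{lo} maps to 0 and \code{hi} to 255; values outside the window
#' are clipped. The window defaults to the acquisition gray range rather
#' than the full bit range: 0-16000 for 16-bit and 0-4000 for 14-bit
#' acquisitions (the camera's linear range), 0-255 for 8-bit.
#'
#' @param raster numeric matrix of gray values.
#' @param window numeric(2), \code{c(lo, hi)} with \code{lo < hi}.
#' @return integer matrix with values in 0..255; the window and the source
#'   range are attached as attributes \code{"window"} and
#'   \code{"sourceRange"}.
#' @examples
#' quantizeTo8bit(matrix(c(0, 8000, 16000, 20000), 2), c(0, 16000))
#' @export
quantizeTo8bit <- function(raster, window = c(0, 16000)) {
  if (length(window) != 2L || window[2] <= window[1])
    stop("quantizeTo8bit: invalid window (need lo < hi)")
  src <- range(raster)
  v <- pmin(pmax(raster, window[1]), window[2])
  q <- floor(255 * (v - window[1]) / (window[2] - window[1]))
  q <- matrix(as.integer(pmin(q, 255L)), nrow(raster), ncol(raster))
  attr(q, "window") <- window
  attr(q, "sourceRange") <- src
  q
}

#' Acquisition gray ceiling for a camera bit depth
#'
#' The gray range used at acquisition to stay in the camera's linear range:
#' 16000 for 16-bit, 4000 for 14-bit, 255 for 8-bit.
#'
#' @param bitDepth 8, 14 or 16.
#' @return numeric(1) ceiling gray value.
#' @export
acquisitionCeiling <- function(bitDepth) {
  switch(as.character(bitDepth),
         "16" = 16000, "14" = 4000, "8" = 255,
         stop("acquisitionCeiling: unsupported bit depth ", bitDepth))
}

#' Subtract the background level from a raster
#'
#' Estimates a single background gray level -- the histogram mode of the
#' rounded values, or a given percentile -- over the pixels outside the ROI
#' if a mask is supplied, else over the whole frame, subtracts it, and
#' floors negative results at zero. Ties (mode or percentile) break toward
#' the lower gray value.
#'
#' @param raster numeric matrix.
#' @param method \code{"mode"} or \code{"percentile"}.
#' @param param percentile in [0, 100] (only for \code{method =
#'   "percentile"}; default 50).
#' @param roiMask optional logical matrix; background is estimated over
#'   \code{!roiMask}.
#' @return matrix of the same shape, background removed; the estimated
#'   level is attached as attribute \code{"background"}.
#' @examples
#' subtractBackground(matrix(50, 4, 4) + diag(4) * 200)
#' @export
subtractBackground <- function(raster, method = c("mode", "percentile"),
                               param = 50, roiMask = NULL) {
  method <- match.arg(method)
  if (!length(raster)) stop("subtractBackground: empty raster")
  pool <- if (!is.null(roiMask)) {
    if (!identical(dim(roiMask), dim(raster)))
      stop("subtractBackground: roiMask shape mismatch")
    bgpx <- raster[!roiMask]
    if (length(bgpx)) bgpx else as.vector(raster)
  } else as.vector(raster)
  bg <- if (method == "mode") {
    v <- round(pool)
    tab <- table(v)  # names sorted ascending: which.max ties -> lower value
    as.numeric(names(tab)[which.max(tab)])
  } else {
    if (param < 0 || param > 100)
      stop("subtractBackground: percentile must lie in [0, 100]")
    as.numeric(quantile(pool, param / 100, type = 1, names = FALSE))
  }
  out <- raster - bg
  out[out < 0] <- 0
  attr(out, "background") <- bg
  out
}

#' Compute the gray-level co-occurrence matrix within a mask
#'
#' Counts ordered gray-level pairs at pixel offset (dx, dy) -- pixel (x, y)
#' paired with (x + dx, y + dy) -- over all pairs with BOTH endpoints inside
#' the mask, and normalizes by the pair count. The default offset (1, 0) is
#' the 0-degree direction at step size 1 pixel. The matrix is directed
#' (asymmetric) unless \code{symmetric = TRUE}, which accumulates both
#' orientations before normalizing.
#'
#' Masked counting keeps background pixels outside the traced outline from
#' inflating homogeneity. Gray levels are not re-binned below 256.
#'
#' @param img integer matrix with values 0..255 (see [quantizeTo8bit()]).
#' @param mask logical matrix of the same shape; \code{NULL} means the
#'   whole frame.
#' @param offset integer(2), (dx, dy) in pixels.
#' @param symmetric logical; symmetrize before normalization.
#' @return a [CooccurrenceMatrix-class].
#' @examples
#' img <- rbind(c(0L, 0L), c(255L, 255L))
#' computeGLCM(img, offset = c(1L, 0L))  # p(0,0) = p(255,255) = 0.5
#' @export
computeGLCM <- function(img, mask = NULL, offset = c(1L, 0L),
                        symmetric = FALSE) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  if (!identical(dim(mask), dim(img)))
    stop("computeGLCM: mask shape mismatch")
  if (min(img) < 0L || max(img) > 255L)
    stop("computeGLCM: img must hold 8-bit levels 0..255")
  dx <- as.integer(offset[1]); dy <- as.integer(offset[2])
  if (dx == 0L && dy == 0L) stop("computeGLCM: offset must be nonzero")
  nr <- nrow(img); nc <- ncol(img)
  rs <- max(1L, 1L - dy):min(nr, nr - dy)
  cs <- max(1L, 1L - dx):min(nc, nc - dx)
  if (!length(rs) || !length(cs))
    stop("computeGLCM: degenerate mask (no valid pixel pair at this offset)")
  both <- mask[rs, cs, drop = FALSE] & mask[rs + dy, cs + dx, drop = FALSE]
  n <- sum(both)
  if (n < 1L)
    stop("computeGLCM: degenerate mask (no valid pixel pair at this offset)")
  i <- img[rs, cs, drop = FALSE][both]
  j <- img[rs + dy, cs + dx, drop = FALSE][both]
  counts <- tabulate(i * 256L + j + 1L, nbins = 65536L)
  if (symmetric) {
    counts <- counts + tabulate(j * 256L + i + 1L, nbins = 65536L)
    n <- 2L * n
  }
  p <- matrix(counts / n, 256L, 256L, byrow = TRUE)
  new("CooccurrenceMatrix", p = p, offset = c(dx, dy), nPairs = as.numeric(n))
}

# 1/(1 + (i-j)^2) weights, computed once
.idmWeights <- local({
  w <- NULL
  function() {
    if (is.null(w)) {
      lv <- 0:255
      w <<- 1 / (1 + outer(lv, lv, "-")^2)
    }
    w
  }
})

#' Texture statistics of a co-occurrence matrix
#'
#' Angular second moment \code{sum(p^2)} (high when few gray-level pairs
#' dominate), inverse difference moment \code{sum(p / (1 + (i - j)^2))}
#' (high when co-occurring levels are similar), and entropy
#' \code{-sum(p * log(p))} in nats with the convention 0 log 0 = 0 (high
#' for heterogeneous signal).
#'
#' @param m a [CooccurrenceMatrix-class], or a bare numeric matrix summing
#'   to 1 whose rows/columns are gray levels starting at 0.
#' @return named numeric: \code{asm}, \code{idm}, \code{entropy},
#'   \code{n_pairs}.
#' @examples
#' img <- rbind(c(0L, 0L), c(255L, 255L))
#' textureFeatures(computeGLCM(img))  # asm 0.5, idm 1, entropy log(2)
#' @export
textureFeatures <- function(m) {
  nPairs <- NA_real_
  if (is(m, "CooccurrenceMatrix")) {
    nPairs <- m@nPairs
    p <- m@p
  } else {
    p <- as.matrix(m)
  }
  if (abs(sum(p) - 1) > 1e-6)
    stop("textureFeatures: invalid matrix (probabilities must sum to 1)")
  if (any(p < 0))
    stop("textureFeatures: invalid matrix (negative probability)")
  w <- if (identical(dim(p), c(256L, 256L))) .idmWeights() else {
    lv <- seq_len(nrow(p)) - 1
    1 / (1 + outer(lv, lv, "-")^2)
  }
  nz <- p > 0
  c(asm = sum(p^2),
    idm = sum(p * w),
    entropy = -sum(p[nz] * log(p[nz])),
    n_pairs = nPairs)
}
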