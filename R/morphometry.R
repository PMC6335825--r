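# Morphometry stage: inward membrane-distance shells, per-shell integrated
# density fractions, and the two shape descriptors (circularity, solidity).

#' Partition a cell mask into inward membrane-distance shells
#'
#' Computes the inward Euclidean distance transform from the mask's outer
#' boundary (the background-adjacent edge) and assigns every ROI pixel to a
#' band: pixel in band k iff \code{edge[k-1] < d <= edge[k]} nm, with a
#' final \code{d > edge[K]} band. Boundary pixels take d = half a pixel
#' (sub-pixel exactness being unattainable, the half-pixel convention is
#' symmetric), so \code{d_nm = (EDT_px - 0.5) * pixelSize * 1000}.
#'
#' The default edges 100/300/500/700 nm are cumulative distances from the
#' traced boundary (band thicknesses 100, 200, 200, 200 nm) plus the
#' remaining \code{> 700} nm interior.
#'
#' @param mask logical (or 0/1) matrix, the ROI mask; must not be empty.
#'   The mask should not touch the raster border (rasterized outlines from
#'   [polygonToMask()] never do).
#' @param pixelSizeUm pixel size in micrometres.
#' @param edgesNm strictly increasing band edges in nanometres.
#' @return a [ShellSet-class].
#' @examples
#' m <- matrix(FALSE, 40, 40); m[11:30, 11:30] <- TRUE
#' shells <- inwardShells(m, 0.03)
#' sapply(shellMasks(shells), sum)
#' @export
inwardShells <- function(mask, pixelSizeUm, edgesNm = c(100, 300, 500, 700)) {
  mask <- mask > 0
  if (!any(mask)) stop("inwardShells: degenerate (empty) mask")
  if (length(edgesNm) < 1L || any(diff(edgesNm) <= 0))
    stop("inwardShells: edges must be strictly increasing")
  d <- EBImage::distmap(mask * 1)  # exact Euclidean, in pixels
  dNm <- (d - 0.5) * pixelSizeUm * 1000
  labels <- matrix(0L, nrow(mask), ncol(mask))
  inside <- which(mask)
  labels[inside] <- findInterval(dNm[inside], edgesNm, left.open = TRUE) + 1L
  new("ShellSet", labels = labels, edgesNm = as.numeric(edgesNm),
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Integrated density fraction per membrane-distance shell
#'
#' The integrated density (sum of gray values) of the signal is computed in
#' the total ROI and within each band; each band's sum is reported as a
#' fraction of the ROI total. Fractions are scale-invariant, so raw (not
#' 8-bit-quantized) intensities are the natural input.
#'
#' @param img numeric matrix, same shape as the shell rasters.
#' @param shells a [ShellSet-class].
#' @return named numeric vector of per-band fractions (innermost-distance
#'   band first), summing to 1.
#' @examples
#' m <- matrix(FALSE, 40, 40); m[11:30, 11:30] <- TRUE
#' img <- matrix(1, 40, 40)
#' densityFractions(img, inwardShells(m, 0.03))
#' @export
densityFractions <- function(img, shells) {
  stopifnot(is(shells, "ShellSet"))
  labels <- shells@labels
  if (!identical(dim(img), dim(labels)))
    stop("densityFractions: image shape does not match shells")
  nb <- length(shells@edgesNm) + 1L
  inside <- labels > 0L
  total <- sum(img[inside])
  if (total <= 0)
    stop("densityFractions: zero signal in ROI")
  sums <- vapply(seq_len(nb), function(k) sum(img[labels == k]), numeric(1))
  setNames(sums / total, .bandNames(shells@edgesNm))
}

# Moore-neighbour boundary trace of the single foreground component.
# Returns the clockwise 8-chain codes and the boundary pixel coordinates.
# Jacob's stopping criterion: stop upon re-entering the start pixel from
# the initial backtrack direction.
.traceBoundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  idx <- which(p, arr.ind = TRUE)
  o <- order(idx[, 2], idx[, 1])
  s <- as.integer(idx[o[1L], ])
  # neighbour order clockwise starting W: W NW N NE E SE S SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  maxSteps <- 8L * nrow(idx) + 8L
  chain <- integer(0)
  px <- integer(0); py <- integer(0)
  cur <- s; b <- 1L  # search starts at the W neighbour (background for s)
  second <- NULL
  steps <- 0L
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- (b - 1L + k) %% 8L + 1L
      r2 <- cur[1L] + dr[d]; c2 <- cur[2L] + dc[d]
      if (p[r2, c2]) {
        # Jacob stopping criterion: the move out of the start pixel
        # repeats -> the cycle is closed
        if (!is.null(second) && cur[1L] == s[1L] && cur[2L] == s[2L] &&
            r2 == second[1L] && c2 == second[2L])
          return(list(chain = chain, x = px, y = py, start = s - 1L))
        chain <- c(chain, d)
        px <- c(px, c2 - 1L); py <- c(py, r2 - 1L)
        # next search starts one step clockwise past the backtrack
        # direction (opposite of d) as seen from the new pixel
        b <- (d - 1L + 5L) %% 8L + 1L
        cur <- c(r2, c2)
        if (is.null(second)) second <- cur
        found <- TRUE
        break
      }
    }
    steps <- steps + 1L
    if (!found || steps > maxSteps) break  # isolated pixel / safety cap
  }
  list(chain = chain, x = px, y = py, start = s - 1L)
}

# Perimeter from the chain code: Vossepoel-Smeulders corrected weights
# (0.980 per axial step, 1.406 per diagonal step, -0.091 per corner)
# estimate the pre-digitization boundary through the pixel centres; the
# +pi term accounts for the half-pixel outward offset of the true crack
# boundary relative to the centres (exact for convex shapes).
.chainPerimeter <- function(chain) {
  if (length(chain) < 4L)
    return(NA_real_)
  isDiag <- chain %% 2L == 0L  # W NW N NE E SE S SW -> even idx = diagonal
  ne <- sum(!isDiag); no <- sum(isDiag)
  nc <- sum(chain != c(chain[-1L], chain[1L]))
  0.980 * ne + 1.406 * no - 0.091 * nc + pi
}

#' Shape descriptors of a cell mask
#'
#' Circularity \code{4 * pi * area / perimeter^2} and solidity
#' \code{area / convex hull area}. The perimeter is estimated from the
#' Moore boundary chain with corner-corrected step weights plus a
#' half-pixel offset term (see the methods vignette); the convex hull is
#' taken over the corners of the boundary pixels, so solidity can never
#' exceed 1. Digitization can push circularity of near-circular masks
#' slightly above 1 (tolerance ~0.05).
#'
#' @param mask logical (or 0/1) matrix with exactly one 8-connected
#'   foreground component.
#' @return named numeric: \code{circularity}, \code{solidity},
#'   \code{area_px}, \code{perimeter_px}.
#' @examples
#' m <- outer(1:60, 1:60, function(r, c) (r - 30)^2 + (c - 30)^2 <= 25^2)
#' shapeDescriptors(m)
#' @export
shapeDescriptors <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop("shapeDescriptors: empty mask")
  lab <- .label8(mask)
  ncomp <- max(lab)
  if (ncomp != 1L)
    stop("shapeDescriptors: ambiguous mask (", ncomp,
         " components; expected exactly 1)")
  area <- sum(mask)
  tr <- .traceBoundary(mask)
  per <- .chainPerimeter(tr$chain)
  if (is.na(per))  # too small to trace: circle-equivalent perimeter
    per <- 2 * sqrt(pi * area)
  # convex hull over boundary-pixel corners
  if (length(tr$x)) {
    bx <- tr$x; by <- tr$y
  } else {
    w <- which(mask, arr.ind = TRUE)
    bx <- w[, 2]; by <- w[, 1]
  }
  corners <- cbind(
    x = c(bx - 1, bx, bx - 1, bx),
    y = c(by - 1, by - 1, by, by))
  h <- chull(corners)
  hullArea <- abs(.polygonArea(corners[h, , drop = FALSE]))
  c(circularity = 4 * pi * area / per^2,
    solidity = area / hullArea,
    area_px = area,
    perimeter_px = per)
}
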