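# Bead-uptake stage: spot segmentation, counting in regions, the
# fraction-within-boundary summary, and time-lapse uptake curves.

# Exact 8-connected labeling: 4-connected pass (EBImage::bwlabel) followed
# by union-find over labels that touch diagonally.
.label8 <- function(binary) {
  lab <- EBImage::bwlabel(binary * 1)
  lab <- matrix(as.integer(round(lab)), nrow(binary), ncol(binary))
  nmax <- max(lab)
  if (nmax <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),  # SE diag
    cbind(as.vector(lab[-nr, -1L]), as.vector(lab[-1L, -nc])))  # SW diag
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nmax)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nmax), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  relabel <- c(0L, dense)
  matrix(relabel[lab + 1L], nr, nc)
}

#' Segment beads/lysosomes by thresholding
#'
#' Binarizes the image at \code{img >= threshold} (Otsu-derived over the
#' 8-bit-equivalent histogram if \code{method = "otsu"}), labels
#' 8-connected components, and computes intensity-weighted sub-pixel
#' centroids. An all-background result returns zero components, not an
#' error. Touching beads merge into one component (no declumping).
#'
#' @param img numeric matrix of gray values.
#' @param method \code{"otsu"} (data-driven threshold, fluorescence beads)
#'   or \code{"fixed"} (explicit threshold, e.g. electron-micrograph-style
#'   inputs).
#' @param threshold gray level; required for \code{method = "fixed"}.
#' @return a [BeadSegmentation-class].
#' @examples
#' img <- matrix(0, 32, 32); img[5:7, 5:7] <- 100; img[20:22, 25:27] <- 120
#' beadCount(segmentSpots(img, method = "fixed", threshold = 50))
#' @export
segmentSpots <- function(img, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  if (!length(img)) stop("segmentSpots: empty image")
  if (method == "otsu") {
    mx <- max(img)
    threshold <- if (mx <= 0) Inf else
      as.numeric(EBImage::otsu(EBImage::Image(img / mx),
                               range = c(0, 1), levels = 256L)) * mx
  } else if (is.null(threshold)) {
    stop("segmentSpots: method = \"fixed\" requires a threshold")
  }
  binary <- img >= threshold
  labels <- if (any(binary)) .label8(binary) else
    matrix(0L, nrow(img), ncol(img))
  ncomp <- max(labels)
  if (ncomp > 0L) {
    idx <- which(labels > 0L)
    w <- img[idx]
    w[w <= 0] <- .Machine$double.eps
    rr <- (idx - 1L) %% nrow(img) + 1L
    cc <- (idx - 1L) %/% nrow(img) + 1L
    g <- labels[idx]
    sw <- tapply(w, g, sum)
    centroids <- data.frame(
      x = as.numeric(tapply(w * (cc - 0.5), g, sum) / sw),
      y = as.numeric(tapply(w * (rr - 0.5), g, sum) / sw),
      intensity = as.numeric(sw))
  } else {
    centroids <- data.frame(x = numeric(0), y = numeric(0),
                            intensity = numeric(0))
  }
  new("BeadSegmentation", binary = binary, labels = labels,
      centroids = centroids, thresholdUsed = as.numeric(threshold))
}

#' Count segmented beads inside the cytoplasm and the membrane band
#'
#' A component is counted in a region iff its intensity-weighted centroid
#' falls in a pixel of that region's mask (membership by centroid, not by
#' any-overlap, so beads spanning band edges are assigned unambiguously).
#'
#' @param seg a [BeadSegmentation-class].
#' @param roiMask logical matrix, the traced cytoplasm mask.
#' @param bandMask logical matrix, the membrane band (e.g. union of shells
#'   within 700 nm); a centroid on the band edge belongs to the band.
#' @return data.frame with \code{n_total_in_roi} and \code{n_in_band}.
#' @export
countInRegions <- function(seg, roiMask, bandMask) {
  stopifnot(is(seg, "BeadSegmentation"))
  if (!identical(dim(roiMask), dim(seg@binary)) ||
      !identical(dim(bandMask), dim(seg@binary)))
    stop("countInRegions: mask shape mismatch")
  cen <- seg@centroids
  if (!nrow(cen))
    return(data.frame(n_total_in_roi = 0L, n_in_band = 0L))
  rr <- pmin(pmax(floor(cen$y) + 1L, 1L), nrow(roiMask))
  cc <- pmin(pmax(floor(cen$x) + 1L, 1L), ncol(roiMask))
  idx <- cbind(rr, cc)
  inRoi <- roiMask[idx]
  inBand <- bandMask[idx] & inRoi
  data.frame(n_total_in_roi = sum(inRoi), n_in_band = sum(inBand))
}

#' Fraction of centroids within a membrane-distance band
#'
#' Among the centroids lying inside the traced outline, the fraction whose
#' inward Euclidean distance to the membrane polygon is at most
#' \code{bandNm} nanometres (closed on the band side: a centroid exactly on
#' the edge counts as inside the band).
#'
#' @param centroids matrix or data.frame with columns x, y (pixel units).
#' @param roi a [CellROI-class].
#' @param bandNm band distance in nanometres (default 700).
#' @return the fraction in [0, 1].
#' @examples
#' roi <- cellROI(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)), 0.03)
#' fractionWithinBoundary(cbind(x = c(5, 50), y = c(5, 50)), roi)
#' @export
fractionWithinBoundary <- function(centroids, roi, bandNm = 700) {
  stopifnot(is(roi, "CellROI"))
  pts <- as.matrix(as.data.frame(centroids)[, c("x", "y")])
  poly <- roiPolygon(roi)
  inside <- .pointsInPolygon(pts, poly)
  if (!any(inside))
    stop("fractionWithinBoundary: no centroid inside the ROI")
  dNm <- .pointsToPolygonDistance(pts[inside, , drop = FALSE], poly) *
    pixelSize(roi) * 1000
  mean(dNm <= bandNm)
}

#' Assemble a time-lapse uptake curve
#'
#' Collates per-frame bead counts into a time series with a first/last
#' summary. No smoothing is applied.
#'
#' @param frames data.frame with columns \code{frame_time_min},
#'   \code{n_total} and optionally \code{n_in_band} (one row per frame,
#'   time-sorted), or a list of such one-row data.frames.
#' @return list with \code{curve} (the collated data.frame), \code{first}
#'   and \code{last} (single-row summaries).
#' @export
uptakeCurve <- function(frames) {
  if (is.data.frame(frames)) df <- frames
  else df <- do.call(rbind, lapply(frames, as.data.frame))
  req <- c("frame_time_min", "n_total")
  if (!all(req %in% names(df)))
    stop("uptakeCurve: frames need columns frame_time_min and n_total")
  if (is.unsorted(df$frame_time_min, strictly = FALSE))
    stop("uptakeCurve: frames must be sorted by time")
  rownames(df) <- NULL
  list(curve = df,
       first = df[1L, , drop = FALSE],
       last = df[nrow(df), , drop = FALSE])
}
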