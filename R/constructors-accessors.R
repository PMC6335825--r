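# Constructors, accessors and show methods.

#' Construct a CellImagePair
#'
#' @param membrane,target numeric matrices of identical shape.
#' @param pixelSizeUm pixel size in micrometres.
#' @param bitDepth camera bit depth (8, 14 or 16).
#' @return a [CellImagePair-class].
#' @export
cellImagePair <- function(membrane, target, pixelSizeUm, bitDepth = 16L) {
  new("CellImagePair", membrane = membrane, target = target,
      pixelSizeUm = as.numeric(pixelSizeUm), bitDepth = as.integer(bitDepth))
}

#' Construct a CellROI
#'
#' @param polygon n x 2 matrix of vertices (columns x, y) in pixel units;
#'   a repeated closing vertex, if present, is dropped.
#' @param pixelSizeUm pixel size in micrometres.
#' @return a [CellROI-class].
#' @export
cellROI <- function(polygon, pixelSizeUm) {
  polygon <- as.matrix(polygon)
  n <- nrow(polygon)
  if (n > 1L && all(polygon[1L, ] == polygon[n, ]))
    polygon <- polygon[-n, , drop = FALSE]
  colnames(polygon) <- c("x", "y")
  new("CellROI", polygon = polygon, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Construct a CellSpec for the synthetic cell generator
#'
#' Defaults mirror superresolution acquisition of brain tissue sections:
#' 1024 x 1024 rasters at 0.030 um/pixel, 16-bit camera with signal kept in
#' its 0-16000 linear range, spots of ~100-200 nm rendered as sigma = 60 nm
#' Gaussians. For live-cell bead imaging use \code{pixelSizeUm = 0.036},
#' \code{bitDepth = 14} and an amplitude inside the 0-4000 range.
#'
#' @param imageSize square raster side in pixels.
#' @param pixelSizeUm pixel size in micrometres.
#' @param membranePolygon n x 2 vertex matrix, or NULL to draw a smoothed
#'   random star-convex contour (radial periodic spline through 12 knots)
#'   from \code{seed}.
#' @param nSpots number of lysosome/bead spots.
#' @param clusteringFraction fraction (phi) of spots placed with inward
#'   membrane distance at most \code{proximalBandNm}; the rest are uniform
#'   over the whole interior.
#' @param proximalBandNm proximal placement band, nanometres.
#' @param spotSigmaNm Gaussian spot standard deviation, nanometres.
#' @param spotAmplitude peak spot gray value before noise.
#' @param bitDepth 8, 14 or 16.
#' @param noiseBackgroundMean,noiseGaussianSd additive Gaussian camera noise
#'   (gray values).
#' @param seed integer random seed.
#' @return a [CellSpec-class].
#' @examples
#' spec <- cellSpec(imageSize = 256, nSpots = 50, seed = 7)
#' sim <- generateCell(spec)
#' @export
cellSpec <- function(imageSize = 1024L, pixelSizeUm = 0.030,
                     membranePolygon = NULL, nSpots = 150L,
                     clusteringFraction = 0.5, proximalBandNm = 700,
                     spotSigmaNm = 60, spotAmplitude = 8000,
                     bitDepth = 16L, noiseBackgroundMean = 100,
                     noiseGaussianSd = 20, seed = 1L) {
  if (is.null(membranePolygon))
    membranePolygon <- matrix(numeric(0), 0L, 2L)
  new("CellSpec",
      imageSize = as.integer(imageSize),
      pixelSizeUm = as.numeric(pixelSizeUm),
      membranePolygon = as.matrix(membranePolygon),
      nSpots = as.integer(nSpots),
      clusteringFraction = as.numeric(clusteringFraction),
      proximalBandNm = as.numeric(proximalBandNm),
      spotSigmaNm = as.numeric(spotSigmaNm),
      spotAmplitude = as.numeric(spotAmplitude),
      bitDepth = as.integer(bitDepth),
      noiseBackgroundMean = as.numeric(noiseBackgroundMean),
      noiseGaussianSd = as.numeric(noiseGaussianSd),
      seed = as.integer(seed))
}

#' @describeIn cellImagePair membrane channel raster.
#' @param object,x a package object.
#' @export
membraneChannel <- function(object) object@membrane

#' @describeIn cellImagePair target channel raster.
#' @export
targetChannel <- function(object) object@target

#' Pixel size accessor
#' @param object a CellImagePair, CellROI, CellSpec or ShellSet.
#' @return pixel size in micrometres.
#' @export
pixelSize <- function(object) object@pixelSizeUm

#' Bit depth accessor
#' @param object a CellImagePair or CellSpec.
#' @export
bitDepth <- function(object) object@bitDepth

#' @describeIn cellROI polygon vertex matrix.
#' @param object a CellROI.
#' @export
roiPolygon <- function(object) object@polygon

#' Co-occurrence probability table accessor
#' @param object a [CooccurrenceMatrix-class].
#' @return 256 x 256 probability matrix.
#' @export
glcmProbabilities <- function(object) object@p

#' @describeIn glcmProbabilities the (dx, dy) offset.
#' @export
glcmOffset <- function(object) object@offset

#' @describeIn glcmProbabilities number of contributing pixel pairs.
#' @export
glcmPairCount <- function(object) object@nPairs

#' Shell masks accessor
#'
#' @param object a [ShellSet-class].
#' @return named list of logical band masks, innermost-distance band first;
#'   pairwise disjoint, union equal to the ROI mask.
#' @export
shellMasks <- function(object) {
  nb <- length(object@edgesNm) + 1L
  out <- lapply(seq_len(nb), function(k) object@labels == k)
  names(out) <- .bandNames(object@edgesNm)
  out
}

#' @describeIn shellMasks band edges in nanometres.
#' @export
shellEdges <- function(object) object@edgesNm

#' @describeIn shellMasks band label raster (0 outside ROI).
#' @export
shellLabels <- function(object) object@labels

#' @describeIn segmentSpots component centroid table (x, y, intensity).
#' @param object a [BeadSegmentation-class].
#' @export
beadCentroids <- function(object) object@centroids

#' @describeIn segmentSpots number of segmented components.
#' @export
beadCount <- function(object) nrow(object@centroids)

#' @describeIn segmentSpots gray-level threshold that was applied.
#' @export
beadThreshold <- function(object) object@thresholdUsed

.bandNames <- function(edgesNm) {
  lo <- c(0, edgesNm)
  hi <- c(edgesNm, Inf)
  ifelse(is.finite(hi),
         sprintf("(%g,%g]nm", lo, hi),
         sprintf(">%gnm", lo))
}

setMethod("show", "CellImagePair", function(object) {
  d <- dim(object@membrane)
  cat("CellImagePair:", d[1], "x", d[2], "px,",
      object@pixelSizeUm, "um/px,", object@bitDepth, "bit\n")
  cat("  membrane range:", paste(round(range(object@membrane), 1),
                                 collapse = "-"), "\n")
  cat("  target range:  ", paste(round(range(object@target), 1),
                                 collapse = "-"), "\n")
})

setMethod("show", "CellROI", function(object) {
  cat("CellROI:", nrow(object@polygon), "vertices,",
      "area", round(abs(.polygonArea(object@polygon)), 1), "px^2,",
      object@pixelSizeUm, "um/px\n")
})

setMethod("show", "CellSpec", function(object) {
  cat("CellSpec:", object@imageSize, "px,", object@pixelSizeUm, "um/px,",
      object@bitDepth, "bit, seed", object@seed, "\n")
  cat("  spots:", object@nSpots,
      sprintf("(phi = %.2f proximal within %g nm, sigma %g nm)",
              object@clusteringFraction, object@proximalBandNm,
              object@spotSigmaNm), "\n")
  cat("  membrane:",
      if (nrow(object@membranePolygon))
        paste(nrow(object@membranePolygon), "vertices")
      else "auto star-convex contour", "\n")
})

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat("CooccurrenceMatrix: offset (", paste(object@offset, collapse = ","),
      "), ", object@nPairs, " pairs, ",
      sum(object@p > 0), " nonzero cells\n", sep = "")
})

setMethod("show", "ShellSet", function(object) {
  cat("ShellSet:", length(object@edgesNm) + 1L, "bands at edges",
      paste(object@edgesNm, collapse = "/"), "nm;",
      sum(object@labels > 0L), "ROI pixels\n")
})

setMethod("show", "BeadSegmentation", function(object) {
  cat("BeadSegmentation:", nrow(object@centroids), "components,",
      "threshold", round(object@thresholdUsed, 2), "\n")
})
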