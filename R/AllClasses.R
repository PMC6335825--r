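# Central S4 containers. Rasters are plain numeric/integer matrices indexed
# [row, col] = [y, x]; the centre of pixel (r, c) sits at (x, y) =
# (c - 0.5, r - 0.5) in pixel units, so a polygon vertex at integer
# coordinates lies on pixel corners. Polygons are n x 2 matrices with
# columns x, y; the last vertex is NOT repeated (closure is implicit).

#' CellImagePair: registered dual-channel cell image
#'
#' Holds a membrane-marker raster and a target (lysosome/bead) raster of
#' identical shape, with the pixel size and camera bit depth they were
#' acquired (or simulated) at.
#'
#' @slot membrane numeric matrix, membrane channel gray values.
#' @slot target numeric matrix, target channel gray values.
#' @slot pixelSizeUm numeric(1), pixel size in micrometres.
#' @slot bitDepth integer(1), one of 8, 14, 16; gray values must lie in
#'   \code{[0, 2^bitDepth - 1]}.
#'
#' @seealso [cellImagePair()], [generateCell()]
#' @exportClass CellImagePair
setClass("CellImagePair",
  representation(
    membrane = "matrix",
    target = "matrix",
    pixelSizeUm = "numeric",
    bitDepth = "integer"
  )
)

setValidity("CellImagePair", function(object) {
  msg <- character(0)
  if (!identical(dim(object@membrane), dim(object@target)))
    msg <- c(msg, "membrane and target channels must have identical shape")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (!(object@bitDepth %in% c(8L, 14L, 16L)))
    msg <- c(msg, "bitDepth must be 8, 14 or 16")
  mx <- 2^object@bitDepth - 1
  rng <- range(object@membrane, object@target)
  if (rng[1] < 0 || rng[2] > mx)
    msg <- c(msg, sprintf("gray values must lie in [0, %d]", mx))
  if (length(msg)) msg else TRUE
})

#' CellROI: traced cell outline
#'
#' A closed simple polygon traced over the membrane signal, in pixel
#' coordinates, together with the pixel size. The polygon is stored without
#' the repeated closing vertex.
#'
#' @slot polygon n x 2 numeric matrix (columns x, y), a simple polygon with
#'   positive area.
#' @slot pixelSizeUm numeric(1), pixel size in micrometres.
#'
#' @seealso [cellROI()], [polygonToMask()]
#' @exportClass CellROI
setClass("CellROI",
  representation(polygon = "matrix", pixelSizeUm = "numeric")
)

setValidity("CellROI", function(object) {
  msg <- character(0)
  p <- object@polygon
  if (ncol(p) != 2L || nrow(p) < 3L)
    msg <- c(msg, "polygon must be an n x 2 matrix with n >= 3")
  else {
    if (abs(.polygonArea(p)) <= 0)
      msg <- c(msg, "polygon has zero area")
    if (!.polygonIsSimple(p))
      msg <- c(msg, "polygon is self-intersecting")
  }
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' CellSpec: parameters of the synthetic cell forward model
#'
#' Describes one simulated dual-channel cell: raster geometry, membrane
#' contour, number of lysosome/bead spots, the mixture weight between
#' membrane-proximal and interior-uniform spot placement, spot rendering
#' parameters, camera noise, and the random seed.
#'
#' @slot imageSize integer(1), square raster side in pixels.
#' @slot pixelSizeUm numeric(1), pixel size in micrometres.
#' @slot membranePolygon n x 2 matrix of vertices, or a 0-row matrix meaning
#'   "draw a smoothed random star-convex contour from the seed".
#' @slot nSpots integer(1), number of lysosome/bead spots.
#' @slot clusteringFraction numeric(1) in [0, 1]; fraction of spots placed
#'   membrane-proximally (inward distance <= \code{proximalBandNm}), the
#'   remainder uniform over the whole interior.
#' @slot proximalBandNm numeric(1), maximal membrane distance for proximal
#'   placement, in nanometres.
#' @slot spotSigmaNm numeric(1), Gaussian spot standard deviation in nm
#'   (approximates a 100-200 nm object imaged at ~130 nm resolution).
#' @slot spotAmplitude numeric(1), peak gray value of a spot before noise.
#' @slot bitDepth integer(1), 8, 14 or 16.
#' @slot noiseBackgroundMean,noiseGaussianSd numeric(1), additive Gaussian
#'   camera noise parameters (gray values).
#' @slot seed integer(1), random seed; identical specs with identical seeds
#'   produce bit-identical output.
#'
#' @seealso [cellSpec()], [generateCell()]
#' @exportClass CellSpec
setClass("CellSpec",
  representation(
    imageSize = "integer",
    pixelSizeUm = "numeric",
    membranePolygon = "matrix",
    nSpots = "integer",
    clusteringFraction = "numeric",
    proximalBandNm = "numeric",
    spotSigmaNm = "numeric",
    spotAmplitude = "numeric",
    bitDepth = "integer",
    noiseBackgroundMean = "numeric",
    noiseGaussianSd = "numeric",
    seed = "integer"
  )
)

setValidity("CellSpec", function(object) {
  msg <- character(0)
  if (object@imageSize < 16L)
    msg <- c(msg, "imageSize must be at least 16 pixels")
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be positive")
  p <- object@membranePolygon
  if (nrow(p) > 0L) {
    if (ncol(p) != 2L || nrow(p) < 3L)
      msg <- c(msg, "membranePolygon must be n x 2 with n >= 3 (or 0-row for auto)")
    else if (!.polygonIsSimple(p))
      msg <- c(msg, "membranePolygon is self-intersecting")
  }
  if (object@nSpots < 0L)
    msg <- c(msg, "nSpots must be non-negative")
  if (object@clusteringFraction < 0 || object@clusteringFraction > 1)
    msg <- c(msg, "clusteringFraction must lie in [0, 1]")
  if (object@proximalBandNm <= 0)
    msg <- c(msg, "proximalBandNm must be positive")
  if (object@spotSigmaNm <= 0)
    msg <- c(msg, "spotSigmaNm must be positive")
  if (!(object@bitDepth %in% c(8L, 14L, 16L)))
    msg <- c(msg, "bitDepth must be 8, 14 or 16")
  if (object@spotAmplitude <= 0 ||
      object@spotAmplitude > 2^object@bitDepth - 1)
    msg <- c(msg, "spotAmplitude must lie in (0, 2^bitDepth - 1]")
  if (object@noiseGaussianSd < 0 || object@noiseBackgroundMean < 0)
    msg <- c(msg, "noise parameters must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CooccurrenceMatrix: gray-level pair distribution
#'
#' Normalized joint distribution p(i, j) of 8-bit gray-level pairs observed
#' at a fixed pixel offset inside a mask. Directed (not symmetrized) unless
#' requested otherwise at construction.
#'
#' @slot p 256 x 256 numeric matrix; entry \code{p[i+1, j+1]} is the
#'   probability of observing levels (i, j) at the offset; sums to 1.
#' @slot offset integer(2), (dx, dy) pixel offset; (1, 0) is the horizontal
#'   0-degree direction.
#' @slot nPairs numeric(1), number of contributing pixel pairs.
#'
#' @seealso [computeGLCM()], [textureFeatures()]
#' @exportClass CooccurrenceMatrix
setClass("CooccurrenceMatrix",
  representation(p = "matrix", offset = "integer", nPairs = "numeric")
)

setValidity("CooccurrenceMatrix", function(object) {
  msg <- character(0)
  if (!identical(dim(object@p), c(256L, 256L)))
    msg <- c(msg, "p must be 256 x 256")
  if (any(object@p < 0))
    msg <- c(msg, "p must be non-negative")
  if (abs(sum(object@p) - 1) > 1e-9)
    msg <- c(msg, "p must sum to 1")
  if (length(object@offset) != 2L)
    msg <- c(msg, "offset must be length 2")
  if (object@nPairs < 1)
    msg <- c(msg, "nPairs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ShellSet: inward membrane-distance bands
#'
#' A partition of the cell mask into disjoint inward Euclidean distance
#' bands: (0, e1], (e1, e2], ..., (eK, Inf) nanometres from the traced
#' membrane boundary. Stored as a label raster (0 = outside the mask,
#' k = band k).
#'
#' @slot labels integer matrix; 0 outside the ROI, band index 1..K+1 inside.
#' @slot edgesNm numeric, strictly increasing band edges in nanometres.
#' @slot pixelSizeUm numeric(1), pixel size in micrometres.
#'
#' @seealso [inwardShells()], [densityFractions()], [shellMasks()]
#' @exportClass ShellSet
setClass("ShellSet",
  representation(labels = "matrix", edgesNm = "numeric",
                 pixelSizeUm = "numeric")
)

setValidity("ShellSet", function(object) {
  msg <- character(0)
  nb <- length(object@edgesNm) + 1L
  if (length(object@edgesNm) < 1L || any(diff(object@edgesNm) <= 0) ||
      any(object@edgesNm <= 0))
    msg <- c(msg, "edgesNm must be positive and strictly increasing")
  if (any(object@labels < 0L) || any(object@labels > nb))
    msg <- c(msg, "labels must lie in 0..(number of bands)")
  if (!any(object@labels > 0L))
    msg <- c(msg, "shell set covers an empty mask")
  if (length(msg)) msg else TRUE
})

#' BeadSegmentation: segmented spots with centroids
#'
#' Result of thresholding and 8-connected labeling of a bead/lysosome
#' channel: the binary raster, the component label raster, intensity-weighted
#' sub-pixel centroids, and the threshold that was applied.
#'
#' @slot binary logical matrix of above-threshold pixels.
#' @slot labels integer matrix of 8-connected component labels (0 background).
#' @slot centroids data.frame with columns \code{x}, \code{y} (pixel units)
#'   and \code{intensity} (summed gray values); one row per component.
#' @slot thresholdUsed numeric(1), gray-level threshold applied.
#'
#' @seealso [segmentSpots()], [countInRegions()]
#' @exportClass BeadSegmentation
setClass("BeadSegmentation",
  representation(binary = "matrix", labels = "matrix",
                 centroids = "data.frame", thresholdUsed = "numeric")
)

setValidity("BeadSegmentation", function(object) {
  msg <- character(0)
  if (!identical(dim(object@binary), dim(object@labels)))
    msg <- c(msg, "binary and labels must have identical shape")
  if (max(object@labels, 0L) != nrow(object@centroids))
    msg <- c(msg, "component count must equal number of centroids")
  if (nrow(object@centroids) > 0) {
    if (any(object@centroids$x < 0 | object@centroids$x > ncol(object@binary)) ||
        any(object@centroids$y < 0 | object@centroids$y > nrow(object@binary)))
      msg <- c(msg, "all centroids must lie inside the image")
  }
  if (length(msg)) msg else TRUE
})
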