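# Synthetic dual-channel cell generator: the forward model every analysis
# stage is validated against. A single cell is a closed membrane contour;
# the target channel is a sum of integrated-Gaussian spots placed by a
# mixture of membrane-proximal and interior-uniform positioning, degraded
# by Poisson shot noise on signal plus additive Gaussian camera noise on a
# constant background, clipped (never wrapped) to the camera bit depth.

# Smoothed random star-convex contour: periodic radial spline through
# 12 knots. Consumes a fixed number of RNG draws (12 radii + 1 phase).
.starPolygon <- function(imageSize, nKnots = 12L, nVertices = 180L,
                         meanRadiusFrac = 0.30, radialJitter = 0.25) {
  r0 <- imageSize * meanRadiusFrac
  radii <- r0 * (1 + radialJitter * (2 * runif(nKnots) - 1))
  phase <- runif(1) * 2 * pi
  thKnot <- seq(0, 2 * pi, length.out = nKnots + 1L)
  rKnot <- c(radii, radii[1L])
  th <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  r <- spline(thKnot, rKnot, method = "periodic", xout = th)$y
  r <- pmax(r, 0.05 * imageSize)
  cx <- imageSize / 2
  cbind(x = cx + r * cos(th + phase), y = cx + r * sin(th + phase))
}

# Uniform rejection sampling of n points inside the polygon, optionally
# constrained to inward boundary distance <= maxDistPx.
.sampleInPolygon <- function(n, poly, maxDistPx = Inf) {
  if (n == 0L)
    return(matrix(numeric(0), 0L, 2L))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(numeric(0), 0L, 2L)
  for (iter in seq_len(1000L)) {
    k <- max(4L * (n - nrow(out)), 256L)
    cand <- cbind(runif(k, xr[1], xr[2]), runif(k, yr[1], yr[2]))
    keep <- .pointsInPolygon(cand, poly)
    if (is.finite(maxDistPx) && any(keep)) {
      d <- .pointsToPolygonDistance(cand[keep, , drop = FALSE], poly)
      cand <- cand[keep, , drop = FALSE][d <= maxDistPx, , drop = FALSE]
    } else {
      cand <- cand[keep, , drop = FALSE]
    }
    out <- rbind(out, cand)
    if (nrow(out) >= n)
      return(out[seq_len(n), , drop = FALSE])
  }
  stop("generateCell: spot placement failed (target region has ",
       "vanishing area relative to the polygon)")
}

# Analytic 2D isotropic Gaussian integrated over each pixel, normalized so
# a spot centred on a pixel centre contributes `amplitude` to that pixel.
# Integration (rather than point sampling) keeps total intensity stable
# against sub-pixel phase, which downstream integrated-density fractions
# rely on.
.renderSpots <- function(shape, centers, amplitudes, sigmaPx,
                         windowSigmas = 4) {
  img <- matrix(0, shape[1], shape[2])
  if (nrow(centers) == 0L)
    return(img)
  w <- ceiling(windowSigmas * sigmaPx)
  norm1d <- pnorm(0.5 / sigmaPx) - pnorm(-0.5 / sigmaPx)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    cs <- max(1L, floor(cx - w) + 1L):min(shape[2], ceiling(cx + w))
    rs <- max(1L, floor(cy - w) + 1L):min(shape[1], ceiling(cy + w))
    gx <- pnorm((cs - cx) / sigmaPx) - pnorm((cs - 1 - cx) / sigmaPx)
    gy <- pnorm((rs - cy) / sigmaPx) - pnorm((rs - 1 - cy) / sigmaPx)
    img[rs, cs] <- img[rs, cs] +
      amplitudes[i] * outer(gy, gx) / (norm1d * norm1d)
  }
  img
}

# Poisson shot noise on signal, additive Gaussian on a constant background,
# rounded and clipped to the bit depth (clip, never wrap).
.addCameraNoise <- function(signal, bgMean, gaussSd, bitDepth) {
  out <- signal
  pos <- which(signal > 0)
  if (length(pos))
    out[pos] <- rpois(length(pos), signal[pos])
  out <- out + rnorm(length(out), bgMean, gaussSd)
  out <- round(out)
  mx <- 2^bitDepth - 1
  out[out < 0] <- 0
  out[out > mx] <- mx
  matrix(out, nrow(signal), ncol(signal))
}

# ~2 px bright contour band along the polygon boundary, via the inward and
# outward distance transforms of the rasterized mask.
.membraneBandMask <- function(mask) {
  din <- EBImage::distmap(mask * 1)
  dout <- EBImage::distmap((!mask) * 1)
  (mask & din <= 1) | (!mask & dout <= 1)
}

# Shared placement + rendering machinery. Assumes the RNG is already
# seeded. Returns centers, distances (nm), labels, per-spot amplitudes.
.placeSpots <- function(spec, poly, nSpots) {
  bandPx <- spec@proximalBandNm / (spec@pixelSizeUm * 1000)
  nProx <- round(spec@clusteringFraction * nSpots)
  nInt <- nSpots - nProx
  prox <- .sampleInPolygon(nProx, poly, maxDistPx = bandPx)
  int <- .sampleInPolygon(nInt, poly)
  centers <- rbind(prox, int)
  labels <- rep(c("proximal", "interior"), c(nProx, nInt))
  dist_nm <- if (nrow(centers)) {
    .pointsToPolygonDistance(centers, poly) * spec@pixelSizeUm * 1000
  } else numeric(0)
  # single nominal amplitude with +/-20% jitter (intensity distribution of
  # real lysosomes is unknown; see the methods vignette)
  amps <- spec@spotAmplitude * runif(nSpots, 0.8, 1.2)
  list(centers = centers, dist_nm = dist_nm, labels = labels, amps = amps)
}

.resolvePolygon <- function(spec) {
  # Draw (and consume the RNG draws for) the default contour even when a
  # polygon is supplied, so spot placement uses the same stream either way.
  auto <- .starPolygon(spec@imageSize)
  if (nrow(spec@membranePolygon)) spec@membranePolygon else auto
}

#' Generate one synthetic dual-channel cell image
#'
#' Renders the membrane channel (bright ~2 px contour band along the
#' polygon) and the target channel (sum of integrated-Gaussian spots), adds
#' Poisson + Gaussian camera noise, clips to the bit depth, and returns the
#' rasters together with the ground truth used to render them. Identical
#' spec and seed give bit-identical output.
#'
#' @param spec a [CellSpec-class].
#' @return a list with elements
#'   \describe{
#'     \item{images}{a [CellImagePair-class];}
#'     \item{truth}{data.frame \code{x_px}, \code{y_px}, \code{distance_nm}
#'       (inward distance of the spot centre to the membrane polygon),
#'       \code{label} ("proximal"/"interior"), \code{frame};}
#'     \item{roi}{the [CellROI-class] of the membrane contour actually
#'       used (needed when the contour was auto-generated).}
#'   }
#' @examples
#' sim <- generateCell(cellSpec(imageSize = 256, nSpots = 40, seed = 3))
#' sim$images
#' head(sim$truth)
#' @export
generateCell <- function(spec) {
  stopifnot(is(spec, "CellSpec"))
  validObject(spec)
  set.seed(spec@seed)
  poly <- .resolvePolygon(spec)
  shape <- c(spec@imageSize, spec@imageSize)
  if (any(poly < 0) || any(poly > spec@imageSize))
    stop("generateCell: membrane polygon exceeds the raster")
  mask <- polygonToMask(poly, shape)
  areaPx <- sum(mask)
  if (areaPx < 4L * spec@nSpots)
    stop("generateCell: polygon area too small to host ", spec@nSpots,
         " spots non-degenerately")
  sp <- .placeSpots(spec, poly, spec@nSpots)
  targetSignal <- .renderSpots(shape, sp$centers, sp$amps,
                               spec@spotSigmaNm / (spec@pixelSizeUm * 1000))
  membraneSignal <- spec@spotAmplitude * .membraneBandMask(mask)
  target <- .addCameraNoise(targetSignal, spec@noiseBackgroundMean,
                            spec@noiseGaussianSd, spec@bitDepth)
  membrane <- .addCameraNoise(membraneSignal, spec@noiseBackgroundMean,
                              spec@noiseGaussianSd, spec@bitDepth)
  truth <- data.frame(
    x_px = sp$centers[, 1], y_px = sp$centers[, 2],
    distance_nm = sp$dist_nm, label = sp$labels, frame = 1L,
    stringsAsFactors = FALSE)
  list(images = cellImagePair(membrane, target, spec@pixelSizeUm,
                              spec@bitDepth),
       truth = truth,
       roi = cellROI(poly, spec@pixelSizeUm))
}

#' Generate a synthetic bead-uptake time lapse
#'
#' Simulates saturating bead internalization: the expected count at time t
#' follows \code{capacity * (1 - exp(-uptakeRate * t / capacity))}. Each of
#' \code{capacity} latent beads carries a fixed uniform draw and becomes
#' (and stays) internalized once the saturating probability exceeds it, so
#' realized counts are thinned around the expectation, monotone
#' non-decreasing within a realization, and never exceed the capacity.
#' Internalized beads keep their positions across frames; every frame gets
#' fresh camera noise.
#'
#' @param spec a [CellSpec-class]; \code{nSpots} is ignored (the bead count
#'   is driven by the uptake model), the remaining fields define geometry,
#'   rendering and noise.
#' @param nFrames number of frames (>= 1).
#' @param frameIntervalMin minutes between frames.
#' @param uptakeRate initial uptake rate, beads/minute (0 = unstimulated).
#' @param capacity maximal number of internalized beads (>= 1).
#' @param firstFrameMin time of the first frame in minutes after bead
#'   exposure (default 20, i.e. frames at 20', 50', ... for a 30' interval).
#' @return list with one element per frame, each a list with
#'   \code{images} ([CellImagePair-class]), \code{truth} (as in
#'   [generateCell()], with \code{frame} set), \code{roi},
#'   \code{timeMin} and \code{nBeads}.
#' @examples
#' tl <- generateTimelapse(cellSpec(imageSize = 256, seed = 5), nFrames = 3,
#'                         frameIntervalMin = 30, uptakeRate = 1,
#'                         capacity = 40)
#' sapply(tl, `[[`, "nBeads")
#' @export
generateTimelapse <- function(spec, nFrames, frameIntervalMin = 30,
                              uptakeRate, capacity, firstFrameMin = 20) {
  stopifnot(is(spec, "CellSpec"))
  validObject(spec)
  if (nFrames < 1L) stop("generateTimelapse: nFrames must be >= 1")
  if (uptakeRate < 0) stop("generateTimelapse: uptakeRate must be >= 0")
  if (capacity < 1) stop("generateTimelapse: capacity must be >= 1")
  set.seed(spec@seed)
  poly <- .resolvePolygon(spec)
  shape <- c(spec@imageSize, spec@imageSize)
  mask <- polygonToMask(poly, shape)
  if (sum(mask) < 4L * capacity)
    stop("generateTimelapse: polygon area too small for the bead capacity")
  roi <- cellROI(poly, spec@pixelSizeUm)
  membraneSignal <- spec@spotAmplitude * .membraneBandMask(mask)
  # latent beads: fixed positions/amplitudes, fixed arrival uniforms
  beadSpec <- spec
  beadSpec@nSpots <- as.integer(capacity)
  sp <- .placeSpots(beadSpec, poly, as.integer(capacity))
  arrival <- runif(capacity)
  times <- firstFrameMin + frameIntervalMin * (seq_len(nFrames) - 1)
  sigmaPx <- spec@spotSigmaNm / (spec@pixelSizeUm * 1000)
  lapply(seq_len(nFrames), function(k) {
    pk <- 1 - exp(-uptakeRate * times[k] / capacity)
    act <- arrival <= pk
    sig <- .renderSpots(shape, sp$centers[act, , drop = FALSE],
                        sp$amps[act], sigmaPx)
    target <- .addCameraNoise(sig, spec@noiseBackgroundMean,
                              spec@noiseGaussianSd, spec@bitDepth)
    membrane <- .addCameraNoise(membraneSignal, spec@noiseBackgroundMean,
                                spec@noiseGaussianSd, spec@bitDepth)
    truth <- data.frame(
      x_px = sp$centers[act, 1], y_px = sp$centers[act, 2],
      distance_nm = sp$dist_nm[act], label = sp$labels[act],
      frame = rep.int(k, sum(act)), stringsAsFactors = FALSE)
    list(images = cellImagePair(membrane, target, spec@pixelSizeUm,
                                spec@bitDepth),
         truth = truth, roi = roi, timeMin = times[k], nBeads = sum(act))
  })
}
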