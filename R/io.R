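# File interfaces: single-plane TIFF channels, ROI vertex files, ground
# truth CSV, YAML-style spec/config files. All plain, text-friendly
# formats; 14-bit data travel in 16-bit TIFF containers.

#' Write / read a single-channel raster as TIFF
#'
#' Gray values are stored scaled to the bit depth's full range; 8-bit data
#' use an 8-bit container and 14/16-bit data a 16-bit container. Integer
#' gray values round-trip exactly.
#'
#' @param raster numeric matrix of gray values in \code{[0, 2^bitDepth-1]}.
#' @param path file path.
#' @param bitDepth 8, 14 or 16.
#' @return \code{readChannelTiff}: the raster as a numeric matrix.
#' @export
writeChannelTiff <- function(raster, path, bitDepth = 16L) {
  mx <- 2^bitDepth - 1
  bits <- if (bitDepth == 8L) 8L else 16L
  tiff::writeTIFF(raster / mx, path, bits.per.sample = bits)
  invisible(path)
}

#' @rdname writeChannelTiff
#' @export
readChannelTiff <- function(path, bitDepth = 16L) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  round(img * (2^bitDepth - 1))
}

#' Write / read a CellImagePair as a pair of TIFF files
#'
#' @param pair a [CellImagePair-class].
#' @param prefix path prefix; \code{<prefix>_membrane.tif} and
#'   \code{<prefix>_target.tif} are written.
#' @param pixelSizeUm,bitDepth acquisition metadata for reading back.
#' @return \code{readCellImagePair}: a [CellImagePair-class].
#' @export
writeCellImagePair <- function(pair, prefix) {
  writeChannelTiff(membraneChannel(pair), paste0(prefix, "_membrane.tif"),
                   bitDepth(pair))
  writeChannelTiff(targetChannel(pair), paste0(prefix, "_target.tif"),
                   bitDepth(pair))
  invisible(prefix)
}

#' @rdname writeCellImagePair
#' @export
readCellImagePair <- function(prefix, pixelSizeUm, bitDepth = 16L) {
  cellImagePair(
    readChannelTiff(paste0(prefix, "_membrane.tif"), bitDepth),
    readChannelTiff(paste0(prefix, "_target.tif"), bitDepth),
    pixelSizeUm = pixelSizeUm, bitDepth = bitDepth)
}

#' Write / read a traced outline as a vertex text file
#'
#' Minimal ROI text format: a comment header carrying the pixel size,
#' then one \code{x,y} vertex per line (CSV, pixel units).
#'
#' @param roi a [CellROI-class].
#' @param path file path.
#' @return \code{readROI}: a [CellROI-class].
#' @export
writeROI <- function(roi, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size_um: %.6g", pixelSize(roi)), con)
  writeLines("x,y", con)
  p <- roiPolygon(roi)
  writeLines(sprintf("%.6g,%.6g", p[, 1], p[, 2]), con)
  invisible(path)
}

#' @rdname writeROI
#' @export
readROI <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  px <- 1
  m <- regmatches(hdr, regexec("pixel_size_um:\\s*([0-9.eE+-]+)", hdr))
  for (mm in m) if (length(mm) == 2L) px <- as.numeric(mm[2L])
  body <- lines[!grepl("^#", lines)]
  df <- read.csv(text = paste(body, collapse = "\n"))
  cellROI(as.matrix(df[, c("x", "y")]), pixelSizeUm = px)
}

#' Write simulator ground truth as CSV
#'
#' @param truth ground-truth data.frame from [generateCell()] or a
#'   [generateTimelapse()] frame.
#' @param path file path.
#' @export
writeGroundTruth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a CellSpec as a YAML key-value file
#'
#' The polygon, when explicit, is stored as parallel x/y vertex lists.
#'
#' @param spec a [CellSpec-class].
#' @param path file path.
#' @return \code{readCellSpec}: a [CellSpec-class].
#' @export
writeCellSpec <- function(spec, path) {
  lst <- list(
    imageSize = spec@imageSize, pixelSizeUm = spec@pixelSizeUm,
    nSpots = spec@nSpots, clusteringFraction = spec@clusteringFraction,
    proximalBandNm = spec@proximalBandNm, spotSigmaNm = spec@spotSigmaNm,
    spotAmplitude = spec@spotAmplitude, bitDepth = spec@bitDepth,
    noiseBackgroundMean = spec@noiseBackgroundMean,
    noiseGaussianSd = spec@noiseGaussianSd, seed = spec@seed)
  if (nrow(spec@membranePolygon)) {
    lst$polygon_x <- as.numeric(spec@membranePolygon[, 1])
    lst$polygon_y <- as.numeric(spec@membranePolygon[, 2])
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeCellSpec
#' @export
readCellSpec <- function(path) {
  lst <- yaml::read_yaml(path)
  poly <- if (!is.null(lst$polygon_x))
    cbind(lst$polygon_x, lst$polygon_y) else NULL
  cellSpec(imageSize = lst$imageSize, pixelSizeUm = lst$pixelSizeUm,
           membranePolygon = poly, nSpots = lst$nSpots,
           clusteringFraction = lst$clusteringFraction,
           proximalBandNm = lst$proximalBandNm,
           spotSigmaNm = lst$spotSigmaNm,
           spotAmplitude = lst$spotAmplitude, bitDepth = lst$bitDepth,
           noiseBackgroundMean = lst$noiseBackgroundMean,
           noiseGaussianSd = lst$noiseGaussianSd, seed = lst$seed)
}

#' Export shell bands as an indexed-label TIFF
#'
#' Band indices (0 outside the ROI, 1..K+1 inside) are written as an 8-bit
#' label image.
#'
#' @param shells a [ShellSet-class].
#' @param path file path.
#' @export
writeShellLabels <- function(shells, path) {
  tiff::writeTIFF(shellLabels(shells) / 255, path, bits.per.sample = 8L)
  invisible(path)
}
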