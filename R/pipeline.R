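# Pipeline stage: per-cell orchestration, per-cell records, group
# comparisons, and whole-experiment runs.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Default analysis configuration
#'
#' @param bitDepth camera bit depth used to resolve the default
#'   quantization window ([acquisitionCeiling()]).
#' @return named list of resolved parameters: \code{window} (8-bit
#'   conversion window), \code{backgroundMethod}, \code{backgroundParam},
#'   \code{edgesNm} (shell edges), \code{offset} (GLCM offset),
#'   \code{symmetric} (GLCM symmetrization), \code{beadMethod},
#'   \code{beadThreshold}, \code{countBeads}.
#' @export
defaultConfig <- function(bitDepth = 16L) {
  list(window = c(0, acquisitionCeiling(bitDepth)),
       backgroundMethod = "mode",
       backgroundParam = 50,
       edgesNm = c(100, 300, 500, 700),
       offset = c(1L, 0L),
       symmetric = FALSE,
       beadMethod = "otsu",
       beadThreshold = NULL,
       countBeads = TRUE)
}

.resolveConfig <- function(config, bitDepth) {
  base <- defaultConfig(bitDepth)
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  base
}

#' Analyze one cell end-to-end
#'
#' Composes the full per-cell analysis: rasterize the traced outline,
#' subtract the background from the target channel, quantize to 8 bit,
#' compute GLCM texture inside the mask, build the membrane-distance
#' shells and integrated-density fractions, measure shape descriptors,
#' and (optionally) segment and count beads in the cytoplasm and within
#' the outermost shell edge. Deterministic for a fixed configuration.
#' Stage errors are propagated with the stage name attached.
#'
#' @param pair a [CellImagePair-class].
#' @param roi a [CellROI-class].
#' @param config named list overriding [defaultConfig()] entries.
#' @param cellId,group,frameTimeMin identifiers copied into the record.
#' @return one-row data.frame (a cell record): identifiers, \code{asm},
#'   \code{idm}, \code{entropy}, \code{n_pairs}, per-band density
#'   fractions \code{frac_*}, \code{frac_within_700} (sum of bands within
#'   the last edge), \code{circularity}, \code{solidity},
#'   \code{n_beads_total}, \code{n_beads_band}.
#' @examples
#' sim <- generateCell(cellSpec(imageSize = 256, nSpots = 40, seed = 11))
#' analyzeCell(sim$images, sim$roi)
#' @export
analyzeCell <- function(pair, roi, config = list(), cellId = "cell1",
                        group = NA_character_, frameTimeMin = NA_real_) {
  stopifnot(is(pair, "CellImagePair"), is(roi, "CellROI"))
  cfg <- .resolveConfig(config, bitDepth(pair))
  target <- targetChannel(pair)
  mask <- .stage("polygon_to_mask", polygonToMask(roi, dim(target)))
  corrected <- .stage("subtract_background",
    subtractBackground(target, method = cfg$backgroundMethod,
                       param = cfg$backgroundParam, roiMask = mask))
  quant <- .stage("quantize", quantizeTo8bit(corrected, cfg$window))
  glcm <- .stage("glcm",
    computeGLCM(quant, mask, offset = cfg$offset,
                symmetric = cfg$symmetric))
  tex <- .stage("texture_features", textureFeatures(glcm))
  shells <- .stage("inward_shells",
    inwardShells(mask, pixelSize(pair), cfg$edgesNm))
  fracs <- .stage("density_fractions", densityFractions(corrected, shells))
  shp <- .stage("shape_descriptors", shapeDescriptors(mask))
  nb <- length(cfg$edgesNm)
  fr <- as.list(fracs)
  names(fr) <- c(sprintf("frac_%g_%g", c(0, cfg$edgesNm[-nb]), cfg$edgesNm),
                 sprintf("frac_gt_%g", cfg$edgesNm[nb]))
  rec <- data.frame(cell_id = cellId, group = group,
                    frame_time_min = frameTimeMin,
                    asm = unname(tex["asm"]), idm = unname(tex["idm"]),
                    entropy = unname(tex["entropy"]),
                    n_pairs = unname(tex["n_pairs"]),
                    stringsAsFactors = FALSE)
  rec <- cbind(rec, as.data.frame(fr))
  rec$frac_within_700 <- sum(fracs[seq_len(nb)])
  rec$circularity <- unname(shp["circularity"])
  rec$solidity <- unname(shp["solidity"])
  if (isTRUE(cfg$countBeads)) {
    seg <- .stage("segment_spots",
      segmentSpots(corrected, method = cfg$beadMethod,
                   threshold = cfg$beadThreshold))
    bandMask <- shellLabels(shells) > 0L & shellLabels(shells) <= nb
    cnt <- .stage("count_in_regions", countInRegions(seg, mask, bandMask))
    rec$n_beads_total <- cnt$n_total_in_roi
    rec$n_beads_band <- cnt$n_in_band
  } else {
    rec$n_beads_total <- NA_integer_
    rec$n_beads_band <- NA_integer_
  }
  rec
}

#' Compare groups of cell records
#'
#' Reporting plumbing over standard tests. \code{design = "two_group"} runs
#' a Welch t test (Student available via \code{varEqual = TRUE}) on one
#' feature between exactly two groups. \code{design = "two_way"} reshapes
#' the per-band density fractions to long form and fits a two-way ANOVA
#' (group x band) with Sidak-adjusted post hoc group contrasts within each
#' band.
#'
#' @param records data.frame of cell records (see [analyzeCell()]) with a
#'   \code{group} column.
#' @param feature column name for \code{two_group}; for \code{two_way},
#'   either \code{"fractions"} (all \code{frac_*} band columns) or a vector
#'   of band column names.
#' @param design \code{"two_group"} or \code{"two_way"}.
#' @param posthoc multiplicity adjustment for the post hoc contrasts
#'   (emmeans adjust keyword; default \code{"sidak"}).
#' @param varEqual use the pooled-variance Student t test instead of Welch.
#' @return data.frame of test results: \code{test}, \code{term},
#'   \code{statistic}, \code{p_value}, and group means/sds where
#'   applicable.
#' @examples
#' rec <- data.frame(group = rep(c("a", "b"), each = 4),
#'                   asm = c(1, 2, 3, 4, 1, 2, 3, 4))
#' compareGroups(rec, "asm")
#' @export
compareGroups <- function(records, feature, design = c("two_group", "two_way"),
                          posthoc = "sidak", varEqual = FALSE) {
  design <- match.arg(design)
  if (!"group" %in% names(records))
    stop("compareGroups: records need a group column")
  records$group <- factor(records$group)
  counts <- table(records$group)
  if (any(counts < 2L))
    stop("compareGroups: insufficient data (each group needs >= 2 records)")
  if (design == "two_group") {
    if (nlevels(records$group) != 2L)
      stop("compareGroups: two_group design needs exactly 2 groups")
    g <- levels(records$group)
    x <- records[records$group == g[1L], feature]
    y <- records[records$group == g[2L], feature]
    tt <- t.test(x, y, var.equal = varEqual)
    data.frame(test = if (varEqual) "t_student" else "t_welch",
               term = feature,
               statistic = unname(tt$statistic),
               p_value = tt$p.value,
               group1 = g[1L], mean1 = mean(x), sd1 = sd(x),
               group2 = g[2L], mean2 = mean(y), sd2 = sd(y),
               stringsAsFactors = FALSE)
  } else {
    bandCols <- if (identical(feature, "fractions"))
      grep("^frac_", names(records), value = TRUE) else feature
    bandCols <- setdiff(bandCols, "frac_within_700")
    if (length(bandCols) < 2L)
      stop("compareGroups: two_way design needs >= 2 band columns")
    long <- do.call(rbind, lapply(bandCols, function(b)
      data.frame(group = records$group, band = b, value = records[[b]])))
    long$band <- factor(long$band, levels = bandCols)
    fit <- aov(value ~ group * band, data = long)
    an <- summary(fit)[[1L]]
    rn <- trimws(rownames(an))
    anovaRows <- data.frame(test = "two_way_anova", term = rn,
                            statistic = an[["F value"]],
                            p_value = an[["Pr(>F)"]],
                            group1 = NA, mean1 = NA, sd1 = NA,
                            group2 = NA, mean2 = NA, sd2 = NA,
                            stringsAsFactors = FALSE)
    anovaRows <- anovaRows[rn != "Residuals", ]
    em <- emmeans::emmeans(fit, ~ group | band)
    ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = posthoc))
    g <- levels(long$group)
    twoGroups <- length(g) == 2L
    agg <- function(f) tapply(long$value, list(long$group, long$band), f)
    mns <- agg(mean); sds <- agg(sd)
    bandOf <- as.character(ct$band)
    posthocRows <- data.frame(
      test = paste0("posthoc_", posthoc),
      term = bandOf,
      statistic = ct$t.ratio,
      p_value = ct$p.value,
      group1 = if (twoGroups) g[1L] else as.character(ct$contrast),
      mean1 = if (twoGroups) mns[g[1L], bandOf] else NA_real_,
      sd1 = if (twoGroups) sds[g[1L], bandOf] else NA_real_,
      group2 = if (twoGroups) g[2L] else NA_character_,
      mean2 = if (twoGroups) mns[g[2L], bandOf] else NA_real_,
      sd2 = if (twoGroups) sds[g[2L], bandOf] else NA_real_,
      stringsAsFactors = FALSE)
    rbind(anovaRows, posthocRows)
  }
}
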