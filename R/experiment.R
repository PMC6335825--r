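# Whole-experiment orchestration: simulated cohorts, simulated time-lapse
# runs, or analysis of images on disk; CSV outputs plus a run log with all
# resolved parameters and seeds.

.specFromConfig <- function(config, seed) {
  cellSpec(
    imageSize = config$imageSize %||% 1024L,
    pixelSizeUm = config$pixelSizeUm %||% 0.030,
    nSpots = config$nSpots %||% 150L,
    clusteringFraction = config$clusteringFraction %||% 0.5,
    proximalBandNm = config$proximalBandNm %||% 700,
    spotSigmaNm = config$spotSigmaNm %||% 60,
    spotAmplitude = config$spotAmplitude %||% 8000,
    bitDepth = config$bitDepth %||% 16L,
    noiseBackgroundMean = config$noiseBackgroundMean %||% 100,
    noiseGaussianSd = config$noiseGaussianSd %||% 20,
    seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeRunLog <- function(path, config, seeds) {
  lines <- c(
    paste0("phagostate version: ", as.character(packageVersion("phagostate"))),
    "resolved configuration:",
    strsplit(yaml::as.yaml(config), "\n")[[1L]],
    paste0("master seed: ", seeds$master),
    paste0("derived seeds: ", paste(seeds$derived, collapse = " ")))
  writeLines(lines, path)
}

#' Run a whole experiment from a configuration
#'
#' Orchestrates one of three run modes and writes per-cell records, group
#' comparisons and a log (seeds, package version, every resolved
#' parameter) to \code{outDir}. Bit-identical outputs are guaranteed for an
#' identical configuration and master seed.
#'
#' Modes (\code{config$mode}):
#' \describe{
#'   \item{\code{"two_group_synthetic"}}{\code{config$groups} is a list of
#'     \code{list(name=, clusteringFraction=, nCells=)}; one synthetic cell
#'     is generated and analyzed per cell. Writes \code{cells.csv} and
#'     \code{comparisons.csv} (Welch t tests on asm/idm/entropy and the
#'     within-700 nm fraction, plus the two-way group x band ANOVA).}
#'   \item{\code{"timelapse_synthetic"}}{\code{config$nRuns} simulated
#'     uptake time lapses (\code{nFrames}, \code{frameIntervalMin},
#'     \code{uptakeRate}, \code{capacity}, \code{firstFrameMin}); every
#'     frame's bead channel is analyzed. Writes \code{uptake.csv} (one row
#'     per run and frame).}
#'   \item{\code{"analyze"}}{\code{config$inputs} is a list of
#'     \code{list(membrane=, target=, roi=, cellId=, group=)} file paths
#'     (TIFF channels, ROI vertex file); writes \code{cells.csv} and, with
#'     two or more groups, \code{comparisons.csv}.}
#' }
#' Remaining config entries override the synthetic-spec defaults
#' (\code{imageSize}, \code{pixelSizeUm}, \code{nSpots},
#' \code{spotAmplitude}, \code{bitDepth}, ...) and the analysis defaults
#' ([defaultConfig()], via \code{config$analysis}).
#'
#' @param config named list, or path to a YAML file of key-value pairs.
#' @param outDir output directory (created if missing).
#' @param masterSeed integer master seed for all randomness.
#' @return invisibly, a list with the per-cell records (and comparisons or
#'   uptake curves, mode-dependent) plus the output file paths.
#' @export
runExperiment <- function(config, outDir, masterSeed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- config$mode %||% stop("runExperiment: config needs a 'mode'")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  analysisCfg <- config$analysis %||% list()
  out <- switch(mode,
    two_group_synthetic = {
      groups <- config$groups %||%
        stop("runExperiment: two_group_synthetic config needs 'groups'")
      nTotal <- sum(vapply(groups, function(g)
        as.integer(g$nCells %||% stop("runExperiment: group needs nCells")),
        integer(1)))
      set.seed(masterSeed)
      seeds <- sample.int(.Machine$integer.max - 1L, nTotal)
      recs <- list(); k <- 0L
      for (g in groups) {
        for (i in seq_len(g$nCells)) {
          k <- k + 1L
          cfg <- config
          cfg$clusteringFraction <- g$clusteringFraction
          sim <- generateCell(.specFromConfig(cfg, seeds[k]))
          recs[[k]] <- analyzeCell(sim$images, sim$roi, analysisCfg,
                                   cellId = sprintf("%s_%03d", g$name, i),
                                   group = g$name)
        }
      }
      cells <- do.call(rbind, recs)
      cmp <- do.call(rbind, lapply(
        c("asm", "idm", "entropy", "frac_within_700"),
        function(f) compareGroups(cells, f, "two_group")))
      cmp2 <- compareGroups(cells, "fractions", "two_way")
      comparisons <- rbind(cmp, cmp2)
      cellsCsv <- file.path(outDir, "cells.csv")
      compCsv <- file.path(outDir, "comparisons.csv")
      write.csv(cells, cellsCsv, row.names = FALSE)
      write.csv(comparisons, compCsv, row.names = FALSE)
      .writeRunLog(file.path(outDir, "run_log.txt"), config,
                   list(master = masterSeed, derived = seeds))
      list(cells = cells, comparisons = comparisons,
           files = c(cellsCsv, compCsv))
    },
    timelapse_synthetic = {
      nRuns <- as.integer(config$nRuns %||% 9L)
      set.seed(masterSeed)
      seeds <- sample.int(.Machine$integer.max - 1L, nRuns)
      rows <- list()
      for (r in seq_len(nRuns)) {
        tl <- generateTimelapse(
          .specFromConfig(config, seeds[r]),
          nFrames = as.integer(config$nFrames %||% 6L),
          frameIntervalMin = config$frameIntervalMin %||% 30,
          uptakeRate = config$uptakeRate %||% 2.3,
          capacity = config$capacity %||% 120,
          firstFrameMin = config$firstFrameMin %||% 20)
        for (k in seq_along(tl)) {
          rec <- analyzeCell(tl[[k]]$images, tl[[k]]$roi, analysisCfg,
                             cellId = sprintf("run%02d", r),
                             group = "LPS_like",
                             frameTimeMin = tl[[k]]$timeMin)
          rec$frame <- k
          rec$n_beads_truth <- tl[[k]]$nBeads
          rows[[length(rows) + 1L]] <- rec
        }
      }
      uptake <- do.call(rbind, rows)
      uptakeCsv <- file.path(outDir, "uptake.csv")
      write.csv(uptake, uptakeCsv, row.names = FALSE)
      .writeRunLog(file.path(outDir, "run_log.txt"), config,
                   list(master = masterSeed, derived = seeds))
      list(uptake = uptake, files = uptakeCsv)
    },
    analyze = {
      inputs <- config$inputs %||%
        stop("runExperiment: analyze config needs 'inputs'")
      bitDepth <- as.integer(config$bitDepth %||% 16L)
      recs <- lapply(seq_along(inputs), function(k) {
        inp <- inputs[[k]]
        for (key in c("membrane", "target", "roi"))
          if (is.null(inp[[key]]))
            stop("runExperiment: input ", k, " misses '", key, "'")
        roi <- readROI(inp$roi)
        pair <- cellImagePair(
          readChannelTiff(inp$membrane, bitDepth),
          readChannelTiff(inp$target, bitDepth),
          pixelSizeUm = config$pixelSizeUm %||% pixelSize(roi),
          bitDepth = bitDepth)
        analyzeCell(pair, roi, analysisCfg,
                    cellId = inp$cellId %||% sprintf("cell_%03d", k),
                    group = inp$group %||% NA_character_)
      })
      cells <- do.call(rbind, recs)
      cellsCsv <- file.path(outDir, "cells.csv")
      write.csv(cells, cellsCsv, row.names = FALSE)
      files <- cellsCsv
      comparisons <- NULL
      grps <- unique(cells$group[!is.na(cells$group)])
      if (length(grps) == 2L && all(table(cells$group) >= 2L)) {
        comparisons <- do.call(rbind, lapply(
          c("asm", "idm", "entropy", "frac_within_700"),
          function(f) compareGroups(cells, f, "two_group")))
        compCsv <- file.path(outDir, "comparisons.csv")
        write.csv(comparisons, compCsv, row.names = FALSE)
        files <- c(files, compCsv)
      }
      .writeRunLog(file.path(outDir, "run_log.txt"), config,
                   list(master = masterSeed, derived = integer(0)))
      list(cells = cells, comparisons = comparisons, files = files)
    },
    stop("runExperiment: unknown mode '", mode, "'"))
  invisible(out)
}
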