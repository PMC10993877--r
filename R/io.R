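## Text formats and end-to-end orchestration. All matrices travel as labeled
## tab-separated text; every artifact regenerates byte-identically from the
## same configuration and root seed.

.fmtNum <- function(x) formatC(x, digits = 15, format = "g")

#' Write / read a weighted network as labeled tab-separated text
#'
#' The file holds a square numeric matrix with region labels as the header
#' row and first column. Values are written with 15 significant digits, so a
#' write/read round trip preserves weights to numerical text precision.
#' Reading rejects non-square tables, mismatched row/column labels,
#' non-numeric cells, and asymmetry beyond 1e-9 (tiny asymmetry is
#' symmetrized away).
#'
#' @param net a \code{WeightedNetwork}.
#' @param path file path.
#' @return \code{writeNetwork}: invisibly, the path. \code{readNetwork}: a
#'   \code{WeightedNetwork}.
#' @export
writeNetwork <- function(net, path) {
  w <- netWeights(net)
  out <- cbind(label = rownames(w), apply(w, 2, .fmtNum))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNetwork
#' @param modality modality tag to stamp on the read network.
#' @export
readNetwork <- function(path, modality = "other") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  labs <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  if (!identical(colnames(m), labs))
    stop("header and column labels disagree in ", path)
  w <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  if (anyNA(w)) stop("non-numeric cell in ", path)
  dimnames(w) <- list(labs, labs)
  if (max(abs(w - t(w))) > 1e-9)
    stop("matrix in ", path, " is asymmetric beyond 1e-9")
  weightedNetwork(w, modality = modality)
}

#' Write / read region metadata as a tab-separated table
#'
#' One row per region with the documented header: region_id, label,
#' hemisphere, lobe, cortical, x, y, z, surface_area, volume,
#' homotopic_partner.
#'
#' @param regions a \code{RegionSet}.
#' @param path file path.
#' @export
writeRegions <- function(regions, path) {
  df <- regions@info
  num <- c("x", "y", "z", "surface_area", "volume")
  df[num] <- lapply(df[num], .fmtNum)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRegions
#' @export
readRegions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$homotopic_partner <- as.integer(df$homotopic_partner)
  new("RegionSet", info = df)
}

#' Write / read a subject-by-region feature table
#'
#' Tab-separated, one row per subject, region labels as header.
#'
#' @param features a \code{CohortFeatures}.
#' @param path file path.
#' @export
writeFeatures <- function(features, path) {
  vals <- featureValues(features)
  out <- apply(vals, 2, .fmtNum)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @param mode feature mode for the read table ("uptake" or "volume").
#' @export
readFeatures <- function(path, mode) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  new("CohortFeatures", values = m, mode = mode)
}

#' Pipeline configuration
#'
#' Collects and validates every knob of the end-to-end synthetic pipeline.
#' Defaults mirror the reference cohort: 56 subjects, 106 regions, 209
#' retained volumes at a 2.26 s sampling interval, coupling 0.8, rank-Gaussian
#' resampling on, consistency threshold 0.75, sparsity step 0.005 with the
#' upper bound capped at 0.80.
#'
#' @param nSubjects,nRegions,nVolumes,samplingInterval cohort dimensions.
#' @param fractionSubcortical,distanceScaleMm,homotopicProb,targetDensity
#'   region / ground-truth generator parameters.
#' @param coupling,noiseSd,globalConfoundSd,dispersion,falsePositiveRate,
#'   dropoutRate,driftAmplitude,highfreqAmplitude,nuisanceLoadingSd noise
#'   model parameters.
#' @param resample,consistencyThreshold group-SC options (variant (b) sets
#'   \code{resample = FALSE}; (c) \code{consistencyThreshold = NULL}; (d)
#'   \code{0.5}).
#' @param lowHz,highHz band-pass specification.
#' @param uptakeNormalization "volume_weighted_mean" or "simple_mean".
#' @param sMin,sMax,step,sMaxCap similarity grid controls ("auto" derives the
#'   bounds from SC sparsity and the connectedness criterion).
#' @param edgeSet,positiveOnly,regressDistance,cortexOnly,pairs similarity
#'   variant flags (see \code{\link{similarityReport}}).
#' @param seed root seed; all stage seeds derive from it deterministically.
#' @param outDir output directory, or \code{NULL} to skip writing.
#' @return a validated configuration list of class "pipelineConfig".
#' @export
pipelineConfig <- function(nSubjects = 56, nRegions = 106, nVolumes = 209,
                           samplingInterval = 2.26,
                           fractionSubcortical = 0.1, distanceScaleMm = 40,
                           homotopicProb = 0.9, targetDensity = 0.342,
                           coupling = 0.8, noiseSd = 10,
                           globalConfoundSd = 0.2, dispersion = 0.5,
                           falsePositiveRate = 0.02, dropoutRate = 0.1,
                           driftAmplitude = 1, highfreqAmplitude = 1,
                           nuisanceLoadingSd = 0.5,
                           resample = TRUE, consistencyThreshold = 0.75,
                           lowHz = 0.009, highHz = 0.080,
                           uptakeNormalization = "volume_weighted_mean",
                           sMin = "auto", sMax = "auto", step = 0.005,
                           sMaxCap = 0.80, edgeSet = "ref_support",
                           positiveOnly = FALSE, regressDistance = FALSE,
                           cortexOnly = FALSE, pairs = "sc-proxy",
                           seed = 1, outDir = NULL) {
  cfg <- as.list(environment())
  stopifnot(nSubjects >= 3, nRegions >= 4, nRegions %% 2 == 0,
            nVolumes >= 32, samplingInterval > 0,
            coupling >= 0, coupling < 1,
            highHz < 1 / (2 * samplingInterval),
            seed == as.integer(seed), abs(seed) < 2^31 - 10)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort from a planted ground truth, builds the four group
#' networks (SC, FC, FDGcov, GMVcov), compares them, and (when \code{outDir}
#' is set) writes every artifact: region table, ground-truth and group
#' matrices, the Table-shaped report, a machine-readable JSON report, the
#' CR curves, and a log of all design-decision settings and stage seeds.
#' Rerunning with the same configuration reproduces every file byte for
#' byte.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param verbose print stage progress to stderr.
#' @return list with elements \code{regions}, \code{groundTruth},
#'   \code{networks} (named list of \code{WeightedNetwork}s) and
#'   \code{report} (a \code{\link{SimilarityReport}}).
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sd0 <- as.integer(config$seed)

  say("simulate: regions + ground truth")
  regions <- stage("simulate", makeRegions(config$nRegions,
                                           config$fractionSubcortical,
                                           seed = sd0 + 1L))
  gt <- stage("simulate", makeGroundTruth(regions, config$distanceScaleMm,
                                          config$homotopicProb,
                                          config$targetDensity,
                                          seed = sd0 + 2L))
  say("simulate: streamlines, features, time series")
  streams <- stage("simulate", simulateStreamlines(
    gt, regions, config$nSubjects, config$dispersion,
    config$falsePositiveRate, config$dropoutRate, seed = sd0 + 3L))
  uptake <- stage("simulate", simulateFeatures(
    gt, regions, config$nSubjects, config$coupling, config$noiseSd,
    config$globalConfoundSd, mode = "uptake", seed = sd0 + 4L))
  volume <- stage("simulate", simulateFeatures(
    gt, regions, config$nSubjects, config$coupling, config$noiseSd,
    config$globalConfoundSd, mode = "volume", seed = sd0 + 5L))
  tsList <- stage("simulate", simulateTimeSeries(
    gt, config$nSubjects, config$nVolumes, config$samplingInterval,
    config$driftAmplitude, config$highfreqAmplitude, config$coupling,
    config$nuisanceLoadingSd, seed = sd0 + 6L))

  say("build-sc")
  sc <- stage("build-sc", groupStructural(
    lapply(streams, normalizeBySurface, regions = regions),
    resample = config$resample,
    consistencyThreshold = config$consistencyThreshold))
  say("build-fc")
  fc <- stage("build-fc", buildFC(tsList, config$lowHz, config$highHz))
  say("build-cov")
  fdg <- stage("build-cov", buildFDGcov(uptake, regions,
                                        config$uptakeNormalization))
  gmv <- stage("build-cov", buildGMVcov(volume))

  networks <- list(SC = sc, FC = fc, FDGcov = fdg, GMVcov = gmv)
  say("compare")
  report <- stage("compare", similarityReport(
    networks, regions, sMin = config$sMin, sMax = config$sMax,
    step = config$step, sMaxCap = config$sMaxCap, edgeSet = config$edgeSet,
    positiveOnly = config$positiveOnly,
    regressDistance = config$regressDistance,
    cortexOnly = config$cortexOnly, pairs = config$pairs))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$outDir, f)
    writeRegions(regions, p("regions.tsv"))
    writeNetwork(weightedNetwork(gtWeights(gt), "other", labels(regions)),
                 p("ground_truth.tsv"))
    for (nm in names(networks))
      writeNetwork(networks[[nm]], p(paste0(tolower(nm), ".tsv")))
    writeLines(formatReport(report), p("report.txt"))
    curves <- do.call(rbind, lapply(names(report@results), function(nm)
      cbind(pair = nm, report@results[[nm]]@crCurve)))
    utils::write.table(curves, p("cr_curves.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jr <- lapply(report@results, function(x) list(
      pair = paste(x@pair, collapse = "-"), rho = x@rho, p = x@pValue,
      p_bonferroni = x@pBonferroni, mean_cr = x@meanCR,
      chance_cr = x@chanceCR))
    jsonlite::write_json(
      list(results = jr,
           grid = list(min = min(report@grid), max = max(report@grid),
                       step = config$step, note = report@gridNote),
           variants = report@variants),
      p("report.json"), auto_unbox = TRUE, digits = NA)
    cfgFlat <- config
    cfgFlat$consistencyThreshold <-
      if (is.null(config$consistencyThreshold)) "none"
      else config$consistencyThreshold
    cfgFlat$outDir <- NULL
    writeLines(c("# pipeline settings and stage seeds",
                 paste0(names(cfgFlat), " = ",
                        vapply(cfgFlat, function(v) paste(format(v), collapse = ","),
                               character(1))),
                 paste0("stage seeds = ",
                        paste(sd0 + 1:6, collapse = ","))),
               p("log.txt"))
  }
  list(regions = regions, groundTruth = gt, networks = networks,
       report = report)
}
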