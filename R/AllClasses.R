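#' @import methods
NULL

.LOBES <- c("frontal", "limbic", "occipital", "parietal", "subcortical",
            "temporal", "cerebellar", "vermis")
.CORTICAL_LOBES <- c("frontal", "limbic", "occipital", "parietal", "temporal")
.MODALITIES <- c("SC", "FC", "FDGcov", "GMVcov", "other")

#' RegionSet: per-region metadata for a grey-matter parcellation
#'
#' Holds one row per region: label, hemisphere, lobe, cortical flag, centroid
#' coordinates (mm), white-matter/grey-matter interface surface area (mm^2),
#' regional volume (mm^3) and the index of the homotopic (mirror-hemisphere)
#' partner, or \code{NA} for midline (vermis) regions.
#'
#' @slot info data.frame with columns \code{region_id}, \code{label},
#'   \code{hemisphere} ("L", "R" or "M" for midline), \code{lobe},
#'   \code{cortical}, \code{x}, \code{y}, \code{z}, \code{surface_area},
#'   \code{volume}, \code{homotopic_partner}.
#' @export
setClass("RegionSet", representation(info = "data.frame"))

setValidity("RegionSet", function(object) {
  df <- object@info
  need <- c("region_id", "label", "hemisphere", "lobe", "cortical",
            "x", "y", "z", "surface_area", "volume", "homotopic_partner")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (anyDuplicated(df$label)) return("region labels must be unique")
  if (!all(df$hemisphere %in% c("L", "R", "M")))
    return("hemisphere must be one of L, R, M")
  if (!all(df$lobe %in% .LOBES))
    return(paste("unknown lobe; allowed:", paste(.LOBES, collapse = ", ")))
  if (any(df$surface_area <= 0)) return("surface_area must be positive")
  if (any(df$volume <= 0)) return("volume must be positive")
  nonv <- df$lobe != "vermis"
  hp <- df$homotopic_partner[nonv]
  if (anyNA(hp)) return("every non-vermis region needs a homotopic partner")
  idx <- match(hp, df$region_id)
  if (anyNA(idx)) return("homotopic_partner refers to unknown region_id")
  if (!all(df$homotopic_partner[idx] == df$region_id[nonv], na.rm = TRUE))
    return("homotopic pairing must be mutual")
  if (any(df$hemisphere[idx] == df$hemisphere[nonv]))
    return("homotopic partners must lie in opposite hemispheres")
  TRUE
})

#' @describeIn RegionSet number of regions
#' @param x,object a \code{RegionSet}
#' @export
setMethod("length", "RegionSet", function(x) nrow(x@info))

#' @describeIn RegionSet region labels
#' @export
setMethod("labels", "RegionSet", function(object, ...) object@info$label)

#' Accessors for RegionSet
#'
#' \code{centroids} returns the n x 3 matrix of centroid coordinates (mm);
#' \code{surfaceAreas} the interface surface areas (mm^2); \code{regionVolumes}
#' the regional volumes (mm^3); \code{regionLobes} the lobe assignment;
#' \code{isCortical} the cortical flag (cerebellum, vermis and subcortical
#' structures are non-cortical).
#'
#' @param regions a \code{RegionSet}
#' @return vector or matrix with one entry/row per region, named by label.
#' @export
centroids <- function(regions) {
  stopifnot(is(regions, "RegionSet"))
  m <- as.matrix(regions@info[, c("x", "y", "z")])
  rownames(m) <- regions@info$label
  m
}

#' @rdname centroids
#' @export
surfaceAreas <- function(regions) {
  stopifnot(is(regions, "RegionSet"))
  stats::setNames(regions@info$surface_area, regions@info$label)
}

#' @rdname centroids
#' @export
regionVolumes <- function(regions) {
  stopifnot(is(regions, "RegionSet"))
  stats::setNames(regions@info$volume, regions@info$label)
}

#' @rdname centroids
#' @export
regionLobes <- function(regions) {
  stopifnot(is(regions, "RegionSet"))
  stats::setNames(regions@info$lobe, regions@info$label)
}

#' @rdname centroids
#' @export
isCortical <- function(regions) {
  stopifnot(is(regions, "RegionSet"))
  stats::setNames(regions@info$cortical, regions@info$label)
}

#' Subset a RegionSet
#'
#' Drops regions and re-indexes; homotopic partners falling outside the subset
#' become \code{NA} only if their mate is removed, which is rejected for
#' non-vermis regions unless both mates go together.
#' @param x a \code{RegionSet}
#' @param i logical or integer index over regions
#' @param j,drop,... ignored
#' @export
setMethod("[", "RegionSet", function(x, i, j, ..., drop = FALSE) {
  df <- x@info[i, , drop = FALSE]
  old_id <- df$region_id
  df$region_id <- seq_len(nrow(df))
  df$homotopic_partner <- match(df$homotopic_partner, old_id)
  rownames(df) <- NULL
  new("RegionSet", info = df)
})

setMethod("show", "RegionSet", function(object) {
  df <- object@info
  cat(sprintf("RegionSet with %d regions (%d cortical)\n",
              nrow(df), sum(df$cortical)))
  tab <- table(df$lobe)
  cat("  lobes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' GroundTruth: planted weighted network for synthetic cohorts
#'
#' @slot weights symmetric nonnegative weight matrix, zero diagonal.
#' @slot support symmetric logical matrix, TRUE exactly where weights > 0.
#' @slot params list of generative parameters (distance scale, homotopic
#'   probability, target density, seed).
#' @export
setClass("GroundTruth",
         representation(weights = "matrix", support = "matrix", params = "list"))

setValidity("GroundTruth", function(object) {
  w <- object@weights; s <- object@support
  if (!identical(dim(w), dim(s))) return("weights and support dims differ")
  if (!isSymmetric(unname(w))) return("weights must be symmetric")
  if (any(diag(w) != 0)) return("weights diagonal must be zero")
  if (any(w < 0)) return("weights must be nonnegative")
  if (!is.logical(s)) return("support must be logical")
  if (!identical(unname(s), unname(w > 0))) return("support must equal weights > 0")
  TRUE
})

#' @describeIn GroundTruth ground-truth weight matrix
#' @param object a \code{GroundTruth}
#' @export
setGeneric("gtWeights", function(object) standardGeneric("gtWeights"))
#' @rdname GroundTruth-class
#' @export
setMethod("gtWeights", "GroundTruth", function(object) object@weights)

#' @describeIn GroundTruth logical edge support matrix
#' @export
setGeneric("gtSupport", function(object) standardGeneric("gtSupport"))
#' @rdname GroundTruth-class
#' @export
setMethod("gtSupport", "GroundTruth", function(object) object@support)

setMethod("show", "GroundTruth", function(object) {
  n <- nrow(object@weights)
  e <- sum(object@support[upper.tri(object@support)])
  cat(sprintf("GroundTruth network: %d regions, %d edges (density %.3f)\n",
              n, e, e / (n * (n - 1) / 2)))
})

#' WeightedNetwork: symmetric weighted connectivity matrix
#'
#' A symmetric region-by-region real matrix with exactly-zero diagonal and a
#' modality tag. Weights are surface-normalized streamline counts (SC),
#' Pearson correlations of time series (FC) or across-subject Pearson
#' correlations of regional features (FDGcov, GMVcov).
#'
#' @slot weights symmetric numeric matrix with region labels as dimnames.
#' @slot modality one of "SC", "FC", "FDGcov", "GMVcov", "other".
#' @export
setClass("WeightedNetwork",
         representation(weights = "matrix", modality = "character"))

setValidity("WeightedNetwork", function(object) {
  w <- object@weights
  if (!is.numeric(w) || nrow(w) != ncol(w)) return("weights must be square numeric")
  if (is.null(rownames(w)) || !identical(rownames(w), colnames(w)))
    return("weights need identical row/column labels")
  if (!isSymmetric(unname(w))) return("weights must be symmetric")
  if (any(diag(w) != 0)) return("diagonal must be exactly zero")
  if (length(object@modality) != 1 || !object@modality %in% .MODALITIES)
    return(paste("modality must be one of", paste(.MODALITIES, collapse = ", ")))
  TRUE
})

#' Construct a WeightedNetwork
#'
#' Symmetrizes tiny numerical asymmetry (averaging with the transpose) and
#' zeroes the diagonal before validity checking.
#'
#' @param weights square numeric matrix (labels as dimnames, or supplied).
#' @param modality modality tag.
#' @param labels optional region labels when \code{weights} has no dimnames.
#' @return a \code{WeightedNetwork}.
#' @export
weightedNetwork <- function(weights, modality = "other", labels = NULL) {
  w <- as.matrix(weights)
  if (!is.null(labels)) dimnames(w) <- list(labels, labels)
  if (is.null(rownames(w)))
    dimnames(w) <- list(paste0("R", seq_len(nrow(w))), paste0("R", seq_len(nrow(w))))
  w <- (w + t(w)) / 2
  diag(w) <- 0
  new("WeightedNetwork", weights = w, modality = modality)
}

#' @describeIn WeightedNetwork weight matrix accessor
#' @param object a \code{WeightedNetwork}
#' @export
setGeneric("netWeights", function(object) standardGeneric("netWeights"))
#' @rdname WeightedNetwork-class
#' @export
setMethod("netWeights", "WeightedNetwork", function(object) object@weights)

#' @describeIn WeightedNetwork modality tag accessor
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))
#' @rdname WeightedNetwork-class
#' @export
setMethod("modality", "WeightedNetwork", function(object) object@modality)

#' @describeIn WeightedNetwork number of regions
#' @param x a \code{WeightedNetwork}
#' @export
setMethod("length", "WeightedNetwork", function(x) nrow(x@weights))

#' @describeIn WeightedNetwork region labels
#' @export
setMethod("labels", "WeightedNetwork", function(object, ...) rownames(object@weights))

setMethod("show", "WeightedNetwork", function(object) {
  w <- object@weights
  cat(sprintf("WeightedNetwork [%s]: %d regions, sparsity %.3f, weight range [%.3g, %.3g]\n",
              object@modality, nrow(w), sparsityOf(object),
              min(w[upper.tri(w)]), max(w[upper.tri(w)])))
})

#' BinaryNetwork: binarized adjacency with its realized sparsity
#'
#' @slot adjacency symmetric logical matrix, FALSE diagonal.
#' @slot sparsity fraction of absent edges among the N(N-1)/2 region pairs.
#' @export
setClass("BinaryNetwork",
         representation(adjacency = "matrix", sparsity = "numeric"))

setValidity("BinaryNetwork", function(object) {
  a <- object@adjacency
  if (!is.logical(a) || nrow(a) != ncol(a)) return("adjacency must be square logical")
  if (!isSymmetric(unname(a * 1))) return("adjacency must be symmetric")
  if (any(diag(a))) return("diagonal must be FALSE")
  E <- nrow(a) * (nrow(a) - 1) / 2
  s <- 1 - sum(a[upper.tri(a)]) / E
  if (abs(s - object@sparsity) > 1e-12)
    return("stored sparsity disagrees with adjacency")
  TRUE
})

#' @describeIn BinaryNetwork adjacency accessor
#' @param object a \code{BinaryNetwork}
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname BinaryNetwork-class
#' @export
setMethod("adjacency", "BinaryNetwork", function(object) object@adjacency)

#' @describeIn BinaryNetwork realized sparsity accessor
#' @export
setGeneric("sparsity", function(object) standardGeneric("sparsity"))
#' @rdname BinaryNetwork-class
#' @export
setMethod("sparsity", "BinaryNetwork", function(object) object@sparsity)

setMethod("show", "BinaryNetwork", function(object) {
  cat(sprintf("BinaryNetwork: %d regions, %d edges, sparsity %.4f\n",
              nrow(object@adjacency),
              sum(object@adjacency[upper.tri(object@adjacency)]),
              object@sparsity))
})

#' RegionalTimeSeries: one subject's regional signals plus nuisance regressors
#'
#' @slot signals region x time numeric matrix (rows named by region label).
#' @slot nuisance time x k numeric matrix (k >= 2; WM-like and CSF-like
#'   components).
#' @slot samplingInterval sampling interval in seconds (TR).
#' @export
setClass("RegionalTimeSeries",
         representation(signals = "matrix", nuisance = "matrix",
                        samplingInterval = "numeric"))

setValidity("RegionalTimeSeries", function(object) {
  if (ncol(object@signals) < 32) return("need at least 32 time points")
  if (nrow(object@nuisance) != ncol(object@signals))
    return("nuisance rows must match signal time points")
  if (object@samplingInterval <= 0) return("samplingInterval must be > 0")
  TRUE
})

#' @describeIn RegionalTimeSeries region x time signal matrix
#' @param object a \code{RegionalTimeSeries}
#' @export
setGeneric("signals", function(object) standardGeneric("signals"))
#' @rdname RegionalTimeSeries-class
#' @export
setMethod("signals", "RegionalTimeSeries", function(object) object@signals)

#' @describeIn RegionalTimeSeries time x k nuisance matrix
#' @export
setGeneric("nuisance", function(object) standardGeneric("nuisance"))
#' @rdname RegionalTimeSeries-class
#' @export
setMethod("nuisance", "RegionalTimeSeries", function(object) object@nuisance)

#' @describeIn RegionalTimeSeries sampling interval (s)
#' @export
setGeneric("samplingInterval", function(object) standardGeneric("samplingInterval"))
#' @rdname RegionalTimeSeries-class
#' @export
setMethod("samplingInterval", "RegionalTimeSeries", function(object) object@samplingInterval)

setMethod("show", "RegionalTimeSeries", function(object) {
  cat(sprintf("RegionalTimeSeries: %d regions x %d volumes, TR %.3g s, %d nuisance regressors\n",
              nrow(object@signals), ncol(object@signals),
              object@samplingInterval, ncol(object@nuisance)))
})

#' CohortFeatures: subject x region table of one regional feature
#'
#' @slot values subject x region numeric matrix (columns named by region).
#' @slot mode "uptake" (tracer uptake) or "volume" (grey-matter volume).
#' @export
setClass("CohortFeatures",
         representation(values = "matrix", mode = "character"))

setValidity("CohortFeatures", function(object) {
  if (anyNA(object@values)) return("no missing entries allowed")
  if (nrow(object@values) < 3)
    return("need at least 3 subjects for across-subject correlation")
  if (!object@mode %in% c("uptake", "volume"))
    return("mode must be 'uptake' or 'volume'")
  TRUE
})

#' @describeIn CohortFeatures subject x region value matrix
#' @param object a \code{CohortFeatures}
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname CohortFeatures-class
#' @export
setMethod("featureValues", "CohortFeatures", function(object) object@values)

#' @describeIn CohortFeatures feature mode ("uptake" or "volume")
#' @export
setGeneric("featureMode", function(object) standardGeneric("featureMode"))
#' @rdname CohortFeatures-class
#' @export
setMethod("featureMode", "CohortFeatures", function(object) object@mode)

setMethod("show", "CohortFeatures", function(object) {
  cat(sprintf("CohortFeatures [%s]: %d subjects x %d regions\n",
              object@mode, nrow(object@values), ncol(object@values)))
})

#' SimilarityResult: one network pair's strength and spatial similarity
#'
#' @slot pair character(2): the two modality tags.
#' @slot rho Spearman rank correlation over the chosen edge set.
#' @slot pValue asymptotic p for rho.
#' @slot pBonferroni Bonferroni-adjusted p (multiplied by the number of pairs
#'   in the enclosing report, capped at 1).
#' @slot crCurve data.frame with columns \code{sparsity}, \code{cr}.
#' @slot meanCR mean convergence ratio over the grid.
#' @slot chanceCR analytic chance convergence ratio for the same grid.
#' @slot edgeSet "ref_support" or "all".
#' @slot positiveOnly,distanceRegressed variant flags.
#' @export
setClass("SimilarityResult",
         representation(pair = "character", rho = "numeric", pValue = "numeric",
                        pBonferroni = "numeric", crCurve = "data.frame",
                        meanCR = "numeric", chanceCR = "numeric",
                        edgeSet = "character", positiveOnly = "logical",
                        distanceRegressed = "logical"))

setValidity("SimilarityResult", function(object) {
  if (length(object@pair) != 2) return("pair must have two modalities")
  if (abs(object@rho) > 1 + 1e-12) return("rho outside [-1, 1]")
  if (object@meanCR < 0 || object@meanCR > 1) return("meanCR outside [0, 1]")
  if (object@chanceCR < 0 || object@chanceCR > 1) return("chanceCR outside [0, 1]")
  TRUE
})

setMethod("show", "SimilarityResult", function(object) {
  cat(sprintf("%s-%s: rho = %.2f (p = %.3g, Bonferroni %.3g), mean CR = %d%%, chance CR = %d%%\n",
              object@pair[1], object@pair[2], object@rho, object@pValue,
              object@pBonferroni, round(100 * object@meanCR),
              round(100 * object@chanceCR)))
})

#' SimilarityReport: all pairwise similarities plus grid and variant metadata
#'
#' @slot results list of \code{SimilarityResult}, named "A-B".
#' @slot grid numeric sparsity grid used.
#' @slot overlaps list of logical matrices: common edges per pair at the grid
#'   maximum sparsity.
#' @slot variants named list of variant flags (resample, consistency,
#'   positiveOnly, regressDistance, cortexOnly, pairs).
#' @slot gridNote "auto", "configured" or "no-connected-sparsity fallback".
#' @export
setClass("SimilarityReport",
         representation(results = "list", grid = "numeric", overlaps = "list",
                        variants = "list", gridNote = "character"))

setMethod("show", "SimilarityReport", function(object) {
  cat(formatReport(object), sep = "\n")
})
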