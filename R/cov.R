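## Inter-subject covariance networks: tracer-uptake covariance (FDGcov) after
## per-subject global normalization, and grey-matter-volume covariance
## (GMVcov) after regressing out each subject's total volume.

#' Normalize regional uptake by each subject's mean grey-matter uptake
#'
#' Divides each subject's row by that subject's mean uptake, removing global
#' (dose, delivery, whole-brain metabolism) scaling. The default mean is
#' volume-weighted across regions -- the closest region-level analog of a
#' whole-grey-matter mean -- with a simple unweighted mean as an option.
#'
#' @param features a \code{CohortFeatures} with mode "uptake".
#' @param regions the matching \code{RegionSet}.
#' @param normalization "volume_weighted_mean" or "simple_mean".
#' @return a normalized \code{CohortFeatures}.
#' @export
normalizeUptake <- function(features, regions,
                            normalization = c("volume_weighted_mean",
                                              "simple_mean")) {
  stopifnot(is(features, "CohortFeatures"), is(regions, "RegionSet"))
  normalization <- match.arg(normalization)
  if (featureMode(features) != "uptake")
    stop("normalizeUptake applies to mode 'uptake' only")
  vals <- featureValues(features)
  if (ncol(vals) != length(regions))
    stop("features and regions are dimension-mismatched")
  wts <- if (normalization == "volume_weighted_mean")
    regionVolumes(regions) else rep(1, length(regions))
  m <- as.numeric(vals %*% (wts / sum(wts)))
  bad <- which(m <= 0)
  if (length(bad))
    stop("nonpositive mean uptake for subject(s): ",
         paste(bad, collapse = ", "))
  new("CohortFeatures", values = vals / m, mode = "uptake")
}

#' Regress total grey-matter volume out of regional volumes
#'
#' Per region, ordinary least squares across subjects of regional volume on
#' the subject's total volume (sum over regions) with an intercept; rows are
#' replaced by the residuals. Removes the global head-size / atrophy factor
#' before covariance estimation.
#'
#' @param features a \code{CohortFeatures} with mode "volume" and >= 3
#'   subjects.
#' @return a \code{CohortFeatures} of residuals.
#' @export
removeGlobalVolume <- function(features) {
  stopifnot(is(features, "CohortFeatures"))
  if (featureMode(features) != "volume")
    stop("removeGlobalVolume applies to mode 'volume' only")
  vals <- featureValues(features)
  total <- rowSums(vals)
  if (stats::sd(total) == 0)
    stop("total volume is constant across subjects: regressor is degenerate")
  fit <- stats::lm.fit(cbind(1, total), vals)
  res <- fit$residuals
  # a region fully explained by total volume keeps only floating-point noise;
  # zero it so downstream correlation refuses instead of correlating noise
  sdRaw <- apply(vals, 2, stats::sd)
  sdRes <- apply(res, 2, stats::sd)
  res[, sdRes < 1e-8 * pmax(sdRaw, .Machine$double.eps)] <- 0
  dimnames(res) <- dimnames(vals)
  new("CohortFeatures", values = res, mode = "volume")
}

#' Across-subject covariance network
#'
#' Pearson correlation between every pair of regions across subjects -- one
#' group-level matrix, not a per-subject estimate. The diagonal is set to
#' zero.
#'
#' @param features a \code{CohortFeatures} (normalized/residualized as
#'   appropriate).
#' @param modalityTag "FDGcov", "GMVcov" or "other".
#' @return a \code{\link{WeightedNetwork}}.
#' @export
covarianceNetwork <- function(features, modalityTag = "other") {
  stopifnot(is(features, "CohortFeatures"))
  vals <- featureValues(features)
  v <- apply(vals, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance region(s) across subjects: ",
         paste(colnames(vals)[v == 0], collapse = ", "))
  r <- stats::cor(vals)
  diag(r) <- 0
  new("WeightedNetwork", weights = r, modality = modalityTag)
}

#' Build the FDGcov network from raw uptake tables
#'
#' Pipeline: per-subject normalization by mean grey-matter uptake, then
#' across-subject correlation. Invariant to per-subject global rescaling of
#' the raw table.
#'
#' @param features raw uptake \code{CohortFeatures}.
#' @param regions the matching \code{RegionSet}.
#' @param normalization see \code{\link{normalizeUptake}}.
#' @return a \code{WeightedNetwork} with modality "FDGcov".
#' @export
buildFDGcov <- function(features, regions,
                        normalization = "volume_weighted_mean") {
  covarianceNetwork(normalizeUptake(features, regions, normalization),
                    modalityTag = "FDGcov")
}

#' Build the GMVcov network from raw regional volume tables
#'
#' Pipeline: regress out each subject's total grey-matter volume, then
#' across-subject correlation of the residuals.
#'
#' @param features raw volume \code{CohortFeatures}.
#' @return a \code{WeightedNetwork} with modality "GMVcov".
#' @export
buildGMVcov <- function(features) {
  covarianceNetwork(removeGlobalVolume(features), modalityTag = "GMVcov")
}
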