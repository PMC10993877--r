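## Group structural connectivity from subject streamline-count matrices:
## surface-area normalization, rank-Gaussian resampling, group averaging and
## the proportional consistency threshold.

#' Normalize streamline counts by interface surface area
#'
#' Converts a subject's raw streamline-count matrix into connection weights
#' \code{w_ij = n_ij / ((A_i + A_j) / 2)} -- streamlines per mm^2 of the mean
#' white-/grey-matter interface area of the two regions -- compensating for
#' surface-driven effects on streamline counts. Zeros stay zero.
#'
#' @param counts symmetric nonnegative integer matrix of streamline counts
#'   (region labels as dimnames).
#' @param regions the matching \code{RegionSet}.
#' @return a \code{\link{WeightedNetwork}} with modality "SC".
#' @examples
#' # 10 streamlines between regions with areas 4 and 6 -> weight 2.0
#' @export
normalizeBySurface <- function(counts, regions) {
  stopifnot(is(regions, "RegionSet"))
  counts <- as.matrix(counts)
  if (nrow(counts) != length(regions))
    stop("counts and regions are dimension-mismatched")
  A <- surfaceAreas(regions)
  if (any(A <= 0)) stop("surface areas must be positive")
  denom <- outer(A, A, `+`) / 2
  w <- counts / denom
  weightedNetwork(w, modality = "SC", labels = labels(regions))
}

#' Rank-Gaussian resampling of connection weights
#'
#' Replaces the m nonzero upper-triangle weights by standard-normal quantiles
#' of their average ranks, \code{qnorm((r - 0.5) / m)}; zeros are structural
#' absences and remain zero; tied weights share the average rank and hence the
#' same quantile. The transform is monotone, so edge ordering is preserved.
#'
#' @param net a \code{WeightedNetwork} with at least one nonzero weight.
#' @return a \code{WeightedNetwork} of resampled weights.
#' @export
gaussianResample <- function(net) {
  w <- netWeights(net)
  ut <- upper.tri(w)
  v <- w[ut]
  nz <- v != 0
  m <- sum(nz)
  if (m == 0) stop("cannot resample an all-zero matrix")
  r <- rank(v[nz])                       # average ranks for ties
  v[nz] <- stats::qnorm((r - 0.5) / m)
  out <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  out[ut] <- v
  out <- out + t(out)
  new("WeightedNetwork", weights = out, modality = modality(net))
}

#' Group structural connectivity network
#'
#' Element-wise mean across subjects of the (optionally rank-Gaussian
#' resampled) subject weights, with absent connections contributing zero.
#' When a consistency threshold c is given, connections whose fraction of
#' subjects with a nonzero count is not strictly greater than c are removed
#' ("present in more than 100c percent of subjects").
#'
#' @param subjectNets list of per-subject \code{WeightedNetwork}s with
#'   identical labels (normalized streamline weights).
#' @param resample apply \code{\link{gaussianResample}} per subject first.
#' @param consistencyThreshold retention threshold in [0, 1], or \code{NULL}
#'   for no thresholding.
#' @return a \code{WeightedNetwork} with modality "SC".
#' @export
groupStructural <- function(subjectNets, resample = TRUE,
                            consistencyThreshold = 0.75) {
  if (length(subjectNets) < 2) stop("need at least 2 subjects")
  labs <- lapply(subjectNets, labels)
  if (!all(vapply(labs, identical, logical(1), y = labs[[1]])))
    stop("subject networks have mismatched region labels")
  if (!is.null(consistencyThreshold) &&
      (consistencyThreshold < 0 || consistencyThreshold > 1))
    stop("consistencyThreshold must lie in [0, 1]")

  present <- Reduce(`+`, lapply(subjectNets, function(n) netWeights(n) != 0))
  use <- if (resample) lapply(subjectNets, gaussianResample) else subjectNets
  avg <- Reduce(`+`, lapply(use, netWeights)) / length(use)

  if (!is.null(consistencyThreshold)) {
    frac <- present / length(subjectNets)
    avg[frac <= consistencyThreshold] <- 0
  }
  diag(avg) <- 0
  new("WeightedNetwork", weights = avg, modality = "SC")
}
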