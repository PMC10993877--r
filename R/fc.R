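## Functional connectivity from regional time series: WM/CSF nuisance
## regression, zero-phase band-pass, per-subject Pearson matrices, and
## Fisher-z group averaging.

#' Regress nuisance components out of regional signals
#'
#' Replaces each regional signal by its residual from an ordinary
#' least-squares fit on the nuisance columns plus an intercept (so the output
#' is also demeaned). Motion regressors are deliberately not part of the
#' model; only the supplied WM-/CSF-like components are removed.
#'
#' @param ts a \code{RegionalTimeSeries}.
#' @return a \code{RegionalTimeSeries} of residuals (nuisance kept for
#'   reference).
#' @export
regressNuisance <- function(ts) {
  stopifnot(is(ts, "RegionalTimeSeries"))
  nuis <- nuisance(ts)
  nuis <- nuis[, colSums(nuis != 0) > 0, drop = FALSE]  # all-zero: intercept only
  X <- cbind(1, nuis)
  if (qr(X)$rank < ncol(X))
    stop("nuisance design is rank-deficient (duplicate or constant columns)")
  fit <- stats::lm.fit(X, t(signals(ts)))
  res <- t(fit$residuals)
  dimnames(res) <- dimnames(signals(ts))
  new("RegionalTimeSeries", signals = res, nuisance = nuisance(ts),
      samplingInterval = samplingInterval(ts))
}

#' Zero-phase temporal band-pass filter
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (\code{signal::filtfilt}), so the output has no phase distortion and the
#' same length as the input. The default band 0.009-0.080 Hz removes scanner
#' drift below and cardiac/respiratory components above the functional band.
#'
#' @param ts a \code{RegionalTimeSeries}.
#' @param lowHz high-pass edge in Hz.
#' @param highHz low-pass edge in Hz; must be below the Nyquist frequency
#'   \code{1 / (2 * samplingInterval)}.
#' @param order filter order (per pass).
#' @return a filtered \code{RegionalTimeSeries}.
#' @export
bandpassFilter <- function(ts, lowHz = 0.009, highHz = 0.080, order = 2) {
  stopifnot(is(ts, "RegionalTimeSeries"))
  nyq <- 1 / (2 * samplingInterval(ts))
  if (!(lowHz > 0 && lowHz < highHz)) stop("need 0 < lowHz < highHz")
  if (highHz >= nyq)
    stop(sprintf("highHz = %g Hz is at or above Nyquist (%g Hz)", highHz, nyq))
  bf <- signal::butter(order, c(lowHz, highHz) / nyq, type = "pass")
  filt <- t(apply(signals(ts), 1, function(x) signal::filtfilt(bf, x)))
  dimnames(filt) <- dimnames(signals(ts))
  new("RegionalTimeSeries", signals = filt, nuisance = nuisance(ts),
      samplingInterval = samplingInterval(ts))
}

#' Subject functional connectivity matrix
#'
#' Pairwise Pearson correlation between regional signals; the diagonal is set
#' to zero.
#'
#' @param ts a \code{RegionalTimeSeries} (typically after
#'   \code{\link{regressNuisance}} and \code{\link{bandpassFilter}}), or a
#'   plain region x time matrix.
#' @return a \code{\link{WeightedNetwork}} with modality "FC".
#' @export
subjectFC <- function(ts) {
  sig <- if (is.matrix(ts)) ts else signals(ts)
  v <- apply(sig, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance region(s): ",
         paste(rownames(sig)[v == 0], collapse = ", "))
  r <- stats::cor(t(sig))
  diag(r) <- 0
  new("WeightedNetwork", weights = r, modality = "FC")
}

#' Group functional connectivity by Fisher-z averaging
#'
#' Per edge, applies the Fisher z-transformation \code{atanh(r)} to each
#' subject's correlation, averages across subjects, and transforms back with
#' \code{tanh}. Correlations are clipped at \code{1 - 1e-15} in magnitude to
#' guard against infinities from degenerate inputs; the group value is
#' therefore strictly inside (-1, 1).
#'
#' @param nets list of subject \code{WeightedNetwork}s with identical labels.
#' @return a \code{WeightedNetwork} with modality "FC".
#' @export
groupAverageFC <- function(nets) {
  if (length(nets) < 1) stop("need at least one subject")
  labs <- lapply(nets, labels)
  if (!all(vapply(labs, identical, logical(1), y = labs[[1]])))
    stop("subject networks have mismatched region labels")
  zs <- lapply(nets, function(n) {
    r <- netWeights(n)
    atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  })
  g <- tanh(Reduce(`+`, zs) / length(zs))
  diag(g) <- 0
  new("WeightedNetwork", weights = g, modality = "FC")
}

#' Build the group FC network from raw subject time series
#'
#' Fixed pipeline order: nuisance regression, zero-phase band-pass, Pearson
#' correlation per subject, Fisher-z group average.
#'
#' @param tsList list of \code{RegionalTimeSeries}.
#' @param lowHz,highHz,order band-pass specification.
#' @return a \code{WeightedNetwork} with modality "FC".
#' @export
buildFC <- function(tsList, lowHz = 0.009, highHz = 0.080, order = 2) {
  nets <- lapply(tsList, function(ts)
    subjectFC(bandpassFilter(regressNuisance(ts), lowHz, highHz, order)))
  groupAverageFC(nets)
}
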