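## Synthetic cohorts with a planted, spatially embedded ground-truth network.
## Everything downstream (SC/FC/covariance construction, similarity) can be
## exercised against a known answer with no imaging data.

.LOBE_ABBREV <- c(frontal = "F", limbic = "L", occipital = "O", parietal = "P",
                  subcortical = "S", temporal = "T", cerebellar = "C",
                  vermis = "V")

## Rough lobe centroid anchors in MNI-like mm coordinates (right hemisphere).
.LOBE_CENTERS <- rbind(
  frontal     = c(25,  40,  30),
  limbic      = c(12, -10,  10),
  occipital   = c(22, -85,   5),
  parietal    = c(30, -55,  50),
  subcortical = c(14,  -8,   2),
  temporal    = c(50, -25, -10),
  cerebellar  = c(25, -65, -40),
  vermis      = c( 0, -62, -35))

## largest-remainder apportionment of n among weights p
.apportion <- function(n, p) {
  q <- n * p / sum(p)
  k <- floor(q)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(q - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  k
}

#' Generate a synthetic bilateral parcellation
#'
#' Builds a mirror-symmetric set of regions: paired left/right blocks (every
#' paired region has exactly one homotopic partner in the opposite hemisphere)
#' plus a small block of unpaired midline vermis regions. Lobes are assigned by
#' spatial blocks around anatomically plausible anchor coordinates; interface
#' surface areas and regional volumes are drawn log-normally.
#'
#' @param nRegions total number of regions; must be even and >= 4.
#' @param fractionSubcortical fraction of paired regions that are subcortical,
#'   in [0, 1].
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @return a \code{\link{RegionSet}}.
#' @examples
#' r <- makeRegions(20, 0.1, seed = 1)
#' length(r)
#' @export
makeRegions <- function(nRegions, fractionSubcortical = 0.1, seed = 1) {
  if (nRegions < 4 || nRegions %% 2 != 0)
    stop("nRegions must be an even integer >= 4: homotopic pairing mirrors ",
         "every paired region into the opposite hemisphere")
  if (fractionSubcortical < 0 || fractionSubcortical > 1)
    stop("fractionSubcortical must lie in [0, 1]")
  set.seed(seed)

  nVermis <- round(0.05 * nRegions)
  if ((nRegions - nVermis) %% 2 != 0) nVermis <- nVermis + 1
  nSide <- (nRegions - nVermis) / 2

  base <- c(frontal = 0.30, limbic = 0.12, occipital = 0.12, parietal = 0.14,
            temporal = 0.18, cerebellar = 0.14)
  w <- c(base * (1 - fractionSubcortical), subcortical = fractionSubcortical)
  counts <- .apportion(nSide, w)
  lobeSide <- rep(names(counts), counts)

  jitter <- function(n) matrix(stats::rnorm(3 * n, 0, 8), n, 3)
  ctr <- .LOBE_CENTERS[lobeSide, , drop = FALSE] + jitter(nSide)
  ctr[, 1] <- pmax(ctr[, 1], 2)            # keep lateral regions off midline

  mkLabels <- function(lobes, hemi) {
    ab <- .LOBE_ABBREV[lobes]
    idx <- stats::ave(seq_along(lobes), lobes, FUN = seq_along)
    sprintf("%s%02d.%s", ab, idx, hemi)
  }

  right <- data.frame(lobe = lobeSide, hemisphere = "R",
                      x = ctr[, 1], y = ctr[, 2], z = ctr[, 3])
  left <- right
  left$hemisphere <- "L"
  left$x <- -left$x

  df <- rbind(right, left)
  if (nVermis > 0) {
    vc <- matrix(rep(.LOBE_CENTERS["vermis", ], each = nVermis), nVermis, 3) +
      cbind(stats::rnorm(nVermis, 0, 2), stats::rnorm(nVermis, 0, 8),
            stats::rnorm(nVermis, 0, 8))
    df <- rbind(df, data.frame(lobe = "vermis", hemisphere = "M",
                               x = vc[, 1], y = vc[, 2], z = vc[, 3]))
  }
  n <- nrow(df)
  df$region_id <- seq_len(n)
  df$label <- c(mkLabels(lobeSide, "R"), mkLabels(lobeSide, "L"),
                if (nVermis > 0) sprintf("V%02d.M", seq_len(nVermis)))
  df$cortical <- df$lobe %in% .CORTICAL_LOBES
  df$surface_area <- stats::rlnorm(n, meanlog = log(600), sdlog = 0.5)
  df$volume <- stats::rlnorm(n, meanlog = log(6000), sdlog = 0.6)
  df$homotopic_partner <- as.integer(c(nSide + seq_len(nSide), seq_len(nSide),
                                       rep(NA_integer_, nVermis)))
  rownames(df) <- NULL
  new("RegionSet", info = df[, c("region_id", "label", "hemisphere", "lobe",
                                 "cortical", "x", "y", "z", "surface_area",
                                 "volume", "homotopic_partner")])
}

#' Plant a spatially embedded ground-truth network
#'
#' Samples an undirected weighted network over a \code{RegionSet}: edge
#' inclusion probability decays exponentially with centroid Euclidean distance,
#' homotopic pairs are connected with probability \code{homotopicProb},
#' intra-lobe pairs are boosted, and edges are drawn without replacement until
#' \code{round(targetDensity * E)} edges exist (E = N(N-1)/2). Weights are
#' positive and decrease with distance on average (log-normal scatter around an
#' exponential distance decay; homotopic edges doubled).
#'
#' @param regions a \code{RegionSet}.
#' @param distanceScaleMm e-folding scale of the distance decay, mm.
#' @param homotopicProb probability that a homotopic pair is connected.
#' @param targetDensity target edge density in (0, 1].
#' @param seed integer seed.
#' @return a \code{\link{GroundTruth}}.
#' @export
makeGroundTruth <- function(regions, distanceScaleMm = 40, homotopicProb = 0.9,
                            targetDensity = 0.342, seed = 1) {
  stopifnot(is(regions, "RegionSet"))
  if (targetDensity <= 0 || targetDensity > 1)
    stop("targetDensity must lie in (0, 1]")
  set.seed(seed)
  n <- length(regions)
  E <- n * (n - 1) / 2
  m <- round(targetDensity * E)
  if (m < n - 1)
    warning("targetDensity * E < nRegions - 1: a connected ground truth ",
            "may be impossible")

  lab <- labels(regions)
  D <- edgeDistances(regions)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[ut]
  lobe <- regionLobes(regions)
  intraLobe <- lobe[ut[, 1]] == lobe[ut[, 2]]
  hp <- regions@info$homotopic_partner
  homot <- !is.na(hp[ut[, 1]]) & hp[ut[, 1]] == ut[, 2]

  chosen <- rep(FALSE, E)
  if (homotopicProb > 0)
    chosen[homot] <- stats::runif(sum(homot)) < homotopicProb
  if (sum(chosen) > m)
    chosen[sample(which(chosen), sum(chosen) - m)] <- FALSE
  need <- m - sum(chosen)
  if (need > 0) {
    cand <- which(!chosen)
    p <- exp(-d[cand] / distanceScaleMm) * ifelse(intraLobe[cand], 3, 1)
    chosen[sample(cand, need, prob = p)] <- TRUE
  }

  w <- numeric(E)
  idx <- which(chosen)
  w[idx] <- exp(-d[idx] / distanceScaleMm) *
    stats::rlnorm(length(idx), meanlog = 0, sdlog = 0.6)
  w[idx[homot[idx]]] <- 2 * w[idx[homot[idx]]]   # homotopic edges run strong

  W <- matrix(0, n, n, dimnames = list(lab, lab))
  W[ut] <- w
  W <- W + t(W)
  new("GroundTruth", weights = W, support = W > 0,
      params = list(distanceScaleMm = distanceScaleMm,
                    homotopicProb = homotopicProb,
                    targetDensity = targetDensity, seed = seed))
}

## Correlation matrix planted on the ground-truth graph: a communicability
## (matrix-exponential diffusion) kernel, R = cov2cor(expm(beta * What)) with
## What the weight matrix rescaled to unit spectral radius and
## beta = coupling / (1 - coupling). Signals diffusing along the planted
## edges induce covariance over direct and, more weakly, indirect paths --
## the standard network-diffusion account of how structural connectivity
## shapes functional covariance. The kernel is positive definite for every
## coupling in [0, 1); coupling = 0 gives independent regions.
.plantedCorrelation <- function(gt, coupling) {
  if (coupling < 0 || coupling >= 1)
    stop(sprintf("coupling = %g outside [0, 1): no valid covariance", coupling))
  W <- gtWeights(gt)
  lam <- max(abs(eigen(W, symmetric = TRUE, only.values = TRUE)$values))
  What <- if (lam > 0) W / lam else W
  beta <- coupling / (1 - coupling)
  ei <- eigen(What, symmetric = TRUE)
  S <- ei$vectors %*% (exp(beta * ei$values) * t(ei$vectors))
  R <- stats::cov2cor((S + t(S)) / 2)
  dimnames(R) <- dimnames(W)
  R
}

## Draw n rows from N(0, R) given a correlation matrix (Cholesky).
.rmvn <- function(n, R) {
  L <- chol(R)
  matrix(stats::rnorm(n * nrow(R)), n, nrow(R)) %*% L
}

#' Simulate per-subject streamline-count matrices
#'
#' For each true edge the expected count is proportional to the ground-truth
#' weight times the mean interface surface area of the two regions (so the
#' downstream surface normalization has something to undo), drawn from an
#' overdispersed gamma-Poisson mixture shifted by one (a detected connection
#' carries at least one streamline; missed detections are modelled by
#' \code{dropoutRate}). Non-edges receive a small spurious count with
#' probability \code{falsePositiveRate}.
#'
#' @param gt a \code{GroundTruth}.
#' @param regions the matching \code{RegionSet}.
#' @param nSubjects number of subjects (>= 1).
#' @param dispersion overdispersion of the gamma mixing variable (variance of
#'   the per-edge rate multiplier); 0 gives plain shifted-Poisson counts.
#' @param falsePositiveRate probability that a non-edge gets a spurious count,
#'   in [0, 1).
#' @param dropoutRate probability that a true edge is missed in a subject, in
#'   [0, 1).
#' @param meanCount target mean streamline count over true edges.
#' @param seed integer seed.
#' @return list of \code{nSubjects} symmetric integer count matrices with
#'   region labels as dimnames.
#' @export
simulateStreamlines <- function(gt, regions, nSubjects, dispersion = 0.5,
                                falsePositiveRate = 0.02, dropoutRate = 0.1,
                                meanCount = 100, seed = 1) {
  stopifnot(is(gt, "GroundTruth"), is(regions, "RegionSet"), nSubjects >= 1)
  if (falsePositiveRate < 0 || falsePositiveRate >= 1)
    stop("falsePositiveRate must lie in [0, 1)")
  if (dropoutRate < 0 || dropoutRate >= 1)
    stop("dropoutRate must lie in [0, 1)")
  set.seed(seed)
  n <- length(regions)
  lab <- labels(regions)
  A <- surfaceAreas(regions)
  W <- gtWeights(gt)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  Abar <- (A[ut[, 1]] + A[ut[, 2]]) / 2
  mu <- W[ut] * Abar
  edges <- mu > 0
  if (any(edges)) mu[edges] <- mu[edges] / mean(mu[edges]) * meanCount

  lapply(seq_len(nSubjects), function(s) {
    cnt <- integer(length(mu))
    ne <- sum(edges)
    if (ne > 0) {
      g <- if (dispersion > 0)
        stats::rgamma(ne, shape = 1 / dispersion, rate = 1 / dispersion)
      else rep(1, ne)
      cnt[edges] <- 1L + stats::rpois(ne, mu[edges] * g)
      if (dropoutRate > 0)
        cnt[edges] <- cnt[edges] *
          (stats::runif(ne) >= dropoutRate)
    }
    nf <- sum(!edges)
    if (falsePositiveRate > 0 && nf > 0) {
      fp <- stats::runif(nf) < falsePositiveRate
      cnt[!edges][fp] <- 1L + stats::rpois(sum(fp), 1)
    }
    M <- matrix(0L, n, n, dimnames = list(lab, lab))
    M[ut] <- as.integer(cnt)
    M + t(M)
  })
}

#' Simulate subject x region feature tables (tracer uptake or volume)
#'
#' Subject rows are drawn from a multivariate normal whose correlation
#' structure is planted on the ground-truth network (see
#' \code{\link{makeGroundTruth}}), around a positive regional mean. For
#' \code{mode = "uptake"} each subject row is then multiplied by a log-normal
#' per-subject global scale (dose / global metabolism confound); for
#' \code{mode = "volume"} a per-subject common factor proportional to regional
#' volume is added, so that total volume varies across subjects.
#'
#' @param gt a \code{GroundTruth}.
#' @param regions the matching \code{RegionSet}.
#' @param nSubjects number of subjects (>= 3 for downstream correlation).
#' @param coupling network coupling strength in [0, 1); 0 gives independent
#'   regions.
#' @param noiseSd regional standard deviation in feature units (uptake mode:
#'   absolute units around a baseline of 100; volume mode: scaled per region
#'   in proportion to its volume).
#' @param globalConfoundSd SD of the per-subject global confound (log-scale
#'   for uptake, fractional volume factor for volume).
#' @param mode "uptake" or "volume".
#' @param seed integer seed.
#' @return a \code{\link{CohortFeatures}}.
#' @export
simulateFeatures <- function(gt, regions, nSubjects, coupling = 0.8,
                             noiseSd = 10, globalConfoundSd = 0.2,
                             mode = c("uptake", "volume"), seed = 1) {
  stopifnot(is(gt, "GroundTruth"), is(regions, "RegionSet"))
  mode <- match.arg(mode)
  if (coupling < 0 || coupling >= 1) stop("coupling must lie in [0, 1)")
  R <- .plantedCorrelation(gt, coupling)
  set.seed(seed)
  Z <- .rmvn(nSubjects, R)
  lab <- labels(regions)
  if (mode == "uptake") {
    vals <- matrix(100, nSubjects, length(lab), dimnames = list(NULL, lab)) +
      noiseSd * Z
    if (globalConfoundSd > 0)
      vals <- vals * exp(stats::rnorm(nSubjects, 0, globalConfoundSd))
  } else {
    v <- regionVolumes(regions)
    vals <- matrix(rep(v, each = nSubjects), nSubjects, length(v),
                   dimnames = list(NULL, lab)) +
      noiseSd * sweep(Z, 2, v / mean(v), `*`)
    if (globalConfoundSd > 0) {
      g <- stats::rnorm(nSubjects, 0, globalConfoundSd)
      vals <- vals + outer(g, v)
    }
  }
  new("CohortFeatures", values = vals, mode = mode)
}

#' Simulate per-subject regional BOLD-like time series
#'
#' Draws temporally autocorrelated multivariate series whose spatial
#' correlation is planted on the ground-truth network, then adds (i) a linear
#' drift with per-region coefficients of SD \code{driftAmplitude}, (ii) a
#' 0.15 Hz sinusoid (above the functional band) of amplitude
#' \code{highfreqAmplitude} with random regional phase, and (iii) two slow
#' nuisance components (WM-like and CSF-like) that contaminate the regional
#' signals with subject-specific loadings of SD \code{nuisanceLoadingSd}. The
#' nuisance matrix is returned alongside the signals, mimicking measured WM /
#' CSF regressors.
#'
#' @param gt a \code{GroundTruth}.
#' @param nSubjects number of subjects.
#' @param nVolumes number of retained time points (>= 32).
#' @param samplingInterval TR in seconds.
#' @param driftAmplitude SD of per-region linear drift coefficients (signal
#'   units over the whole run).
#' @param highfreqAmplitude amplitude of the out-of-band sinusoid.
#' @param coupling network coupling strength in [0, 1).
#' @param nuisanceLoadingSd SD of the regional loadings on the two nuisance
#'   components (signal units).
#' @param seed integer seed.
#' @return list of \code{nSubjects} \code{\link{RegionalTimeSeries}}.
#' @export
simulateTimeSeries <- function(gt, nSubjects, nVolumes = 209,
                               samplingInterval = 2.26, driftAmplitude = 1,
                               highfreqAmplitude = 1, coupling = 0.8,
                               nuisanceLoadingSd = 0.5, seed = 1) {
  stopifnot(is(gt, "GroundTruth"))
  if (nVolumes < 32) stop("nVolumes must be >= 32")
  if (samplingInterval <= 0) stop("samplingInterval must be positive")
  R <- .plantedCorrelation(gt, coupling)
  L <- chol(R)
  n <- nrow(R)
  lab <- rownames(R)
  set.seed(seed)
  tIdx <- seq_len(nVolumes)
  ramp <- (tIdx - mean(tIdx)) / (nVolumes / 2)   # -1..1 over the run
  sine <- sin(2 * pi * 0.15 * samplingInterval * tIdx)
  cosn <- cos(2 * pi * 0.15 * samplingInterval * tIdx)

  smooth1 <- function(x, a) as.numeric(stats::filter(x, a, "recursive"))
  lapply(seq_len(nSubjects), function(s) {
    X <- matrix(stats::rnorm(nVolumes * n), nVolumes, n) %*% L
    X <- apply(X, 2, smooth1, a = 0.5)          # AR(1)-like temporal smoothing
    if (driftAmplitude > 0)
      X <- X + outer(ramp, stats::rnorm(n, 0, driftAmplitude))
    if (highfreqAmplitude > 0) {
      phi <- stats::runif(n, 0, 2 * pi)
      X <- X + highfreqAmplitude * (outer(sine, cos(phi)) + outer(cosn, sin(phi)))
    }
    nuis <- cbind(WM = scale(smooth1(stats::rnorm(nVolumes), 0.9))[, 1],
                  CSF = scale(smooth1(stats::rnorm(nVolumes), 0.8))[, 1])
    if (nuisanceLoadingSd > 0) {
      Lo <- matrix(stats::rnorm(2 * n, 0, nuisanceLoadingSd), n, 2)
      X <- X + nuis %*% t(Lo)
    }
    sig <- t(X)
    rownames(sig) <- lab
    new("RegionalTimeSeries", signals = sig, nuisance = nuis,
        samplingInterval = samplingInterval)
  })
}
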