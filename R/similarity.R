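## Similarity between connectivity networks: strength (Spearman) and space
## (convergence ratio over a sparsity sweep), with chance levels, a
## connectedness bound on the sweep, and distance residualization.

## upper-triangle index pairs in ascending (row, column) order
.utPairs <- function(n) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
}

#' Build an inclusive sparsity grid
#'
#' Regular grid from \code{sMin} to \code{sMax} in steps of \code{step}; the
#' upper endpoint is always included even when the range is not a multiple of
#' the step.
#'
#' @param sMin,sMax sparsity bounds, 0 <= sMin < sMax < 1.
#' @param step grid step (default 0.005).
#' @return numeric vector of sparsities.
#' @export
sparsityGrid <- function(sMin, sMax, step = 0.005) {
  if (!(sMin >= 0 && sMin < sMax && sMax < 1))
    stop("need 0 <= sMin < sMax < 1")
  if (step <= 0) stop("step must be positive")
  g <- seq(sMin, sMax, by = step)
  if (g[length(g)] < sMax - 1e-12) g <- c(g, sMax)
  g
}

#' Sparsity of a weighted network
#'
#' Fraction of exactly-zero upper-triangle entries over E = N(N-1)/2; the
#' diagonal is excluded. Density is the complement 1 - sparsity.
#'
#' @param net a \code{WeightedNetwork}.
#' @return sparsity in [0, 1].
#' @export
sparsityOf <- function(net) {
  w <- netWeights(net)
  u <- w[upper.tri(w)]
  sum(u == 0) / length(u)
}

#' Binarize a weighted network at a target sparsity
#'
#' Keeps exactly \code{k = round((1 - s) * E)} edges: the k largest by signed
#' weight (so negative weights drop out first), ties broken deterministically
#' by ascending (row, column) index. Exact zeros are structural absences and
#' rank below every present (even negative) connection, so binarizing a
#' thresholded network at its own sparsity returns exactly its support. The
#' realized sparsity \code{1 - k/E} differs from the request by at most 1/E.
#'
#' @param net a \code{WeightedNetwork}.
#' @param s target sparsity, 0 <= s < 1.
#' @return a \code{\link{BinaryNetwork}}.
#' @export
binarize <- function(net, s) {
  if (s < 0 || s >= 1) stop("sparsity must lie in [0, 1)")
  w <- netWeights(net)
  n <- nrow(w)
  ij <- .utPairs(n)
  E <- nrow(ij)
  k <- round((1 - s) * E)
  if (k < 1) stop("requested sparsity leaves no edges")
  v <- w[ij]
  keep <- order(v == 0, -v, ij[, 1], ij[, 2])[seq_len(k)]
  a <- matrix(FALSE, n, n, dimnames = dimnames(w))
  a[ij[keep, , drop = FALSE]] <- TRUE
  a <- a | t(a)
  new("BinaryNetwork", adjacency = a, sparsity = 1 - k / E)
}

#' Convergence ratio (Dice overlap) of two binary networks
#'
#' Number of common edges divided by the average edge count of the pair,
#' which equals the Dice similarity coefficient 2|A n B| / (|A| + |B|).
#'
#' @param a,b \code{BinaryNetwork}s of the same dimension.
#' @return convergence ratio in [0, 1].
#' @export
convergenceRatio <- function(a, b) {
  A <- adjacency(a); B <- adjacency(b)
  if (!identical(dim(A), dim(B))) stop("networks must have the same dimension")
  ua <- A[upper.tri(A)]; ub <- B[upper.tri(B)]
  na <- sum(ua); nb <- sum(ub)
  if (na + nb == 0) stop("convergence ratio undefined for two empty networks")
  sum(ua & ub) / ((na + nb) / 2)
}

#' Convergence ratio across a sparsity sweep
#'
#' Binarizes both networks at each grid sparsity and computes the convergence
#' ratio there; the summary is the unweighted arithmetic mean over grid points.
#'
#' @param a,b \code{WeightedNetwork}s.
#' @param grid numeric sparsity grid (see \code{\link{sparsityGrid}}).
#' @return list with \code{curve} (data.frame of \code{sparsity}, \code{cr})
#'   and \code{meanCR}.
#' @export
crSweep <- function(a, b, grid) {
  cr <- vapply(grid, function(s)
    convergenceRatio(binarize(a, s), binarize(b, s)), numeric(1))
  list(curve = data.frame(sparsity = grid, cr = cr), meanCR = mean(cr))
}

#' Analytic chance convergence ratio for a sparsity grid
#'
#' For two independent random edge sets of equal size k at sparsity s, the
#' expected intersection is k^2/E, so the expected convergence ratio is k/E =
#' 1 - s, the density. The chance level for a sweep is the mean of 1 - s over
#' the grid.
#'
#' @param grid numeric sparsity grid.
#' @return expected chance convergence ratio in [0, 1].
#' @export
chanceCR <- function(grid) {
  stopifnot(length(grid) >= 1, all(grid >= 0 & grid < 1))
  mean(1 - grid)
}

#' Monte-Carlo chance convergence ratio
#'
#' Validation oracle for \code{\link{chanceCR}}: at each grid sparsity draws
#' pairs of independent uniform random edge sets of the matched size and
#' measures their convergence ratio directly.
#'
#' @param grid numeric sparsity grid.
#' @param nRegions number of regions (E = n(n-1)/2 possible edges).
#' @param nDraws number of Monte-Carlo draws (>= 10).
#' @param seed integer seed.
#' @return list with \code{mean} and \code{sd} of the per-draw grid-mean
#'   convergence ratio.
#' @export
monteCarloChanceCR <- function(grid, nRegions, nDraws = 100, seed = 1) {
  if (nDraws < 10) stop("nDraws must be >= 10")
  E <- nRegions * (nRegions - 1) / 2
  set.seed(seed)
  perDraw <- vapply(seq_len(nDraws), function(d) {
    mean(vapply(grid, function(s) {
      k <- round((1 - s) * E)
      a <- sample.int(E, k)
      b <- sample.int(E, k)
      length(intersect(a, b)) / k
    }, numeric(1)))
  }, numeric(1))
  list(mean = mean(perDraw), sd = stats::sd(perDraw))
}

#' Is a binary network connected?
#'
#' TRUE iff every region can be reached from every other by following edges
#' (a single connected component covering all regions).
#'
#' @param bin a \code{BinaryNetwork}.
#' @return logical.
#' @export
isConnected <- function(bin) {
  g <- igraph::graph_from_adjacency_matrix(adjacency(bin) * 1,
                                           mode = "undirected")
  igraph::is_connected(g)
}

#' Largest grid sparsity keeping every network connected
#'
#' Scans the grid from the top down and returns the largest sparsity at which
#' the binarization of every supplied network is connected, or \code{NA} when
#' no grid point qualifies (the caller then falls back to a configured range).
#'
#' @param nets list of \code{WeightedNetwork}s.
#' @param grid numeric sparsity grid.
#' @return sparsity value or \code{NA_real_}.
#' @export
maxConnectedSparsity <- function(nets, grid) {
  stopifnot(length(nets) >= 1)
  for (s in sort(grid, decreasing = TRUE)) {
    ok <- all(vapply(nets, function(n) isConnected(binarize(n, s)), logical(1)))
    if (ok) return(s)
  }
  NA_real_
}

#' Pairwise Euclidean distances between region centroids
#'
#' @param regions a \code{RegionSet}.
#' @return symmetric distance matrix in mm, zero diagonal.
#' @export
edgeDistances <- function(regions) {
  as.matrix(stats::dist(centroids(regions)))
}

#' Residualize network weights on inter-region distance
#'
#' Ordinary least squares of weight on centroid distance (with intercept) over
#' the chosen edge set; weights are replaced by the residuals. With
#' \code{edgeSet = "support"} only nonzero entries enter the regression and
#' zeros stay zero (structural absences are not data points).
#'
#' @param net a \code{WeightedNetwork}.
#' @param distances symmetric distance matrix (see \code{\link{edgeDistances}}).
#' @param edgeSet "support" (nonzero entries only) or "all".
#' @return a \code{WeightedNetwork} of residuals (modality preserved).
#' @export
residualizeOnDistance <- function(net, distances, edgeSet = c("support", "all")) {
  edgeSet <- match.arg(edgeSet)
  w <- netWeights(net)
  n <- nrow(w)
  ij <- .utPairs(n)
  v <- w[ij]
  d <- distances[ij]
  sel <- if (edgeSet == "support") v != 0 else rep(TRUE, length(v))
  if (sum(sel) < 3) stop("need at least 3 edges to residualize")
  if (stats::sd(d[sel]) == 0) stop("distances constant over the edge set")
  fit <- stats::lm.fit(cbind(1, d[sel]), v[sel])
  v[sel] <- fit$residuals
  out <- matrix(0, n, n, dimnames = dimnames(w))
  out[ij] <- v
  out <- out + t(out)
  new("WeightedNetwork", weights = out, modality = modality(net))
}

## weight vectors of a pair over a chosen edge set
.pairVectors <- function(ref, proxy, edgeSet, positiveOnly = FALSE) {
  wr <- netWeights(ref); wp <- netWeights(proxy)
  if (!identical(dim(wr), dim(wp))) stop("networks must have the same dimension")
  ij <- .utPairs(nrow(wr))
  x <- wr[ij]; y <- wp[ij]; d <- ij
  sel <- if (edgeSet == "ref_support") x != 0 else rep(TRUE, length(x))
  if (positiveOnly) sel <- sel & y > 0
  list(x = x[sel], y = y[sel], idx = d[sel, , drop = FALSE])
}

#' Spearman similarity between two networks
#'
#' Spearman rank correlation between the weight vectors of the pair over the
#' chosen edge set. \code{edgeSet = "ref_support"} restricts to edges nonzero
#' in the reference network (the structurally consistent connections when the
#' reference is SC); \code{positiveOnly} additionally restricts to positive
#' proxy weights. The p-value uses the asymptotic t-approximation.
#'
#' @param ref reference \code{WeightedNetwork}.
#' @param proxy comparison \code{WeightedNetwork}.
#' @param edgeSet "ref_support" or "all".
#' @param positiveOnly restrict to proxy weights > 0.
#' @return list with \code{rho} and \code{p}.
#' @export
spearmanSimilarity <- function(ref, proxy, edgeSet = c("ref_support", "all"),
                               positiveOnly = FALSE) {
  edgeSet <- match.arg(edgeSet)
  v <- .pairVectors(ref, proxy, edgeSet, positiveOnly)
  if (length(v$x) < 3) stop("fewer than 3 edges in the chosen edge set")
  ct <- suppressWarnings(
    stats::cor.test(v$x, v$y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Partial Spearman correlation with distance as covariate
#'
#' Rank-transforms the two weight vectors and the distances over the chosen
#' edge set and applies the first-order partial-correlation formula
#' (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)) on the ranks.
#'
#' @param ref,proxy \code{WeightedNetwork}s.
#' @param distances symmetric distance matrix.
#' @param edgeSet "ref_support" or "all".
#' @return partial Spearman rho.
#' @export
partialSpearmanDistance <- function(ref, proxy, distances,
                                    edgeSet = c("ref_support", "all")) {
  edgeSet <- match.arg(edgeSet)
  v <- .pairVectors(ref, proxy, edgeSet)
  if (length(v$x) < 4) stop("need at least 4 edges")
  z <- distances[v$idx]
  rx <- rank(v$x); ry <- rank(v$y); rz <- rank(z)
  rxy <- stats::cor(rx, ry); rxz <- stats::cor(rx, rz); ryz <- stats::cor(ry, rz)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("distance covariate is degenerate (perfectly rank-correlated)")
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Full similarity report across network pairs
#'
#' For each reference-proxy pair (and optionally each proxy-proxy pair over
#' all edges) computes the Spearman similarity with Bonferroni-adjusted
#' p-values, the convergence-ratio sweep with its mean and analytic chance
#' level, and the overlap matrix (common edges) at the grid maximum. The grid
#' lower bound defaults to the sparsity of the SC network; the upper bound to
#' the largest sparsity keeping all networks connected, capped at
#' \code{sMaxCap}. When no grid point keeps all networks connected (as can
#' happen after distance residualization) the configured \code{[sMin,
#' sMaxCap]} range is kept and flagged.
#'
#' @param networks named list of \code{WeightedNetwork}s; must contain "SC"
#'   plus at least one proxy ("FC", "FDGcov", "GMVcov").
#' @param regions the matching \code{RegionSet}.
#' @param sMin lower sparsity bound or "auto" (sparsity of SC).
#' @param sMax upper sparsity bound or "auto" (connectedness bound).
#' @param step grid step.
#' @param sMaxCap cap on the automatic upper bound.
#' @param edgeSet edge set for SC-proxy Spearman ("ref_support" or "all").
#' @param positiveOnly restrict Spearman to positive proxy weights.
#' @param regressDistance residualize weights on centroid distance before CRs
#'   and use partial Spearman for the correlations.
#' @param cortexOnly drop subcortical, cerebellar and vermis regions first.
#' @param pairs "sc-proxy" or "all" (adds proxy-proxy pairs over all edges).
#' @return a \code{\link{SimilarityReport}}.
#' @export
similarityReport <- function(networks, regions, sMin = "auto", sMax = "auto",
                             step = 0.005, sMaxCap = 0.80,
                             edgeSet = c("ref_support", "all"),
                             positiveOnly = FALSE, regressDistance = FALSE,
                             cortexOnly = FALSE,
                             pairs = c("sc-proxy", "all")) {
  edgeSet <- match.arg(edgeSet)
  pairs <- match.arg(pairs)
  if (!"SC" %in% names(networks) || length(networks) < 2)
    stop("need an SC network plus at least one proxy")

  if (cortexOnly) {
    keep <- which(isCortical(regions))
    regions <- regions[keep]
    networks <- lapply(networks, function(n)
      new("WeightedNetwork", weights = netWeights(n)[keep, keep],
          modality = modality(n)))
  }
  distances <- edgeDistances(regions)

  lower <- if (identical(sMin, "auto")) sparsityOf(networks$SC) else as.numeric(sMin)

  crNets <- networks
  if (regressDistance) {
    crNets <- lapply(names(networks), function(nm)
      residualizeOnDistance(networks[[nm]], distances,
                            edgeSet = if (nm == "SC") "support" else "all"))
    names(crNets) <- names(networks)
  }

  gridNote <- "configured"
  if (identical(sMax, "auto")) {
    cand <- sparsityGrid(lower, sMaxCap, step)
    upper <- maxConnectedSparsity(crNets, cand)
    if (is.na(upper) || upper <= lower) {
      upper <- sMaxCap
      gridNote <- "no-connected-sparsity fallback"
    } else {
      gridNote <- "auto"
    }
  } else {
    upper <- as.numeric(sMax)
  }
  grid <- sparsityGrid(lower, upper, step)

  proxies <- setdiff(names(networks), "SC")
  pairList <- lapply(proxies, function(p) c("SC", p))
  if (pairs == "all" && length(proxies) >= 2) {
    cmb <- utils::combn(proxies, 2)
    pairList <- c(pairList, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  nPairs <- length(pairList)
  chance <- chanceCR(grid)

  results <- list()
  overlaps <- list()
  for (pr in pairList) {
    ref <- networks[[pr[1]]]; proxy <- networks[[pr[2]]]
    es <- if (pr[1] == "SC") edgeSet else "all"
    if (regressDistance) {
      rho <- partialSpearmanDistance(ref, proxy, distances, edgeSet = es)
      pval <- NA_real_
    } else {
      sp <- spearmanSimilarity(ref, proxy, edgeSet = es,
                               positiveOnly = positiveOnly)
      rho <- sp$rho; pval <- sp$p
    }
    sw <- crSweep(crNets[[pr[1]]], crNets[[pr[2]]], grid)
    key <- paste(pr, collapse = "-")
    aTop <- binarize(crNets[[pr[1]]], grid[length(grid)])
    bTop <- binarize(crNets[[pr[2]]], grid[length(grid)])
    overlaps[[key]] <- adjacency(aTop) & adjacency(bTop)
    results[[key]] <- new("SimilarityResult", pair = pr, rho = rho,
                          pValue = pval,
                          pBonferroni = min(1, pval * nPairs),
                          crCurve = sw$curve, meanCR = sw$meanCR,
                          chanceCR = chance, edgeSet = es,
                          positiveOnly = positiveOnly,
                          distanceRegressed = regressDistance)
  }
  new("SimilarityReport", results = results, grid = grid, overlaps = overlaps,
      variants = list(edgeSet = edgeSet, positiveOnly = positiveOnly,
                      regressDistance = regressDistance,
                      cortexOnly = cortexOnly, pairs = pairs),
      gridNote = gridNote)
}

#' Format a similarity report as a Table-1-shaped text table
#'
#' One SCC row and one mean-CR row per pair, then chance CR and the sparsity
#' bounds; correlations to 2 decimals, percentages to integers.
#'
#' @param report a \code{\link{SimilarityReport}}.
#' @return character vector of lines.
#' @export
formatReport <- function(report) {
  res <- report@results
  grid <- report@grid
  lines <- c("SCC")
  for (nm in names(res))
    lines <- c(lines, sprintf("%s\t%.2f", nm, res[[nm]]@rho))
  lines <- c(lines, "CR")
  for (nm in names(res))
    lines <- c(lines, sprintf("%s\t%d", nm, round(100 * res[[nm]]@meanCR)))
  lines <- c(lines,
             sprintf("CR by chance\t%d", round(100 * chanceCR(grid))),
             sprintf("Min sparsity\t%d", round(100 * min(grid))),
             sprintf("Max sparsity\t%d", round(100 * max(grid))),
             sprintf("Grid\t%s", report@gridNote))
  lines
}
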