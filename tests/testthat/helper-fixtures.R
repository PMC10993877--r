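# Shared fixtures and independent oracles, all built in code.

smallRegions <- function(n = 20, seed = 3) makeRegions(n, 0.1, seed = seed)

smallGT <- function(regions = smallRegions(), density = 0.3, seed = 5)
  makeGroundTruth(regions, distanceScaleMm = 40, homotopicProb = 0.9,
                  targetDensity = density, seed = seed)

# symmetric weighted network from an upper-triangle vector (row-major order)
netFromUpper <- function(v, n, modality = "other") {
  w <- matrix(0, n, n)
  k <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) { w[i, j] <- v[k]; k <- k + 1 }
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 0
  weightedNetwork(w, modality)
}

binFromEdges <- function(edges, n) {
  a <- matrix(FALSE, n, n)
  for (e in edges) { a[e[1], e[2]] <- TRUE; a[e[2], e[1]] <- TRUE }
  dimnames(a) <- list(paste0("R", 1:n), paste0("R", 1:n))
  E <- n * (n - 1) / 2
  new("BinaryNetwork", adjacency = a, sparsity = 1 - length(edges) / E)
}

# definitional Dice coefficient on two adjacency matrices
oracleDice <- function(A, B) {
  a <- A[upper.tri(A)]; b <- B[upper.tri(B)]
  2 * sum(a & b) / (sum(a) + sum(b))
}

# definitional Spearman: Pearson product-moment formula applied to ranks
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# partial rank correlation via the residual method: regress the ranks of x
# and y on the ranks of z, then correlate the residuals
oraclePartialSpearman <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::residuals(stats::lm(rx ~ rz))
  ey <- stats::residuals(stats::lm(ry ~ rz))
  stats::cor(ex, ey)
}

randomSymmetricNet <- function(n, seed, modality = "other") {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::rnorm(n * (n - 1) / 2)
  w <- w + t(w)
  weightedNetwork(w, modality)
}
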