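test_that("sparsity counts exact zeros over the upper triangle", {
  expect_equal(sparsityOf(netFromUpper(rep(0, 6), 4)), 1)
  expect_equal(sparsityOf(netFromUpper(rep(1.5, 6), 4)), 0)
  expect_equal(sparsityOf(netFromUpper(c(1, 2, 0, 0, 0, 0), 4)), 4 / 6)
})

test_that("sparsity grid is inclusive of both endpoints", {
  g <- sparsityGrid(0.658, 0.80)
  expect_equal(g[1], 0.658)
  expect_equal(g[length(g)], 0.80)
  expect_equal(length(g), 30)           # 29 regular points + forced endpoint
  g2 <- sparsityGrid(0.55, 0.80)
  expect_equal(length(g2), 51)          # exact multiple: no extra point
  expect_error(sparsityGrid(0.9, 0.5), "sMin")
})

test_that("binarize keeps the k strongest edges with deterministic ties", {
  # weights e1..e6 (row-major): top-2 at s = 2/3 are e1, e2
  net <- netFromUpper(c(3, 2, -1, 0.5, 0.1, -2), 4)
  b <- binarize(net, 2 / 3)
  a <- adjacency(b)
  expect_true(a[1, 2] && a[1, 3])
  expect_equal(sum(a[upper.tri(a)]), 2)
  expect_equal(sparsity(b), 1 - 2 / 6)

  # s = 0 keeps everything
  expect_equal(sum(adjacency(binarize(net, 0))[upper.tri(a)]), 6)

  # equal weights: lexicographically smallest (row, col) pairs win
  tied <- netFromUpper(rep(1, 6), 4)
  at <- adjacency(binarize(tied, 0.5))
  expect_true(at[1, 2] && at[1, 3] && at[1, 4])
  expect_false(at[2, 3] || at[2, 4] || at[3, 4])

  # structural zeros rank below present negative weights
  sc <- netFromUpper(c(2, -1, 0, 0, 0, 0), 4)
  asc <- adjacency(binarize(sc, sparsityOf(sc)))
  expect_true(asc[1, 2] && asc[1, 3])

  expect_error(binarize(net, 0.999), "no edges")
})

test_that("realized sparsity is within 1/E of the request", {
  for (n in c(10, 23)) {
    E <- n * (n - 1) / 2
    for (s in seq(0.1, 0.9, by = 0.2)) {
      net <- randomSymmetricNet(n, seed = round(100 * s) + n)
      expect_lte(abs(sparsity(binarize(net, s)) - s), 1 / E)
    }
  }
})

test_that("convergence ratio equals the Dice coefficient", {
  n <- 8
  a <- binFromEdges(list(c(1, 2), c(1, 3), c(2, 3), c(4, 5)), n)
  b <- binFromEdges(list(c(1, 2), c(2, 3), c(4, 6), c(5, 6), c(7, 8),
                         c(1, 8)), n)
  # |A|=4, |B|=6, |A n B|=2 -> 2 / 5
  expect_equal(convergenceRatio(a, b), 0.4)
  expect_equal(convergenceRatio(a, b), oracleDice(adjacency(a), adjacency(b)))
  expect_equal(convergenceRatio(a, b), convergenceRatio(b, a))
  expect_equal(convergenceRatio(a, a), 1)
  disj <- binFromEdges(list(c(6, 7), c(6, 8)), n)
  expect_equal(convergenceRatio(a, disj), 0)
  empty <- binFromEdges(list(), n)
  expect_error(convergenceRatio(empty, empty), "empty")
})

test_that("cr sweep is the unweighted mean of per-point overlaps", {
  net <- randomSymmetricNet(12, seed = 4)
  grid <- sparsityGrid(0.3, 0.6, 0.1)
  sw <- crSweep(net, net, grid)
  expect_true(all(sw$curve$cr == 1))
  expect_equal(sw$meanCR, 1)

  other <- randomSymmetricNet(12, seed = 5)
  sw2 <- crSweep(net, other, grid)
  expect_equal(sw2$meanCR, mean(sw2$curve$cr))
  # single-point grid: mean equals the point value
  sw1 <- crSweep(net, other, 0.5)
  expect_equal(sw1$meanCR, sw1$curve$cr[1])
})

test_that("chance CR is the mean density of the grid", {
  expect_equal(chanceCR(0.5), 0.5)
  expect_equal(round(100 * chanceCR(sparsityGrid(0.658, 0.80))), 27)
  expect_equal(round(100 * chanceCR(sparsityGrid(0.133, 0.80))), 53)
})

test_that("Monte-Carlo chance CR agrees with the closed form", {
  for (n in c(10, 30)) {
    grid <- sparsityGrid(0.1, 0.9, 0.1)
    mc <- monteCarloChanceCR(grid, n, nDraws = 200, seed = 2)
    expect_lt(abs(mc$mean - chanceCR(grid)), 2 * mc$sd / sqrt(200) + 0.02)
  }
  a <- monteCarloChanceCR(0.5, 12, nDraws = 50, seed = 9)
  b <- monteCarloChanceCR(0.5, 12, nDraws = 50, seed = 9)
  expect_identical(a, b)
  expect_error(monteCarloChanceCR(0.5, 12, nDraws = 5), ">= 10")
})

test_that("connectedness detects single components and the sweep bound", {
  path5 <- binFromEdges(list(c(1, 2), c(2, 3), c(3, 4), c(4, 5)), 5)
  expect_true(isConnected(path5))
  iso <- binFromEdges(list(c(1, 2), c(2, 3), c(3, 4)), 5)
  expect_false(isConnected(iso))
  cliques <- binFromEdges(list(c(1, 2), c(1, 3), c(2, 3),
                               c(4, 5), c(4, 6), c(5, 6)), 6)
  expect_false(isConnected(cliques))

  # a star network stays connected up to the grid maximum
  set.seed(7)
  n <- 8; E <- n * (n - 1) / 2
  w <- matrix(0, n, n)
  mask <- upper.tri(w)
  w[mask] <- -abs(rnorm(E))        # weak everywhere ...
  w[1, 2:n] <- 10 + seq_len(n - 1) # ... except the spokes of region 1
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  star <- weightedNetwork(w, "other")
  grid <- sparsityGrid(0.5, (E - (n - 1)) / E, 0.05)
  expect_equal(maxConnectedSparsity(list(star), grid), max(grid))

  # two separate cliques are disconnected everywhere on the grid
  bw <- matrix(0, 8, 8)
  bw[1:4, 1:4] <- 1; bw[5:8, 5:8] <- 1; diag(bw) <- 0
  two <- weightedNetwork(bw, "other")
  expect_true(is.na(maxConnectedSparsity(list(two), sparsityGrid(0.7, 0.9, 0.1))))
})

test_that("edge distances are Euclidean and symmetric", {
  r <- makeRegions(4, 0, seed = 1)
  r@info$x <- c(0, 3, 0, 1); r@info$y <- c(0, 4, 0, 1); r@info$z <- c(0, 0, 0, 1)
  D <- edgeDistances(r)
  expect_equal(D[1, 2], 5)          # 3-4-5 triangle
  expect_equal(D[1, 3], 0)          # coincident centroids
  expect_true(isSymmetric(unname(D)))
  expect_true(all(diag(D) == 0))
})

test_that("distance residualization behaves like OLS residuals", {
  r <- smallRegions()
  D <- edgeDistances(r)
  n <- length(r)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  # weights exactly linear in distance vanish
  w <- matrix(0, n, n); w[ut] <- 2 - 0.01 * D[ut]; w <- w + t(w)
  lin <- weightedNetwork(w, "other", labels(r))
  expect_lt(max(abs(netWeights(residualizeOnDistance(lin, D, "all")))), 1e-10)

  # generic weights: residuals sum to zero; support zeros stay zero
  net <- randomSymmetricNet(n, seed = 3)
  wz <- netWeights(net); wz[abs(wz) < 0.4] <- 0
  net <- weightedNetwork(wz, "SC")
  res <- residualizeOnDistance(net, D, "support")
  rw <- netWeights(res)
  expect_identical(rw == 0, wz == 0)
  expect_lt(abs(sum(rw[upper.tri(rw)][wz[upper.tri(wz)] != 0])), 1e-8)

  expect_error(residualizeOnDistance(net, matrix(1, n, n) - diag(n), "all"),
               "constant")
})

test_that("Spearman similarity matches the definitional oracle", {
  x <- c(0.2, 1.5, 0.9, 2.4, 0.1, 3.0)
  y <- c(1.1, 0.3, 2.2, 2.0, 0.9, 2.8)
  ref <- netFromUpper(x, 4)
  proxy <- netFromUpper(y, 4)
  sp <- spearmanSimilarity(ref, proxy, "all")
  expect_equal(sp$rho, oracleSpearman(x, y), tolerance = 1e-10)

  # monotone transform of ref has rho 1; negation has rho -1
  mono <- netFromUpper(exp(x), 4)
  expect_equal(spearmanSimilarity(ref, mono, "all")$rho, 1)
  neg <- netFromUpper(-x, 4)
  expect_equal(spearmanSimilarity(ref, neg, "all")$rho, -1)

  # ref_support drops edges absent from the reference
  refz <- netFromUpper(c(0.2, 1.5, 0, 2.4, 0, 3.0), 4)
  spz <- spearmanSimilarity(refz, proxy, "ref_support")
  expect_equal(spz$rho, oracleSpearman(x[c(1, 2, 4, 6)], y[c(1, 2, 4, 6)]),
               tolerance = 1e-10)

  tiny <- netFromUpper(c(1, 0, 0, 0, 0, 0), 4)
  expect_error(spearmanSimilarity(tiny, proxy, "ref_support"), "fewer than 3")
})

test_that("positive-only restriction drops nonpositive proxy weights", {
  x <- c(0.2, 1.5, 0.9, 2.4, 0.1, 3.0)
  y <- c(1.1, -0.3, 2.2, -2.0, 0.9, 2.8)
  sp <- spearmanSimilarity(netFromUpper(x, 4), netFromUpper(y, 4), "all",
                           positiveOnly = TRUE)
  keep <- y > 0
  expect_equal(sp$rho, oracleSpearman(x[keep], y[keep]), tolerance = 1e-10)
})

test_that("partial Spearman matches the residual-of-ranks oracle", {
  set.seed(8)
  x <- rnorm(6); y <- x + rnorm(6); z <- rnorm(6)
  D <- matrix(0, 4, 4); k <- 1
  for (i in 1:3) for (j in (i + 1):4) { D[i, j] <- z[k]; k <- k + 1 }
  D <- D + t(D)
  ref <- netFromUpper(x, 4); proxy <- netFromUpper(y, 4)
  expect_equal(partialSpearmanDistance(ref, proxy, D, "all"),
               oraclePartialSpearman(x, y, z), tolerance = 1e-10)

  # a second hand-built case against the same oracle
  set.seed(21)
  x2 <- runif(6); y2 <- runif(6); z2 <- runif(6)
  D2 <- matrix(0, 4, 4); k <- 1
  for (i in 1:3) for (j in (i + 1):4) { D2[i, j] <- z2[k]; k <- k + 1 }
  D2 <- D2 + t(D2)
  expect_equal(partialSpearmanDistance(netFromUpper(x2, 4),
                                       netFromUpper(y2, 4), D2, "all"),
               oraclePartialSpearman(x2, y2, z2), tolerance = 1e-10)

  # degenerate covariate: proxy equal to distance
  expect_error(partialSpearmanDistance(ref, netFromUpper(z, 4), D, "all"),
               "degenerate")
})

test_that("similarity report on identical networks is saturated", {
  net <- randomSymmetricNet(20, seed = 6)
  r <- smallRegions()
  nets <- list(SC = weightedNetwork(netWeights(net), "SC", labels(r)),
               FC = weightedNetwork(netWeights(net), "FC", labels(r)),
               FDGcov = weightedNetwork(netWeights(net), "FDGcov", labels(r)))
  rep <- similarityReport(nets, r, sMin = 0.4, sMax = 0.7)
  for (res in rep@results) {
    expect_equal(res@meanCR, 1)
    expect_equal(res@rho, 1)
  }
  # Bonferroni never drops below the raw p
  for (res in rep@results) expect_gte(res@pBonferroni, res@pValue)
})

test_that("report grid bounds follow SC sparsity and connectedness", {
  r <- smallRegions(); gt <- smallGT(r)
  run <- runPipeline(pipelineConfig(nSubjects = 8, nRegions = 20,
                                    nVolumes = 64, seed = 2))
  rep <- run$report
  expect_equal(min(rep@grid), sparsityOf(run$networks$SC))
  expect_lte(max(rep@grid), 0.80)
  # row structure of the formatted table
  lines <- formatReport(rep)
  expect_true(any(grepl("^CR by chance\t", lines)))
  expect_true(any(grepl("^Min sparsity\t", lines)))
  expect_true(any(grepl("^Max sparsity\t", lines)))
  expect_equal(sum(grepl("^SC-", lines)), 2 * 3)  # SCC + CR row per pair
})

test_that("random networks overlap at chance level", {
  grid <- sparsityGrid(0.658, 0.80, 0.02)
  crs <- vapply(1:20, function(sd) {
    a <- randomSymmetricNet(40, seed = sd)
    b <- randomSymmetricNet(40, seed = 1000 + sd)
    crSweep(a, b, grid)$meanCR
  }, numeric(1))
  expect_lt(abs(mean(crs) - chanceCR(grid)), 0.03)
})
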