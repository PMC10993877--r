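test_that("makeRegions builds mirrored hemispheres with homotopic partners", {
  r <- makeRegions(4, 0, seed = 1)
  expect_s4_class(r, "RegionSet")
  expect_equal(length(r), 4)
  hemi <- r@info$hemisphere
  expect_equal(sum(hemi == "L"), 2)
  expect_equal(sum(hemi == "R"), 2)
  hp <- r@info$homotopic_partner
  expect_false(anyNA(hp[r@info$lobe != "vermis"]))
  # mirror symmetry of centroids
  ctr <- centroids(r)
  expect_equal(ctr[hp[1], "x"], -ctr[1, "x"])
  expect_equal(ctr[hp[1], c("y", "z")], ctr[1, c("y", "z")])

  expect_error(makeRegions(3, 0, seed = 1), "even")
  expect_error(makeRegions(5, 0, seed = 1), "even")
})

test_that("makeRegions is bit-identical under a fixed seed", {
  a <- makeRegions(106, 0.1, seed = 7)
  b <- makeRegions(106, 0.1, seed = 7)
  expect_identical(a@info, b@info)
  expect_equal(length(a), 106)
  # positive geometry
  expect_true(all(surfaceAreas(a) > 0))
  expect_true(all(regionVolumes(a) > 0))
})

test_that("makeGroundTruth hits the target density and respects forcings", {
  r <- makeRegions(20, 0, seed = 3)
  E <- 20 * 19 / 2
  gt <- makeGroundTruth(r, targetDensity = 0.3, seed = 4)
  sup <- gtSupport(gt)
  expect_equal(sum(sup[upper.tri(sup)]), round(0.3 * E))
  expect_true(isSymmetric(unname(gtWeights(gt))))
  expect_true(all(diag(gtWeights(gt)) == 0))

  # density 1 forces a complete graph
  full <- makeGroundTruth(r, targetDensity = 1, seed = 4)
  expect_true(all(gtSupport(full)[upper.tri(full@support)]))

  # homotopicProb = 1 with enough room forces every homotopic pair in
  gt2 <- makeGroundTruth(r, homotopicProb = 1, targetDensity = 0.3, seed = 4)
  hp <- r@info$homotopic_partner
  for (i in which(!is.na(hp) & hp > seq_along(hp)))
    expect_true(gtSupport(gt2)[i, hp[i]])

  expect_warning(makeGroundTruth(r, targetDensity = 0.02, seed = 1),
                 "connected")
})

test_that("ground-truth weights decrease with distance on average", {
  r <- makeRegions(60, 0.1, seed = 2)
  gt <- makeGroundTruth(r, distanceScaleMm = 40, targetDensity = 0.4, seed = 9)
  D <- edgeDistances(r)
  ut <- upper.tri(D)
  sel <- gtSupport(gt)[ut]
  expect_lt(stats::cor(D[ut][sel], gtWeights(gt)[ut][sel]), -0.3)
})

test_that("streamline simulation recovers support in the noise-free limit", {
  r <- smallRegions(); gt <- smallGT(r)
  st <- simulateStreamlines(gt, r, nSubjects = 4, dispersion = 0,
                            falsePositiveRate = 0, dropoutRate = 0, seed = 6)
  for (m in st) {
    expect_true(isSymmetric(unname(m)))
    expect_true(all(m >= 0))
    expect_identical(unname(m > 0), unname(gtSupport(gt)))
  }
  # no false positives means no counts on non-edges even with noise
  st2 <- simulateStreamlines(gt, r, 4, dispersion = 1, falsePositiveRate = 0,
                             dropoutRate = 0.3, seed = 6)
  for (m in st2) expect_true(all(m[!gtSupport(gt)] == 0))
  # determinism
  a <- simulateStreamlines(gt, r, 3, seed = 12)
  b <- simulateStreamlines(gt, r, 3, seed = 12)
  expect_identical(a, b)
})

test_that("feature simulation plants the requested covariance structure", {
  r <- smallRegions(); gt <- smallGT(r)
  # coupling 0: across-subject correlations vanish at large n
  f0 <- simulateFeatures(gt, r, 2000, coupling = 0, globalConfoundSd = 0,
                         seed = 8)
  C <- stats::cor(featureValues(f0))
  diag(C) <- 0
  expect_lt(max(abs(C)), 0.1)
  # strong coupling: edges more correlated than non-edges
  f9 <- simulateFeatures(gt, r, 400, coupling = 0.9, globalConfoundSd = 0,
                         seed = 8)
  C9 <- stats::cor(featureValues(f9))
  ut <- upper.tri(C9)
  sup <- gtSupport(gt)
  expect_gt(mean(C9[ut & sup]), mean(C9[ut & !sup]))
  # determinism
  expect_identical(
    featureValues(simulateFeatures(gt, r, 10, seed = 4)),
    featureValues(simulateFeatures(gt, r, 10, seed = 4)))
  expect_error(simulateFeatures(gt, r, 10, coupling = 1.2), "coupling")
})

test_that("edge correlation increases monotonically with coupling", {
  r <- smallRegions(); gt <- smallGT(r)
  sup <- gtSupport(gt); ut <- upper.tri(sup)
  meanEdgeCor <- function(coupling, seed) {
    f <- simulateFeatures(gt, r, 100, coupling = coupling,
                          globalConfoundSd = 0, seed = seed)
    C <- stats::cor(featureValues(f))
    mean(C[ut & sup])
  }
  lvls <- c(0.1, 0.4, 0.7)
  avg <- vapply(lvls, function(cc)
    mean(vapply(1:10, function(s) meanEdgeCor(cc, s), numeric(1))), numeric(1))
  expect_true(all(diff(avg) > 0))
})

test_that("time-series simulation has the right shape and planted correlation", {
  r <- smallRegions(); gt <- smallGT(r)
  ts <- simulateTimeSeries(gt, 2, nVolumes = 209, samplingInterval = 2.26,
                           seed = 3)
  expect_length(ts, 2)
  expect_equal(ncol(signals(ts[[1]])), 209)
  expect_equal(nrow(signals(ts[[1]])), length(r))
  expect_equal(nrow(nuisance(ts[[1]])), 209)

  # clean limit: band-passed correlations approximate the planted structure
  tsc <- simulateTimeSeries(gt, 1, nVolumes = 2000, samplingInterval = 2.26,
                            driftAmplitude = 0, highfreqAmplitude = 0,
                            nuisanceLoadingSd = 0, coupling = 0.8, seed = 10)
  filt <- bandpassFilter(tsc[[1]])
  C <- stats::cor(t(signals(filt)))
  R <- netconverge:::.plantedCorrelation(gt, 0.8)
  ut <- upper.tri(C)
  expect_lt(mean(abs(C[ut] - R[ut])), 0.15)

  # determinism and input validation
  a <- simulateTimeSeries(gt, 2, seed = 5)
  b <- simulateTimeSeries(gt, 2, seed = 5)
  expect_identical(signals(a[[1]]), signals(b[[1]]))
  expect_error(simulateTimeSeries(gt, 1, samplingInterval = 0), "positive")
  expect_error(simulateTimeSeries(gt, 1, nVolumes = 20), ">= 32")
})
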