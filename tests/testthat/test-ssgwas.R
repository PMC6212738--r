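test_that("zero GEBVs back-solve to zero SNP effects", {
  gm <- toyGenotypes(rbind(c(0L, 2L), c(1L, 1L), c(2L, 0L)))
  z <- centerGenotypes(gm)
  G <- buildG(z, tuneDiagonal = FALSE, blendTau = 0)
  u <- backsolveSnpEffects(rep(0, 3), z, g = relValues(G),
                           scalingC = relMetadata(G)$scalingC,
                           ridge = 1e-10)
  expect_equal(unname(u), c(0, 0))
})

test_that("the one-marker back-solve matches its scalar closed form", {
  gm <- toyGenotypes(cbind(c(0L, 1L, 2L)))
  z <- centerGenotypes(gm, 0.5)
  G <- buildG(z, tuneDiagonal = FALSE, blendTau = 0)
  ag <- as.numeric(z$z)                # in the range of the rank-1 G
  u <- backsolveSnpEffects(ag, z, g = G, ridge = 1e-10)
  closed <- sum(z$z * ag) / sum(z$z^2)
  expect_equal(unname(u), closed, tolerance = 1e-6)
})

test_that("back-solving reconstructs the GEBVs exactly when G is invertible", {
  for (seed in c(201, 202)) {
    cfg <- simpleConfig(seed, nFounders = 30, nGenerations = 2,
                        offspringPerMating = 2, nChromosomes = 2,
                        markersPerChromosome = 100, missingRate = 0,
                        genotypedFraction = 0.5)
    dat <- simulateDataset(cfg)
    pFull <- alleleFrequencies(dat$genotypes)   # reference-population freqs
    z <- centerGenotypes(dat$panel, pFull[markerMap(dat$panel)$snp])
    d <- runif(ncol(z$z), 0.2, 2)
    G <- buildG(z, d, tuneDiagonal = FALSE, blendTau = 0)
    ag <- rnorm(nrow(z$z))
    u <- backsolveSnpEffects(ag, z, d, G)
    expect_lt(max(abs(z$z %*% u - ag)), 1e-8)
  }
})

test_that("weight updates follow d = u^2 2p(1-p) and conserve the trace", {
  w <- updateWeights(c(0.5, 1), c(0.5, 0))
  expect_equal(unname(w), c(2, 0))     # raw {0.125, 0} renormalized to sum 2
  expect_error(updateWeights(c(0, 0), c(0.3, 0.4)), "zero")
  set.seed(2)
  for (i in 1:5) {
    u <- rnorm(50); p <- runif(50, 0.01, 0.99)
    expect_lt(abs(sum(updateWeights(u, p)) - 50), 1e-10)
  }
})

test_that("the weighted scan is deterministic and logs its weight history", {
  cfg <- simpleConfig(211, nFounders = 20, nGenerations = 2,
                      offspringPerMating = 2, nChromosomes = 1,
                      markersPerChromosome = 60, missingRate = 0,
                      genotypedFraction = 0.6)
  dat <- simulateDataset(cfg)
  vc <- VarianceComponents(matrix(1), matrix(3), "y")
  run <- function() runSsgwas(dat$panel, dat$pedigree, dat$phenotypes, "y",
                              "farm", vc, nIterations = 2)
  e1 <- run(); e2 <- run()
  expect_identical(snpEffects(e1$y), snpEffects(e2$y))
  expect_identical(ncol(weightHistory(e1$y)), 3L)   # D = I + two passes
  expect_true(all(abs(colSums(weightHistory(e1$y)[, -1]) - 60) < 1e-8))
})

test_that("zero iterations give the classical unweighted SNP effects", {
  cfg <- simpleConfig(223, nFounders = 20, nGenerations = 2,
                      offspringPerMating = 2, nChromosomes = 1,
                      markersPerChromosome = 50, missingRate = 0,
                      genotypedFraction = 0.6)
  dat <- simulateDataset(cfg)
  vc <- VarianceComponents(matrix(1), matrix(3), "y")
  pFull <- alleleFrequencies(dat$genotypes)
  e0 <- runSsgwas(dat$panel, dat$pedigree, dat$phenotypes, "y", "farm", vc,
                  nIterations = 0, blendTau = 0,
                  p = pFull[markerMap(dat$panel)$snp])
  # manual classical pass: D = I throughout
  z <- attr(e0, "z")
  a22 <- subsetA22(dat$pedigree, animalIds(dat$panel))
  G <- buildG(z, a22 = a22$a22, tuneDiagonal = TRUE, blendTau = 0)
  Hinv <- buildHInverse(aInverse(dat$pedigree), a22$a22Inv,
                        invertRelationship(G))
  d <- buildDesign(dat$phenotypes, "y", "farm", animalIds(dat$pedigree))
  fit <- solveMME(d, Hinv, vc)
  manual <- backsolveSnpEffects(fit$u[animalIds(dat$panel), "y"], z, g = G)
  expect_equal(snpEffects(e0$y), manual, tolerance = 1e-10)
})

test_that("two weighting passes concentrate weight on a planted QTL", {
  hits <- 0L
  for (seed in 301:310) {
    a <- sqrt(0.2 * 1 / (2 * 0.5 * 0.5))   # QTL = 20% of total sigma_a = 1
    cfg <- simpleConfig(seed, nFounders = 100, nGenerations = 2,
                        offspringPerMating = 3, nChromosomes = 2,
                        markersPerChromosome = 50, missingRate = 0,
                        genotypedFraction = 0.6, sigmaA = matrix(0.8),
                        sigmaE = matrix(7 / 3),
                        qtl = list(list(chr = "2", posBp = floor(25 * 1e8 / 51),
                                        effects = a, maf = 0.5)))
    dat <- simulateDataset(cfg)
    vc <- VarianceComponents(matrix(1), matrix(7 / 3), "y")
    eff <- runSsgwas(dat$panel, dat$pedigree, dat$phenotypes, "y", "farm",
                     vc, nIterations = 2)
    w <- weightHistory(eff$y)[, 3L]
    if (names(which.max(w)) == dat$truth$qtlMarkers) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("window bookkeeping yields m - size + 1 windows per chromosome", {
  cfg <- simpleConfig(227, nFounders = 10, nGenerations = 1,
                      offspringPerMating = 1, nChromosomes = 1,
                      markersPerChromosome = 10, missingRate = 0,
                      genotypedFraction = 1)
  dat <- simulateDataset(cfg)
  z <- centerGenotypes(dat$panel)
  u <- rnorm(10)
  scan <- windowVariance(z, u, 1, markerMap(dat$panel), windowSize = 5)
  expect_identical(nrow(scanWindows(scan)), 6L)
  # u = 0 makes every window zero
  zero <- windowVariance(z, rep(0, 10), 1, markerMap(dat$panel), 5)
  expect_true(all(scanWindows(zero)$pctVar == 0))
})

test_that("window percentages match a brute-force enumeration", {
  calls <- rbind(c(0L, 1L, 2L, 0L, 1L, 2L),
                 c(2L, 2L, 0L, 1L, 1L, 0L),
                 c(1L, 0L, 1L, 2L, 0L, 1L),
                 c(0L, 2L, 2L, 2L, 1L, 0L),
                 c(1L, 1L, 0L, 0L, 2L, 2L))
  gm <- toyGenotypes(calls)
  z <- centerGenotypes(gm)
  u <- c(0.3, -0.1, 0.25, 0.05, -0.4, 0.2)
  sigmaA2 <- 0.9
  scan <- windowVariance(z, u, sigmaA2, markerMap(gm), windowSize = 5)
  got <- scanWindows(scan)$pctVar
  # independent oracle: explicit per-animal window values
  expected <- vapply(1:2, function(s) {
    aVal <- numeric(5)
    for (i in 1:5)
      for (j in s:(s + 4)) aVal[i] <- aVal[i] + z$z[i, j] * u[j]
    100 * var(aVal) / sigmaA2
  }, numeric(1))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("the all-marker window accounts for all of Var(Z u) empirically", {
  cfg <- simpleConfig(229, nFounders = 20, nGenerations = 1,
                      offspringPerMating = 1, nChromosomes = 1,
                      markersPerChromosome = 30, missingRate = 0,
                      genotypedFraction = 1)
  dat <- simulateDataset(cfg)
  z <- centerGenotypes(dat$panel)
  u <- rnorm(30)
  scan <- windowVariance(z, u, "empirical", markerMap(dat$panel),
                         windowSize = 30)
  expect_equal(scanWindows(scan)$pctVar, 100, tolerance = 1e-10)
})

test_that("region selection applies the >= threshold and merges overlaps", {
  w <- data.frame(chr = "1", startIndex = c(1, 2, 10),
                  snps = c("s1,s2,s3,s4,s5", "s2,s3,s4,s5,s6",
                           "s10,s11,s12,s13,s14"),
                  startBp = c(100, 200, 1000), endBp = c(500, 600, 1400),
                  midBp = c(300, 400, 1200), trait = "y",
                  pctVar = c(0.5, 1.0, 2.3))
  scan <- new("WindowScan", windows = w, sigmaATotal = c(y = 1),
              windowSize = 5L)
  sel <- selectRegions(scan, 1.0)
  expect_identical(nrow(sel), 2L)
  none <- selectRegions(scan, 50)
  expect_identical(nrow(none), 0L)
  # adjacent selected windows sharing 4 SNPs merge into one region
  w2 <- w; w2$pctVar <- c(1.2, 1.5, 0.2)
  scan2 <- new("WindowScan", windows = w2, sigmaATotal = c(y = 1),
               windowSize = 5L)
  sel2 <- selectRegions(scan2, 1.0)
  expect_identical(nrow(sel2), 1L)
  expect_identical(sel2$startBp, 100)
  expect_identical(sel2$endBp, 600)
  expect_identical(sel2$pctVar, 1.5)
  expect_identical(sel2$snps, "s1,s2,s3,s4,s5,s6")
})
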