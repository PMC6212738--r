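test_that("the trio gives textbook A and A-inverse", {
  ped <- trioPedigree()
  A <- relValues(numeratorRelationship(ped))
  expect_equal(unname(A),
               rbind(c(1, 0, .5), c(0, 1, .5), c(.5, .5, 1)))
  Ai <- relValues(aInverse(ped))
  expect_equal(unname(Ai),
               rbind(c(1.5, .5, -1), c(.5, 1.5, -1), c(-1, -1, 2)))
})

test_that("full-sib mating produces inbreeding 0.25 on the diagonal", {
  ped <- Pedigree(c("s", "d", "a", "b", "x"),
                  c(NA, NA, "s", "s", "a"), c(NA, NA, "d", "d", "b"))
  A <- relValues(numeratorRelationship(ped))
  expect_equal(A["x", "x"], 1.25)
  F <- relMetadata(aInverse(ped))$F
  expect_equal(unname(F["x"]), 0.25)
})

test_that("a founders-only pedigree has identity A-inverse", {
  ped <- Pedigree(letters[1:4], rep(NA, 4), rep(NA, 4))
  expect_equal(relValues(aInverse(ped)), diag(4),
               ignore_attr = TRUE)
})

test_that("A-inverse times A is the identity on simulated pedigrees", {
  for (seed in c(91, 92, 93)) {
    cfg <- simpleConfig(seed, nFounders = 30, nGenerations = 3,
                        offspringPerMating = 2)
    ped <- simulatePedigree(cfg)
    expect_lte(length(ped), 200L)
    A <- relValues(numeratorRelationship(ped))
    Ai <- relValues(aInverse(ped))
    expect_lt(max(abs(Ai %*% A - diag(nrow(A)))), 1e-8)
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("A22 subsetting and its dense inverse behave", {
  ped <- trioPedigree()
  all3 <- subsetA22(ped, animalIds(ped))
  expect_equal(relValues(all3$a22),
               relValues(numeratorRelationship(ped)))
  two <- subsetA22(ped, c("kid1", "dam1"))
  expect_equal(unname(relValues(two$a22)), rbind(c(1, .5), c(.5, 1)))
  expect_equal(unname(relValues(two$a22Inv)),
               rbind(c(4 / 3, -2 / 3), c(-2 / 3, 4 / 3)))
  one <- subsetA22(ped, "kid1")
  expect_equal(unname(relValues(one$a22)), matrix(1))
  expect_error(subsetA22(ped, "ghost"), "ghost")
})

test_that("genotype centering subtracts 2p and zero-fills missing", {
  gm <- toyGenotypes(cbind(c(0L, 1L, 2L), c(0L, NA, 2L)))
  z <- centerGenotypes(gm, c(0.5, 0.5))
  expect_equal(unname(z$z[, 1]), c(-1, 0, 1))
  expect_equal(unname(z$z[2, 2]), 0)
  # columns of z average to zero under panel-internal frequencies
  cfg <- simpleConfig(97, nFounders = 30, nGenerations = 1,
                      offspringPerMating = 1, nChromosomes = 1,
                      markersPerChromosome = 50, missingRate = 0,
                      genotypedFraction = 1)
  g2 <- simulateGenotypes(simulatePedigree(cfg), cfg)
  z2 <- centerGenotypes(g2)
  expect_lt(max(abs(colMeans(z2$z))), 1e-12)
})

test_that("the single-marker G has its closed form", {
  gm <- toyGenotypes(cbind(c(0L, 1L, 2L)))
  z <- centerGenotypes(gm, 0.5)
  G <- buildG(z, tuneDiagonal = FALSE, blendTau = 0)
  expect_equal(unname(diag(relValues(G))), c(2, 0, 2))
  expect_equal(relValues(G), tcrossprod(z$z) / 0.5, ignore_attr = TRUE)
})

test_that("diagonal tuning matches G's average diagonal to A22's", {
  cfg <- simpleConfig(101, nFounders = 20, nGenerations = 2,
                      offspringPerMating = 2, nChromosomes = 2,
                      markersPerChromosome = 30, genotypedFraction = 0.5)
  dat <- simulateDataset(cfg)
  a22 <- subsetA22(dat$pedigree, animalIds(dat$panel))
  G <- buildG(centerGenotypes(dat$panel), a22 = a22$a22,
              tuneDiagonal = TRUE, blendTau = 0)
  expect_lt(abs(mean(diag(relValues(G))) -
                mean(diag(relValues(a22$a22)))), 1e-10)
})

test_that("realized genomic and expected pedigree relationships are compatible", {
  cfg <- simpleConfig(103, nFounders = 80, nGenerations = 1,
                      offspringPerMating = 1, nChromosomes = 3,
                      markersPerChromosome = 100, missingRate = 0,
                      genotypedFraction = 0.6)
  dat <- simulateDataset(cfg)
  a22 <- subsetA22(dat$pedigree, animalIds(dat$panel))
  G <- relValues(buildG(centerGenotypes(dat$panel), a22 = a22$a22,
                        tuneDiagonal = TRUE, blendTau = 0))
  A22 <- relValues(a22$a22)
  off <- upper.tri(G)
  expect_lt(abs(mean(G[off]) - mean(A22[off])), 0.05)
})

test_that("G is PSD after blending and permutation-equivariant", {
  cfg <- simpleConfig(107, nFounders = 16, nGenerations = 2,
                      offspringPerMating = 2, nChromosomes = 1,
                      markersPerChromosome = 40, genotypedFraction = 1)
  dat <- simulateDataset(cfg)
  a22 <- subsetA22(dat$pedigree, animalIds(dat$panel))
  G <- relValues(buildG(centerGenotypes(dat$panel), a22 = a22$a22,
                        blendTau = 0.05))
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # permuting the panel animals permutes G identically
  ids <- animalIds(dat$panel)
  set.seed(1); perm <- sample(ids)
  p <- alleleFrequencies(dat$panel)
  Gp <- relValues(buildG(centerGenotypes(dat$panel[perm, ], p),
                         a22 = subsetA22(dat$pedigree, perm)$a22,
                         blendTau = 0.05))
  expect_equal(Gp, G[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("with unit weights G reduces to the classical genomic matrix", {
  cfg <- simpleConfig(109, nFounders = 20, nGenerations = 1,
                      offspringPerMating = 1, nChromosomes = 1,
                      markersPerChromosome = 60, missingRate = 0,
                      genotypedFraction = 1)
  dat <- simulateDataset(cfg)
  z <- centerGenotypes(dat$panel)
  G <- relValues(buildG(z, tuneDiagonal = FALSE, blendTau = 0))
  direct <- tcrossprod(z$z) / sum(2 * z$p * (1 - z$p))
  expect_equal(G, direct, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("H-inverse reduces to A-inverse without genomic information", {
  ped <- trioPedigree()
  aInv <- aInverse(ped)
  empty <- wssGWAS:::relationshipMatrix(matrix(0, 0, 0), character(0), "Ginv")
  emptyA <- wssGWAS:::relationshipMatrix(matrix(0, 0, 0), character(0),
                                         "A22inv")
  H0 <- buildHInverse(aInv, emptyA, empty)
  expect_equal(relValues(H0), relValues(aInv))
  # exact cancellation when G = A22
  a22 <- subsetA22(ped, c("kid1", "dam1"))
  Hc <- buildHInverse(aInv, a22$a22Inv, a22$a22Inv)
  expect_equal(relValues(Hc), relValues(aInv))
})

test_that("with every animal genotyped, H equals G", {
  cfg <- simpleConfig(113, nFounders = 12, nGenerations = 2,
                      offspringPerMating = 2, nChromosomes = 1,
                      markersPerChromosome = 50, genotypedFraction = 1)
  dat <- simulateDataset(cfg)
  ids <- animalIds(dat$pedigree)
  a22 <- subsetA22(dat$pedigree, ids)
  G <- buildG(centerGenotypes(dat$panel[ids, ]), a22 = a22$a22,
              blendTau = 0.05)
  Hinv <- buildHInverse(aInverse(dat$pedigree), a22$a22Inv,
                        invertRelationship(G))
  H <- solve(relValues(Hinv))
  expect_lt(max(abs(H - relValues(G))), 1e-6)
})
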