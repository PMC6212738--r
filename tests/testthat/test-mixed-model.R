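test_that("design matrices drop the first-observed level and have full rank", {
  df <- data.frame(animal = c("a", "b", "c"), y = c(1, 2, 3),
                   farm = c("f1", "f2", "f1"), lot = "only")
  d <- buildDesign(df, "y", c("farm", "lot"), c("a", "b", "c"))
  expect_identical(colnames(d$X), c("(Intercept)", "farm:f2"))
  expect_identical(dim(d$Zinc), c(3L, 3L))

  df2 <- data.frame(animal = letters[1:8], y = rnorm(8),
                    farm = rep(c("f1", "f2"), each = 4),
                    season = rep(c("s1", "s2", "s3", "s4"), 2))
  d2 <- buildDesign(df2, "y", c("farm", "season"), letters[1:8])
  expect_identical(qr(d2$X)$rank, 1L + 1L + 3L)
  expect_error(buildDesign(data.frame(animal = "zz", y = 1), "y",
                           character(0), letters[1:8]), "zz")
})

test_that("MME solutions equal the closed-form GLS on a small system", {
  ped <- trioPedigree()
  K <- relValues(numeratorRelationship(ped))
  Kinv <- relValues(aInverse(ped))
  df <- data.frame(animal = animalIds(ped), y = c(1.2, -0.5, 2.0),
                   farm = c("f1", "f2", "f1"))
  d <- buildDesign(df, "y", "farm", animalIds(ped))
  va <- 1.3; ve <- 2.1
  vc <- VarianceComponents(matrix(va), matrix(ve), "y")
  fit <- solveMME(d, Kinv, vc)
  V <- d$Zinc %*% K %*% t(d$Zinc) * va + diag(3) * ve
  Vi <- solve(V)
  X <- d$X; y <- df$y
  betaGLS <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  uGLS <- va * K %*% t(d$Zinc) %*% Vi %*% (y - X %*% betaGLS)
  expect_lt(max(abs(fit$beta - betaGLS)), 1e-8)
  expect_lt(max(abs(fit$u - uGLS)), 1e-8)
  expect_lt(fit$residualNorm, 1e-8)
})

test_that("vanishing additive variance shrinks every GEBV to zero", {
  cfg <- simpleConfig(121, nFounders = 10, nGenerations = 2,
                      offspringPerMating = 2)
  dat <- simulateDataset(cfg)
  d <- buildDesign(dat$phenotypes, "y", "farm", animalIds(dat$pedigree))
  vc <- VarianceComponents(matrix(1e-9), matrix(3), "y")
  fit <- solveMME(d, aInverse(dat$pedigree), vc)
  expect_lt(max(abs(fit$u)), 1e-6)
})

test_that("an unrelated, unphenotyped animal gets GEBV exactly zero", {
  ped <- Pedigree(c("s", "d", "k", "lone"), c(NA, NA, "s", NA),
                  c(NA, NA, "d", NA))
  df <- data.frame(animal = c("s", "d", "k"), y = c(1, 2, 3))
  d <- buildDesign(df, "y", character(0), animalIds(ped))
  fit <- solveMME(d, aInverse(ped),
                  VarianceComponents(matrix(1), matrix(2), "y"))
  expect_lt(abs(fit$u["lone", 1]), 1e-12)
  expect_gt(abs(fit$u["k", 1]), 1e-6)
})

test_that("EM-REML collapses to the boundary when the true additive variance is zero", {
  # a single null draw is half-normal with SE comparable to the 2% bound,
  # so the boundary behaviour is asserted on the replicate average
  est <- vapply(201:210, function(seed) {
    cfg <- simpleConfig(seed, nFounders = 60, nGenerations = 2,
                        offspringPerMating = 6, sigmaA = matrix(0),
                        sigmaE = matrix(2))
    dat <- simulateDataset(cfg)
    d <- buildDesign(dat$phenotypes, "y", "farm", animalIds(dat$pedigree))
    r <- suppressWarnings(emReml(d, aInverse(dat$pedigree), tol = 1e-9,
                                 maxit = 5000))
    h2Of(r$varcomp)
  }, numeric(1))
  expect_lte(mean(est), 0.02)
})

test_that("the restricted likelihood never decreases across EM rounds", {
  cfg <- simpleConfig(131, nFounders = 16, nGenerations = 2,
                      offspringPerMating = 2)
  dat <- simulateDataset(cfg)
  # drop one record so the generic (non-identity-incidence) path runs too
  d <- buildDesign(dat$phenotypes[-1, ], "y", "farm",
                   animalIds(dat$pedigree))
  r <- suppressWarnings(emReml(d, aInverse(dat$pedigree), tol = 0,
                               maxit = 25, computeLogLik = TRUE))
  expect_true(all(diff(r$logLik) > -1e-6))
  dFast <- buildDesign(dat$phenotypes, "y", "farm",
                       animalIds(dat$pedigree))
  rf <- suppressWarnings(emReml(dFast, aInverse(dat$pedigree), tol = 0,
                                maxit = 25, computeLogLik = TRUE))
  expect_true(all(diff(rf$logLik) > -1e-6))
})

test_that("EM-REML estimates ignore the fixed-factor reference level", {
  cfg <- simpleConfig(137, nFounders = 30, nGenerations = 2,
                      offspringPerMating = 2)
  dat <- simulateDataset(cfg)
  ph <- dat$phenotypes
  d1 <- buildDesign(ph, "y", "farm", animalIds(dat$pedigree))
  # reorder records so a different farm level is observed first
  ord <- order(ph$farm, decreasing = TRUE)
  d2 <- buildDesign(ph[ord, ], "y", "farm", animalIds(dat$pedigree))
  Ai <- aInverse(dat$pedigree)
  r1 <- suppressWarnings(emReml(d1, Ai, tol = 1e-10, maxit = 400))
  r2 <- suppressWarnings(emReml(d2, Ai, tol = 1e-10, maxit = 400))
  expect_equal(sigmaA(r1$varcomp), sigmaA(r2$varcomp), tolerance = 1e-6)
  expect_equal(sigmaE(r1$varcomp), sigmaE(r2$varcomp), tolerance = 1e-6)
})

test_that("multi-trait EM-REML recovers a two-trait covariance structure", {
  Sa <- matrix(c(1, 0.5, 0.5, 0.8), 2)
  Se <- matrix(c(2, -0.3, -0.3, 1.5), 2)
  cfg <- simulationConfig(seed = 139, nFounders = 80, nGenerations = 2,
                          offspringPerMating = 3, nChromosomes = 1,
                          markersPerChromosome = 3,
                          sigmaA = Sa, sigmaE = Se, traits = c("t1", "t2"),
                          fixedEffects = list(farm = c(-0.3, 0.3),
                                              parity = 0, farrowMonth = 0,
                                              farrowYear = 0))
  dat <- simulateDataset(cfg)
  d <- buildDesign(dat$phenotypes, c("t1", "t2"), "farm",
                   animalIds(dat$pedigree))
  r <- suppressWarnings(emReml(d, aInverse(dat$pedigree), tol = 1e-7,
                               maxit = 150))
  gp <- geneticParameters(r$varcomp)
  expect_gt(gp$rg[1, 2], 0)            # sign of the genetic correlation
  expect_lt(abs(gp$h2[1] - 1 / 3), 0.2)
  expect_lt(abs(gp$h2[2] - 0.8 / 2.3), 0.2)
})

test_that("heritability arithmetic reproduces published component pairs", {
  vc <- VarianceComponents(diag(c(0.18, 115.60)), diag(c(1.78, 343.50)),
                           c("PWL", "NPD"))
  gp <- geneticParameters(vc)
  expect_equal(round(unname(gp$h2), 2), c(0.09, 0.25))
  expect_equal(diag(sigmaP(vc)), c(1.96, 459.10), ignore_attr = TRUE)
  # diagonal covariances imply zero correlations, and the h2/e2 shares sum to 1
  expect_equal(gp$rg[1, 2], 0)
  expect_equal(unname(gp$h2 + diag(sigmaE(vc)) / diag(sigmaP(vc))),
               c(1, 1))
})
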