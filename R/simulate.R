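# Synthetic-data generator: discrete-generation pedigrees, gene-dropped
# SNP genotypes (optionally with linkage), and multi-trait phenotypes with
# known ground truth (planted QTL, variance components).  One global seed;
# the three stages draw from fixed per-stage offsets (pedigree seed+0,
# genotypes seed+1, phenotypes seed+2) so each stage is independently
# reproducible and the composed dataset is too.

#' Default six-trait variance regime for the simulator
#'
#' Additive and residual covariance matrices for the six sow reproduction
#' traits (PWL, BAL, W2CL, LSY, PWSY, NPD) assembled from published
#' Large White variance components and genetic/phenotypic correlations,
#' projected to the nearest positive semi-definite matrices (the reported
#' -0.99 LSY/NPD correlations leave the raw matrices marginally
#' indefinite).
#'
#' @return list with `traits`, `sigmaA`, `sigmaE`.
#' @export
defaultTraitSpec <- function() {
  tn <- c("PWL", "BAL", "W2CL", "LSY", "PWSY", "NPD")
  va <- c(0.30, 0.44, 1.31, 0.01, 2.78, 115.60)
  ve <- c(2.15, 2.55, 15.46, 0.02, 12.09, 343.50)
  rg <- diag(6)
  rg[upper.tri(rg)] <- c(0.87,
                         -0.21, -0.15,
                         0.25, 0.08, -0.53,
                         0.90, 0.73, -0.41, 0.65,
                         -0.26, -0.08, 0.53, -0.99, -0.65)
  rg <- rg + t(rg) - diag(6)
  rp <- diag(6)
  rp[upper.tri(rp)] <- c(0.83,
                         0.02, 0.05,
                         -0.10, -0.06, -0.38,
                         0.92, 0.77, -0.14, 0.29,
                         0.08, 0.05, 0.39, -0.99, -0.31)
  rp <- rp + t(rp) - diag(6)
  sa <- sqrt(va); sp <- sqrt(va + ve)
  Sa <- nearPSD(tcrossprod(sa) * rg)
  Sp <- nearPSD(tcrossprod(sp) * rp)
  Se <- nearPSD(Sp - Sa)
  dimnames(Sa) <- dimnames(Se) <- list(tn, tn)
  list(traits = tn, sigmaA = Sa, sigmaE = Se)
}

#' Simulation configuration
#'
#' Defaults emulate the structure of a multi-farm sow population genotyped
#' on a medium-density chip at package scale: discrete generations, six
#' farms, up to ten parities, a uniform founder MAF spectrum, linked
#' markers (1 Morgan per chromosome) and a genotyped subset filled from the
#' youngest generation backwards.
#'
#' @param seed integer seed governing all draws.
#' @param nFounders,nGenerations,offspringPerMating pedigree shape.
#' @param nChromosomes,markersPerChromosome,chromosomeLengthBp marker map
#'   (markers evenly spaced).
#' @param founderMafRange founder minor-allele-frequency range (low, high].
#' @param missingRate fraction of calls masked as missing.
#' @param genotypedFraction fraction of animals emitted as the genotyped
#'   panel (youngest generation first).
#' @param linkage gene-drop with recombination along each chromosome
#'   (Haldane map, `morgansPerChromosome`); `FALSE` = independent markers.
#' @param morgansPerChromosome genetic length per chromosome.
#' @param qtl list of planted QTL, each `list(chr=, posBp=, effects=)` with
#'   per-trait additive allele-substitution effects, optionally `maf=` to
#'   force that marker's founder frequency.
#' @param sigmaA,sigmaE polygenic and residual covariance matrices
#'   (default: [defaultTraitSpec()]).
#' @param traits trait names.
#' @param fixedEffects list of per-factor level-effect vectors on the
#'   residual-SD scale (factors: farm, parity, farrowMonth, farrowYear).
#' @return validated config list of class `"wssgwasSimConfig"`.
#' @export
simulationConfig <- function(seed,
                             nFounders = 80, nGenerations = 4,
                             offspringPerMating = 3,
                             nChromosomes = 5, markersPerChromosome = 100,
                             chromosomeLengthBp = 1e8,
                             founderMafRange = c(0.05, 0.5),
                             missingRate = 0.02, genotypedFraction = 0.3,
                             linkage = TRUE, morgansPerChromosome = 1,
                             qtl = list(),
                             sigmaA = NULL, sigmaE = NULL, traits = NULL,
                             fixedEffects = list(
                               farm = seq(-0.5, 0.5, length.out = 6),
                               parity = seq(-0.2, 0.2, length.out = 10),
                               farrowMonth = rep(c(-0.1, 0.1), 6),
                               farrowYear = seq(-0.1, 0.1, length.out = 10))) {
  if (is.null(sigmaA) || is.null(sigmaE)) {
    spec <- defaultTraitSpec()
    sigmaA <- sigmaA %||% spec$sigmaA
    sigmaE <- sigmaE %||% spec$sigmaE
    traits <- traits %||% spec$traits
  }
  sigmaA <- as.matrix(sigmaA); sigmaE <- as.matrix(sigmaE)
  traits <- traits %||% paste0("trait", seq_len(nrow(sigmaA)))
  stopIf(nFounders < 2, "need at least 2 founders")
  stopIf(nGenerations < 1, "need at least 1 generation")
  stopIf(missingRate < 0 || missingRate > 1, "missingRate must be in [0,1]")
  stopIf(genotypedFraction < 0 || genotypedFraction > 1,
         "genotypedFraction must be in [0,1]")
  stopIf(founderMafRange[1] <= 0 || founderMafRange[2] > 0.5 ||
         founderMafRange[1] > founderMafRange[2],
         "founderMafRange must be within (0, 0.5]")
  for (qt in qtl) {
    stopIf(is.null(qt$chr) || is.null(qt$posBp) || is.null(qt$effects),
           "each QTL needs chr, posBp and effects")
    stopIf(qt$posBp < 1 || qt$posBp > chromosomeLengthBp,
           "QTL position outside the chromosome")
    stopIf(length(qt$effects) != length(traits),
           "QTL effects must have one entry per trait")
  }
  structure(list(seed = as.integer(seed), nFounders = nFounders,
                 nGenerations = nGenerations,
                 offspringPerMating = offspringPerMating,
                 nChromosomes = nChromosomes,
                 markersPerChromosome = markersPerChromosome,
                 chromosomeLengthBp = chromosomeLengthBp,
                 founderMafRange = founderMafRange,
                 missingRate = missingRate,
                 genotypedFraction = genotypedFraction,
                 linkage = isTRUE(linkage),
                 morgansPerChromosome = morgansPerChromosome,
                 qtl = qtl, sigmaA = sigmaA, sigmaE = sigmaE,
                 traits = traits, fixedEffects = fixedEffects),
            class = "wssgwasSimConfig")
}

#' Simulate a discrete-generation pedigree
#'
#' Founders are assigned alternating sexes; in each later generation every
#' dam of the previous generation is mated to a randomly drawn sire and
#' produces `offspringPerMating` offspring of random sex.  Deterministic
#' for a fixed seed.
#'
#' @param config a [simulationConfig()].
#' @return A [Pedigree-class]; generation numbers in
#'   `attr(, "generation")`.
#' @export
simulatePedigree <- function(config) {
  withSeed(config$seed, {
    id <- sprintf("F%04d", seq_len(config$nFounders))
    sire <- rep(NA_character_, config$nFounders)
    dam <- rep(NA_character_, config$nFounders)
    sex <- rep(c("M", "F"), length.out = config$nFounders)
    gen <- rep(0L, config$nFounders)
    prev <- seq_along(id)
    for (g in seq_len(config$nGenerations)) {
      sires <- id[prev][sex[prev] == "M"]
      dams <- id[prev][sex[prev] == "F"]
      stopIf(length(sires) < 1 || length(dams) < 1,
             "generation %d has no animals of one sex", g - 1L)
      mateSire <- sample(sires, length(dams), replace = TRUE)
      newId <- character(0); newSire <- character(0); newDam <- character(0)
      for (k in seq_along(dams)) {
        off <- sprintf("G%d_%04d", g,
                       length(newId) + seq_len(config$offspringPerMating))
        newId <- c(newId, off)
        newSire <- c(newSire, rep(mateSire[k], length(off)))
        newDam <- c(newDam, rep(dams[k], length(off)))
      }
      newSex <- ifelse(stats::runif(length(newId)) < 0.5, "M", "F")
      prev <- length(id) + seq_along(newId)
      id <- c(id, newId); sire <- c(sire, newSire); dam <- c(dam, newDam)
      sex <- c(sex, newSex); gen <- c(gen, rep(g, length(newId)))
    }
    ped <- Pedigree(id, sire, dam, sex = sex)
    attr(ped, "generation") <- setNames(gen, id)[animalIds(ped)]
    ped
  })
}

# Evenly spaced marker map.
simMarkerMap <- function(config) {
  m <- config$markersPerChromosome
  pos <- floor(seq_len(m) * config$chromosomeLengthBp / (m + 1))
  do.call(rbind, lapply(seq_len(config$nChromosomes), function(cc)
    data.frame(snp = sprintf("snp%d_%03d", cc, seq_len(m)),
               chr = as.character(cc), pos = as.integer(pos),
               stringsAsFactors = FALSE)))
}

# One transmitted gamete from parent haplotypes h1, h2 (vectors over all
# markers), recombining within chromosomes (chrId groups markers).
simGamete <- function(h1, h2, rprob, chrStart) {
  m <- length(h1)
  pick <- integer(m)
  start <- stats::runif(length(chrStart)) < 0.5
  sw <- stats::runif(m) < rprob          # rprob is 0.5 at chromosome starts
  sw[chrStart] <- FALSE
  cur <- rep(start, diff(c(chrStart, m + 1L)))
  pick <- (cumsumReset(sw, chrStart) + cur) %% 2L
  ifelse(pick == 0L, h1, h2)
}

# cumulative sum of switch indicators, reset at each chromosome start
cumsumReset <- function(x, starts) {
  cs <- cumsum(x)
  base <- rep(cs[starts] - x[starts], diff(c(starts, length(x) + 1L)))
  cs - base
}

#' Simulate gene-dropped SNP genotypes along a pedigree
#'
#' Founder haplotypes are drawn marker-wise Bernoulli at MAFs sampled
#' uniformly from `founderMafRange` (Hardy-Weinberg); descendants receive
#' one recombined gamete from each parent (Haldane map when `linkage` is
#' on, independent markers otherwise).  Missingness is applied at
#' `missingRate`.  The full matrix over all animals is returned; the
#' genotyped panel (a `genotypedFraction` subset filled from the youngest
#' generation backwards) is recorded in
#' `metadata$genotyped` — use [genotypedSubset()] to extract it.
#'
#' @param pedigree a [Pedigree-class] (typically from [simulatePedigree()]).
#' @param config a [simulationConfig()].
#' @return A [GenotypeMatrix-class] over all pedigree animals; metadata
#'   holds `genotyped` (panel ids) and `founderMaf`.
#' @export
simulateGenotypes <- function(pedigree, config) {
  withSeed(config$seed + 1L, {
    map <- simMarkerMap(config)
    m <- nrow(map)
    ids <- animalIds(pedigree)
    n <- length(ids)
    pos <- setNames(seq_len(n), ids)
    si <- ifelse(is.na(pedigree@sire), 0L, pos[pedigree@sire])
    di <- ifelse(is.na(pedigree@dam), 0L, pos[pedigree@dam])

    p <- stats::runif(m, config$founderMafRange[1], config$founderMafRange[2])
    for (qt in config$qtl) {
      if (!is.null(qt$maf)) {
        j <- which(map$chr == as.character(qt$chr) & map$pos == qt$posBp)
        stopIf(!length(j), "QTL at %s:%d does not coincide with a marker",
               qt$chr, qt$posBp)
        p[j] <- qt$maf
      }
    }

    chrStart <- which(!duplicated(map$chr))
    if (config$linkage) {
      dM <- c(0, diff(map$pos)) / config$chromosomeLengthBp *
            config$morgansPerChromosome
      rprob <- 0.5 * (1 - exp(-2 * dM))
    } else {
      rprob <- rep(0.5, m)
    }
    rprob[chrStart] <- 0.5

    H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      if (si[i] == 0L && di[i] == 0L) {
        H1[i, ] <- stats::rbinom(m, 1L, p)
        H2[i, ] <- stats::rbinom(m, 1L, p)
      } else {
        stopIf(si[i] == 0L || di[i] == 0L,
               "gene dropping requires both parents known for '%s'", ids[i])
        H1[i, ] <- simGamete(H1[si[i], ], H2[si[i], ], rprob, chrStart)
        H2[i, ] <- simGamete(H1[di[i], ], H2[di[i], ], rprob, chrStart)
      }
    }
    calls <- H1 + H2
    dimnames(calls) <- list(ids, map$snp)
    if (config$missingRate > 0) {
      mask <- stats::runif(length(calls)) < config$missingRate
      calls[mask] <- NA_integer_
    }
    gen <- attr(pedigree, "generation")
    if (is.null(gen)) gen <- setNames(rep(0L, n), ids)
    nGeno <- min(n, ceiling(config$genotypedFraction * n))
    genoIds <- ids[order(-gen, match(ids, ids))][seq_len(nGeno)]
    GenotypeMatrix(calls, map,
                   metadata = list(genotyped = genoIds, founderMaf = p,
                                   coding = "simulated second-allele counts"))
  })
}

#' Extract the genotyped panel recorded by the simulator
#'
#' @param genotypes a [GenotypeMatrix-class] whose metadata lists the
#'   `genotyped` panel ids (as produced by [simulateGenotypes()]).
#' @return A [GenotypeMatrix-class] restricted to the panel animals.
#' @export
genotypedSubset <- function(genotypes) {
  ids <- genotypes@metadata$genotyped
  stopIf(is.null(ids), "metadata carries no genotyped panel")
  genotypes[ids, ]
}

# eigen-based symmetric square root (tolerates PSD matrices incl. zero)
matrixSqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate multi-trait phenotypes with known ground truth
#'
#' Breeding value = planted-QTL part (allele count x effect, summed over
#' QTL) + polygenic part drawn by mendelian-sampling recursion (founders
#' ~ N(0, Sigma_a); non-founders = parent average + deviation with variance
#' 0.5 (1 - (F_s + F_d)/2) Sigma_a, inbreeding by Meuwissen-Luo).
#' Phenotype = fixed-level effects + breeding value + residual
#' ~ N(0, Sigma_e).  All traits are generated jointly; deterministic per
#' seed.  Missing QTL calls are mean-imputed before computing the QTL part.
#'
#' @param pedigree a [Pedigree-class].
#' @param genotypes a [GenotypeMatrix-class] covering all pedigree animals.
#' @param config a [simulationConfig()].
#' @return list with `traits` (per-animal data.frame: id, trait values,
#'   fixed-effect levels) and `truth` (list: `tbv`, `polygenic`,
#'   `qtlEffects`, `qtlMarkers`, `realizedVarcomp`).
#' @export
simulatePhenotypes <- function(pedigree, genotypes, config) {
  withSeed(config$seed + 2L, {
    ids <- animalIds(pedigree)
    n <- length(ids)
    tn <- config$traits
    t <- length(tn)
    calls <- genoCalls(genotypes)
    stopIf(!all(ids %in% rownames(calls)),
           "genotypes must cover every pedigree animal")
    map <- markerMap(genotypes)

    # planted-QTL breeding values
    qtlBv <- matrix(0, n, t)
    qtlEff <- matrix(0, nrow(map), t,
                     dimnames = list(map$snp, tn))
    qtlMarkers <- character(0)
    for (qt in config$qtl) {
      j <- which(map$chr == as.character(qt$chr) & map$pos == qt$posBp)
      stopIf(!length(j), "QTL at %s:%s is not a simulated marker",
             qt$chr, format(qt$posBp, scientific = FALSE))
      dos <- calls[ids, j]
      if (anyNA(dos)) dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
      qtlBv <- qtlBv + outer(as.numeric(dos), as.numeric(qt$effects))
      qtlEff[j, ] <- qtlEff[j, ] + as.numeric(qt$effects)
      qtlMarkers <- c(qtlMarkers, map$snp[j])
    }

    # polygenic breeding values by mendelian-sampling recursion
    pos <- setNames(seq_len(n), ids)
    si <- ifelse(is.na(pedigree@sire), 0L, pos[pedigree@sire])
    di <- ifelse(is.na(pedigree@dam), 0L, pos[pedigree@dam])
    Fi <- inbreedingML(si, di)$F
    Lt <- matrixSqrt(config$sigmaA)
    polyBv <- matrix(0, n, t)
    zDraws <- matrix(stats::rnorm(n * t), n, t)
    for (i in seq_len(n)) {
      if (si[i] == 0L && di[i] == 0L) {
        polyBv[i, ] <- Lt %*% zDraws[i, ]
      } else {
        pm <- (polyBv[si[i], ] + polyBv[di[i], ]) / 2
        k <- 0.5 * (1 - (Fi[si[i]] + Fi[di[i]]) / 2)
        polyBv[i, ] <- pm + sqrt(k) * (Lt %*% zDraws[i, ])
      }
    }
    tbv <- qtlBv + polyBv

    # fixed-effect levels and residuals
    fe <- config$fixedEffects
    lev <- data.frame(
      farm = sample(seq_along(fe$farm), n, replace = TRUE),
      parity = sample(seq_along(fe$parity), n, replace = TRUE),
      farrowMonth = sample(seq_along(fe$farrowMonth), n, replace = TRUE),
      farrowYear = sample(seq_along(fe$farrowYear), n, replace = TRUE))
    seSd <- sqrt(diag(as.matrix(config$sigmaE)))
    fixedPart <- (fe$farm[lev$farm] + fe$parity[lev$parity] +
                  fe$farrowMonth[lev$farrowMonth] +
                  fe$farrowYear[lev$farrowYear]) %o% seSd
    resid <- matrix(stats::rnorm(n * t), n, t) %*% matrixSqrt(config$sigmaE)
    y <- fixedPart + tbv + resid
    colnames(y) <- tn
    traits <- data.frame(animal = ids, y, lev, stringsAsFactors = FALSE)

    list(traits = traits,
         truth = list(tbv = `dimnames<-`(tbv, list(ids, tn)),
                      polygenic = `dimnames<-`(polyBv, list(ids, tn)),
                      qtlEffects = qtlEff, qtlMarkers = qtlMarkers,
                      realizedVarcomp = stats::cov(tbv)))
  })
}

#' Simulate a complete dataset and optionally write it to disk
#'
#' Runs [simulatePedigree()], [simulateGenotypes()] and
#' [simulatePhenotypes()] with the config's seed, and if `dir` is given
#' writes the fixture files the readers consume (pedigree CSV, panel
#' genotype matrix TSV + map, phenotype TSV) plus a ground-truth JSON.
#'
#' @param config a [simulationConfig()].
#' @param dir optional output directory.
#' @return list with `pedigree`, `genotypes` (all animals), `panel`
#'   (genotyped subset), `phenotypes`, `truth`, and `paths` (when written).
#' @export
simulateDataset <- function(config, dir = NULL) {
  ped <- simulatePedigree(config)
  gm <- simulateGenotypes(ped, config)
  ph <- simulatePhenotypes(ped, gm, config)
  panel <- genotypedSubset(gm)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      pedigree = file.path(dir, "pedigree.csv"),
      genotypes = file.path(dir, "genotypes.tsv"),
      map = file.path(dir, "map.tsv"),
      phenotypes = file.path(dir, "phenotypes.tsv"),
      truth = file.path(dir, "ground_truth.json"))
    writePedigree(ped, paths$pedigree)
    writeGenotypes(panel, paths$genotypes, paths$map)
    utils::write.table(ph$traits, paths$phenotypes, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(qtlMarkers = ph$truth$qtlMarkers,
           realizedVarcomp = ph$truth$realizedVarcomp,
           seed = config$seed),
      paths$truth, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  }
  list(pedigree = ped, genotypes = gm, panel = panel,
       phenotypes = ph$traits, truth = ph$truth, paths = paths)
}

#' Simulate litter-level sow records
#'
#' A light record layer for exercising trait derivation: litters per sow
#' truncated-Poisson (1..10 parities), gestation 115 +/- 2 days, lactation
#' ~ 25 +/- 3 days, wean-to-conception ~ 5 + Exp(7) days (last litter open
#' with probability `openRate`), herd days consistent with the litter
#' cycle.
#'
#' @param nSows number of sows.
#' @param seed RNG seed.
#' @param meanLitters mean litter count before truncation.
#' @param openRate probability the last litter has no conception record.
#' @return litter-level data.frame consumable by [deriveTraits()].
#' @export
simulateSowRecords <- function(nSows, seed, meanLitters = 4,
                               openRate = 0.3) {
  withSeed(seed, {
    rows <- lapply(seq_len(nSows), function(s) {
      nl <- min(10L, max(1L, stats::rpois(1, meanLitters)))
      gest <- round(stats::rnorm(nl, 115, 2))
      lact <- round(stats::rnorm(nl, 25, 3))
      w2c <- round(5 + stats::rexp(nl, 1 / 7))
      if (stats::runif(1) < openRate) w2c[nl] <- NA
      herd <- sum(gest + lact + ifelse(is.na(w2c), 7, w2c)) +
              round(stats::runif(1, 0, 60))
      data.frame(sow = sprintf("S%04d", s), parity = seq_len(nl),
                 pigsWeaned = pmax(0, round(stats::rnorm(nl, 10, 2))),
                 bornAlive = pmax(0, round(stats::rnorm(nl, 11, 2))),
                 w2cDays = w2c, gestationDays = gest, lactationDays = lact,
                 farrowMonth = sample(1:12, nl, replace = TRUE),
                 farrowYear = sample(2006:2015, nl, replace = TRUE),
                 farm = sample(sprintf("farm%d", 1:6), nl, replace = TRUE),
                 herdDays = herd, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Inject Mendelian errors into genotype calls (QC exercise hook)
#'
#' Overwrites the offspring's calls with the opposite homozygote at up to
#' `nMarkers` markers where the parent is homozygous, creating
#' parent-progeny conflicts for [mendelianConflicts()] to find.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param parent,offspring animal ids.
#' @param nMarkers number of conflicting markers to force.
#' @param seed RNG seed for marker choice.
#' @return the modified [GenotypeMatrix-class].
#' @export
injectMendelianErrors <- function(genotypes, parent, offspring, nMarkers,
                                  seed = 1) {
  withSeed(seed, {
    calls <- genoCalls(genotypes)
    hom <- which(!is.na(calls[parent, ]) & calls[parent, ] != 1L)
    stopIf(length(hom) < nMarkers,
           "parent has only %d homozygous markers", length(hom))
    j <- sample(hom, nMarkers)
    calls[offspring, j] <- 2L - calls[parent, j]
    GenotypeMatrix(calls, markerMap(genotypes), genotypes@metadata)
  })
}
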