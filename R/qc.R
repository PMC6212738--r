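# Marker and sample quality control: call rates, minor allele frequency,
# monomorphic markers, and parent-progeny Mendelian-conflict checks.

#' QC thresholds
#'
#' @param minSnpCallRate minimum per-SNP call rate (default 0.90).
#' @param minSampleCallRate minimum per-animal call rate (default 0.90).
#' @param minMaf minimum minor allele frequency (default 0.05).
#' @param dropMonomorphic drop markers with MAF 0 (default `TRUE`).
#' @param maxMendelianConflictRate flag a parent-offspring pair whose
#'   opposite-homozygote rate exceeds this (default 0.01); the offspring is
#'   removed.
#' @return list of thresholds, validated.
#' @export
qcThresholds <- function(minSnpCallRate = 0.90, minSampleCallRate = 0.90,
                         minMaf = 0.05, dropMonomorphic = TRUE,
                         maxMendelianConflictRate = 0.01) {
  th <- list(minSnpCallRate = minSnpCallRate,
             minSampleCallRate = minSampleCallRate, minMaf = minMaf,
             dropMonomorphic = isTRUE(dropMonomorphic),
             maxMendelianConflictRate = maxMendelianConflictRate)
  for (nm in c("minSnpCallRate", "minSampleCallRate", "minMaf",
               "maxMendelianConflictRate"))
    stopIf(th[[nm]] < 0 || th[[nm]] > 1, "%s must be in [0, 1]", nm)
  th
}

#' Second-allele frequencies per marker
#'
#' `p_i` = (sum of codes over non-missing animals) / (2 x non-missing
#' count): the frequency of the counted (second) allele in the current
#' genotyped population.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @return named numeric vector of frequencies in `[0, 1]`.
#' @export
alleleFrequencies <- function(genotypes) {
  calls <- genoCalls(genotypes)
  nObs <- colSums(!is.na(calls))
  if (any(nObs == 0))
    stopIf(TRUE, "marker '%s' has no non-missing calls",
           colnames(calls)[which(nObs == 0)[1L]])
  colSums(calls, na.rm = TRUE) / (2 * nObs)
}

#' Parent-progeny Mendelian conflicts
#'
#' A conflict at a marker is an opposite-homozygote pair (codes 0 vs 2);
#' missing calls are skipped.  Only pairs where both members are genotyped
#' are compared.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param pedigree a [Pedigree-class].
#' @return data.frame (parent, offspring, nConflicts, nCompared).
#' @export
mendelianConflicts <- function(genotypes, pedigree) {
  calls <- genoCalls(genotypes)
  gids <- rownames(calls)
  ped <- as.data.frame(pedigree)
  pairs <- rbind(
    data.frame(parent = ped$sire, offspring = ped$animal,
               stringsAsFactors = FALSE),
    data.frame(parent = ped$dam, offspring = ped$animal,
               stringsAsFactors = FALSE))
  pairs <- pairs[!is.na(pairs$parent) & pairs$parent %in% gids &
                 pairs$offspring %in% gids, , drop = FALSE]
  if (!nrow(pairs))
    return(data.frame(parent = character(0), offspring = character(0),
                      nConflicts = integer(0), nCompared = integer(0)))
  cp <- calls[pairs$parent, , drop = FALSE]
  co <- calls[pairs$offspring, , drop = FALSE]
  both <- !is.na(cp) & !is.na(co)
  confl <- both & ((cp == 0L & co == 2L) | (cp == 2L & co == 0L))
  data.frame(parent = pairs$parent, offspring = pairs$offspring,
             nConflicts = as.integer(rowSums(confl)),
             nCompared = as.integer(rowSums(both)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the marker/sample QC filters
#'
#' Filter order is fixed and documented: (1) SNP call rate, (2) sample call
#' rate, (3) MAF computed on the survivors, (4) monomorphic markers,
#' (5) Mendelian conflict rate per genotyped parent-offspring pair (the
#' offspring of a conflicted pair is removed).  Each step operates on the
#' matrix surviving the previous one and every removal carries exactly one
#' primary reason.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param thresholds a [qcThresholds()] list.
#' @param pedigree optional [Pedigree-class] enabling the Mendelian step.
#' @return A [QcResult-class].
#' @export
applyQc <- function(genotypes, thresholds = qcThresholds(), pedigree = NULL) {
  th <- thresholds
  calls <- genoCalls(genotypes)
  remSnp <- data.frame(snp = character(0), reason = character(0),
                       statistic = numeric(0), stringsAsFactors = FALSE)
  remAni <- data.frame(animal = character(0), reason = character(0),
                       statistic = numeric(0), stringsAsFactors = FALSE)
  gm <- genotypes

  # (1) SNP call rate
  cr <- colMeans(!is.na(genoCalls(gm)))
  drop <- cr < th$minSnpCallRate
  if (any(drop)) {
    remSnp <- rbind(remSnp, data.frame(snp = names(cr)[drop],
                                       reason = "snp_call_rate",
                                       statistic = unname(cr[drop])))
    gm <- gm[, !drop]
  }

  # (2) sample call rate
  if (ncol(genoCalls(gm))) {
    cr <- rowMeans(!is.na(genoCalls(gm)))
    drop <- cr < th$minSampleCallRate
    if (any(drop)) {
      remAni <- rbind(remAni, data.frame(animal = names(cr)[drop],
                                         reason = "sample_call_rate",
                                         statistic = unname(cr[drop])))
      gm <- gm[!drop, ]
    }
  }

  # (3) MAF on survivors; (4) monomorphic
  if (ncol(genoCalls(gm)) && nrow(genoCalls(gm))) {
    p <- alleleFrequencies(gm)
    maf <- pmin(p, 1 - p)
    mono <- maf == 0 & th$dropMonomorphic
    low <- maf < th$minMaf & maf > 0
    if (any(low)) {
      remSnp <- rbind(remSnp, data.frame(snp = names(maf)[low],
                                         reason = "low_maf",
                                         statistic = unname(maf[low])))
    }
    if (any(mono)) {
      remSnp <- rbind(remSnp, data.frame(snp = names(maf)[mono],
                                         reason = "monomorphic",
                                         statistic = unname(maf[mono])))
    }
    if (any(low | mono)) gm <- gm[, !(low | mono)]
  }

  # (5) Mendelian conflicts
  confl <- data.frame(parent = character(0), offspring = character(0),
                      nConflicts = integer(0), nCompared = integer(0))
  if (!is.null(pedigree) && nrow(genoCalls(gm)) && ncol(genoCalls(gm))) {
    confl <- mendelianConflicts(gm, pedigree)
    if (nrow(confl)) {
      rate <- ifelse(confl$nCompared > 0,
                     confl$nConflicts / confl$nCompared, 0)
      bad <- unique(confl$offspring[rate > th$maxMendelianConflictRate])
      if (length(bad)) {
        stat <- vapply(bad, function(a)
          max(rate[confl$offspring == a]), numeric(1))
        remAni <- rbind(remAni, data.frame(animal = bad,
                                           reason = "mendelian_conflict",
                                           statistic = unname(stat)))
        gm <- gm[!(rownames(genoCalls(gm)) %in% bad), ]
      }
    }
  }

  new("QcResult", kept = gm, removedSnps = remSnp, removedAnimals = remAni,
      conflictPairs = confl)
}
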