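# One-config orchestration of the full analysis: QC -> trait table ->
# REML -> weighted single-step scan -> annotation, with a hashed artifact
# manifest so a rerun with identical inputs is verifiably identical.

#' Read and validate a pipeline configuration (YAML or JSON)
#'
#' @param path config file; YAML and JSON dialects both accepted.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @param config a config list built in R.
#' @export
validatePipelineConfig <- function(config) {
  defaults <- list(
    qc = list(minSnpCallRate = 0.90, minSampleCallRate = 0.90,
              minMaf = 0.05, dropMonomorphic = TRUE,
              maxMendelianConflictRate = 0.01),
    scan = list(iterations = 2, windowSize = 5, thresholdPct = 1.0,
                denominator = "reml", blendTau = 0.05, tuneDiagonal = TRUE),
    reml = list(tol = 1e-8, maxit = 1000),
    npdFormula = "per-litter",
    flankBp = 2e6,
    seed = 1)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (k in names(defaults[[nm]]))
        if (is.null(config[[nm]][[k]])) config[[nm]][[k]] <- defaults[[nm]][[k]]
  }
  stopIf(is.null(config$paths$pedigree), "config needs paths$pedigree")
  stopIf(is.null(config$paths$genotypes) || is.null(config$paths$genotypeMap),
         "config needs paths$genotypes and paths$genotypeMap")
  stopIf(is.null(config$paths$phenotypes) && is.null(config$paths$sowRecords),
         "config needs paths$phenotypes or paths$sowRecords")
  stopIf(is.null(config$paths$outputDir), "config needs paths$outputDir")
  stopIf(is.null(config$model$traits), "config needs model$traits")
  sc <- config$scan
  stopIf(sc$thresholdPct < 0 || sc$thresholdPct > 100,
         "scan$thresholdPct must be in [0, 100]")
  stopIf(sc$windowSize < 1, "scan$windowSize must be >= 1")
  stopIf(sc$iterations < 0, "scan$iterations must be >= 0")
  stopIf(sc$blendTau < 0 || sc$blendTau >= 1, "scan$blendTau must be in [0, 1)")
  stopIf(!sc$denominator %in% c("reml", "empirical"),
         "scan$denominator must be 'reml' or 'empirical'")
  for (p in c("pedigree", "genotypes", "genotypeMap", "phenotypes",
              "sowRecords", "geneAnnotation")) {
    f <- config$paths[[p]]
    stopIf(!is.null(f) && !file.exists(f), "input file not found: %s", f)
  }
  config
}

#' Run the full pipeline from a config
#'
#' Stages run in order: genotype QC, trait table (derived from sow records
#' or read per-animal), EM-REML variance components under the single-step
#' H-inverse, the iterative weighted scan with window scoring and region
#' selection, and (when a gene file is configured) candidate annotation.
#' Every output file is hashed into `manifest.json` together with the
#' echoed config; a rerun with the same config and inputs reproduces
#' identical hashes.
#'
#' @param config validated config list (see [readPipelineConfig()]).
#' @return invisibly, list with the manifest and the in-memory stage
#'   results.  Any stage error aborts with the stage name.
#' @export
runPipeline <- function(config) {
  config <- validatePipelineConfig(config)
  outDir <- config$paths$outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- "load"
  result <- tryCatch({
    ped <- readPedigree(config$paths$pedigree)
    gm <- readGenotypes(config$paths$genotypes, "matrix-tsv",
                        mapPath = config$paths$genotypeMap)

    stage <- "qc"
    th <- do.call(qcThresholds, config$qc)
    qc <- applyQc(gm, th, pedigree = ped)
    qcReport <- rbind(
      data.frame(item = removedSnps(qc)$snp,
                 type = rep("snp", nrow(removedSnps(qc))),
                 reason = removedSnps(qc)$reason,
                 statistic = removedSnps(qc)$statistic),
      data.frame(item = removedAnimals(qc)$animal,
                 type = rep("animal", nrow(removedAnimals(qc))),
                 reason = removedAnimals(qc)$reason,
                 statistic = removedAnimals(qc)$statistic))
    f <- file.path(outDir, "qc_report.tsv")
    utils::write.table(qcReport, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    outputs <- c(outputs, f)
    panel <- keptGenotypes(qc)

    stage <- "traits"
    if (!is.null(config$paths$sowRecords)) {
      rec <- utils::read.table(config$paths$sowRecords, header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
      traits <- deriveTraits(rec, npdFormula = config$npdFormula)
      names(traits)[names(traits) == "sow"] <- "animal"
    } else {
      traits <- utils::read.table(config$paths$phenotypes, header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
    }
    traits <- traits[complete.cases(traits[, config$model$traits,
                                           drop = FALSE]), , drop = FALSE]
    f <- file.path(outDir, "trait_table.tsv")
    utils::write.table(traits, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    outputs <- c(outputs, f)

    stage <- "reml"
    traitCols <- config$model$traits
    fixedCols <- config$model$fixedEffects %||% character(0)
    fixedCols <- unlist(fixedCols)
    design <- buildDesign(traits, traitCols, fixedCols,
                          relationshipIds = animalIds(ped))
    aInv <- aInverse(ped)
    a22 <- subsetA22(ped, animalIds(panel))
    z0 <- centerGenotypes(panel)
    G0 <- buildG(z0, a22 = a22$a22,
                 tuneDiagonal = isTRUE(config$scan$tuneDiagonal),
                 blendTau = config$scan$blendTau)
    Hinv <- buildHInverse(aInv, a22$a22Inv, invertRelationship(G0))
    reml <- emReml(design, Hinv, tol = config$reml$tol,
                   maxit = config$reml$maxit)
    vc <- reml$varcomp
    gp <- geneticParameters(vc)
    vcTab <- data.frame(trait = traitNames(vc),
                        sigmaA2 = diag(sigmaA(vc)),
                        sigmaE2 = diag(sigmaE(vc)),
                        sigmaP2 = diag(sigmaP(vc)),
                        h2 = gp$h2)
    f <- file.path(outDir, "variance_components.tsv")
    utils::write.table(vcTab, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    outputs <- c(outputs, f)
    f <- file.path(outDir, "genetic_correlations.tsv")
    utils::write.table(data.frame(trait = rownames(gp$rg),
                                  round(gp$rg, 4)), f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, f)

    stage <- "scan"
    eff <- runSsgwas(panel, ped, traits, traitCols, fixedCols, vc,
                     nIterations = config$scan$iterations,
                     tuneDiagonal = isTRUE(config$scan$tuneDiagonal),
                     blendTau = config$scan$blendTau)
    denom <- if (config$scan$denominator == "empirical") "empirical"
             else setNames(diag(sigmaA(vc)), traitNames(vc))
    scan <- windowVariance(attr(eff, "z"), eff, denom,
                           map = markerMap(panel),
                           windowSize = config$scan$windowSize)
    f <- file.path(outDir, "window_scan.tsv")
    writeWindowScan(scan, f)
    outputs <- c(outputs, f)
    regions <- selectRegions(scan, config$scan$thresholdPct)
    snpRows <- regionsToSnps(regions, markerMap(panel))

    stage <- "annotate"
    if (!is.null(config$paths$geneAnnotation)) {
      genes <- readGeneAnnotation(config$paths$geneAnnotation)
      ann <- annotateRegions(snpRows, genes, flankBp = config$flankBp)
      f <- file.path(outDir, "candidate_regions.tsv")
      writeRegionTable(ann, f)
      outputs <- c(outputs, f)
      f <- file.path(outDir, "candidate_summary.tsv")
      utils::write.table(summarizeCandidates(ann), f, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, f)
    }

    list(qc = qc, traits = traits, reml = reml, scan = scan,
         regions = regions)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(config = config,
                   outputs = lapply(setNames(outputs, basename(outputs)),
                                    function(f)
                                      unname(tools::md5sum(f))))
  mf <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(result, list(manifest = manifest, manifestPath = mf)))
}

# Explode merged regions into one row per member SNP (the shape of the
# published candidate tables: one row per SNP with the region's percent).
regionsToSnps <- function(regions, map) {
  if (!nrow(regions))
    return(data.frame(trait = character(0), chr = character(0),
                      snpPos = integer(0), snpId = character(0),
                      pctVar = numeric(0)))
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    snps <- strsplit(regions$snps[i], ",")[[1L]]
    idx <- match(snps, map$snp)
    data.frame(trait = regions$trait[i], chr = regions$chr[i],
               snpPos = map$pos[idx], snpId = snps,
               pctVar = regions$pctVar[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
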