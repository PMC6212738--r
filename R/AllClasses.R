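#' @import methods
#' @importFrom stats var sd rnorm rbinom runif rpois setNames model.matrix
#'   aggregate complete.cases
#' @importFrom utils read.table write.table head tail
NULL

#' Pedigree of animals with sire/dam links
#'
#' Ordered animal records.  The constructor topologically sorts the records
#' so that every parent precedes its offspring, and refuses pedigrees with
#' duplicate identifiers or ancestral cycles.  Unknown parents are stored as
#' `NA`.
#'
#' @slot id character vector of unique animal identifiers, parents first.
#' @slot sire character vector of sire identifiers (`NA` = unknown).
#' @slot dam character vector of dam identifiers (`NA` = unknown).
#' @slot sex optional character vector ("M"/"F"/NA), used by the simulator.
#' @exportClass Pedigree
setClass("Pedigree",
  representation(id = "character", sire = "character", dam = "character",
                 sex = "character"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n)
    return("id, sire and dam must have equal length")
  if (anyDuplicated(object@id)) {
    dup <- object@id[duplicated(object@id)][1L]
    return(sprintf("duplicate animal id '%s'", dup))
  }
  pos <- seq_len(n)
  names(pos) <- object@id
  for (col in list(object@sire, object@dam)) {
    known <- !is.na(col)
    idx <- pos[col[known]]
    if (anyNA(idx))
      return(sprintf("parent '%s' not in pedigree",
                     col[known][which(is.na(idx))[1L]]))
    if (any(idx >= pos[known]))
      return("pedigree not ordered: a parent appears at or after its offspring")
  }
  TRUE
})

#' Coded SNP genotypes with a marker map
#'
#' Animals x markers matrix of second-allele counts (0, 1, 2 or `NA`),
#' together with the marker map (SNP id, chromosome, 1-based position).
#' Markers are kept sorted by (chromosome, position).
#'
#' @slot calls integer matrix, rownames = animal ids, colnames = SNP ids.
#' @slot map data.frame with columns `snp`, `chr`, `pos`.
#' @slot metadata list of provenance notes (allele coding, genotyped subset).
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(calls = "matrix", map = "data.frame", metadata = "list"))

setValidity("GenotypeMatrix", function(object) {
  m <- object@map
  if (!all(c("snp", "chr", "pos") %in% names(m)))
    return("map must have columns snp, chr, pos")
  if (ncol(object@calls) != nrow(m))
    return("number of call columns does not match the marker map")
  if (!identical(colnames(object@calls), as.character(m$snp)))
    return("call column names do not match map snp ids")
  if (is.null(rownames(object@calls)))
    return("calls must carry animal ids as rownames")
  if (any(m$pos < 1)) return("positions must be >= 1 (1-based)")
  ok <- !is.na(object@calls)
  if (any(object@calls[ok] < 0L | object@calls[ok] > 2L))
    return("calls must be 0, 1, 2 or NA")
  o <- orderMarkers(m$chr, m$pos)
  if (!identical(o, seq_len(nrow(m))))
    return("markers must be sorted by (chromosome, position)")
  TRUE
})

#' Gene intervals for candidate-gene annotation
#'
#' A thin wrapper around a [GenomicRanges::GRanges] holding 1-based
#' inclusive gene intervals with a `gene` metadata column, whatever the
#' source dialect (BED input is shifted at the boundary).
#'
#' @slot ranges a `GRanges` with a `gene` metadata column.
#' @exportClass GeneIntervalSet
setClass("GeneIntervalSet", representation(ranges = "GRanges"))

setValidity("GeneIntervalSet", function(object) {
  if (is.null(object@ranges$gene)) return("ranges must carry a 'gene' column")
  if (length(object@ranges) &&
      any(GenomicRanges::start(object@ranges) >
          GenomicRanges::end(object@ranges)))
    return("interval start exceeds end")
  TRUE
})

#' Relationship matrix (A, A22, G or an H-inverse block)
#'
#' @slot ids ordered animal ids labelling rows/columns.
#' @slot values symmetric numeric matrix.
#' @slot kind one of "A", "Ainv", "A22", "A22inv", "G", "Ginv", "Hinv".
#' @slot metadata list (e.g. the scaling constants used to build G).
#' @exportClass RelationshipMatrix
setClass("RelationshipMatrix",
  representation(ids = "character", values = "matrix", kind = "character",
                 metadata = "list"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (length(object@ids) != nrow(v)) return("ids do not match matrix order")
  if (nrow(v) && max(abs(v - t(v))) > 1e-8)
    return("matrix is not symmetric")
  TRUE
})

#' Additive and residual (co)variance components
#'
#' @slot sigmaA t x t additive-genetic covariance matrix.
#' @slot sigmaE t x t residual covariance matrix.
#' @slot traits trait names (row/col labels of both matrices).
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(sigmaA = "matrix", sigmaE = "matrix", traits = "character"))

setValidity("VarianceComponents", function(object) {
  t <- length(object@traits)
  if (!all(dim(object@sigmaA) == t) || !all(dim(object@sigmaE) == t))
    return("covariance matrices must be t x t for t traits")
  for (m in list(object@sigmaA, object@sigmaE)) {
    if (max(abs(m - t(m))) > 1e-8) return("covariance matrix not symmetric")
    if (t && min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-6 * max(1, max(abs(m))))
      return("covariance matrix not positive semi-definite")
  }
  TRUE
})

#' Genotype quality-control result
#'
#' @slot kept the surviving [GenotypeMatrix].
#' @slot removedSnps data.frame (snp, reason, statistic).
#' @slot removedAnimals data.frame (animal, reason, statistic).
#' @slot conflictPairs data.frame (parent, offspring, nConflicts, nCompared).
#' @exportClass QcResult
setClass("QcResult",
  representation(kept = "GenotypeMatrix", removedSnps = "data.frame",
                 removedAnimals = "data.frame", conflictPairs = "data.frame"))

#' Per-trait SNP effects and weight trajectory from a wssGWAS run
#'
#' @slot trait trait name.
#' @slot uhat named numeric vector of back-solved SNP effects.
#' @slot weightHistory markers x (passes + 1) matrix: initial D = I column
#'   followed by the normalized weights computed after each pass.
#' @slot iterations number of solve/back-solve passes performed.
#' @slot gebv named numeric vector: GEBVs of genotyped animals (final pass).
#' @exportClass SnpEffectSet
setClass("SnpEffectSet",
  representation(trait = "character", uhat = "numeric",
                 weightHistory = "matrix", iterations = "integer",
                 gebv = "numeric"))

#' Sliding-window percent-of-genetic-variance scan
#'
#' @slot windows data.frame with one row per (window, trait): columns
#'   `chr`, `startIndex`, `snps` (comma-joined ids), `startBp`, `endBp`,
#'   `midBp`, `trait`, `pctVar`.
#' @slot sigmaATotal named per-trait denominator used (total genetic variance).
#' @slot windowSize window size in markers.
#' @exportClass WindowScan
setClass("WindowScan",
  representation(windows = "data.frame", sigmaATotal = "numeric",
                 windowSize = "integer"))

setValidity("WindowScan", function(object) {
  w <- object@windows
  need <- c("chr", "startIndex", "snps", "startBp", "endBp", "trait", "pctVar")
  if (!all(need %in% names(w))) return("missing window columns")
  if (nrow(w) && any(w$pctVar < -1e-12)) return("pctVar must be non-negative")
  TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  cat(sprintf("Pedigree with %d animals (%d founders)\n", n,
              sum(is.na(object@sire) & is.na(object@dam))))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d animals x %d markers on %d chromosome(s)\n",
              nrow(object@calls), ncol(object@calls),
              length(unique(object@map$chr))))
  mr <- mean(is.na(object@calls))
  cat(sprintf("  missing rate %.3f\n", mr))
})

setMethod("show", "GeneIntervalSet", function(object) {
  cat(sprintf("GeneIntervalSet with %d gene interval(s)\n",
              length(object@ranges)))
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix '%s': %d x %d, mean diagonal %.4f\n",
              object@kind, nrow(object@values), ncol(object@values),
              if (nrow(object@values)) mean(diag(object@values)) else NA_real_))
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents for traits:", paste(object@traits, collapse = ", "),
      "\n  additive:", paste(signif(diag(object@sigmaA), 4), collapse = ", "),
      "\n  residual:", paste(signif(diag(object@sigmaE), 4), collapse = ", "),
      "\n")
})

setMethod("show", "QcResult", function(object) {
  cat(sprintf("QcResult: kept %d animals x %d SNPs; removed %d SNP(s), %d animal(s)\n",
              nrow(object@kept@calls), ncol(object@kept@calls),
              nrow(object@removedSnps), nrow(object@removedAnimals)))
})

setMethod("show", "SnpEffectSet", function(object) {
  cat(sprintf("SnpEffectSet for trait '%s': %d markers, %d pass(es)\n",
              object@trait, length(object@uhat), object@iterations))
})

setMethod("show", "WindowScan", function(object) {
  cat(sprintf("WindowScan: %d window rows (size %d), trait(s): %s\n",
              nrow(object@windows), object@windowSize,
              paste(unique(object@windows$trait), collapse = ", ")))
})
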