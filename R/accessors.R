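# Accessor generics and methods.  Downstream code and user scripts go
# through these rather than reaching into slots.

#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))
#' @export
setGeneric("sireIds", function(x) standardGeneric("sireIds"))
#' @export
setGeneric("damIds", function(x) standardGeneric("damIds"))
#' @export
setGeneric("genoCalls", function(x) standardGeneric("genoCalls"))
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))
#' @export
setGeneric("relIds", function(x) standardGeneric("relIds"))
#' @export
setGeneric("relKind", function(x) standardGeneric("relKind"))
#' @export
setGeneric("relMetadata", function(x) standardGeneric("relMetadata"))
#' @export
setGeneric("sigmaA", function(x) standardGeneric("sigmaA"))
#' @export
setGeneric("sigmaE", function(x) standardGeneric("sigmaE"))
#' @export
setGeneric("sigmaP", function(x) standardGeneric("sigmaP"))
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))
#' @export
setGeneric("keptGenotypes", function(x) standardGeneric("keptGenotypes"))
#' @export
setGeneric("removedSnps", function(x) standardGeneric("removedSnps"))
#' @export
setGeneric("removedAnimals", function(x) standardGeneric("removedAnimals"))
#' @export
setGeneric("conflictPairs", function(x) standardGeneric("conflictPairs"))
#' @export
setGeneric("snpEffects", function(x) standardGeneric("snpEffects"))
#' @export
setGeneric("weightHistory", function(x) standardGeneric("weightHistory"))
#' @export
setGeneric("scanWindows", function(x) standardGeneric("scanWindows"))

#' @describeIn Pedigree-class animal identifiers in pedigree order.
#' @param x object.
#' @export
setMethod("animalIds", "Pedigree", function(x) x@id)
#' @describeIn Pedigree-class sire identifiers (`NA` = unknown).
#' @export
setMethod("sireIds", "Pedigree", function(x) setNames(x@sire, x@id))
#' @describeIn Pedigree-class dam identifiers (`NA` = unknown).
#' @export
setMethod("damIds", "Pedigree", function(x) setNames(x@dam, x@id))
#' @describeIn Pedigree-class number of animals.
#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

#' @export
as.data.frame.Pedigree <- function(x, ...) {
  data.frame(animal = x@id, sire = x@sire, dam = x@dam, sex = x@sex,
             stringsAsFactors = FALSE)
}

#' @describeIn GenotypeMatrix-class animal identifiers (row order of calls).
#' @param x object.
#' @export
setMethod("animalIds", "GenotypeMatrix", function(x) rownames(x@calls))
#' @describeIn GenotypeMatrix-class integer call matrix (0/1/2/NA).
#' @export
setMethod("genoCalls", "GenotypeMatrix", function(x) x@calls)
#' @describeIn GenotypeMatrix-class marker map data.frame (snp, chr, pos).
#' @export
setMethod("markerMap", "GenotypeMatrix", function(x) x@map)

#' Subset a GenotypeMatrix by animals and/or markers
#'
#' @param x a [GenotypeMatrix-class].
#' @param i animal ids or indices.
#' @param j marker ids or indices.
#' @param ... ignored.
#' @param drop ignored (always `FALSE`).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  calls <- x@calls
  map <- x@map
  if (!missing(i)) calls <- calls[i, , drop = FALSE]
  if (!missing(j)) {
    if (is.character(j)) j <- match(j, map$snp)
    calls <- calls[, j, drop = FALSE]
    map <- map[j, , drop = FALSE]
  }
  GenotypeMatrix(calls, map, x@metadata)
})

#' @describeIn GeneIntervalSet-class the underlying `GRanges`.
#' @param x object.
#' @export
setMethod("geneRanges", "GeneIntervalSet", function(x) x@ranges)
#' @describeIn GeneIntervalSet-class number of gene intervals.
#' @export
setMethod("length", "GeneIntervalSet", function(x) length(x@ranges))

#' @export
as.data.frame.GeneIntervalSet <- function(x, ...) {
  gr <- x@ranges
  data.frame(gene = gr$gene, chr = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' @describeIn RelationshipMatrix-class numeric matrix of coefficients.
#' @param x object.
#' @export
setMethod("relValues", "RelationshipMatrix", function(x) x@values)
#' @describeIn RelationshipMatrix-class animal ids labelling the matrix.
#' @export
setMethod("relIds", "RelationshipMatrix", function(x) x@ids)
#' @describeIn RelationshipMatrix-class matrix kind tag.
#' @export
setMethod("relKind", "RelationshipMatrix", function(x) x@kind)
#' @describeIn RelationshipMatrix-class construction metadata list.
#' @export
setMethod("relMetadata", "RelationshipMatrix", function(x) x@metadata)

#' @describeIn VarianceComponents-class additive covariance matrix.
#' @param x object.
#' @export
setMethod("sigmaA", "VarianceComponents", function(x) x@sigmaA)
#' @describeIn VarianceComponents-class residual covariance matrix.
#' @export
setMethod("sigmaE", "VarianceComponents", function(x) x@sigmaE)
#' @describeIn VarianceComponents-class phenotypic covariance (sum).
#' @export
setMethod("sigmaP", "VarianceComponents", function(x) x@sigmaA + x@sigmaE)
#' @describeIn VarianceComponents-class trait names.
#' @export
setMethod("traitNames", "VarianceComponents", function(x) x@traits)

#' @describeIn QcResult-class surviving genotypes.
#' @param x object.
#' @export
setMethod("keptGenotypes", "QcResult", function(x) x@kept)
#' @describeIn QcResult-class removed SNPs with reasons.
#' @export
setMethod("removedSnps", "QcResult", function(x) x@removedSnps)
#' @describeIn QcResult-class removed animals with reasons.
#' @export
setMethod("removedAnimals", "QcResult", function(x) x@removedAnimals)
#' @describeIn QcResult-class per-pair Mendelian-conflict counts.
#' @export
setMethod("conflictPairs", "QcResult", function(x) x@conflictPairs)

#' @describeIn SnpEffectSet-class named vector of back-solved SNP effects.
#' @param x object.
#' @export
setMethod("snpEffects", "SnpEffectSet", function(x) x@uhat)
#' @describeIn SnpEffectSet-class weight trajectory matrix.
#' @export
setMethod("weightHistory", "SnpEffectSet", function(x) x@weightHistory)

#' @describeIn WindowScan-class the per-window data.frame.
#' @param x object.
#' @export
setMethod("scanWindows", "WindowScan", function(x) x@windows)
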