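# Readers and writers for every external representation the pipeline
# touches.  All genomic coordinates are held 1-based inclusive internally;
# BED is converted at the boundary.

#' Read a pedigree CSV
#'
#' Expects a header `animal,sire,dam` (extra columns are ignored, except an
#' optional `sex`).  Unknown parents may be coded `0` or left empty.  The
#' returned pedigree is topologically sorted; duplicate ids and ancestral
#' cycles (including self-parenting) are errors.
#'
#' @param path path to the CSV file.
#' @return A [Pedigree-class].
#' @export
readPedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  stopIf(!all(c("animal", "sire", "dam") %in% names(df)),
         "pedigree file must have columns animal, sire, dam")
  bad <- !is.na(df$sire) & df$sire == df$animal
  stopIf(any(bad), "pedigree contains a cycle: %s -> %s",
         df$animal[bad][1L], df$animal[bad][1L])
  Pedigree(df$animal, df$sire, df$dam, sex = df[["sex"]])
}

#' Write a pedigree CSV
#'
#' @param pedigree a [Pedigree-class].
#' @param path output path; unknown parents written as `0`.
#' @export
writePedigree <- function(pedigree, path) {
  df <- as.data.frame(pedigree)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read SNP genotypes (PLINK PED/MAP or coded matrix TSV)
#'
#' For `format = "ped-map"`, `path` is the PED file and `mapPath` the MAP
#' file; allele pairs are recoded to counts of the *second* allele, fixed as
#' the lexicographically larger allele observed at each locus.  `0` denotes
#' a missing allele.  A locus with more than two alleles is an error.
#'
#' For `format = "matrix-tsv"`, `path` is a TSV whose first column holds
#' animal ids and remaining columns (named by SNP id) hold 0/1/2/NA codes;
#' `mapPath` is a TSV with columns `snp`, `chr`, `pos`.
#'
#' @param path genotype file.
#' @param format `"ped-map"` or `"matrix-tsv"`.
#' @param mapPath companion marker-map file.
#' @return A [GenotypeMatrix-class] with markers sorted by (chr, pos).
#' @export
readGenotypes <- function(path, format = c("matrix-tsv", "ped-map"),
                          mapPath) {
  format <- match.arg(format)
  map <- utils::read.table(mapPath, header = (format == "matrix-tsv"),
                           stringsAsFactors = FALSE)
  if (format == "ped-map") {
    names(map) <- c("chr", "snp", "cm", "pos")[seq_len(ncol(map))]
    map <- map[, c("snp", "chr", "pos")]
    ped <- utils::read.table(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    m <- nrow(map)
    stopIf(ncol(ped) != 6 + 2 * m,
           "PED has %d allele columns but MAP lists %d markers",
           ncol(ped) - 6, m)
    ids <- ped[[2L]]
    calls <- matrix(NA_integer_, nrow(ped), m)
    for (j in seq_len(m)) {
      a1 <- ped[[6 + 2 * j - 1]]
      a2 <- ped[[6 + 2 * j]]
      alleles <- sort(unique(c(a1, a2)))
      alleles <- alleles[alleles != "0"]
      stopIf(length(alleles) > 2,
             "marker '%s' is not biallelic (alleles %s)",
             map$snp[j], paste(alleles, collapse = ","))
      counted <- if (length(alleles)) alleles[length(alleles)] else NA
      ok <- a1 != "0" & a2 != "0"
      calls[ok, j] <- (a1[ok] == counted) + (a2[ok] == counted)
    }
    rownames(calls) <- ids
    colnames(calls) <- map$snp
    meta <- list(coding = "count of lexicographically larger observed allele")
    return(GenotypeMatrix(calls, map, meta))
  }
  stopIf(!all(c("snp", "chr", "pos") %in% names(map)),
         "map file must have columns snp, chr, pos")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1L]])
  calls <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(calls) <- "integer"
  rownames(calls) <- ids
  stopIf(ncol(calls) != nrow(map),
         "matrix has %d markers but map lists %d", ncol(calls), nrow(map))
  calls <- calls[, map$snp, drop = FALSE]
  GenotypeMatrix(calls, map, list(coding = "second-allele counts as given"))
}

#' Write a GenotypeMatrix as matrix TSV + map TSV
#'
#' Round-trips exactly through [readGenotypes()] with `format="matrix-tsv"`.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param path,mapPath output paths for the call matrix and the marker map.
#' @export
writeGenotypes <- function(genotypes, path, mapPath) {
  calls <- genoCalls(genotypes)
  df <- data.frame(animal = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(markerMap(genotypes), mapPath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene intervals from BED or GFF3
#'
#' Import goes through `rtracklayer::import()`, so coordinates arrive
#' 1-based inclusive regardless of the source dialect (the 0-based
#' half-open BED starts are shifted by +1 on ingest).  Gene symbols are
#' taken from the BED name column, or from the `Name`/`gene_name`/`ID`
#' attribute of GFF3 `gene` features.
#'
#' @param path annotation file.
#' @param format `"bed"` or `"gff3"`; default guesses from the extension.
#' @return A [GeneIntervalSet-class].
#' @export
readGeneAnnotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
              else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3"
                                           else "bed")
  if (format == "gff3") {
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    gene <- gr$Name
    if (is.null(gene)) gene <- gr$gene_name
    if (is.null(gene)) gene <- gr$ID
    stopIf(is.null(gene), "GFF3 features carry no Name/gene_name/ID attribute")
    gene[is.na(gene)] <- gr$ID[is.na(gene)]
  } else {
    gene <- gr$name
    stopIf(is.null(gene), "BED file has no name column")
  }
  GeneIntervalSet(data.frame(gene = as.character(gene),
                             chr = as.character(GenomicRanges::seqnames(gr)),
                             start = GenomicRanges::start(gr),
                             end = GenomicRanges::end(gr),
                             stringsAsFactors = FALSE))
}

#' Write the candidate-region table
#'
#' Seven tab-separated columns per annotated SNP: trait, chromosome, SNP
#' position, SNP id, gene location (either a `start-end` span for
#' within-gene hits or a `<kb> kb upstream/downstream gene` label for
#' flanking hits), candidate gene, and percent of genetic variance printed
#' with two decimals.
#'
#' @param regions data.frame as returned by [annotateRegions()].
#' @param path output TSV path.
#' @export
writeRegionTable <- function(regions, path) {
  cols <- c("trait", "chr", "snpPos", "snpId", "geneLocation", "gene",
            "pctVar")
  header <- c("Trait", "Chr", "SNP position", "SNP ID", "Gene location (bp)",
              "Candidate gene", "Pct var")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (is.null(regions) || nrow(regions) == 0) return(invisible(path))
  stopIf(!all(cols %in% names(regions)),
         "regions must have columns %s", paste(cols, collapse = ", "))
  out <- regions[, cols]
  out$pctVar <- sprintf("%.2f", out$pctVar)
  utils::write.table(out, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a window scan as TSV (one row per window per trait)
#'
#' Columns: chr, startBp, endBp, midBp, snps, trait, pctVar — directly
#' plottable as a Manhattan profile of percent genetic variance.
#'
#' @param scan a [WindowScan-class].
#' @param path output TSV path.
#' @export
writeWindowScan <- function(scan, path) {
  utils::write.table(scanWindows(scan), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
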