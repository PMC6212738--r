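# User-facing constructors.  They normalize inputs (topological order,
# marker sorting, coordinate dialects) so downstream code can rely on the
# class invariants.

#' Build a Pedigree, sorting parents before offspring
#'
#' Records may arrive in any order; they are topologically sorted so that
#' every sire/dam precedes its offspring.  Unknown parents are coded `NA`
#' (the readers also accept `"0"` and `""`).
#'
#' @param id,sire,dam character vectors of equal length.
#' @param sex optional character vector ("M"/"F") used by the simulator.
#' @return A [Pedigree-class] object.
#' @export
Pedigree <- function(id, sire, dam, sex = NULL) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  unk <- function(x) { x[!is.na(x) & (x == "0" | x == "")] <- NA; x }
  sire <- unk(sire); dam <- unk(dam)
  stopIf(anyDuplicated(id) > 0, "duplicate animal id '%s'",
         id[duplicated(id)][1L])
  bad <- !is.na(sire) & !(sire %in% id)
  stopIf(any(bad), "sire '%s' has no pedigree record", sire[bad][1L])
  bad <- !is.na(dam) & !(dam %in% id)
  stopIf(any(bad), "dam '%s' has no pedigree record", dam[bad][1L])
  if (is.null(sex)) sex <- rep(NA_character_, length(id))

  ord <- topoOrderPedigree(id, sire, dam)
  new("Pedigree", id = id[ord], sire = sire[ord], dam = dam[ord],
      sex = as.character(sex)[ord])
}

# Kahn's algorithm; on failure reports one cycle found by following parent
# links from an unplaced animal.
topoOrderPedigree <- function(id, sire, dam) {
  n <- length(id)
  pos <- seq_len(n); names(pos) <- id
  si <- ifelse(is.na(sire), 0L, pos[sire])
  di <- ifelse(is.na(dam), 0L, pos[dam])
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed & (si == 0L | placed[pmax(si, 1L)]) &
                             (di == 0L | placed[pmax(di, 1L)]))
    if (!length(ready)) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    cur <- which(!placed)[1L]
    seen <- integer(0)
    while (!(cur %in% seen)) {
      seen <- c(seen, cur)
      nxt <- c(si[cur], di[cur])
      nxt <- nxt[nxt > 0L & !placed[nxt]]
      cur <- nxt[1L]
    }
    cyc <- seen[which(seen == cur)[1L]:length(seen)]
    stop("pedigree contains a cycle: ",
         paste(id[c(cyc, cyc[1L])], collapse = " -> "), call. = FALSE)
  }
  ord
}

#' Build a GenotypeMatrix from coded calls and a marker map
#'
#' @param calls animals x markers matrix of 0/1/2/`NA` second-allele counts;
#'   rownames are animal ids, colnames SNP ids (taken from `map$snp` if
#'   absent).
#' @param map data.frame with columns `snp`, `chr`, `pos` (1-based bp).
#' @param metadata optional list of provenance notes.
#' @return A [GenotypeMatrix-class]; markers sorted by (chromosome, position).
#' @export
GenotypeMatrix <- function(calls, map, metadata = list()) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  map <- as.data.frame(map)
  stopIf(!all(c("snp", "chr", "pos") %in% names(map)),
         "map must have columns snp, chr, pos")
  map$snp <- as.character(map$snp); map$chr <- as.character(map$chr)
  map$pos <- as.integer(map$pos)
  stopIf(ncol(calls) != nrow(map),
         "map has %d markers but calls have %d columns", nrow(map), ncol(calls))
  if (is.null(colnames(calls))) colnames(calls) <- map$snp
  o <- orderMarkers(map$chr, map$pos)
  map <- map[o, , drop = FALSE]
  rownames(map) <- NULL
  calls <- calls[, o, drop = FALSE]
  colnames(calls) <- map$snp
  new("GenotypeMatrix", calls = calls, map = map, metadata = metadata)
}

#' Build a GeneIntervalSet from 1-based inclusive intervals
#'
#' @param gene,chr,start,end vectors of equal length, or a single data.frame
#'   in `gene` with those columns.
#' @return A [GeneIntervalSet-class].
#' @export
GeneIntervalSet <- function(gene, chr = NULL, start = NULL, end = NULL) {
  if (is.data.frame(gene)) {
    df <- gene
    gene <- df$gene; chr <- df$chr; start <- df$start; end <- df$end
  }
  stopIf(any(start > end), "gene '%s' has start > end",
         as.character(gene)[which(start > end)[1L]])
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chr),
    ranges = IRanges::IRanges(start = as.integer(start), end = as.integer(end)))
  gr$gene <- as.character(gene)
  new("GeneIntervalSet", ranges = gr)
}

#' Build a VarianceComponents object
#'
#' Scalars are accepted for single-trait models.
#'
#' @param sigmaA,sigmaE additive and residual covariance matrices (t x t).
#' @param traits trait names.
#' @return A [VarianceComponents-class].
#' @export
VarianceComponents <- function(sigmaA, sigmaE, traits = NULL) {
  sigmaA <- as.matrix(sigmaA); sigmaE <- as.matrix(sigmaE)
  if (is.null(traits))
    traits <- rownames(sigmaA) %||% paste0("trait", seq_len(nrow(sigmaA)))
  dimnames(sigmaA) <- dimnames(sigmaE) <- list(traits, traits)
  new("VarianceComponents", sigmaA = sigmaA, sigmaE = sigmaE,
      traits = as.character(traits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

relationshipMatrix <- function(values, ids, kind, metadata = list()) {
  dimnames(values) <- list(ids, ids)
  new("RelationshipMatrix", ids = as.character(ids), values = values,
      kind = kind, metadata = metadata)
}
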