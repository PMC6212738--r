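# Candidate-gene annotation of selected SNPs/regions against a local gene
# interval set: within-gene lookup first, then the nearest gene within a
# 2.0 Mb flanking window.  "Upstream" means the SNP lies before the gene
# start in chromosome coordinates, "downstream" after its end — a fixed
# coordinate convention, ignoring strand.

#' Annotate selected SNPs with candidate genes
#'
#' For each SNP: if the position falls inside a gene interval the relation
#' is `within-gene` (distance 0); otherwise the nearest gene on the same
#' chromosome within `flankBp` (distance = SNP to the nearer gene
#' boundary, ties broken by smaller gene start) gives `upstream` /
#' `downstream`; beyond `flankBp` the relation is `none`.  The formatted
#' `geneLocation` column carries the gene span (`start-end`) for
#' within-gene hits and a `"<kb> kb upstream/downstream gene"` label
#' (distance truncated to two decimals) for flanking hits.
#'
#' @param regions data.frame with one row per SNP to annotate: columns
#'   `trait`, `chr`, `snpPos`, `snpId`, `pctVar`.
#' @param genes a [GeneIntervalSet-class] in the same assembly coordinates
#'   (caller's responsibility; a note is emitted, not enforced).
#' @param flankBp flanking limit in bp (default 2,000,000).  `flankBp = 0`
#'   reduces the rule to pure interval membership.
#' @return `regions` with added columns `relation` (`within-gene`,
#'   `upstream`, `downstream`, `none`), `distanceBp`, `gene`,
#'   `geneLocation`.
#' @export
annotateRegions <- function(regions, genes, flankBp = 2e6) {
  gdf <- as.data.frame(genes)
  n <- nrow(regions)
  relation <- character(n); distance <- numeric(n)
  gene <- character(n); location <- character(n)
  for (i in seq_len(n)) {
    pos <- regions$snpPos[i]
    g <- gdf[gdf$chr == as.character(regions$chr[i]), , drop = FALSE]
    relation[i] <- "none"; distance[i] <- NA_real_
    gene[i] <- ""; location[i] <- ""
    if (!nrow(g)) next
    inside <- g$start <= pos & pos <= g$end
    if (any(inside)) {
      hit <- g[inside, , drop = FALSE]
      hit <- hit[order(hit$start), , drop = FALSE][1L, ]
      relation[i] <- "within-gene"; distance[i] <- 0
      gene[i] <- hit$gene
      location[i] <- paste0(fmtBp(hit$start), "-", fmtBp(hit$end))
      next
    }
    d <- ifelse(pos < g$start, g$start - pos, pos - g$end)
    ord <- order(d, g$start)
    best <- ord[1L]
    if (d[best] <= flankBp) {
      relation[i] <- if (pos < g$start[best]) "upstream" else "downstream"
      distance[i] <- d[best]
      gene[i] <- g$gene[best]
      location[i] <- paste(kbLabel(d[best]), relation[i], "gene")
    } else {
      distance[i] <- d[best]
    }
  }
  cbind(regions,
        data.frame(relation = relation, distanceBp = distance, gene = gene,
                   geneLocation = location, stringsAsFactors = FALSE))
}

#' Summarize candidate genes across traits
#'
#' One row per (dataset, chromosome, gene) hit by at least one trait's
#' selected regions, with the hitting traits listed in the fixed order
#' PWL, BAL, W2CL, LSY, PWSY, NPD (unknown traits appended in first-seen
#' order); a gene hit by all six reproduction traits is labelled
#' `"Six traits"`.
#'
#' @param annotations data.frame from [annotateRegions()] (possibly several
#'   traits concatenated); rows with empty `gene` are ignored.
#' @param dataset optional label (e.g. breed) for the first column.
#' @return data.frame with columns `dataset`, `chr`, `gene`, `location`,
#'   `traits`.
#' @export
summarizeCandidates <- function(annotations, dataset = "") {
  ann <- annotations[!is.na(annotations$gene) & annotations$gene != "", ,
                     drop = FALSE]
  if (!nrow(ann))
    return(data.frame(dataset = character(0), chr = character(0),
                      gene = character(0), location = character(0),
                      traits = character(0)))
  canonical <- c("PWL", "BAL", "W2CL", "LSY", "PWSY", "NPD")
  keys <- unique(ann[, c("chr", "gene")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- ann[ann$chr == keys$chr[k] & ann$gene == keys$gene[k], ,
               drop = FALSE]
    trs <- unique(as.character(sub$trait))
    ordered <- c(intersect(canonical, trs), setdiff(trs, canonical))
    lab <- if (setequal(ordered, canonical)) "Six traits"
           else paste(ordered, collapse = ", ")
    within <- sub[sub$relation == "within-gene", , drop = FALSE]
    loc <- if (nrow(within)) within$geneLocation[1L]
           else sub$geneLocation[1L]
    data.frame(dataset = dataset, chr = keys$chr[k], gene = keys$gene[k],
               location = loc, traits = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$chr, out$gene), , drop = FALSE]
}
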