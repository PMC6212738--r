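# The iterative weighted single-step GWAS: GEBV-to-SNP-effect
# back-solving, SNP variance-weight updates, the solve/back-solve loop,
# 5-SNP sliding-window percent-of-genetic-variance scoring, and region
# selection.

#' Back-solve genotyped-animal GEBVs into SNP effects
#'
#' `u_hat = q D Z' G^-1 a_g` with G the exact unblended `Z D Z' q` of the
#' current iteration (blending is a numerical device for the MME, not part
#' of the SNP-effect map).  With that G, `Z u_hat` reconstructs `a_g`
#' exactly.
#'
#' @param ag named GEBV vector of the genotyped animals (matching Z rows).
#' @param z centered genotypes from [centerGenotypes()].
#' @param d per-marker weights used to build G.
#' @param g the G [RelationshipMatrix-class] from [buildG()] (its metadata
#'   supplies the unblended matrix and scaling), or a plain unblended
#'   matrix if `scalingC` is given.
#' @param scalingC effective scalar c with `G = c Z D Z'` (only when `g`
#'   is a plain matrix).
#' @param ridge added to G's diagonal only if it is numerically singular.
#' @return named vector of SNP effects.
#' @export
backsolveSnpEffects <- function(ag, z, d = NULL, g, scalingC = NULL,
                                ridge = 0) {
  Z <- z$z
  m <- ncol(Z)
  if (is.null(d)) d <- rep(1, m)
  if (is(g, "RelationshipMatrix")) {
    md <- relMetadata(g)
    G <- md$unblended %||% relValues(g)
    scalingC <- scalingC %||% md$scalingC
  } else G <- g
  stopIf(is.null(scalingC), "scalingC required when g is a plain matrix")
  stopIf(nrow(G) != nrow(Z), "G and Z disagree on the number of animals")
  sol <- if (ridge > 0) {
    tryCatch(solve(G + diag(ridge, nrow(G)), ag), error = function(e) NULL)
  } else {
    tryCatch(symSolve(G, ag), error = function(e) NULL)
  }
  if (is.null(sol))
    stop("G is singular: exact back-solving is incompatible with blending; ",
         "retry with ridge = 1e-8", call. = FALSE)
  setNames(as.numeric(scalingC * d * crossprod(Z, sol)), colnames(Z))
}

#' Update SNP variance weights from back-solved effects
#'
#' Raw weight `d_i = u_hat_i^2 2 p_i (1 - p_i)`, then normalized so the
#' weights sum to the marker count (total variance, tr(D), is conserved
#' across iterations).
#'
#' @param uhat SNP effects.
#' @param p second-allele frequencies (same length).
#' @return normalized weight vector summing to `length(uhat)`.
#' @export
updateWeights <- function(uhat, p) {
  stopIf(length(uhat) != length(p), "uhat and p lengths differ")
  raw <- uhat^2 * 2 * p * (1 - p)
  stopIf(all(raw == 0), "all raw SNP weights are zero: nothing to reweight")
  raw * length(raw) / sum(raw)
}

#' Run the iterative weighted single-step GWAS
#'
#' Per trait: start from D = I, build G (tuned/blended for the MME), solve
#' the (multi-trait) mixed-model equations under H-inverse, back-solve the
#' trait's genotyped GEBVs into SNP effects through the unblended G, update
#' the weights, rebuild G, and repeat.  `nIterations` counts the
#' solve/back-solve passes (the default 2 reweights once between passes);
#' `nIterations = 0` performs the single classical unweighted pass.
#' Variance components stay fixed across iterations.
#'
#' @param genotypes post-QC [GenotypeMatrix-class] of the genotyped panel.
#' @param pedigree a [Pedigree-class] containing all phenotyped and
#'   genotyped animals.
#' @param phenotypes per-animal data.frame (id column `animal`, trait and
#'   fixed-effect columns).
#' @param traitCols,fixedCols columns defining the model.
#' @param varcomp a [VarianceComponents-class] for `traitCols`.
#' @param nIterations solve/back-solve passes (default 2).
#' @param tuneDiagonal,blendTau G construction options (see [buildG()]).
#' @param p allele frequencies used for centering; default: computed from
#'   the panel itself.  Note that panel-internal frequencies make the
#'   centered columns sum to exactly zero, so the unblended G is singular
#'   (rank n - 1) and back-solving goes through a 1e-8 ridge; frequencies
#'   from a wider reference population (e.g. all genotyped candidates
#'   before subsetting) keep the unblended G invertible and the
#'   reconstruction `Z u_hat = a_g` exact.
#' @return named list (one [SnpEffectSet-class] per trait); attributes
#'   `"p"` (allele frequencies) and `"z"` (centered genotypes) for window
#'   scoring.
#' @export
runSsgwas <- function(genotypes, pedigree, phenotypes, traitCols,
                      fixedCols = character(0), varcomp, nIterations = 2,
                      tuneDiagonal = TRUE, blendTau = 0.05, p = NULL) {
  passes <- max(1L, as.integer(nIterations))
  if (is.null(p)) p <- alleleFrequencies(genotypes)
  z <- centerGenotypes(genotypes, p)
  gids <- animalIds(genotypes)
  m <- length(p)

  aInv <- aInverse(pedigree)
  a22 <- subsetA22(pedigree, gids)
  design <- buildDesign(phenotypes, traitCols, fixedCols,
                        relationshipIds = animalIds(pedigree))

  out <- list()
  for (tr in traitCols) {
    d <- rep(1, m)
    hist <- matrix(d, m, 1, dimnames = list(names(p), NULL))
    uhat <- NULL; ag <- NULL
    for (pass in seq_len(passes)) {
      G <- buildG(z, d, a22 = a22$a22, tuneDiagonal = tuneDiagonal,
                  blendTau = blendTau)
      Ginv <- invertRelationship(G)
      Hinv <- buildHInverse(aInv, a22$a22Inv, Ginv)
      fit <- solveMME(design, Hinv, varcomp)
      ag <- fit$u[gids, tr]
      uhat <- backsolveSnpEffects(ag, z, d, G,
                                  ridge = if (blendTau > 0) 1e-8 else 0)
      d <- updateWeights(uhat, p)
      hist <- cbind(hist, d)
    }
    out[[tr]] <- new("SnpEffectSet", trait = tr, uhat = uhat,
                     weightHistory = hist, iterations = passes,
                     gebv = ag)
  }
  attr(out, "p") <- p
  attr(out, "z") <- z
  out
}

#' Sliding-window percent of genetic variance
#'
#' For every run of `windowSize` consecutive markers on a chromosome
#' (stride 1), the window genetic value per genotyped animal is
#' `a_i = sum_j z_j u_hat_j` over the window, and the window score is
#' `100 * Var(a_i) / sigma_a^2`.  Windows never span chromosome
#' boundaries; a chromosome with fewer markers than the window contributes
#' none.
#'
#' @param z centered genotypes ([centerGenotypes()]) of the panel.
#' @param uhat SNP effects (one trait), or a named list of
#'   [SnpEffectSet-class] as from [runSsgwas()].
#' @param sigmaATotal per-trait total genetic variance used as denominator
#'   (named vector when `uhat` is a list).  Use `"empirical"` to divide by
#'   `Var(Z u_hat)` of each trait instead.
#' @param map marker map (snp, chr, pos) aligned with `z` columns.
#' @param windowSize markers per window (default 5).
#' @return A [WindowScan-class].
#' @export
windowVariance <- function(z, uhat, sigmaATotal, map, windowSize = 5L) {
  stopIf(windowSize < 1, "windowSize must be >= 1")
  effList <- if (is.list(uhat))
    lapply(uhat, snpEffects) else list(trait = uhat)
  Z <- z$z
  empirical <- identical(sigmaATotal, "empirical")
  rows <- list()
  denoms <- numeric(0)
  for (tr in names(effList)) {
    u <- effList[[tr]]
    denom <- if (empirical) stats::var(as.numeric(Z %*% u))
             else if (length(sigmaATotal) > 1) sigmaATotal[[tr]]
             else as.numeric(sigmaATotal)
    denoms[tr] <- denom
    for (cc in unique(map$chr)) {
      idx <- which(map$chr == cc)
      mc <- length(idx)
      if (mc < windowSize) {
        message("chromosome ", cc, " has ", mc, " marker(s) < window size ",
                windowSize, "; no windows")
        next
      }
      nw <- mc - windowSize + 1L
      # cumulative trick: window value per animal via difference of cumsums
      contrib <- Z[, idx, drop = FALSE] *
                 rep(u[idx], each = nrow(Z))
      cs <- cbind(0, t(apply(contrib, 1L, cumsum)))
      starts <- seq_len(nw)
      pct <- vapply(starts, function(s) {
        a <- cs[, s + windowSize] - cs[, s]
        100 * stats::var(a) / denom
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        chr = cc, startIndex = starts,
        snps = vapply(starts, function(s)
          paste(map$snp[idx[s:(s + windowSize - 1L)]], collapse = ","),
          character(1)),
        startBp = map$pos[idx[starts]],
        endBp = map$pos[idx[starts + windowSize - 1L]],
        midBp = (map$pos[idx[starts]] +
                 map$pos[idx[starts + windowSize - 1L]]) %/% 2L,
        trait = tr, pctVar = pct, stringsAsFactors = FALSE)
    }
  }
  w <- if (length(rows)) do.call(rbind, rows)
       else data.frame(chr = character(0), startIndex = integer(0),
                       snps = character(0), startBp = integer(0),
                       endBp = integer(0), midBp = integer(0),
                       trait = character(0), pctVar = numeric(0))
  new("WindowScan", windows = w, sigmaATotal = denoms,
      windowSize = as.integer(windowSize))
}

#' Select and merge windows above the percent-variance threshold
#'
#' Windows with `pctVar >= thresholdPct` are retained per trait;
#' overlapping retained windows on the same chromosome are merged into
#' regions spanning their union, reporting the maximum window percentage
#' and the union of SNP ids.
#'
#' @param scan a [WindowScan-class].
#' @param thresholdPct selection threshold (default 1.0, i.e. at least 1
#'   percent of genetic variance).
#' @return data.frame with one row per merged region: `trait`, `chr`,
#'   `startBp`, `endBp`, `snps`, `nWindows`, `pctVar` (max).
#' @export
selectRegions <- function(scan, thresholdPct = 1.0) {
  w <- scanWindows(scan)
  ws <- scan@windowSize
  sel <- w[w$pctVar >= thresholdPct, , drop = FALSE]
  if (!nrow(sel))
    return(data.frame(trait = character(0), chr = character(0),
                      startBp = integer(0), endBp = integer(0),
                      snps = character(0), nWindows = integer(0),
                      pctVar = numeric(0)))
  out <- list()
  for (key in unique(paste(sel$trait, sel$chr, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1L]]
    s <- sel[sel$trait == parts[1L] & sel$chr == parts[2L], , drop = FALSE]
    s <- s[order(s$startIndex), , drop = FALSE]
    grp <- cumsum(c(1L, diff(s$startIndex) > ws - 1L))
    for (g in unique(grp)) {
      b <- s[grp == g, , drop = FALSE]
      snps <- unique(unlist(strsplit(b$snps, ",")))
      out[[length(out) + 1L]] <- data.frame(
        trait = parts[1L], chr = parts[2L], startBp = min(b$startBp),
        endBp = max(b$endBp), snps = paste(snps, collapse = ","),
        nWindows = nrow(b), pctVar = max(b$pctVar),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
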