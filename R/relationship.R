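# Pedigree and genomic relationship matrices: A (tabular method with
# inbreeding), A-inverse (Henderson rules with Meuwissen-Luo inbreeding),
# A22 and its dense inverse, the weighted genomic matrix G = ZDZ'q, and
# the single-step H-inverse assembly.

#' Pedigree numerator relationship matrix A
#'
#' Tabular (recursive) method with inbreeding: `a_ii = 1 + 0.5 a(sire,dam)`
#' and `a_ij = 0.5 (a_i,sire(j) + a_i,dam(j))`; unknown parents contribute
#' zero.
#'
#' @param pedigree a topologically ordered [Pedigree-class].
#' @return A [RelationshipMatrix-class] of kind `"A"`.
#' @export
numeratorRelationship <- function(pedigree) {
  ids <- animalIds(pedigree)
  n <- length(ids)
  pos <- setNames(seq_len(n), ids)
  si <- ifelse(is.na(pedigree@sire), 0L, pos[pedigree@sire])
  di <- ifelse(is.na(pedigree@dam), 0L, pos[pedigree@dam])
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    A[j, j] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    if (j > 1L) {
      i <- seq_len(j - 1L)
      v <- numeric(j - 1L)
      if (s > 0L) v <- v + A[i, s]
      if (d > 0L) v <- v + A[i, d]
      v <- 0.5 * v
      A[i, j] <- v
      A[j, i] <- v
    }
  }
  relationshipMatrix(A, ids, "A")
}

# Meuwissen & Luo (1992): inbreeding coefficients and within-family
# (mendelian sampling) variances without forming dense A.
# Returns list(F, Dvec) where a_ii = 1 + F_i and D_i is the diagonal of the
# LDL' decomposition of A.
inbreedingML <- function(si, di) {
  n <- length(si)
  F <- numeric(n)
  Dv <- numeric(n)
  L <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    Dv[i] <- if (s > 0L && d > 0L) 0.5 - 0.25 * (F[s] + F[d])
             else if (s > 0L) 0.75 - 0.25 * F[s]
             else if (d > 0L) 0.75 - 0.25 * F[d]
             else 1
    # a_ii by tracing ancestors, youngest first
    L[i] <- 1
    anc <- i
    aii <- 0
    while (length(anc)) {
      j <- max(anc)
      anc <- anc[anc != j]
      lj <- L[j]
      if (si[j] > 0L) { L[si[j]] <- L[si[j]] + 0.5 * lj; anc <- union(anc, si[j]) }
      if (di[j] > 0L) { L[di[j]] <- L[di[j]] + 0.5 * lj; anc <- union(anc, di[j]) }
      aii <- aii + lj * lj * Dv[j]
      L[j] <- 0
    }
    F[i] <- aii - 1
  }
  list(F = F, Dvec = Dv)
}

#' Inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding accounted for via the Meuwissen-Luo
#' recursion for mendelian-sampling variances; the dense A is never formed.
#'
#' @param pedigree a [Pedigree-class].
#' @return A [RelationshipMatrix-class] of kind `"Ainv"`; metadata carries
#'   the per-animal inbreeding coefficients `F`.
#' @export
aInverse <- function(pedigree) {
  ids <- animalIds(pedigree)
  n <- length(ids)
  pos <- setNames(seq_len(n), ids)
  si <- ifelse(is.na(pedigree@sire), 0L, pos[pedigree@sire])
  di <- ifelse(is.na(pedigree@dam), 0L, pos[pedigree@dam])
  ml <- inbreedingML(si, di)
  Ai <- matrix(0, n, n)
  for (i in seq_len(n)) {
    a <- 1 / ml$Dvec[i]
    s <- si[i]; d <- di[i]
    Ai[i, i] <- Ai[i, i] + a
    for (p in c(s, d)[c(s, d) > 0L]) {
      Ai[i, p] <- Ai[i, p] - a / 2
      Ai[p, i] <- Ai[p, i] - a / 2
    }
    if (s > 0L) Ai[s, s] <- Ai[s, s] + a / 4
    if (d > 0L) Ai[d, d] <- Ai[d, d] + a / 4
    if (s > 0L && d > 0L) {
      Ai[s, d] <- Ai[s, d] + a / 4
      Ai[d, s] <- Ai[d, s] + a / 4
    }
  }
  relationshipMatrix(Ai, ids, "Ainv", metadata = list(F = setNames(ml$F, ids)))
}

#' Pedigree relationship among genotyped animals (A22) and its inverse
#'
#' A22 is the genotyped-animal submatrix of A; its inverse is computed from
#' the dense A22 directly (subsetting A-inverse would be wrong).
#'
#' @param x a [Pedigree-class] or a precomputed A [RelationshipMatrix-class].
#' @param genotypedIds animal ids of the genotyped subset.
#' @return list with elements `a22` and `a22Inv` ([RelationshipMatrix-class]).
#' @export
subsetA22 <- function(x, genotypedIds) {
  A <- if (is(x, "Pedigree")) numeratorRelationship(x) else x
  stopIf(!is(A, "RelationshipMatrix") || relKind(A) != "A",
         "x must be a Pedigree or an A RelationshipMatrix")
  idx <- match(genotypedIds, relIds(A))
  stopIf(anyNA(idx), "animal '%s' not in the pedigree",
         genotypedIds[which(is.na(idx))[1L]])
  a22 <- relValues(A)[idx, idx, drop = FALSE]
  a22i <- symSolve(a22)
  list(a22 = relationshipMatrix(a22, genotypedIds, "A22"),
       a22Inv = relationshipMatrix((a22i + t(a22i)) / 2, genotypedIds,
                                   "A22inv"))
}

#' Center genotype codes by twice the allele frequency
#'
#' `z_ij = code_ij - 2 p_j`; missing codes are mean-imputed as `2 p_j`
#' (centered value 0).
#'
#' @param genotypes a [GenotypeMatrix-class] (post-QC).
#' @param p per-marker second-allele frequencies, as from
#'   [alleleFrequencies()] of the same matrix.
#' @return list with `z` (animals x markers numeric matrix) and `p`.
#' @export
centerGenotypes <- function(genotypes, p = alleleFrequencies(genotypes)) {
  calls <- genoCalls(genotypes)
  stopIf(length(p) != ncol(calls),
         "frequency vector length %d does not match %d markers",
         length(p), ncol(calls))
  z <- sweep(calls, 2L, 2 * p)
  z[is.na(z)] <- 0
  list(z = z, p = as.numeric(p))
}

#' Weighted genomic relationship matrix G = ZDZ'q
#'
#' Two-stage scaling: the base matrix is `G0 = Z D Z' / sum_j d_j 2 p_j
#' (1 - p_j)`, then (optionally) a multiplier `q` matches the average
#' diagonal of G to that of A22.  An optional blend
#' `G <- (1 - tau) G + tau A22` guarantees invertibility; the unblended
#' matrix and the effective scaling constant are kept in the metadata
#' because exact back-solving of SNP effects needs them.
#'
#' @param z centered genotypes, as from [centerGenotypes()].
#' @param d per-marker non-negative weights (diagonal of D); default all 1.
#' @param a22 A22 [RelationshipMatrix-class] (needed for tuning/blending).
#' @param tuneDiagonal match `mean(diag(G))` to `mean(diag(A22))`.
#' @param blendTau blending proportion with A22 (0 = off).
#' @return A [RelationshipMatrix-class] of kind `"G"`; metadata holds
#'   `scalingC` (the effective scalar c with G_unblended = c ZDZ'),
#'   `q`, `baseDenominator`, `blendTau` and `unblended`.
#' @export
buildG <- function(z, d = NULL, a22 = NULL, tuneDiagonal = TRUE,
                   blendTau = 0.05) {
  Z <- z$z; p <- z$p
  m <- ncol(Z)
  if (is.null(d)) d <- rep(1, m)
  stopIf(length(d) != m, "weight vector length %d does not match %d markers",
         length(d), m)
  stopIf(any(d < 0), "SNP weights must be non-negative")
  denom <- sum(d * 2 * p * (1 - p))
  stopIf(denom <= 0,
         "sum of d_j 2 p_j (1 - p_j) is zero (all markers monomorphic?)")
  G0 <- tcrossprod(Z %*% diag(d, m), Z) / denom
  q <- 1
  if (tuneDiagonal) {
    stopIf(is.null(a22), "diagonal tuning requires a22")
    q <- mean(diag(relValues(a22))) / mean(diag(G0))
  }
  G <- q * G0
  Gun <- G
  if (blendTau > 0) {
    stopIf(is.null(a22), "blending requires a22")
    G <- (1 - blendTau) * G + blendTau * relValues(a22)
  }
  ids <- rownames(Z)
  relationshipMatrix((G + t(G)) / 2, ids, "G",
    metadata = list(scalingC = q / denom, q = q, baseDenominator = denom,
                    blendTau = blendTau, unblended = (Gun + t(Gun)) / 2,
                    d = d, p = p))
}

#' Assemble the single-step H-inverse
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]`, the correction added into the
#' genotyped-animal block of A-inverse.
#'
#' @param aInv A-inverse [RelationshipMatrix-class] over all animals.
#' @param a22Inv A22-inverse over the genotyped subset.
#' @param gInv G-inverse over the genotyped subset (same id order).
#' @return A [RelationshipMatrix-class] of kind `"Hinv"`.
#' @export
buildHInverse <- function(aInv, a22Inv, gInv) {
  ids <- relIds(aInv)
  H <- relValues(aInv)
  gids <- relIds(gInv)
  stopIf(!identical(gids, relIds(a22Inv)),
         "G-inverse and A22-inverse must use the same id order")
  if (length(gids)) {
    idx <- match(gids, ids)
    stopIf(anyNA(idx), "genotyped animal '%s' not in A-inverse",
           gids[which(is.na(idx))[1L]])
    H[idx, idx] <- H[idx, idx] + relValues(gInv) - relValues(a22Inv)
  }
  relationshipMatrix((H + t(H)) / 2, ids, "Hinv")
}

#' Invert a relationship matrix
#'
#' @param x a [RelationshipMatrix-class] (typically G or A22).
#' @return A [RelationshipMatrix-class] of the inverse kind.  A singular G
#'   without blending raises an error advising [buildG()] blending.
#' @export
invertRelationship <- function(x) {
  inv <- tryCatch(symSolve(relValues(x)), error = function(e) NULL)
  if (is.null(inv)) {
    hint <- if (relKind(x) == "G")
      " (G is singular; rebuild with blendTau > 0)" else ""
    stop("relationship matrix is singular", hint, call. = FALSE)
  }
  relationshipMatrix((inv + t(inv)) / 2, relIds(x),
                     paste0(relKind(x), "inv"), metadata = x@metadata)
}
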