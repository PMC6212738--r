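# Henderson mixed-model equations for the (multi-trait) animal model
# y = X b + Z u + e with u ~ N(0, Sigma_a (x) K) and e ~ N(0, Sigma_e (x) I),
# plus EM-REML variance-component estimation and genetic parameters.
#
# Multivariate systems use the trait-Kronecker structure with effects
# stacked trait-by-trait; single-trait systems are the t = 1 special case.

#' Build design (incidence) structures for the animal model
#'
#' Fixed effects are categorical factors one-hot coded with the
#' first-observed level as the (dropped) reference, plus an intercept.
#' The record incidence maps each record to its animal in the relationship
#' id order.
#'
#' @param traits data.frame with one row per record: an `animal` (or `sow`)
#'   id column, the trait columns, and the fixed-effect factor columns.
#' @param traitCols names of the trait columns to analyse.
#' @param fixedCols names of the fixed-effect factor columns (possibly
#'   empty: intercept-only model).
#' @param relationshipIds ordered animal ids of the relationship matrix.
#' @return list with `X` (records x fixed columns), `Zinc` (records x
#'   animals 0/1), `y` (records x traits), `traits`, `fixedLevels`.
#' @export
buildDesign <- function(traits, traitCols, fixedCols = character(0),
                        relationshipIds) {
  idCol <- if ("animal" %in% names(traits)) "animal" else "sow"
  stopIf(!idCol %in% names(traits), "records need an 'animal' or 'sow' column")
  ids <- as.character(traits[[idCol]])
  idx <- match(ids, relationshipIds)
  stopIf(anyNA(idx), "animal '%s' not among the relationship ids",
         ids[which(is.na(idx))[1L]])
  n <- nrow(traits)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fixedLevels <- list()
  for (f in fixedCols) {
    v <- as.character(traits[[f]])
    levs <- unique(v)                     # first-observed level = reference
    fixedLevels[[f]] <- levs
    if (length(levs) > 1) {
      M <- outer(v, levs[-1L], "==") * 1
      colnames(M) <- paste(f, levs[-1L], sep = ":")
      X <- cbind(X, M)
    }
  }
  q <- length(relationshipIds)
  Zinc <- matrix(0, n, q, dimnames = list(NULL, relationshipIds))
  Zinc[cbind(seq_len(n), idx)] <- 1
  y <- as.matrix(traits[, traitCols, drop = FALSE])
  list(X = X, Zinc = Zinc, y = y, traits = traitCols,
       fixedLevels = fixedLevels)
}

# Build the (multivariate) Henderson coefficient matrix and RHS.
# Effects order: fixed blocks by trait, then animal blocks by trait.
mmeSystem <- function(design, Kinv, varcomp) {
  X <- design$X; Z <- design$Zinc; Y <- design$y
  t <- ncol(Y)
  Sa <- sigmaA(varcomp); Se <- sigmaE(varcomp)
  stopIf(nrow(Sa) != t, "variance components are for %d traits, data has %d",
         nrow(Sa), t)
  Einv <- symSolve(Se)
  Sainv <- symSolve(Sa)
  XtX <- crossprod(X); XtZ <- crossprod(X, Z); ZtZ <- crossprod(Z)
  C <- rbind(
    cbind(kronecker(Einv, XtX), kronecker(Einv, XtZ)),
    cbind(kronecker(Einv, t(XtZ)),
          kronecker(Einv, ZtZ) + kronecker(Sainv, Kinv)))
  rhs <- c(as.vector(crossprod(X, Y) %*% Einv),
           as.vector(crossprod(Z, Y) %*% Einv))
  list(C = C, rhs = rhs, p = ncol(X), q = ncol(Z), t = t)
}

#' Solve the mixed-model equations
#'
#' Dense symmetric factorization with a pseudo-inverse fallback for
#' rank-deficient fixed blocks.  GEBVs are returned for every animal in the
#' relationship matrix, phenotyped or not.
#'
#' @param design from [buildDesign()].
#' @param Kinv relationship inverse (numeric matrix or
#'   [RelationshipMatrix-class]), ids matching `design`.
#' @param varcomp a [VarianceComponents-class] (PSD required).
#' @return list with `beta` (fixed-effect estimates, columns = traits),
#'   `u` (animals x traits GEBV matrix) and `residualNorm` (relative MME
#'   residual of the returned solution).
#' @export
solveMME <- function(design, Kinv, varcomp) {
  if (is(Kinv, "RelationshipMatrix")) Kinv <- relValues(Kinv)
  sys <- mmeSystem(design, Kinv, varcomp)
  sol <- symSolve(sys$C, sys$rhs, pseudo = TRUE)
  res <- sqrt(sum((sys$C %*% sol - sys$rhs)^2)) /
         max(1e-300, sqrt(sum(sys$rhs^2)))
  p <- sys$p; q <- sys$q; t <- sys$t
  beta <- matrix(sol[seq_len(p * t)], p, t,
                 dimnames = list(colnames(design$X), design$traits))
  u <- matrix(sol[p * t + seq_len(q * t)], q, t,
              dimnames = list(colnames(design$Zinc), design$traits))
  list(beta = beta, u = u, residualNorm = res)
}

#' EM-REML variance components for the animal model
#'
#' Expectation-maximization REML with the classic Henderson updates:
#' `Sigma_a[s,t] <- (u_s' Kinv u_t + tr(Kinv C^{u_s u_t})) / q` and the
#' symmetrized residual quadratic-form update divided by `n - rank(X)`,
#' iterated until the relative parameter change falls below `tol`.
#' Components are floored at `1e-10` of the phenotypic variance.  When a
#' single trait is analysed and every animal has exactly one record, a
#' structure-exploiting path (one eigendecomposition of `Kinv`, fixed
#' effects absorbed by the Woodbury identity) makes each round O(n p^2).
#'
#' @param design from [buildDesign()]; requires more records than fixed
#'   columns.
#' @param Kinv relationship inverse over the design's animals.
#' @param start starting [VarianceComponents-class]; default: half the
#'   phenotypic (co)variance each.
#' @param tol relative-change convergence tolerance (default 1e-8).
#' @param maxit maximum EM rounds (default 1000).
#' @param computeLogLik record the restricted log-likelihood each round
#'   (adds an O((nt)^3) solve per round on the generic path; default off).
#' @return list with `varcomp` ([VarianceComponents-class]), `converged`,
#'   `iterations`, and `logLik` (trajectory, or `NULL`).
#' @export
emReml <- function(design, Kinv, start = NULL, tol = 1e-8, maxit = 1000,
                   computeLogLik = FALSE) {
  if (is(Kinv, "RelationshipMatrix")) Kinv <- relValues(Kinv)
  Y <- design$y; X <- design$X; Z <- design$Zinc
  n <- nrow(Y); t <- ncol(Y); q <- ncol(Z)
  rX <- qr(X)$rank
  stopIf(n <= ncol(X), "need more records than fixed-effect columns")
  if (is.null(start)) {
    Sp <- stats::cov(Y)
    start <- VarianceComponents(Sp / 2, Sp / 2, design$traits)
  }
  Sa <- sigmaA(start); Se <- sigmaE(start)
  floorAt <- 1e-10 * mean(diag(Sa + Se))

  fast <- t == 1L && n == q && all(Z == diag(n))
  if (fast) {
    eg <- eigen((Kinv + t(Kinv)) / 2, symmetric = TRUE)
    S <- pmax(eg$values, 1e-12)
    U <- eg$vectors
    Xt <- crossprod(U, X)          # q x p
    yt <- as.vector(crossprod(U, Y))
    XtX <- crossprod(X)
    Xy <- crossprod(X, Y)
  } else {
    K <- NULL
  }
  yy <- crossprod(Y)               # t x t of y_s' y_t
  XtYfull <- crossprod(X, Y)
  ZtYfull <- crossprod(Z, Y)

  ll <- if (computeLogLik) numeric(0) else NULL
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxit)) {
    iter <- it
    if (fast) {
      lambda <- Se[1, 1] / Sa[1, 1]
      Dg <- 1 + lambda * S
      M <- symSolve(XtX - crossprod(Xt, Xt / Dg), pseudo = TRUE)
      beta <- M %*% (Xy - crossprod(Xt, yt / Dg))
      alpha <- (yt - Xt %*% beta) / Dg
      u <- U %*% alpha
      # tr(Kinv C^{uu}), with the unscaled-system inverse block
      # Dg^-1 + Dg^-1 Xt M Xt' Dg^-1 rotated back through U
      B <- Xt / Dg
      trBase <- sum(S / Dg)
      trCorr <- sum((B %*% M) * (B * S))
      uKu <- sum(S * alpha^2)
      SaNew <- matrix((uKu + Se[1, 1] * (trBase + trCorr)) / q, 1, 1)
      SeNew <- matrix((yy[1, 1] - sum(beta * Xy) - sum(u * Y)) / (n - rX),
                      1, 1)
    } else {
      sys <- mmeSystem(design, Kinv, VarianceComponents(Sa, Se,
                                                        design$traits))
      Cinv <- symSolve(sys$C, pseudo = TRUE)
      sol <- Cinv %*% sys$rhs
      p <- sys$p
      beta <- matrix(sol[seq_len(p * t)], p, t)
      u <- matrix(sol[p * t + seq_len(q * t)], q, t)
      Cuu <- Cinv[p * t + seq_len(q * t), p * t + seq_len(q * t),
                  drop = FALSE]
      SaNew <- matrix(0, t, t)
      for (s in seq_len(t)) for (r in seq_len(t)) {
        blk <- Cuu[(s - 1) * q + seq_len(q), (r - 1) * q + seq_len(q)]
        SaNew[s, r] <- (crossprod(u[, s], Kinv %*% u[, r]) +
                        sum(Kinv * t(blk))) / q
      }
      SaNew <- (SaNew + t(SaNew)) / 2
      Equad <- yy - crossprod(beta, XtYfull) - crossprod(u, ZtYfull)
      SeNew <- (Equad + t(Equad)) / 2 / (n - rX)
    }
    SaNew <- pmax(SaNew, ifelse(diag(t) == 1, floorAt, -Inf))
    SeNew <- pmax(SeNew, ifelse(diag(t) == 1, floorAt, -Inf))

    if (computeLogLik)
      ll <- c(ll, remlLogLik(design, Kinv, SaNew, SeNew))

    delta <- max(abs(c(SaNew - Sa, SeNew - Se))) /
             max(abs(c(Sa, Se)), floorAt)
    Sa <- SaNew; Se <- SeNew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM-REML did not converge in ", maxit, " rounds", call. = FALSE)
  list(varcomp = VarianceComponents(Sa, Se, design$traits),
       converged = converged, iterations = iter, logLik = ll)
}

# Restricted log-likelihood, dense V; intended for modest n in diagnostics.
remlLogLik <- function(design, Kinv, Sa, Se) {
  X <- design$X; Z <- design$Zinc; Y <- design$y
  t <- ncol(Y); n <- nrow(Y)
  K <- symSolve((Kinv + t(Kinv)) / 2)
  ZKZ <- Z %*% K %*% t(Z)
  V <- kronecker(Sa, ZKZ) + kronecker(Se, diag(n))
  Xs <- kronecker(diag(t), X)
  ys <- as.vector(Y)
  chV <- chol((V + t(V)) / 2)
  Vi <- chol2inv(chV)
  XtVi <- crossprod(Xs, Vi)
  XVX <- XtVi %*% Xs
  P <- Vi - t(XtVi) %*% symSolve(XVX, XtVi, pseudo = TRUE)
  -0.5 * (2 * sum(log(diag(chV))) +
          determinant(XVX, logarithm = TRUE)$modulus +
          as.numeric(crossprod(ys, P %*% ys)))
}

#' Heritabilities and genetic/phenotypic correlations
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)` per trait; genetic correlations
#' standardize the additive covariances, phenotypic correlations the
#' summed ones.  A zero-variance trait gets `NaN`-flagged correlations.
#'
#' @param varcomp a [VarianceComponents-class].
#' @return list with `h2` (named vector), `rg` and `rp` (t x t matrices
#'   with unit diagonal).
#' @export
geneticParameters <- function(varcomp) {
  Sa <- sigmaA(varcomp); Sp <- sigmaP(varcomp)
  tn <- traitNames(varcomp)
  h2 <- diag(Sa) / diag(Sp)
  corrOf <- function(M) {
    s <- sqrt(diag(M))
    out <- M / tcrossprod(s)
    out[!is.finite(out)] <- NaN
    diag(out) <- ifelse(diag(M) > 0, 1, NaN)
    dimnames(out) <- list(tn, tn)
    out
  }
  list(h2 = setNames(h2, tn), rg = corrOf(Sa), rp = corrOf(Sp))
}
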