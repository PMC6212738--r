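# Internal helpers shared across modules.

# Deterministic marker order: numeric chromosomes first in numeric order,
# then non-numeric (X, Y, ...) alphabetically; positions ascending within.
orderMarkers <- function(chr, pos) {
  chr <- as.character(chr)
  num <- suppressWarnings(as.numeric(chr))
  order(is.na(num), num, chr, pos)
}

stopIf <- function(cond, fmt, ...) if (cond) stop(sprintf(fmt, ...), call. = FALSE)

# Truncate (not round) a bp distance to a 2-dp kb label, matching the
# convention of published flanking-distance tables (74,579 bp -> "74.57 kb").
kbLabel <- function(bp) sprintf("%.2f kb", floor(bp / 10) / 100)

fmtBp <- function(x) formatC(x, format = "d", big.mark = ",")

# Project a symmetric matrix to the nearest positive semi-definite matrix
# (eigenvalue clipping), preserving symmetry.
nearPSD <- function(m, eps = 1e-8) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps * max(abs(e$values)))
  out <- e$vectors %*% (vals * t(e$vectors))
  (out + t(out)) / 2
}

# Symmetric solve with an informative error and optional pseudo-inverse.
symSolve <- function(m, b = NULL, pseudo = FALSE) {
  res <- tryCatch({
    ch <- chol(m)
    if (is.null(b)) chol2inv(ch) else backsolve(ch, forwardsolve(t(ch), b))
  }, error = function(e) NULL)
  if (is.null(res)) {
    if (!pseudo) stop("matrix is singular or not positive definite",
                      call. = FALSE)
    gi <- MASS::ginv(m)
    res <- if (is.null(b)) gi else gi %*% b
  }
  res
}

# Run code with the RNG seeded, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
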