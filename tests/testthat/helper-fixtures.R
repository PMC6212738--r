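# Shared in-code fixtures for the suite.

trioPedigree <- function() {
  Pedigree(c("sire1", "dam1", "kid1"), c(NA, NA, "sire1"),
           c(NA, NA, "dam1"))
}

# Small GenotypeMatrix from an explicit call matrix (markers on one
# chromosome, evenly spaced).
toyGenotypes <- function(calls, chr = NULL, pos = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("A%d", seq_len(nrow(calls)))
  m <- ncol(calls)
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("S%d", seq_len(m))
  map <- data.frame(snp = colnames(calls),
                    chr = if (is.null(chr)) rep("1", m) else chr,
                    pos = if (is.null(pos)) seq_len(m) * 1000L else pos)
  GenotypeMatrix(calls, map)
}

# Single-trait simulation config with quiet fixed effects.
simpleConfig <- function(seed, ..., sigmaA = matrix(1), sigmaE = matrix(3),
                         farmEffects = c(-0.3, 0.3)) {
  simulationConfig(seed = seed, sigmaA = sigmaA, sigmaE = sigmaE,
                   traits = "y",
                   fixedEffects = list(farm = farmEffects, parity = 0,
                                       farrowMonth = 0, farrowYear = 0),
                   ...)
}

h2Of <- function(varcomp) {
  va <- sigmaA(varcomp)[1, 1]; ve <- sigmaE(varcomp)[1, 1]
  va / (va + ve)
}

# 6 animals x 5 SNPs with engineered violations, brute-forced by hand
# under thresholds (minSnpCallRate 0.75, minMaf 0.15):
#  S1 missing for 3/6 animals (rate 0.50 < 0.75) -> snp_call_rate;
#  S2-S4 each miss only A6 (rate 0.83)           -> survive step 1;
#  A6 then has 1/4 calls (0.25 < 0.9)            -> sample_call_rate;
#  among survivors (A1-A5): S3 has one het -> maf 0.1 < 0.15 -> low_maf;
#  S4 all homozygous 2                           -> monomorphic;
#  S2, S5 stay.
engineeredToy <- function() {
  calls <- rbind(
    A1 = c(NA, 0L, 0L, 2L, 0L),
    A2 = c(NA, 1L, 0L, 2L, 2L),
    A3 = c(NA, 1L, 0L, 2L, 1L),
    A4 = c(1L, 2L, 0L, 2L, 1L),
    A5 = c(1L, 0L, 1L, 2L, 0L),
    A6 = c(1L, NA, NA, NA, 0L))
  toyGenotypes(calls)
}
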