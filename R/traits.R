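# Derivation of the six sow reproduction traits from litter-level records,
# plus descriptive statistics.
#
# Trait definitions (per sow, over her recorded litters):
#   PWL  = total pigs weaned / litters
#   BAL  = total born alive / litters
#   W2CL = mean wean-to-conception interval (open last litters excluded)
#   LSY  = (total gestation days / 115) / (days in breeding herd / 365)
#   PWSY = LSY * PWL
#   NPD  = 365 - (mean productive days per litter) * LSY, where productive
#          days = gestation + lactation days summed over litters.  The
#          literal left-to-right reading (365 - total productive days) * LSY
#          is available via `npdFormula = "literal"`.

#' Derive the six reproduction traits from sow litter records
#'
#' `records` is a litter-level data.frame with columns `sow`, `parity`
#' (1-10), `pigsWeaned`, `bornAlive`, `w2cDays` (NA for an open last
#' litter), `gestationDays`, `lactationDays`, `farrowMonth`, `farrowYear`,
#' `farm`, and `herdDays` (days in the breeding herd, constant per sow).
#' Fixed-effect levels are taken from each sow's last (highest-parity)
#' litter.  Sows with zero litters or zero herd days are skipped with a
#' logged reason (attribute `"skipped"`).
#'
#' @param records litter-level data.frame (one row per litter).
#' @param npdFormula `"per-litter"` (default) or `"literal"`; see Details.
#' @return data.frame with one row per sow: `sow`, `PWL`, `BAL`, `W2CL`,
#'   `LSY`, `PWSY`, `NPD`, `farm`, `lastParity`, `lastFarrowMonth`,
#'   `lastFarrowYear`.
#' @export
deriveTraits <- function(records, npdFormula = c("per-litter", "literal")) {
  npdFormula <- match.arg(npdFormula)
  need <- c("sow", "parity", "pigsWeaned", "bornAlive", "w2cDays",
            "gestationDays", "lactationDays", "farrowMonth", "farrowYear",
            "farm", "herdDays")
  stopIf(!all(need %in% names(records)), "records must have columns %s",
         paste(setdiff(need, names(records)), collapse = ", "))
  stopIf(any(records$parity < 1 | records$parity > 10),
         "parity must be between 1 and 10")

  skipped <- character(0)
  rows <- lapply(split(records, records$sow), function(r) {
    sow <- r$sow[1L]
    nl <- nrow(r)
    herd <- r$herdDays[1L]
    if (nl == 0 || is.na(herd) || herd <= 0) {
      skipped <<- c(skipped, sprintf("%s: zero litters or herd days", sow))
      return(NULL)
    }
    pwl <- sum(r$pigsWeaned) / nl
    bal <- sum(r$bornAlive) / nl
    w2c <- r$w2cDays[!is.na(r$w2cDays)]
    w2cl <- if (length(w2c)) sum(w2c) / length(w2c) else NA_real_
    lsy <- (sum(r$gestationDays) / 115) / (herd / 365)
    pwsy <- lsy * pwl
    pd <- sum(r$gestationDays + r$lactationDays)
    npd <- if (npdFormula == "per-litter") 365 - (pd / nl) * lsy
           else (365 - pd) * lsy
    last <- r[which.max(r$parity), ]
    data.frame(sow = sow, PWL = pwl, BAL = bal, W2CL = w2cl, LSY = lsy,
               PWSY = pwsy, NPD = npd, farm = last$farm,
               lastParity = last$parity, lastFarrowMonth = last$farrowMonth,
               lastFarrowYear = last$farrowYear, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  outside <- !is.na(out$NPD) & (out$NPD < 0 | out$NPD > 365)
  if (any(outside))
    message(sum(outside), " sow(s) with NPD outside [0, 365]; kept, ",
            "flagging possible data issues")
  attr(out, "skipped") <- skipped
  out
}

#' Descriptive statistics per trait
#'
#' Mean, SD, coefficient of variation and the moment-based normality
#' diagnostics (skewness g1, excess kurtosis g2), computed over non-missing
#' values.
#'
#' @param traits data.frame of trait values (non-numeric columns ignored),
#'   or a numeric matrix.
#' @return data.frame with one row per trait: `trait`, `n`, `mean`, `sd`,
#'   `cv`, `skewness`, `kurtosis`.  `cv` and `skewness` are `NaN`-flagged
#'   when undefined (near-zero mean / zero variance).
#' @export
summaryStatistics <- function(traits) {
  if (is.data.frame(traits))
    traits <- traits[vapply(traits, is.numeric, logical(1))]
  traits <- as.matrix(traits)
  rows <- lapply(colnames(traits), function(tn) {
    x <- traits[, tn]
    x <- x[!is.na(x)]
    n <- length(x)
    stopIf(n < 2, "trait '%s' has fewer than 2 non-missing values", tn)
    m <- mean(x); s <- stats::sd(x)
    cv <- if (abs(m) < 1e-12) NaN else s / m
    z2 <- mean((x - m)^2)
    skew <- if (z2 < 1e-24) NaN else mean((x - m)^3) / z2^1.5
    kurt <- if (z2 < 1e-24) NaN else mean((x - m)^4) / z2^2 - 3
    data.frame(trait = tn, n = n, mean = m, sd = s, cv = cv,
               skewness = skew, kurtosis = kurt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a per-sow trait table as TSV
#'
#' @param traits data.frame from [deriveTraits()].
#' @param path output path.
#' @export
writeTraitTable <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
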