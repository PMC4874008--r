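# Independent monoisotopic mass oracle: residue masses recomputed from
# elemental composition (CHNOS monoisotopic atom masses), so agreement with
# the package's residue table is a genuine cross-check, not a tautology.
ATOM <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
          O = 15.9949146221, S = 31.97207069)

RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

oracleResidueMass <- function(letter) {
  f <- RESIDUE_FORMULA[[letter]]
  sum(ATOM[names(f)] * f)
}

oracleWater <- 2 * ATOM["H"] + ATOM["O"]

oraclePeptideMass <- function(sequence) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(vapply(aa, oracleResidueMass, numeric(1))) + unname(oracleWater)
}

# random peptide ending in K or R (tryptic-like), with K/R sprinkled inside
randomTrypticPeptide <- function(minLen = 5L, maxLen = 20L) {
  n <- sample(minLen:maxLen, 1L)
  letters20 <- names(RESIDUE_FORMULA)
  body <- sample(letters20, n - 1L, replace = TRUE,
                 prob = ifelse(letters20 %in% c("K", "R"), 0.06, 0.88 / 18))
  paste(c(body, sample(c("K", "R"), 1L)), collapse = "")
}

# dense dot product oracle for sparse (bins, values) pairs
denseDot <- function(aBins, aVals, bBins, bVals) {
  n <- max(aBins, bBins) + 1L
  da <- numeric(n)
  db <- numeric(n)
  da[aBins + 1L] <- aVals
  db[bBins + 1L] <- bVals
  sum(da * db)
}

# direct normalized cross-correlation on the assembled theoretical vector
directScore <- function(x1, x2, yBins, yInt) {
  allBins <- sort(unique(c(x1$bins, x2$bins)))
  xv <- numeric(length(allBins))
  xv[match(x1$bins, allBins)] <- xv[match(x1$bins, allBins)] + x1$counts
  xv[match(x2$bins, allBins)] <- xv[match(x2$bins, allBins)] + x2$counts
  hit <- match(allBins, yBins)
  ok <- !is.na(hit)
  sum(xv[ok] * yInt[hit[ok]]) / sqrt(sum(xv^2))
}

# random sparse non-negative vector (sorted integer bins, values)
randomSparse <- function(nBins = 30L, universe = 500L, integerValues = TRUE) {
  bins <- sort(sample.int(universe, nBins))
  vals <- if (integerValues) sample(1:4, nBins, replace = TRUE) else
    stats::runif(nBins)
  list(bins = as.integer(bins), counts = vals)
}

rawSpectrum <- function(mz, intensity, scanId = "s1", precursorMz = 500,
                        charge = 2L) {
  ord <- order(mz)
  list(scanId = scanId, precursorMz = precursorMz,
       precursorCharge = as.integer(charge),
       mz = mz[ord], intensity = intensity[ord])
}
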