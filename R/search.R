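#' Sparse dot product by two-pointer merge
#'
#' Dot product of two sparse vectors given as sorted bin indices plus values.
#' A single merge pass over the two supports gives cost linear in the total
#' number of occupied bins, which is what keeps exhaustive pair scoring
#' tractable.
#'
#' @param aBins,bBins Strictly increasing integer vectors of occupied bins.
#' @param aValues,bValues Numeric values aligned with the bins.
#' @return The scalar dot product over shared bins.
#' @examples
#' sparseDot(c(1L, 3L), c(1, 2), c(3L, 5L), c(4, 1))  # 8
#' @export
sparseDot <- function(aBins, aValues, bBins, bValues) {
  sparse_dot_cpp(as.integer(aBins), as.numeric(aValues),
                 as.integer(bBins), as.numeric(bValues))
}

#' Score one chain pair against a processed spectrum
#'
#' The normalized cross-correlation between the theoretical spectrum
#' X = X1 + X2 and the unit-normalized experimental spectrum:
#' \deqn{score = (X_1^T \tilde{Y} + X_2^T \tilde{Y}) / \lVert X \rVert}
#' where the two half-vectors are summed element-wise over bins before taking
#' the norm. For non-negative vectors the score lies in [0, 1], reaching 1
#' exactly when the experimental vector is proportional to X
#' (Cauchy-Schwarz).
#'
#' @param x1,x2 Half-vectors from [buildHalfVector()] (fields `bins`,
#'   `counts`), built with the spectrum's precursor mass and bin width.
#' @param spectrumBins,spectrumIntensities The spectrum's sparse unit vector.
#' @return The score in [0, 1]; 0 with a warning if X is empty.
#' @export
scorePair <- function(x1, x2, spectrumBins, spectrumIntensities) {
  nrm <- merged_norm_cpp(as.integer(x1$bins), as.numeric(x1$counts),
                         as.integer(x2$bins), as.numeric(x2$counts))
  if (nrm == 0) {
    warning("empty theoretical spectrum; score set to 0")
    return(0)
  }
  d1 <- sparse_dot_cpp(as.integer(x1$bins), as.numeric(x1$counts),
                       as.integer(spectrumBins), as.numeric(spectrumIntensities))
  d2 <- sparse_dot_cpp(as.integer(x2$bins), as.numeric(x2$counts),
                       as.integer(spectrumBins), as.numeric(spectrumIntensities))
  (d1 + d2) / nrm
}

# order a candidate so the lighter chain (ties: lexicographically smaller
# sequence; self-pairs: smaller site) is alpha
canonicalPair <- function(seqA, siteA, massA, seqB, siteB, massB) {
  swap <- if (massA != massB) massA > massB
    else if (seqA != seqB) seqA > seqB
    else siteA > siteB
  if (swap) list(aSeq = seqB, aSite = siteB, bSeq = seqA, bSite = siteA)
  else list(aSeq = seqA, aSite = siteA, bSeq = seqB, bSite = siteB)
}

# TRUE if candidate key (aSeq, bSeq, aSite, bSite) precedes the incumbent
keyPrecedes <- function(cand, inc) {
  if (cand$aSeq != inc$aSeq) return(cand$aSeq < inc$aSeq)
  if (cand$bSeq != inc$bSeq) return(cand$bSeq < inc$bSeq)
  if (cand$aSite != inc$aSite) return(cand$aSite < inc$aSite)
  cand$bSite < inc$bSite
}

psmClass <- function(decoyA, decoyB) classifyPsm(decoyA, decoyB)

psmTopology <- function(parentsA, parentsB) {
  a <- sub("^DECOY_", "", parentsA)
  b <- sub("^DECOY_", "", parentsB)
  if (length(intersect(a, b))) "intra" else "inter"
}

emptyPsmFrame <- function() {
  data.frame(scan_id = character(), alpha_sequence = character(),
             alpha_site = integer(), beta_sequence = character(),
             beta_site = integer(), alpha_proteins = character(),
             beta_proteins = character(), score = numeric(),
             class = character(), topology = character(),
             stringsAsFactors = FALSE)
}

# assemble the per-spectrum best records into the PSM data.frame
collectPsms <- function(best, scanIds) {
  hit <- !vapply(best, is.null, logical(1))
  if (!any(hit)) return(emptyPsmFrame())
  rows <- lapply(which(hit), function(s) {
    b <- best[[s]]
    data.frame(scan_id = scanIds[s],
               alpha_sequence = b$key$aSeq, alpha_site = b$key$aSite,
               beta_sequence = b$key$bSeq, beta_site = b$key$bSite,
               alpha_proteins = paste(b$aParents, collapse = ";"),
               beta_proteins = paste(b$bParents, collapse = ";"),
               score = b$score, class = b$class, topology = b$topology,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exhaustive cross-link search
#'
#' Scores every mass-compatible (chain, site) pair against every spectrum and
#' keeps each spectrum's single best match. The outer loop walks chains in
#' ascending mass up to half of the (tolerance-adjusted, linker-subtracted)
#' largest precursor mass, so every unordered pair is visited exactly once.
#' For each outer chain, the spectra with precursor mass at least
#' \code{2c + r - o} are selected, the half-vector dot product X1' Y is
#' computed once per (chain, site, spectrum), and partner chains are those
#' whose mass falls in the half-open window
#' \code{[p - o - c - r, p + o - c - r)}; o is the per-spectrum absolute
#' tolerance \code{p * ppm * 1e-6}. Ties in the top score are broken toward
#' the lexicographically smallest (alpha sequence, beta sequence, alpha site,
#' beta site), with alpha the lighter chain.
#'
#' @param chainIndex A [ChainIndex].
#' @param spectrumIndex A [SpectrumIndex] built with the same fragment
#'   tolerance as `config`.
#' @param config An [XLSearchConfig].
#' @return A data.frame of PSMs with columns `scan_id`, `alpha_sequence`,
#'   `alpha_site`, `beta_sequence`, `beta_site`, `alpha_proteins`,
#'   `beta_proteins`, `score`, `class` (TT/TD/DD), `topology`
#'   (intra/inter). Spectra with no admissible pair are absent.
#' @seealso [bruteForceSearch()] for the reference implementation used as a
#'   test oracle, [assignConfidence()] for FDR/q-value annotation.
#' @export
searchCrosslinks <- function(chainIndex, spectrumIndex,
                             config = SearchConfig()) {
  stopifnot(methods::is(chainIndex, "ChainIndex"),
            methods::is(spectrumIndex, "SpectrumIndex"))
  if (length(chainIndex) == 0L || length(spectrumIndex) == 0L)
    stop("empty index")
  if (abs(spectrumIndex@binWidth - 2 * config@fragmentTol) > 1e-12)
    stop("spectrum index bin width does not match the fragment tolerance")

  masses <- chainIndex@mass
  seqs <- chainIndex@sequence
  siteList <- chainIndex@linkSites
  nChains <- length(masses)
  p <- spectrumIndex@precursorMass
  z <- spectrumIndex@precursorCharge
  ns <- length(p)
  r <- config@linkerMass
  o <- p * config@precursorPpm * 1e-6
  pAdj <- p + o   # increasing in p
  maxOuter <- (p[ns] + o[ns] - r) / 2

  best <- vector("list", ns)
  for (i in seq_len(nChains)) {
    ci <- masses[i]
    if (ci > maxOuter) break
    sFrom <- findInterval(2 * ci + r, pAdj, left.open = TRUE) + 1L
    if (sFrom > ns) next
    sIdx <- sFrom:ns
    lo <- p[sIdx] - o[sIdx] - ci - r
    hi <- p[sIdx] + o[sIdx] - ci - r
    jFrom <- pmax(findInterval(lo, masses, left.open = TRUE) + 1L, i)
    jTo <- findInterval(hi, masses, left.open = TRUE)
    hasCand <- jFrom <= jTo
    if (!any(hasCand)) next
    sitesI <- siteList[[i]]
    for (sPos in which(hasCand)) {
      s <- sIdx[sPos]
      yBins <- spectrumIndex@bins[[s]]
      yInt <- spectrumIndex@intensities[[s]]
      # X1 and X1' Y once per (outer chain, site, spectrum)
      x1 <- lapply(sitesI, buildHalfVector, sequence = seqs[i],
                   precursorMass = p[s], precursorCharge = z[s],
                   config = config)
      d1 <- vapply(x1, function(v)
        sparse_dot_cpp(v$bins, as.numeric(v$counts), yBins, yInt), numeric(1))
      for (j in jFrom[sPos]:jTo[sPos]) {
        for (sb in siteList[[j]]) {
          x2 <- buildHalfVector(seqs[j], sb, p[s], z[s], config)
          d2 <- sparse_dot_cpp(x2$bins, as.numeric(x2$counts), yBins, yInt)
          for (ai in seq_along(sitesI)) {
            if (j == i && sb < sitesI[ai]) next  # unordered site pairs once
            nrm <- merged_norm_cpp(x1[[ai]]$bins, as.numeric(x1[[ai]]$counts),
                                   x2$bins, as.numeric(x2$counts))
            score <- if (nrm > 0) (d1[ai] + d2) / nrm else 0
            inc <- best[[s]]
            if (!is.null(inc) && score < inc$score) next
            key <- canonicalPair(seqs[i], sitesI[ai], masses[i],
                                 seqs[j], sb, masses[j])
            if (!is.null(inc) && score == inc$score &&
                !keyPrecedes(key, inc$key)) next
            aIsI <- key$aSeq == seqs[i] && key$aSite == sitesI[ai]
            best[[s]] <- list(
              score = score, key = key,
              aParents = if (aIsI) chainIndex@parents[[i]] else chainIndex@parents[[j]],
              bParents = if (aIsI) chainIndex@parents[[j]] else chainIndex@parents[[i]],
              class = psmClass(chainIndex@isDecoy[i], chainIndex@isDecoy[j]),
              topology = psmTopology(chainIndex@parents[[i]],
                                     chainIndex@parents[[j]])
            )
          }
        }
      }
    }
  }
  collectPsms(best, spectrumIndex@scanId)
}

#' Brute-force reference search
#'
#' Enumerates every unordered chain pair and site pair for every spectrum,
#' admits a pair when its total mass (both chains plus linker) falls in the
#' half-open precursor window \code{[p - o, p + o)}, and scores it by the
#' direct normalized cross-correlation: the full theoretical vector X is
#' assembled from both chains' ions in one pass and the score is
#' \code{X'Y / (||X|| ||Y||)}. This is an independent implementation used to
#' validate [searchCrosslinks()] on small instances; it shares neither the
#' half-vector decomposition, the index queries, nor the C++ kernels.
#'
#' @inheritParams searchCrosslinks
#' @return A PSM data.frame with the same columns as [searchCrosslinks()].
#' @export
bruteForceSearch <- function(chainIndex, spectrumIndex,
                             config = SearchConfig()) {
  masses <- chainIndex@mass
  seqs <- chainIndex@sequence
  nChains <- length(masses)
  w <- spectrumIndex@binWidth
  r <- config@linkerMass
  best <- vector("list", length(spectrumIndex))

  for (s in seq_len(length(spectrumIndex))) {
    p <- spectrumIndex@precursorMass[s]
    z <- spectrumIndex@precursorCharge[s]
    o <- p * config@precursorPpm * 1e-6
    yBins <- spectrumIndex@bins[[s]]
    yInt <- spectrumIndex@intensities[[s]]
    zmax <- max(1L, min(config@maxFragmentCharge, z - 1L))
    for (i in seq_len(nChains)) {
      for (j in i:nChains) {
        total <- masses[i] + masses[j] + r
        if (total < p - o || total >= p + o) next
        for (sa in chainIndex@linkSites[[i]]) {
          for (sb in chainIndex@linkSites[[j]]) {
            if (j == i && sb < sa) next
            fa <- classifyFragments(seqs[i], sa, p)
            fb <- classifyFragments(seqs[j], sb, p)
            x <- halfVectorFromMasses(c(fa$neutralMass, fb$neutralMass),
                                      zmax, w)
            # dense-style dot via match(), independent of the C++ kernels
            hit <- match(x$bins, yBins)
            ok <- !is.na(hit)
            num <- sum(x$counts[ok] * yInt[hit[ok]])
            score <- num / sqrt(sum(x$counts^2))
            inc <- best[[s]]
            if (!is.null(inc) && score < inc$score) next
            key <- canonicalPair(seqs[i], sa, masses[i], seqs[j], sb, masses[j])
            if (!is.null(inc) && score == inc$score &&
                !keyPrecedes(key, inc$key)) next
            aIsI <- key$aSeq == seqs[i] && key$aSite == sa
            best[[s]] <- list(
              score = score, key = key,
              aParents = if (aIsI) chainIndex@parents[[i]] else chainIndex@parents[[j]],
              bParents = if (aIsI) chainIndex@parents[[j]] else chainIndex@parents[[i]],
              class = psmClass(chainIndex@isDecoy[i], chainIndex@isDecoy[j]),
              topology = psmTopology(chainIndex@parents[[i]],
                                     chainIndex@parents[[j]])
            )
          }
        }
      }
    }
  }
  collectPsms(best, spectrumIndex@scanId)
}
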