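#' Neutral b/y fragment masses of a linear chain
#'
#' CID fragmentation of a peptide of length m yields b-ions (prefixes) and
#' y-ions (suffixes), i = 1..m-1. Neutral masses: b_i is the sum of the first
#' i residue masses; y_j is the sum of the last j residue masses plus one
#' water. Complementarity: b_i + y_(m-i) equals the chain's neutral mass.
#'
#' @param sequence Peptide sequence with at least 2 residues.
#' @return A list with numeric vectors `b` and `y` (each of length m-1).
#' @examples
#' linearFragmentMasses("GG")  # b1 = 57.0215, y1 = 75.0320
#' @export
linearFragmentMasses <- function(sequence) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- length(aa)
  if (m < 2L) stop("chain must have at least 2 residues")
  rm <- unname(AA_MONO[aa])
  if (anyNA(rm)) stop("non-standard residue in sequence: ", sequence)
  list(b = cumsum(rm)[-m], y = cumsum(rev(rm))[-m] + MASS_WATER)
}

#' Classify fragments as linear or cross-linking and shift their masses
#'
#' A fragment that contains the linked residue carries the cross-linker and
#' the entire partner chain: a b_i ion is cross-linking iff i >= link site, a
#' y_j ion iff j >= m - link site + 1. Cross-linking ions take the shifted
#' mass p - c + l, where p is the spectrum's neutral precursor mass, c the
#' chain's neutral mass and l the corresponding linear fragment mass; linear
#' ions keep l. The shift p - c equals the partner chain's mass plus the
#' linker mass, so x - l is constant across a chain's cross-linking ions.
#'
#' @param sequence Chain sequence.
#' @param linkSite 1-based position of the linked residue within the chain.
#' @param precursorMass Neutral precursor mass p of the spectrum (Da).
#' @return A data.frame with columns `ion` ("b"/"y"), `index` (1..m-1),
#'   `linearMass`, `isCrosslinking`, `neutralMass`.
#' @examples
#' p <- peptideMass("EAKELIEGLPR") + peptideMass("EVRKELDDLR") + 138.06808
#' frags <- classifyFragments("EAKELIEGLPR", 3, p)
#' subset(frags, ion == "b" & index == 4)  # cross-linking, linear part "EAKE"
#' @export
classifyFragments <- function(sequence, linkSite, precursorMass) {
  m <- nchar(sequence)
  stopifnot(linkSite >= 1L, linkSite <= m)
  lf <- linearFragmentMasses(sequence)
  c0 <- peptideMass(sequence)
  if (precursorMass <= c0) stop("precursor mass must exceed the chain mass")
  idx <- seq_len(m - 1L)
  bx <- idx >= linkSite
  yx <- idx >= (m - linkSite + 1L)
  out <- data.frame(
    ion = rep(c("b", "y"), each = m - 1L),
    index = c(idx, idx),
    linearMass = c(lf$b, lf$y),
    isCrosslinking = c(bx, yx),
    stringsAsFactors = FALSE
  )
  out$neutralMass <- ifelse(out$isCrosslinking,
                            precursorMass - c0 + out$linearMass,
                            out$linearMass)
  out
}

#' Build the sparse theoretical half-vector for one linked chain
#'
#' Converts every linear and cross-linking b/y ion to m/z at fragment charges
#' 1..min(precursor charge - 1, charge cap), bins the m/z values with the
#' same bin width as experimental vectors, and counts co-binned ions: the
#' theoretical intensity of a bin is the number of ions falling into it.
#'
#' @param sequence Chain sequence.
#' @param linkSite 1-based linked position.
#' @param precursorMass Neutral precursor mass p of the target spectrum (Da).
#' @param precursorCharge Precursor charge of the target spectrum.
#' @param config An [XLSearchConfig] (fragment tolerance and charge cap).
#' @return A list with fields `bins` (strictly increasing integers) and
#'   `counts` (positive integers).
#' @export
buildHalfVector <- function(sequence, linkSite, precursorMass,
                            precursorCharge, config = SearchConfig()) {
  zmax <- max(1L, min(config@maxFragmentCharge, precursorCharge - 1L))
  halfVectorFromMasses(
    fragmentNeutralMasses(sequence, linkSite, precursorMass),
    zmax, 2 * config@fragmentTol)
}

# all neutral b/y ion masses (linear kept, cross-linking shifted by p - c)
# without the bookkeeping of classifyFragments; the search hot path
fragmentNeutralMasses <- function(sequence, linkSite, precursorMass) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- length(aa)
  rm <- unname(AA_MONO[aa])
  b <- cumsum(rm)[-m]
  y <- cumsum(rev(rm))[-m] + MASS_WATER
  shift <- precursorMass - peptideMass(sequence)
  idx <- seq_len(m - 1L)
  b[idx >= linkSite] <- b[idx >= linkSite] + shift
  yx <- idx >= (m - linkSite + 1L)
  y[yx] <- y[yx] + shift
  c(b, y)
}

# bin all (ion, charge) m/z values; intensity = ion multiplicity per bin
halfVectorFromMasses <- function(neutralMasses, zmax, binWidth) {
  z <- seq_len(zmax)
  mz <- as.vector(outer(neutralMasses, z, function(m, z) (m + z * MASS_PROTON) / z))
  bins <- as.integer(floor(mz / binWidth))
  u <- sort(unique(bins))
  list(bins = u, counts = tabulate(match(bins, u)))
}
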