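# Monoisotopic masses (Da). Residue masses are for the amino-acid residue
# (i.e. the amino acid minus one water) as incorporated in a peptide chain.
MASS_WATER <- 18.010565
MASS_PROTON <- 1.00727646

# Default linker mass: DSS / BS3 after reaction with two primary amines
# (C8H10O2 bridge), monoisotopic.
MASS_DSS <- 138.06808

AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

AA_LETTERS <- names(AA_MONO)

#' Monoisotopic mass of a peptide
#'
#' Neutral monoisotopic mass of one or more peptide sequences: the sum of the
#' residue masses plus one water. The sum is accumulated over the residue
#' composition in a fixed amino-acid order, so sequences that are permutations
#' of one another (e.g. a peptide and its lysine/arginine-fixed decoy) get
#' bit-identical masses.
#'
#' @param sequences Character vector of peptide sequences over the 20 standard
#'   amino-acid one-letter codes.
#' @return Numeric vector of neutral masses in Da.
#' @examples
#' peptideMass(c("GG", "EVRKELDDLR"))
#' @export
peptideMass <- function(sequences) {
  stopifnot(is.character(sequences))
  vapply(sequences, function(s) {
    if (nchar(s) == 0L) stop("empty peptide sequence")
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(aa), AA_LETTERS)
    if (length(bad)) {
      stop("non-standard residue(s) in sequence: ", paste(bad, collapse = ", "))
    }
    counts <- table(factor(aa, levels = AA_LETTERS))
    sum(as.numeric(counts) * AA_MONO) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}
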