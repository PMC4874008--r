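#' Search configuration
#'
#' Holds every tunable of the cross-link search: the linker mass, mass
#' tolerances, digestion settings and the q-value cut-off. Construct with
#' [SearchConfig()].
#'
#' @slot linkerMass Mass added by the cross-linker bridge (Da, monoisotopic).
#'   Default 138.06808, the DSS/BS3 bridge after amine reaction.
#' @slot precursorPpm Precursor mass tolerance in parts per million. The
#'   absolute tolerance used for a spectrum with neutral precursor mass p is
#'   \code{p * precursorPpm * 1e-6}.
#' @slot fragmentTol Fragment (tandem) mass tolerance in Da. Spectrum vectors
#'   are binned with width \code{2 * fragmentTol}.
#' @slot maxMissedCleavages Maximum internal missed cleavage sites per peptide.
#' @slot minLength,maxLength Peptide length bounds (residues) kept after
#'   digestion.
#' @slot maxFragmentCharge Cap on fragment-ion charge; fragments are generated
#'   at charges 1..min(precursor charge - 1, maxFragmentCharge).
#' @slot qThreshold q-value cut-off used by [filterResults()].
#' @slot nTermLinking Whether position 1 of a protein N-terminal peptide is a
#'   linkable site (the protein alpha-amine). Default FALSE.
#' @slot sqrtIntensity Whether experimental peak intensities are square-root
#'   transformed before vectorization. Default FALSE (raw intensities).
#' @slot cleavageResidues Residues cleaved C-terminally (trypsin: "KR").
#' @slot cleavageException Residue blocking cleavage when it follows the site
#'   (trypsin: "P").
#' @name XLSearchConfig-class
#' @aliases XLSearchConfig
#' @exportClass XLSearchConfig
setClass("XLSearchConfig", representation(
  linkerMass = "numeric",
  precursorPpm = "numeric",
  fragmentTol = "numeric",
  maxMissedCleavages = "integer",
  minLength = "integer",
  maxLength = "integer",
  maxFragmentCharge = "integer",
  qThreshold = "numeric",
  nTermLinking = "logical",
  sqrtIntensity = "logical",
  cleavageResidues = "character",
  cleavageException = "character"
))

setValidity("XLSearchConfig", function(object) {
  msg <- character()
  if (object@linkerMass <= 0) msg <- c(msg, "linkerMass must be > 0")
  if (object@precursorPpm <= 0) msg <- c(msg, "precursorPpm must be > 0")
  if (object@fragmentTol <= 0) msg <- c(msg, "fragmentTol must be > 0")
  if (object@maxMissedCleavages < 0L) msg <- c(msg, "maxMissedCleavages must be >= 0")
  if (object@minLength < 1L || object@minLength > object@maxLength)
    msg <- c(msg, "need 1 <= minLength <= maxLength")
  if (object@maxFragmentCharge < 1L) msg <- c(msg, "maxFragmentCharge must be >= 1")
  if (object@qThreshold < 0 || object@qThreshold > 1)
    msg <- c(msg, "qThreshold must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Mass-sorted index of digested peptide chains
#'
#' The digested, decoy-augmented peptide database: one entry per distinct
#' linkable peptide sequence, sorted by neutral monoisotopic mass so that
#' mass-window queries are binary searches. Built by [buildChainIndex()].
#'
#' @slot sequence Peptide sequences.
#' @slot mass Neutral monoisotopic masses (Da), ascending.
#' @slot missedCleavages Internal missed cleavage count per chain.
#' @slot isDecoy TRUE for chains that exist only in the decoy database. A
#'   sequence found in both target and decoy databases is labelled target.
#' @slot linkSites List of integer vectors: 1-based positions of linkable
#'   lysines (and optionally the protein N-terminus) within each chain.
#' @slot parents List of character vectors: accessions of the proteins each
#'   chain derives from (decoy chains carry the "DECOY_" prefix).
#' @name ChainIndex-class
#' @aliases ChainIndex
#' @exportClass ChainIndex
setClass("ChainIndex", representation(
  sequence = "character",
  mass = "numeric",
  missedCleavages = "integer",
  isDecoy = "logical",
  linkSites = "list",
  parents = "list"
))

setValidity("ChainIndex", function(object) {
  n <- length(object@sequence)
  msg <- character()
  if (length(object@mass) != n || length(object@missedCleavages) != n ||
      length(object@isDecoy) != n || length(object@linkSites) != n ||
      length(object@parents) != n)
    msg <- c(msg, "slot lengths differ")
  if (is.unsorted(object@mass)) msg <- c(msg, "masses must be ascending")
  if (n && any(vapply(object@linkSites, length, integer(1)) == 0L))
    msg <- c(msg, "every chain must have at least one link site")
  if (length(msg)) msg else TRUE
})

#' Mass-sorted index of processed spectra
#'
#' Processed (de-noised, binned, unit-normalized) experimental spectra sorted
#' by neutral precursor mass. Each spectrum is a sparse unit vector: occupied
#' bin indices plus intensities with Euclidean norm 1. Built by
#' [buildSpectrumIndex()].
#'
#' @slot scanId Scan identifiers, verbatim from the input file.
#' @slot precursorMass Neutral precursor masses (Da), ascending;
#'   \code{(m/z - proton) * z}.
#' @slot precursorCharge Precursor charge states.
#' @slot bins List of strictly increasing integer vectors of occupied bins.
#' @slot intensities List of numeric vectors, one per spectrum, unit norm.
#' @slot binWidth Bin width (Da/charge) shared by all spectra in the index;
#'   twice the fragment tolerance.
#' @name SpectrumIndex-class
#' @aliases SpectrumIndex
#' @exportClass SpectrumIndex
setClass("SpectrumIndex", representation(
  scanId = "character",
  precursorMass = "numeric",
  precursorCharge = "integer",
  bins = "list",
  intensities = "list",
  binWidth = "numeric"
))

setValidity("SpectrumIndex", function(object) {
  n <- length(object@scanId)
  msg <- character()
  if (length(object@precursorMass) != n || length(object@precursorCharge) != n ||
      length(object@bins) != n || length(object@intensities) != n)
    msg <- c(msg, "slot lengths differ")
  if (is.unsorted(object@precursorMass)) msg <- c(msg, "precursor masses must be ascending")
  if (n) {
    norms <- vapply(object@intensities, function(v) sqrt(sum(v * v)), numeric(1))
    if (any(abs(norms - 1) > 1e-9)) msg <- c(msg, "spectrum vectors must have unit norm")
    if (any(vapply(object@bins, length, integer(1)) == 0L))
      msg <- c(msg, "empty spectrum vectors are not allowed")
  }
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    msg <- c(msg, "binWidth must be a positive scalar")
  if (length(msg)) msg else TRUE
})
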