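#' Create a search configuration
#'
#' @param linkerMass Cross-linker bridge mass in Da (default DSS/BS3,
#'   138.06808).
#' @param precursorPpm Precursor mass tolerance, ppm (default 10).
#' @param fragmentTol Fragment mass tolerance, Da (default 0.5, suiting
#'   ion-trap CID spectra; use 0.2 for higher-accuracy tandem spectra).
#' @param maxMissedCleavages Maximum missed cleavages (default 2; a
#'   cross-linked lysine always implies at least one).
#' @param minLength,maxLength Peptide length bounds (default 5..60).
#' @param maxFragmentCharge Fragment charge cap (default 4).
#' @param qThreshold q-value cut-off for reporting (default 0.05).
#' @param nTermLinking Allow linking at the protein N-terminal alpha-amine
#'   (default FALSE).
#' @param sqrtIntensity Square-root transform experimental intensities before
#'   vectorization (default FALSE).
#' @param cleavageResidues,cleavageException Enzyme rule: cleave C-terminal to
#'   any residue in `cleavageResidues` unless the next residue is
#'   `cleavageException`. Defaults encode trypsin (after K/R, not before P).
#' @return An [XLSearchConfig] object.
#' @examples
#' cfg <- SearchConfig(fragmentTol = 0.2)
#' fragmentTol(cfg)
#' @export
SearchConfig <- function(linkerMass = MASS_DSS,
                         precursorPpm = 10,
                         fragmentTol = 0.5,
                         maxMissedCleavages = 2L,
                         minLength = 5L,
                         maxLength = 60L,
                         maxFragmentCharge = 4L,
                         qThreshold = 0.05,
                         nTermLinking = FALSE,
                         sqrtIntensity = FALSE,
                         cleavageResidues = "KR",
                         cleavageException = "P") {
  methods::new("XLSearchConfig",
    linkerMass = as.numeric(linkerMass),
    precursorPpm = as.numeric(precursorPpm),
    fragmentTol = as.numeric(fragmentTol),
    maxMissedCleavages = as.integer(maxMissedCleavages),
    minLength = as.integer(minLength),
    maxLength = as.integer(maxLength),
    maxFragmentCharge = as.integer(maxFragmentCharge),
    qThreshold = as.numeric(qThreshold),
    nTermLinking = isTRUE(nTermLinking),
    sqrtIntensity = isTRUE(sqrtIntensity),
    cleavageResidues = cleavageResidues,
    cleavageException = cleavageException
  )
}

#' @describeIn SearchConfig Linker mass accessor.
#' @param x An [XLSearchConfig].
#' @export
linkerMass <- function(x) x@linkerMass

#' @describeIn SearchConfig Precursor tolerance (ppm) accessor.
#' @export
precursorPpm <- function(x) x@precursorPpm

#' @describeIn SearchConfig Fragment tolerance (Da) accessor.
#' @export
fragmentTol <- function(x) x@fragmentTol

#' @describeIn SearchConfig q-value threshold accessor.
#' @export
qThreshold <- function(x) x@qThreshold

setMethod("show", "XLSearchConfig", function(object) {
  cat("XLSearchConfig\n")
  cat(sprintf("  linker mass      : %.5f Da\n", object@linkerMass))
  cat(sprintf("  precursor tol    : %g ppm\n", object@precursorPpm))
  cat(sprintf("  fragment tol     : %g Da (bin width %g)\n",
              object@fragmentTol, 2 * object@fragmentTol))
  cat(sprintf("  missed cleavages : <= %d\n", object@maxMissedCleavages))
  cat(sprintf("  peptide length   : %d..%d\n", object@minLength, object@maxLength))
  cat(sprintf("  fragment charge  : <= %d\n", object@maxFragmentCharge))
  cat(sprintf("  q threshold      : %g\n", object@qThreshold))
  invisible(object)
})
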