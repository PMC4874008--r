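#' @title Range and threshold queries on mass-sorted indices
#' @description Generics for the binary-search queries the exhaustive search
#'   relies on. `chainsInRange` returns the chains whose neutral mass lies in
#'   the half-open interval \code{[lower, upper)}; `spectraWithMassAtLeast`
#'   returns the spectra whose neutral precursor mass is greater than or equal
#'   to `threshold` (boundary inclusive); `largestPrecursorMass` returns the
#'   largest neutral precursor mass in an index.
#' @param x A [ChainIndex] or [SpectrumIndex].
#' @param lower,upper Mass interval bounds in Da; the interval is
#'   \code{[lower, upper)}.
#' @param threshold Mass threshold in Da (inclusive).
#' @return Integer vector of 1-based positions in the index, in ascending mass
#'   order (`largestPrecursorMass`: a numeric scalar).
#' @name index-queries
NULL

#' @rdname index-queries
#' @export
setGeneric("chainsInRange", function(x, lower, upper) standardGeneric("chainsInRange"))

#' @rdname index-queries
#' @export
setGeneric("spectraWithMassAtLeast", function(x, threshold) standardGeneric("spectraWithMassAtLeast"))

#' @rdname index-queries
#' @export
setGeneric("largestPrecursorMass", function(x) standardGeneric("largestPrecursorMass"))
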