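#' Read centroided MS2 spectra
#'
#' Reads tandem mass spectra from MGF (parsed natively) or mzML (via
#' \pkg{mzR}). Only MS2 scans with a known precursor m/z and charge are
#' returned; scans with precursor charge below 2 are dropped with a logged
#' count, since a cross-linked pair carries at least two protons. Scans
#' missing a charge are skipped with a warning.
#'
#' @param path Path to the spectra file.
#' @param format "mgf", "mzml", or "auto" (from the file extension).
#' @return A list of raw spectra; each element is a list with fields
#'   `scanId`, `precursorMz`, `precursorCharge`, `mz`, `intensity` (peaks
#'   sorted by m/z).
#' @export
readSpectra <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("spectra file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf"
      else if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
      else stop("cannot infer spectra format from extension: ", path)
  }
  specs <- switch(format, mgf = readMgf(path), mzml = readMzml(path))
  charges <- vapply(specs, function(s) s$precursorCharge, integer(1))
  nLow <- sum(charges < 2L)
  if (nLow > 0L) {
    message(nLow, " scan(s) with precursor charge < 2 skipped")
    specs <- specs[charges >= 2L]
  }
  specs
}

readMgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) == 0L) stop("no scans found in MGF file: ", path)
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF file (unbalanced BEGIN/END IONS): ", path)
  out <- vector("list", length(begins))
  nSkipped <- 0L
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    isKv <- grepl("=", block, fixed = TRUE)
    kv <- block[isKv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      paste0("scan_", i)
    pep <- if ("PEPMASS" %in% keys) {
      as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "\\s+")[[1]][1])
    } else NA_real_
    charge <- if ("CHARGE" %in% keys) {
      ch <- trimws(vals[match("CHARGE", keys)])
      sgn <- if (grepl("-", ch, fixed = TRUE)) -1L else 1L
      sgn * as.integer(gsub("[^0-9]", "", ch))
    } else NA_integer_
    if (is.na(pep) || is.na(charge) || charge <= 0L) {
      warning("scan '", title, "' skipped: missing precursor m/z or charge")
      nSkipped <- nSkipped + 1L
      next
    }
    pk <- block[!isKv]
    pk <- pk[nzchar(trimws(pk))]
    mz <- numeric(0)
    int <- numeric(0)
    if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"), function(p)
        as.numeric(p[1:2])))
      ord <- order(m[, 1L])
      mz <- m[ord, 1L]
      int <- m[ord, 2L]
    }
    out[[i]] <- list(scanId = title, precursorMz = pep,
                     precursorCharge = as.integer(charge),
                     mz = mz, intensity = int)
  }
  out[!vapply(out, is.null, logical(1))]
}

readMzml <- function(path) {
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  ms2 <- which(hdr$msLevel == 2L)
  if (length(ms2) == 0L) stop("no MS2 scans in mzML file: ", path)
  out <- vector("list", length(ms2))
  for (i in seq_along(ms2)) {
    row <- hdr[ms2[i], ]
    sid <- if (!is.null(row$spectrumId) && nzchar(row$spectrumId))
      row$spectrumId else paste0("scan_", ms2[i])
    charge <- suppressWarnings(as.integer(row$precursorCharge))
    pmz <- row$precursorMZ
    if (is.na(charge) || charge <= 0L || is.na(pmz) || pmz <= 0) {
      warning("scan '", sid, "' skipped: missing precursor m/z or charge")
      next
    }
    p <- mzR::peaks(handle, ms2[i])
    ord <- order(p[, 1L])
    out[[i]] <- list(scanId = sid, precursorMz = pmz,
                     precursorCharge = charge,
                     mz = p[ord, 1L], intensity = p[ord, 2L])
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Remove the modal-intensity peaks from a spectrum
#'
#' Ion-trap CID spectra carry many low, heavily quantized noise peaks whose
#' intensity value repeats; the filter removes every peak whose intensity
#' equals the most frequent intensity value. Ties are removed together. If
#' every intensity is unique (modal frequency 1) the spectrum is returned
#' unchanged. If nothing survives the filter the spectrum is discarded
#' (returns NULL with a warning).
#'
#' @param spectrum A raw spectrum (see [readSpectra()]).
#' @return The filtered spectrum, or NULL if all peaks were removed.
#' @examples
#' s <- list(scanId = "s", precursorMz = 500, precursorCharge = 2,
#'           mz = c(100, 150, 200, 250, 300),
#'           intensity = c(5, 5, 5, 100, 200))
#' denoiseSpectrum(s)$intensity  # 100 200
#' @export
denoiseSpectrum <- function(spectrum) {
  int <- spectrum$intensity
  if (length(int) == 0L) stop("cannot de-noise an empty spectrum")
  u <- unique(int)
  freq <- tabulate(match(int, u))
  top <- max(freq)
  if (top <= 1L) return(spectrum)
  modal <- u[freq == top]
  keep <- !(int %in% modal)
  if (!any(keep)) {
    warning("spectrum '", spectrum$scanId,
            "' discarded: no peaks left after de-noising")
    return(NULL)
  }
  spectrum$mz <- spectrum$mz[keep]
  spectrum$intensity <- int[keep]
  spectrum
}

#' Vectorize a spectrum into a sparse unit vector
#'
#' Bins peak m/z values with bin width twice the fragment tolerance (floor
#' binning), sums co-binned intensities, and scales the vector to unit
#' Euclidean norm. The neutral precursor mass is
#' \code{(precursor m/z - proton) * charge}.
#'
#' @param spectrum A (de-noised) raw spectrum.
#' @param fragmentTol Fragment tolerance in Da; bin width is `2 * fragmentTol`.
#' @param sqrtIntensity Square-root transform intensities before binning.
#' @return A list with fields `scanId`, `precursorMass`, `precursorCharge`,
#'   `bins` (strictly increasing integer vector), `intensities` (unit norm).
#' @export
vectorizeSpectrum <- function(spectrum, fragmentTol, sqrtIntensity = FALSE) {
  if (length(spectrum$mz) == 0L) stop("cannot vectorize an empty spectrum")
  w <- 2 * fragmentTol
  int <- spectrum$intensity
  if (sqrtIntensity) int <- sqrt(int)
  bins <- as.integer(floor(spectrum$mz / w))
  u <- sort(unique(bins))
  val <- vapply(split(int, factor(bins, levels = u)), sum, numeric(1),
                USE.NAMES = FALSE)
  nrm <- sqrt(sum(val * val))
  if (nrm == 0) stop("spectrum '", spectrum$scanId, "' has zero total intensity")
  list(scanId = spectrum$scanId,
       precursorMass = (spectrum$precursorMz - MASS_PROTON) *
         spectrum$precursorCharge,
       precursorCharge = spectrum$precursorCharge,
       bins = u, intensities = val / nrm)
}

#' Build the mass-sorted spectrum index
#'
#' De-noises (optionally) and vectorizes raw spectra, then sorts them by
#' neutral precursor mass. Spectra emptied by de-noising are dropped with a
#' warning.
#'
#' @param spectra List of raw spectra from [readSpectra()].
#' @param config An [XLSearchConfig] (supplies the fragment tolerance and the
#'   intensity transform).
#' @param denoise Apply [denoiseSpectrum()] first (default TRUE).
#' @return A [SpectrumIndex].
#' @export
buildSpectrumIndex <- function(spectra, config = SearchConfig(),
                               denoise = TRUE) {
  stopifnot(length(spectra) >= 1L)
  if (denoise) {
    spectra <- lapply(spectra, denoiseSpectrum)
    spectra <- spectra[!vapply(spectra, is.null, logical(1))]
    if (length(spectra) == 0L) stop("all spectra were emptied by de-noising")
  }
  proc <- lapply(spectra, vectorizeSpectrum,
                 fragmentTol = config@fragmentTol,
                 sqrtIntensity = config@sqrtIntensity)
  p <- vapply(proc, function(s) s$precursorMass, numeric(1))
  ord <- order(p)
  methods::new("SpectrumIndex",
    scanId = vapply(proc, function(s) s$scanId, character(1))[ord],
    precursorMass = p[ord],
    precursorCharge = vapply(proc, function(s) s$precursorCharge,
                             integer(1))[ord],
    bins = lapply(proc, function(s) s$bins)[ord],
    intensities = lapply(proc, function(s) s$intensities)[ord],
    binWidth = 2 * config@fragmentTol
  )
}

#' @describeIn SpectrumIndex-class Number of spectra in the index.
#' @param x A [SpectrumIndex].
#' @export
setMethod("length", "SpectrumIndex", function(x) length(x@scanId))

#' @rdname index-queries
#' @export
setMethod("spectraWithMassAtLeast", "SpectrumIndex", function(x, threshold) {
  n <- length(x@precursorMass)
  from <- findInterval(threshold, x@precursorMass, left.open = TRUE) + 1L
  if (from > n) integer(0) else from:n
})

#' @rdname index-queries
#' @export
setMethod("largestPrecursorMass", "SpectrumIndex", function(x) {
  n <- length(x@precursorMass)
  if (n == 0L) stop("empty spectrum index")
  x@precursorMass[n]
})

setMethod("show", "SpectrumIndex", function(object) {
  n <- length(object)
  cat("SpectrumIndex with", n, "processed spectra\n")
  if (n) cat(sprintf("  precursor mass range %.4f..%.4f Da, bin width %g\n",
                     object@precursorMass[1L], object@precursorMass[n],
                     object@binWidth))
  invisible(object)
})
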