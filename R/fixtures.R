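#' Generate a synthetic protein FASTA database
#'
#' Random protein sequences over the 20 standard amino acids with lysine and
#' arginine enriched to about 12 percent combined, so tryptic digestion
#' yields realistically sized peptides with linkable lysines. Fully
#' deterministic for a fixed seed. User-supplied sequences (e.g. synthetic
#' peptides to plant) can be appended as extra records.
#'
#' @param nProteins Number of random proteins.
#' @param lengthRange Protein length bounds (residues), default 100..300.
#' @param seed RNG seed; reruns are byte-identical.
#' @param appendSequences Named character vector of extra sequences appended
#'   after the random proteins (names become accessions; unnamed entries get
#'   SYNPEP accessions).
#' @param path Output FASTA path.
#' @return Invisibly, the protein data.frame (`accession`, `sequence`).
#' @export
generateFasta <- function(nProteins, lengthRange = c(100L, 300L), seed = 1L,
                          appendSequences = character(), path) {
  stopifnot(nProteins >= 1L, length(lengthRange) == 2L,
            lengthRange[1] >= 1L, lengthRange[1] <= lengthRange[2])
  set.seed(seed)
  probs <- rep(0.88 / 18, 20)
  names(probs) <- AA_LETTERS
  probs[c("K", "R")] <- 0.06
  lens <- sample(lengthRange[1]:lengthRange[2], nProteins, replace = TRUE)
  seqs <- vapply(lens, function(n)
    paste(sample(AA_LETTERS, n, replace = TRUE, prob = probs), collapse = ""),
    character(1))
  acc <- sprintf("SYN_P%04d", seq_len(nProteins))
  if (length(appendSequences)) {
    extraAcc <- names(appendSequences)
    if (is.null(extraAcc)) extraAcc <- rep("", length(appendSequences))
    blank <- !nzchar(extraAcc)
    extraAcc[blank] <- sprintf("SYNPEP%02d", which(blank))
    acc <- c(acc, extraAcc)
    seqs <- c(seqs, unname(appendSequences))
  }
  aas <- Biostrings::AAStringSet(seqs)
  names(aas) <- acc
  Biostrings::writeXStringSet(aas, path)
  invisible(data.frame(accession = acc, sequence = seqs,
                       stringsAsFactors = FALSE))
}

#' Generate one planted cross-linked spectrum
#'
#' Builds the complete theoretical peak list of a cross-linked pair (every
#' linear and cross-linking b/y ion of both chains at fragment charges
#' 1..charge-1, capped by `maxFragmentCharge`) and optionally adds uniform
#' random noise peaks. Under the default "flat" intensity model noise peaks
#' all get intensity exactly 1 and signal peaks intensities near 100:
#' exactly 100 when the spectrum is noiseless (the binned experimental
#' vector is then exactly proportional to the theoretical ion-count vector,
#' so the true pair scores exactly 1), otherwise a narrow ladder of distinct
#' values starting at 100, which makes the repeated noise intensity the
#' unique modal value so the modal-intensity filter removes exactly the
#' noise whatever the signal/noise peak ratio. The "hard" model draws all
#' intensities from one uniform distribution, so de-noising no longer
#' separates signal from noise.
#'
#' @param alphaSeq,betaSeq Chain sequences.
#' @param alphaSite,betaSite 1-based link sites.
#' @param scanId Scan identifier written to the MGF TITLE.
#' @param charge Precursor charge (>= 2).
#' @param noisePeaks Number of uniform random noise peaks.
#' @param intensityModel "flat" (signal 100 / noise 1) or "hard" (both drawn
#'   from U(50, 150)).
#' @param linkerMass Cross-linker mass (Da).
#' @param maxFragmentCharge Fragment charge cap.
#' @return A raw spectrum list (see [readSpectra()]) with an extra `truth`
#'   field recording the planted pair.
#' @export
generateSpectrum <- function(alphaSeq, alphaSite, betaSeq, betaSite,
                             scanId = "planted_1", charge = 2L,
                             noisePeaks = 0L,
                             intensityModel = c("flat", "hard"),
                             linkerMass = MASS_DSS,
                             maxFragmentCharge = 4L) {
  intensityModel <- match.arg(intensityModel)
  stopifnot(charge >= 2L)
  p <- peptideMass(alphaSeq) + peptideMass(betaSeq) + linkerMass
  zmax <- max(1L, min(maxFragmentCharge, charge - 1L))
  masses <- c(fragmentNeutralMasses(alphaSeq, alphaSite, p),
              fragmentNeutralMasses(betaSeq, betaSite, p))
  z <- seq_len(zmax)
  mz <- as.vector(outer(masses, z, function(m, z) (m + z * MASS_PROTON) / z))
  int <- if (intensityModel == "flat") {
    if (noisePeaks > 0L) {
      # distinct signal intensities: the repeated value-1 noise is then the
      # unique modal intensity and de-noising removes exactly the noise,
      # whatever the signal/noise peak ratio. With a constant signal
      # intensity the signal itself becomes the mode as soon as signal
      # peaks outnumber noise peaks, and the filter would erase it.
      100 + 0.01 * (seq_along(mz) - 1)
    } else {
      # noiseless: a constant intensity keeps the binned experimental
      # vector exactly proportional to the theoretical ion-count vector
      rep(100, length(mz))
    }
  } else {
    stats::runif(length(mz), 50, 150)
  }
  if (noisePeaks > 0L) {
    nmz <- stats::runif(noisePeaks, 100, max(mz))
    nint <- if (intensityModel == "flat") rep(1, noisePeaks) else
      stats::runif(noisePeaks, 50, 150)
    mz <- c(mz, nmz)
    int <- c(int, nint)
  }
  ord <- order(mz)
  list(scanId = scanId,
       precursorMz = (p + charge * MASS_PROTON) / charge,
       precursorCharge = as.integer(charge),
       mz = mz[ord], intensity = int[ord],
       truth = list(alphaSeq = alphaSeq, alphaSite = as.integer(alphaSite),
                    betaSeq = betaSeq, betaSite = as.integer(betaSite),
                    charge = as.integer(charge),
                    noisePeaks = as.integer(noisePeaks)))
}

#' Write spectra to MGF
#'
#' Writes the MGF dialect the reader accepts (BEGIN IONS / TITLE / PEPMASS /
#' CHARGE / peak lines). Fixed number formats make reruns byte-identical.
#'
#' @param spectra List of raw spectra.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$scanId),
                 sprintf("PEPMASS=%.8f", s$precursorMz),
                 sprintf("CHARGE=%d+", s$precursorCharge),
                 sprintf("%.6f %.6f", s$mz, s$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Write spectra to mzML
#'
#' A minimal, schema-conformant mzML 1.1 writer (64-bit little-endian floats,
#' no compression) so that fixtures exist in both supported input formats.
#'
#' @inheritParams writeMgf
#' @return `path`, invisibly.
#' @export
writeMzml <- function(spectra, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writeMzml needs the 'jsonlite' package for base64 encoding")
  enc <- function(x) {
    # base64_enc wraps long output; mzML needs one unbroken token
    gsub("[\r\n]", "",
         jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                       endian = "little")))
  }
  spec <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    emz <- enc(s$mz)
    eint <- enc(s$intensity)
    paste0(
      sprintf('      <spectrum index="%d" id="%s" defaultArrayLength="%d">\n',
              i - 1L, s$scanId, length(s$mz)),
      '        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>\n',
      '        <cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>\n',
      '        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
      '        <precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>\n',
      sprintf('          <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.8f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
              s$precursorMz),
      sprintf('          <cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>\n',
              s$precursorCharge),
      '        </selectedIon></selectedIonList>',
      '<activation><cvParam cvRef="MS" accession="MS:1000133" name="collision-induced dissociation" value=""/></activation></precursor></precursorList>\n',
      '        <binaryDataArrayList count="2">\n',
      sprintf('          <binaryDataArray encodedLength="%d">\n', nchar(emz)),
      '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
      sprintf('            <binary>%s</binary>\n', emz),
      '          </binaryDataArray>\n',
      sprintf('          <binaryDataArray encodedLength="%d">\n', nchar(eint)),
      '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
      sprintf('            <binary>%s</binary>\n', eint),
      '          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n      </spectrum>')
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '  <cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>\n',
    '  <fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/></fileContent></fileDescription>\n',
    '  <softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="xlexhaust fixture writer"/></software></softwareList>\n',
    '  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>\n',
    '  <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>\n',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    sprintf('    <spectrumList count="%d" defaultDataProcessingRef="dp">\n',
            length(spectra)),
    paste(spec, collapse = "\n"), "\n",
    '    </spectrumList>\n  </run>\n</mzML>'
  )
  writeLines(xml, path)
  invisible(path)
}

#' Generate a full planted cross-link dataset
#'
#' Emulates a small cross-linking experiment: a random FASTA database, a set
#' of cross-linked chain pairs drawn from its linkable tryptic peptides, and
#' one spectrum per pair, written as MGF together with a truth manifest. The
#' planted chains are restricted to short tryptic peptides (default 5..12
#' residues), matching the scale of synthetic-peptide cross-linking
#' experiments and keeping each spectrum's signal peak count below typical
#' noise-peak counts so the modal-intensity filter behaves as designed.
#'
#' @param nProteins Number of database proteins.
#' @param nSpectra Number of planted spectra.
#' @param noisePeaks Noise peaks per spectrum.
#' @param charge Precursor charge of planted spectra.
#' @param plantMaxLength Maximum length of planted chains.
#' @param seed RNG seed.
#' @param dir Output directory (created if needed).
#' @param config An [XLSearchConfig]; supplies digestion rules and linker
#'   mass.
#' @param intensityModel Passed to [generateSpectrum()].
#' @param decoyPairs If TRUE, pairs are drawn from decoy chains instead
#'   (exercises TD/DD bookkeeping).
#' @return A list with `fastaPath`, `mgfPath`, `truthPath`, `truth` (a
#'   data.frame), and `proteins`.
#' @export
generatePlantedDataset <- function(nProteins = 20L, nSpectra = 30L,
                                   noisePeaks = 0L, charge = 2L,
                                   plantMaxLength = 12L, seed = 1L,
                                   dir = tempfile("xlfixture"),
                                   config = SearchConfig(),
                                   intensityModel = "flat",
                                   decoyPairs = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fastaPath <- file.path(dir, "database.fasta")
  proteins <- generateFasta(nProteins, seed = seed, path = fastaPath)
  index <- buildChainIndex(proteins, config)
  tab <- chainTable(index)
  pool <- which(tab$isDecoy == decoyPairs &
                  nchar(tab$sequence) >= config@minLength &
                  nchar(tab$sequence) <= plantMaxLength)
  if (length(pool) < 2L) stop("too few linkable chains to plant pairs")
  set.seed(seed + 1L)
  spectra <- vector("list", nSpectra)
  truth <- vector("list", nSpectra)
  for (s in seq_len(nSpectra)) {
    pair <- sample(pool, 2L, replace = FALSE)
    # sample() treats a length-1 vector as 1:n, so index then subset
    siteA <- tab$linkSites[[pair[1L]]][sample(length(tab$linkSites[[pair[1L]]]), 1L)]
    siteB <- tab$linkSites[[pair[2L]]][sample(length(tab$linkSites[[pair[2L]]]), 1L)]
    sp <- generateSpectrum(tab$sequence[pair[1L]], siteA,
                           tab$sequence[pair[2L]], siteB,
                           scanId = sprintf("planted_%03d", s),
                           charge = charge, noisePeaks = noisePeaks,
                           intensityModel = intensityModel,
                           linkerMass = config@linkerMass,
                           maxFragmentCharge = config@maxFragmentCharge)
    spectra[[s]] <- sp
    truth[[s]] <- data.frame(scan_id = sp$scanId,
                             alpha_sequence = sp$truth$alphaSeq,
                             alpha_site = sp$truth$alphaSite,
                             beta_sequence = sp$truth$betaSeq,
                             beta_site = sp$truth$betaSite,
                             charge = sp$truth$charge,
                             noise_peaks = sp$truth$noisePeaks,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  mgfPath <- file.path(dir, "spectra.mgf")
  writeMgf(spectra, mgfPath)
  truthPath <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fastaPath = fastaPath, mgfPath = mgfPath, truthPath = truthPath,
       truth = truth, proteins = proteins)
}

#' Compare search results against a planted truth manifest
#'
#' A planted scan counts as recovered when the result table contains a PSM
#' for that scan whose chain sequences and link sites match the planted pair,
#' in either order.
#'
#' @param psms A PSM data.frame (all PSMs for the rank-1 rate; the accepted
#'   subset for recall after filtering).
#' @param truth Truth data.frame from [generatePlantedDataset()] (or read
#'   from its TSV).
#' @return A list with `recall` (fraction of planted scans recovered),
#'   `precision` (fraction of reported planted-scan PSMs that match truth),
#'   `rank1Rate` (alias of recall over the supplied table), and the logical
#'   vector `recovered`.
#' @export
evaluateResults <- function(psms, truth) {
  pairKey <- function(s1, p1, s2, p2) {
    a <- paste(s1, p1, sep = "#")
    b <- paste(s2, p2, sep = "#")
    ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
  }
  truthKey <- pairKey(truth$alpha_sequence, truth$alpha_site,
                      truth$beta_sequence, truth$beta_site)
  hit <- match(truth$scan_id, psms$scan_id)
  found <- !is.na(hit)
  match_ <- found
  match_[found] <- pairKey(psms$alpha_sequence[hit[found]],
                           psms$alpha_site[hit[found]],
                           psms$beta_sequence[hit[found]],
                           psms$beta_site[hit[found]]) == truthKey[found]
  nReported <- sum(found)
  list(recall = mean(match_),
       precision = if (nReported) sum(match_) / nReported else NA_real_,
       rank1Rate = mean(match_),
       recovered = match_)
}
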