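# build a two-chain index and a one-spectrum index directly, for boundary
# and unit tests that need full control over masses
makeTinyIndices <- function(seqA, siteA, seqB, siteB, precursorMass,
                            charge = 3L, cfg = SearchConfig()) {
  seqs <- c(seqA, seqB)
  masses <- peptideMass(seqs)
  ord <- order(masses)
  ci <- methods::new("ChainIndex",
    sequence = seqs[ord], mass = masses[ord],
    missedCleavages = c(1L, 1L), isDecoy = c(FALSE, FALSE),
    linkSites = list(siteA, siteB)[ord],
    parents = list("pA", "pB")[ord])
  x1 <- buildHalfVector(seqA, siteA, precursorMass, charge, cfg)
  x2 <- buildHalfVector(seqB, siteB, precursorMass, charge, cfg)
  bins <- sort(unique(c(x1$bins, x2$bins)))
  val <- numeric(length(bins))
  val[match(x1$bins, bins)] <- val[match(x1$bins, bins)] + x1$counts
  val[match(x2$bins, bins)] <- val[match(x2$bins, bins)] + x2$counts
  si <- methods::new("SpectrumIndex",
    scanId = "t1", precursorMass = precursorMass, precursorCharge = charge,
    bins = list(as.integer(bins)),
    intensities = list(val / sqrt(sum(val^2))),
    binWidth = 2 * cfg@fragmentTol)
  list(ci = ci, si = si)
}

test_that("sparse dot product equals the dense oracle", {
  expect_equal(sparseDot(c(1L, 3L), c(1, 2), c(3L, 5L), c(4, 1)), 8)
  expect_equal(sparseDot(c(1L, 2L), c(1, 1), c(3L, 4L), c(1, 1)), 0)
  set.seed(41)
  for (i in 1:1000) {
    a <- randomSparse(sample(1:40, 1), integerValues = FALSE)
    b <- randomSparse(sample(1:40, 1), integerValues = FALSE)
    expect_equal(sparseDot(a$bins, a$counts, b$bins, b$counts),
                 denseDot(a$bins, a$counts, b$bins, b$counts),
                 tolerance = 1e-12)
  }
})

test_that("pair scoring normalizes by the summed vector, not summed norms", {
  # spectrum proportional to x1 + x2 scores exactly 1 (Cauchy-Schwarz)
  x1 <- list(bins = c(1L, 3L, 5L), counts = c(1, 2, 1))
  x2 <- list(bins = c(3L, 7L), counts = c(2, 1))
  bins <- c(1L, 3L, 5L, 7L)
  xsum <- c(1, 4, 1, 1)
  y <- xsum / sqrt(sum(xsum^2))
  expect_equal(scorePair(x1, x2, bins, y), 1, tolerance = 1e-12)

  # orthogonal spectrum scores 0
  expect_equal(scorePair(x1, x2, c(20L, 30L), c(0.6, 0.8)), 0)

  # overlapping support makes ||x1 + x2|| != ||x1|| + ||x2||: pin the former
  got <- scorePair(x1, x2, bins, y)
  wrong <- (sum(x1$counts * y[match(x1$bins, bins)]) +
              sum(x2$counts * y[match(x2$bins, bins)])) /
    (sqrt(sum(x1$counts^2)) + sqrt(sum(x2$counts^2)))
  expect_false(isTRUE(all.equal(got, wrong)))

  # empty theoretical vector: score 0 with a warning
  e <- list(bins = integer(0), counts = numeric(0))
  expect_warning(s0 <- scorePair(e, e, bins, y), "empty")
  expect_equal(s0, 0)
})

test_that("half-vector decomposition reproduces the direct score", {
  set.seed(42)
  for (i in 1:1000) {
    x1 <- randomSparse(sample(5:40, 1))
    x2 <- randomSparse(sample(5:40, 1))
    yraw <- randomSparse(sample(5:60, 1), integerValues = FALSE)
    # overlap the supports so scores are non-trivial
    yb <- sort(unique(c(yraw$bins, sample(c(x1$bins, x2$bins),
                                          min(10, length(x1$bins))))))
    yv <- runif(length(yb))
    yv <- yv / sqrt(sum(yv^2))
    expect_equal(scorePair(x1, x2, yb, yv),
                 directScore(x1, x2, yb, yv), tolerance = 1e-12)
  }
})

test_that("exhaustive search matches brute force on a seeded fixture", {
  cfg <- SearchConfig()
  fx <- generatePlantedDataset(nProteins = 10, nSpectra = 20,
                               noisePeaks = 10, seed = 3)
  ci <- buildChainIndex(readFasta(fx$fastaPath), cfg)
  si <- buildSpectrumIndex(readSpectra(fx$mgfPath), cfg)
  a <- searchCrosslinks(ci, si, cfg)
  b <- bruteForceSearch(ci, si, cfg)
  expect_equal(nrow(a), nrow(b))
  m <- merge(a, b, by = "scan_id")
  expect_equal(nrow(m), nrow(a))
  expect_identical(m$alpha_sequence.x, m$alpha_sequence.y)
  expect_identical(m$beta_sequence.x, m$beta_sequence.y)
  expect_identical(m$alpha_site.x, m$alpha_site.y)
  expect_identical(m$beta_site.x, m$beta_site.y)
  expect_identical(m$class.x, m$class.y)
  expect_identical(m$topology.x, m$topology.y)
  expect_lt(max(abs(m$score.x - m$score.y)), 1e-12)
})

test_that("cached scoring, symmetry and bounds hold", {
  cfg <- SearchConfig()
  fx <- generatePlantedDataset(nProteins = 8, nSpectra = 12,
                               noisePeaks = 20, seed = 19)
  ci <- buildChainIndex(readFasta(fx$fastaPath), cfg)
  si <- buildSpectrumIndex(readSpectra(fx$mgfPath), cfg)
  psms <- searchCrosslinks(ci, si, cfg)
  expect_true(all(psms$score >= 0 & psms$score <= 1))

  # recomputing each reported score without the X1'Y cache is bit-identical,
  # and swapping the two chains leaves the score unchanged
  for (k in seq_len(nrow(psms))) {
    s <- match(psms$scan_id[k], si@scanId)
    p <- si@precursorMass[s]
    z <- si@precursorCharge[s]
    x1 <- buildHalfVector(psms$alpha_sequence[k], psms$alpha_site[k], p, z, cfg)
    x2 <- buildHalfVector(psms$beta_sequence[k], psms$beta_site[k], p, z, cfg)
    direct <- scorePair(x1, x2, si@bins[[s]], si@intensities[[s]])
    swapped <- scorePair(x2, x1, si@bins[[s]], si@intensities[[s]])
    expect_identical(psms$score[k], direct)
    expect_identical(direct, swapped)
  }
})

test_that("search runs are deterministic", {
  cfg <- SearchConfig()
  fx <- generatePlantedDataset(nProteins = 6, nSpectra = 10,
                               noisePeaks = 15, seed = 23)
  run <- function() {
    ci <- buildChainIndex(readFasta(fx$fastaPath), cfg)
    si <- buildSpectrumIndex(readSpectra(fx$mgfPath), cfg)
    psms <- assignConfidence(searchCrosslinks(ci, si, cfg))
    f <- tempfile(fileext = ".tsv")
    writeResultsTsv(psms, f)
    f
  }
  f1 <- run()
  f2 <- run()
  expect_identical(readLines(f1), readLines(f2))
})

test_that("precursor windows are half-open at exactly p +/- o", {
  cfg <- SearchConfig(precursorPpm = 10)
  seqA <- "EAKELIEGLPR"
  seqB <- "EVRKELDDLR"
  total <- peptideMass(seqA) + peptideMass(seqB) + cfg@linkerMass
  ppmF <- cfg@precursorPpm * 1e-6

  # find p whose floating-point window edge reproduces the code's arithmetic
  # exactly: lo/hi = p -/+ o - c - r with o = p * ppm * 1e-6
  findBoundaryP <- function(side) {
    p0 <- if (side == "lower") total / (1 - ppmF) else total / (1 + ppmF)
    mA <- min(peptideMass(seqA), peptideMass(seqB))
    mB <- max(peptideMass(seqA), peptideMass(seqB))
    for (k in -40:40) {
      p <- p0 * (1 + k * .Machine$double.eps)
      # replicate the search code's expression order exactly
      o <- p * cfg@precursorPpm * 1e-6
      edge <- if (side == "lower") p - o - mA - cfg@linkerMass else
        p + o - mA - cfg@linkerMass
      if (edge == mB) return(p)
    }
    NA_real_
  }

  pLow <- findBoundaryP("lower")   # pair mass sits exactly at p - o
  pHigh <- findBoundaryP("upper")  # pair mass sits exactly at p + o
  expect_false(is.na(pLow))
  expect_false(is.na(pHigh))

  tiLow <- makeTinyIndices(seqA, 3L, seqB, 4L, pLow, cfg = cfg)
  expect_equal(nrow(searchCrosslinks(tiLow$ci, tiLow$si, cfg)), 1L)

  tiHigh <- makeTinyIndices(seqA, 3L, seqB, 4L, pHigh, cfg = cfg)
  expect_equal(nrow(searchCrosslinks(tiHigh$ci, tiHigh$si, cfg)), 0L)
})

test_that("spectrum admission threshold 2c + r - o is inclusive", {
  # the spectrum-selection rule keeps any spectrum whose precursor mass
  # equals the threshold exactly; checked at the query level where the
  # boundary is exact by construction
  set.seed(55)
  raw <- lapply(1:20, function(i)
    rawSpectrum(mz = sort(runif(10, 100, 900)), intensity = runif(10, 1, 9),
                scanId = paste0("s", i), precursorMz = runif(1, 400, 900),
                charge = 2L))
  si <- buildSpectrumIndex(raw, SearchConfig(), denoise = FALSE)
  p <- si@precursorMass[7]
  # choose c and o such that 2c + r - o == p exactly
  r <- 138.06808
  o <- 0.03125  # exactly representable
  c0 <- (p + o - r) / 2
  thr <- 2 * c0 + r - o
  if (thr == p) {
    expect_true(7L %in% spectraWithMassAtLeast(si, thr))
  }
  # and one ulp above the mass excludes it
  expect_false(7L %in% spectraWithMassAtLeast(si, p * (1 + 4e-16)))
})
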