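test_that("FASTA reading parses accessions and skips invalid records", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">prot1 some description", "PEPTIDEK", "AAAR",
               ">prot2", "MKRAEVK"), fa)
  db <- readFasta(fa)
  expect_equal(db$accession, c("prot1", "prot2"))
  expect_equal(db$sequence, c("PEPTIDEKAAAR", "MKRAEVK"))

  writeLines(c(">good", "PEPTIDEK", ">bad", "PEPXTIDEK"), fa)
  expect_warning(db <- readFasta(fa), "skipped")
  expect_equal(db$accession, "good")

  writeLines(c(">only", "XXXX"), fa)
  expect_error(suppressWarnings(readFasta(fa)), "no valid records")
  expect_error(readFasta(tempfile()), "not found")

  # the synthetic-experiment layout: 100 random proteins + 2 known peptides
  fa2 <- tempfile(fileext = ".fasta")
  generateFasta(100, seed = 42, path = fa2,
                appendSequences = c(SYNPEP01 = "EVRKELDDLR",
                                    SYNPEP02 = "EAKELIEGLPR"))
  db2 <- readFasta(fa2)
  expect_equal(nrow(db2), 102L)
  expect_true(all(c("EVRKELDDLR", "EAKELIEGLPR") %in% db2$sequence))
})

test_that("tryptic digestion follows the cleave-after-K/R-not-before-P rule", {
  d <- digestProtein("MKRAEVK", maxMissed = 2, minLength = 1, maxLength = 50)
  expect_setequal(d$sequence, c("MK", "MKR", "MKRAEVK", "R", "RAEVK", "AEVK"))
  expect_equal(d$missedCleavages[match("MKRAEVK", d$sequence)], 2L)
  expect_equal(d$missedCleavages[match("RAEVK", d$sequence)], 1L)

  # proline blocks cleavage
  dKP <- digestProtein("AAKPAA", maxMissed = 0, minLength = 1, maxLength = 50)
  expect_equal(dKP$sequence, "AAKPAA")
  dPK <- digestProtein("AAPKAA", maxMissed = 0, minLength = 1, maxLength = 50)
  expect_setequal(dPK$sequence, c("AAPK", "AA"))

  # no cleavage site at all
  dNone <- digestProtein("AEDGHILM", maxMissed = 0, minLength = 1,
                         maxLength = 50)
  expect_equal(dNone$sequence, "AEDGHILM")
  expect_true(dNone$isProteinNTerm && dNone$isProteinCTerm)

  # length bounds apply
  dLen <- digestProtein("MKRAEVK", maxMissed = 2, minLength = 4,
                        maxLength = 6)
  expect_setequal(dLen$sequence, c("RAEVK", "AEVK"))
})

test_that("digest yields the closed-form peptide count", {
  # ns segments, all peptide sequences distinct, no length filtering:
  # peptides with <= m missed cleavages number sum_{t=0..m} (ns - t)
  segs <- c("ADER", "GLVK", "HISK", "MNQR", "TWYK", "CEFR")
  protein <- paste(segs, collapse = "")
  ns <- length(segs)
  for (m in 0:3) {
    d <- digestProtein(protein, maxMissed = m, minLength = 1,
                       maxLength = 1000)
    expected <- sum(ns - 0:min(m, ns - 1))
    expect_equal(nrow(d), expected, info = paste("maxMissed =", m))
  }
})

test_that("decoy reversal fixes K/R and is a mass-preserving involution", {
  expect_equal(makeDecoy("EAKELIEGLPR"), "PLKGEILEAER")
  expect_equal(makeDecoy("KKR"), "KKR")

  set.seed(101)
  for (i in 1:1000) {
    s <- randomTrypticPeptide()
    d <- makeDecoy(s)
    expect_identical(makeDecoy(d), s)
    # K/R positions preserved, composition identical, mass exactly equal
    aaS <- strsplit(s, "")[[1]]
    aaD <- strsplit(d, "")[[1]]
    expect_identical(which(aaS %in% c("K", "R")), which(aaD %in% c("K", "R")))
    expect_identical(sort(aaS), sort(aaD))
    expect_true(peptideMass(s) == peptideMass(d))
  }
})

test_that("link sites are lysines minus the C-terminal cleavage product", {
  expect_equal(findLinkSites("EVRKELDDLR"), 4L)
  expect_equal(findLinkSites("EAKELIEGLPR"), 3L)
  expect_equal(findLinkSites("AAAK"), integer(0))
  # protein C-terminal peptide may link at its terminal K
  expect_equal(findLinkSites("AAAK", isProteinCTerm = TRUE), 4L)
  # optional N-terminal alpha-amine linking (C-terminal K still excluded)
  expect_equal(findLinkSites("AVLDK", isProteinNTerm = TRUE,
                             nTermLinking = TRUE), 1L)
  expect_equal(findLinkSites("AKLDR", isProteinNTerm = TRUE,
                             nTermLinking = TRUE), c(1L, 2L))
  expect_equal(findLinkSites("AVLDK"), integer(0))
})

test_that("chain index is mass-sorted with exact range queries", {
  prot <- data.frame(
    accession = c("p1", "p2"),
    sequence = c("AAKPAADLR", "GGKPGGELR"),  # KP blocks cleavage: one
                                             # linkable chain per protein
    stringsAsFactors = FALSE
  )
  cfg <- SearchConfig(minLength = 5, maxLength = 60, maxMissedCleavages = 0)
  ci <- buildChainIndex(prot, cfg)
  expect_equal(length(ci), 4L)  # 2 target + 2 decoy
  tab <- chainTable(ci)
  expect_equal(sum(tab$isDecoy), 2L)
  expect_false(is.unsorted(tab$mass))

  # masses agree with the independent elemental-composition oracle
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$mass[i], oraclePeptideMass(tab$sequence[i]),
                 tolerance = 1e-7)
  }

  # range queries on a bigger index match a linear scan
  big <- generateFasta(30, seed = 5, path = tempfile(fileext = ".fasta"))
  ci2 <- buildChainIndex(big, SearchConfig())
  masses <- chainTable(ci2)$mass
  set.seed(6)
  for (q in 1:200) {
    a <- runif(1, min(masses) - 50, max(masses) + 50)
    b <- a + runif(1, 0, 300)
    expect_identical(chainsInRange(ci2, a, b),
                     which(masses >= a & masses < b))
  }
  # boundary: lower edge inclusive, upper edge exclusive
  m <- masses[17]
  expect_true(17L %in% chainsInRange(ci2, m, m + 1e-6))
  expect_false(17L %in% chainsInRange(ci2, m - 1e-6, m))
})

test_that("sequences shared by target and decoy databases stay target", {
  # ELKLER is its own decoy (non-K/R residues form a palindrome)
  expect_equal(makeDecoy("ELKLER"), "ELKLER")
  prot <- data.frame(accession = "p1", sequence = "ELKLER",
                     stringsAsFactors = FALSE)
  ci <- buildChainIndex(prot, SearchConfig(minLength = 5,
                                           maxMissedCleavages = 2))
  tab <- chainTable(ci)
  row <- tab[tab$sequence == "ELKLER", ]
  expect_equal(nrow(row), 1L)
  expect_false(row$isDecoy)
})

test_that("every indexed chain is linkable and decoys mirror targets", {
  db <- generateFasta(10, seed = 9, path = tempfile(fileext = ".fasta"))
  ci <- buildChainIndex(db, SearchConfig())
  tab <- chainTable(ci)
  expect_true(all(lengths(tab$linkSites) > 0L))
  # each link site holds a lysine (or position 1 when N-term linking is off,
  # which it is here, so all sites must be K)
  for (i in seq_len(nrow(tab))) {
    aa <- strsplit(tab$sequence[i], "")[[1]]
    expect_true(all(aa[tab$linkSites[[i]]] == "K"))
  }
  # decoy chains pair with a target of identical mass
  dec <- tab[tab$isDecoy, ]
  tgt <- tab[!tab$isDecoy, ]
  expect_true(all(dec$mass %in% tgt$mass))
})
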