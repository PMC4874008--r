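#' Read a protein database from FASTA
#'
#' Parses a FASTA file with [Biostrings::readAAStringSet()]. The accession is
#' the header token before the first whitespace; sequences are uppercased.
#' Records containing letters outside the 20 standard amino acids (e.g. X, B,
#' Z, U) are skipped with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `accession` and `sequence`, one row per
#'   valid record.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot parse FASTA file: ",
                                           conditionMessage(e)))
  if (length(aas) == 0L) stop("no records in FASTA file: ", path)
  acc <- sub("\\s.*$", "", names(aas))
  seqs <- toupper(as.character(aas))
  ok <- !grepl(sprintf("[^%s]", paste(AA_LETTERS, collapse = "")), seqs) &
    nchar(seqs) > 0L
  if (any(!ok)) {
    warning(sum(!ok), " record(s) skipped (non-standard residues): ",
            paste(utils::head(acc[!ok], 5), collapse = ", "))
  }
  acc <- acc[ok]
  seqs <- seqs[ok]
  if (length(seqs) == 0L) stop("no valid records in FASTA file: ", path)
  if (anyDuplicated(acc)) stop("duplicate accessions in FASTA file: ",
                               paste(unique(acc[duplicated(acc)]), collapse = ", "))
  data.frame(accession = acc, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Digest one protein sequence in silico
#'
#' Applies the configured cleavage rule (default trypsin: cleave C-terminal to
#' K or R, not before P) and enumerates every peptide with up to
#' `maxMissed` internal missed cleavage sites and length within
#' \code{[minLength, maxLength]}. Duplicate sequences within the protein are
#' collapsed, keeping the smallest missed-cleavage count and merging terminal
#' flags.
#'
#' @param sequence Protein sequence (one string).
#' @param maxMissed Maximum internal missed cleavages.
#' @param minLength,maxLength Peptide length bounds (residues).
#' @param cleavageResidues,cleavageException Enzyme rule, see [SearchConfig()].
#' @return A data.frame with columns `sequence`, `missedCleavages`,
#'   `isProteinNTerm`, `isProteinCTerm`.
#' @examples
#' digestProtein("MKRAEVK", maxMissed = 2, minLength = 1, maxLength = 50)
#' @export
digestProtein <- function(sequence, maxMissed = 2L, minLength = 5L,
                          maxLength = 60L, cleavageResidues = "KR",
                          cleavageException = "P") {
  stopifnot(length(sequence) == 1L, nchar(sequence) > 0L,
            maxMissed >= 0L, minLength >= 1L, minLength <= maxLength)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  cres <- strsplit(cleavageResidues, "", fixed = TRUE)[[1]]
  # cleavage after position i unless the next residue blocks it
  cut <- which(aa[-n] %in% cres)
  if (nzchar(cleavageException)) cut <- cut[aa[cut + 1L] != cleavageException]
  bounds <- c(0L, cut, n)
  nb <- length(bounds)
  out <- vector("list", nb - 1L)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + maxMissed)
    js <- (i + 1L):jmax
    starts <- bounds[i] + 1L
    ends <- bounds[js]
    len <- ends - starts + 1L
    keep <- len >= minLength & len <= maxLength
    if (!any(keep)) next
    js <- js[keep]
    ends <- ends[keep]
    out[[i]] <- data.frame(
      sequence = substring(sequence, starts, ends),
      missedCleavages = js - i - 1L,
      isProteinNTerm = starts == 1L,
      isProteinCTerm = ends == n,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(sequence = character(), missedCleavages = integer(),
                      isProteinNTerm = logical(), isProteinCTerm = logical(),
                      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(res$sequence)) {
    res <- do.call(rbind, lapply(split(res, res$sequence), function(d) {
      data.frame(sequence = d$sequence[1L],
                 missedCleavages = min(d$missedCleavages),
                 isProteinNTerm = any(d$isProteinNTerm),
                 isProteinCTerm = any(d$isProteinCTerm),
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(res) <- NULL
  res
}

#' Build a decoy peptide by reversal with K/R fixed
#'
#' Every lysine and arginine keeps its original position; the subsequence of
#' all remaining residues is reversed across the remaining positions. The
#' decoy therefore has the same length, residue composition, neutral mass and
#' link-site positions as the target, and the transform is an involution:
#' applying it twice returns the original sequence.
#'
#' @param sequences Character vector of peptide sequences.
#' @return Character vector of decoy sequences.
#' @examples
#' makeDecoy("EAKELIEGLPR")  # "PLKGEILEAER"
#' @export
makeDecoy <- function(sequences) {
  vapply(sequences, function(s) {
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(aa) == 0L) stop("empty peptide sequence")
    free <- !(aa %in% c("K", "R"))
    aa[free] <- rev(aa[free])
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Find linkable sites within a peptide chain
#'
#' Amine-reactive linkers (DSS, BS3) react with lysine side chains. A lysine
#' at the peptide C-terminus is not linkable unless the peptide is the protein
#' C-terminal peptide: a cross-linked lysine blocks tryptic cleavage, so an
#' internal linked lysine always sits left of the cleavage point. Position 1
#' of the protein N-terminal peptide can optionally be linkable through the
#' alpha-amine.
#'
#' @param sequence Peptide sequence.
#' @param isProteinNTerm,isProteinCTerm Whether the peptide is the first/last
#'   peptide of its parent protein.
#' @param nTermLinking Allow linking at position 1 of the protein N-terminal
#'   peptide.
#' @return Sorted integer vector of 1-based linkable positions (possibly
#'   empty).
#' @examples
#' findLinkSites("EVRKELDDLR")   # 4
#' findLinkSites("AAAK")         # integer(0): C-terminal K
#' @export
findLinkSites <- function(sequence, isProteinNTerm = FALSE,
                          isProteinCTerm = FALSE, nTermLinking = FALSE) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  sites <- which(aa == "K")
  if (!isProteinCTerm) sites <- sites[sites < n]
  if (nTermLinking && isProteinNTerm) sites <- union(1L, sites)
  sort(unique(as.integer(sites)))
}

#' Build the mass-sorted chain index
#'
#' Digests every target protein, builds the decoy database by applying
#' [makeDecoy()] to each tryptic peptide in place (one decoy protein per
#' target, accession prefixed with "DECOY_"), keeps only chains with at least
#' one linkable site, and sorts all chains by neutral monoisotopic mass.
#' Chains with identical sequences are merged across proteins; a sequence
#' present in both target and decoy databases is labelled target.
#'
#' @param proteins A data.frame with columns `accession` and `sequence`, as
#'   returned by [readFasta()].
#' @param config An [XLSearchConfig].
#' @return A [ChainIndex].
#' @export
buildChainIndex <- function(proteins, config = SearchConfig()) {
  stopifnot(is.data.frame(proteins), nrow(proteins) > 0L,
            all(c("accession", "sequence") %in% names(proteins)))
  if (any(grepl("^DECOY_", proteins$accession)))
    stop("target accessions must not use the reserved DECOY_ prefix")

  records <- vector("list", 2L * nrow(proteins))
  k <- 0L
  for (i in seq_len(nrow(proteins))) {
    peps <- digestProtein(proteins$sequence[i],
                          maxMissed = config@maxMissedCleavages,
                          minLength = config@minLength,
                          maxLength = config@maxLength,
                          cleavageResidues = config@cleavageResidues,
                          cleavageException = config@cleavageException)
    if (nrow(peps) == 0L) next
    sites <- lapply(seq_len(nrow(peps)), function(j) {
      findLinkSites(peps$sequence[j], peps$isProteinNTerm[j],
                    peps$isProteinCTerm[j], config@nTermLinking)
    })
    linkable <- lengths(sites) > 0L
    if (!any(linkable)) next
    peps <- peps[linkable, , drop = FALSE]
    sites <- sites[linkable]
    k <- k + 1L
    records[[k]] <- data.frame(
      sequence = peps$sequence,
      missedCleavages = peps$missedCleavages,
      isDecoy = FALSE,
      parent = proteins$accession[i],
      site = I(sites),
      stringsAsFactors = FALSE
    )
    # decoy: reverse each peptide with K/R fixed; K positions, and hence
    # link sites, are unchanged
    k <- k + 1L
    records[[k]] <- data.frame(
      sequence = makeDecoy(peps$sequence),
      missedCleavages = peps$missedCleavages,
      isDecoy = TRUE,
      parent = paste0("DECOY_", proteins$accession[i]),
      site = I(sites),
      stringsAsFactors = FALSE
    )
  }
  if (k == 0L) stop("no linkable chains found in the database")
  all <- do.call(rbind, records[seq_len(k)])

  grp <- split(seq_len(nrow(all)), all$sequence)
  seqs <- names(grp)
  isDecoy <- logical(length(grp))
  missed <- integer(length(grp))
  sites <- vector("list", length(grp))
  parents <- vector("list", length(grp))
  for (g in seq_along(grp)) {
    idx <- grp[[g]]
    tgt <- idx[!all$isDecoy[idx]]
    use <- if (length(tgt)) tgt else idx   # target label wins on collision
    isDecoy[g] <- length(tgt) == 0L
    missed[g] <- min(all$missedCleavages[use])
    sites[[g]] <- sort(unique(unlist(all$site[use])))
    parents[[g]] <- sort(unique(all$parent[use]))
  }
  mass <- peptideMass(seqs)
  ord <- order(mass, seqs)
  methods::new("ChainIndex",
    sequence = seqs[ord],
    mass = mass[ord],
    missedCleavages = missed[ord],
    isDecoy = isDecoy[ord],
    linkSites = sites[ord],
    parents = parents[ord]
  )
}

#' @describeIn ChainIndex-class Number of chains in the index.
#' @param x A [ChainIndex].
#' @export
setMethod("length", "ChainIndex", function(x) length(x@sequence))

#' @describeIn ChainIndex-class Chain table as a data.frame (`linkSites` and
#'   `parents` are list columns).
#' @param index A [ChainIndex].
#' @export
chainTable <- function(index) {
  stopifnot(methods::is(index, "ChainIndex"))
  data.frame(sequence = index@sequence, mass = index@mass,
             missedCleavages = index@missedCleavages,
             isDecoy = index@isDecoy,
             linkSites = I(index@linkSites), parents = I(index@parents),
             stringsAsFactors = FALSE)
}

#' @rdname index-queries
#' @export
setMethod("chainsInRange", "ChainIndex", function(x, lower, upper) {
  idx <- halfOpenRange(x@mass, lower, upper)
  idx
})

# indices i with lower <= v[i] < upper for sorted v (half-open interval)
halfOpenRange <- function(v, lower, upper) {
  if (upper <= lower) return(integer(0))
  from <- findInterval(lower, v, left.open = TRUE) + 1L
  to <- findInterval(upper, v, left.open = TRUE)
  if (from > to) integer(0) else from:to
}

setMethod("show", "ChainIndex", function(object) {
  n <- length(object)
  cat("ChainIndex with", n, "chains (",
      sum(!object@isDecoy), "target /", sum(object@isDecoy), "decoy )\n")
  if (n) cat(sprintf("  mass range %.4f..%.4f Da\n",
                     object@mass[1L], object@mass[n]))
  invisible(object)
})
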