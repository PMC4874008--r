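#' Classify PSMs by target/decoy origin of the two chains
#'
#' @param isDecoyAlpha,isDecoyBeta Logical vectors: whether each chain of the
#'   PSM comes from the decoy database.
#' @return Character vector: "TT" (both target), "DD" (both decoy), "TD"
#'   (one of each).
#' @export
classifyPsm <- function(isDecoyAlpha, isDecoyBeta) {
  stopifnot(length(isDecoyAlpha) == length(isDecoyBeta))
  ifelse(!isDecoyAlpha & !isDecoyBeta, "TT",
         ifelse(isDecoyAlpha & isDecoyBeta, "DD", "TD"))
}

#' Three-class target-decoy FDR estimation
#'
#' Every PSM falls in one of three classes by the origin of its two chains:
#' TT (both target), DD (both decoy), TD (one of each). At a score threshold
#' s, with t(s), d(s), f(s) the numbers of TT, DD and TD PSMs scoring at
#' least s, the false discovery rate among the accepted TT PSMs is estimated
#' as
#' \deqn{FDR(s) = (f(s) - d(s)) / t(s),}
#' the decoy-decoy count correcting for target-decoy PSMs whose target chain
#' is actually right. The estimate is clamped into [0, 1]; a threshold
#' accepting no TT PSM gets FDR 1.
#'
#' @param scores Numeric vector of PSM scores.
#' @param classes Character vector, "TT"/"TD"/"DD", aligned with `scores`.
#' @return A data.frame with one row per distinct observed score, descending:
#'   columns `score`, `t`, `d`, `f`, `fdr`.
#' @export
estimateFdr <- function(scores, classes) {
  stopifnot(length(scores) == length(classes),
            all(classes %in% c("TT", "TD", "DD")))
  if (length(scores) == 0L) {
    warning("empty PSM stratum; no FDR estimates")
    return(data.frame(score = numeric(), t = integer(), d = integer(),
                      f = integer(), fdr = numeric()))
  }
  u <- sort(unique(scores), decreasing = TRUE)
  grp <- match(scores, u)   # not factor(): distinct doubles may share a label
  t <- cumsum(tabulate(grp[classes == "TT"], nbins = length(u)))
  d <- cumsum(tabulate(grp[classes == "DD"], nbins = length(u)))
  f <- cumsum(tabulate(grp[classes == "TD"], nbins = length(u)))
  fdr <- ifelse(t == 0L, 1, pmin(1, pmax(0, (f - d) / t)))
  data.frame(score = u, t = t, d = d, f = f, fdr = fdr)
}

#' Convert FDR estimates to q-values
#'
#' The q-value at score t is the minimal FDR over all observed thresholds s
#' at which a PSM scoring t is still accepted (s <= t):
#' \deqn{q(t) = \min_{s \le t} FDR(s).}
#' q is therefore non-increasing as the score increases.
#'
#' @param fdrMap A data.frame from [estimateFdr()] (columns `score`, `fdr`).
#' @return The same data.frame with a `q` column appended, still sorted by
#'   descending score.
#' @export
fdrToQvalue <- function(fdrMap) {
  stopifnot(is.data.frame(fdrMap), nrow(fdrMap) >= 1L)
  asc <- order(fdrMap$score)
  q <- numeric(nrow(fdrMap))
  q[asc] <- cummin(fdrMap$fdr[asc])
  fdrMap$q <- q
  fdrMap
}

#' Annotate PSMs with FDR and q-values
#'
#' Intra-protein and inter-protein PSMs are independent hypotheses with very
#' different prior plausibility, so the FDR/q-value computation runs
#' separately within each topology stratum.
#'
#' @param psms A PSM data.frame from [searchCrosslinks()].
#' @return The same data.frame with `fdr` and `q_value` columns.
#' @export
assignConfidence <- function(psms) {
  stopifnot(is.data.frame(psms))
  psms$fdr <- rep(NA_real_, nrow(psms))
  psms$q_value <- rep(NA_real_, nrow(psms))
  for (topo in unique(psms$topology)) {
    idx <- which(psms$topology == topo)
    fmap <- estimateFdr(psms$score[idx], psms$class[idx])
    if (nrow(fmap) == 0L) next
    fmap <- fdrToQvalue(fmap)
    pos <- match(psms$score[idx], fmap$score)
    psms$fdr[idx] <- fmap$fdr[pos]
    psms$q_value[idx] <- fmap$q[pos]
  }
  psms
}

#' Filter identifications at a q-value threshold
#'
#' Keeps target-target PSMs with q-value at or below the threshold (each
#' topology stratum was filtered at its own q-values) and derives the
#' non-redundant peptide-pair list: unique (alpha sequence, alpha site, beta
#' sequence, beta site) combinations with their spectral count and best
#' score.
#'
#' @param psms A PSM data.frame with q-values (see [assignConfidence()]).
#' @param qCutoff q-value threshold (default 0.05).
#' @return A list with `psms` (accepted TT PSM rows) and `pairs` (the
#'   non-redundant pair table).
#' @export
filterResults <- function(psms, qCutoff = 0.05) {
  stopifnot(is.data.frame(psms), "q_value" %in% names(psms))
  acc <- psms[psms$class == "TT" & !is.na(psms$q_value) &
                psms$q_value <= qCutoff, , drop = FALSE]
  rownames(acc) <- NULL
  if (nrow(acc) == 0L) {
    pairs <- data.frame(alpha_sequence = character(), alpha_site = integer(),
                        beta_sequence = character(), beta_site = integer(),
                        topology = character(), n_spectra = integer(),
                        best_score = numeric(), stringsAsFactors = FALSE)
    return(list(psms = acc, pairs = pairs))
  }
  keyOf <- paste(acc$alpha_sequence, acc$alpha_site,
                 acc$beta_sequence, acc$beta_site, sep = "\r")
  grp <- split(seq_len(nrow(acc)), keyOf)
  pairs <- do.call(rbind, lapply(grp, function(idx) {
    data.frame(alpha_sequence = acc$alpha_sequence[idx[1L]],
               alpha_site = acc$alpha_site[idx[1L]],
               beta_sequence = acc$beta_sequence[idx[1L]],
               beta_site = acc$beta_site[idx[1L]],
               topology = acc$topology[idx[1L]],
               n_spectra = length(idx),
               best_score = max(acc$score[idx]),
               stringsAsFactors = FALSE)
  }))
  pairs <- pairs[order(pairs$alpha_sequence, pairs$beta_sequence,
                       pairs$alpha_site, pairs$beta_site), , drop = FALSE]
  rownames(pairs) <- NULL
  list(psms = acc, pairs = pairs)
}

#' Write a PSM table as TSV
#'
#' Numeric columns are rendered with `%.12g` so that repeated runs on
#' identical inputs produce byte-identical files.
#'
#' @param psms A PSM data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeResultsTsv <- function(psms, path) {
  out <- psms
  for (col in c("score", "fdr", "q_value")) {
    if (col %in% names(out)) out[[col]] <- sprintf("%.12g", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
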