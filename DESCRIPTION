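Package: xlexhaust
Title: Exhaustive Identification of Cross-Linked Peptides from Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A search engine for chemical cross-linking mass spectrometry
    (CX-MS) with non-cleavable amine-reactive linkers such as DSS and BS3.
    Proteins are digested in silico, decoys are built by reversing tryptic
    peptides with lysine and arginine held in place, and every
    mass-compatible peptide pair is scored against every CID tandem mass
    spectrum with a normalized cross-correlation. An additive two-chain
    decomposition of the theoretical spectrum lets the engine cache
    half-vector dot products and search the full quadratic pair space
    without heuristic candidate pre-selection. Confidence is assigned by a
    three-class (target-target, target-decoy, decoy-decoy) false discovery
    rate estimator converted to q-values, computed separately for intra- and
    inter-protein links. A fixture generator plants cross-linked pairs in
    synthetic databases and spectra so the whole pipeline can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    mzR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
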