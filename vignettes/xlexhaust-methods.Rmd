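---
title: "Exhaustive cross-linked peptide identification: model and methods"
author: "xlexhaust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive cross-linked peptide identification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlexhaust)
```

## The problem

Chemical cross-linking mass spectrometry (CX-MS) maps protein–protein
interactions by covalently joining spatially close lysines with a
bifunctional reagent (DSS or BS3, bridge mass r = 138.06808 Da), digesting
with trypsin, and fragmenting the cross-linked peptide pairs by CID. Each
tandem spectrum must then be matched against *pairs* of peptides, so the
candidate space grows quadratically with the database. Most engines prune
that space with heuristic pre-selection, which can silently discard the
correct pair. This package takes the opposite route: every mass-compatible
pair of chains (the two peptides of a cross-link) is scored against every
spectrum, and a decomposition of the score makes the exhaustive scan
affordable at desk scale.

## Scoring model

A candidate pair is turned into a theoretical spectrum X: all b- and y-ions
of both chains at fragment charges $1..\min(z-1, z_{max})$, where a fragment
containing the linked residue (a *cross-linking ion*) carries the linker and
the entire partner chain. With p the neutral precursor mass and c the
chain's own mass, a cross-linking ion with linear-counterpart mass $l_i$ has
mass

$$x_i = p - c + l_i,$$

because $p - c$ equals the partner mass plus the linker mass. A b-ion $b_i$
is cross-linking iff $i \ge$ link site; a y-ion $y_j$ iff
$j \ge m - \text{site} + 1$ for a chain of length m. Theoretical
intensities are ion multiplicities per m/z bin. The match score against the
binned, unit-normalized experimental vector $\tilde Y = Y / \lVert Y
\rVert$ is the normalized cross-correlation

$$\mathrm{score} = \frac{X^T Y}{\lVert X \rVert \lVert Y \rVert}
 = \frac{X_1^T \tilde Y + X_2^T \tilde Y}{\lVert X_1 + X_2 \rVert},$$

where $X_1$ and $X_2$ are the two chains' half-vectors. The additive split
is exact (it is an algebraic identity, asserted to 1e-12 in the tests), and
it is what makes exhaustiveness tractable: $X_1^T \tilde Y$ depends only on
(chain, site, spectrum), so when the outer loop holds a chain fixed, that
dot product is computed once and reused for every partner. Only the cheap
merged norm $\lVert X_1 + X_2 \rVert$ is pair-specific — note it must be
computed on the *summed* vector, not as $\lVert X_1 \rVert + \lVert X_2
\rVert$, because half-vectors can share bins.

Sparse vectors are kept as sorted (bin, value) pairs; dot products and
merged norms are two-pointer merges in C++, linear in the number of
occupied bins.

## Search organisation

Chains are digested in silico (trypsin: cleave after K/R, not before P; up
to 2 missed cleavages; length 5–60), restricted to chains with a linkable
lysine, and indexed by ascending neutral mass. Spectra are indexed by
ascending neutral precursor mass $p = (m/z - \mathrm{proton}) \cdot z$. The
outer loop walks chains ascending while $c$ is at most half the
(tolerance-adjusted) largest precursor mass minus the linker, so each
unordered pair is visited exactly once with the lighter chain outside. For
an outer chain c, admissible spectra satisfy $p \ge 2c + r - o$ (boundary
inclusive) with the per-spectrum absolute tolerance $o = p \cdot
\mathrm{ppm} \cdot 10^{-6}$; partner chains live in the half-open window
$[p - o - c - r,\; p + o - c - r)$, i.e. the pair's total mass lies in
$[p - o, p + o)$. All (site, site) combinations are scored and each
spectrum keeps its single best PSM. Ties are broken toward the
lexicographically smallest (alpha sequence, beta sequence, alpha site, beta
site), alpha being the lighter chain, so runs are bit-reproducible.

A deliberately naive `bruteForceSearch()` — triple loop, direct score on the
assembled X, no index, no cache, no C++ — serves as the oracle: on seeded
fixtures the indexed search must reproduce its best pairs and scores to
1e-12, which is the operational definition of "exhaustive" used throughout
the test suite.

## Link-site rules

Linkable sites are lysine side chains. A peptide C-terminal lysine is not
linkable (a cross-linked lysine blocks tryptic cleavage, so an internal
linked K always implies a missed cleavage), except on the protein
C-terminal peptide, where the terminal K was not produced by cleavage.
Linking through the protein N-terminal alpha-amine is supported behind a
flag, default off — amine-reactive linkers do react with protein N-termini,
but leaving it off keeps the default search space the conventional
lysine–lysine one.

## Decoys and confidence

Decoys are built per target protein by reversing each tryptic peptide with
K and R held in place. This preserves length, composition, mass, and
link-site positions exactly (mass conservation is asserted as exact
floating-point equality — chain masses are accumulated over the residue
composition in a fixed order precisely so that permutations sum
identically), and the transform is an involution. A sequence arising in
both databases is labelled target.

Every PSM is TT, TD or DD by the origin of its two chains. At score
threshold s, with t, d, f the counts of TT, DD, TD PSMs scoring ≥ s,

$$\mathrm{FDR}(s) = \frac{f(s) - d(s)}{t(s)},$$

clamped into [0, 1], with FDR 1 where t = 0. The DD subtraction corrects
for TD matches whose target chain is genuinely right. q-values are the
running minimum $q(t) = \min_{s \le t} \mathrm{FDR}(s)$, non-increasing in
score. Intra-protein and inter-protein PSMs are distinct hypothesis
classes with very different priors, so estimation and filtering run
separately per stratum; reported identifications are TT PSMs with
$q \le 0.05$ plus the non-redundant pair list.

## De-noising

Ion-trap CID spectra carry many low, quantized noise peaks whose intensity
value repeats exactly. The filter removes every peak whose intensity equals
the modal intensity value, provided the mode's frequency exceeds one; ties
at the modal frequency are removed together; a spectrum whose intensities
are all distinct passes unchanged. Two properties are worth knowing. The
filter is not idempotent (removing the mode can create a new mode), but it
can never remove a unique maximum-intensity peak. And on a pathological
spectrum whose intensities are all equal it removes everything — the
spectrum is then discarded with a warning. This is why the noiseless
fixture runs below disable de-noising: a noiseless planted spectrum has
constant intensity by construction and is exactly such a pathological case.

## Vectorization choices

The bin width is twice the fragment tolerance with floor binning, so a
theoretical m/z matches any experimental peak within ± tolerance of its bin
span; mismatches at bin edges are accepted as the cost of the dot-product
formulation. Experimental intensities enter raw (a square-root transform is
available behind a flag). Fragment charges run from 1 to precursor charge
minus one, capped at 4. Monoisotopic masses throughout (water 18.010565,
proton 1.00727646); no modifications, no neutral losses, no a-ions — CID
b/y only.

## What the synthetic fixtures emulate

The generator builds random protein databases (default 100–300 residues,
K/R enriched to ~12 % so tryptic peptides are realistically sized) and
plants cross-linked pairs drawn from the database's own linkable tryptic
chains, default length ≤ 12 at precursor charge 2 — the scale of
synthetic-peptide cross-linking experiments, two ~10-mers joined by DSS.
Planted spectra contain the complete theoretical fragment list plus
uniform-random noise peaks; everything is deterministic under a seed.

The default intensity model gives noise peaks intensity exactly 1 and
signal peaks intensities near 100. In a noiseless spectrum the signal
intensity is exactly constant, which makes the binned experimental vector
exactly proportional to the theoretical ion-count vector: the true pair
scores exactly 1 by Cauchy–Schwarz, a sharp end-to-end correctness check.
When noise is present the signal intensities are instead a narrow ladder of
distinct values, so the repeated noise value is always the unique mode and
de-noising removes exactly the noise regardless of the signal/noise peak
ratio — with a constant signal intensity the signal itself would become the
mode as soon as signal peaks outnumbered noise peaks, and the filter would
erase the spectrum's information content. A "hard" model draws all
intensities from one distribution for robustness exercises.

What passing fixture tests do *not* show about real data: real CID
intensities follow fragmentation propensities, not ion counts; real spectra
contain unfragmented precursors, isotope peaks and co-isolated
contaminants; and real noise is not uniform. The fixtures validate the
engine's bookkeeping — windows, indices, decomposition, FDR accounting —
not spectral realism.

## Numerical and degenerate-input choices

Chain masses are computed from residue composition in fixed amino-acid
order so that sequence permutations (decoys) get bit-identical masses. All
window comparisons are half-open $[\cdot, \cdot)$ with inclusive spectrum
admission at $2c + r - o$; boundary behaviour is pinned by tests that
construct precursors whose floating-point window edges coincide exactly
with chain masses. Empty theoretical vectors score 0 with a warning; empty
FDR strata yield empty maps with a warning; spectra emptied by de-noising
are dropped with a warning. Leucine/isoleucine are mass-identical, so a
chain and a decoy differing only by an I/L swap produce identical
theoretical spectra and tie exactly; the deterministic tie-break then picks
the lexicographically smaller sequence. This is the familiar I/L ambiguity
of mass spectrometry and the one systematic way a planted fixture pair can
be "lost" to its own decoy.

## Problem sizes used in validation

The test suite validates oracle equivalence on a 10-protein / 20-spectrum
fixture, planted-pair recovery on 20 proteins / 30 spectra (noiseless and
with 50 noise peaks per spectrum), and repeatability plus throughput on a
100-protein / 1000-spectrum search run twice, which completes in a few
minutes single-threaded. The acceptance script reruns the pipeline on a
100-protein / 300-spectrum planted dataset. These sizes were chosen as the
smallest at which the quadratic pair enumeration, the index queries and the
three-class FDR all operate in their intended regime.

## Known limitations

Only non-cleavable amine-reactive linkers and CID b/y fragmentation;
no mono-links or loop-links; no modifications; no semi-tryptic digestion;
no precursor mass correction or fragment de-isotoping; single-threaded by
design (determinism first). The FDR estimator is the standard three-class
construction and inherits its small-sample noisiness: with few PSMs per
stratum, q-values are coarse.
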