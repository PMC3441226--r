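---
title: "Coexpression trees and term enrichment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression trees and term enrichment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coextree)
```

## The problem

Genes that act together tend to be transcribed together. Given a large
compendium of expression profiles — probe-set level signal values across
hundreds or thousands of array samples — the profile of an uncharacterized
gene can be compared against every other gene's profile, and the genes
that covary with it ("guilt by association") suggest its function,
regulation, or disease involvement. `coextree` implements this analysis
end to end: per-sample normalization, all-against-all Pearson
correlation with significance, a Neighbour-Joining (NJ) tree over
correlation distances, height-adjustable coexpression neighbourhoods
around a driver probe set, annotation-term over-representation in those
neighbourhoods, and PWM scanning of promoters for co-regulation
hypotheses.

## Preprocessing model

**QC and deduplication.** Raw chip intensities are valid in
[0, 65535]; a sample fails QC if any value falls outside that range.
Public repositories contain resubmitted copies of the same arrays, which
would silently inflate correlations, so each sample's intensities are
serialized to a canonical string and hashed with MD5, SHA-1 and CRC32;
the concatenated 80-hex-character signature identifies exact duplicates,
of which one representative (smallest sample ID) is retained. The
serialization renders each value as its shortest exact decimal with no
separator; it is internally consistent and deterministic, but a
different serialization convention would produce different (equally
valid) signatures, so signatures are only comparable within this tool.

**Balanced selection.** To avoid over-representing heavily deposited
tissues, samples are selected as evenly as possible across tissues and,
within a tissue, across sample series. The algorithm is a deterministic
round robin: repeatedly pick from the non-exhausted tissue with the
fewest selections so far, within it the series with the fewest, ties
broken lexicographically. This guarantees per-tissue and per-series
counts differ by at most one unless a group is exhausted, and the output
is invariant to input order.

**Scaling.** Each sample is normalized with the standard trimmed-mean
procedure: drop the `floor(0.02 N)` largest and smallest order
statistics, and multiply the sample by the factor that brings the mean
of the remaining 96% to 500. Trim counts use `floor` (the tie rule is
not externally specified; any fixed convention works, and `floor` keeps
at least 96% of the data). Values are then rounded to the nearest 0.5,
with exact midpoints rounded half away from zero — again a convention,
as no external tie rule exists. Rounding makes normalization only
approximately idempotent: a second pass changes values by at most one
0.5-step for signals in the typical range.

## Correlation and significance

For profiles x, y over n samples the Pearson coefficient is the
covariance over the product of standard deviations; the package also
implements the algebraically identical "mean cross-product of
standardized variables" form, and the test suite verifies the two agree
to 1e-12 — a cheap guard against centering/scaling bugs. Under the null
of no association, `t = r sqrt(n - 2) / sqrt(1 - r^2)` is Student-t
with `nu = n - 2` degrees of freedom, giving a two-sided p-value.
Bonferroni correction multiplies p by the family size and caps at 1.

Two conventions required a decision:

* **Family size.** The correction formula reuses the symbol n, which is
  ambiguous between sample count and test count. `bonferroni()` takes an
  explicit `n_tests`, defaulting in the pipeline to `m (m - 1) / 2`, the
  number of unordered probe pairs in an all-against-all screen — the
  standard Bonferroni family for this design.
* **Degenerate profiles.** A constant (zero-variance) profile has no
  defined correlation; `pearson_r()` raises an error and
  `correlation_matrix()` excludes such rows with a warning rather than
  fabricating r = 0. Exactly collinear pairs (|r| = 1) are reported
  with p = e = 0, avoiding the division by zero in the t formula.

## Tree construction

The correlation matrix R becomes a distance matrix D = 1 − R
(range [0, 2]). The tree is built with canonical Saitou–Nei NJ:
join the pair minimizing
`Q(i,j) = (N − 2) d(i,j) − Σ_k d(i,k) − Σ_k d(j,k)`, with the standard
two-point branch lengths and reduction formula. Design choices:

* **Rooting.** NJ is unrooted; the final three nodes are joined at a
  trifurcating root, which is deterministic and matches common NJ
  output. An optional midpoint-rooting flag (via phangorn) produces a
  bifurcating root when a rooted display is preferred.
* **Ties.** Equal Q values are resolved by the lowest (i, j) index pair
  in canonical input order, making the topology fully deterministic.
* **Negative branches.** NJ can produce negative branch lengths on
  non-additive data; they are clamped to zero with the deficit added to
  the sister edge, which preserves all leaf-to-leaf path lengths, and
  the event is logged.
* **No heuristics.** Speed-up heuristics that promise "the same tree as
  the original algorithm" are unnecessary at package scale; the O(N³)
  canonical algorithm *is* the contract, and the suite verifies
  topological identity against an independent NJ implementation (ape)
  and exact recovery of generating topologies from additive matrices.

**Neighbourhoods.** The interactive notion of "enlarging or shrinking
the neighbourhood by adjusting the tree height" needs a formal
definition; this package defines the neighbourhood at height h as the
leaves of the clade under the deepest ancestor whose path length from
the query leaf is at most h. This is monotone in h (h = 0 gives the
query alone; h beyond the tree diameter gives all leaves) and is the
semantics used by `neighborhood()` and the CLI.

## Over-representation

For a list of c probe sets from a universe of n, a term carried by m
probe sets overall and k in the list is scored with the hypergeometric
upper tail `P(X >= k)`, summed in log space. The printed form of the
corresponding formula in the method's source is typographically garbled,
but its variable glossary is unambiguous, so the upper tail (equivalently
1 − P(X ≤ k − 1)) is implemented. Conventions:

* the universe n is the number of probe sets present in the annotation
  catalog, not a hard-coded chip size;
* the Benjamini–Hochberg family is all terms tested within one category
  for one query (per-category correction);
* the 0.05 trimming cutoff applies to the BH-adjusted value, since the
  stated significance measure is the corrected p-value;
* free-text categories (gene names, descriptions) are tokenized —
  uppercase alphanumeric tokens, minimum length 3, bare numerals and a
  small fixed stop-word list removed — while structured categories
  (GO, EC, OMIM, pathways, InterPro, TransFac) are matched as whole
  terms.

Both raw and adjusted p-values are reported, since external summaries of
comparable analyses do not always say which is printed.

## Promoter scanning

Promoters are the 500 bp immediately upstream of the TSS. Scoring
follows the information-weighted similarity of MATCH-style PWM search:
position i contributes `info(i) * freq(i, base_i)`, where
`info(i) = Σ_b freq(i,b) ln(4 freq(i,b))` (0 for uniform positions,
ln 4 for conserved ones); the sum is min-max normalized to [0, 1] using
the per-position best and worst bases. The matrix similarity (MSS) uses
all positions; the core similarity (CSS) uses the 5 consecutive
positions with the highest total information and acts as a pre-filter:
a window is reported only if CSS ≥ 0.95, then MSS ≥ 0.90 (the default
high-stringency cutoffs). Both strands are scanned by default — whether
the original analysis scanned one or both is unstated, and both-strand
scanning is the field's norm. Windows containing N are skipped. Zero
frequencies keep `0 ln 0 = 0` in the information vector; count matrices
are converted to frequencies with an optional pseudocount (default 0).

## Synthetic data: what it emulates and what it does not

`make_expression()` uses a latent-factor model on the log scale: module
members share `log x = mu_p + lambda f + sigma eps` with lambda
calibrated analytically so `corr = lambda^2 / (lambda^2 + sigma^2)`
equals the requested within-module correlation; background probes are
independent noise, and signals are exponentiated around a baseline of
~500 to mimic MAS5-like positive intensity scales. Defaults — 50 probe
sets, 100 samples, one 5-member module at target r = 0.9, log-noise SD
0.1 — reflect a desk-scale version of the structure the method is meant
to detect (tightly coexpressed functional modules against an
uncorrelated background). Exponentiation shrinks the realized Pearson r
slightly below the log-scale target (about 0.895 for target 0.9 at the
default noise level), which the recovery tolerances absorb.

The generator reproduces the *correlation structure* that Pearson + NJ
assume, not microarray physics: no probe-affinity effects, no
background correction artifacts, no heteroskedastic noise, no
cross-hybridization. A green recovery test therefore establishes that
the pipeline correctly detects planted linear coexpression at realistic
strength — not that it is robust to every failure mode of real chips.
Likewise `make_intensity_set()` plants *exact* duplicates (the hash
signature detects only exact copies, as in the original QC), and
`make_promoters()` plants consensus sites in i.i.d. background, so motif
recovery tests measure scanner correctness, not motif-discovery power.

## Numerical choices

* Phylip output uses a relaxed dialect (full whitespace-delimited names)
  because classic 10-character name truncation mangles 11-character
  probe-set IDs; a strict mode truncates for interoperability.
* Newick branch lengths are written with 9 significant digits
  (round-trip error < 1e-9 for correlation distances ≤ 2).
* Correlations are clamped to [−1, 1] after the vectorized
  cross-product to absorb last-bit floating-point excursions.
* The hypergeometric sum exponentiates shifted log terms to avoid
  overflow at large n.
* All generators take explicit seeds and are pure functions of their
  spec; the pipeline writes a manifest with configuration and output
  checksums so reruns can be verified byte for byte.

## Known limitations

* Dedup detects only exact intensity duplicates; near-duplicates
  (rescanned or renormalized arrays) pass.
* The NJ implementation is O(N³) in time and O(N²) memory: fine to a
  few thousand leaves, not for a full 54,613-probe-set chip in R alone.
* Enrichment treats annotation terms as flat labels; GO ancestor
  propagation is deliberately out of scope.
* The neighbourhood height semantics are this package's formalization
  of an interactive viewer behaviour and may differ from other tools'
  notions of cutting a dendrogram at a height.
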