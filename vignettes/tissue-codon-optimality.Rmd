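---
title: "Tissue codon optimality: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue codon optimality: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonopt)
```

This vignette is the package's account of the science it implements: the
estimators, the tunable parameters and why their defaults are what they
are, what the synthetic generators do and do not emulate, and the numerical
decisions taken where the design was genuinely open.

## From expression tables to PTR gene sets

Translational efficiency differs across tissues; its observable proxy here
is the per-gene, per-tissue **protein-to-mRNA ratio**. `compute_ptr()`
implements the standard filtering pipeline on paired protein and mRNA (TPM)
matrices:

1. protein abundances of exactly 0 become missing (a proteomics zero is a
   detection failure, not a measurement);
2. protein values are adjusted so each tissue's median equals the overall
   median — performed on log10 values, since proteomics intensities are
   log-scale quantities, with the ratio then taken on the linear scale;
3. mRNA below `tpm_threshold` (default 10 TPM) is treated as
   non-transcribed and the cell becomes missing.

Consequences worth knowing: PTR is only defined where both modalities pass
their filters, and the median adjustment absorbs per-tissue scale
differences but deliberately not the global scale — a global rescaling of
the protein matrix rescales all PTR values by the same factor, leaving
fold changes, and therefore the gene sets, untouched.

`define_gene_sets()` encodes the three-part tissue-specificity rule:
fold change above `fc = 2` versus the *average* of all other tissues
(strictly above — a tie at exactly 2 is excluded), the argmax across
tissues (strict mode only), and detection (defined PTR) in at least
`min_tissues = 3` tissues; low-PTR sets mirror all three. "Average" is the
arithmetic mean over non-missing values; the median is available via
`other_average = "median"` since the choice is not dictated by the rule
itself. The relaxed mode (conditions 1 and 3 only) exists for set-overlap
analyses, where the argmax condition would make per-tissue sets disjoint by
construction. Multi-sample datasets are collapsed to per-tissue medians
first (`collapse_samples()`), and an exclusion list (e.g. blood-secreted
proteins, whose site of synthesis and site of detection differ) can be
applied before set definition.

Cross-dataset agreement uses the union-minus-contradictions merge and a
one-tailed upper binomial test at success probability 1/2
(`concordance_test()`), counted per tissue over the genes labeled in both
datasets.

## The tissue signature

`tissue_signature()` is the package's central fit. Features are the
length-normalized frequencies of the 61 sense codons (each gene's vector
sums to 1, so gene length cancels); the classifier is a random forest of
`n_trees = 100` trees. Class imbalance between high- and low-PTR sets is
handled by **balanced resampling**: each of `n_iter = 100` iterations
subsamples the larger class to the smaller class's size without
replacement, then runs a stratified 5-fold cross-validation; the iteration
AUC is the mean over folds, and the report keeps the mean and standard
deviation over iterations. AUC is the rank-based (Mann–Whitney) form with
half credit for ties, so it is invariant to monotone transforms of the
scores. Reproducibility is by construction: per-iteration seeds are
`seed + iteration`.

Feature importances are the forest's mean impurity decrease (Gini),
averaged over folds and iterations and renormalized to sum 1. Impurity
importances are the natural choice for a pure ranking use — they are what
the forest itself uses — and the known caveats (bias toward high-cardinality
features) do not apply to features on a common frequency scale.
Permutation importance would be a drop-in alternative at ~5× the cost.

Importances carry no sign, so direction comes from `usage_ratio()`: the
elementwise ratio of mean per-gene usage in high vs low genes, with a
pseudocount of `1e-4` on both mean frequencies. The pseudocount is two
orders of magnitude below a typical codon frequency (~1/61), so it only
matters where a codon is essentially absent; for the 4096 codon-pair ratios
typical frequencies are ~1/3721 and the same default shrinks noticeably, so
pair analyses that feed the observed-vs-expected regression should pass a
smaller value (the package's own consistency test uses `1e-6`). A codon is
*enriched* iff its ratio is strictly greater than 1.

Mean usage over a gene set is the mean of per-gene normalized vectors, not
the pooled count vector: pooling would weight genes by length and let a few
long genes define a tissue's signature.

Control models (misframed +1/+2 codon usage, dinucleotide usage) reuse the
same pipeline; `compare_to_controls()` counts tissues where the control AUC
is strictly lower and applies the same upper binomial tail. Ties count
against the main model, the conservative direction.

`recursive_feature_elimination()` retrains after dropping the least
important feature until one remains, returning all 61 points. Its default
`n_iter = 5` is lower than the training default because the full curve
costs 61 retrainings; the parameter passes through for users who want the
full-budget curve.

## Codon pairs

Codon-pair usage counts **overlapping** adjacent in-frame pairs (window
stepping one codon). Disjoint counting would halve the data and make the
vector depend on the parity of the start position; overlapping counting is
also what makes the expected-ratio factorization testable, since both
margins of every window are single-codon frequencies. Pair features keep
stop-containing pairs so the space is exactly 64 × 64 = 4096.

Under independent codon draws the pair ratio factorizes:
`expected(AB) = ratio(A) × ratio(B)` (`expected_pair_ratio()`), and
`regress_observed_expected()` fits observed on expected by OLS, reporting
R², residual standard error and the model F-test p-value. On synthetic
gene sets where codons are drawn independently (150 genes × 6000 codons per
set) the package's own test observes R² ≈ 0.97 with slope ≈ 1 — the
residual shortfall from 1 is finite-count sampling noise in the rare-pair
ratios, which shrinks as set size grows. `pca_pair_ratios()` is a plain
centered PCA over tissues × 4096 ratios.

## Gene-design metrics

* **CAI** — geometric mean over the sequence's sense codons of
  w(c) = f(c)/max f within the synonymous family; Met, Trp and stops are
  excluded (their w is identically 1 and would only dilute). Reference
  counts get a 0.5-per-codon pseudocount (standard Sharp–Li practice), the
  one place CAI deviates from exact scale invariance — by under 1% for any
  realistically sized reference.
* **CPB** — mean Coleman codon-pair score over the sequence's adjacent
  sense pairs, CPS(AB) = ln[F(AB) / (F(A)F(B)/(F(aA)F(aB)) · F(aAaB))],
  with a pseudocount of 1 on reference pair counts. Pairs whose amino-acid
  pair is absent from the reference have no defined expectation and are
  dropped from the mean. A reference whose pairs match their marginal
  expectation scores 0 up to the pseudocount.
* **ENC** — Wright's estimator from family homozygosities
  F̂ = (nΣp² − 1)/(n − 1), class means F̄k, and
  Nc = singles + Σk (observed families in class k)/F̄k, with each class
  contribution capped at its maximum (families × k) and the total clipped
  at 61. Degenerate inputs are the real design question: families with
  fewer than 2 codons, or with F̂ ≤ 0 (which happens whenever every codon
  of a family appears exactly once), cannot contribute a usable
  homozygosity; if an entire class is unusable, each observed family
  contributes its observed distinct-codon count. This rule keeps the two
  analytic anchors exact — the all-61-codons sequence scores exactly 61,
  the one-codon-per-amino-acid sequence exactly 20 — and yields 2 for a
  Met/Trp-only sequence.
* **GC** — |GC fraction − target|, over the full CDS including the stop.
* **MFE / MFEini** — the folding score of nt 41–end and nt 1–40
  respectively (a sequence of ≤ 40 nt is all "ini"; an empty rest scores
  0). The split reflects the two known, opposite roles of mRNA structure:
  weak structure around the start improves initiation, strong structure in
  the body associates with transcript stability. The default backend is a
  dynamic-programming minimizer over nested structures with pair energies
  GC −3, AT −2, GT −1 and a minimum hairpin loop of 3 nt — a deliberately
  dependency-free, *non-thermodynamic* score whose contract is exactness
  (it provably equals exhaustive structure enumeration; the test suite
  checks all 16384 heptamers and random 12–14-mers) and monotone meaning
  (more negative = more stable). `backend = "vienna"` delegates to an
  external `RNAfold` binary for kcal/mol values; absolute numbers change,
  ranking direction does not.

## The optimizer

For each amino-acid position the codon is drawn from the synonymous family
with probability proportional to the signature importances (renormalized
within the family; a zero-importance family falls back to uniform); a drawn
codon is kept if enriched (ratio > 1), otherwise excluded and redrawn.
A useful identity: the first enriched codon reached by weighted
draw-without-replacement is distributed proportionally to the weights
*within the enriched subset*, so the implementation samples enriched codons
directly — same distribution, one draw. When a family has no enriched codon
the fallback fires (default: the codon with the largest ratio; largest
importance and reference usage are selectable), and the output flags the
affected positions.

Stop codons are never optimized: a trailing `*` (or the stop of a DNA
input, which is translated first) is copied through, defaulting to TAA.
`top_codons = k` restricts the enrich/deplete logic to the k
highest-importance codons; positions whose family contains none of them are
drawn from reference codon usage, mirroring the observation that a handful
of top codons already carries most of the discriminative signal.

`select_best()` filters (homopolymer runs ≥ 7 by default — at that length
synthesis fidelity and slippage become real concerns — plus an optional
motif blocklist), deduplicates, computes the requested metrics, converts
each column to ranks oriented so the requested direction is best, and
orders by mean rank. Rank aggregation was chosen over z-scores because the
metrics live on incommensurable scales and ranks are robust to outliers; a
z-score aggregate is available via `aggregate = "zscore"`. Ties break by
sequence content, so the result is invariant to pool order. The pool keeps
duplicates (it is an honest sample of the sampling distribution); only the
final ranked list deduplicates.

## What the synthetic generators emulate — and what they do not

`generate_cds()` draws amino acids uniformly and codons uniformly within
families, times a planted multiplicative bias for chosen codons. The
defaults of `generate_expression()` are log-normal mRNA with meanlog
log(50) and sdlog 1 — so the TPM < 10 filter removes a realistic minority
(~5%) of cells — and a gene-level PTR spread (sdlog 0.5) plus tissue-level
noise (sdlog 0.3), giving protein abundances a marginal log-sd near 1.2.
Signal genes get their PTR multiplied (divided) by `ptr_boost = 8` in the
signal tissue, comfortably clearing the fold-change-2 rule under the noise;
their expression cells are protected from the ~5% missing-at-random
injection and TPM-floored so the planted construction is actually
recoverable rather than probabilistically so.

What this does **not** emulate: real amino-acid composition (uniform, not
proteome-weighted), gene-length and expression-level dependence of codon
usage, correlated missingness (real proteomics misses low-abundance
proteins preferentially), between-tissue correlation structure, and any
biophysical coupling between codon usage and expression. Passing the
recovery tests therefore demonstrates that the estimators recover what was
planted under honest noise — not that real tissues carry signals of this
size.

## Null calibration

The no-skill check re-permutes the labels freshly in each of its 20
iterations and averages the cross-validated AUC. A single fixed permutation
would measure that permutation's chance association with codon usage
(spread ~±0.04 at 200 genes, plus the familiar slight pessimistic bias of
cross-validation on null data), not the no-skill level itself; averaging
over permutations is standard permutation-test practice and lands at
0.49–0.52 across seeds at the problem sizes used here.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in well under a minute of classifier time: 200
genes × 150 codons for the null and planted benchmarks (100 trees, 20
iterations, 5-fold CV), 150 genes × 6000 codons per set for the pair-ratio
regression, 1000-candidate pools for the optimizer contracts. Every
stochastic path takes an explicit seed and derives per-iteration seeds
deterministically, so all results in this vignette and the README are
byte-reproducible.

## Known limitations

* The default folding score is not a thermodynamic MFE; use the `vienna`
  backend for physical energies.
* CAI/CPB quality is bounded by the reference tables; the bundled
  `default_reference()` is computed from a small synthetic CDS set and is a
  convenience for examples and tests, not a genome reference.
* IUPAC ambiguity codes are rejected throughout, and motif filtering is
  forward-strand literal matching.
* `read_signature_json()` restores importances and ratios but not the
  fitted forest, so `predict()` requires the original fit.
* PTR set definitions assume tissues are comparable after median
  adjustment; batch structure beyond a per-tissue scale factor is out of
  scope.
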