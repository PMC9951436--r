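# codonopt

Tissue-specific codon optimality signatures from protein-to-mRNA ratios, and
a probabilistic codon optimizer that designs synonymous coding sequences for
a target tissue.

## The problem

The protein output of an mRNA differs between human tissues even at equal
transcript levels: the per-gene **protein-to-mRNA ratio (PTR)** is a proxy
for translational efficiency, and genes translated unusually well (or badly)
in one tissue carry a distinctive synonymous-codon fingerprint. `codonopt`
implements the full analysis stack for working with that fingerprint:

1. **PTR matrices** from paired protein and mRNA (TPM) expression tables,
   with the standard filtering pipeline — zero protein abundances treated as
   missing, per-tissue protein medians adjusted to the overall median (in
   log10 space), genes below a TPM threshold (default 10) treated as
   non-transcribed.
2. **High-PTR / low-PTR gene sets** per tissue: fold change above 2 (below
   0.5) versus the average of all other tissues, argmax (argmin) across
   tissues, detected in at least 3 tissues; plus a relaxed variant, set
   merging across datasets with contradictory labels excluded, a one-tailed
   binomial concordance test, and the overlap coefficient
   |A∩B| / min(|A|,|B|).
3. **Tissue signatures**: a balanced-resampling random-forest classifier of
   high vs low genes on length-normalized usage of the 61 sense codons
   (100 trees, 100 iterations subsampling the larger class, stratified
   5-fold cross-validation, rank-based ROC AUC), yielding relative feature
   weights per codon and high/low usage ratios; plus recursive feature
   elimination, misframe/dinucleotide control models, codon-pair ratios,
   their PCA, and the observed-vs-expected pair-ratio regression
   (expected(AB) = ratio(A)·ratio(B)).
4. **Codon optimization**: for each amino acid a codon is drawn with
   probability proportional to its feature weight; enriched codons
   (ratio > 1) are incorporated, depleted ones excluded and redrawn. A
   seeded pool of n_pool candidates is then ranked by the mean rank of
   standard gene-design metrics — MFE (folding score of nt 41+), MFEini
   (nt 1–40), CAI, codon pair bias, effective number of codons, GC — after
   homopolymer and motif filtering.
5. **Synthetic data generators** for every input: coding sequences with
   planted within-family codon biases and paired expression matrices with
   planted tissue-specific PTR structure, all pure functions of a seed.

The core statistics follow the field's standard definitions: Sharp–Li CAI
(geometric mean of within-family relative adaptiveness), Coleman codon pair
score CPS(AB) = ln[F(AB) / (F(A)F(B)/(F(aA)F(aB)) · F(aAaB))], and Wright's
effective number of codons Nc = 2 + 9/F̄2 + 1/F̄3 + 5/F̄4 + 3/F̄6 with its
printed anchors (61 = even usage, 20 = one codon per amino acid). The
default folding backend is an in-package dynamic-programming minimizer over
nested structures (weighted base pairs, minimum hairpin loop 3 nt); an
external `RNAfold` backend is pluggable.

## Worked example

Simulate a four-tissue study with a kidney signal (5 codons enriched 4-fold
in high-PTR genes), recover the gene sets and signature, and design a
kidney-optimized sequence:

```r
library(codonopt)

planted <- c("AAA", "GGC", "CTG", "GTG", "CCA")
sig_def <- planted_signal(tissue = "kidney", enriched = planted, factor = 4,
                          n_high = 60, n_low = 60)
ex   <- generate_expression(300, c("kidney", "lung", "liver", "brain"),
                            sig_def, seed = 11)
seqs <- generate_signal_cds(ex$truth, rownames(ex$protein), sig_def, seed = 12)

ptr  <- compute_ptr(ex$protein, ex$mrna)          # NA/median/TPM<10 rules
sets <- define_gene_sets(ptr, fc = 2, min_tissues = 3, mode = "strict")
hi <- sets$kidney$high; lo <- sets$kidney$low     # 61 high, 63 low genes

sig <- tissue_signature(seqs[c(hi, lo)],
                        rep(c("high", "low"), c(length(hi), length(lo))),
                        tissue = "kidney", n_iter = 20, seed = 13)
summary(sig)
#> Tissue codon signature: kidney
#>   genes: 61 high-PTR, 63 low-PTR
#>   cross-validated AUC: 0.979 +/- 0.008
#>   top 10 codons by relative feature weight:
#>    codon amino_acid importance ratio
#> 1    GGC          G     0.1093 2.465
#> 2    AAG          K     0.0916 0.382
#> 3    GTG          V     0.0742 2.520
#> 4    CCA          P     0.0731 2.375
#> 5    CTG          L     0.0499 2.217
#> ...
```

The classifier separates the recovered sets almost perfectly (AUC 0.98 vs
the no-skill 0.5), and the top feature weights are the planted codons — GGC,
GTG, CCA, CTG with usage ratios above 2 — plus their family partners (AAG
carries the mirrored signal of AAA: its ratio 0.38 marks it depleted).

```r
pool <- optimize_sequences("MVSKGEELFTGVVPILVELDGDVNGHKFSVSG*", sig,
                           n_pool = 1000, seed = 14)
best <- select_best(pool, homopolymers = 7, top = 3)
best[, c("rank", "MFE", "MFEini", "CAI", "CPB", "ENC", "score")]
#>   rank MFE MFEini       CAI       CPB ENC score
#> 1    1 -47    -30 0.7753330 0.5762813  14   1.9
#> 2    2 -46    -30 0.7504636 0.6642788  14   2.0
#> 3    3 -47    -30 0.7483370 0.6252982  14   2.1
```

Every candidate translates back to the input protein; the low ENC (14)
reflects the deliberately narrow codon choice of a tissue-optimized
sequence, and `score` is the mean rank across the five requested metrics
(MFE minimized, MFEini maximized, CAI and CPB maximized, ENC minimized).

A thin command-line front end over the same functions is installed at
`inst/scripts/codonopt` (`simulate`, `train`, `optimize` subcommands).

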