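# Shared fixtures and independent oracles. Oracles are deliberately naive
# (recounts, O(n^2) scans, memoless recursions) and never reuse the package's
# computation path.

GC_TABLE <- Biostrings::GENETIC_CODE
ALL_SENSE <- sort(names(GC_TABLE)[GC_TABLE != "*"])
FAMILIES <- split(ALL_SENSE, GC_TABLE[ALL_SENSE])

random_cds <- function(n_codons, seed) {
  set.seed(seed)
  paste(sample(ALL_SENSE, n_codons, replace = TRUE), collapse = "")
}

# hand-built signature with chosen importance/ratio values
toy_signature <- function(importance = NULL, ratio = NULL, tissue = "toy") {
  imp <- stats::setNames(rep(1 / 61, 61), ALL_SENSE)
  rat <- stats::setNames(rep(1.5, 61), ALL_SENSE)
  if (!is.null(importance)) imp[names(importance)] <- importance
  if (!is.null(ratio)) rat[names(ratio)] <- ratio
  codonopt:::new_tissue_signature(tissue, imp / sum(imp), rat)
}

# reference tables from explicit count vectors, via the TSV round trip
ref_from_counts <- function(codon_count, pair_count) {
  ct <- tempfile(fileext = ".tsv"); pt <- tempfile(fileext = ".tsv")
  write_usage_tsv(codon_count, ct, value_name = "count")
  write_usage_tsv(pair_count, pt, value_name = "count")
  reference_from_tsv(ct, pt)
}

# O(n^2) AUC oracle: concordant pair count with half credit for ties
auc_oracle <- function(scores, labels) {
  pos <- which(labels); neg <- which(!labels)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive fold oracle: memoless recursion over every nested structure
# with hairpin loops of >= min_loop unpaired bases; returns the minimum
# total pair energy (GC -3, AT -2, GT -1).
brute_fold <- function(s, min_loop = 3) {
  ch <- strsplit(s, "")[[1]]
  pe <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(-2)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(-1)
    NA_real_
  }
  best <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    vals <- best(i + 1, j)
    for (k in seq(i + min_loop + 1, j)) {
      e <- pe(ch[i], ch[k])
      if (is.na(e)) next
      inner <- best(i + 1, k - 1)
      rest <- if (k < j) best(k + 1, j) else 0
      vals <- min(vals, e + inner + rest)
    }
    vals
  }
  best(1, length(ch))
}
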