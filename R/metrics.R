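#' Reference codon and codon-pair tables
#'
#' Builds the reference tables used by [cai()] and [cpb()] from a set of
#' coding sequences: pooled codon counts over the 64 codons and pooled
#' overlapping codon-pair counts over the 4096 ordered pairs, plus the
#' amino-acid and amino-acid-pair marginals derived from them.
#'
#' @param seqs character vector of CDS strings.
#' @return Object of class `"reference_tables"` with fields `codon_count`,
#'   `pair_count`, `aa_count`, `aa_pair_count`.
#' @seealso [reference_from_tsv()], [default_reference()]
#' @export
reference_tables <- function(seqs) {
  if (length(seqs) == 0) stop("empty reference set")
  codon_count <- stats::setNames(numeric(64), CODONS64)
  pair_count <- stats::setNames(numeric(4096), PAIRS4096)
  for (s in seqs) {
    codons <- split_codons(as_cds(s))
    tab <- table(codons)
    codon_count[names(tab)] <- codon_count[names(tab)] + as.numeric(tab)
    if (length(codons) >= 2) {
      ptab <- table(paste0(codons[-length(codons)], codons[-1L]))
      pair_count[names(ptab)] <- pair_count[names(ptab)] + as.numeric(ptab)
    }
  }
  new_reference_tables(codon_count, pair_count)
}

new_reference_tables <- function(codon_count, pair_count) {
  stopifnot(setequal(names(codon_count), CODONS64),
            setequal(names(pair_count), PAIRS4096))
  codon_count <- codon_count[CODONS64]
  pair_count <- pair_count[PAIRS4096]
  aa_of_codon <- GENCODE[CODONS64]
  aa_count <- tapply(codon_count, aa_of_codon, sum)
  pair_aa <- paste0(GENCODE[substr(PAIRS4096, 1, 3)],
                    GENCODE[substr(PAIRS4096, 4, 6)])
  aa_pair_count <- tapply(pair_count, pair_aa, sum)
  structure(list(codon_count = codon_count, pair_count = pair_count,
                 aa_count = aa_count, aa_pair_count = aa_pair_count),
            class = "reference_tables")
}

#' @export
print.reference_tables <- function(x, ...) {
  cat(sprintf("<reference_tables: %.0f codons, %.0f codon pairs counted>\n",
              sum(x$codon_count), sum(x$pair_count)))
  invisible(x)
}

#' Read reference tables from TSV files
#'
#' @param codon_path TSV with columns `feature` (codon) and `count` (or
#'   `frequency`).
#' @param pair_path TSV with columns `feature` (hexamer codon pair) and
#'   `count`/`frequency`.
#' @return `reference_tables` object.
#' @export
reference_from_tsv <- function(codon_path, pair_path) {
  cc <- read_usage_tsv(codon_path)
  pc <- read_usage_tsv(pair_path)
  full_c <- stats::setNames(numeric(64), CODONS64); full_c[names(cc)] <- cc
  full_p <- stats::setNames(numeric(4096), PAIRS4096); full_p[names(pc)] <- pc
  new_reference_tables(full_c, full_p)
}

#' Bundled default reference
#'
#' Reference tables computed from the small synthetic CDS set shipped with
#' the package (a convenience stand-in for genome-scale usage tables, which
#' users should supply for real design work).
#'
#' @return `reference_tables` object.
#' @export
default_reference <- function() {
  fa <- system.file("extdata", "synthetic_reference_cds.fa",
                    package = "codonopt", mustWork = TRUE)
  reference_tables(read_cds_fasta(fa))
}

#' Codon Adaptation Index
#'
#' Geometric mean, over the sense codons of the sequence, of the relative
#' adaptiveness w(c) = f(c) / max f(c') within c's synonymous family, with
#' f the reference codon frequencies. Single-codon families (Met, Trp) and
#' stop codons are excluded. Reference counts receive a pseudocount of 0.5
#' per codon so unobserved codons keep w > 0.
#'
#' @param cds CDS string.
#' @param ref [reference_tables()].
#' @return CAI in (0, 1]; 1 when every codon is its family's most frequent.
#' @export
cai <- function(cds, ref) {
  cds <- as_cds(cds)
  f <- ref$codon_count + 0.5
  w <- stats::setNames(numeric(0), character(0))
  for (fam in AA_FAMILIES) w[fam] <- f[fam] / max(f[fam])
  multi <- unlist(AA_FAMILIES[AA_DEGENERACY > 1], use.names = FALSE)
  codons <- split_codons(cds)
  codons <- codons[codons %in% multi]
  if (length(codons) == 0)
    stop("no codons from multi-codon families; CAI undefined")
  exp(mean(log(w[codons])))
}

#' Codon Pair Bias
#'
#' Mean codon pair score (CPS) over the sequence's adjacent sense codon
#' pairs, with CPS(AB) = ln of the observed reference pair count over its
#' expectation conditioned on the amino-acid pair:
#' `CPS(AB) = ln( F(AB) / ( F(A) F(B) / (F(aA) F(aB)) * F(aA aB) ) )`.
#' Reference pair counts receive a pseudocount of 1; pairs containing a
#' stop codon are excluded from the mean.
#'
#' @param cds CDS string with at least 2 codons.
#' @param ref [reference_tables()].
#' @return CPB (0 when the reference pairs match their marginal
#'   expectation exactly).
#' @export
cpb <- function(cds, ref) {
  cds <- as_cds(cds)
  codons <- split_codons(cds)
  if (length(codons) < 2) stop("CPB needs at least 2 codons")
  a <- codons[-length(codons)]; b <- codons[-1L]
  sense <- !(a %in% STOP_CODONS) & !(b %in% STOP_CODONS)
  a <- a[sense]; b <- b[sense]
  if (length(a) == 0) stop("no sense codon pairs")
  cps <- codon_pair_score(paste0(a, b), ref)
  # pairs whose amino-acid pair or codons are absent from the reference
  # have no defined expectation; they are dropped from the mean
  cps <- cps[is.finite(cps)]
  if (length(cps) == 0) stop("no codon pair has a defined reference score")
  mean(cps)
}

# CPS for a vector of hexamer pairs (sense codons only)
codon_pair_score <- function(pairs, ref) {
  a <- substr(pairs, 1, 3); b <- substr(pairs, 4, 6)
  aa_a <- GENCODE[a]; aa_b <- GENCODE[b]
  f_ab <- ref$pair_count[pairs] + 1
  expected <-ref$codon_count[a] * ref$codon_count[b] /
    (ref$aa_count[aa_a] * ref$aa_count[aa_b]) *
    ref$aa_pair_count[paste0(aa_a, aa_b)]
  unname(log(f_ab / expected))
}

#' Effective Number of Codons (Wright's estimator)
#'
#' Codon-evenness statistic: 61 means unbiased synonymous usage, 20 means
#' every amino acid uses a single codon. Computed from family homozygosities
#' `F = (n * sum(p^2) - 1) / (n - 1)` averaged within each degeneracy class
#' (2-, 3-, 4-, 6-fold); each observed family then contributes `1 / Fbar` of
#' its class, capped at the family size, and the two single-codon amino
#' acids contribute 1 each when observed.
#'
#' Degenerate inputs: families with fewer than 2 observed codons, or with
#' non-positive homozygosity, do not enter the class mean; if a whole class
#' has no usable homozygosity, each of its observed families contributes its
#' observed distinct-codon count instead. The result is clipped at 61.
#'
#' @param cds CDS string (stop codons ignored).
#' @return ENC value; 2 for a Met/Trp-only sequence, up to 61.
#' @export
enc <- function(cds) {
  cds <- as_cds(cds)
  codons <- split_codons(cds)
  codons <- codons[!codons %in% STOP_CODONS]
  if (length(codons) == 0) stop("no sense codons")
  counts <- table(codons)

  fam_stats <- lapply(names(AA_FAMILIES), function(aa) {
    fam <- AA_FAMILIES[[aa]]
    n_c <- as.numeric(counts[fam]); n_c[is.na(n_c)] <- 0
    n <- sum(n_c)
    f_hat <- if (n >= 2) (n * sum((n_c / n)^2) - 1) / (n - 1) else NA_real_
    list(deg = length(fam), n = n, n_distinct = sum(n_c > 0), f_hat = f_hat)
  })
  deg <- vapply(fam_stats, `[[`, numeric(1), "deg")
  n <- vapply(fam_stats, `[[`, numeric(1), "n")
  n_distinct <- vapply(fam_stats, `[[`, numeric(1), "n_distinct")
  f_hat <- vapply(fam_stats, `[[`, numeric(1), "f_hat")

  nc <- sum(deg == 1 & n > 0)   # Met, Trp
  for (k in c(2, 3, 4, 6)) {
    in_class <- deg == k & n > 0
    if (!any(in_class)) next
    usable <- in_class & !is.na(f_hat) & f_hat > 0
    if (any(usable)) {
      fbar <- mean(f_hat[usable])
      nc <- nc + min(sum(in_class) / fbar, sum(in_class) * k)
    } else {
      nc <- nc + sum(n_distinct[in_class])
    }
  }
  min(nc, 61)
}

#' GC-content distance
#'
#' Absolute difference between the sequence GC fraction (computed over the
#' full CDS, stop codon included) and a target value.
#'
#' @param cds CDS string.
#' @param target desired GC fraction in \[0, 1\].
#' @return Non-negative distance.
#' @export
gc_distance <- function(cds, target) {
  if (target < 0 || target > 1) stop("'target' must be in [0, 1]")
  s <- clean_nt(cds)
  gc <- (nchar(gsub("[AT]", "", s))) / nchar(s)
  abs(gc - target)
}

# normalize an arbitrary-length nucleotide string (regions need not be
# codon-aligned)
clean_nt <- function(x) {
  s <- toupper(chartr("u", "t", tolower(x)))
  if (grepl("[^ACGT]", s) || !nzchar(s)) stop("sequence must be ACGT/U only")
  s
}

#' Minimum folding score of a (sub)sequence
#'
#' Scores the stability of the most stable nested secondary structure of
#' the chosen region. Two backends:
#' * `"dp"` (default): an in-package dynamic-programming minimizer over
#'   nested structures with weighted base pairs (GC -3, AT/AU -2, GT/GU -1)
#'   and a minimum hairpin loop of 3 nt. This is a base-pair-level score in
#'   arbitrary units, deliberately dependency-free; it is **not** a
#'   thermodynamic nearest-neighbor folder, but more negative still means
#'   more stable.
#' * `"vienna"`: calls the external `RNAfold` program if present on the
#'   PATH, returning its MFE in kcal/mol.
#'
#' The translation-initiation region is scored separately from the rest:
#' `region = "ini40"` takes nucleotides 1-40 (the whole sequence if
#' shorter), `"rest"` nucleotides 41-end (score 0 if empty), `"full"` the
#' entire sequence.
#'
#' @param cds CDS string.
#' @param region `"full"`, `"ini40"`, or `"rest"`.
#' @param backend `"dp"` or `"vienna"`.
#' @return Folding score <= 0 (0 when no pairs can form).
#' @export
mfe <- function(cds, region = c("full", "ini40", "rest"),
                backend = c("dp", "vienna")) {
  region <- match.arg(region)
  backend <- match.arg(backend)
  cds <- clean_nt(cds)
  s <- switch(region,
              full  = cds,
              ini40 = substr(cds, 1, min(40L, nchar(cds))),
              rest  = if (nchar(cds) > 40L) substr(cds, 41L, nchar(cds))
                      else "")
  if (!nzchar(s)) return(0)
  switch(backend,
         dp = fold_min_energy(s, 3L),
         vienna = vienna_mfe(s))
}

vienna_mfe <- function(seq) {
  if (Sys.which("RNAfold") == "")
    stop("backend 'vienna' requires RNAfold on the PATH")
  out <- system2("RNAfold", args = "--noPS",
                 input = chartr("T", "U", seq), stdout = TRUE)
  m <- regmatches(out[2], regexpr("\\(\\s*-?[0-9.]+\\)$", out[2]))
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}

#' Homopolymer filter predicate
#'
#' @param seq nucleotide string.
#' @param k run length; `TRUE` iff any single-nucleotide run of length at
#'   least `k` exists.
#' @export
has_homopolymer <- function(seq, k) {
  if (k < 2) stop("'k' must be >= 2")
  grepl(sprintf("([ACGT])\\1{%d,}", as.integer(k) - 1L), seq)
}

#' Motif filter predicate
#'
#' Forward-strand substring search; overlapping occurrences count.
#'
#' @param seq nucleotide string.
#' @param motifs character vector of ACGT motifs.
#' @return `TRUE` iff any motif occurs in `seq`.
#' @export
contains_motif <- function(seq, motifs) {
  if (length(motifs) == 0) return(rep(FALSE, length(seq)))
  if (any(!nzchar(motifs))) stop("empty motif string")
  Reduce(`|`, lapply(motifs, function(m) grepl(m, seq, fixed = TRUE)))
}
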