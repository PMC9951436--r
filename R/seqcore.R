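#' Validate and normalize a coding sequence
#'
#' Uppercases, maps RNA U to DNA T, and checks that the sequence is a proper
#' CDS: alphabet ACGT, length a positive multiple of 3. Ambiguity codes (N,
#' R, Y, ...) are rejected.
#'
#' @param raw character scalar, DNA or RNA sequence.
#' @param id optional sequence identifier, stored as an attribute.
#' @return The normalized sequence, a character scalar of class `"cds"` with
#'   attribute `id`.
#' @examples
#' validate_cds("atgugg", id = "g1")
#' @export
validate_cds <- function(raw, id = NULL) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("'raw' must be a single non-empty string")
  nt <- chartr("u", "t", tolower(raw))
  nt <- toupper(nt)
  bad <- gsub("[ACGT]", "", nt)
  if (nzchar(bad))
    stop("non-ACGT/U characters in sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  if (nchar(nt) %% 3L != 0L || nchar(nt) < 3L)
    stop("CDS length must be a positive multiple of 3, got ", nchar(nt))
  structure(nt, class = "cds", id = if (is.null(id)) NA_character_ else id)
}

# cheap re-validation for internal call sites that accept plain strings
as_cds <- function(x, id = NULL) {
  if (inherits(x, "cds")) x else validate_cds(x, id = id)
}

#' @export
print.cds <- function(x, ...) {
  cat(sprintf("<cds %s: %d nt, %d codons>\n",
              attr(x, "id"), nchar(x), nchar(x) %/% 3L))
  invisible(x)
}

split_codons <- function(nt, shift = 0L) {
  n <- nchar(nt)
  starts <- seq.int(1L + shift, n - 2L, by = 3L)
  substring(nt, starts, starts + 2L)
}

#' Translate a coding sequence
#'
#' Standard-code translation. An internal stop codon is an error unless
#' `allow_internal_stop = TRUE`; a terminal stop translates to `"*"`.
#'
#' @param cds a CDS string (validated with [validate_cds()] if not already).
#' @param allow_internal_stop logical; permit `*` before the last codon.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGTGG")   # "MW"
#' translate_cds("ATGTAA")   # "M*"
#' @export
translate_cds <- function(cds, allow_internal_stop = FALSE) {
  cds <- as_cds(cds)
  aa <- unname(GENCODE[split_codons(cds)])
  if (!allow_internal_stop && any(aa[-length(aa)] == "*"))
    stop("internal stop codon at codon position ",
         which(aa[-length(aa)] == "*")[1])
  paste(aa, collapse = "")
}

normalize_counts <- function(counts, features) {
  v <- stats::setNames(numeric(length(features)), features)
  tab <- table(counts)
  v[names(tab)] <- as.numeric(tab)
  total <- sum(v)
  if (total == 0) stop("no features counted")
  v / total
}

#' In-frame codon usage of a CDS
#'
#' Counts in-frame codons and normalizes by the total so frequencies sum to
#' 1. With `alphabet = 61` (the default used for tissue analysis) stop
#' codons are dropped before normalization, so the 61 sense codons sum to 1;
#' with `alphabet = 64` all codons including stops are kept.
#'
#' @param cds CDS string.
#' @param alphabet 61 (sense codons only) or 64 (all codons).
#' @return Named numeric vector over the chosen codon set, summing to 1.
#' @export
codon_usage <- function(cds, alphabet = 61) {
  cds <- as_cds(cds)
  codons <- split_codons(cds)
  if (alphabet == 61) {
    codons <- codons[!codons %in% STOP_CODONS]
    if (length(codons) == 0)
      stop("CDS contains only stop codons; no sense codons to count")
    normalize_counts(codons, SENSE_CODONS)
  } else if (alphabet == 64) {
    normalize_counts(codons, CODONS64)
  } else stop("'alphabet' must be 61 or 64")
}

#' Codon usage of a misframed CDS
#'
#' Reads codons from frame offset `shift` (1 or 2 nucleotides), drops the
#' trailing partial codon, and normalizes over all 64 codons. Used as a
#' control feature set: misframed usage carries nucleotide composition but
#' not in-frame codon identity.
#'
#' @param cds CDS string.
#' @param shift frame shift, 1 or 2.
#' @return Named numeric vector over the 64 codons, summing to 1.
#' @export
misframed_codon_usage <- function(cds, shift) {
  cds <- as_cds(cds)
  if (!shift %in% c(1L, 2L)) stop("'shift' must be 1 or 2")
  if (nchar(cds) < shift + 3L) stop("sequence too short for shift ", shift)
  normalize_counts(split_codons(cds, shift = as.integer(shift)), CODONS64)
}

#' Codon-pair usage of a CDS
#'
#' Counts overlapping adjacent in-frame codon pairs (window stepping one
#' codon) over the 64 x 64 = 4096 ordered pairs, normalized to sum 1. Pairs
#' are keyed by their hexamer (first codon then second).
#'
#' @param cds CDS string with at least two codons.
#' @return Named numeric vector of length 4096, summing to 1.
#' @export
codon_pair_usage <- function(cds) {
  cds <- as_cds(cds)
  codons <- split_codons(cds)
  if (length(codons) < 2L) stop("codon-pair usage needs at least 2 codons")
  pairs <- paste0(codons[-length(codons)], codons[-1L])
  normalize_counts(pairs, PAIRS4096)
}

#' Dinucleotide usage of a sequence
#'
#' Overlapping dinucleotide frequencies over the 16 dinucleotides,
#' normalized to sum 1. Accepts any nucleotide string of length >= 2 (the
#' window is not codon-aligned).
#'
#' @param cds nucleotide string (length >= 2 nt).
#' @return Named numeric vector of length 16.
#' @export
dinucleotide_usage <- function(cds) {
  cds <- clean_nt(cds)
  n <- nchar(cds)
  if (n < 2L) stop("need at least 2 nucleotides")
  dinucs <- substring(cds, 1:(n - 1L), 2:n)
  normalize_counts(dinucs, DINUCS16)
}

usage_fun <- function(kind) {
  switch(kind,
         codon61  = function(s) codon_usage(s, 61),
         codon64  = function(s) codon_usage(s, 64),
         pair4096 = codon_pair_usage,
         dinuc16  = dinucleotide_usage,
         stop("unknown usage kind: ", kind))
}

#' Mean usage vector of a gene set
#'
#' Averages per-gene length-normalized usage vectors with equal gene weight
#' (not pooled counts), so long genes do not dominate.
#'
#' @param seqs character vector of CDS strings (names taken as gene ids).
#' @param kind one of `"codon61"`, `"codon64"`, `"pair4096"`, `"dinuc16"`.
#' @return Named numeric vector summing to 1.
#' @export
mean_usage <- function(seqs, kind = "codon61") {
  if (length(seqs) == 0) stop("empty gene set")
  f <- usage_fun(kind)
  rowMeans(vapply(seqs, f, numeric(length(usage_feature_set(kind)))))
}

#' Gene-by-feature usage matrix
#'
#' Stacks per-gene usage vectors into a matrix, the feature table consumed
#' by the classifier.
#'
#' @inheritParams mean_usage
#' @return Numeric matrix, genes in rows (named), features in columns.
#' @export
usage_matrix <- function(seqs, kind = "codon61") {
  f <- usage_fun(kind)
  t(vapply(seqs, f, numeric(length(usage_feature_set(kind)))))
}
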