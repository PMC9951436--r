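# Genetic-code constants shared across the package. Derived once, at install
# time, from the standard code shipped with Biostrings.

GENCODE <- Biostrings::GENETIC_CODE

#' The 64 DNA codons in lexicographic order
#' @keywords internal
CODONS64 <- sort(names(GENCODE))

STOP_CODONS <- sort(names(GENCODE)[GENCODE == "*"])

#' The 61 sense (amino-acid-encoding) codons
#' @keywords internal
SENSE_CODONS <- setdiff(CODONS64, STOP_CODONS)

# amino acid -> synonymous sense codons (the degeneracy family)
AA_FAMILIES <- split(SENSE_CODONS, GENCODE[SENSE_CODONS])

# degeneracy (family size) per amino acid; standard code: nine 2-fold, one
# 3-fold (Ile), five 4-fold, three 6-fold (Leu/Ser/Arg), two 1-fold (Met, Trp)
AA_DEGENERACY <- vapply(AA_FAMILIES, length, integer(1))

# ordered codon pairs as hexamers, first codon major
PAIRS4096 <- as.vector(t(outer(CODONS64, CODONS64, paste0)))

DINUCS16 <- as.vector(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              paste0)))

usage_feature_set <- function(kind) {
  switch(kind,
         codon61  = SENSE_CODONS,
         codon64  = CODONS64,
         pair4096 = PAIRS4096,
         dinuc16  = DINUCS16,
         stop("unknown usage kind: ", kind))
}
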