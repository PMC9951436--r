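#' Read coding sequences from a FASTA file
#'
#' Each record is validated as a CDS (ACGT/U alphabet, length a multiple of
#' 3). Returns plain strings so downstream code stays vector-friendly.
#'
#' @param path FASTA file.
#' @return Named character vector of validated CDS strings.
#' @export
read_cds_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  vapply(seq_along(seqs),
         function(i) as.character(validate_cds(seqs[[i]], id = names(seqs)[i])),
         character(1), USE.NAMES = FALSE) |>
    stats::setNames(names(seqs))
}

#' Read amino-acid sequences from a FASTA file
#' @param path FASTA file.
#' @return Named character vector of protein strings.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

#' Write sequences to FASTA
#' @param seqs named character vector (DNA or protein).
#' @param path output file; records wrapped at 60 columns.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Layout: first column gene id, header row of tissue ids, empty cells are
#' missing values.
#'
#' @param path TSV file.
#' @return Numeric matrix, genes in rows, tissues in columns.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values in ", path)
  m
}

#' Write an expression (or PTR) matrix to TSV
#' @param m numeric matrix, genes x tissues.
#' @param path output file.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a usage table (feature, frequency) from TSV
#' @param path TSV with columns `feature`, `frequency` (or `count`).
#' @return Named numeric vector.
#' @export
read_usage_tsv <- function(path) {
  df <- utils::read.delim(path)
  val_col <- intersect(c("frequency", "count"), names(df))[1]
  if (is.na(val_col)) stop("expected a 'frequency' or 'count' column")
  stats::setNames(as.numeric(df[[val_col]]), as.character(df[[1]]))
}

#' Write a usage table to TSV
#' @param usage named numeric vector.
#' @param path output file.
#' @param value_name column name for the values.
#' @export
write_usage_tsv <- function(usage, path, value_name = "frequency") {
  df <- data.frame(feature = names(usage), value = unname(usage))
  names(df)[2] <- value_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-tissue gene sets to TSV
#' @param sets list of gene-set pairs as returned by [define_gene_sets()].
#' @param path output file with columns tissue, label, gene.
#' @export
write_gene_sets_tsv <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(s) {
    rbind(
      if (length(s$high)) data.frame(tissue = s$tissue, label = "high",
                                     gene = s$high),
      if (length(s$low)) data.frame(tissue = s$tissue, label = "low",
                                    gene = s$low))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-tissue gene sets from TSV
#' @param path TSV with columns tissue, label, gene.
#' @return List of gene-set pairs (tissue, high, low).
#' @export
read_gene_sets_tsv <- function(path) {
  df <- utils::read.delim(path)
  lapply(split(df, df$tissue), function(d) {
    list(tissue = d$tissue[1],
         high = d$gene[d$label == "high"],
         low  = d$gene[d$label == "low"])
  })
}
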