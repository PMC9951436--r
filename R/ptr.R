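#' Protein-to-mRNA ratio matrix
#'
#' Computes per-gene, per-tissue PTR ratios from paired protein and mRNA
#' (TPM) matrices, applying the standard filtering pipeline:
#' zero protein abundances become missing; protein quantifications are
#' adjusted so every tissue has the same median as the overall median
#' (adjustment on log10 scale, ratio on linear scale); genes below the TPM
#' threshold are treated as non-transcribed (missing). The gene and tissue
#' label intersection of the two matrices is used.
#'
#' @param protein numeric matrix, genes x tissues, protein abundances.
#' @param mrna numeric matrix, genes x tissues, mRNA TPM.
#' @param tpm_threshold TPM below which a gene counts as non-transcribed
#'   (default 10).
#' @return Numeric matrix of PTR ratios with `NA` where undefined.
#' @export
compute_ptr <- function(protein, mrna, tpm_threshold = 10) {
  genes <- intersect(rownames(protein), rownames(mrna))
  tissues <- intersect(colnames(protein), colnames(mrna))
  if (length(genes) == 0 || length(tissues) == 0)
    stop("protein and mRNA matrices share no genes/tissues")
  p <- protein[genes, tissues, drop = FALSE]
  m <- mrna[genes, tissues, drop = FALSE]

  p[p == 0] <- NA_real_
  lp <- log10(p)
  overall_med <- stats::median(lp, na.rm = TRUE)
  tissue_med <- apply(lp, 2, stats::median, na.rm = TRUE)
  lp <- sweep(lp, 2, tissue_med - overall_med)
  p_adj <- 10^lp

  m[is.na(m) | m < tpm_threshold] <- NA_real_
  p_adj / m
}

#' Collapse multi-sample tissues to per-tissue medians
#'
#' For datasets with several samples per tissue, aggregates columns sharing
#' a tissue label to their per-gene median before PTR computation.
#'
#' @param m numeric matrix, genes x samples.
#' @param tissue_of character vector mapping each column to a tissue id.
#' @return Genes x tissues matrix of medians.
#' @export
collapse_samples <- function(m, tissue_of) {
  stopifnot(length(tissue_of) == ncol(m))
  tissues <- unique(tissue_of)
  out <- vapply(tissues, function(tt) {
    apply(m[, tissue_of == tt, drop = FALSE], 1, stats::median, na.rm = TRUE)
  }, numeric(nrow(m)))
  out[is.nan(out)] <- NA_real_
  rownames(out) <- rownames(m)
  out
}

#' Tissue-specific high-PTR and low-PTR gene sets
#'
#' For each tissue, the high-PTR set contains genes whose PTR fold change
#' versus the average of all other tissues exceeds `fc` (strictly), that are
#' detected (PTR defined) in at least `min_tissues` tissues, and — in
#' `"strict"` mode — whose PTR in that tissue is the maximum across all
#' tissues. The low-PTR set mirrors these conditions with fold change below
#' `1/fc` and the argmin condition. `"relaxed"` mode drops the
#' argmax/argmin condition, which lets a gene appear in several tissues'
#' sets.
#'
#' @param ptr PTR matrix from [compute_ptr()].
#' @param fc fold-change threshold (> 1); default 2.
#' @param min_tissues minimum number of tissues with defined PTR; default 3.
#' @param mode `"strict"` (adds the argmax/argmin condition) or `"relaxed"`.
#' @param other_average `"mean"` (default) or `"median"` over the other
#'   tissues' non-missing PTR values.
#' @param exclude optional gene ids removed before set definition (e.g. a
#'   blood-secretome exclusion list).
#' @return List with one element per tissue: `list(tissue, high, low)`,
#'   the high/low gene-id sets (always disjoint).
#' @export
define_gene_sets <- function(ptr, fc = 2, min_tissues = 3,
                             mode = c("strict", "relaxed"),
                             other_average = c("mean", "median"),
                             exclude = NULL) {
  mode <- match.arg(mode)
  other_average <- match.arg(other_average)
  if (fc <= 1) stop("'fc' must be > 1")
  if (min_tissues < 1) stop("'min_tissues' must be >= 1")
  if (ncol(ptr) < 2) stop("need at least 2 tissues")
  if (!is.null(exclude)) ptr <- ptr[!rownames(ptr) %in% exclude, , drop = FALSE]

  avg_fun <- if (other_average == "mean") mean else stats::median
  n_det <- rowSums(!is.na(ptr))
  row_max <- suppressWarnings(apply(ptr, 1, max, na.rm = TRUE))
  row_min <- suppressWarnings(apply(ptr, 1, min, na.rm = TRUE))

  lapply(colnames(ptr), function(tt) {
    x <- ptr[, tt]
    others <- ptr[, colnames(ptr) != tt, drop = FALSE]
    other_avg <- apply(others, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else avg_fun(v)
    })
    fold <- x / other_avg
    detected <- !is.na(x) & n_det >= min_tissues
    hi <- detected & !is.na(fold) & fold > fc
    lo <- detected & !is.na(fold) & fold < 1 / fc
    if (mode == "strict") {
      hi <- hi & x == row_max
      lo <- lo & x == row_min
    }
    list(tissue = tt,
         high = rownames(ptr)[which(hi)],
         low  = rownames(ptr)[which(lo)])
  }) |> stats::setNames(colnames(ptr))
}

#' Merge gene sets from two datasets
#'
#' Per shared tissue, takes the union of high (and low) sets, excluding
#' genes with contradictory labels (high in one dataset, low in the other).
#'
#' @param a,b gene-set lists from [define_gene_sets()].
#' @return Merged gene-set list over the shared tissues.
#' @export
merge_gene_sets <- function(a, b) {
  tissues <- intersect(names(a), names(b))
  lapply(tissues, function(tt) {
    hi <- union(a[[tt]]$high, b[[tt]]$high)
    lo <- union(a[[tt]]$low, b[[tt]]$low)
    contradictory <- intersect(hi, lo)
    list(tissue = tt,
         high = setdiff(hi, contradictory),
         low  = setdiff(lo, contradictory))
  }) |> stats::setNames(tissues)
}

#' Concordance of gene labels between two datasets
#'
#' Over genes labeled (high or low) in both datasets for the same tissue,
#' counts agreements and tests whether agreement exceeds chance with a
#' one-tailed (upper) binomial test at success probability 1/2.
#'
#' @param a,b single gene-set pairs (`list(tissue, high, low)`).
#' @return `list(n_common, n_agree, p_value)`.
#' @export
concordance_test <- function(a, b) {
  common <- intersect(union(a$high, a$low), union(b$high, b$low))
  n_common <- length(common)
  if (n_common == 0) stop("no genes labeled in both datasets")
  lab_a <- ifelse(common %in% a$high, "high", "low")
  lab_b <- ifelse(common %in% b$high, "high", "low")
  n_agree <- sum(lab_a == lab_b)
  # P(X >= n_agree), X ~ Binom(n_common, 1/2)
  p <- stats::pbinom(n_agree - 1, n_common, 0.5, lower.tail = FALSE)
  list(n_common = n_common, n_agree = n_agree, p_value = p)
}

#' Overlap coefficient between two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`, the similarity used for enrichment-map
#' style comparisons of tissue gene sets.
#'
#' @param A,B non-empty character vectors of gene ids.
#' @return Numeric in \[0, 1\].
#' @export
overlap_coefficient <- function(A, B) {
  if (length(A) == 0 || length(B) == 0) stop("sets must be non-empty")
  length(intersect(A, B)) / min(length(unique(A)), length(unique(B)))
}

#' Translational efficiency matrix
#'
#' Elementwise ratio of ribosome-profiling to mRNA-seq FPKM over the shared
#' gene/tissue labels; missing wherever the denominator is zero or missing.
#'
#' @param ribo_fpkm,mrna_fpkm numeric matrices, genes x tissues.
#' @return Numeric matrix of TE values with `NA` where undefined.
#' @export
translational_efficiency <- function(ribo_fpkm, mrna_fpkm) {
  genes <- intersect(rownames(ribo_fpkm), rownames(mrna_fpkm))
  tissues <- intersect(colnames(ribo_fpkm), colnames(mrna_fpkm))
  r <- ribo_fpkm[genes, tissues, drop = FALSE]
  m <- mrna_fpkm[genes, tissues, drop = FALSE]
  m[!is.na(m) & m == 0] <- NA_real_
  r / m
}
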