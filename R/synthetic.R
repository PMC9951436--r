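#' Describe a planted tissue signal
#'
#' Constructor for the planted-signal description consumed by
#' [generate_cds()] and [generate_expression()]: which sense codons are
#' enriched (multiplicative within-family bias > 1) or depleted (< 1) in a
#' tissue's high-PTR genes, and the shape of the gene sets carrying it.
#'
#' @param tissue tissue id.
#' @param enriched sense codons biased upward in high genes.
#' @param depleted sense codons biased downward.
#' @param factor multiplicative bias applied to `enriched` (default 4).
#' @param depleted_factor bias applied to `depleted` (default `1/factor`).
#' @param n_high,n_low genes per set (defaults 100).
#' @param length_codons gene length in codons (default 150).
#' @param ptr_boost multiplicative PTR boost of high genes in the signal
#'   tissue (default 8; comfortably above the fold-change threshold 2).
#' @return `list` of class `"planted_signal"`.
#' @export
planted_signal <- function(tissue = "t1", enriched = character(),
                           depleted = character(), factor = 4,
                           depleted_factor = 1 / factor,
                           n_high = 100, n_low = 100,
                           length_codons = 150, ptr_boost = 8) {
  bad <- setdiff(c(enriched, depleted), SENSE_CODONS)
  if (length(bad)) stop("not sense codons: ", paste(bad, collapse = ", "))
  if (factor <= 0 || depleted_factor <= 0) stop("bias factors must be > 0")
  structure(list(tissue = tissue, enriched = enriched, depleted = depleted,
                 factor = factor, depleted_factor = depleted_factor,
                 n_high = n_high, n_low = n_low,
                 length_codons = length_codons, ptr_boost = ptr_boost),
            class = "planted_signal")
}

codon_bias_weights <- function(bias) {
  w <- stats::setNames(rep(1, length(SENSE_CODONS)), SENSE_CODONS)
  if (!is.null(bias)) {
    w[bias$enriched] <- bias$factor
    w[bias$depleted] <- bias$depleted_factor
  }
  w
}

#' Generate random coding sequences
#'
#' Amino acids are drawn uniformly over the 20 standard residues (no
#' internal stops); within each synonymous family codons are drawn with
#' probability proportional to a uniform base usage times the planted bias
#' factor, if any. Reproducible given `seed`.
#'
#' @param n number of sequences.
#' @param length_codons sequence length in codons (>= 2).
#' @param bias optional [planted_signal()] whose enriched/depleted codons
#'   are biased within their families.
#' @param seed RNG seed.
#' @param prefix names are `paste0(prefix, 1:n)`.
#' @return Named character vector of CDS strings.
#' @export
generate_cds <- function(n, length_codons, bias = NULL, seed = 1,
                         prefix = "gene") {
  if (n < 1 || length_codons < 2) stop("need n >= 1 and length_codons >= 2")
  set.seed(seed)
  w <- codon_bias_weights(bias)
  aas <- names(AA_FAMILIES)
  aa_mat <- matrix(sample(aas, n * length_codons, replace = TRUE),
                   n, length_codons)
  codon_mat <- matrix("", n, length_codons)
  for (a in aas) {                      # fill per amino acid, vectorized
    pos <- which(aa_mat == a)
    if (length(pos) == 0) next
    fam <- AA_FAMILIES[[a]]
    codon_mat[pos] <- if (length(fam) == 1L) fam else
      sample(fam, length(pos), replace = TRUE, prob = w[fam] / sum(w[fam]))
  }
  seqs <- apply(codon_mat, 1, paste, collapse = "")
  stats::setNames(seqs, paste0(prefix, seq_len(n)))
}

#' Generate paired protein/mRNA expression matrices with planted PTR signal
#'
#' Emulates the shape of tissue proteomics + transcriptomics inputs:
#' log-normal mRNA abundances on the TPM scale (so a TPM < 10 filter
#' removes a realistic minority), protein abundances proportional to mRNA
#' times a gene-level log-normal PTR with tissue-level noise. For each
#' planted signal, `n_high` genes get their PTR multiplied by `ptr_boost`
#' in the signal tissue (and `n_low` genes divided by it), so the strict
#' high/low-PTR set rules recover them. About `missing_rate` of the
#' remaining protein cells are zeroed (missing completely at random);
#' signal-carrying cells are left intact so the planted construction holds.
#'
#' @param n_genes total genes (must cover all signal genes).
#' @param tissues character vector of tissue ids (>= 2).
#' @param signal a [planted_signal()] or list of them.
#' @param seed RNG seed.
#' @param mrna_meanlog,mrna_sdlog log-normal mRNA parameters (defaults
#'   log(50), 1).
#' @param ptr_sdlog gene-level PTR spread (default 0.5) and
#' @param noise_sdlog tissue-level PTR noise (default 0.3); together with
#'   the mRNA spread these give protein abundances a marginal log-sd near
#'   1.2.
#' @param missing_rate fraction of protein cells zeroed (default 0.05).
#' @return `list(protein, mrna, truth)`: two genes x tissues matrices and a
#'   `data.frame` of planted labels (gene, tissue, label).
#' @export
generate_expression <- function(n_genes, tissues, signal = list(), seed = 1,
                                mrna_meanlog = log(50), mrna_sdlog = 1,
                                ptr_sdlog = 0.5, noise_sdlog = 0.3,
                                missing_rate = 0.05) {
  if (length(tissues) < 2) stop("need >= 2 tissues")
  if (inherits(signal, "planted_signal")) signal <- list(signal)
  n_signal <- sum(vapply(signal, function(s) s$n_high + s$n_low, numeric(1)))
  if (n_signal > n_genes) stop("more signal genes than n_genes")
  set.seed(seed)

  genes <- paste0("gene", seq_len(n_genes))
  nt <- length(tissues)
  mrna <- matrix(stats::rlnorm(n_genes * nt, mrna_meanlog, mrna_sdlog),
                 n_genes, nt, dimnames = list(genes, tissues))
  base_ptr <- stats::rlnorm(n_genes, 0, ptr_sdlog)
  noise <- matrix(stats::rlnorm(n_genes * nt, 0, noise_sdlog), n_genes, nt)
  ptr <- base_ptr * noise
  dimnames(ptr) <- dimnames(mrna)

  truth <- NULL
  used <- 0L
  protected <- matrix(FALSE, n_genes, nt, dimnames = dimnames(mrna))
  for (s in signal) {
    hi <- genes[used + seq_len(s$n_high)]; used <- used + s$n_high
    lo <- genes[used + seq_len(s$n_low)]; used <- used + s$n_low
    ptr[hi, s$tissue] <- ptr[hi, s$tissue] * s$ptr_boost
    ptr[lo, s$tissue] <- ptr[lo, s$tissue] / s$ptr_boost
    # keep signal genes detectable: TPM floor in every tissue
    mrna[c(hi, lo), ] <- pmax(mrna[c(hi, lo), ], 10)
    protected[c(hi, lo), ] <- TRUE
    truth <- rbind(truth,
                   data.frame(gene = c(hi, lo), tissue = s$tissue,
                              label = rep(c("high", "low"),
                                          c(s$n_high, s$n_low))))
  }

  protein <- ptr * mrna
  miss <- matrix(stats::runif(n_genes * nt) < missing_rate, n_genes, nt) &
    !protected
  protein[miss] <- 0
  list(protein = protein, mrna = mrna,
       truth = if (is.null(truth))
         data.frame(gene = character(), tissue = character(),
                    label = character())
       else truth)
}

#' Generate the CDS complement of an expression simulation
#'
#' Convenience wrapper tying the two generators together for end-to-end
#' tests: genes labeled high in a planted signal get that signal's codon
#' bias; all other genes are unbiased.
#'
#' @param truth truth table from [generate_expression()].
#' @param all_genes character vector of every gene id in the simulation.
#' @param signal the same [planted_signal()] (or list) used for expression.
#' @param length_codons gene length in codons (default 150).
#' @param seed RNG seed.
#' @return Named character vector of CDS strings for `all_genes`.
#' @export
generate_signal_cds <- function(truth, all_genes, signal,
                                length_codons = 150, seed = 1) {
  if (inherits(signal, "planted_signal")) signal <- list(signal)
  seqs <- generate_cds(length(all_genes), length_codons, bias = NULL,
                       seed = seed)
  names(seqs) <- all_genes
  for (i in seq_along(signal)) {
    s <- signal[[i]]
    hi <- truth$gene[truth$tissue == s$tissue & truth$label == "high"]
    if (length(hi)) {
      biased <- generate_cds(length(hi), length_codons, bias = s,
                             seed = seed + i)
      names(biased) <- hi
      seqs[hi] <- biased
    }
  }
  seqs
}
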