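#' Fit a tissue codon-optimality signature
#'
#' The central fitting function of the package. From coding sequences
#' labeled high-PTR or low-PTR in one tissue it (1) computes the
#' length-normalized usage of the 61 sense codons per gene, (2) trains a
#' balanced-resampling random-forest classifier of high vs low genes
#' ([train_tissue_classifier()]), and (3) computes per-codon high/low
#' enrichment ratios ([usage_ratio()]). The result bundles the relative
#' feature weights (importances, summing to 1), the ratios (enriched
#' when above 1), and the cross-validated AUC — everything the probabilistic codon
#' optimizer needs for that tissue.
#'
#' @param seqs named character vector of CDS strings.
#' @param labels `"high"`/`"low"` label per sequence (same order or named
#'   like `seqs`).
#' @param tissue tissue identifier stored in the object.
#' @param n_trees,n_iter,n_folds,seed passed to
#'   [train_tissue_classifier()].
#' @param pseudocount passed to [usage_ratio()].
#' @return An object of class `"tissue_signature"` with fields `tissue`,
#'   `importance`, `ratio`, `auc_mean`, `auc_sd`, `report` (the full
#'   [train_tissue_classifier()] report) and a forest refit on the full
#'   balanced data used by [predict.tissue_signature()].
#' @seealso [optimize_sequences()], [write_signature_json()]
#' @examples
#' \donttest{
#' high <- generate_cds(30, 60, bias = planted_signal(enriched = c("AAA", "GGC")),
#'                      seed = 1)
#' low <- generate_cds(30, 60, seed = 2)
#' sig <- tissue_signature(c(high, low),
#'                         rep(c("high", "low"), each = 30),
#'                         tissue = "demo", n_iter = 5, seed = 7)
#' summary(sig)
#' }
#' @export
tissue_signature <- function(seqs, labels, tissue = "tissue",
                             n_trees = 100, n_iter = 100, n_folds = 5,
                             seed = 1, pseudocount = 1e-4) {
  if (length(seqs) != length(labels))
    stop("'seqs' and 'labels' must have equal length")
  pos <- as_positive(labels)
  X <- usage_matrix(seqs, "codon61")
  report <- train_tissue_classifier(X, pos, n_trees = n_trees,
                                    n_iter = n_iter, n_folds = n_folds,
                                    seed = seed)
  ratio <- usage_ratio(seqs[pos], seqs[!pos], kind = "codon61",
                       pseudocount = pseudocount)

  # one forest on a balanced draw of the full data, for predict()
  set.seed(seed)
  m <- min(sum(pos), sum(!pos))
  bal <- c(sample(which(pos), m), sample(which(!pos), m))
  forest <- randomForest::randomForest(
    X[bal, , drop = FALSE],
    factor(ifelse(pos[bal], "high", "low"), levels = c("low", "high")),
    ntree = n_trees)

  structure(list(tissue = tissue,
                 importance = report$importance,
                 ratio = ratio,
                 auc_mean = report$auc_mean,
                 auc_sd = report$auc_sd,
                 report = report,
                 forest = forest,
                 n_high = sum(pos), n_low = sum(!pos),
                 call = match.call()),
            class = "tissue_signature")
}

# minimal constructor used when deserializing or building signatures by hand
new_tissue_signature <- function(tissue, importance, ratio,
                                 auc_mean = NA_real_, auc_sd = NA_real_) {
  stopifnot(setequal(names(importance), SENSE_CODONS),
            setequal(names(ratio), SENSE_CODONS))
  importance <- importance[SENSE_CODONS]
  s <- sum(importance)
  if (!isTRUE(all.equal(s, 1, tolerance = 1e-6))) importance <- importance / s
  structure(list(tissue = tissue, importance = importance,
                 ratio = ratio[SENSE_CODONS],
                 auc_mean = auc_mean, auc_sd = auc_sd,
                 report = NULL, forest = NULL),
            class = "tissue_signature")
}

#' @export
print.tissue_signature <- function(x, ...) {
  cat(sprintf("Tissue codon signature: %s\n", x$tissue))
  if (!is.na(x$auc_mean))
    cat(sprintf("  cross-validated AUC: %.3f +/- %.3f\n",
                x$auc_mean, x$auc_sd))
  n_enr <- sum(x$ratio > 1)
  cat(sprintf("  %d of %d sense codons enriched (ratio > 1)\n",
              n_enr, length(x$ratio)))
  top <- names(sort(x$importance, decreasing = TRUE))[1:5]
  cat("  top codons by importance:", paste(top, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.tissue_signature <- function(object, n_top = 10, ...) {
  ord <- order(object$importance, decreasing = TRUE)
  tab <- data.frame(codon = names(object$importance)[ord],
                    amino_acid = unname(GENCODE[names(object$importance)[ord]]),
                    importance = unname(object$importance[ord]),
                    ratio = unname(object$ratio[names(object$importance)[ord]]),
                    row.names = NULL)
  out <- list(tissue = object$tissue, auc_mean = object$auc_mean,
              auc_sd = object$auc_sd, table = tab, n_top = n_top,
              n_high = object$n_high, n_low = object$n_low)
  class(out) <- "summary.tissue_signature"
  out
}

#' @export
print.summary.tissue_signature <- function(x, ...) {
  cat(sprintf("Tissue codon signature: %s\n", x$tissue))
  if (!is.null(x$n_high))
    cat(sprintf("  genes: %d high-PTR, %d low-PTR\n", x$n_high, x$n_low))
  if (!is.na(x$auc_mean))
    cat(sprintf("  cross-validated AUC: %.3f +/- %.3f\n", x$auc_mean, x$auc_sd))
  cat(sprintf("  top %d codons by relative feature weight:\n", x$n_top))
  print(utils::head(x$table, x$n_top), digits = 3)
  invisible(x)
}

#' @export
coef.tissue_signature <- function(object, ...) object$importance

#' Classify new sequences with a fitted signature
#'
#' Scores coding sequences (or a precomputed sense-codon usage matrix) with
#' the signature's forest; the score is the predicted probability of the
#' high-PTR class.
#'
#' @param object a [tissue_signature()] fit.
#' @param newdata character vector of CDS strings, or a genes x 61 usage
#'   matrix.
#' @param ... unused.
#' @return Named numeric vector of high-PTR probabilities.
#' @export
predict.tissue_signature <- function(object, newdata, ...) {
  if (is.null(object$forest))
    stop("this signature has no stored forest (deserialized from JSON?)")
  X <- if (is.matrix(newdata)) newdata else usage_matrix(newdata, "codon61")
  stats::predict(object$forest, X, type = "prob")[, "high"]
}

#' Plot a tissue signature
#'
#' Importance against log2 enrichment ratio for the 61 sense codons;
#' enriched codons (ratio > 1) to the right of the dashed line are the ones
#' the optimizer will incorporate.
#'
#' @param x a `tissue_signature`.
#' @param n_label number of top-importance codons to label.
#' @param ... passed to [plot()].
#' @export
plot.tissue_signature <- function(x, n_label = 8, ...) {
  lr <- log2(x$ratio)
  plot(lr, x$importance, xlab = "log2 high/low usage ratio",
       ylab = "relative feature weight",
       main = paste("Codon signature:", x$tissue),
       pch = 19, col = ifelse(x$ratio > 1, "firebrick", "grey40"), ...)
  graphics::abline(v = 0, lty = 2)
  top <- order(x$importance, decreasing = TRUE)[seq_len(n_label)]
  graphics::text(lr[top], x$importance[top], names(x$importance)[top],
                 pos = 3, cex = 0.7)
  invisible(x)
}

#' Write a tissue signature to JSON
#'
#' Serializes `{tissue, auc_mean, auc_sd, importance, ratio}`. The stored
#' forest and per-iteration report are not serialized.
#'
#' @param sig a `tissue_signature`.
#' @param path output file.
#' @export
write_signature_json <- function(sig, path) {
  jsonlite::write_json(
    list(tissue = sig$tissue,
         auc_mean = sig$auc_mean, auc_sd = sig$auc_sd,
         importance = as.list(sig$importance),
         ratio = as.list(sig$ratio)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a tissue signature from JSON
#' @param path JSON file written by [write_signature_json()].
#' @return A `tissue_signature` (without forest; [predict()] unavailable).
#' @export
read_signature_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_tissue_signature(x$tissue, unlist(x$importance), unlist(x$ratio),
                       auc_mean = x$auc_mean, auc_sd = x$auc_sd)
}
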