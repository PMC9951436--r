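#' Area under the ROC curve
#'
#' Rank-based AUC, equal to the normalized Mann-Whitney U statistic; tied
#' scores contribute 1/2. Invariant under strictly monotone transforms of
#' the scores.
#'
#' @param scores numeric classifier scores, larger = more "positive".
#' @param labels logical, 0/1, or `"high"`/`"low"` labels; `TRUE`/1/"high"
#'   is the positive class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)          # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  lab <- as.character(labels)
  if (!all(lab %in% c("high", "low")))
    stop("labels must be logical, 0/1, or 'high'/'low'")
  lab == "high"
}

# stratified fold assignment: within each class, shuffled 1..k recycling
stratified_folds <- function(pos, k) {
  fold <- integer(length(pos))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(pos == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Balanced-resampling random-forest classification of gene sets
#'
#' Trains a random forest (impurity-based importances) to separate high
#' from low genes from their usage features. To control for class-size
#' differences, each iteration subsamples the larger class down to the
#' smaller class's size (without replacement) and evaluates by stratified
#' k-fold cross-validation; per-iteration AUC is the mean over folds, and
#' the report aggregates mean/sd AUC and mean feature importances over all
#' iterations. Fully reproducible given `seed` (per-iteration seeds are
#' `seed + iteration`).
#'
#' @param X numeric matrix, genes x features (e.g. from [usage_matrix()]).
#' @param y labels per gene (`"high"`/`"low"`, logical, or 0/1).
#' @param n_trees trees per forest (default 100).
#' @param n_iter balanced resampling iterations (default 100).
#' @param n_folds cross-validation folds (default 5); the smaller class
#'   must have at least this many members.
#' @param seed master RNG seed.
#' @return A `classifier_report`: list with `aucs` (per iteration),
#'   `auc_mean`, `auc_sd`, `importance` (named, normalized to sum 1),
#'   and the training parameters.
#' @export
train_tissue_classifier <- function(X, y, n_trees = 100, n_iter = 100,
                                    n_folds = 5, seed = 1) {
  pos <- as_positive(y)
  X <- as.matrix(X)
  idx_pos <- which(pos); idx_neg <- which(!pos)
  m <- min(length(idx_pos), length(idx_neg))
  if (m < n_folds)
    stop("smaller class (", m, ") has fewer members than n_folds (",
         n_folds, ")")

  aucs <- numeric(n_iter)
  imp_sum <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (it in seq_len(n_iter)) {
    set.seed(seed + it)
    bal <- c(if (length(idx_pos) > m) sample(idx_pos, m) else idx_pos,
             if (length(idx_neg) > m) sample(idx_neg, m) else idx_neg)
    Xb <- X[bal, , drop = FALSE]
    yb <- factor(ifelse(pos[bal], "high", "low"), levels = c("low", "high"))
    fold <- stratified_folds(pos[bal], n_folds)
    fold_auc <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      train <- fold != f
      fit <- randomForest::randomForest(Xb[train, , drop = FALSE], yb[train],
                                        ntree = n_trees)
      p <- stats::predict(fit, Xb[!train, , drop = FALSE],
                          type = "prob")[, "high"]
      fold_auc[f] <- roc_auc(p, yb[!train] == "high")
      imp_sum <- imp_sum +
        fit$importance[colnames(X), "MeanDecreaseGini"] / n_folds
    }
    aucs[it] <- mean(fold_auc)
  }
  imp <- imp_sum / n_iter
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  structure(list(aucs = aucs, auc_mean = mean(aucs),
                 auc_sd = stats::sd(aucs),
                 importance = stats::setNames(as.numeric(imp), colnames(X)),
                 n_trees = n_trees, n_iter = n_iter, n_folds = n_folds,
                 seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "Balanced RF classifier: AUC %.3f +/- %.3f (%d iterations, %d trees, %d-fold CV)\n",
    x$auc_mean, x$auc_sd, x$n_iter, x$n_trees, x$n_folds))
  invisible(x)
}

#' Recursive feature elimination
#'
#' Starting from the full feature set, repeatedly retrains the balanced
#' classifier, records the cross-validated AUC, and removes the feature
#' with the smallest mean importance, down to a single feature. Returns one
#' row per feature count.
#'
#' @inheritParams train_tissue_classifier
#' @return `data.frame` with columns `n_features`, `auc`, and `dropped`
#'   (the feature eliminated after that evaluation).
#' @export
recursive_feature_elimination <- function(X, y, n_trees = 100, n_iter = 5,
                                          n_folds = 5, seed = 1) {
  feats <- colnames(X)
  out <- vector("list", length(feats))
  step <- 1L
  while (length(feats) >= 1L) {
    rep_ <- train_tissue_classifier(X[, feats, drop = FALSE], y,
                                    n_trees = n_trees, n_iter = n_iter,
                                    n_folds = n_folds, seed = seed)
    worst <- feats[which.min(rep_$importance)]
    out[[step]] <- data.frame(n_features = length(feats),
                              auc = rep_$auc_mean, dropped = worst)
    feats <- setdiff(feats, worst)
    step <- step + 1L
  }
  do.call(rbind, out)
}

#' Codon (or codon-pair) enrichment ratios between gene sets
#'
#' Elementwise ratio of the mean length-normalized usage of the high set to
#' that of the low set, with a pseudocount added to both numerator and
#' denominator frequencies so rare features do not divide by zero. A ratio
#' above 1 marks a feature enriched in high genes.
#'
#' @param high,low character vectors of CDS strings.
#' @param kind `"codon61"` or `"pair4096"`.
#' @param pseudocount added to both mean frequencies (default 1e-4).
#' @return Named numeric vector of positive ratios.
#' @export
usage_ratio <- function(high, low, kind = c("codon61", "pair4096"),
                        pseudocount = 1e-4) {
  kind <- match.arg(kind)
  if (length(high) == 0 || length(low) == 0) stop("empty gene set")
  (mean_usage(high, kind) + pseudocount) /
    (mean_usage(low, kind) + pseudocount)
}

#' Expected codon-pair ratios from single-codon ratios
#'
#' Under independence the expected pair ratio is the product of the two
#' constituent codons' single ratios: `expected(AB) = ratio(A) * ratio(B)`.
#' Computed for every ordered pair of codons present in `single`, keyed by
#' hexamer.
#'
#' @param single named numeric vector of single-codon ratios.
#' @return Named numeric vector of expected pair ratios.
#' @export
expected_pair_ratio <- function(single) {
  if (is.null(names(single)) || anyNA(single))
    stop("'single' must be a complete named ratio vector")
  codons <- names(single)
  out <- as.vector(outer(single, single))          # column-major: B varies first
  names(out) <- as.vector(outer(codons, codons, function(a, b) paste0(b, a)))
  # reorder to first-codon-major for readability
  keys <- as.vector(t(outer(codons, codons, paste0)))
  out[keys]
}

#' Regress observed codon-pair ratios on expected ratios
#'
#' Ordinary least squares of observed (dependent) on expected (independent)
#' pair ratios, matched by name; reports slope, intercept, R squared,
#' residual standard error and the model F-test p-value.
#'
#' @param observed,expected named numeric vectors of pair ratios.
#' @return `list(slope, intercept, r_squared, rse, p_value, n)`.
#' @export
regress_observed_expected <- function(observed, expected) {
  keys <- intersect(names(observed), names(expected))
  if (length(keys) < 3) stop("need at least 3 shared pairs")
  x <- expected[keys]; yv <- observed[keys]
  if (stats::var(x) == 0) stop("expected ratios have zero variance")
  fit <- stats::lm(yv ~ x)
  sm <- summary(fit)
  p <- if (is.null(sm$fstatistic)) NA_real_ else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, rse = sm$sigma,
       p_value = unname(p), n = length(keys))
}

#' PCA of per-tissue codon-pair ratios
#'
#' Centered principal component analysis of a tissue x pair-ratio matrix,
#' to explore the main variability among tissues along the 4096 codon-pair
#' ratios.
#'
#' @param ratios numeric matrix, tissues in rows, pair features in columns.
#' @param n_components number of components to keep (default 2).
#' @return `list(scores, explained_variance, rotation)`; explained-variance
#'   fractions are non-increasing and sum to at most 1.
#' @export
pca_pair_ratios <- function(ratios, n_components = 2) {
  if (nrow(ratios) < 2) stop("need at least 2 tissues")
  centered <- scale(ratios, center = TRUE, scale = FALSE)
  if (sum(centered^2) == 0) stop("zero total variance across tissues")
  pc <- stats::prcomp(ratios, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2)),
       rotation = pc$rotation[, seq_len(k), drop = FALSE])
}

#' Compare main-model AUCs to control-model AUCs
#'
#' Counts tissues where the control AUC is strictly lower than the main
#' model's (ties do not count) and tests, one-tailed (upper) binomial at
#' success probability 1/2, whether controls are lower more often than
#' chance.
#'
#' @param main_auc,control_auc numeric vectors of per-tissue AUCs, equal
#'   length and matching order.
#' @return `list(n_lower, n, p_value)`.
#' @export
compare_to_controls <- function(main_auc, control_auc) {
  if (length(main_auc) != length(control_auc)) stop("length mismatch")
  n <- length(main_auc)
  if (n < 1) stop("need at least one tissue")
  n_lower <- sum(control_auc < main_auc)
  list(n_lower = n_lower, n = n,
       p_value = stats::pbinom(n_lower - 1, n, 0.5, lower.tail = FALSE))
}
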