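test_that("roc_auc equals the concordant-pair count and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8), c(1, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(5)
  for (rep_i in 1:5) {
    scores <- sample(seq(0, 1, 0.1), 20, replace = TRUE)  # forces ties
    labels <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), auc_oracle(scores, labels))
  }
})

test_that("roc_auc is invariant under strictly monotone transforms", {
  set.seed(9)
  scores <- rnorm(30)
  labels <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)
  expect_equal(roc_auc(rank(scores), labels), a)
  # independent implementation cross-check
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                 quiet = TRUE,
                                                 direction = "<"))))
})

test_that("classifier training is reproducible and balanced", {
  set.seed(1)
  X <- usage_matrix(generate_cds(40, 50, seed = 3), "codon61")
  y <- rep(c("high", "low"), each = 20)
  r1 <- train_tissue_classifier(X, y, n_trees = 20, n_iter = 3, seed = 11)
  r2 <- train_tissue_classifier(X, y, n_trees = 20, n_iter = 3, seed = 11)
  expect_identical(r1, r2)
  expect_length(r1$aucs, 3)
  expect_true(all(r1$aucs >= 0 & r1$aucs <= 1))
  expect_equal(sum(r1$importance), 1, tolerance = 1e-9)
  expect_error(train_tissue_classifier(X[1:6, ], rep(c("high", "low"), 3),
                                       n_folds = 5),
               "fewer members than n_folds")
})

test_that("permuted labels give no-skill AUC and planted signal is learned", {
  planted <- c("AAA", "GGC", "CTG", "GTG", "CCA")
  high <- generate_cds(50, 100, bias = planted_signal(enriched = planted,
                                                      factor = 4),
                       seed = 21, prefix = "h")
  low <- generate_cds(50, 100, seed = 22, prefix = "l")
  X <- usage_matrix(c(high, low), "codon61")
  y <- rep(c("high", "low"), each = 50)
  # permuted-label null
  set.seed(33)
  y_perm <- sample(y)
  null_rep <- train_tissue_classifier(X, y_perm, n_trees = 50, n_iter = 10,
                                      seed = 44)
  expect_lt(abs(null_rep$auc_mean - 0.5), 0.1)
  # planted signal: near-perfect separation, planted codons on top
  sig_rep <- train_tissue_classifier(X, y, n_trees = 50, n_iter = 10,
                                     seed = 44)
  expect_gt(sig_rep$auc_mean, 0.8)
  # at this reduced problem size family partners of planted codons (which
  # carry the mirrored signal) can displace one; the top-10 weights must
  # still be dominated by the planted families
  top10 <- names(sort(sig_rep$importance, decreasing = TRUE))[1:10]
  expect_gte(length(intersect(top10, planted)), 4)
  planted_fams <- unique(GC_TABLE[planted])
  expect_gte(sum(GC_TABLE[top10] %in% planted_fams), 6)
})

test_that("recursive feature elimination returns one point per feature count", {
  high <- generate_cds(20, 60, bias = planted_signal(enriched = "AAA",
                                                     factor = 8),
                       seed = 51, prefix = "h")
  low <- generate_cds(20, 60, seed = 52, prefix = "l")
  X <- usage_matrix(c(high, low), "codon61")
  y <- rep(c("high", "low"), each = 20)
  rfe <- recursive_feature_elimination(X, y, n_trees = 10, n_iter = 1,
                                       n_folds = 2, seed = 61)
  expect_equal(nrow(rfe), 61)
  expect_equal(rfe$n_features, 61:1)
  expect_false(anyNA(rfe$auc))
  # a single strongly planted codon keeps most of the AUC at n_features = 1
  expect_gt(rfe$auc[rfe$n_features == 1], rfe$auc[rfe$n_features == 61] - 0.2)
})

test_that("usage ratios follow pseudocount arithmetic", {
  s <- random_cds(30, 71)
  expect_equal(unname(usage_ratio(s, s)), rep(1, 61))
  # two-gene toy: high uses only AAA for Lys, low only AAG
  high <- "AAAAAA"; low <- "AAGAAG"
  r <- usage_ratio(high, low, pseudocount = 1e-4)
  expect_equal(unname(r["AAA"]), (1 + 1e-4) / 1e-4)
  expect_equal(unname(r["AAG"]), 1e-4 / (1 + 1e-4))
  expect_length(usage_ratio(high, low, kind = "pair4096"), 4096)
})

test_that("expected pair ratios are products of single ratios", {
  single <- c(AAA = 2, GGG = 3, TTT = 1)
  ep <- expected_pair_ratio(single)
  expect_equal(unname(ep["AAAGGG"]), 6)
  expect_equal(unname(ep["GGGAAA"]), 6)
  expect_equal(unname(ep["TTTTTT"]), 1)
  # uniform in, uniform out
  expect_true(all(expected_pair_ratio(c(A = 1, B = 1, C = 1)) == 1))
  # brute-force double loop over a full 61-codon map
  set.seed(81)
  full <- stats::setNames(rlnorm(61, 0, 0.5), ALL_SENSE)
  ep_full <- expected_pair_ratio(full)
  expect_length(ep_full, 61^2)
  for (i in sample(61, 5)) for (j in sample(61, 5)) {
    key <- paste0(ALL_SENSE[i], ALL_SENSE[j])
    expect_equal(unname(ep_full[key]), full[[i]] * full[[j]])
  }
})

test_that("observed-vs-expected regression matches the OLS oracle", {
  ep <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  # exact fits trigger lm's perfect-fit warning by design
  fit0 <- suppressWarnings(regress_observed_expected(ep, ep))
  expect_equal(fit0$r_squared, 1)
  expect_equal(fit0$rse, 0, tolerance = 1e-12)
  fit2 <- suppressWarnings(regress_observed_expected(2 * ep, ep))
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$r_squared, 1)
  # noisy case against the closed-form normal equations
  set.seed(91)
  x <- rlnorm(50); obs <- 1.5 * x + 0.2 + rnorm(50, 0, 0.1)
  names(x) <- names(obs) <- paste0("p", 1:50)
  fit <- regress_observed_expected(obs, x)
  beta <- cov(x, obs) / var(x)
  alpha <- mean(obs) - beta * mean(x)
  expect_equal(fit$slope, beta)
  expect_equal(fit$intercept, alpha)
  resid <- obs - alpha - beta * x
  expect_equal(fit$r_squared, 1 - sum(resid^2) / sum((obs - mean(obs))^2))
  expect_equal(fit$rse, sqrt(sum(resid^2) / 48))
  expect_error(regress_observed_expected(ep, ep * 0 + 1), "zero variance")
})

test_that("PCA of pair ratios separates duplicated tissue clusters", {
  set.seed(101)
  base1 <- rlnorm(200); base2 <- rlnorm(200)
  m <- rbind(t1 = base1, t2 = base1 + rnorm(200, 0, 1e-3),
             t3 = base2, t4 = base2 + rnorm(200, 0, 1e-3))
  pc <- pca_pair_ratios(m)
  expect_gt(pc$explained_variance[1], 0.99)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  # PC1 separates the two groups
  s1 <- pc$scores[, 1]
  expect_true(max(s1[c("t1", "t2")]) < min(s1[c("t3", "t4")]) ||
                min(s1[c("t1", "t2")]) > max(s1[c("t3", "t4")]))
  expect_error(pca_pair_ratios(m[1, , drop = FALSE]), "at least 2")
  expect_error(pca_pair_ratios(rbind(base1, base1)), "zero total variance")
})

test_that("control comparison counts strict wins with a binomial tail", {
  r <- compare_to_controls(rep(0.8, 36), rep(0.6, 36))
  expect_equal(r$n_lower, 36)
  expect_equal(r$p_value, 0.5^36)
  half <- compare_to_controls(c(rep(0.8, 5), rep(0.6, 5)),
                              c(rep(0.6, 5), rep(0.8, 5)))
  expect_equal(half$n_lower, 5)
  expect_equal(half$p_value, sum(dbinom(5:10, 10, 0.5)))
  # ties are not wins
  expect_equal(compare_to_controls(c(0.7, 0.7), c(0.7, 0.6))$n_lower, 1)
  expect_error(compare_to_controls(1:3 / 10, 1:2 / 10), "length mismatch")
})

test_that("tissue_signature bundles report, ratios and a usable predictor", {
  planted <- c("AAA", "GGC")
  high <- generate_cds(25, 80, bias = planted_signal(enriched = planted,
                                                     factor = 6),
                       seed = 111, prefix = "h")
  low <- generate_cds(25, 80, seed = 112, prefix = "l")
  sig <- tissue_signature(c(high, low), rep(c("high", "low"), each = 25),
                          tissue = "demo", n_trees = 50, n_iter = 5,
                          seed = 120)
  expect_s3_class(sig, "tissue_signature")
  expect_equal(sum(sig$importance), 1, tolerance = 1e-9)
  expect_setequal(names(sig$ratio), ALL_SENSE)
  expect_true(all(sig$ratio[planted] > 1))
  expect_gt(sig$auc_mean, 0.7)
  # coef() is the importance vector; predict() separates fresh genes
  expect_equal(coef(sig), sig$importance)
  fresh_high <- generate_cds(10, 80, bias = planted_signal(enriched = planted,
                                                           factor = 6),
                             seed = 113, prefix = "fh")
  fresh_low <- generate_cds(10, 80, seed = 114, prefix = "fl")
  p <- predict(sig, c(fresh_high, fresh_low))
  expect_gt(roc_auc(p, rep(c(TRUE, FALSE), each = 10)), 0.7)
  # JSON round trip preserves the signature content
  path <- tempfile(fileext = ".json")
  write_signature_json(sig, path)
  back <- read_signature_json(path)
  expect_equal(back$importance, sig$importance, tolerance = 1e-12)
  expect_equal(back$ratio, sig$ratio, tolerance = 1e-12)
  expect_equal(back$auc_mean, sig$auc_mean)
  expect_error(predict(back, fresh_high), "no stored forest")
})
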