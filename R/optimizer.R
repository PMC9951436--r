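#' Sample one tissue-optimized synonymous sequence
#'
#' For each amino acid a synonymous codon is drawn with probability
#' proportional to the signature's relative feature weights within the
#' family; a drawn codon is incorporated if it is enriched in the tissue
#' (usage ratio > 1) and otherwise excluded and redrawn from the remaining
#' family members. When every family member is depleted the fallback policy
#' applies (default: the family codon with the largest ratio).
#' Single-codon families (Met, Trp) are emitted directly. A trailing `*`
#' emits the stop codon `stop_codon`.
#'
#' Draws use the current RNG state; seed control lives in
#' [optimize_sequences()], which also implements the `top_codons`
#' restriction.
#'
#' @param protein amino-acid string (optionally ending in `*`).
#' @param sig a [tissue_signature()].
#' @param fallback `"max_ratio"` (default), `"max_importance"`, or
#'   `"reference"` (reference-usage draw; needs `ref`).
#' @param ref optional [reference_tables()] for `fallback = "reference"`.
#' @param stop_codon codon emitted for a trailing `*` (default `"TAA"`).
#' @return CDS string translating back to `protein`, with attribute
#'   `fallback_positions` listing positions where the fallback fired.
#' @export
optimize_one <- function(protein, sig, fallback = "max_ratio", ref = NULL,
                         stop_codon = "TAA") {
  aa <- strsplit(protein, "")[[1]]
  has_stop <- length(aa) > 0 && aa[length(aa)] == "*"
  if (has_stop) aa <- aa[-length(aa)]
  if (any(aa == "*")) stop("internal '*' in protein sequence")
  unknown <- setdiff(aa, names(AA_FAMILIES))
  if (length(unknown))
    stop("unknown amino-acid symbol(s): ", paste(unknown, collapse = ", "))

  plans <- family_sampling_plans(sig, fallback, ref)
  codons <- character(length(aa))
  fell_back <- logical(length(aa))
  for (i in seq_along(aa)) {
    plan <- plans[[aa[i]]]
    codons[i] <- sample_codon_once(plan)
    fell_back[i] <- plan$fallback_only
  }
  out <- paste0(paste(codons, collapse = ""),
                if (has_stop) stop_codon else "")
  structure(out, fallback_positions = which(fell_back))
}

# Per-amino-acid sampling plan. The sequential draw-and-exclude process
# lands on each enriched codon with probability proportional to its weight
# (the first enriched element of a weight-proportional random permutation),
# so enriched families reduce to a single weighted draw over the enriched
# codons; fully depleted families resolve to the fallback codon.
family_sampling_plans <- function(sig, fallback = "max_ratio", ref = NULL) {
  lapply(AA_FAMILIES, function(fam) {
    if (length(fam) == 1L)
      return(list(codons = fam, prob = 1, fallback_only = FALSE))
    enriched <- fam[sig$ratio[fam] > 1]
    if (length(enriched) > 0) {
      w <- sig$importance[enriched]
      if (sum(w) <= 0) w <- rep(1, length(enriched))
      return(list(codons = enriched, prob = w / sum(w),
                  fallback_only = FALSE))
    }
    pick <- switch(fallback,
      max_ratio = fam[which.max(sig$ratio[fam])],
      max_importance = fam[which.max(sig$importance[fam])],
      reference = {
        if (is.null(ref)) stop("fallback 'reference' needs 'ref'")
        fam[which.max(ref$codon_count[fam])]
      },
      stop("unknown fallback policy: ", fallback))
    list(codons = pick, prob = 1, fallback_only = TRUE)
  })
}

sample_codon_once <- function(plan) {
  if (length(plan$codons) == 1L) return(plan$codons)
  sample(plan$codons, 1L, prob = plan$prob)
}

#' Generate a pool of tissue-optimized synonymous sequences
#'
#' Repeats the probabilistic optimization of [optimize_one()] `n_pool`
#' times with a seeded RNG, returning the pool as a `codon_pool` object.
#' Duplicates are retained (the pool is a multiset). The input may be an
#' amino-acid sequence or a DNA CDS; DNA is translated first and its stop
#' codon, if present, is copied through unoptimized.
#'
#' With `top_codons = k`, only the k codons with the largest signature
#' importances are subject to the enrich/deplete logic; positions whose
#' synonymous family contains none of them are drawn from the reference
#' codon usage within the family.
#'
#' @param input amino-acid string or DNA CDS; see `input_type`.
#' @param sig a [tissue_signature()].
#' @param n_pool number of candidates (default 1000).
#' @param top_codons `"all"` (default) or an integer in \[1, 61\].
#' @param seed RNG seed; same seed, same pool.
#' @param input_type `"auto"` (ACGTU-only strings of length divisible by 3
#'   are treated as DNA), `"protein"`, or `"dna"`.
#' @param ref [reference_tables()]; required when `top_codons` is numeric,
#'   defaults to [default_reference()].
#' @param fallback,stop_codon passed to [optimize_one()].
#' @return A `codon_pool`: list with `candidates` (character vector),
#'   `protein`, `tissue`, `fallback_count` per candidate, and the call
#'   parameters.
#' @export
optimize_sequences <- function(input, sig, n_pool = 1000, top_codons = "all",
                               seed = 1, input_type = c("auto", "protein", "dna"),
                               ref = NULL, fallback = "max_ratio",
                               stop_codon = "TAA") {
  input_type <- match.arg(input_type)
  if (n_pool < 1) stop("'n_pool' must be >= 1")
  up <- toupper(input)
  is_dna <- switch(input_type,
                   dna = TRUE, protein = FALSE,
                   auto = !grepl("[^ACGTU]", up) && nchar(up) %% 3 == 0)
  if (is_dna) {
    cds_in <- validate_cds(up)
    protein <- translate_cds(cds_in)
    last <- substr(cds_in, nchar(cds_in) - 2, nchar(cds_in))
    if (last %in% STOP_CODONS) stop_codon <- last
  } else {
    protein <- up
  }

  aa <- strsplit(sub("\\*$", "", protein), "")[[1]]
  unknown <- setdiff(aa, names(AA_FAMILIES))
  if (length(unknown))
    stop("unknown amino-acid symbol(s): ", paste(unknown, collapse = ", "))
  has_stop <- grepl("\\*$", protein)

  plans <- family_sampling_plans(sig, fallback, ref)
  if (!identical(top_codons, "all")) {
    top_codons <- as.integer(top_codons)
    if (top_codons < 1 || top_codons > 61)
      stop("'top_codons' must be 'all' or an integer in [1, 61]")
    if (is.null(ref)) ref <- default_reference()
    top_set <- names(sort(sig$importance, decreasing = TRUE))[seq_len(top_codons)]
    plans <- lapply(names(plans), function(a) {
      fam <- AA_FAMILIES[[a]]
      if (any(fam %in% top_set)) return(plans[[a]])
      w <- ref$codon_count[fam] + 0.5
      list(codons = fam, prob = as.numeric(w / sum(w)), fallback_only = FALSE)
    }) |> stats::setNames(names(plans))
  }

  # column-wise sampling: position i is i.i.d. across the pool
  set.seed(seed)
  pool_codons <- matrix("", nrow = n_pool, ncol = length(aa))
  for (i in seq_along(aa)) {
    plan <- plans[[aa[i]]]
    pool_codons[, i] <- if (length(plan$codons) == 1L)
      rep(plan$codons, n_pool)
    else sample(plan$codons, n_pool, replace = TRUE, prob = plan$prob)
  }
  candidates <- apply(pool_codons, 1, paste, collapse = "")
  if (has_stop) candidates <- paste0(candidates, stop_codon)
  fb_positions <- which(vapply(plans[aa], `[[`, logical(1), "fallback_only"))

  structure(list(candidates = candidates,
                 protein = protein,
                 tissue = sig$tissue,
                 n_pool = n_pool, top_codons = top_codons, seed = seed,
                 fallback_positions = fb_positions),
            class = "codon_pool")
}

#' @export
print.codon_pool <- function(x, ...) {
  cat(sprintf("Codon pool for tissue '%s': %d candidates, %d aa protein\n",
              x$tissue, length(x$candidates),
              nchar(sub("\\*$", "", x$protein))))
  cat(sprintf("  unique sequences: %d; seed %d; top_codons %s\n",
              length(unique(x$candidates)), x$seed,
              paste(x$top_codons, collapse = "")))
  if (length(x$fallback_positions))
    cat("  fallback (all-depleted family) at positions:",
        paste(x$fallback_positions, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.codon_pool <- function(object, ...) {
  syn <- vapply(object$candidates,
                function(s) translate_cds(s) == object$protein, logical(1))
  cat(sprintf("Codon pool: %d candidates (%d unique), synonymy %.1f%%\n",
              length(object$candidates), length(unique(object$candidates)),
              100 * mean(syn)))
  invisible(list(n = length(object$candidates),
                 n_unique = length(unique(object$candidates)),
                 synonymy = mean(syn)))
}

metric_value <- function(metric, seqs, ref, gc_target) {
  switch(metric,
         MFE    = vapply(seqs, mfe, numeric(1), region = "rest"),
         MFEini = vapply(seqs, mfe, numeric(1), region = "ini40"),
         CAI    = vapply(seqs, cai, numeric(1), ref = ref),
         CPB    = vapply(seqs, cpb, numeric(1), ref = ref),
         ENC    = vapply(seqs, enc, numeric(1)),
         GC     = vapply(seqs, gc_distance, numeric(1), target = gc_target),
         stop("unknown metric: ", metric))
}

#' Rank and select the best candidates of a pool
#'
#' Applies the homopolymer and motif filters, computes the requested
#' metrics on the surviving unique sequences, converts each metric column
#' to ranks oriented so the requested direction is best (rank 1), and
#' orders candidates by mean rank (ties broken by sequence content, so the
#' result does not depend on pool order). `GC` is scored as distance to
#' `gc_target` and minimized.
#'
#' @param pool a [optimize_sequences()] pool (or plain character vector).
#' @param metrics named character vector mapping metric name (`MFE`,
#'   `MFEini`, `CAI`, `CPB`, `ENC`, `GC`) to direction `"min"`/`"max"`.
#'   Default is the standard design recipe
#'   `c(MFE = "min", MFEini = "max", CAI = "max", CPB = "max", ENC = "min")`.
#' @param ref [reference_tables()] (default [default_reference()]).
#' @param homopolymers drop candidates containing a run of this length or
#'   longer (default 7); `NULL` disables.
#' @param motifs character vector of forbidden motifs; `NULL` disables.
#' @param top number of candidates to return (default 10).
#' @param gc_target GC fraction target, required if `GC` is requested.
#' @param aggregate `"rank"` (default, mean rank) or `"zscore"` (mean
#'   direction-oriented z-score).
#' @return `data.frame` with columns `rank`, `sequence`, one column per
#'   metric, and `score`; best candidate first.
#' @export
select_best <- function(pool,
                        metrics = c(MFE = "min", MFEini = "max", CAI = "max",
                                    CPB = "max", ENC = "min"),
                        ref = NULL, homopolymers = 7, motifs = NULL,
                        top = 10, gc_target = NULL,
                        aggregate = c("rank", "zscore")) {
  aggregate <- match.arg(aggregate)
  seqs <- if (inherits(pool, "codon_pool")) pool$candidates else pool
  if (length(seqs) == 0) stop("empty pool")
  if (is.null(ref) && any(names(metrics) %in% c("CAI", "CPB")))
    ref <- default_reference()
  if ("GC" %in% names(metrics) && is.null(gc_target))
    stop("metric 'GC' needs 'gc_target'")
  if (!all(metrics %in% c("min", "max")))
    stop("metric directions must be 'min' or 'max'")

  keep <- rep(TRUE, length(seqs))
  if (!is.null(homopolymers)) keep <- keep & !has_homopolymer(seqs, homopolymers)
  if (!is.null(motifs)) keep <- keep & !contains_motif(seqs, motifs)
  seqs <- unique(seqs[keep])
  if (length(seqs) == 0)
    stop("all candidates removed by homopolymer/motif filters")

  vals <- vapply(names(metrics), metric_value, numeric(length(seqs)),
                 seqs = seqs, ref = ref, gc_target = gc_target)
  vals <- matrix(vals, nrow = length(seqs),
                 dimnames = list(NULL, names(metrics)))
  oriented <- sweep(vals, 2, ifelse(metrics == "min", 1, -1), `*`)
  score <- if (aggregate == "rank") {
    ranks <- apply(oriented, 2, rank)
    if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = length(seqs))
    rowMeans(ranks)
  } else {
    z <- scale(oriented)
    z[is.nan(z)] <- 0                       # zero-variance column
    rowMeans(z)
  }
  ord <- order(score, seqs)
  sel <- utils::head(ord, top)
  data.frame(rank = seq_along(sel), sequence = seqs[sel],
             vals[sel, , drop = FALSE], score = score[sel],
             row.names = NULL)
}

#' Full per-candidate metric audit table
#'
#' Computes every standard metric plus filter flags for each candidate in
#' the pool, without any filtering; each row is reproducible from the
#' sequence alone.
#'
#' @param pool [optimize_sequences()] pool or character vector.
#' @param ref [reference_tables()] (default [default_reference()]).
#' @param gc_target GC target for the `GC` column (default 0.5).
#' @param homopolymers run length for the homopolymer flag (default 7).
#' @param motifs motifs for the motif flag (default none).
#' @return `data.frame`, one row per candidate.
#' @export
score_report <- function(pool, ref = NULL, gc_target = 0.5,
                         homopolymers = 7, motifs = NULL) {
  seqs <- if (inherits(pool, "codon_pool")) pool$candidates else pool
  if (length(seqs) == 0) stop("empty pool")
  if (is.null(ref)) ref <- default_reference()
  data.frame(
    sequence = seqs,
    MFE = vapply(seqs, mfe, numeric(1), region = "rest"),
    MFEini = vapply(seqs, mfe, numeric(1), region = "ini40"),
    CAI = vapply(seqs, cai, numeric(1), ref = ref),
    CPB = vapply(seqs, cpb, numeric(1), ref = ref),
    ENC = vapply(seqs, enc, numeric(1)),
    GC = vapply(seqs, gc_distance, numeric(1), target = gc_target),
    homopolymer = has_homopolymer(seqs, homopolymers),
    motif = contains_motif(seqs, motifs),
    row.names = NULL)
}
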