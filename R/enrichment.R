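# Gene-set over-representation, matched-background rank-sum enrichment,
# metabolic keyword filtering, and tier classification of candidate genes.

#' Hypergeometric over-representation of a gene set among top genes
#'
#' One-sided hypergeometric tail probability of observing at least the
#' realized overlap between the top-ranked genes and a gene set, within a
#' stated gene universe. Fold enrichment is the overlap fraction among top
#' genes divided by the set's fraction of the universe.
#'
#' @param top_genes Character vector of top-ranked genes (subset of
#'   `universe`).
#' @param set Character vector, the gene set (intersected with the
#'   universe).
#' @param universe Character vector of all testable genes.
#' @param set_name Optional label.
#' @return Data frame: `set`, `method`, `overlap`, `fold`, `p`,
#'   `contributing` (comma-separated overlap genes), `background`.
#' @export
hypergeometric_enrichment <- function(top_genes, set, universe,
                                      set_name = "set") {
  if (!length(universe)) stopf("empty universe")
  universe <- unique(universe)
  set_u <- intersect(unique(set), universe)
  if (!length(set_u)) stopf("gene set has no members in the universe")
  top <- intersect(unique(top_genes), universe)
  if (length(top) < length(unique(top_genes)))
    warnf("%d top genes are outside the universe and were dropped",
          length(unique(top_genes)) - length(top))
  k <- length(intersect(top, set_u))
  m <- length(set_u)
  N <- length(universe)
  n <- length(top)
  p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  fold <- (k / n) / (m / N)
  data.frame(set = set_name, method = "hypergeometric",
             overlap = k, fold = fold, p = p,
             contributing = paste(sort(intersect(top, set_u)),
                                  collapse = ","),
             background = sprintf("universe of %d genes", N),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values for a vector of P-values
#'
#' Thin wrapper over `p.adjust(method = "BH")`, provided as the package's
#' false-discovery-rate control for batches of hypergeometric tests.
#'
#' @param p P-value vector.
#' @return q-values in the input order.
#' @export
bh_qvalues <- function(p) stats::p.adjust(p, method = "BH")

#' Select background genes matched on variant count and frequency
#'
#' Bins all genes into deciles of variant count crossed with deciles of
#' combined minor allele frequency, then samples non-target genes from the
#' bins occupied by the target genes (a configured multiple per target
#' gene, without replacement while possible). A bin with no available
#' candidates falls back to the nearest occupied bin by Manhattan distance
#' on the decile grid, with a message.
#'
#' @param target_genes Character vector of target genes.
#' @param gene_stats Data frame with `gene`, `n_variants`, `combined_maf`
#'   for every gene in the universe.
#' @param n_bins Number of quantile bins per dimension (default 10).
#' @param multiple Background size as a multiple of the target size
#'   (default 10).
#' @param seed RNG seed for the sampling.
#' @return List of class `background_match`: `background` (gene vector),
#'   `bins` (per-gene bin table), `description`.
#' @export
match_background <- function(target_genes, gene_stats, n_bins = 10,
                             multiple = 10, seed = 1L) {
  stopifnot(all(c("gene", "n_variants", "combined_maf") %in%
                  names(gene_stats)))
  missing <- setdiff(target_genes, gene_stats$gene)
  if (length(missing))
    stopf("match_background: no variant stats for gene(s) %s",
          paste(utils::head(missing, 5), collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  qbin <- function(x) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                 na.rm = TRUE))
    if (length(br) < 2) return(rep(1L, length(x)))
    as.integer(cut(x, br, include.lowest = TRUE))
  }
  gs <- gene_stats
  gs$bin_nvar <- qbin(gs$n_variants)
  gs$bin_maf <- qbin(gs$combined_maf)
  is_target <- gs$gene %in% target_genes
  pool <- gs[!is_target, , drop = FALSE]
  taken <- character()
  for (g in target_genes) {
    tg <- gs[gs$gene == g, ]
    avail <- pool[!(pool$gene %in% taken), , drop = FALSE]
    if (!nrow(avail)) break
    dist <- abs(avail$bin_nvar - tg$bin_nvar) +
      abs(avail$bin_maf - tg$bin_maf)
    exact <- which(dist == 0)
    if (!length(exact)) {
      message(sprintf(
        "match_background: bin (%d,%d) of gene %s empty; nearest-bin fallback",
        tg$bin_nvar, tg$bin_maf, g))
      exact <- which(dist == min(dist))
    }
    take <- sample(exact, min(multiple, length(exact)))
    taken <- c(taken, avail$gene[take])
  }
  structure(list(background = taken,
                 bins = gs[, c("gene", "bin_nvar", "bin_maf")],
                 description = sprintf(
                   "%d genes matched on variant-count x combined-MAF deciles (%dx target size requested)",
                   length(taken), multiple)),
            class = "background_match")
}

#' Rank-sum enrichment of a gene set against a matched background
#'
#' One-sided Wilcoxon rank-sum test that the set's gene-level P-values are
#' smaller than those of the matched background. Fold enrichment is the
#' ratio of nominal-significance fractions (share of genes with P < 0.05
#' in the set versus the background); a zero denominator yields a missing
#' fold. Invariant to any strictly monotone transform of the P-values.
#'
#' @param set Character vector of set genes.
#' @param gene_p Named vector of gene-level P-values.
#' @param background A [match_background()] result or a character vector of
#'   background genes.
#' @param set_name Optional label.
#' @param nominal Nominal significance threshold for the fold numerator
#'   and the contributing-gene list (default 0.05).
#' @return Data frame in the same layout as
#'   [hypergeometric_enrichment()].
#' @export
rank_sum_enrichment <- function(set, gene_p, background, set_name = "set",
                                nominal = 0.05) {
  bg_genes <- if (inherits(background, "background_match"))
    background$background else background
  if (!length(bg_genes)) stopf("rank_sum_enrichment: empty background")
  x <- gene_p[intersect(set, names(gene_p))]
  x <- x[!is.na(x)]
  y <- gene_p[intersect(setdiff(bg_genes, set), names(gene_p))]
  y <- y[!is.na(y)]
  if (length(x) < 2) stopf("need >= 2 set genes with P-values")
  if (!length(y)) stopf("rank_sum_enrichment: empty background")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "less",
                                            exact = FALSE, correct = TRUE))
  fx <- mean(x < nominal)
  fy <- mean(y < nominal)
  fold <- if (fy == 0) NA_real_ else fx / fy
  data.frame(set = set_name, method = "rank-sum",
             overlap = length(x), fold = fold, p = wt$p.value,
             contributing = paste(sort(names(x)[x < nominal]),
                                  collapse = ","),
             background = sprintf("%d matched background genes", length(y)),
             stringsAsFactors = FALSE)
}

#' Filter gene sets by metabolic keywords
#'
#' Case-insensitive substring match of keywords against set names, in a
#' deterministic (input) order. The default keywords select phenotype
#' ontology sets related to the metabolic presentation of type 2 diabetes.
#'
#' @param sets Named list of gene sets.
#' @param keywords Character vector of keywords.
#' @return The matching subset of `sets`.
#' @export
filter_metabolic_sets <- function(sets,
                                  keywords = c("diabetes", "hyperglycemia",
                                               "overweight", "waist",
                                               "insulin", "c-peptide")) {
  if (!length(keywords)) stopf("keyword list must be non-empty")
  keywords <- unique(tolower(keywords))
  nm <- tolower(names(sets))
  hit <- vapply(nm, function(x) any(vapply(keywords, grepl, TRUE,
                                           x = x, fixed = TRUE)), TRUE)
  sets[hit]
}

#' Combined enrichment test for a cluster of gene sets
#'
#' Deduplicated union of the member genes of all sets in the cluster,
#' tested by [rank_sum_enrichment()] against a freshly matched background.
#'
#' @param cluster Named list of gene sets (>= 1).
#' @param gene_p Named vector of gene-level P-values.
#' @param gene_stats Per-gene variant count and combined MAF table for
#'   [match_background()].
#' @param cluster_name Optional label.
#' @param ... Passed to [match_background()].
#' @return Data frame as in [rank_sum_enrichment()], method
#'   "cluster-combined".
#' @export
cluster_combined_test <- function(cluster, gene_p, gene_stats,
                                  cluster_name = "cluster", ...) {
  if (!length(cluster)) stopf("empty cluster")
  union_genes <- unique(unlist(cluster))
  bg <- match_background(intersect(union_genes, gene_stats$gene),
                         gene_stats, ...)
  res <- rank_sum_enrichment(union_genes, gene_p, bg,
                             set_name = cluster_name)
  res$method <- "cluster-combined"
  res
}

#' Bonferroni significance threshold
#'
#' @param n_tests Number of tests (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  n_tests <- check_count(n_tests, "n_tests")
  alpha / n_tests
}

#' Classify genes into evidence tiers
#'
#' Four nested evidence tiers for candidate risk genes:
#' tier 1, exome-wide significant corrected gene-level P; tier 2, adds
#' top-K genes that are known monogenic-disease genes or harbor causal
#' coding variants; tier 3, adds top-K genes that are members of at least
#' two enriched metabolic gene sets; tier 4, genes at nominal significance
#' that are members of the enriched metabolic sets. Each gene receives its
#' strongest (smallest-numbered) qualifying tier.
#'
#' @param gene_results Data frame with `gene` and `corrected_p`.
#' @param known_lists Named list of character vectors of known genes
#'   (e.g. roles "monogenic" and "causal_coding"); lists named elsewhere
#'   are ignored for tier 2 but kept for the justification codes. `NULL`
#'   skips tiers 2-3 with a warning.
#' @param enriched_sets Named list of enriched metabolic gene sets.
#' @param top_k Number of top-ranked genes eligible for tiers 2-3
#'   (default 50).
#' @param exome_threshold Tier-1 corrected-P threshold (default
#'   `bonferroni_threshold(20000)`).
#' @param nominal Tier-4 nominal threshold (default 0.05).
#' @return Data frame: `gene`, `tier` (1-4 or NA), `justification`.
#' @export
classify_tiers <- function(gene_results, known_lists = NULL,
                           enriched_sets = list(), top_k = 50,
                           exome_threshold = bonferroni_threshold(20000),
                           nominal = 0.05) {
  stopifnot(all(c("gene", "corrected_p") %in% names(gene_results)))
  gr <- gene_results[order(gene_results$corrected_p, gene_results$gene), ]
  top <- utils::head(gr$gene, top_k)
  tier <- rep(NA_integer_, nrow(gr))
  just <- rep("", nrow(gr))

  t1 <- gr$corrected_p < exome_threshold
  tier[t1] <- 1L
  just[t1] <- "exome-wide"

  if (is.null(known_lists) || !length(known_lists)) {
    warnf("classify_tiers: no known-gene lists; tiers 2-3 skipped")
    known <- character()
  } else {
    known <- unique(unlist(known_lists[names(known_lists) %in%
                                         c("monogenic", "causal_coding")]))
    if (!length(known)) known <- unique(unlist(known_lists))
  }
  in_top <- gr$gene %in% top
  t2 <- is.na(tier) & in_top & gr$gene %in% known
  tier[t2] <- 2L
  just[t2] <- "top-K+known"

  set_count <- table(unlist(lapply(enriched_sets, unique)))
  n_sets <- as.integer(set_count[gr$gene])
  n_sets[is.na(n_sets)] <- 0L
  t3 <- is.na(tier) & in_top & n_sets >= 2
  tier[t3] <- 3L
  just[t3] <- "top-K+>=2 enriched sets"

  t4 <- is.na(tier) & gr$corrected_p < nominal & n_sets >= 1
  tier[t4] <- 4L
  just[t4] <- "nominal-in-enriched-sets"

  data.frame(gene = gr$gene, tier = tier, corrected_p = gr$corrected_p,
             justification = just, stringsAsFactors = FALSE)
}
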