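test_that("hypergeometric tail matches exhaustive enumeration", {
  # enumerate every possible top-gene subset of a small universe and count
  # how often the overlap is at least the observed one
  universe <- sprintf("g%02d", 1:12)
  set <- universe[c(1, 2, 3, 4)]
  top <- universe[c(1, 2, 5, 9)]
  k_obs <- length(intersect(top, set))
  combos <- utils::combn(12, 4)
  overlaps <- colSums(combos <= 4) # set genes are the first four indices
  p_enum <- mean(overlaps >= k_obs)
  res <- hypergeometric_enrichment(top, set, universe)
  expect_equal(res$p, p_enum, tolerance = 1e-12)
  expect_equal(res$overlap, k_obs)
  expect_equal(res$fold, (k_obs / 4) / (4 / 12))
})

test_that("bh_qvalues matches the step-up definition", {
  p <- c(0.001, 0.02, 0.03, 0.5, 0.9)
  q <- bh_qvalues(p)
  m <- length(p)
  manual <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(p)]
  expect_equal(q, manual)
})

test_that("matched backgrounds respect bins, size and determinism", {
  set.seed(20)
  gene_stats <- data.frame(gene = sprintf("g%03d", 1:300),
                           n_variants = stats::rpois(300, 12) + 1,
                           combined_maf = stats::runif(300, 1e-3, 1e-2))
  targets <- gene_stats$gene[1:8]
  a <- match_background(targets, gene_stats, multiple = 5, seed = 3)
  b <- match_background(targets, gene_stats, multiple = 5, seed = 3)
  expect_identical(a$background, b$background)
  expect_false(any(targets %in% a$background))
  expect_false(any(duplicated(a$background)))
  expect_lte(length(a$background), 5 * length(targets))
  expect_error(match_background("absent_gene", gene_stats), "absent_gene")
})

test_that("rank-sum enrichment detects planted shifts and is monotone-invariant", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:200)
  gene_p <- stats::setNames(stats::runif(200), genes)
  set <- genes[1:15]
  gene_p[set] <- gene_p[set]^6          # shift the set toward small P
  bg <- genes[16:165]
  res <- rank_sum_enrichment(set, gene_p, bg, set_name = "planted")
  expect_lt(res$p, 0.01)
  # invariance under a strictly monotone transform of the P-values
  res2 <- rank_sum_enrichment(set, gene_p^0.37, bg, set_name = "planted")
  expect_equal(res$p, res2$p, tolerance = 1e-12)
  # a null set should not be enriched
  null_set <- genes[166:180]
  res0 <- rank_sum_enrichment(null_set, gene_p, bg)
  expect_gt(res0$p, 0.01)
})

test_that("metabolic keyword filtering is case-insensitive and order-preserving", {
  sets <- list(HP_DIABETES_MELLITUS = "a", GO_CILIUM = "b",
               HP_Insulin_Resistance = "c", HP_OVERWEIGHT = "d",
               REACTOME_SPLICING = "e")
  got <- filter_metabolic_sets(sets)
  expect_identical(names(got), c("HP_DIABETES_MELLITUS",
                                 "HP_Insulin_Resistance",
                                 "HP_OVERWEIGHT"))
  expect_identical(names(filter_metabolic_sets(sets, "cilium")),
                   "GO_CILIUM")
})

test_that("bonferroni_threshold reproduces the standard cutoffs", {
  expect_equal(bonferroni_threshold(25), 0.002)
  expect_equal(bonferroni_threshold(20000), 2.5e-6)
  expect_error(bonferroni_threshold(0), "n_tests")
})

test_that("tier classification applies the four rules with precedence", {
  set.seed(23)
  genes <- sprintf("G%02d", 1:60)
  p <- sort(c(1e-7, 5e-7, 1e-6, stats::runif(57, 1e-4, 0.9)))
  gr <- data.frame(gene = genes, corrected_p = p)
  known <- list(monogenic = c("G04", "G05"), causal_coding = c("G06",
                                                               "G07"))
  enriched <- list(SET1 = c("G08", "G09", "G10", "G30"),
                   SET2 = c("G08", "G09", "G11", "G31"))
  tiers <- classify_tiers(gr, known, enriched, top_k = 20,
                          exome_threshold = 2.5e-6, nominal = 0.05)
  tier_of <- stats::setNames(tiers$tier, tiers$gene)
  expect_identical(unname(tier_of[c("G01", "G02", "G03")]), rep(1L, 3))
  expect_identical(unname(tier_of[c("G04", "G07")]), rep(2L, 2))
  expect_identical(unname(tier_of[c("G08", "G09")]), rep(3L, 2))
  # G10 is in only one enriched set: tier 4 only if nominal
  expect_true(is.na(tier_of["G10"]) || tier_of["G10"] == 4L)
  # beyond top_k, known genes cannot reach tier 2
  expect_false(isTRUE(tier_of["G30"] == 2L))
  # tiers are cumulative in strength: tier-1 genes have the smallest P
  expect_lt(max(gr$corrected_p[match(names(tier_of)[which(tier_of == 1)],
                                     gr$gene)]), 2.5e-6)
})

test_that("cluster_combined_test pools a set cluster against fresh background", {
  set.seed(22)
  genes <- sprintf("g%03d", 1:250)
  gene_p <- stats::setNames(stats::runif(250), genes)
  cluster <- list(A = genes[1:10], B = genes[8:18])
  gene_p[unique(unlist(cluster))] <- gene_p[unique(unlist(cluster))]^4
  gene_stats <- data.frame(gene = genes,
                           n_variants = stats::rpois(250, 10) + 1,
                           combined_maf = stats::runif(250, 1e-3, 1e-2))
  res <- cluster_combined_test(cluster, gene_p, gene_stats, seed = 5)
  expect_lt(res$p, 0.05)
  expect_equal(res$overlap, length(unique(unlist(cluster))))
})
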