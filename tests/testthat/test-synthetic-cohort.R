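test_that("sim_config validates its arguments", {
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(fst_per_cluster = 0.4), "fst_per_cluster")
  expect_error(sim_config(mody_params = list(case_carrier_rate = 0.02,
                                             penetrance = 0.005,
                                             n_genes = 1)),
               "penetrance")
  expect_error(sim_config(n_clusters = 0), "n_clusters")
})

test_that("drift moments follow the Balding-Nichols variance for common variants", {
  cfg <- sim_config(seed = 5, n_clusters = 40, fst_per_cluster = 0.06,
                    n_common_causal = 0L,
                    rare_gene_params = data.frame(
                      combined_maf = numeric(), or = numeric(),
                      frac_deleterious = numeric()),
                    mody_params = NULL, n_null_genes = 0L,
                    n_background_common = 400L)
  fr <- simulate_frequencies(cfg)
  anc <- fr$variants$ancestral_maf
  common <- which(anc >= 0.05)
  expect_gt(length(common), 100)
  # per-variant across-cluster mean and variance vs Beta moments
  m <- rowMeans(fr$af[common, , drop = FALSE])
  v <- apply(fr$af[common, , drop = FALSE], 1, stats::var)
  expect_equal(mean(m - anc[common]), 0, tolerance = 0.01)
  ratio <- v / (cfg$fst_per_cluster[1] * anc[common] * (1 - anc[common]))
  expect_equal(mean(ratio), 1, tolerance = 0.15)
})

test_that("rare variants keep their configured frequencies across clusters", {
  fr <- simulate_frequencies(tiny_config())
  rare <- which(fr$variants$ancestral_maf < 0.05)
  expect_gt(length(rare), 10)
  spread <- apply(fr$af[rare, , drop = FALSE], 1, function(x)
    max(x) - min(x))
  expect_true(all(spread == 0))
  expect_equal(fr$af[rare, 1], fr$variants$ancestral_maf[rare],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cohort dimensions and sampling design are exact", {
  co <- tiny_cohort()
  cfg <- tiny_config()
  tab <- table(co$samples$cluster, co$samples$status)
  expect_equal(unname(tab[, "1"]), cfg$cases_per_cluster,
               ignore_attr = TRUE)
  expect_equal(unname(tab[, "0"]), cfg$controls_per_cluster,
               ignore_attr = TRUE)
  expect_identical(rownames(co$genotypes), co$samples$sample_id)
  expect_identical(colnames(co$genotypes), co$annotations$variant_id)
  expect_true(all(co$genotypes %in% 0:2))
})

test_that("planted rare risk genes are enriched in cases", {
  co <- tiny_cohort()
  # pooled across all rare causal genes, carriers of effect variants
  # (beta_true > 0) must be more frequent among cases
  tv <- co$truth$variants
  vids <- tv$variant_id[tv$beta_true > 0 & tv$ancestral_maf < 0.05]
  expect_gt(length(vids), 10)
  carrier <- rowSums(co$genotypes[, vids, drop = FALSE]) > 0
  case <- co$samples$status == 1
  expect_gt(mean(carrier[case]), mean(carrier[!case]))
})

test_that("MODY carrier rate among cases matches the configured target", {
  co <- tiny_cohort()
  cfg <- tiny_config()
  case <- co$samples$status == 1
  vids <- co$annotations$variant_id[co$annotations$pathogenic_flag == 1]
  carrier <- rowSums(co$genotypes[, vids, drop = FALSE]) > 0
  rate <- mean(carrier[case])
  target <- cfg$mody_params$case_carrier_rate
  # binomial tolerance: 4 sd
  tol <- 4 * sqrt(target * (1 - target) / sum(case))
  expect_lt(abs(rate - target), tol)
  expect_identical(sort(co$mody_genes),
                   sort(unique(co$annotations$gene[
                     co$annotations$pathogenic_flag == 1])))
})

test_that("phenotypes carry the planted structure", {
  co <- tiny_cohort()
  case <- co$samples$status == 1
  expect_true(all(is.na(co$samples$age_at_diagnosis[!case])))
  expect_true(all(is.finite(co$samples$age_at_diagnosis[case])))
  expect_true(all(co$samples$c_peptide > 0))
  # controls have lower BMI-Z on average by construction
  expect_gt(mean(co$samples$bmi_z[case]), mean(co$samples$bmi_z[!case]))
})

test_that("simulation is deterministic in the seed", {
  a <- simulate_cohort(tiny_config(seed = 33))
  b <- simulate_cohort(tiny_config(seed = 33))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$samples, b$samples)
  c2 <- simulate_cohort(tiny_config(seed = 34))
  expect_false(identical(a$genotypes, c2$genotypes))
})

test_that("null cohorts attach no signal to status", {
  co <- null_cohort()
  expect_true(all(co$truth$variants$beta_true == 0))
  expect_length(co$mody_genes, 0)
})
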