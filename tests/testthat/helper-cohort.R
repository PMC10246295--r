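# Shared small cohorts, memoized so several test files can reuse one
# simulation without paying for it repeatedly.

.rvarch_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.rvarch_test_cache[[key]]))
    .rvarch_test_cache[[key]] <- force(expr)
  .rvarch_test_cache[[key]]
}

tiny_config <- function(seed = 11, ...) {
  sim_config(seed = seed, n_clusters = 3, cases_per_cluster = 120,
             controls_per_cluster = 360, n_null_genes = 20L,
             n_background_common = 120L, n_common_causal = 6L, ...)
}

tiny_cohort <- function() cached("tiny_cohort", simulate_cohort(tiny_config()))

# a cohort with no planted effects at all: status independent of genotype
null_config <- function(seed = 21, n_null_genes = 100L,
                        n_background_common = 150L,
                        cases_per_cluster = 200,
                        controls_per_cluster = 200, ...) {
  sim_config(seed = seed, n_clusters = 3,
             cases_per_cluster = cases_per_cluster,
             controls_per_cluster = controls_per_cluster,
             n_common_causal = 0L,
             rare_gene_params = data.frame(combined_maf = numeric(),
                                           or = numeric(),
                                           frac_deleterious = numeric()),
             mody_params = NULL,
             n_null_genes = n_null_genes,
             n_background_common = n_background_common, ...)
}

null_cohort <- function() cached("null_cohort",
                                 simulate_cohort(null_config()))

# cluster indicator covariates for a cohort's samples
cluster_covariates <- function(samples) {
  cl <- factor(samples$cluster)
  if (nlevels(cl) < 2) return(NULL)
  stats::model.matrix(~ cl)[, -1, drop = FALSE]
}

# fast 2x2 chi-square (no continuity correction) used by permutation
# oracles: carrier count among cases vs controls
chisq_p_2x2 <- function(a, n_case, carriers, n) {
  N <- n
  expa <- n_case * carriers / N
  stat <- (a - expa)^2 * N^3 /
    (n_case * (N - n_case) * carriers * (N - carriers))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}
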