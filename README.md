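# rvarch

Rare-variant association and genetic architecture analysis for
case–control exome studies that borrow **external, unscreened controls**
— the design typical of early-onset complex-disease cohorts, where cases
are ascertained clinically and controls come from population biobanks.

The scientific question the package is built around: in a disease such
as youth-onset type 2 diabetes, how much of the genetic signal is
monogenic (MODY-like, high-penetrance), how much is rare-variant burden
in a handful of genes, and how much is common polygenic background — and
how do those components differ in per-unit impact on the liability
scale? Answering that requires a chain of methods that each have to be
right: ancestry matching of external controls (confounding), penalized
burden tests over nested variant masks (sparse carriers, multiple
correlated tests per gene), enrichment against frequency-matched
backgrounds, winner's-curse-corrected liability-variance estimates, and
per-individual score decomposition. `rvarch` implements the full chain,
plus a seeded synthetic-cohort generator with complete ground truth so
every stage can be validated end to end.

## Modules

| Module | Key functions |
|---|---|
| Synthetic cohort | `sim_config`, `simulate_cohort`, `write_cohort`, `read_vcf`, `read_gmt` |
| Ancestry matching | `ld_prune`, `compute_pcs`, `project_pcs`, `assign_clusters`, `match_controls`, `effective_sample_size` |
| Association | `single_variant_test`, `gene_burden_test`, `default_masks`, `synonymous_mask`, `firth_logistic`, `inflation_diagnostics` |
| Gene-set enrichment | `hypergeometric_enrichment`, `rank_sum_enrichment`, `match_background`, `bh_qvalues`, `classify_tiers`, `bonferroni_threshold` |
| Genetic architecture | `liability_model`, `variant_lve`, `winners_curse_correct`, `aggregate_lve`, `compare_architectures`, `overlap_correlation`, `exceedance_probability` |
| Individual scores | `burden_collapse`, `compute_scores`, `mody_flag`, `assign_bands`, `phenotype_regression`, `mody_phenotype_comparison`, `mody_leave_out_test`, `rare_fraction_trend` |
| Pipeline | `pipeline_config`, `read_pipeline_config`, `run_pipeline` |

Statistical highlights:

* **Firth-penalized logistic regression** written in-package
  (Newton–Raphson with hat-diagonal score correction and step-halving),
  engaged automatically at low carrier counts; the default gene-level
  test is the penalized likelihood ratio, which keeps type-I error
  calibrated where Wald tests are erratic.
* **Nested mask ladder with effective-number-of-tests correction**: seven
  strictly nested masks per gene (PTV → +missense → all nonsynonymous,
  with rising control-AF ceilings), minimum-P corrected by the eigenvalue
  count explaining 99.5% of the inter-mask carrier-correlation trace —
  validated in the test suite against a 10,000-permutation oracle.
* **Liability-scale variance explained** under a threshold model, with
  conditional-MLE winner's-curse correction and bootstrap CIs; a
  closed-form correlation for association statistics of studies that
  share controls, validated against a retrospective-sampling simulation.
* **Reproducible pipeline**: file-contract stages, YAML configs, and a
  manifest stamped with a config hash — reruns are byte-identical.

See the methods vignette (`vignettes/methods.Rmd`) for the model behind
each module, parameter tables, and the generator's scope and limits.

## Worked example

Simulate a structured cohort, match controls to cases in PC space, run
the nested-mask burden test, and estimate liability variance explained
by the top genes:

```r
library(rvarch)

cfg <- sim_config(seed = 7, n_clusters = 3, cases_per_cluster = 250,
                  controls_per_cluster = 750, n_null_genes = 40L,
                  n_background_common = 150L)
cohort <- simulate_cohort(cfg)
table(status = cohort$samples$status)
#> status
#>    0    1
#> 2250  750

## ancestry matching ---------------------------------------------------
case_ids <- cohort$samples$sample_id[cohort$samples$status == 1]
ctrl_ids <- setdiff(cohort$samples$sample_id, case_ids)
keep <- ld_prune(cohort$genotypes[case_ids, ])
pcs <- compute_pcs(cohort$genotypes[case_ids, keep], 4)
ctrl <- project_pcs(pcs, cohort$genotypes[ctrl_ids, ])
cl <- assign_clusters(pcs$coords, 3, seed = 7)
m <- match_controls(pcs$coords, ctrl, max_ratio = 3,
                    case_clusters = cl$cluster)
m
#> match_result: 728 controls matched to 750 cases (caliper 0.563)
#> effective sample size: 1478
#> per-cluster counts:
#>  cluster n_cases n_controls
#>        1     253        263
#>        2     248        226
#>        3     249        239

## gene burden tests ---------------------------------------------------
ids <- c(case_ids, m$selected)
samp <- cohort$samples[match(ids, cohort$samples$sample_id), ]
covars <- cbind(model.matrix(~ factor(samp$cluster))[, -1], sex = samp$sex)
genes <- grep("^RG|^NG", unique(cohort$annotations$gene), value = TRUE)
res <- gene_burden_test(cohort$genotypes[ids, ], cohort$annotations,
                        samp$status, genes = genes, covariates = covars)
head(res[order(res$corrected_p),
         c("gene", "min_p_mask", "n_eff", "corrected_p", "direction")])
#>     gene  min_p_mask n_eff  corrected_p direction
#> 2   RG02  nonsyn_0.5     3 0.0000794833         1
#> 6   RG06  nonsyn_0.5     3 0.0057907588         1
#> 5   RG05  nonsyn_0.5     2 0.0078714401         1
#> 12 NG002 ptv_ms_0.25     3 0.0156341158        -1
#> 25 NG015  nonsyn_0.5     3 0.0373761851         1
#> 21 NG011  ptv_ms_0.1     2 0.0577930337         1

## liability variance explained by the top risk genes ------------------
model <- liability_model(0.01)
top <- res[res$direction > 0, ]
top <- top[order(top$corrected_p), ][1:5, ]
units <- data.frame(unit = top$gene,
                    beta = mapply(function(mk, i) top[[paste0(mk, "_beta")]][i],
                                  top$min_p_mask, seq_len(5)),
                    se = mapply(function(mk, i) top[[paste0(mk, "_se")]][i],
                                top$min_p_mask, seq_len(5)),
                    freq = mapply(function(mk, i) top[[paste0(mk, "_cmaf")]][i],
                                  top$min_p_mask, seq_len(5)))
units <- units[is.finite(units$beta) & units$freq > 0, ]
set.seed(1)
aggregate_lve(units, model, n_bootstrap = 200)
#> liability variance explained: 0.0035 (95% CI 0.0016-0.0104, 200 bootstrap draws)
#> 4 units
```

The three genes with planted risk burden (`RG02`, `RG06`, `RG05` carry
simulated odds ratios) head the ranking; the null genes (`NG…`) scatter
around the nominal level.

The full chain — simulation through matching, association, enrichment,
architecture, scores, and report — also runs as a single pipeline:

```r
cfgp <- pipeline_config(out_dir = "run1", seed = 7,
                        cohort = list(n_clusters = 3,
                                      cases_per_cluster = 150,
                                      controls_per_cluster = 450))
run_pipeline(cfgp)   # writes TSV/JSON stage outputs + run_manifest.json
```

or from the shell via the installed wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","rvarch-pipeline.R",package="rvarch"))')" config.yaml
```

## License

MIT (see `LICENSE`).
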