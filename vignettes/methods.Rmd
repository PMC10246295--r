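---
title: "Methods: rare-variant association and genetic architecture with external controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant association and genetic architecture with external controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvarch)
```

`rvarch` implements an analysis stack for case–control exome studies of
early-onset complex disease that borrow external (unscreened) controls:
ancestry matching, single-variant and gene-level burden association,
gene-set enrichment, liability-scale architecture estimation, and
per-individual genetic scores. A seeded synthetic-cohort generator with
full ground truth supports end-to-end validation of every stage. This
vignette documents the statistical model behind each module, the main
tuning parameters, the scope and limits of the generator, and the
numerical choices made in the implementation.

## 1. Synthetic cohort generator

`simulate_cohort(sim_config(...))` draws a stratified case–control cohort
with known generating values, returned in `cohort$truth`.

**Population structure.** Samples belong to `n_clusters` ancestry
clusters. Common variants (ancestral MAF ≥ 0.05) receive cluster-specific
allele frequencies via the Balding–Nichols model: for ancestral frequency
$p$ and cluster differentiation $F$, cluster frequencies are drawn from
$\mathrm{Beta}\!\big(p\,\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$, which
has mean $p$ and variance $F\,p(1-p)$. Rare variants keep their configured
frequencies in every cluster: Beta draws at $p \ll F$ are degenerate
(most mass at zero) and would destroy the exact combined MAFs that the
burden-calibration and parameter-recovery analyses rely on. Structure
therefore lives in the common variants — which is also what drives PCA
and matching — while rare-variant frequencies are exact by construction.

**Disease model.** Case status follows a logistic liability:
$\Pr(\text{case} \mid g) = \operatorname{logit}^{-1}(\alpha + \sum_v
\beta_v g_v)$, with the intercept $\alpha$ solved numerically (Monte
Carlo + `uniroot`) so that population prevalence equals the configured
$K$ (default 1%). The logistic form means every planted per-variant or
per-gene log odds ratio is exactly the estimand of the logistic
regressions used downstream, so parameter recovery is well defined.
Cases and controls are sampled retrospectively from the simulated
population within each cluster.

**Signal classes.** Config rows plant (i) rare causal genes with a target
combined MAF, odds ratio, and fraction of deleterious variants;
(ii) monogenic (MODY-like) genes whose pathogenic variants act through a
penetrance $f$ directly, with population carrier frequency
$c = r\,K/f$ chosen so a fraction $r$ of cases carry one; (iii) common
causal loci with configured ORs; (iv) null genes and synonymous
background variants carrying no signal. Carrier phenotypes (age at
diagnosis, BMI z-score, C-peptide) are generated with configurable shifts
per standard deviation of the true rare and common genetic scores and for
monogenic carriers.

**Limits.** Genotypes are unlinked within class (no LD beyond the
cluster-frequency structure), there is no relatedness, no genotyping
batch effects, and rare-variant counts are Binomial rather than drawn
from a site-frequency spectrum. The generator is a validation instrument,
not a population-genetics simulator.

## 2. Ancestry matching

PCA is fit on LD-pruned (`ld_prune`: MAF ≥ 0.05, windowed $r^2$ < 0.2)
case genotypes with `compute_pcs`, and external controls are projected
onto the case PCs with `project_pcs` (centering and scaling by the case
allele frequencies, loadings applied to the standardized matrix — the
standard reference-projection construction). `assign_clusters` runs
k-means (many restarts, fixed seed) in PC space; `match_controls`
greedily assigns each control to its nearest case centroid subject to an
optional Euclidean `caliper` and a per-case `max_ratio`, preserving
case:control balance per cluster. The result records the matched-set
effective sample size $n_\mathrm{eff} = 4/(1/n_1 + 1/n_0)$
(`effective_sample_size`), the familiar harmonic-mean equivalent of a
balanced design.

## 3. Association tests

**Single variants** (`single_variant_test`) use logistic regression with
ancestry covariates; Wald P-values by default, switching to
Firth-penalized fits when carrier counts are small or the fit separates.

**Firth regression** is implemented directly (`firth_logistic`):
Newton–Raphson on the Jeffreys-penalized likelihood, with the score
correction $h_i(1/2 - \pi_i)$ from the hat diagonal and step-halving for
stability. No suitable penalized-likelihood package is assumed; the
implementation is validated in the test suite against `glm` on
well-conditioned data and against the closed-form Jeffreys posterior mode
$(k + 1/2)/(n + 1)$ for the intercept-only model, and checked to yield
finite estimates under complete separation.

**Gene-level burden** (`gene_burden_test`) collapses carriers under a
strictly nested ladder of seven variant masks (`default_masks`): PTVs at
control-AF ceilings 5e-4 and 1e-3, PTV+strict-missense at 1e-3 and
2.5e-3, PTV+broad-missense at 5e-3, and all nonsynonymous at 5e-3 and
1e-2. Nesting — every mask's qualifying variants a subset of the next —
is enforced by `check_masks` and is what makes the effective-test
correction below work. A synonymous mask (`synonymous_mask`) provides a
negative control. The default per-mask test is the penalized likelihood
ratio (`test = "lrt"`): at rare-variant carrier counts the Wald statistic
is erratically conservative or anti-conservative, and the LRT is what
keeps the type-I error of the corrected gene P within calibration
tolerance. Firth penalization engages below a carrier-count threshold
(default 50).

**Effective number of tests.** The seven mask P-values per gene are
strongly dependent (nested carrier sets). The per-gene minimum P is
corrected via the effective number of tests $N_\mathrm{eff}$: the number
of eigenvalues of the inter-mask carrier-indicator correlation matrix
needed to reach 99.5% of the trace. The corrected P is
$1 - (1 - p_{\min})^{N_\mathrm{eff}}$. The test suite validates this
against a 10,000-permutation minimum-P oracle that uses the identical
per-mask statistic on permuted case labels, isolating the correction
itself from the choice of statistic.

**Diagnostics.** `inflation_diagnostics` reports the genomic-control
$\lambda$ (median $\chi^2_1$ ratio).

## 4. Gene-set enrichment

`hypergeometric_enrichment` computes the exact tail probability of the
overlap between the top-$k$ association genes and a set within a stated
universe (validated against full enumeration in tests).
`rank_sum_enrichment` is a one-sided Wilcoxon rank-sum test of the set's
gene-level P-values against a `match_background` control set matched on
variant count and combined MAF bins — this uses the full ranking rather
than an arbitrary top-$k$ cut, and is invariant to monotone transforms of
the P-values. `bh_qvalues` applies Benjamini–Hochberg across sets;
`cluster_combined_test` pools overlapping significant sets and retests
the union against fresh matched background. `classify_tiers` assigns
genes to four evidence tiers (exome-wide significant; top-$k$ and a known
causal/monogenic gene; nominal and in ≥ 2 enriched sets; nominal and in
one enriched set), with precedence to the strongest tier.

## 5. Genetic architecture

All variance-explained quantities live on the liability scale of a
threshold model `liability_model(K)` with threshold $t = \Phi^{-1}(1-K)$.

**Per-unit LVE** (`variant_lve`): for a unit (variant or gene-burden
genotype) with frequency $q$ and log-OR $\beta$, the baseline risk is
solved by `uniroot` so the genotype-weighted penetrances average $K$;
each genotype's penetrance $f_g$ maps to a liability-mean shift
$\mu_g = t - \Phi^{-1}(1 - f_g)$, and the liability variance explained is
$\mathrm{Var}(\mu)/(\mathrm{Var}(\mu) + 1)$. This is validated in tests
against a 10-million-draw simulation of the threshold model.

**Winner's curse.** Effect sizes of units selected by a significance
threshold are corrected by the conditional maximum likelihood of
$\hat\beta \mid |\hat\beta/se| > z_c$ (`winners_curse_correct`),
maximized over $[0, |\hat\beta|]$ by `optimize`; tests verify it against
a dense grid search.

**Aggregation.** `aggregate_lve` sums per-unit LVE over independent units
after winner's-curse correction and bootstraps units for a CI.
`compare_architectures` contrasts two studies' aggregate LVE, reporting
the fold ratio with a bootstrap CI. `overlap_correlation` gives the
expected correlation of association statistics for two studies sharing
controls. The implemented form is
$r = n_s \sqrt{(n_{c1} n_{c2})/(n_{k1} n_{k2})} / \sqrt{N_1 N_2}$ with
$n_s$ shared controls and $N_i$ total study sizes — the asymptotic
covariance of the two score statistics — which matches a retrospective
logistic simulation oracle to within 0.05 in tests; a harmonic-mean
"effective N" denominator does not. `exceedance_probability` gives the
Binomial tail used for directional-consistency checks across studies.

## 6. Individual scores

`burden_collapse` builds carrier indicators per gene/mask;
`compute_scores` combines winner's-curse-corrected weights over rare
burden units and common variants into per-individual rare, common and
combined scores. `mody_flag` flags carriers of annotated pathogenic
variants in a monogenic registry. `assign_bands` partitions individuals
into mutually exclusive risk bands (monogenic flag first, then descending
score thresholds); `phenotype_regression` regresses phenotypes on a
standardized score in cases, excluding monogenic carriers by default so
their shifted phenotypes cannot masquerade as a score effect;
`mody_phenotype_comparison` contrasts carrier versus non-carrier cases.
`mody_leave_out_test` re-runs the burden test after removing flagged
carriers: a purely monogenic signal collapses (attenuation), whereas a
gene with additional non-pathogenic association persists — a useful
screen for whether a hit is "just" known monogenic disease.
`rare_fraction_trend` tests whether the rare-score share of the combined
score falls with later onset ages (Spearman trend across onset bins).

## 7. Pipeline

`run_pipeline(pipeline_config(out_dir, seed, ...))` chains the stages
simulate → match → assoc → enrich → architecture → scores → report
through file contracts in `out_dir`; each stage reads only its declared
inputs and errors with the name of the producing stage if one is missing,
so partial re-runs are safe. `run_manifest.json` records a configuration
hash (32-bit FNV-1a over the serialized config, excluding the
serialization header), the seed, the package version, and per-stage row
counts and timings. Configs round-trip through YAML
(`read_pipeline_config`); a thin command-line wrapper is installed at
`system.file("cli", "rvarch-pipeline.R", package = "rvarch")`.

## Key parameters at a glance

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `prevalence` | `sim_config` | 0.01 | population disease prevalence $K$ |
| `fst_per_cluster` | `sim_config` | 0.02 | Balding–Nichols differentiation |
| `maf_min`, `r2_max` | `ld_prune` | 0.05, 0.2 | pruning thresholds before PCA |
| `max_ratio`, `caliper` | `match_controls` | 4, NULL | per-case control budget, PC distance cap |
| `firth_threshold` | `gene_burden_test` | 50 | carrier count below which Firth engages |
| `trace_frac` | effective-tests rule | 0.995 | eigenvalue trace fraction for $N_\mathrm{eff}$ |
| `n_bootstrap` | `aggregate_lve` | 1000 | units bootstrap for LVE CIs |
| `top_k` | `classify_tiers` | 50 | association genes eligible for tier 2 |
| `exome_wide` | `pipeline_config` | 2.5e-6 | exome-wide significance (0.05/20,000) |

## Numerical choices

* Firth fits use step-halving with a convergence tolerance of 1e-8 on the
  score norm and a cap on Newton iterations; LRT P-values compare
  penalized deviances of nested fits.
* `variant_lve` and the disease-model intercept use `uniroot` on
  monotone functions with wide brackets rather than closed forms.
* P-values are serialized to 6 significant digits in scientific notation
  in pipeline TSVs; JSON numbers are written unrounded.
* All stochastic steps (simulation, k-means, bootstraps, background
  matching) take explicit seeds; pipeline runs are byte-identical for a
  fixed config.
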