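#' Configuration for a synthetic case-control exome cohort
#'
#' Builds and validates the configuration object consumed by
#' [simulate_frequencies()] and [simulate_cohort()]. Defaults emulate a
#' multi-ancestry early-onset disease study: seven ancestry clusters,
#' roughly 3,000 cases matched to roughly 9,800 external controls, a
#' disease prevalence of 1%, a handful of common causal variants with
#' modest odds ratios, rare causal gene burdens with combined minor allele
#' frequencies between 1e-3 and 1e-2 and odds ratios between 1.5 and 8,
#' and high-penetrance pathogenic ("monogenic-like") variants carried by
#' about 2% of cases.
#'
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @param n_clusters Number of ancestry clusters.
#' @param cases_per_cluster,controls_per_cluster Ascertained counts per
#'   cluster (scalar or vector of length `n_clusters`).
#' @param fst_per_cluster Balding-Nichols differentiation parameter per
#'   cluster, each in (0, 0.25].
#' @param prevalence Population disease prevalence K in (0, 0.5).
#' @param n_common_causal Number of common causal variants.
#' @param common_or_range Ordered pair of per-allele odds ratios (>= 1);
#'   common causal effects are drawn log-uniformly within it.
#' @param rare_gene_params Data frame with one row per rare causal gene and
#'   columns `combined_maf` (summed allele frequency of the gene's
#'   nonsynonymous variants), `or` (carrier odds ratio) and
#'   `frac_deleterious` (fraction of nonsynonymous variants that carry the
#'   full effect). `NULL` uses a deterministic default ladder of
#'   `n_causal_genes` genes spanning OR 1.5-8 and combined MAF 1e-3 to 1e-2.
#' @param n_causal_genes Number of rare causal genes when
#'   `rare_gene_params` is `NULL`.
#' @param mody_params List with `case_carrier_rate` (target fraction of
#'   cases carrying a pathogenic-flagged variant), `penetrance` (must
#'   exceed the prevalence) and `n_genes`.
#' @param n_null_genes Number of genes with no effect.
#' @param variants_per_gene_range Ordered integer pair; variants per gene
#'   are drawn uniformly within it.
#' @param n_background_common Number of common non-causal variants used for
#'   principal components and ancestry structure.
#' @param phenotype_effects List of linear couplings between true genetic
#'   scores and phenotypes: `age_beta_per_sd_rare` (years per 1 SD of true
#'   rare score, cases), `cpep_beta_per_sd_common` (log10 C-peptide units
#'   per 1 SD of true common score, cases), `mody_age_shift`,
#'   `mody_bmiz_shift`, `mody_cpep_shift` (additive shifts for carriers of
#'   pathogenic-flagged variants).
#' @param phenotype_noise List of residual SDs: `age`, `bmiz`, `cpep`.
#' @param phenotype_baselines List of phenotype means for non-carrier cases
#'   (`age`, `bmiz`, `cpep_log10`) and for controls (`control_bmiz`,
#'   `control_cpep_log10`).
#' @param max_pool Per-cluster cap on the number of individuals simulated
#'   during liability-threshold ascertainment; requesting more cases than
#'   can plausibly be found below this cap is an error rather than a silent
#'   truncation.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clusters = 7L,
                       cases_per_cluster = 430L,
                       controls_per_cluster = 1397L,
                       fst_per_cluster = 0.05,
                       prevalence = 0.01,
                       n_common_causal = 10L,
                       common_or_range = c(1.1, 1.5),
                       rare_gene_params = NULL,
                       n_causal_genes = 10L,
                       mody_params = list(case_carrier_rate = 0.021,
                                          penetrance = 0.5,
                                          n_genes = 2L),
                       n_null_genes = 50L,
                       variants_per_gene_range = c(8L, 25L),
                       n_background_common = 200L,
                       phenotype_effects = list(age_beta_per_sd_rare = -0.102,
                                                cpep_beta_per_sd_common = 0.040,
                                                mody_age_shift = -0.9,
                                                mody_bmiz_shift = -0.38,
                                                mody_cpep_shift = -0.12),
                       phenotype_noise = list(age = 2.3, bmiz = 0.57,
                                              cpep = 0.33),
                       phenotype_baselines = list(age = 13.6, bmiz = 2.18,
                                                  cpep_log10 = 0.55,
                                                  control_bmiz = 1.2,
                                                  control_cpep_log10 = 0.55),
                       max_pool = 2e6) {
  n_clusters <- check_count(n_clusters, "n_clusters")
  cases_per_cluster <- rep_len(as.integer(cases_per_cluster), n_clusters)
  controls_per_cluster <- rep_len(as.integer(controls_per_cluster), n_clusters)
  if (sum(cases_per_cluster) <= 0) stopf("total case count must be positive")
  if (any(cases_per_cluster < 0) || any(controls_per_cluster < 0))
    stopf("per-cluster counts must be non-negative")
  fst_per_cluster <- rep_len(fst_per_cluster, n_clusters)
  if (any(fst_per_cluster <= 0) || any(fst_per_cluster > 0.25))
    stopf("fst_per_cluster must lie in (0, 0.25]")
  check_fraction(prevalence, "prevalence", 0, 0.5)
  if (length(common_or_range) != 2 || any(common_or_range < 1) ||
      diff(common_or_range) < 0)
    stopf("common_or_range must be an ordered pair of ORs >= 1")
  if (is.null(rare_gene_params)) {
    k <- check_count(n_causal_genes, "n_causal_genes", min = 0)
    rare_gene_params <- if (k > 0) data.frame(
      combined_maf = exp(seq(log(1e-3), log(1e-2), length.out = k)),
      or = exp(seq(log(8), log(1.5), length.out = k)),
      frac_deleterious = 0.5
    ) else data.frame(combined_maf = numeric(), or = numeric(),
                      frac_deleterious = numeric())
  }
  stopifnot(is.data.frame(rare_gene_params),
            all(c("combined_maf", "or", "frac_deleterious") %in%
                  names(rare_gene_params)))
  if (nrow(rare_gene_params)) {
    check_fraction(rare_gene_params$combined_maf, "combined_maf", 0, 1)
    if (any(rare_gene_params$or < 1)) stopf("rare gene ORs must be >= 1")
    check_fraction(rare_gene_params$frac_deleterious, "frac_deleterious",
                   0, 1, open = FALSE)
  }
  if (!is.null(mody_params)) {
    check_fraction(mody_params$case_carrier_rate, "case_carrier_rate", 0, 1)
    if (mody_params$penetrance <= prevalence || mody_params$penetrance > 1)
      stopf("penetrance must lie in (prevalence, 1]")
    mody_params$n_genes <- check_count(mody_params$n_genes %||% 1L,
                                       "mody n_genes")
  }
  variants_per_gene_range <- as.integer(variants_per_gene_range)
  if (length(variants_per_gene_range) != 2 ||
      variants_per_gene_range[1] < 1 || diff(variants_per_gene_range) < 0)
    stopf("variants_per_gene_range must be an ordered positive integer pair")
  cfg <- list(seed = as.integer(seed), n_clusters = n_clusters,
              cases_per_cluster = cases_per_cluster,
              controls_per_cluster = controls_per_cluster,
              fst_per_cluster = fst_per_cluster,
              prevalence = prevalence,
              n_common_causal = check_count(n_common_causal,
                                            "n_common_causal", 0),
              common_or_range = common_or_range,
              rare_gene_params = rare_gene_params,
              mody_params = mody_params,
              n_null_genes = check_count(n_null_genes, "n_null_genes", 0),
              variants_per_gene_range = variants_per_gene_range,
              n_background_common = check_count(n_background_common,
                                                "n_background_common", 0),
              phenotype_effects = phenotype_effects,
              phenotype_noise = phenotype_noise,
              phenotype_baselines = phenotype_baselines,
              max_pool = max_pool)
  class(cfg) <- "sim_config"
  cfg
}

# Category weights used to distribute a gene-level burden effect over its
# variants: full effect for protein-truncating and strictly damaging
# missense, half for broadly damaging missense, none for synonymous.
category_weights <- c(ptv = 1, missense_strict = 1, missense_broad = 0.5,
                      synonymous = 0)

# Lay out genes and variants: ids, categories, ancestral frequencies.
build_variant_table <- function(config) {
  rows <- list()
  gene_rows <- list()
  vid <- 0L
  add_gene <- function(gene, class, n_var, total_maf, or = 1,
                       frac_del = 0, pathogenic = FALSE) {
    cats <- sample(names(category_weights), n_var, replace = TRUE,
                   prob = c(0.12, 0.22, 0.36, 0.30))
    if (pathogenic) cats <- sample(c("ptv", "missense_strict"), n_var,
                                   replace = TRUE)
    nonsyn <- cats != "synonymous"
    if (!any(nonsyn)) {
      cats[1] <- "missense_strict"
      nonsyn[1] <- TRUE
    }
    maf <- numeric(n_var)
    w <- stats::rexp(sum(nonsyn))
    maf[nonsyn] <- total_maf * w / sum(w)
    if (any(!nonsyn))
      maf[!nonsyn] <- pmin(0.005, stats::rexp(sum(!nonsyn)) *
                             total_maf / max(1, sum(nonsyn)))
    # deleterious subset carries the gene effect
    beta <- numeric(n_var)
    if (or > 1) {
      del <- nonsyn & (cats == "ptv" |
                         stats::runif(n_var) < frac_del)
      if (!any(del)) del <- which(nonsyn)[1]
      beta[del] <- category_weights[cats[del]] * log(or)
    }
    ids <- sprintf("v%06d", vid + seq_len(n_var))
    vid <<- vid + n_var
    rows[[length(rows) + 1L]] <<- data.frame(
      variant_id = ids, gene = gene, category = cats,
      ancestral_maf = maf, beta_true = beta,
      pathogenic_flag = as.integer(pathogenic),
      stringsAsFactors = FALSE)
    gene_rows[[length(gene_rows) + 1L]] <<- data.frame(
      gene = gene, class = class, or_true = or,
      combined_maf = total_maf, stringsAsFactors = FALSE)
  }

  nv_range <- config$variants_per_gene_range
  draw_nv <- function() sample(seq(nv_range[1], nv_range[2]), 1)

  # common causal variants, one per pseudo-locus
  if (config$n_common_causal > 0) {
    or_rng <- log(config$common_or_range)
    for (i in seq_len(config$n_common_causal)) {
      maf <- stats::runif(1, 0.10, 0.45)
      or <- exp(stats::runif(1, or_rng[1], or_rng[2]))
      gene <- sprintf("CL%02d", i)
      ids <- sprintf("v%06d", vid + 1L)
      vid <- vid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = ids, gene = gene, category = "missense_broad",
        ancestral_maf = maf, beta_true = log(or), pathogenic_flag = 0L,
        stringsAsFactors = FALSE)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene = gene, class = "common_locus", or_true = or,
        combined_maf = maf, stringsAsFactors = FALSE)
    }
  }

  # rare causal genes
  rg <- config$rare_gene_params
  for (i in seq_len(nrow(rg)))
    add_gene(sprintf("RG%02d", i), "rare_causal", draw_nv(),
             rg$combined_maf[i], rg$or[i], rg$frac_deleterious[i])

  # monogenic-like high-penetrance genes
  mody_genes <- character()
  if (!is.null(config$mody_params)) {
    mp <- config$mody_params
    carrier_freq <- mp$case_carrier_rate * config$prevalence / mp$penetrance
    per_gene_maf <- carrier_freq / 2 / mp$n_genes
    for (i in seq_len(mp$n_genes)) {
      g <- sprintf("MG%02d", i)
      mody_genes <- c(mody_genes, g)
      add_gene(g, "mody", 5L, per_gene_maf, or = 1, pathogenic = TRUE)
    }
  }

  # null genes
  for (i in seq_len(config$n_null_genes))
    add_gene(sprintf("NG%03d", i), "null", draw_nv(),
             exp(stats::runif(1, log(1e-3), log(1e-2))))

  # common background variants for ancestry structure, one pseudo-gene
  if (config$n_background_common > 0) {
    n <- config$n_background_common
    ids <- sprintf("v%06d", vid + seq_len(n))
    vid <- vid + n
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = ids, gene = "BACKGROUND", category = "synonymous",
      ancestral_maf = stats::runif(n, 0.05, 0.5), beta_true = 0,
      pathogenic_flag = 0L, stringsAsFactors = FALSE)
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene = "BACKGROUND", class = "background", or_true = 1,
      combined_maf = NA_real_, stringsAsFactors = FALSE)
  }

  list(variants = do.call(rbind, rows),
       genes = do.call(rbind, gene_rows),
       mody_genes = mody_genes)
}

#' Simulate per-cluster allele frequencies
#'
#' Lays out the cohort's genes and variants and draws per-cluster allele
#' frequencies. Common variants (ancestral MAF >= 0.05) drift between
#' clusters under the Balding-Nichols model: the cluster frequency is a
#' Beta draw with mean equal to the ancestral frequency and variance
#' `fst * p * (1 - p)`. Rare variants are held at their configured
#' frequencies in every cluster, so configured combined MAFs are exact in
#' expectation (the Beta drift model degenerates at frequencies far below
#' the differentiation parameter).
#'
#' @param config A [sim_config()] object.
#' @param set_seed Set the generator seed from the config (default). Pass
#'   `FALSE` to consume the current RNG stream instead.
#' @return List with `variants` (variant table including ancestral
#'   frequency and true effect), `genes`, `mody_genes`, and `af`, the
#'   variants-by-clusters frequency matrix.
#' @export
simulate_frequencies <- function(config, set_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (set_seed) set.seed(config$seed)
  layout <- build_variant_table(config)
  v <- layout$variants
  m <- nrow(v)
  af <- matrix(rep(v$ancestral_maf, config$n_clusters), nrow = m)
  common <- which(v$ancestral_maf >= 0.05)
  for (k in seq_len(config$n_clusters)) {
    f <- config$fst_per_cluster[k]
    if (f > 0 && length(common)) {
      p <- v$ancestral_maf[common]
      shape <- (1 - f) / f
      af[common, k] <- stats::rbeta(length(common), p * shape,
                                    (1 - p) * shape)
    }
  }
  af <- pmin(pmax(af, 0), 1)
  dimnames(af) <- list(v$variant_id,
                       sprintf("cluster_%d", seq_len(config$n_clusters)))
  layout$af <- af
  layout$config <- config
  layout
}

# Solve the disease-model intercept so that the population prevalence of
# the liability model equals K (Monte-Carlo expectation over the genotype
# mixture across clusters).
solve_intercept <- function(freqs, config, n_mc = 40000L) {
  v <- freqs$variants
  causal <- which(v$beta_true != 0)
  mody_idx <- which(v$pathogenic_flag == 1)
  K <- config$prevalence
  w <- config$cases_per_cluster + config$controls_per_cluster
  cl <- sample.int(config$n_clusters, n_mc, replace = TRUE, prob = w)
  score <- numeric(n_mc)
  for (j in causal) {
    g <- stats::rbinom(n_mc, 2, freqs$af[j, cl])
    score <- score + v$beta_true[j] * g
  }
  mody <- rep(FALSE, n_mc)
  for (j in mody_idx)
    mody <- mody | stats::rbinom(n_mc, 2, freqs$af[j, cl]) > 0
  pen <- if (length(mody_idx)) config$mody_params$penetrance else 0
  f <- function(alpha)
    mean(ifelse(mody, pen, stats::plogis(alpha + score))) - K
  stats::uniroot(f, c(-30, 5), tol = 1e-10)$root
}

#' Simulate a case-control cohort with known ground truth
#'
#' Draws genotypes in Hardy-Weinberg equilibrium within each ancestry
#' cluster and ascertains cases under a logistic liability model: the
#' latent liability is the genetic log-odds score plus a standard logistic
#' residual, and an individual is a case when it exceeds the threshold
#' implied by the configured prevalence (equivalently, case status is
#' Bernoulli with probability `plogis(alpha + sum(beta * genotype))`, with
#' the intercept solved so the population prevalence equals K). Configured
#' odds ratios are therefore exactly the generating per-allele effects and
#' are directly recoverable by logistic regression. Carriers of
#' pathogenic-flagged variants are assigned their configured penetrance
#' directly. Cases are oversampled to the configured per-cluster counts by
#' rejection sampling; null-gene genotypes are drawn conditionally on
#' cluster after ascertainment (exact, since they are independent of
#' status given cluster). Phenotypes are linear in the standardized true
#' rare/common scores and pathogenic-carrier status plus Gaussian noise.
#'
#' @param config A [sim_config()] object.
#' @return Object of class `synthetic_cohort`: list with `genotypes`
#'   (samples x variants integer dosage matrix), `annotations` (variant
#'   table with per-cluster allele frequencies and pathogenicity flags),
#'   `samples` (phenotype table), `truth` (list of variant-, gene- and
#'   sample-level generating values), `mody_genes`, `af` and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  freqs <- simulate_frequencies(config, set_seed = FALSE)
  v <- freqs$variants
  af <- freqs$af
  K <- config$prevalence
  causal <- which(v$beta_true != 0)
  mody_idx <- which(v$pathogenic_flag == 1)
  active <- union(causal, mody_idx)
  passive <- setdiff(seq_len(nrow(v)), active)
  pen <- if (length(mody_idx)) config$mody_params$penetrance else 0

  # feasibility check before sampling
  need_pool <- max(config$cases_per_cluster) / K * 3
  if (need_pool > config$max_pool)
    stopf(paste("infeasible ascertainment: %d cases per cluster at",
                "prevalence %.4g needs ~%.0f simulated individuals,",
                "above max_pool = %.0f"),
          max(config$cases_per_cluster), K, need_pool, config$max_pool)

  alpha <- solve_intercept(freqs, config)

  draw_active <- function(n, k) {
    g <- matrix(0L, n, length(active))
    for (i in seq_along(active))
      g[, i] <- stats::rbinom(n, 2, af[active[i], k])
    g
  }
  beta_active <- v$beta_true[active]
  mody_cols <- match(mody_idx, active)

  samples <- list()
  geno_active <- list()
  for (k in seq_len(config$n_clusters)) {
    need_case <- config$cases_per_cluster[k]
    need_ctrl <- config$controls_per_cluster[k]
    got_case <- got_ctrl <- 0L
    acc_g <- list(); acc_s <- list()
    attempts <- 0
    chunk <- min(config$max_pool,
                 max(2000L, ceiling(need_case / K * 1.3), need_ctrl * 2L))
    while (got_case < need_case || got_ctrl < need_ctrl) {
      attempts <- attempts + chunk
      if (attempts > config$max_pool * 3)
        stopf("infeasible ascertainment in cluster %d: pool cap reached", k)
      g <- draw_active(chunk, k)
      score <- drop(g %*% beta_active)
      mody <- if (length(mody_cols))
        rowSums(g[, mody_cols, drop = FALSE]) > 0 else rep(FALSE, chunk)
      pcase <- ifelse(mody, pen, stats::plogis(alpha + score))
      status <- stats::rbinom(chunk, 1, pcase)
      take_case <- which(status == 1)[seq_len(min(need_case - got_case,
                                                  sum(status == 1)))]
      take_ctrl <- which(status == 0)[seq_len(min(need_ctrl - got_ctrl,
                                                  sum(status == 0)))]
      take <- c(take_case, take_ctrl)
      if (length(take)) {
        acc_g[[length(acc_g) + 1L]] <- g[take, , drop = FALSE]
        acc_s[[length(acc_s) + 1L]] <- data.frame(
          status = status[take], cluster = k, mody_carrier = mody[take],
          genetic_score = score[take])
        got_case <- got_case + length(take_case)
        got_ctrl <- got_ctrl + length(take_ctrl)
      }
    }
    samples[[k]] <- do.call(rbind, acc_s)
    geno_active[[k]] <- do.call(rbind, acc_g)
  }
  samp <- do.call(rbind, samples)
  n <- nrow(samp)
  samp$sample_id <- sprintf("S%05d", seq_len(n))
  samp$sex <- stats::rbinom(n, 1, 0.5)

  G <- matrix(0L, n, nrow(v),
              dimnames = list(samp$sample_id, v$variant_id))
  G[, active] <- do.call(rbind, geno_active)
  # passive (null and background) genotypes: independent of status | cluster
  for (k in seq_len(config$n_clusters)) {
    rows <- which(samp$cluster == k)
    for (j in passive)
      G[rows, j] <- stats::rbinom(length(rows), 2, af[j, k])
  }

  # true per-sample scores
  rare_idx <- which(v$gene %in% freqs$genes$gene[freqs$genes$class ==
                                                   "rare_causal"] &
                      v$beta_true != 0)
  common_idx <- which(v$gene %in% freqs$genes$gene[freqs$genes$class ==
                                                     "common_locus"])
  rare_score <- numeric(n)
  if (length(rare_idx)) {
    for (g in unique(v$gene[rare_idx])) {
      idx <- rare_idx[v$gene[rare_idx] == g]
      carrier <- rowSums(G[, idx, drop = FALSE]) > 0
      or_g <- freqs$genes$or_true[freqs$genes$gene == g]
      rare_score <- rare_score + carrier * log(or_g)
    }
  }
  common_score <- if (length(common_idx))
    drop(G[, common_idx, drop = FALSE] %*% v$beta_true[common_idx])
  else numeric(n)

  # phenotypes: linear in standardized-within-cases true scores + noise
  pe <- config$phenotype_effects
  pn <- config$phenotype_noise
  pb <- config$phenotype_baselines
  case <- samp$status == 1
  zstd <- function(x, sub) {
    s <- stats::sd(x[sub])
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x[sub])) / s
  }
  z_rare <- zstd(rare_score, case)
  z_common <- zstd(common_score, case)
  samp$age_at_diagnosis <- NA_real_
  samp$age_at_diagnosis[case] <- pb$age +
    pe$age_beta_per_sd_rare * z_rare[case] +
    pe$mody_age_shift * samp$mody_carrier[case] +
    stats::rnorm(sum(case), 0, pn$age)
  samp$bmi_z <- ifelse(case, pb$bmiz, pb$control_bmiz) +
    ifelse(case, pe$mody_bmiz_shift * samp$mody_carrier, 0) +
    stats::rnorm(n, 0, pn$bmiz)
  log_cpep <- ifelse(case, pb$cpep_log10, pb$control_cpep_log10) +
    ifelse(case, pe$cpep_beta_per_sd_common * z_common, 0) +
    ifelse(case, pe$mody_cpep_shift * samp$mody_carrier, 0) +
    stats::rnorm(n, 0, pn$cpep)
  samp$c_peptide <- 10 ^ log_cpep

  ann <- v[, c("variant_id", "gene", "category", "pathogenic_flag")]
  ann <- cbind(ann, as.data.frame(af))
  truth <- list(
    variants = v[, c("variant_id", "gene", "category", "ancestral_maf",
                     "beta_true", "pathogenic_flag")],
    genes = freqs$genes,
    samples = data.frame(sample_id = samp$sample_id,
                         rare_score_true = rare_score,
                         common_score_true = common_score,
                         genetic_score = samp$genetic_score,
                         mody_carrier = samp$mody_carrier),
    intercept = alpha)
  samp <- samp[, c("sample_id", "status", "cluster", "sex",
                   "age_at_diagnosis", "bmi_z", "c_peptide")]
  structure(list(genotypes = G, annotations = ann, samples = samp,
                 truth = truth, mody_genes = freqs$mody_genes,
                 af = af, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d samples (%d cases), %d variants, %d genes\n",
              nrow(x$samples), sum(x$samples$status == 1),
              ncol(x$genotypes), length(unique(x$annotations$gene))))
  invisible(x)
}
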