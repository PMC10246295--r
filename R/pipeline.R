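# End-to-end orchestration: simulate -> match -> assoc -> enrich ->
# architecture -> scores -> report, with file-based stage contracts and a
# reproducibility manifest.

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. All
#' randomness derives from `seed`; stages can be toggled, and a stage
#' whose upstream outputs are missing fails with a named error.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param cohort List of arguments for [sim_config()] (the `seed` is set
#'   from the master seed unless given explicitly).
#' @param stages Character vector of stages to run, in dependency order
#'   among `"simulate"`, `"match"`, `"assoc"`, `"enrich"`,
#'   `"architecture"`, `"scores"`, `"report"`.
#' @param n_pcs Number of genetic PCs (matching and covariates).
#' @param k_clusters k-means cluster count (default: the cohort's
#'   configured cluster count).
#' @param max_ratio,caliper Matching parameters (see [match_controls()]).
#' @param exome_wide,nominal Gene-level significance thresholds.
#' @param top_k Top-gene count for enrichment and tiers.
#' @param or_bands Descending OR band thresholds.
#' @param liability_k Prevalence for the liability model.
#' @param n_bootstrap Bootstrap draws for LVE intervals.
#' @param n_top_units Units per frequency class entering the LVE sums.
#' @param gmt Optional GMT path with gene sets; when `NULL`, demonstration
#'   sets are synthesized around the cohort's causal genes.
#' @param verbose Log stage progress to stderr.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, cohort = list(),
                            stages = c("simulate", "match", "assoc",
                                       "enrich", "architecture", "scores",
                                       "report"),
                            n_pcs = 4, k_clusters = NULL, max_ratio = 4,
                            caliper = NULL, exome_wide = 2.5e-6,
                            nominal = 0.05, top_k = 50, or_bands = c(5, 3),
                            liability_k = 0.01, n_bootstrap = 200,
                            n_top_units = 10, gmt = NULL, verbose = FALSE) {
  all_stages <- c("simulate", "match", "assoc", "enrich", "architecture",
                  "scores", "report")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (exome_wide <= 0 || nominal <= 0) stopf("thresholds must be positive")
  if (is.null(cohort$seed)) cohort$seed <- seed
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
              stages = all_stages[all_stages %in% stages],
              n_pcs = n_pcs, k_clusters = k_clusters,
              max_ratio = max_ratio, caliper = caliper,
              exome_wide = exome_wide, nominal = nominal,
              top_k = as.integer(top_k),
              or_bands = or_bands, liability_k = liability_k,
              n_bootstrap = n_bootstrap, n_top_units = n_top_units,
              gmt = gmt, verbose = isTRUE(verbose))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: '%s'", path)
  args <- yaml::read_yaml(path)
  if (is.null(args$out_dir)) stopf("config '%s' lacks out_dir", path)
  do.call(pipeline_config, args)
}

log_stage <- function(config, stage, fmt, ...) {
  if (config$verbose)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

require_stage_file <- function(config, stage, path, produced_by) {
  if (!file.exists(path))
    stopf("stage '%s' requires '%s' produced by stage '%s'; run it first or enable it",
          stage, basename(path), produced_by)
  path
}

pp <- function(config, ...) file.path(config$out_dir, ...)

stage_simulate <- function(config) {
  cohort <- simulate_cohort(do.call(sim_config, config$cohort))
  write_cohort(cohort, pp(config, "cohort"))
  log_stage(config, "simulate", "%d samples, %d variants",
            nrow(cohort$samples), ncol(cohort$genotypes))
  c(rows = nrow(cohort$samples))
}

load_cohort <- function(config, stage) {
  require_stage_file(config, stage, pp(config, "cohort", "manifest.json"),
                     "simulate")
  read_cohort(pp(config, "cohort"))
}

stage_match <- function(config) {
  cohort <- load_cohort(config, "match")
  G <- cohort$genotypes
  case <- cohort$samples$status == 1
  case_ids <- cohort$samples$sample_id[case]
  ctrl_ids <- cohort$samples$sample_id[!case]
  pruned <- ld_prune(G[case_ids, , drop = FALSE])
  pcs <- compute_pcs(G[case_ids, pruned, drop = FALSE], config$n_pcs)
  ctrl_coords <- project_pcs(pcs, G[ctrl_ids, , drop = FALSE])
  k <- config$k_clusters %||% max(cohort$samples$cluster)
  cl <- assign_clusters(pcs$coords, k, seed = config$seed)
  mres <- match_controls(pcs$coords, ctrl_coords,
                         max_ratio = config$max_ratio,
                         caliper = config$caliper,
                         case_clusters = cl$cluster)
  coords <- rbind(pcs$coords, ctrl_coords)
  write_tsv_strict(data.frame(sample_id = rownames(coords), coords),
                   pp(config, "pcs.tsv"))
  write_tsv_strict(data.frame(sample_id = names(cl$cluster),
                              cluster = unname(cl$cluster)),
                   pp(config, "clusters.tsv"))
  write_tsv_strict(data.frame(sample_id = mres$selected,
                              cluster = unname(mres$control_cluster)),
                   pp(config, "matched_controls.tsv"))
  jsonlite::write_json(list(effective_n = mres$effective_n,
                            caliper = mres$caliper,
                            n_cases = length(case_ids),
                            n_controls_selected = length(mres$selected)),
                       pp(config, "match_summary.json"), auto_unbox = TRUE)
  log_stage(config, "match", "%d controls selected, effective n %d",
            length(mres$selected), mres$effective_n)
  c(rows = length(mres$selected))
}

# matched analysis set + covariates shared by assoc and scores stages
analysis_set <- function(config, stage) {
  cohort <- load_cohort(config, stage)
  matched <- read_tsv_strict(
    require_stage_file(config, stage, pp(config, "matched_controls.tsv"),
                       "match"), required = "sample_id")
  pcs <- read_tsv_strict(
    require_stage_file(config, stage, pp(config, "pcs.tsv"), "match"),
    required = "sample_id")
  case_ids <- cohort$samples$sample_id[cohort$samples$status == 1]
  ids <- c(case_ids, matched$sample_id)
  samp <- cohort$samples[match(ids, cohort$samples$sample_id), ]
  pc_cols <- grep("^PC", names(pcs), value = TRUE)
  pc_mat <- as.matrix(pcs[match(ids, pcs$sample_id), pc_cols])
  cl <- factor(samp$cluster)
  covars <- cbind(pc_mat,
                  if (nlevels(cl) > 1)
                    stats::model.matrix(~ cl)[, -1, drop = FALSE],
                  sex = samp$sex)
  list(cohort = cohort, ids = ids,
       G = cohort$genotypes[ids, , drop = FALSE],
       status = samp$status, samples = samp, covariates = covars)
}

stage_assoc <- function(config) {
  as_ <- analysis_set(config, "assoc")
  maf <- apply(as_$G, 2, function(g) min(mean(g) / 2, 1 - mean(g) / 2))
  common <- colnames(as_$G)[maf >= 0.05]
  sv <- single_variant_test(as_$G[, common, drop = FALSE], as_$status,
                            as_$covariates)
  write_tsv_strict(sv, pp(config, "assoc_single.tsv"))
  ann <- as_$cohort$annotations
  genes <- setdiff(unique(ann$gene),
                   c("BACKGROUND", grep("^CL", unique(ann$gene),
                                        value = TRUE)))
  gb <- gene_burden_test(as_$G, ann, as_$status, genes = genes,
                         covariates = as_$covariates)
  write_tsv_strict(gb, pp(config, "assoc_gene.tsv"))
  syn <- gene_burden_test(as_$G, ann, as_$status, genes = genes,
                          masks = list(synonymous_mask()),
                          covariates = as_$covariates)
  write_tsv_strict(syn, pp(config, "assoc_gene_synonymous.tsv"))
  diag <- list(
    lambda_single = if (sum(!is.na(sv$p)) >= 2)
      suppressWarnings(inflation_diagnostics(sv$p)$lambda) else NA,
    lambda_gene = if (sum(!is.na(gb$corrected_p)) >= 2)
      suppressWarnings(inflation_diagnostics(gb$min_p)$lambda) else NA,
    n_single = sum(!is.na(sv$p)), n_gene = nrow(gb),
    n_synonymous_significant =
      sum(syn$corrected_p < config$exome_wide, na.rm = TRUE))
  jsonlite::write_json(diag, pp(config, "diagnostics.json"),
                       auto_unbox = TRUE)
  log_stage(config, "assoc", "%d variants, %d genes, lambda %.3f",
            nrow(sv), nrow(gb), diag$lambda_single %||% NA)
  c(rows = nrow(gb))
}

# demonstration gene sets synthesized around the cohort's causal genes
demo_gene_sets <- function(cohort, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 7L)
  truth <- cohort$truth$genes
  causal <- truth$gene[truth$class %in% c("rare_causal", "mody")]
  nulls <- truth$gene[truth$class == "null"]
  pad <- function(core, n_pad) unique(c(
    core, sample(nulls, min(n_pad, length(nulls)))))
  list(SYN_DIABETES_CORE = pad(causal, 5),
       SYN_INSULIN_SECRETION = pad(causal[seq_len(ceiling(length(causal) / 2))], 8),
       SYN_OVERWEIGHT_RELATED = pad(causal[c(TRUE, FALSE)], 8),
       SYN_UNRELATED_A = pad(character(), 12),
       SYN_UNRELATED_B = pad(character(), 12))
}

stage_enrich <- function(config) {
  cohort <- load_cohort(config, "enrich")
  gb <- read_tsv_strict(
    require_stage_file(config, "enrich", pp(config, "assoc_gene.tsv"),
                       "assoc"), required = c("gene", "corrected_p"))
  sets <- if (!is.null(config$gmt)) read_gmt(config$gmt)
  else demo_gene_sets(cohort, config$seed)
  gene_p <- stats::setNames(gb$corrected_p, gb$gene)
  universe <- gb$gene
  top <- gb$gene[order(gb$corrected_p)][seq_len(min(config$top_k,
                                                    nrow(gb)))]
  gene_stats <- do.call(rbind, lapply(split(
    cohort$annotations, cohort$annotations$gene), function(a)
      data.frame(gene = a$gene[1], n_variants = nrow(a),
                 combined_maf = sum(rowMeans(
                   as.matrix(a[, grep("^cluster_", names(a)),
                               drop = FALSE]))))))
  gene_stats <- gene_stats[gene_stats$gene %in% universe, ]
  res <- list()
  for (nm in names(sets)) {
    set_u <- intersect(sets[[nm]], universe)
    if (length(set_u) < 2) next
    res[[length(res) + 1L]] <-
      hypergeometric_enrichment(top, set_u, universe, set_name = nm)
    bg <- match_background(set_u, gene_stats, seed = config$seed)
    res[[length(res) + 1L]] <-
      rank_sum_enrichment(set_u, gene_p, bg, set_name = nm)
  }
  enr <- do.call(rbind, res)
  enr$q <- NA_real_
  hg <- enr$method == "hypergeometric"
  enr$q[hg] <- bh_qvalues(enr$p[hg])
  write_tsv_strict(enr, pp(config, "enrichment.tsv"))
  rs <- enr[enr$method == "rank-sum", , drop = FALSE]
  enriched <- rs$set[rs$p < bonferroni_threshold(nrow(rs))]
  if (!length(enriched))
    enriched <- utils::head(rs$set[order(rs$p)], 2)
  enriched_sets <- sets[intersect(names(sets), enriched)]
  known <- list(monogenic = cohort$mody_genes,
                causal_coding = utils::head(
                  cohort$truth$genes$gene[cohort$truth$genes$class ==
                                            "rare_causal"], 4))
  tiers <- classify_tiers(gb, known, enriched_sets, top_k = config$top_k,
                          exome_threshold = config$exome_wide,
                          nominal = config$nominal)
  write_tsv_strict(tiers, pp(config, "tiers.tsv"))
  log_stage(config, "enrich", "%d sets tested, %d genes tiered",
            length(sets), sum(!is.na(tiers$tier)))
  c(rows = nrow(enr))
}

stage_architecture <- function(config) {
  gb <- read_tsv_strict(
    require_stage_file(config, "architecture", pp(config, "assoc_gene.tsv"),
                       "assoc"),
    required = c("gene", "corrected_p", "min_p_mask"))
  sv <- read_tsv_strict(
    require_stage_file(config, "architecture",
                       pp(config, "assoc_single.tsv"), "assoc"),
    required = c("variant_id", "beta", "se", "p", "maf"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 11L)
  n_top <- config$n_top_units
  gb <- gb[order(gb$corrected_p), ]
  rare_units <- do.call(rbind, lapply(
    utils::head(seq_len(nrow(gb)), n_top), function(i) {
      mk <- gb$min_p_mask[i]
      data.frame(unit = gb$gene[i],
                 beta = gb[[paste0(mk, "_beta")]][i],
                 se = gb[[paste0(mk, "_se")]][i],
                 freq = max(gb[[paste0(mk, "_cmaf")]][i], 1e-5),
                 z_c = 0)
    }))
  rare_units <- rare_units[is.finite(rare_units$beta) &
                             is.finite(rare_units$se), , drop = FALSE]
  sv_ok <- sv[!is.na(sv$p), ]
  sv_ok <- sv_ok[order(sv_ok$p), ]
  common_units <- data.frame(unit = utils::head(sv_ok$variant_id, n_top),
                             beta = utils::head(sv_ok$beta, n_top),
                             se = utils::head(sv_ok$se, n_top),
                             freq = utils::head(sv_ok$maf, n_top), z_c = 0)
  model <- liability_model(config$liability_k)
  lve_rare <- aggregate_lve(rare_units, model, config$n_bootstrap)
  lve_common <- aggregate_lve(common_units, model, config$n_bootstrap)
  out <- rbind(
    data.frame(class = "rare_gene", unit = lve_rare$per_unit$unit,
               beta_corrected = lve_rare$per_unit$beta_corrected,
               freq = lve_rare$per_unit$freq, lve = lve_rare$per_unit$lve),
    data.frame(class = "common_variant", unit = lve_common$per_unit$unit,
               beta_corrected = lve_common$per_unit$beta_corrected,
               freq = lve_common$per_unit$freq,
               lve = lve_common$per_unit$lve))
  write_tsv_strict(out, pp(config, "lve.tsv"))
  sens <- lapply(c(0.005, 0.01, 0.02, 0.05, 0.1), function(K) {
    m <- liability_model(K)
    list(K = K,
         lve_rare = aggregate_lve(rare_units, m, 0)$lve,
         lve_common = aggregate_lve(common_units, m, 0)$lve)
  })
  report <- list(
    K = config$liability_k,
    lve_rare = lve_rare$lve, lve_rare_ci = lve_rare$ci,
    lve_common = lve_common$lve, lve_common_ci = lve_common$ci,
    common_to_rare_fold = lve_common$lve / max(lve_rare$lve, 1e-12),
    sensitivity = sens)
  jsonlite::write_json(report, pp(config, "architecture_report.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage(config, "architecture", "LVE rare %.4f, common %.4f",
            lve_rare$lve, lve_common$lve)
  c(rows = nrow(out))
}

stage_scores <- function(config) {
  as_ <- analysis_set(config, "scores")
  gb <- read_tsv_strict(
    require_stage_file(config, "scores", pp(config, "assoc_gene.tsv"),
                       "assoc"),
    required = c("gene", "corrected_p", "min_p_mask"))
  sv <- read_tsv_strict(
    require_stage_file(config, "scores", pp(config, "assoc_single.tsv"),
                       "assoc"), required = c("variant_id", "beta", "p"))
  ann <- as_$cohort$annotations
  control_af <- colMeans(as_$G[as_$status == 0, , drop = FALSE]) / 2
  # rare weights: nominally significant risk genes, winner's-curse
  # corrected at the nominal selection threshold
  z_nom <- stats::qnorm(1 - config$nominal / 2)
  sel <- which(gb$corrected_p < config$nominal)
  masks <- default_masks()
  mask_by_name <- stats::setNames(masks, vapply(masks, `[[`, "", "name"))
  rare_w <- list(); carrier_cols <- list()
  for (i in sel) {
    mk <- gb$min_p_mask[i]
    beta <- gb[[paste0(mk, "_beta")]][i]
    se <- gb[[paste0(mk, "_se")]][i]
    if (!is.finite(beta) || !is.finite(se) || beta <= 0) next
    bc <- if (abs(beta) / se >= z_nom)
      winners_curse_correct(beta, se, z_nom) else beta
    coll <- burden_collapse(as_$G, ann, mask_by_name[[mk]], control_af,
                            gene = gb$gene[i])
    if (!coll$n_variants) next
    rare_w[[length(rare_w) + 1L]] <-
      data.frame(unit = gb$gene[i], log_or = bc, source = "rare")
    carrier_cols[[gb$gene[i]]] <- coll$carrier
  }
  rare_carriers <- if (length(carrier_cols))
    do.call(cbind, carrier_cols) else NULL
  if (!is.null(rare_carriers)) rownames(rare_carriers) <- as_$ids
  sv_sel <- sv[!is.na(sv$p) & sv$p < config$nominal & sv$beta > 0, ]
  common_w <- if (nrow(sv_sel)) data.frame(
    unit = sv_sel$variant_id,
    log_or = mapply(function(b, s) if (abs(b) / s >= z_nom)
      winners_curse_correct(b, s, z_nom) else b, sv_sel$beta, sv_sel$se),
    source = "common") else NULL
  weights <- rbind(do.call(rbind, rare_w), common_w)
  if (is.null(weights) || !nrow(weights))
    stopf("stage 'scores': no usable score weights from the association results")
  scores <- compute_scores(rare_carriers,
                           as_$G[, intersect(weights$unit[weights$source ==
                                                            "common"],
                                             colnames(as_$G)),
                                 drop = FALSE],
                           weights)
  flags <- mody_flag(as_$G, ann, as_$cohort$mody_genes)
  scores <- assign_bands(scores, flags, config$or_bands)
  case_scores <- scores[as_$status == 1, ]
  case_flags <- flags[as_$status == 1]
  write_tsv_strict(weights, pp(config, "weights.tsv"))
  write_tsv_strict(scores, pp(config, "scores.tsv"))
  bands <- as.data.frame(table(band = case_scores$band),
                         responseName = "n_cases")
  write_tsv_strict(bands, pp(config, "bands.tsv"))
  # a score component can be constant (e.g. no rare weights selected);
  # report the components that vary rather than failing the stage
  safe_reg <- function(label, s) {
    out <- tryCatch(phenotype_regression(s, as_$samples, flags),
                    error = function(e) NULL)
    if (is.null(out)) NULL else cbind(score = label, out)
  }
  reg <- rbind(safe_reg("rare", scores$rare_log_or),
               safe_reg("common", scores$common_log_or))
  if (is.null(reg))
    reg <- data.frame(score = character(), phenotype = character(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      n = integer())
  write_tsv_strict(reg, pp(config, "phenotype_assoc.tsv"))
  cmp <- mody_phenotype_comparison(as_$samples, flags)
  write_tsv_strict(cmp, pp(config, "mody_phenotypes.tsv"))
  trend <- tryCatch(rare_fraction_trend(case_scores,
                                        bin_size = max(10, nrow(case_scores)
                                                       %/% 12)),
                    error = function(e) NULL)
  if (!is.null(trend))
    write_tsv_strict(trend$bins, pp(config, "rare_fraction_trend.tsv"))
  log_stage(config, "scores", "%d weights, %d banded cases", nrow(weights),
            sum(case_scores$band != "none"))
  c(rows = nrow(scores))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order (simulate, match,
#' assoc, enrich, architecture, scores, report), writing each stage's TSV
#' and JSON outputs under the configured directory. A failure halts with
#' the stage named; the final manifest records the configuration hash,
#' seed, package version and per-stage row counts and runtimes, so any
#' output can be traced to the configuration and seed that produced it.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  runners <- list(simulate = stage_simulate, match = stage_match,
                  assoc = stage_assoc, enrich = stage_enrich,
                  architecture = stage_architecture, scores = stage_scores,
                  report = function(config) c(rows = 0))
  stage_info <- list()
  for (stage in config$stages) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(runners[[stage]](config), error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    stage_info[[stage]] <- list(rows = unname(res[["rows"]]),
                                seconds = round(proc.time()[["elapsed"]] -
                                                  t0, 2))
  }
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("rvarch")),
    stages = stage_info)
  jsonlite::write_json(manifest, pp(config, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
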