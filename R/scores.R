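# Per-individual contribution scores: monogenic-variant flags,
# rare/common/combined log-OR scores, risk bands, phenotype regressions.

#' Flag carriers of pathogenic variants in monogenic-disease genes
#'
#' A sample is flagged when it carries at least one allele of a
#' pathogenic-flagged variant in a gene of the monogenic registry.
#'
#' @param genotypes Samples-by-variants dosage matrix.
#' @param annotations Variant table with `variant_id`, `gene`,
#'   `pathogenic_flag`.
#' @param registry Character vector of monogenic-disease genes.
#' @return Named logical vector (one flag per sample).
#' @export
mody_flag <- function(genotypes, annotations, registry) {
  if (is.null(registry) || !length(registry))
    stopf("mody_flag: monogenic gene registry is missing")
  vids <- annotations$variant_id[annotations$pathogenic_flag == 1 &
                                   annotations$gene %in% registry]
  vids <- intersect(vids, colnames(genotypes))
  flags <- if (length(vids))
    rowSums(genotypes[, vids, drop = FALSE]) > 0
  else rep(FALSE, nrow(genotypes))
  stats::setNames(flags, rownames(genotypes))
}

#' Re-run gene-level tests after removing flagged carriers
#'
#' Leave-out reanalysis: drops every flagged sample and repeats the
#' nested-mask burden test, to ask whether an association survives once
#' carriers of known pathogenic variants are excluded.
#'
#' @param genotypes,annotations,status As in [gene_burden_test()].
#' @param flags Logical vector from [mody_flag()].
#' @param covariates Optional covariate matrix (subset to the retained
#'   samples before refitting).
#' @param ... Passed to [gene_burden_test()].
#' @return [gene_burden_test()] result on the reduced cohort.
#' @export
mody_leave_out_test <- function(genotypes, annotations, status, flags,
                                covariates = NULL, ...) {
  keep <- !flags
  if (!is.null(covariates))
    covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  gene_burden_test(genotypes[keep, , drop = FALSE], annotations,
                   status[keep], covariates = covariates, ...)
}

#' Per-individual rare, common and combined contribution scores
#'
#' The rare score is the sum of (winner's-curse corrected) log odds ratios
#' of the rare-gene burdens a sample carries, counting each gene once
#' (carrier level); the common score is the dosage-weighted sum of common
#' variant log odds ratios; the combined score is their sum on the log
#' scale, so reported ORs multiply. Samples carrying nothing score 0
#' (OR 1). Weights referencing units absent from the inputs are skipped
#' with a message.
#'
#' @param rare_carriers Samples-by-genes 0/1 carrier matrix (e.g. built by
#'   [burden_collapse()] under each gene's qualifying mask).
#' @param common_dosages Samples-by-variants dosage matrix.
#' @param weights Data frame with `unit`, `log_or`, `source`
#'   (`"rare"`/`"common"`); rare units are gene names, common units
#'   variant ids.
#' @return Data frame of class `contribution_scores`: `sample_id`,
#'   `rare_log_or`, `common_log_or`, `combined_log_or` and the
#'   corresponding ORs.
#' @export
compute_scores <- function(rare_carriers, common_dosages, weights) {
  stopifnot(all(c("unit", "log_or", "source") %in% names(weights)))
  if (!all(is.finite(weights$log_or))) stopf("weights must be finite")
  n <- if (!is.null(rare_carriers)) nrow(rare_carriers)
  else nrow(common_dosages)
  ids <- rownames(rare_carriers) %||% rownames(common_dosages)
  score_block <- function(mat, w) {
    if (is.null(mat) || nrow(w) == 0) return(numeric(n))
    hit <- w$unit %in% colnames(mat)
    if (any(!hit))
      message(sprintf("compute_scores: %d weight(s) reference absent units and were skipped (%s)",
                      sum(!hit),
                      paste(utils::head(w$unit[!hit], 3), collapse = ", ")))
    w <- w[hit, , drop = FALSE]
    if (!nrow(w)) return(numeric(n))
    drop(mat[, w$unit, drop = FALSE] %*% w$log_or)
  }
  rare <- score_block(rare_carriers,
                      weights[weights$source == "rare", , drop = FALSE])
  common <- score_block(common_dosages,
                        weights[weights$source == "common", , drop = FALSE])
  out <- data.frame(sample_id = ids,
                    rare_log_or = rare, common_log_or = common,
                    combined_log_or = rare + common)
  out$rare_or <- exp(out$rare_log_or)
  out$common_or <- exp(out$common_log_or)
  out$combined_or <- exp(out$combined_log_or)
  class(out) <- c("contribution_scores", class(out))
  out
}

#' Assign each sample to a single genetic-risk band
#'
#' Mutually exclusive bands with fixed precedence: monogenic-variant
#' carriers first; then, at each descending OR threshold, rare score, then
#' common score, then combined score (the combined band therefore captures
#' samples whose combined OR clears the threshold although neither
#' component does). Default thresholds 5 then 3 yield bands `MODY`,
#' `rare_ge5`, `common_ge5`, `combined_ge5`, `rare_3_5`, `common_3_5`,
#' `combined_3_5`, `none`; bands partition the cohort.
#'
#' @param scores A [compute_scores()] result.
#' @param flags Logical monogenic-carrier flags (same order as `scores`).
#' @param thresholds Strictly descending OR thresholds (default `c(5, 3)`).
#' @return `scores` with a `band` factor column appended.
#' @export
assign_bands <- function(scores, flags, thresholds = c(5, 3)) {
  if (length(thresholds) < 1 || any(diff(thresholds) >= 0) ||
      any(thresholds <= 1))
    stopf("thresholds must be strictly descending ORs > 1")
  n <- nrow(scores)
  stopifnot(length(flags) == n)
  suffix <- function(i) if (i == 1) sprintf("ge%g", thresholds[1])
  else sprintf("%g_%g", thresholds[i], thresholds[i - 1])
  levels <- c("MODY",
              unlist(lapply(seq_along(thresholds), function(i)
                paste0(c("rare_", "common_", "combined_"), suffix(i)))),
              "none")
  band <- rep("none", n)
  unset <- !flags
  band[flags] <- "MODY"
  for (i in seq_along(thresholds)) {
    thr <- thresholds[i]
    for (comp in c("rare", "common", "combined")) {
      hit <- unset & scores[[paste0(comp, "_or")]] >= thr
      band[hit] <- paste0(comp, "_", suffix(i))
      unset <- unset & !hit
    }
  }
  scores$band <- factor(band, levels = levels)
  scores
}

#' Rare-score share of the combined score across the risk ranking
#'
#' Restricts to samples with combined OR at or above `min_combined_or` and
#' both component ORs above 1, ranks them by combined score (descending),
#' groups them into bins of `bin_size`, and reports the per-bin mean of
#' the rare share `rare / (rare + common)` on the log-OR scale, together
#' with a Spearman trend statistic of bin index against bin mean (negative
#' when the rare contribution concentrates among the most extreme cases).
#'
#' @param scores A [compute_scores()] result.
#' @param bin_size Samples per rank bin (default 50).
#' @param min_combined_or Combined-OR floor (default 3).
#' @return List: `bins` (data frame with bin index, n, mean rare
#'   fraction), `spearman_rho`, `spearman_p`, `n_samples`.
#' @export
rare_fraction_trend <- function(scores, bin_size = 50,
                                min_combined_or = 3) {
  sel <- scores$combined_or >= min_combined_or & scores$rare_or > 1 &
    scores$common_or > 1
  s <- scores[sel, , drop = FALSE]
  if (nrow(s) < 1) stopf("no samples qualify for the trend analysis")
  s <- s[order(-s$combined_log_or), , drop = FALSE]
  frac <- s$rare_log_or / s$combined_log_or
  bin <- (seq_len(nrow(s)) - 1L) %/% bin_size + 1L
  if (max(bin) < 1) stopf("fewer than one bin")
  bins <- data.frame(bin = sort(unique(bin)))
  bins$n <- as.integer(table(bin))
  bins$mean_rare_fraction <- as.numeric(tapply(frac, bin, mean))
  rho <- NA_real_; pv <- NA_real_
  if (nrow(bins) >= 3 && stats::sd(bins$mean_rare_fraction) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(bins$bin, bins$mean_rare_fraction,
                      method = "spearman"))
    rho <- unname(ct$estimate)
    pv <- ct$p.value
  } else if (stats::sd(bins$mean_rare_fraction) == 0) {
    rho <- 0
  }
  list(bins = bins, spearman_rho = rho, spearman_p = pv,
       n_samples = nrow(s))
}

#' Regress case phenotypes on a standardized contribution score
#'
#' Ordinary least squares of each phenotype on the score standardized to
#' unit variance, adjusting for sex and ancestry-cluster indicators.
#' C-peptide is log10-transformed. Monogenic-variant carriers are excluded
#' by default, since their shifted phenotypes would otherwise masquerade
#' as a score effect.
#'
#' @param score Numeric score per sample (cases; others may be NA).
#' @param phenotypes Data frame with `age_at_diagnosis`, `bmi_z`,
#'   `c_peptide`, `sex`, `cluster`, `status`.
#' @param flags Monogenic carrier flags; carriers are dropped when
#'   `exclude_mody`.
#' @param exclude_mody Drop flagged carriers (default TRUE).
#' @return Data frame: `phenotype`, `beta` (per 1 SD of score), `se`, `p`,
#'   `n`.
#' @export
phenotype_regression <- function(score, phenotypes, flags = NULL,
                                 exclude_mody = TRUE) {
  case <- phenotypes$status == 1
  keep <- case
  if (exclude_mody && !is.null(flags)) keep <- keep & !flags
  s <- score[keep]
  if (stats::sd(s, na.rm = TRUE) == 0)
    stopf("phenotype_regression: score has zero variance")
  ph <- phenotypes[keep, , drop = FALSE]
  z <- (s - mean(s)) / stats::sd(s)
  targets <- list(age_at_diagnosis = ph$age_at_diagnosis,
                  bmi_z = ph$bmi_z,
                  log10_c_peptide = log10(ph$c_peptide))
  covs <- data.frame(sex = ph$sex, cluster = factor(ph$cluster))
  rows <- lapply(names(targets), function(nm) {
    y <- targets[[nm]]
    ok <- !is.na(y)
    df <- data.frame(y = y[ok], z = z[ok], covs[ok, , drop = FALSE])
    form <- if (nlevels(droplevels(df$cluster)) > 1)
      y ~ z + sex + cluster else y ~ z + sex
    fit <- stats::lm(form, data = df)
    co <- summary(fit)$coefficients
    data.frame(phenotype = nm, beta = co["z", 1], se = co["z", 2],
               p = co["z", 4], n = sum(ok))
  })
  do.call(rbind, rows)
}

#' Compare phenotypes of monogenic-variant carriers versus other cases
#'
#' Two-sample comparison (Welch t-test by default, Wilcoxon rank-sum with
#' `method = "wilcoxon"`) of each phenotype between flagged and unflagged
#' cases.
#'
#' @param phenotypes Phenotype data frame (see [phenotype_regression()]).
#' @param flags Monogenic carrier flags.
#' @param method "t" or "wilcoxon".
#' @return Data frame: `phenotype`, `mean_carrier`, `mean_other`, `diff`,
#'   `ci_lo`, `ci_hi` (t method only), `p`, `n_carrier`, `n_other`.
#' @export
mody_phenotype_comparison <- function(phenotypes, flags,
                                      method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  case <- phenotypes$status == 1
  targets <- list(age_at_diagnosis = phenotypes$age_at_diagnosis,
                  bmi_z = phenotypes$bmi_z,
                  log10_c_peptide = log10(phenotypes$c_peptide))
  rows <- lapply(names(targets), function(nm) {
    y <- targets[[nm]]
    a <- y[case & flags & !is.na(y)]
    b <- y[case & !flags & !is.na(y)]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(phenotype = nm, mean_carrier = NA_real_,
                        mean_other = NA_real_, diff = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                        n_carrier = length(a), n_other = length(b)))
    if (method == "t") {
      tt <- stats::t.test(a, b)
      data.frame(phenotype = nm, mean_carrier = mean(a),
                 mean_other = mean(b), diff = mean(a) - mean(b),
                 ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
                 p = tt$p.value, n_carrier = length(a),
                 n_other = length(b))
    } else {
      wt <- stats::wilcox.test(a, b, exact = FALSE)
      data.frame(phenotype = nm, mean_carrier = mean(a),
                 mean_other = mean(b), diff = mean(a) - mean(b),
                 ci_lo = NA_real_, ci_hi = NA_real_, p = wt$p.value,
                 n_carrier = length(a), n_other = length(b))
    }
  })
  do.call(rbind, rows)
}
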