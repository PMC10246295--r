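# Single-variant and nested-mask gene-level association testing.

#' Default nested variant masks
#'
#' Seven strictly nested masks combining consequence severity with a
#' control-frequency ceiling, from ultra-rare protein-truncating variants
#' only to all nonsynonymous variants below 1% frequency. Each mask's rule
#' is a superset-monotone relaxation of the previous one (categories only
#' grow, ceilings only rise), so carrier sets are nested by construction.
#'
#' @return List of masks, each a list with `name`, `categories`, `max_af`.
#' @export
default_masks <- function() {
  ps <- c("ptv", "missense_strict")
  psb <- c(ps, "missense_broad")
  masks <- list(
    list(name = "ptv_0.05", categories = "ptv", max_af = 5e-4),
    list(name = "ptv_0.1", categories = "ptv", max_af = 1e-3),
    list(name = "ptv_ms_0.1", categories = ps, max_af = 1e-3),
    list(name = "ptv_ms_0.25", categories = ps, max_af = 2.5e-3),
    list(name = "ptv_ms_0.5", categories = ps, max_af = 5e-3),
    list(name = "nonsyn_0.5", categories = psb, max_af = 5e-3),
    list(name = "nonsyn_1", categories = psb, max_af = 1e-2))
  check_masks(masks)
  masks
}

#' Synonymous-only negative-control mask
#' @return A single mask selecting synonymous variants below 1% frequency.
#' @export
synonymous_mask <- function() {
  list(name = "synonymous_1", categories = "synonymous", max_af = 1e-2)
}

#' Verify that a mask list is strictly nested
#'
#' Each mask's allowed categories must be a subset of the next mask's and
#' its frequency ceiling no larger, so that every mask's variant set is
#' contained in the next looser mask's set for any annotation table.
#'
#' @param masks List of masks as in [default_masks()].
#' @return `masks`, invisibly; errors if nesting is violated.
#' @export
check_masks <- function(masks) {
  if (!length(masks)) stopf("empty mask list")
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!all(c("name", "categories", "max_af") %in% names(m)))
      stopf("mask %d lacks name/categories/max_af", i)
    if (i > 1) {
      prev <- masks[[i - 1]]
      if (!all(prev$categories %in% m$categories) ||
          prev$max_af > m$max_af)
        stopf("masks are not nested at position %d ('%s' vs '%s')",
              i, prev$name, m$name)
    }
  }
  invisible(masks)
}

#' Collapse qualifying variants of a gene into a carrier indicator
#'
#' A sample is a carrier under a mask when it holds at least one allele of
#' a variant whose consequence category is allowed by the mask and whose
#' control-only allele frequency is below the mask's ceiling. Frequency
#' ceilings are evaluated on controls so that case enrichment cannot leak
#' into mask membership.
#'
#' @param genotypes Samples-by-variants dosage matrix.
#' @param annotations Variant table with `variant_id`, `gene`, `category`.
#' @param mask A single mask (see [default_masks()]).
#' @param control_af Named vector of control-only allele frequencies.
#' @param gene Optional gene to restrict to.
#' @return List with `carrier` (0/1 integer per sample), `variants`
#'   (qualifying ids), `n_variants` and `combined_maf` (summed control AF).
#'   A gene with no qualifying variants yields a zero indicator and an
#'   empty variant list.
#' @export
burden_collapse <- function(genotypes, annotations, mask, control_af,
                            gene = NULL) {
  ann <- annotations
  if (!is.null(gene)) ann <- ann[ann$gene == gene, , drop = FALSE]
  af <- control_af[ann$variant_id]
  qual <- ann$variant_id[ann$category %in% mask$categories &
                           !is.na(af) & af <= mask$max_af]
  qual <- intersect(qual, colnames(genotypes))
  n <- nrow(genotypes)
  if (!length(qual))
    return(list(carrier = integer(n), variants = character(),
                n_variants = 0L, combined_maf = 0))
  carrier <- as.integer(rowSums(genotypes[, qual, drop = FALSE]) > 0)
  list(carrier = carrier, variants = qual, n_variants = length(qual),
       combined_maf = sum(control_af[qual]))
}

# Build a design matrix from covariates, dropping constant columns.
build_design <- function(n, covariates = NULL) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    keep <- apply(C, 2, function(x) stats::sd(x) > 0)
    if (any(keep)) X <- cbind(X, C[, keep, drop = FALSE])
  }
  X
}

#' Single-variant association tests
#'
#' Per-variant logistic regression of case status on allele dosage plus
#' covariates, with Firth penalization engaged when the minor-allele
#' carrier count falls below `firth_threshold` (rare exposures are
#' otherwise biased and prone to separation) and ordinary maximum
#' likelihood above it. Two-sided Wald P. Monomorphic variants are skipped
#' with a reason; fits that remain unstable despite penalization are
#' flagged with a missing P rather than dropped.
#'
#' @param genotypes Samples-by-variants dosage matrix.
#' @param status Binary case indicator per sample.
#' @param covariates Optional matrix of covariates (top PCs, cluster
#'   indicators, sex).
#' @param firth_threshold Carrier count below which Firth penalization is
#'   used (default 50).
#' @return Data frame with one row per variant: `variant_id`, `beta`,
#'   `se`, `p`, `or`, `maf`, `n_carriers`, `firth`, `flagged`,
#'   `skip_reason`.
#' @export
single_variant_test <- function(genotypes, status, covariates = NULL,
                                firth_threshold = 50) {
  n <- nrow(genotypes)
  stopifnot(length(status) == n)
  X0 <- build_design(n, covariates)
  m <- ncol(genotypes)
  out <- data.frame(variant_id = colnames(genotypes) %||% seq_len(m),
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    or = NA_real_, maf = NA_real_, n_carriers = NA_integer_,
                    firth = FALSE, flagged = FALSE,
                    skip_reason = NA_character_)
  j_g <- ncol(X0) + 1L
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    af <- mean(g) / 2
    out$maf[j] <- min(af, 1 - af)
    minor_dosage <- if (af <= 0.5) g else 2L - g
    carriers <- sum(minor_dosage > 0)
    out$n_carriers[j] <- carriers
    if (stats::var(g) == 0) {
      out$skip_reason[j] <- "monomorphic"
      next
    }
    use_firth <- carriers < firth_threshold
    out$firth[j] <- use_firth
    fit <- logistic_fit(cbind(X0, g = g), status, firth = use_firth)
    out$beta[j] <- fit$coef[j_g]
    out$se[j] <- fit$se[j_g]
    out$or[j] <- exp(fit$coef[j_g])
    if (fit$flagged) {
      out$flagged[j] <- TRUE
      out$p[j] <- NA_real_
    } else {
      out$p[j] <- wald_p(fit, j_g)
    }
  }
  out
}

# effective number of tests from the eigenvalues of the inter-mask carrier
# correlation matrix: smallest count of eigenvalues reaching 99.5% of trace
n_eff_from_carriers <- function(carrier_mat, trace_frac = 0.995) {
  k <- ncol(carrier_mat)
  if (k <= 1) return(1L)
  R <- suppressWarnings(stats::cor(carrier_mat))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  ev <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  cum <- cumsum(ev) / sum(ev)
  as.integer(which(cum >= trace_frac)[1])
}

#' Gene-level nested-mask burden test
#'
#' For each gene, collapses variants under each mask, fits a
#' Firth-penalized logistic burden regression per non-degenerate mask,
#' takes the smallest P across masks, estimates the effective number of
#' tests from the eigenvalues of the inter-mask carrier correlation matrix
#' (count needed to reach 99.5% of the trace), and reports a single
#' corrected P per gene: `1 - (1 - minP)^Neff`. Identical masks therefore
#' cost nothing (Neff = 1) and fully distinct masks cost a Bonferroni-like
#' factor. Burden P-values use a penalized likelihood-ratio test by
#' default, which is better calibrated than the Wald test at the carrier
#' counts typical of rare-variant masks; `test = "wald"` is available.
#'
#' @param genotypes Samples-by-variants dosage matrix.
#' @param annotations Variant table (`variant_id`, `gene`, `category`).
#' @param status Binary case indicator per sample.
#' @param masks Mask list (default [default_masks()]).
#' @param covariates Optional covariate matrix.
#' @param genes Genes to test (default: all genes in `annotations`).
#' @param firth_threshold Carrier count below which Firth penalization is
#'   engaged.
#' @param test "lrt" (default) or "wald".
#' @param control_af Control-only allele frequencies; computed from
#'   `status == 0` samples when omitted.
#' @return Data frame with one row per testable gene: summary columns
#'   (`gene`, `min_p`, `min_p_mask`, `n_eff`, `corrected_p`, `direction`,
#'   `n_masks_tested`) and per-mask columns
#'   `<mask>_{carriers,beta,se,p,cmaf,nvar}`. Genes whose masks are all
#'   empty or degenerate are omitted (and listed in the
#'   `omitted` attribute with a reason).
#' @export
gene_burden_test <- function(genotypes, annotations, status,
                             masks = default_masks(), covariates = NULL,
                             genes = NULL, firth_threshold = 50,
                             test = c("lrt", "wald"), control_af = NULL) {
  test <- match.arg(test)
  check_masks(masks)
  n <- nrow(genotypes)
  stopifnot(length(status) == n)
  if (is.null(control_af))
    control_af <- colMeans(genotypes[status == 0, , drop = FALSE]) / 2
  X0 <- build_design(n, covariates)
  j_g <- ncol(X0) + 1L
  genes <- genes %||% unique(annotations$gene)
  mask_names <- vapply(masks, `[[`, "", "name")

  rows <- vector("list", length(genes))
  omitted <- character()
  for (gi in seq_along(genes)) {
    gene <- genes[gi]
    ann_g <- annotations[annotations$gene == gene, , drop = FALSE]
    coll <- lapply(masks, function(m)
      burden_collapse(genotypes, ann_g, m, control_af))
    carrier_mat <- vapply(coll, `[[`, integer(n), "carrier")
    counts <- colSums(carrier_mat)
    nondeg <- which(counts > 0 & counts < n)
    if (!length(nondeg)) {
      omitted <- c(omitted, gene)
      next
    }
    # fit each distinct carrier pattern once
    keys <- vapply(nondeg, function(j)
      paste(which(carrier_mat[, j] == 1L), collapse = ","), "")
    fits <- list()
    per_mask <- data.frame(mask = mask_names,
                           carriers = counts,
                           beta = NA_real_, se = NA_real_, p = NA_real_,
                           cmaf = vapply(coll, `[[`, 0, "combined_maf"),
                           nvar = vapply(coll, `[[`, 0L, "n_variants"))
    for (idx in seq_along(nondeg)) {
      j <- nondeg[idx]
      key <- keys[idx]
      if (is.null(fits[[key]])) {
        carrier <- carrier_mat[, j]
        use_firth <- min(sum(carrier), n - sum(carrier)) < firth_threshold
        X <- cbind(X0, burden = carrier)
        if (test == "lrt") {
          lr <- lrt_p(X, status, j_g, firth = use_firth)
          fit <- lr$full
          pv <- if (fit$flagged) NA_real_ else lr$p
        } else {
          fit <- logistic_fit(X, status, firth = use_firth)
          pv <- if (fit$flagged) NA_real_ else wald_p(fit, j_g)
        }
        fits[[key]] <- list(beta = fit$coef[j_g], se = fit$se[j_g], p = pv)
      }
      f <- fits[[key]]
      per_mask$beta[j] <- f$beta
      per_mask$se[j] <- f$se
      per_mask$p[j] <- f$p
    }
    if (all(is.na(per_mask$p))) {
      omitted <- c(omitted, gene)
      next
    }
    min_idx <- which.min(per_mask$p)
    min_p <- per_mask$p[min_idx]
    n_eff <- n_eff_from_carriers(carrier_mat[, nondeg, drop = FALSE])
    corrected <- 1 - (1 - min_p)^n_eff
    row <- data.frame(gene = gene, min_p = min_p,
                      min_p_mask = mask_names[min_idx],
                      n_eff = n_eff, corrected_p = corrected,
                      direction = sign(per_mask$beta[min_idx]),
                      n_masks_tested = length(nondeg))
    wide <- unlist(lapply(seq_along(masks), function(j)
      stats::setNames(list(per_mask$carriers[j], per_mask$beta[j],
                           per_mask$se[j], per_mask$p[j], per_mask$cmaf[j],
                           per_mask$nvar[j]),
                      paste(mask_names[j],
                            c("carriers", "beta", "se", "p", "cmaf", "nvar"),
                            sep = "_"))), recursive = FALSE)
    rows[[gi]] <- cbind(row, as.data.frame(wide))
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res)) res <- data.frame()
  attr(res, "omitted") <- omitted
  res
}

#' Genomic-control inflation diagnostics
#'
#' Lambda is the median observed 1-df association chi-square divided by the
#' null median (0.4549). A lambda near 1 indicates well-calibrated tests;
#' values well above 1 indicate systematic inflation, e.g. from residual
#' population stratification.
#'
#' @param p Vector of P-values.
#' @return List with `lambda`, `n`, and `qq`, a data frame of expected vs
#'   observed -log10 P quantile pairs. Fewer than 100 P-values triggers a
#'   warning (lambda is still computed).
#' @export
inflation_diagnostics <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stopf("no P-values supplied")
  if (length(p) < 100)
    warnf("inflation_diagnostics: only %d P-values; lambda is unstable",
          length(p))
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  obs <- sort(p)
  expd <- stats::ppoints(length(obs))
  list(lambda = lambda, n = length(p),
       qq = data.frame(expected = -log10(expd), observed = -log10(obs)))
}
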