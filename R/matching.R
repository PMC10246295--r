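# External-control ancestry matching: LD pruning, genetic PCs, k-means
# cluster assignment, greedy caliper matching, effective sample size.

#' Windowed LD pruning
#'
#' Greedily removes variants whose squared correlation with a retained
#' variant inside a trailing window exceeds `r2_max`, after filtering to
#' common variants. Standard preprocessing before computing genetic PCs.
#'
#' @param genotypes Samples-by-variants dosage matrix.
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param r2_max Maximum allowed squared correlation (default 0.2).
#' @param window Trailing window size in variants.
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(genotypes, maf_min = 0.05, r2_max = 0.2, window = 50) {
  af <- colMeans(genotypes) / 2
  maf <- pmin(af, 1 - af)
  keep_common <- which(maf >= maf_min & maf > 0)
  if (!length(keep_common)) return(character())
  G <- genotypes[, keep_common, drop = FALSE]
  kept <- integer()
  for (j in seq_len(ncol(G))) {
    recent <- kept[kept > j - window]
    ok <- TRUE
    if (length(recent)) {
      r <- suppressWarnings(stats::cor(G[, j], G[, recent, drop = FALSE]))
      ok <- all(is.na(r) | r^2 <= r2_max)
    }
    if (ok) kept <- c(kept, j)
  }
  colnames(G)[kept]
}

#' Genetic principal components
#'
#' Top principal components of the column-standardized genotype matrix.
#' Deterministic up to sign; the sign of each component is fixed by making
#' its largest-magnitude loading positive.
#'
#' @param genotypes Samples-by-variants dosage matrix, pre-filtered to
#'   common LD-pruned variants (see [ld_prune()]).
#' @param n_components Number of components to retain.
#' @return Object of class `pc_model`: loadings, eigenvalues, variant ids,
#'   centering/scaling vectors and per-sample `coords`.
#' @export
compute_pcs <- function(genotypes, n_components = 10) {
  n <- nrow(genotypes)
  if (is.null(n) || n < 2) stopf("compute_pcs needs >= 2 samples")
  ctr <- colMeans(genotypes)
  scl <- apply(genotypes, 2, stats::sd)
  keep <- which(scl > 0)
  if (!length(keep)) stopf("no polymorphic variants for PCA")
  rank_max <- min(n - 1, length(keep))
  if (n_components > rank_max)
    stopf("requested %d components but rank is at most %d",
          n_components, rank_max)
  Z <- scale(genotypes[, keep, drop = FALSE], center = ctr[keep],
             scale = scl[keep])
  sv <- svd(Z, nu = n_components, nv = n_components)
  loadings <- sv$v
  coords <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(n_components)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      coords[, k] <- -coords[, k]
    }
  }
  dimnames(coords) <- list(rownames(genotypes),
                           paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(colnames(genotypes)[keep],
                             colnames(coords))
  structure(list(loadings = loadings,
                 eigenvalues = sv$d[seq_len(n_components)]^2 / (n - 1),
                 variants = colnames(genotypes)[keep],
                 center = ctr[keep], scale = scl[keep],
                 coords = coords),
            class = "pc_model")
}

#' Project samples into an existing PC space
#'
#' @param model A [compute_pcs()] result (typically fitted on cases).
#' @param genotypes Dosage matrix for the samples to project; must contain
#'   the model's variants.
#' @return Coordinates matrix (samples x components).
#' @export
project_pcs <- function(model, genotypes) {
  missing <- setdiff(model$variants, colnames(genotypes))
  if (length(missing))
    stopf("project_pcs: %d model variants absent from input", length(missing))
  Z <- scale(genotypes[, model$variants, drop = FALSE],
             center = model$center, scale = model$scale)
  out <- Z %*% model$loadings
  rownames(out) <- rownames(genotypes)
  out
}

#' Cluster samples on top PCs
#'
#' k-means on PC coordinates with a fixed seed for determinism.
#'
#' @param coords PC coordinate matrix.
#' @param k Number of clusters.
#' @param seed RNG seed for the k-means initialization.
#' @return List with `cluster` (integer ids named by sample) and `centers`.
#' @export
assign_clusters <- function(coords, k, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- stats::kmeans(coords, centers = k, nstart = 10, iter.max = 100)
  list(cluster = stats::setNames(km$cluster, rownames(coords)),
       centers = km$centers)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Greedy nearest-neighbor control matching
#'
#' Matches external controls to cases in PC space: in each of `max_ratio`
#' rounds, every case (in lexicographic id order) claims its nearest
#' not-yet-used control within the caliper; ties break on control id. The
#' default caliper is 0.1 times the root-mean-square pairwise distance
#' among cases, a deliberately tight default that excludes controls from
#' populations unrepresented among cases.
#'
#' @param case_coords,control_coords PC coordinate matrices with sample id
#'   rownames (controls projected into the case-derived space).
#' @param max_ratio Maximum controls matched per case.
#' @param caliper Maximum matching distance; `NULL` for the default.
#' @param case_clusters Optional integer cluster ids for cases (named);
#'   matched controls inherit the cluster of the case that claimed them,
#'   and per-cluster counts are reported. Clusters that end up with zero
#'   matched controls are flagged with a warning.
#' @return Object of class `match_result`: `selected` control ids,
#'   `control_cluster`, `case_cluster`, per-cluster `counts`,
#'   `effective_n` and the `caliper` used.
#' @export
match_controls <- function(case_coords, control_coords, max_ratio = 4,
                           caliper = NULL, case_clusters = NULL) {
  if (is.null(dim(case_coords)) || nrow(case_coords) == 0)
    stopf("match_controls: empty case set")
  if (is.null(dim(control_coords)) || nrow(control_coords) == 0)
    stopf("match_controls: empty control set")
  d <- ncol(case_coords)
  stopifnot(ncol(control_coords) == d)
  if (is.null(caliper)) {
    # RMS pairwise distance among cases = sqrt(2 * sum of coordinate vars)
    v <- sum(apply(case_coords, 2, stats::var))
    caliper <- 0.1 * sqrt(2 * v)
  }
  case_ids <- rownames(case_coords) %||% sprintf("case%05d",
                                                 seq_len(nrow(case_coords)))
  ctrl_ids <- rownames(control_coords) %||%
    sprintf("ctrl%05d", seq_len(nrow(control_coords)))
  ord_case <- lex_order(case_ids)
  ord_ctrl <- lex_order(ctrl_ids)
  CC <- case_coords[ord_case, , drop = FALSE]
  KK <- control_coords[ord_ctrl, , drop = FALSE]
  case_ids <- case_ids[ord_case]
  ctrl_ids <- ctrl_ids[ord_ctrl]

  # full distance matrix; fine at the scales this package targets
  D <- outer(rowSums(CC^2), rowSums(KK^2), "+") - 2 * CC %*% t(KK)
  D <- sqrt(pmax(D, 0))
  D[D > caliper] <- Inf

  available <- rep(TRUE, length(ctrl_ids))
  matched_to <- integer(0)
  matched_ctrl <- integer(0)
  for (round in seq_len(max_ratio)) {
    for (i in seq_along(case_ids)) {
      cand <- D[i, ]
      cand[!available] <- Inf
      j <- which.min(cand)
      if (length(j) && is.finite(cand[j])) {
        available[j] <- FALSE
        matched_ctrl <- c(matched_ctrl, j)
        matched_to <- c(matched_to, i)
      }
    }
  }
  selected <- ctrl_ids[matched_ctrl]
  control_cluster <- NULL
  counts <- NULL
  if (!is.null(case_clusters)) {
    cl <- case_clusters[case_ids]
    control_cluster <- stats::setNames(cl[matched_to], selected)
    counts <- data.frame(cluster = sort(unique(cl)))
    counts$n_cases <- as.integer(table(factor(cl, counts$cluster)))
    counts$n_controls <- as.integer(table(factor(control_cluster,
                                                 counts$cluster)))
    empty <- counts$cluster[counts$n_controls == 0]
    if (length(empty))
      warnf("cluster(s) %s matched zero controls and should be dropped from stratified analyses",
            paste(empty, collapse = ", "))
  }
  structure(list(selected = selected,
                 case_ids = case_ids,
                 control_cluster = control_cluster,
                 case_cluster = if (!is.null(case_clusters))
                   stats::setNames(case_clusters[case_ids], case_ids),
                 counts = counts,
                 effective_n = effective_sample_size(length(case_ids),
                                                     max(1, length(selected))),
                 caliper = caliper),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d controls matched to %d cases (caliper %.3g)\n",
              length(x$selected), length(x$case_ids), x$caliper))
  cat(sprintf("effective sample size: %d\n", x$effective_n))
  if (!is.null(x$counts)) {
    cat("per-cluster counts:\n")
    print(x$counts, row.names = FALSE)
  }
  invisible(x)
}

#' Effective sample size of an unbalanced case-control design
#'
#' The count-equivalent `4 / (1/n_cases + 1/n_controls)`, i.e. the size of
#' a balanced study with the same power; reported rounded to the nearest
#' integer. Bounded above by `n_cases + n_controls`, with equality only
#' for a balanced design, and by `4 * min(n_cases, n_controls)` in the
#' extreme unbalanced limit.
#'
#' @param n_cases,n_controls Positive counts.
#' @return Integer effective sample size.
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  if (any(c(n_cases, n_controls) <= 0))
    stopf("effective_sample_size: counts must be positive")
  as.integer(round(4 / (1 / n_cases + 1 / n_controls)))
}
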