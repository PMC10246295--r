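make_blobs <- function(n_per = 60, k = 3, sep = 6, d = 2, seed = 9) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(k * d, sd = sep), k, d)
  coords <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(stats::rnorm(n_per * d, sd = 0.5), n_per, d), 2,
          centers[i, ], "+")))
  rownames(coords) <- sprintf("s%03d", seq_len(nrow(coords)))
  list(coords = coords, labels = rep(seq_len(k), each = n_per))
}

test_that("effective sample size reproduces the count-equivalent formula", {
  expect_identical(effective_sample_size(100, 100), 200L)
  expect_identical(effective_sample_size(3005, 9777), 9194L)
  expect_error(effective_sample_size(0, 10), "positive")
})

test_that("PCA separates simulated ancestry clusters and projection is consistent", {
  co <- tiny_cohort()
  case <- co$samples$status == 1
  Gc <- co$genotypes[case, , drop = FALSE]
  pruned <- ld_prune(Gc)
  pcs <- compute_pcs(Gc[, pruned, drop = FALSE], 2)
  # projecting the training samples must reproduce their own coordinates
  proj <- project_pcs(pcs, Gc)
  expect_equal(unname(proj), unname(pcs$coords), tolerance = 1e-8)
  # top-2 PC k-means must recover the generating clusters (3 clusters,
  # Fst 0.05 is strongly separated at this variant count)
  cl <- assign_clusters(pcs$coords, 3, seed = 2)
  truth <- co$samples$cluster[case]
  tab <- table(cl$cluster, truth)
  # each inferred cluster maps to one true cluster almost purely
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gt(purity, 0.95)
})

test_that("compute_pcs validates rank and determinism", {
  set.seed(3)
  G <- matrix(stats::rbinom(50 * 30, 2, 0.3), 50, 30)
  rownames(G) <- sprintf("s%02d", 1:50)
  colnames(G) <- sprintf("v%02d", 1:30)
  expect_error(compute_pcs(G[1:3, ], 5), "rank")
  a <- compute_pcs(G, 4)
  b <- compute_pcs(G, 4)
  expect_identical(a$coords, b$coords)
})

test_that("ld_prune removes duplicated and low-frequency variants", {
  set.seed(4)
  g1 <- stats::rbinom(200, 2, 0.3)
  g2 <- g1                              # perfect LD with g1
  g3 <- stats::rbinom(200, 2, 0.4)
  g4 <- stats::rbinom(200, 2, 0.005)    # too rare
  G <- cbind(a = g1, b = g2, c = g3, d = g4)
  kept <- ld_prune(G)
  expect_true("a" %in% kept)
  expect_false("b" %in% kept)
  expect_true("c" %in% kept)
  expect_false("d" %in% kept)
})

test_that("greedy matching respects the caliper, the ratio cap and uniqueness", {
  blobs <- make_blobs()
  cases <- blobs$coords[1:40, , drop = FALSE]
  ctrls <- blobs$coords[41:180, , drop = FALSE]
  res <- match_controls(cases, ctrls, max_ratio = 2, caliper = 1.5)
  expect_s3_class(res, "match_result")
  expect_lte(length(res$selected), 2 * nrow(cases))
  expect_false(any(duplicated(res$selected)))
  # every selected control lies within the caliper of at least one case
  d <- as.matrix(stats::dist(rbind(cases, ctrls[res$selected, ])))
  dsel <- d[seq_len(nrow(cases)), nrow(cases) + seq_along(res$selected)]
  expect_true(all(apply(dsel, 2, min) <= 1.5))
})

test_that("cases in a cluster with no nearby controls trigger the zero-control warning", {
  cases <- matrix(c(0, 0, 100, 100), 2, 2, byrow = TRUE,
                  dimnames = list(c("c1", "c2"), NULL))
  ctrls <- matrix(c(0.1, 0, 0.2, 0.1), 2, 2, byrow = TRUE,
                  dimnames = list(c("k1", "k2"), NULL))
  expect_warning(
    res <- match_controls(cases, ctrls, max_ratio = 1, caliper = 1,
                          case_clusters = c(c1 = 1L, c2 = 2L)),
    "zero controls")
  expect_identical(unname(res$control_cluster), 1L)
})

test_that("matching is invariant to input row order", {
  blobs <- make_blobs(seed = 12)
  cases <- blobs$coords[1:30, , drop = FALSE]
  ctrls <- blobs$coords[31:180, , drop = FALSE]
  a <- match_controls(cases, ctrls, max_ratio = 3, caliper = 2)
  perm <- sample(nrow(ctrls))
  b <- match_controls(cases, ctrls[perm, , drop = FALSE],
                      max_ratio = 3, caliper = 2)
  expect_identical(sort(a$selected), sort(b$selected))
})
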