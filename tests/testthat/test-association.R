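test_that("default masks are strictly nested in category and frequency", {
  masks <- default_masks()
  expect_length(masks, 7)
  expect_silent(check_masks(masks))
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i]]$categories %in% masks[[i + 1]]$categories))
    expect_lte(masks[[i]]$max_af, masks[[i + 1]]$max_af)
  }
  bad <- masks
  bad[[2]]$categories <- "synonymous"
  expect_error(check_masks(bad), "nest")
})

test_that("burden_collapse matches a hand computation and uses control-only AF", {
  G <- rbind(s1 = c(1L, 0L, 0L), s2 = c(0L, 2L, 0L), s3 = c(0L, 0L, 1L),
             s4 = c(0L, 0L, 0L))
  colnames(G) <- c("va", "vb", "vc")
  ann <- data.frame(variant_id = c("va", "vb", "vc"),
                    gene = "g1",
                    category = c("ptv", "missense_strict", "synonymous"))
  control_af <- c(va = 0.001, vb = 0.5, vc = 0.001)
  mask <- list(name = "m", categories = c("ptv", "missense_strict"),
               max_af = 0.01)
  coll <- burden_collapse(G, ann, mask, control_af)
  # vb fails the frequency ceiling, vc the category: only va qualifies
  expect_identical(coll$variants, "va")
  expect_identical(coll$carrier, c(1L, 0L, 0L, 0L))
  expect_equal(coll$combined_maf, 0.001)
  # a case-only variant (control AF zero) must still qualify
  control_af["va"] <- 0
  coll0 <- burden_collapse(G, ann, mask, control_af)
  expect_identical(coll0$variants, "va")
})

test_that("single_variant_test agrees with glm for a common variant", {
  set.seed(6)
  n <- 600
  g <- stats::rbinom(n, 2, 0.3)
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(-0.8 + 0.35 * g + 0.2 * x))
  G <- cbind(v1 = g, v2 = rep(0L, n))
  res <- single_variant_test(G, y, covariates = cbind(x = x))
  ref <- summary(stats::glm(y ~ x + g,
                            family = stats::binomial()))$coefficients
  expect_false(res$firth[1])
  expect_equal(res$beta[1], ref["g", 1], tolerance = 1e-5)
  expect_equal(res$p[1], ref["g", 4], tolerance = 1e-4)
  expect_identical(res$skip_reason[2], "monomorphic")
  expect_true(is.na(res$p[2]))
})

test_that("rare exposures engage Firth penalization", {
  set.seed(8)
  n <- 800
  g <- as.integer(stats::rbinom(n, 1, 0.01))
  y <- stats::rbinom(n, 1, stats::plogis(-1 + 1.5 * g))
  res <- single_variant_test(cbind(v = g), y)
  expect_true(res$firth[1])
  expect_true(is.finite(res$beta[1]) && is.finite(res$p[1]))
})

test_that("mask carrier sets are nested for every gene in a simulated cohort", {
  co <- tiny_cohort()
  masks <- default_masks()
  control_af <- colMeans(co$genotypes[co$samples$status == 0, ,
                                      drop = FALSE]) / 2
  genes <- setdiff(unique(co$annotations$gene), "BACKGROUND")
  for (gene in genes) {
    prev <- NULL
    for (m in masks) {
      cur <- burden_collapse(co$genotypes, co$annotations, m, control_af,
                             gene = gene)$carrier
      if (!is.null(prev)) expect_true(all(cur >= prev))
      prev <- cur
    }
  }
})

test_that("corrected P obeys its analytic bounds and mask accounting", {
  co <- tiny_cohort()
  covars <- cluster_covariates(co$samples)
  genes <- grep("^RG|^NG0[0-5]", unique(co$annotations$gene), value = TRUE)
  res <- gene_burden_test(co$genotypes, co$annotations,
                          co$samples$status, genes = genes,
                          covariates = covars)
  expect_gt(nrow(res), 5)
  expect_true(all(res$corrected_p >= res$min_p - 1e-12))
  expect_true(all(res$corrected_p <=
                    pmin(1, res$n_eff * res$min_p) + 1e-12))
  expect_true(all(res$n_eff >= 1 & res$n_eff <= res$n_masks_tested))
  # planted genes should collectively outrank the null genes
  is_rg <- grepl("^RG", res$gene)
  expect_lt(min(res$corrected_p[is_rg]),
            stats::median(res$corrected_p[!is_rg]))
  expect_lt(min(res$corrected_p[is_rg]), 0.05)
})

test_that("identical masks cost nothing: Neff 1 and corrected == min P", {
  set.seed(10)
  n <- 400
  g <- as.integer(stats::rbinom(n, 1, 0.05))
  y <- stats::rbinom(n, 1, stats::plogis(-1 + 0.9 * g))
  G <- cbind(v1 = g)
  ann <- data.frame(variant_id = "v1", gene = "gX", category = "ptv")
  masks <- list(list(name = "m1", categories = "ptv", max_af = 0.5),
                list(name = "m2", categories = c("ptv", "missense_strict"),
                     max_af = 0.5))
  res <- gene_burden_test(G, ann, y, masks = masks)
  expect_identical(res$n_eff, 1L)
  expect_equal(res$corrected_p, res$min_p)
})

test_that("corrected P tracks a permutation min-P oracle on a null gene", {
  co <- null_cohort()
  status <- co$samples$status
  n <- length(status)
  masks <- default_masks()
  control_af <- colMeans(co$genotypes[status == 0, , drop = FALSE]) / 2
  gene <- "NG001"
  res <- gene_burden_test(co$genotypes, co$annotations, status,
                          genes = gene, test = "wald")
  carrier <- vapply(masks, function(m)
    burden_collapse(co$genotypes, co$annotations, m, control_af,
                    gene = gene)$carrier, integer(n))
  counts <- colSums(carrier)
  ok <- counts > 0 & counts < n
  carrier <- carrier[, ok, drop = FALSE]
  # permutation oracle on the chi-square scale: both observed and permuted
  # min P use the same 2x2 statistic, so the comparison isolates the
  # effective-number-of-tests correction
  set.seed(99)
  n_case <- sum(status)
  obs_a <- drop(crossprod(carrier, status))
  obs_min <- min(chisq_p_2x2(obs_a, n_case, colSums(carrier), n))
  B <- 4000
  perm_status <- replicate(B, sample(status))
  A <- crossprod(carrier, perm_status)          # masks x B carrier cases
  Pm <- chisq_p_2x2(A, n_case, colSums(carrier), n)
  perm_min <- apply(Pm, 2, min)
  emp <- mean(perm_min <= obs_min)
  corrected <- 1 - (1 - obs_min)^res$n_eff
  expect_gt(emp, 0.001)
  ratio <- corrected / emp
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("inflation diagnostics are calibrated on uniform P-values", {
  set.seed(11)
  p <- stats::runif(20000)
  d <- inflation_diagnostics(p)
  expect_equal(d$lambda, 1, tolerance = 0.03)
  expect_equal(nrow(d$qq) > 10, TRUE)
  expect_warning(inflation_diagnostics(stats::runif(20)), "unstable")
})
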