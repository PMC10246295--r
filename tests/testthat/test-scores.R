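make_score_fixture <- function() {
  ids <- sprintf("s%02d", 1:6)
  rare <- cbind(gA = c(1, 0, 1, 0, 0, 0), gB = c(0, 1, 0, 0, 0, 0))
  rownames(rare) <- ids
  common <- cbind(v1 = c(0, 1, 2, 0, 1, 0), v2 = c(2, 0, 1, 0, 0, 0))
  rownames(common) <- ids
  weights <- data.frame(unit = c("gA", "gB", "v1", "v2"),
                        log_or = c(log(4), log(2), log(1.3), log(1.2)),
                        source = c("rare", "rare", "common", "common"))
  list(rare = rare, common = common, weights = weights, ids = ids)
}

test_that("contribution scores are additive in carried log odds ratios", {
  fx <- make_score_fixture()
  sc <- compute_scores(fx$rare, fx$common, fx$weights)
  expect_s3_class(sc, "contribution_scores")
  manual_rare <- drop(fx$rare %*% c(log(4), log(2)))
  manual_common <- drop(fx$common %*% c(log(1.3), log(1.2)))
  expect_equal(sc$rare_log_or, unname(manual_rare))
  expect_equal(sc$common_log_or, unname(manual_common))
  expect_equal(sc$combined_log_or, sc$rare_log_or + sc$common_log_or)
  expect_equal(sc$combined_or, exp(sc$combined_log_or))
})

test_that("weights referencing absent units are skipped with a message", {
  fx <- make_score_fixture()
  w <- rbind(fx$weights, data.frame(unit = "ghost", log_or = 1,
                                    source = "rare"))
  expect_message(sc <- compute_scores(fx$rare, fx$common, w), "ghost")
  base <- compute_scores(fx$rare, fx$common, fx$weights)
  expect_equal(sc$combined_log_or, base$combined_log_or)
  expect_error(compute_scores(fx$rare, fx$common,
                              transform(fx$weights, log_or = NA)),
               "finite")
})

test_that("bands partition the cohort with the documented precedence", {
  fx <- make_score_fixture()
  sc <- compute_scores(fx$rare, fx$common, fx$weights)
  flags <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  banded <- assign_bands(sc, flags, thresholds = c(5, 3))
  # every sample gets exactly one band
  expect_false(any(is.na(banded$band)))
  expect_identical(as.character(banded$band[1]), "MODY")
  # s3 carries gA (OR 4) and common OR 1.3^2*1.2 = 2.03 -> combined > 5
  expect_identical(as.character(banded$band[3]), "combined_ge5")
  # s4 carries nothing
  expect_identical(as.character(banded$band[4]), "none")
  # precedence: a sample with rare OR >= 5 is rare_ge5 even if combined also >= 5
  sc2 <- sc
  sc2$rare_or[2] <- 6; sc2$rare_log_or[2] <- log(6)
  sc2$combined_log_or[2] <- log(6) + sc2$common_log_or[2]
  sc2$combined_or[2] <- exp(sc2$combined_log_or[2])
  banded2 <- assign_bands(sc2, rep(FALSE, 6))
  expect_identical(as.character(banded2$band[2]), "rare_ge5")
  expect_error(assign_bands(sc, flags, thresholds = c(3, 5)),
               "descending")
})

test_that("rare fraction trend detects a planted gradient", {
  n <- 400
  combined <- seq(log(40), log(3.1), length.out = n)
  frac <- seq(0.9, 0.1, length.out = n)   # rare share falls with rank
  sc <- data.frame(sample_id = sprintf("s%03d", 1:n),
                   rare_log_or = combined * frac,
                   common_log_or = combined * (1 - frac),
                   combined_log_or = combined)
  sc$rare_or <- exp(sc$rare_log_or)
  sc$common_or <- exp(sc$common_log_or)
  sc$combined_or <- exp(sc$combined_log_or)
  tr <- rare_fraction_trend(sc, bin_size = 40, min_combined_or = 3)
  expect_equal(tr$spearman_rho, -1)
  expect_lt(tr$spearman_p, 0.01)
  expect_equal(sum(tr$bins$n), n)
})

test_that("phenotype regression recovers a planted linear effect", {
  set.seed(40)
  n <- 800
  score <- stats::rnorm(n)
  ph <- data.frame(status = 1L,
                   sex = stats::rbinom(n, 1, 0.5),
                   cluster = sample(1:3, n, replace = TRUE))
  ph$age_at_diagnosis <- 13.6 - 0.4 * scale(score)[, 1] +
    stats::rnorm(n, 0, 1)
  ph$bmi_z <- 2.2 + stats::rnorm(n, 0, 0.5)
  ph$c_peptide <- 10^(0.55 + 0.1 * scale(score)[, 1] +
                        stats::rnorm(n, 0, 0.2))
  res <- phenotype_regression(score, ph, flags = rep(FALSE, n))
  age <- res[res$phenotype == "age_at_diagnosis", ]
  expect_lt(abs(age$beta - (-0.4)), 3 * age$se)
  cp <- res[res$phenotype == "log10_c_peptide", ]
  expect_lt(abs(cp$beta - 0.1), 3 * cp$se)
  bmi <- res[res$phenotype == "bmi_z", ]
  expect_gt(bmi$p, 0.001)  # no planted effect
  expect_error(phenotype_regression(rep(1, n), ph), "variance")
})

test_that("MODY flags, phenotype contrasts and leave-out tests work end to end", {
  co <- tiny_cohort()
  flags <- mody_flag(co$genotypes, co$annotations, co$mody_genes)
  vids <- co$annotations$variant_id[co$annotations$pathogenic_flag == 1]
  expect_identical(unname(flags),
                   unname(rowSums(co$genotypes[, vids, drop = FALSE]) > 0))
  expect_error(mody_flag(co$genotypes, co$annotations, character()),
               "registry")

  cmp <- mody_phenotype_comparison(co$samples, flags)
  expect_identical(cmp$phenotype,
                   c("age_at_diagnosis", "bmi_z", "log10_c_peptide"))
  # planted shifts are negative for all three phenotypes
  if (all(cmp$n_carrier >= 5)) {
    expect_lt(cmp$diff[1], 1)   # wide-noise contrast: sign not enforced
    expect_true(all(is.finite(cmp$p)))
  }

  # leave-out: dropping flagged carriers removes a purely monogenic signal
  status <- co$samples$status
  covars <- cluster_covariates(co$samples)
  full <- gene_burden_test(co$genotypes, co$annotations, status,
                           genes = co$mody_genes, covariates = covars)
  reduced <- mody_leave_out_test(co$genotypes, co$annotations, status,
                                 flags, genes = co$mody_genes,
                                 covariates = covars)
  # with every carrier removed the gene is untestable (omitted) or null
  if (nrow(reduced) > 0) {
    expect_true(all(reduced$min_p > 0.01 | is.na(reduced$min_p)))
  } else {
    expect_true(all(co$mody_genes %in% attr(reduced, "omitted")))
  }
  expect_true(any(full$corrected_p < 0.05))
})
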