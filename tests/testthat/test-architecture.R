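test_that("liability model threshold matches the normal quantile", {
  m <- liability_model(0.01)
  expect_equal(m$t, stats::qnorm(0.99))
  expect_equal(m$K, 0.01)
  expect_error(liability_model(0), "prevalence")
})

test_that("winner's-curse correction matches a dense grid search", {
  for (case in list(c(b = 0.40, se = 0.10, zc = 1.96),
                    c(b = 0.25, se = 0.12, zc = 1.96),
                    c(b = 0.80, se = 0.15, zc = 3.0))) {
    b <- case["b"]; se <- case["se"]; zc <- case["zc"]
    est <- winners_curse_correct(b, se, zc)
    grid <- seq(0, b, length.out = 40001)
    ll <- stats::dnorm((b - grid) / se, log = TRUE) -
      log(stats::pnorm(-zc - grid / se) + stats::pnorm(grid / se - zc))
    best <- grid[which.max(ll)]
    expect_lt(abs(est - best), 1e-3)
    expect_lte(est, b)
  }
})

test_that("winner's-curse correction is an identity without selection and errors below threshold", {
  expect_equal(winners_curse_correct(0.3, 0.1, 0), 0.3)
  expect_error(winners_curse_correct(0.1, 0.1, 1.96), "threshold")
  # negative estimates are handled by sign symmetry
  expect_equal(winners_curse_correct(-0.4, 0.1, 1.96),
               -winners_curse_correct(0.4, 0.1, 1.96))
})

test_that("variant_lve matches a threshold-model simulation", {
  model <- liability_model(0.02)
  beta <- log(2.5)
  freq <- 0.01
  lve <- variant_lve(beta, freq, model)
  # independent construction: solve the per-genotype penetrances from
  # (OR, freq, K) with a plain bisection, build the liability group means,
  # and simulate the threshold model
  K <- 0.02
  w <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  pen <- function(l0) stats::plogis(l0 + (0:2) * beta)
  lo <- -30; hi <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sum(w * pen(mid)) < K) lo <- mid else hi <- mid
  }
  f <- pen((lo + hi) / 2)
  mu <- model$t - stats::qnorm(1 - f)
  set.seed(30)
  n <- 2e6
  g <- stats::rbinom(n, 2, freq)
  liab <- mu[g + 1] + stats::rnorm(n)
  disease <- liab > model$t
  expect_equal(mean(disease), K, tolerance = 0.05)
  # empirical per-allele odds ratio recovers the input OR
  a1 <- mean(disease[g == 1]); a0 <- mean(disease[g == 0])
  expect_equal((a1 / (1 - a1)) / (a0 / (1 - a0)), 2.5, tolerance = 0.1)
  # empirical variance decomposition of the simulated liability
  emp_lve <- stats::var(mu[g + 1]) / stats::var(liab)
  expect_equal(lve, emp_lve, tolerance = 0.1)
})

test_that("aggregate_lve sums unit contributions and bootstraps a CI", {
  model <- liability_model(0.01)
  units <- data.frame(unit = c("a", "b"), beta = c(0.6, 0.3),
                      se = c(0.1, 0.08), freq = c(0.005, 0.02))
  est <- aggregate_lve(units, model, n_bootstrap = 300)
  expect_s3_class(est, "lve_estimate")
  expect_equal(est$lve, sum(est$per_unit$lve))
  expect_true(est$ci[1] < est$lve && est$lve < est$ci[2])
  # no selection means no correction
  expect_equal(est$per_unit$beta_corrected, units$beta)
  est0 <- aggregate_lve(units, model, n_bootstrap = 0)
  expect_true(all(is.na(est0$ci)))
  expect_output(print(est), "liability variance explained")
})

test_that("overlap correlation has the right limits and symmetry", {
  s <- list(n_cases = 500, n_controls = 1500)
  expect_equal(overlap_correlation(s, s, 0), 0)
  expect_equal(overlap_correlation(s, s, 1500, 500), 1, tolerance = 1e-12)
  r1 <- overlap_correlation(s, list(n_cases = 300, n_controls = 900), 400)
  r2 <- overlap_correlation(list(n_cases = 300, n_controls = 900), s, 400)
  expect_equal(r1, r2)
  expect_error(overlap_correlation(s, s, 2000), "shared")
})

test_that("overlap correlation matches the simulation oracle", {
  s1 <- list(n_cases = 600, n_controls = 600)
  s2 <- list(n_cases = 600, n_controls = 600)
  r_formula <- overlap_correlation(s1, s2, 300)
  set.seed(31)
  r_sim <- simulate_overlap_correlation(s1, s2, 300, beta = 0.15,
                                        freq = 0.3, n_reps = 300)
  expect_lt(abs(r_formula - r_sim), 0.08)
})

test_that("exceedance expectations behave at the boundaries", {
  set.seed(32)
  e <- expected_exceedance_frequency(0.4, 0.05, 0.05, r = 0, z_c = 0,
                                     n_sims = 20000)
  expect_gt(e["frac_same_direction"], 0.99)
  expect_equal(unname(e["frac_larger_in_study1"]), 0.5, tolerance = 0.02)
  # selection without correction would bias this far below 0.5; with the
  # correction it should stay in a moderate band
  e2 <- expected_exceedance_frequency(0.2, 0.08, 0.08, r = 0, z_c = 1.96,
                                      n_sims = 20000)
  expect_gt(unname(e2["frac_larger_in_study1"]), 0.35)
})

test_that("binomial enrichment test matches pbinom", {
  expect_equal(binomial_enrichment_test(21, 27, 0.5),
               stats::pbinom(20, 27, 0.5, lower.tail = FALSE))
  expect_error(binomial_enrichment_test(30, 27, 0.5), "observed")
})

test_that("compare_architectures recovers a planted fold", {
  model <- liability_model(0.01)
  units1 <- data.frame(unit = sprintf("u%d", 1:5),
                       beta = c(0.9, 0.8, 0.7, 0.6, 0.5),
                       se = rep(0.02, 5), freq = rep(0.004, 5))
  units2 <- units1
  units2$beta <- units2$beta * 0.5
  cmp <- compare_architectures(units1, units2, model, model,
                               n_bootstrap = 300)
  true_fold <- sum(vapply(units1$beta, variant_lve, 0, freq = 0.004,
                          model = model)) /
    sum(vapply(units2$beta, variant_lve, 0, freq = 0.004, model = model))
  expect_equal(cmp$fold, true_fold, tolerance = 1e-8)
  expect_true(cmp$fold_ci[1] <= true_fold && true_fold <= cmp$fold_ci[2])
})
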