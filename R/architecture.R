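# Liability-scale variance explained, winner's-curse correction, and
# shared-control-aware cross-study comparison.

#' Liability threshold model
#'
#' @param prevalence Disease prevalence K in (0, 0.5).
#' @return List of class `liability_model` with `K` and the liability
#'   threshold `t = qnorm(1 - K)`.
#' @export
liability_model <- function(prevalence) {
  check_fraction(prevalence, "prevalence", 0, 0.5)
  structure(list(K = prevalence, t = stats::qnorm(1 - prevalence)),
            class = "liability_model")
}

#' Winner's-curse correction by conditional maximum likelihood
#'
#' An effect estimate that was selected for passing a discovery
#' significance threshold is biased away from zero. The corrected estimate
#' is the effect size maximizing the likelihood of the observed estimate
#' under Normal(beta, se^2) truncated to the selection region
#' `|estimate| / se > z_c`, searched between zero and the observed estimate
#' (shrinkage without sign flip). With `z_c = 0` (no selection) the
#' estimate is returned unchanged; the corrected magnitude never exceeds
#' the observed one.
#'
#' @param beta_hat Observed log odds ratio.
#' @param se Standard error (> 0).
#' @param z_c Selection Z threshold used at discovery (>= 0).
#' @return Corrected log odds ratio.
#' @export
winners_curse_correct <- function(beta_hat, se, z_c) {
  if (se <= 0) stopf("se must be positive")
  if (z_c < 0) stopf("z_c must be >= 0")
  if (z_c == 0) return(beta_hat)
  if (abs(beta_hat) / se < z_c)
    stopf("unit did not pass the discovery threshold (|z| = %.2f < %.2f); pass z_c = 0 for unselected units",
          abs(beta_hat) / se, z_c)
  if (beta_hat == 0) return(0)
  s <- sign(beta_hat)
  b <- abs(beta_hat)
  nll <- function(beta) {
    # log density of the truncated sampling distribution
    log_tail <- log(stats::pnorm(-z_c - beta / se) +
                      stats::pnorm(beta / se - z_c))
    -(stats::dnorm((b - beta) / se, log = TRUE) - log_tail)
  }
  opt <- stats::optimize(nll, interval = c(0, b), tol = 1e-9)
  s * opt$minimum
}

#' Liability variance explained by one variant or gene burden
#'
#' Converts an odds ratio and risk-allele (or carrier pseudo-allele)
#' frequency into the fraction of liability variance explained under a
#' liability threshold model: genotype frequencies follow Hardy-Weinberg;
#' per-genotype penetrances solve `odds(f_g) = OR^g * odds(f_0)` subject to
#' the population prevalence; each genotype's mean liability is
#' `t - qnorm(1 - f_g)`; and LVE is the between-genotype variance of these
#' means over the total liability variance (between + unit residual).
#'
#' @param beta Log odds ratio per allele (gene burdens enter as carrier
#'   pseudo-variants at their combined MAF).
#' @param freq Risk-allele frequency in (0, 1).
#' @param model A [liability_model()].
#' @return Fraction of liability variance in `[0, 1)`.
#' @export
variant_lve <- function(beta, freq, model) {
  stopifnot(inherits(model, "liability_model"))
  check_fraction(freq, "freq", 0, 1)
  if (beta == 0) return(0)
  K <- model$K
  w <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  pen_at <- function(logit_f0)
    stats::plogis(logit_f0 + (0:2) * beta)
  eq <- function(logit_f0) sum(w * pen_at(logit_f0)) - K
  root <- tryCatch(
    stats::uniroot(eq, c(stats::qlogis(1e-12), stats::qlogis(1 - 1e-12)),
                   tol = 1e-12),
    error = function(e)
      stopf("no feasible penetrance solution for OR = %.3g at K = %.3g",
            exp(beta), K))
  f <- pen_at(root$root)
  if (any(f >= 1 - 1e-12))
    stopf("penetrance saturates (f_%d >= 1) for OR = %.3g at K = %.3g",
          which(f >= 1 - 1e-12)[1] - 1, exp(beta), K)
  mu <- model$t - stats::qnorm(1 - f)
  mbar <- sum(w * mu)
  v <- sum(w * (mu - mbar)^2)
  v / (v + 1)
}

#' Aggregate liability variance explained with bootstrap CI
#'
#' Sums per-unit LVE over a list of association summaries (independence of
#' units assumed), after winner's-curse correcting every unit that was
#' subject to discovery selection. The confidence interval is a percentile
#' bootstrap: each draw resamples every unit's estimate from
#' Normal(corrected beta, se^2), re-applies the correction (when the draw
#' passes the unit's selection threshold), and re-sums.
#'
#' @param units Data frame with `beta`, `se`, `freq` and optionally `z_c`
#'   (default 0 = no selection).
#' @param model A [liability_model()].
#' @param n_bootstrap Bootstrap draws (default 1000; 0 skips the CI).
#' @param conf Confidence level.
#' @return List of class `lve_estimate`: `lve` (point estimate), `ci`,
#'   `per_unit` (data frame with corrected betas and unit LVEs),
#'   `n_bootstrap`.
#' @export
aggregate_lve <- function(units, model, n_bootstrap = 1000, conf = 0.95) {
  if (is.null(units) || nrow(units) == 0)
    return(structure(list(lve = 0, ci = c(0, 0), per_unit = units,
                          n_bootstrap = n_bootstrap),
                     class = "lve_estimate"))
  stopifnot(all(c("beta", "se", "freq") %in% names(units)))
  if (is.null(units$z_c)) units$z_c <- 0
  correct1 <- function(b, se, zc)
    if (zc > 0 && abs(b) / se >= zc) winners_curse_correct(b, se, zc) else b
  units$beta_corrected <- mapply(correct1, units$beta, units$se, units$z_c)
  units$lve <- mapply(function(b, f) variant_lve(b, f, model),
                      units$beta_corrected, units$freq)
  point <- sum(units$lve)
  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0) {
    draws <- vapply(seq_len(n_bootstrap), function(i) {
      b_star <- stats::rnorm(nrow(units), units$beta_corrected, units$se)
      b_corr <- mapply(correct1, b_star, units$se, units$z_c)
      sum(mapply(function(b, f) variant_lve(b, f, model), b_corr,
                 units$freq))
    }, 0)
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(draws, c(a, 1 - a)))
  }
  structure(list(lve = point, ci = ci, per_unit = units,
                 n_bootstrap = n_bootstrap),
            class = "lve_estimate")
}

#' @export
print.lve_estimate <- function(x, ...) {
  cat(sprintf("liability variance explained: %.4f", x$lve))
  if (!any(is.na(x$ci)))
    cat(sprintf(" (95%% CI %.4f-%.4f, %d bootstrap draws)",
                x$ci[1], x$ci[2], x$n_bootstrap))
  cat(sprintf("\n%d units\n", nrow(x$per_unit) %||% 0))
  invisible(x)
}

#' Correlation of effect estimates between studies sharing controls
#'
#' Two case-control studies that reuse controls produce correlated effect
#' estimates for the same unit. Under standard asymptotics the correlation
#' from `n_shared` shared controls (and optionally shared cases) is
#' \deqn{r = [n^{sh}_{ctrl} \sqrt{n_{1c} n_{2c} / (n_{1k} n_{2k})} +
#'            n^{sh}_{case} \sqrt{n_{1k} n_{2k} / (n_{1c} n_{2c})}] /
#'           \sqrt{N_1 N_2}}
#' with \eqn{N_i} the total sample size of study i. The closed form is
#' validated against an overlapping-cohort simulation oracle; see
#' [simulate_overlap_correlation()].
#'
#' @param study1,study2 Lists or vectors with `n_cases` and `n_controls`.
#' @param n_shared_controls Number of controls present in both studies.
#' @param n_shared_cases Number of shared cases (default 0).
#' @return Correlation in `[0, 1]`.
#' @export
overlap_correlation <- function(study1, study2, n_shared_controls,
                                n_shared_cases = 0) {
  s1 <- as.list(study1); s2 <- as.list(study2)
  n1c <- s1$n_cases; n1k <- s1$n_controls
  n2c <- s2$n_cases; n2k <- s2$n_controls
  if (any(c(n1c, n1k, n2c, n2k) <= 0)) stopf("counts must be positive")
  if (n_shared_controls > min(n1k, n2k) || n_shared_controls < 0)
    stopf("shared controls must lie in [0, min(control counts)]")
  if (n_shared_cases > min(n1c, n2c) || n_shared_cases < 0)
    stopf("shared cases must lie in [0, min(case counts)]")
  num <- n_shared_controls * sqrt((n1c * n2c) / (n1k * n2k)) +
    n_shared_cases * sqrt((n1k * n2k) / (n1c * n2c))
  r <- num / sqrt((n1c + n1k) * (n2c + n2k))
  min(max(r, 0), 1)
}

#' Simulation oracle for the shared-control correlation
#'
#' Simulates pairs of overlapping case-control studies with a shared true
#' log odds ratio, estimates the effect in each by logistic regression,
#' and returns the empirical correlation of the two estimates across
#' replicates. Used to validate [overlap_correlation()].
#'
#' @param study1,study2 Lists with `n_cases`, `n_controls`.
#' @param n_shared_controls Shared control count.
#' @param beta True log odds ratio.
#' @param freq Risk-allele frequency.
#' @param n_reps Number of simulated study pairs.
#' @param prevalence Population prevalence used to set the intercept.
#' @param n_variants Independent variants simulated per replicate. Each
#'   variant contributes an independent estimate pair, so the Monte Carlo
#'   standard error of the returned correlation scales with
#'   `1 / sqrt(n_reps * n_variants)`; raise this when the correlation must
#'   be pinned down more tightly than the replicate count alone allows.
#' @return Empirical correlation, pooled over replicates and variants.
#' @export
simulate_overlap_correlation <- function(study1, study2, n_shared_controls,
                                         beta = 0.1, freq = 0.3,
                                         n_reps = 500, prevalence = 0.05,
                                         n_variants = 1) {
  s1 <- as.list(study1); s2 <- as.list(study2)
  alpha <- stats::qlogis(prevalence) - 2 * freq * beta
  draw_group <- function(n, case) {
    # retrospective sampling: genotype | status
    g <- 0:2
    pg <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
    pcase <- stats::plogis(alpha + beta * g)
    w <- if (case) pg * pcase else pg * (1 - pcase)
    sample(g, n, replace = TRUE, prob = w / sum(w))
  }
  est <- function(g_case, g_ctrl) {
    y <- c(rep(1, length(g_case)), rep(0, length(g_ctrl)))
    g <- c(g_case, g_ctrl)
    fit <- logistic_fit(cbind(1, g), y)
    fit$coef[2]
  }
  b1 <- b2 <- matrix(0, n_reps, n_variants)
  for (i in seq_len(n_reps)) {
    for (v in seq_len(n_variants)) {
      shared <- draw_group(n_shared_controls, case = FALSE)
      k1 <- c(shared, draw_group(s1$n_controls - n_shared_controls, FALSE))
      k2 <- c(shared, draw_group(s2$n_controls - n_shared_controls, FALSE))
      b1[i, v] <- est(draw_group(s1$n_cases, TRUE), k1)
      b2[i, v] <- est(draw_group(s2$n_cases, TRUE), k2)
    }
  }
  stats::cor(as.vector(b1), as.vector(b2))
}

# cached grid interpolator for the winner's-curse correction at fixed
# (se, z_c): corrected beta as a smooth function of the observed estimate
wc_grid_fun <- function(se, z_c, b_max, n_grid = 400) {
  if (z_c == 0) return(identity)
  lo <- z_c * se
  hi <- max(b_max, lo * 1.001)
  xs <- seq(lo, hi, length.out = n_grid)
  ys <- vapply(xs, function(b) winners_curse_correct(b, se, z_c), 0)
  function(b) {
    s <- sign(b)
    ab <- pmin(pmax(abs(b), lo), hi)
    s * stats::approx(xs, ys, ab)$y
  }
}

#' Expected direction and magnitude exceedance between two studies
#'
#' Monte-Carlo expectation, under a shared true effect, of (a) the
#' fraction of estimate pairs with the same direction and (b) the fraction
#' in which study 1's estimate magnitude exceeds study 2's
#' winner's-curse-corrected magnitude. Pairs are drawn from a bivariate
#' normal with correlation `r` (shared controls); study-2 draws are
#' conditioned on passing its discovery threshold `z_c`, and are corrected
#' by conditional maximum likelihood before the comparison. These expected
#' fractions are the natural null frequencies for
#' [binomial_enrichment_test()].
#'
#' @param true_beta Shared true log odds ratio.
#' @param se1,se2 Standard errors in studies 1 and 2.
#' @param r Correlation between the estimates (see
#'   [overlap_correlation()]).
#' @param z_c Discovery selection threshold applied in study 2.
#' @param n_sims Monte-Carlo draws (values below 1000 trigger a warning).
#' @return Named vector: `frac_same_direction`, `frac_larger_in_study1`.
#' @export
expected_exceedance_frequency <- function(true_beta, se1, se2, r = 0,
                                          z_c = 0, n_sims = 20000) {
  if (se1 <= 0 || se2 <= 0) stopf("SEs must be positive")
  if (n_sims < 1000)
    warnf("n_sims < 1000; exceedance expectations will be noisy")
  z1 <- stats::rnorm(n_sims)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_sims)
  b1 <- true_beta + se1 * z1
  b2 <- true_beta + se2 * z2
  keep <- abs(b2) / se2 > z_c
  if (!any(keep)) stopf("no draws pass the study-2 selection threshold")
  b1 <- b1[keep]
  b2 <- b2[keep]
  b2c <- if (z_c > 0) {
    f <- wc_grid_fun(se2, z_c, max(abs(b2)))
    f(b2)
  } else b2
  c(frac_same_direction = mean(sign(b1) == sign(b2)),
    frac_larger_in_study1 = mean(abs(b1) > abs(b2c)))
}

#' Exact one-sided binomial enrichment test
#'
#' Tail probability of observing at least `observed` successes in `n`
#' trials at the expected success fraction.
#'
#' @param observed Observed success count.
#' @param n Number of trials.
#' @param expected Expected success probability.
#' @return One-sided P-value `P(X >= observed)`.
#' @export
binomial_enrichment_test <- function(observed, n, expected) {
  n <- check_count(n, "n")
  if (observed < 0 || observed > n)
    stopf("observed must lie in [0, n]")
  check_fraction(expected, "expected", 0, 1)
  stats::pbinom(observed - 1, n, expected, lower.tail = FALSE)
}

#' Cross-study comparison of liability variance explained
#'
#' Aggregates LVE in two studies (e.g. an early-onset and an adult-onset
#' study of the same disease at different prevalences) and reports the
#' fold change with a joint percentile bootstrap that propagates the
#' winner's-curse re-correction and, for units present in both studies,
#' the correlation of their estimates induced by shared controls.
#'
#' @param units1,units2 Association-summary data frames (`unit`, `beta`,
#'   `se`, `freq`, optional `z_c`).
#' @param model1,model2 [liability_model()] objects for the two studies.
#' @param overlap_r Correlation between the two studies' estimates of the
#'   same unit (0 = independent; see [overlap_correlation()]).
#' @param n_bootstrap Bootstrap draws.
#' @param conf Confidence level.
#' @return List: `lve1`, `lve2` (see [aggregate_lve()]), `fold`
#'   (lve1/lve2), `fold_ci`.
#' @export
compare_architectures <- function(units1, units2, model1, model2,
                                  overlap_r = 0, n_bootstrap = 1000,
                                  conf = 0.95) {
  e1 <- aggregate_lve(units1, model1, n_bootstrap = 0)
  e2 <- aggregate_lve(units2, model2, n_bootstrap = 0)
  u1 <- e1$per_unit
  u2 <- e2$per_unit
  shared <- if (!is.null(units1$unit) && !is.null(units2$unit))
    intersect(units1$unit, units2$unit) else character()
  correct1 <- function(b, se, zc)
    if (zc > 0 && abs(b) / se >= zc) winners_curse_correct(b, se, zc) else b
  folds <- l1 <- l2 <- numeric(n_bootstrap)
  for (i in seq_len(n_bootstrap)) {
    z1 <- stats::rnorm(nrow(u1))
    z2 <- stats::rnorm(nrow(u2))
    if (length(shared) && overlap_r > 0) {
      i1 <- match(shared, u1$unit)
      i2 <- match(shared, u2$unit)
      z2[i2] <- overlap_r * z1[i1] + sqrt(1 - overlap_r^2) * z2[i2]
    }
    b1 <- mapply(correct1, u1$beta_corrected + u1$se * z1, u1$se, u1$z_c)
    b2 <- mapply(correct1, u2$beta_corrected + u2$se * z2, u2$se, u2$z_c)
    l1[i] <- sum(mapply(function(b, f) variant_lve(b, f, model1), b1,
                        u1$freq))
    l2[i] <- sum(mapply(function(b, f) variant_lve(b, f, model2), b2,
                        u2$freq))
    folds[i] <- l1[i] / max(l2[i], 1e-12)
  }
  a <- (1 - conf) / 2
  list(lve1 = e1, lve2 = e2,
       lve1_ci = unname(stats::quantile(l1, c(a, 1 - a))),
       lve2_ci = unname(stats::quantile(l2, c(a, 1 - a))),
       fold = e1$lve / max(e2$lve, 1e-12),
       fold_ci = unname(stats::quantile(folds, c(a, 1 - a))))
}
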