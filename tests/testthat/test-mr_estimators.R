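test_that("Wald ratio arithmetic and error cases", {
  w <- wald_ratio(0.1, 0.05, 0.02)
  expect_equal(w$ratio, 0.5)
  expect_equal(w$se_ratio, 0.2)
  expect_equal(wald_ratio(0.1, 0, 0.02)$ratio, 0)
  # sign handling: negative exposure effect flips the ratio, not the se
  wn <- wald_ratio(-0.1, 0.05, 0.02)
  expect_equal(wn$ratio, -0.5)
  expect_equal(wn$se_ratio, 0.2)
  expect_error(wald_ratio(0, 0.05, 0.02), "beta_exp")
})

test_that("IVW reproduces the hand-computed two-SNP worked example", {
  h <- hset_from_ratios(c(0.5, 1.0), c(0.1, 0.2))
  e <- mr_ivw(h, model = "fixed")
  # weights {100, 25}: beta = (100*0.5 + 25*1)/125 = 0.6, se = 1/sqrt(125)
  expect_equal(e$beta, 0.6, tolerance = 1e-12)
  expect_equal(e$se, 1 / sqrt(125), tolerance = 1e-12)
  expect_equal(e$q_stat, 5, tolerance = 1e-12)
  expect_equal(e$q_df, 1L)
  expect_equal(e$q_pvalue, pchisq(5, 1, lower.tail = FALSE))
  expect_equal(e$or, exp(0.6))
})

test_that("homogeneous ratios give Q = 0 and coinciding fixed/random IVW", {
  h <- hset_from_ratios(rep(0.4, 5), c(0.1, 0.2, 0.15, 0.3, 0.25))
  ef <- mr_ivw(h, model = "fixed")
  er <- mr_ivw(h, model = "random")
  expect_equal(ef$beta, 0.4, tolerance = 1e-12)
  expect_equal(ef$q_stat, 0, tolerance = 1e-12)
  expect_equal(er$se, ef$se)          # scale floored at 1
  expect_equal(er$overdispersion_scale, 1)
})

test_that("IVW equals the origin-regression weighted-least-squares oracle", {
  set.seed(101)
  for (i in 1:10) {
    k <- sample(4:12, 1)
    bx <- rnorm(k, 0.2, 0.05)
    by <- 0.3 * bx + rnorm(k, 0, 0.05)
    so <- runif(k, 0.02, 0.1)
    h <- make_hset(bx, by, so)
    e <- mr_ivw(h, model = "fixed")
    o <- oracle_wls(bx, by, 1 / so^2, intercept = FALSE)
    expect_equal(e$beta, unname(o$coef), tolerance = 1e-10)
  }
})

test_that("auto IVW follows the Q-test fixed/random switch", {
  homog <- hset_from_ratios(rep(0.4, 4) + c(0, 1e-4, -1e-4, 0), rep(0.1, 4))
  expect_equal(mr_ivw(homog, model = "auto")$model_used, "fixed")
  heterog <- hset_from_ratios(c(-1, 0.2, 1.5, 3), rep(0.05, 4))
  ea <- mr_ivw(heterog, model = "auto")
  expect_equal(ea$model_used, "random")
  expect_gt(ea$se, mr_ivw(heterog, model = "fixed")$se)
})

test_that("a single instrument degenerates to the Wald ratio", {
  h <- make_hset(0.1, 0.05, 0.02)
  e <- mr_ivw(h)
  expect_equal(e$method, "wald")
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.2)
})

test_that("MR-Egger recovers exact linear data and matches the WLS oracle", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_hset(bx, 0.1 + 0.3 * bx, c(0.1, 0.12, 0.15, 0.2))
  e <- mr_egger(h)
  expect_equal(e$intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$beta, 0.3, tolerance = 1e-10)

  # no-pleiotropy limit: zero intercept
  h0 <- make_hset(bx, 0.3 * bx, rep(0.1, 4))
  expect_equal(mr_egger(h0)$intercept, 0, tolerance = 1e-10)

  # 5-SNP numeric case against independent normal equations
  set.seed(5)
  bx5 <- rnorm(5, 0.25, 0.08)
  by5 <- 0.05 + 0.4 * bx5 + rnorm(5, 0, 0.03)
  so5 <- runif(5, 0.02, 0.08)
  h5 <- make_hset(bx5, by5, so5)
  e5 <- mr_egger(h5)
  o <- oracle_wls(abs(bx5), by5 * sign(bx5), 1 / so5^2)
  expect_equal(e5$intercept, unname(o$coef[1]), tolerance = 1e-10)
  expect_equal(e5$beta, unname(o$coef[2]), tolerance = 1e-10)
  scale <- max(1, o$sigma)
  expect_equal(e5$se, unname(sqrt(diag(o$cov_unscaled))[2]) * scale,
               tolerance = 1e-10)
  expect_error(mr_egger(make_hset(1:2 / 10, 1:2 / 10, 0.1)), "at least 3")
})

test_that("weighted median matches the brute-force percentile oracle", {
  h <- hset_from_ratios(c(0.4, 0.5, 0.9), rep(0.1, 3))
  e <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(e$beta, 0.5, tolerance = 1e-12)

  set.seed(77)
  for (i in 1:8) {
    k <- sample(3:15, 1)
    theta <- rnorm(k, 0.3, 0.5)
    ses <- runif(k, 0.05, 0.4)
    h <- hset_from_ratios(theta, ses)
    e <- mr_weighted_median(h, n_boot = 100, seed = i)
    expect_equal(e$beta, oracle_weighted_median(theta, 1 / ses^2),
                 tolerance = 1e-12)
  }
})

test_that("weighted median is deterministic under a fixed seed and a dominant SNP wins", {
  h <- hset_from_ratios(c(0.1, 0.8, 0.85, 0.9), c(0.01, 1, 1, 1))
  # first SNP carries weight 10000 of 10003 (> 50%): the interpolated
  # weighted median collapses onto its ratio (up to the interpolation step
  # toward the adjacent ratio, vanishing as the dominant weight grows)
  expect_equal(mr_weighted_median(h, n_boot = 100, seed = 3)$beta, 0.1,
               tolerance = 0.005)

  a <- mr_weighted_median(h, n_boot = 500, seed = 42)
  b <- mr_weighted_median(h, n_boot = 500, seed = 42)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)

  # degenerate distribution: all ratios equal, tiny SEs -> se near zero
  hd <- make_hset(rep(1, 3), rep(0.7, 3), 1e-6, se_exp = 1e-6)
  ed <- mr_weighted_median(hd, n_boot = 200, seed = 9)
  expect_equal(ed$beta, 0.7, tolerance = 1e-9)
  expect_lt(ed$se, 1e-4)
})

test_that("odds-ratio conversion and CI follow the normal-quantile convention", {
  expect_equal(to_odds_ratio(0, 0), list(or = 1, ci_low = 1, ci_high = 1))
  expect_equal(to_odds_ratio(log(2), 0)$or, 2)
  o <- to_odds_ratio(-0.2485, 0.0857)
  expect_equal(round(o$or, 2), 0.78)
  expect_equal(round(o$ci_low, 2), 0.66)
  expect_equal(round(o$ci_high, 2), 0.92)
  e <- mr_ivw(hset_from_ratios(c(0.5, 1.0), c(0.1, 0.2)), model = "fixed")
  expect_equal(e$or, exp(e$beta))
  expect_true(e$ci_low <= e$or && e$or <= e$ci_high)
})

test_that("estimates are scale-equivariant and outcome-sign symmetric", {
  set.seed(13)
  bx <- rnorm(6, 0.2, 0.05)
  by <- 0.25 * bx + rnorm(6, 0, 0.03)
  so <- runif(6, 0.02, 0.08)
  h <- make_hset(bx, by, so)
  c_ <- 2.5
  h_scaled <- make_hset(bx * c_, by, so, se_exp = 0.01 * c_)
  h_neg <- make_hset(bx, -by, so)
  for (est in list(function(x) mr_ivw(x, model = "fixed"),
                   mr_egger,
                   function(x) mr_weighted_median(x, n_boot = 100, seed = 2))) {
    e <- est(h); es <- est(h_scaled); en <- est(h_neg)
    expect_equal(es$beta, e$beta / c_, tolerance = 1e-9)
    expect_equal(en$beta, -e$beta, tolerance = 1e-9)
  }
})

test_that("parameter recovery across simulations: IVW unbiased, Egger handles directional pleiotropy, WM robust", {
  n_rep <- 200
  true_beta <- 0.25
  # no pleiotropy: IVW mean within Monte-Carlo error of the truth
  ivw_est <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_two_sample(simulation_config(
      n_snps = 20, causal_beta = true_beta, seed = 1000 + r))
    mr_ivw(harmonize(sim$exposure, sim$outcome), model = "fixed")$beta
  }, numeric(1))
  expect_lt(abs(mean(ivw_est) - true_beta),
            4 * sd(ivw_est) / sqrt(n_rep) + 0.01)

  # directional pleiotropy under InSIDE: Egger slope stays near the truth
  # while IVW is biased upward
  res <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_two_sample(simulation_config(
      n_snps = 20, causal_beta = true_beta, pleiotropy = "directional",
      pleiotropy_mean = 0.05, pleiotropy_sd = 0.01, prop_invalid = 0.9,
      seed = 2000 + r))
    h <- harmonize(sim$exposure, sim$outcome)
    c(ivw = mr_ivw(h, model = "fixed")$beta, egger = mr_egger(h)$beta)
  }, numeric(2))
  ivw_bias <- abs(mean(res["ivw", ]) - true_beta)
  egger_bias <- abs(mean(res["egger", ]) - true_beta)
  expect_gt(ivw_bias, 0.1)
  expect_lt(egger_bias, ivw_bias / 2)

  # 30% invalid instruments: weighted median less biased than IVW
  res2 <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_two_sample(simulation_config(
      n_snps = 20, causal_beta = true_beta, pleiotropy = "directional",
      pleiotropy_mean = 0.08, pleiotropy_sd = 0.01, prop_invalid = 0.3,
      seed = 3000 + r))
    h <- harmonize(sim$exposure, sim$outcome)
    c(ivw = mr_ivw(h, model = "fixed")$beta,
      wm = mr_weighted_median(h, n_boot = 100, seed = r)$beta)
  }, numeric(2))
  expect_lt(abs(mean(res2["wm", ]) - true_beta),
            abs(mean(res2["ivw", ]) - true_beta))
})
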