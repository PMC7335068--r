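test_that("power has its analytic values and monotonicity", {
  for (a in c(5e-8, 1e-5, 0.05))
    expect_lt(abs(gwas_power(0, 1e5, a) - a), 1e-12)
  # beta = c_{alpha/2}/sqrt(n): power 0.5000 to 4 decimals
  a <- 5e-8
  b <- qnorm(1 - a / 2) / sqrt(1e5)
  expect_equal(round(gwas_power(b, 1e5, a), 4), 0.5)
  # symmetry and monotone approach to 1
  bs <- seq(0, 0.1, by = 0.005)
  pw <- gwas_power(bs, 1e5, a)
  expect_equal(pw, gwas_power(-bs, 1e5, a))
  expect_true(all(diff(pw) >= 0))
  expect_equal(gwas_power(1, 1e5, a), 1)
  expect_error(gwas_power(0.1, 1e5, 0), "alpha")
})

test_that("expected discoveries and variance match Monte-Carlo oracles", {
  m <- mixture_model(1e5, 0.01, 1, 1e-4)  # M pi_c = 1000
  n_eff <- 1e5; alpha <- 5e-8
  set.seed(99)
  bdraw <- rnorm(1e6, 0, sqrt(1e-4))
  pw <- gwas_power(bdraw, n_eff, alpha)
  # ED oracle
  ed_mc <- 1000 * mean(pw)
  ed_se <- 1000 * sd(pw) / sqrt(1e6)
  expect_lt(abs(expected_discoveries(m, NULL, n_eff, alpha) - ed_mc),
            3 * ed_se)
  # EV oracle
  evt <- bdraw^2 * pw
  ev_mc <- 1000 * mean(evt)
  ev_se <- 1000 * sd(evt) / sqrt(1e6)
  expect_lt(abs(expected_variance(m, NULL, n_eff, alpha)$abs - ev_mc),
            3 * ev_se)
})

test_that("alpha = 1 limits recover totals exactly", {
  m <- mixture_model(1e5, 0.01, c(0.8, 0.2), c(1e-4, 5e-4))
  large <- structure(list(
    top = data.frame(SNP = "big", CHR = 1, BP = 1, BETA = 0.05,
                     SE = 0.005, Z = 10),
    removed = character(0)), class = "large_effect_set")
  a1 <- 1 - 1e-12
  expect_equal(expected_discoveries(m, large, 1e5, a1),
               1e5 * 0.01 + 1, tolerance = 1e-6)
  ev <- expected_variance(m, NULL, 1e5, a1)
  expect_equal(ev$abs, 1e5 * 0.01 * m$e_beta2, tolerance = 1e-6)
  expect_equal(ev$frac, 1, tolerance = 1e-6)
  # a powered large-effect SNP contributes its full heritability share
  evl <- expected_variance(m, large, 1e7, 5e-8)
  share <- (0.05^2 - 0.005^2)
  expect_equal(evl$abs - expected_variance(m, NULL, 1e7, 5e-8)$abs,
               share, tolerance = 1e-6)
})

test_that("ED and EV are monotone in n_eff and alpha", {
  m <- mixture_model(2e4, 0.02, 1, 3e-4)
  ns <- c(1e4, 3e4, 1e5, 3e5)
  eds <- vapply(ns, function(n) expected_discoveries(m, NULL, n, 5e-8),
                numeric(1))
  evs <- vapply(ns, function(n)
    expected_variance(m, NULL, n, 5e-8)$abs, numeric(1))
  expect_true(all(diff(eds) > 0))
  expect_true(all(diff(evs) > 0))
  as <- c(1e-10, 5e-8, 1e-5, 1e-2)
  eda <- vapply(as, function(a) expected_discoveries(m, NULL, 5e4, a),
                numeric(1))
  expect_true(all(diff(eda) > 0))
})

test_that("PRS variance respects its bounds and limits", {
  m <- mixture_model(1e5, 0.01, 1, 1e-4)
  h2 <- 0.1
  # bounded by EV and h2
  for (n in c(1e4, 1e5, 1e6)) {
    hp <- prs_variance(m, NULL, n, 5e-8)
    ev <- expected_variance(m, NULL, n, 5e-8)$abs
    expect_lte(hp, ev + 1e-12)
    expect_lte(ev, h2 + 1e-12)
  }
  # n -> infinity at fixed alpha: h2_prs -> h2
  expect_equal(prs_variance(m, NULL, 1e10, 5e-8), h2, tolerance = 1e-3)
  # alpha -> 0 at fixed n: nothing selected
  expect_lt(prs_variance(m, NULL, 1e4, 1e-300), 1e-6)
})

test_that("PRS variance agrees with an individual-level cohort oracle", {
  # small-M genotype simulation: train marginal effects on one cohort,
  # score an independent one, compare the signal variance of the score
  m_snps <- 2000
  truth <- mixture_model(m_snps, 0.05, 1, 1e-3)  # h2 = 0.1
  panel <- the_panel_cache(m_snps)
  n_eff <- 2e4
  alpha <- 1e-3
  # summary stats at n_eff; select and build the score analytically:
  # selected SNP j contributes beta_hat_j ~ N(beta_j, 1/n) if |z| passes;
  # each replicate redraws the architecture, since the projection formula
  # averages over the effect-size distribution
  set.seed(42)
  reps <- 60
  sig <- vapply(seq_len(reps), function(r) {
    arch <- simulate_effect_sizes(panel, truth, seed = 40L + r)
    z <- rnorm(m_snps, sqrt(n_eff) * arch$BETA, 1)
    sel <- abs(z) > qnorm(1 - alpha / 2)
    bh <- z[sel] / sqrt(n_eff)
    # variance of the score signal = (sum_j bh_j beta_j)^2 / sum bh^2 ...
    # directly: score on fresh genotypes S = sum bh G; var explained by
    # true PRS part is cov(S, PRS)^2 / var(PRS) with independent SNPs:
    cv <- sum(bh * arch$BETA[sel])
    vs <- sum(bh^2)
    if (vs == 0) 0 else cv^2 / vs
  }, numeric(1))
  pred <- prs_variance(truth, NULL, n_eff, alpha)
  expect_lt(abs(mean(sig) - pred) / pred, 0.2)
})

test_that("threshold optimization never loses to genome-wide significance", {
  weak <- mixture_model(1e5, 0.05, 1, 2e-5)   # polygenic, weak effects
  strong <- mixture_model(1e5, 5e-4, 1, 2e-3) # few strong effects
  # weak model at small n prefers a liberal threshold
  opt_w <- optimize_threshold(weak, NULL, 2e4)
  expect_gt(opt_w$alpha, 5e-8)
  expect_gte(opt_w$h2_prs, prs_variance(weak, NULL, 2e4, 5e-8))
  # strong effects at large n: optimized gain is modest
  nbig <- 1e6
  opt_s <- optimize_threshold(strong, NULL, nbig)
  gws_s <- prs_variance(strong, NULL, nbig, 5e-8)
  expect_lt((opt_s$h2_prs - gws_s) / gws_s, 0.05)
  # generic: optimum at least the gws value on any model
  for (m in list(weak, strong))
    expect_gte(optimize_threshold(m, NULL, 1e5)$h2_prs,
               prs_variance(m, NULL, 1e5, 5e-8))
})

test_that("sample-size search inverts the variance-explained curve", {
  m <- mixture_model(5e4, 0.01, 1, 2e-4)
  h2 <- 0.1
  # inversion consistency in gws mode
  n0 <- 2e5
  frac0 <- expected_variance(m, NULL, n0, 5e-8)$abs / h2
  n_hat <- sample_size_for_fraction(m, NULL, frac0, "gws")
  expect_equal(n_hat / n0, 1, tolerance = 0.01)
  # brute-force grid oracle: smallest grid n reaching the fraction
  grid <- 10^seq(4, 7, by = 0.05)
  g <- vapply(grid, function(n)
    expected_variance(m, NULL, n, 5e-8)$abs / h2, numeric(1))
  target <- 0.5
  oracle <- grid[which(g >= target)[1]]
  est <- sample_size_for_fraction(m, NULL, target, "gws")
  expect_lt(abs(log10(est) - log10(oracle)), 0.06)
  # monotone in fraction
  expect_gt(sample_size_for_fraction(m, NULL, 0.8, "gws"),
            sample_size_for_fraction(m, NULL, 0.4, "gws"))
  expect_error(sample_size_for_fraction(m, NULL, 0.99, "gws", n_cap = 1e5),
               "not reachable")
})

test_that("projection curves carry both threshold modes consistently", {
  m <- mixture_model(2e4, 0.01, 1, 5e-4)
  pc <- projection_curve(m, NULL, c(5e4, 1e5))
  expect_equal(nrow(pc), 4)
  expect_setequal(unique(pc$alpha_mode), c("gws", "optimized"))
  for (n in unique(pc$n_eff)) {
    sub <- pc[pc$n_eff == n, ]
    expect_gte(sub$h2_prs[sub$alpha_mode == "optimized"],
               sub$h2_prs[sub$alpha_mode == "gws"])
    expect_equal(sub$AUC, auc_from_h2(sub$h2_prs))
  }
})
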