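test_that("participant summaries: means, SDs, and missing flags", {
  d <- tibble::tibble(participant_id = c("A", "A", "A", "B", "C", "C"),
                      waso_min = c(40, 50, 60, 30, 20, 20),
                      so_density = c(4, 5, NA, 3, 2, 2))
  s <- summarize_participants(d)
  expect_equal(s$waso_min_mean[s$participant_id == "A"], 50)
  expect_equal(s$so_density_mean[s$participant_id == "A"], 4.5) # NA dropped
  expect_true(is.na(s$waso_min_sd[s$participant_id == "B"])) # single night
  expect_equal(s$waso_min_sd[s$participant_id == "C"], 0)    # constant
})

test_that("cohort mean WASO matches the generator's stationary target", {
  mm <- do.call(rbind, lapply(1:20, function(s)
    compute_macro_metrics(generate_hypnogram(
      hypnogram_spec(n_epochs = 960, seed = 7000 + s)))))
  st <- stationary_distribution(default_transition_matrix())
  target_wake <- 480 * st[["W"]]
  # WASO is total wake minus onset/terminal wake; sampling SD across 20
  # nights is large, so check the mean against the target within 4 SE
  se <- sd(mm$waso_min) / sqrt(nrow(mm))
  expect_lt(abs(mean(mm$waso_min) - target_wake), 10 + 4 * se)
})

test_that("correlations match closed forms and a permutation oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$r, 1)
  expect_equal(correlate(x, x^3, "spearman")$r, 1)
  expect_error(correlate(x, rep(1, 7)), "zero variance")
  expect_error(correlate(1:2, 1:2), "at least 3")

  set.seed(11)
  xs <- rnorm(17); ys <- 0.5 * xs + rnorm(17)
  cc <- correlate(xs, ys, "pearson")
  # permutation oracle for the two-tailed p-value
  robs <- abs(cor(xs, ys))
  perm <- mean(replicate(10000, abs(cor(xs, sample(ys))) >= robs))
  expect_lt(abs(cc$p - perm), 4 * sqrt(perm * (1 - perm) / 10000) + 0.01)
  expect_equal(cc$r, cor(xs, ys))
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(5)
  for (m in 2:8) {
    p <- runif(m)^2
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12)) # monotone in ranks
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("ICC formulas match worked examples and handle edge cases", {
  expect_equal(round(icc_from_variances(2404.27, 1440.80), 2), 0.63)
  expect_equal(icc_from_variances(0, 5), 0)
  expect_equal(icc_from_variances(3, 3), 0.5)
  expect_error(icc_from_variances(0, 0), "undefined")
  expect_error(icc_from_variances(-1, 1), "non-negative")

  expect_equal(latent_icc(0.21, 1), 0.21 / 1.21) # 0.1736
  expect_equal(latent_icc(0), 0)
  expect_equal(latent_icc(0.21, pi^2 / 3), 0.21 / (0.21 + pi^2 / 3))
  expect_equal(round(latent_icc(0.21, pi^2 / 3), 4), 0.0600)
})

test_that("GLMM recovers known fixed effects and variance components", {
  # beta = -5 per SO-density unit at study-scale variances
  est <- vapply(1:40, function(s) {
    set.seed(8000 + s)
    idx <- rep(1:17, each = 11)
    x <- pmax(rnorm(187, 4.2, 2.85), 0)
    y <- 430 - 5 * x + rnorm(17, 0, sqrt(2404.27))[idx] +
      rnorm(187, 0, sqrt(1440.8))
    d <- tibble::tibble(participant = idx, so_density = x, outcome = y)
    fit <- fit_glmm(d, "outcome", "so_density")
    fit$fixed$estimate[fit$fixed$term == "so_density"]
  }, numeric(1))
  expect_lt(abs(mean(est) - (-5)) / 5, 0.20)

  # large-sample recovery of the generating variance components
  set.seed(901)
  idx <- rep(1:100, each = 50)
  y <- 10 + rnorm(100, 0, sqrt(2404.27))[idx] + rnorm(5000, 0, sqrt(1440.8))
  fit <- fit_glmm(tibble::tibble(participant = idx, outcome = y), "outcome")
  expect_lt(abs(fit$var_between / 2404.27 - 1), 0.30) # single draw
  expect_lt(abs(fit$var_within / 1440.8 - 1), 0.10)
  expect_lt(abs(fit$icc / icc_from_variances(2404.27, 1440.8) - 1), 0.12)

  # zero between-variance generator -> boundary estimates dominate
  at_bound <- vapply(1:8, function(s) {
    set.seed(950 + s)
    idx <- rep(1:17, each = 11)
    y <- rnorm(187, 100, 10)
    f <- suppressWarnings(
      fit_glmm(tibble::tibble(participant = idx, outcome = y), "outcome"))
    f$var_between < 1 # boundary (var scale 100)
  }, logical(1))
  expect_gte(mean(at_bound), 0.5)
})

test_that("standardized and raw coefficients carry the same Z statistics", {
  set.seed(77)
  idx <- rep(1:17, each = 11)
  x <- rnorm(187, 4, 2)
  y <- 400 - 4 * x + rnorm(17, 0, 40)[idx] + rnorm(187, 0, 35)
  fit <- fit_glmm(tibble::tibble(participant = idx, x = x, outcome = y),
                  "outcome", "x")
  raw <- fit$fixed[fit$fixed$term == "x", ]
  z_std <- raw$std_estimate / ((raw$std_ci_hi - raw$std_ci_lo) / (2 * 1.96))
  expect_equal(unname(z_std), unname(raw$z), tolerance = 1e-4)
  # Type III Wald chi-square equals Z^2 for a 1-df predictor
  expect_equal(unname(fit$typeIII$chisq[fit$typeIII$term == "x"]),
               unname(raw$z^2), tolerance = 1e-3)
  expect_true(all(fit$fixed$p >= 0 & fit$fixed$p <= 1))
})

test_that("zero-inflated beta model carries zeros and reports latent ICC", {
  out <- simulate_behavior(behavior_sim_spec(
    n_participants = 17, n_days = 11, beta0 = -2.6, var_between = 0.21,
    var_within = 40, family = "beta", zero_inflation_prob = 0.4, seed = 5))
  expect_gt(sum(out$outcome == 0), 10)
  fit <- fit_glmm(out, "outcome", family = "beta_zi")
  expect_true(is.na(fit$var_within))
  expect_equal(fit$icc, latent_icc(fit$var_between, 1))
  zi_hat <- stats::plogis(glmmTMB::fixef(fit$model)$zi[[1]])
  expect_lt(abs(zi_hat - 0.4), 0.12)
})

test_that("bootstrap ICC interval is deterministic and hits limits", {
  out <- simulate_behavior(behavior_sim_spec(seed = 31))
  fit <- fit_glmm(out, "outcome")
  ci1 <- bootstrap_icc_ci(fit, n_boot = 200, seed = 9, engine = "anova")
  ci2 <- bootstrap_icc_ci(fit, n_boot = 200, seed = 9, engine = "anova")
  expect_identical(ci1[c("lower", "upper")], ci2[c("lower", "upper")])
  expect_true(ci1$lower < fit$icc && fit$icc < ci1$upper)

  # near-zero within-variance: interval concentrates near 1
  outd <- simulate_behavior(behavior_sim_spec(var_between = 2000,
                                              var_within = 0.01, seed = 4))
  fitd <- fit_glmm(outd, "outcome")
  cid <- bootstrap_icc_ci(fitd, n_boot = 100, seed = 2, engine = "anova")
  expect_gt(cid$lower, 0.999)

  # ml engine agrees with the moment engine on balanced data
  cim <- bootstrap_icc_ci(fit, n_boot = 60, seed = 9, engine = "ml")
  expect_lt(abs(cim$lower - ci1$lower), 0.12)
  expect_error(bootstrap_icc_ci(fit_glmm(
    simulate_behavior(behavior_sim_spec(family = "beta", beta0 = -2,
                                        var_between = 0.2, var_within = 30,
                                        seed = 3)),
    "outcome", family = "beta_zi"), seed = 1), "Gaussian")
})
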