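test_that("absorbing chains, determinism and validation behave", {
  I5 <- diag(5); dimnames(I5) <- list(c("W","N1","N2","N3","REM"),
                                      c("W","N1","N2","N3","REM"))
  h <- generate_hypnogram(hypnogram_spec(I5, n_epochs = 50,
                                         initial_stage = "N2", seed = 4))
  expect_true(all(h$stages == "N2"))

  s1 <- generate_hypnogram(hypnogram_spec(n_epochs = 300, seed = 99))
  s2 <- generate_hypnogram(hypnogram_spec(n_epochs = 300, seed = 99))
  expect_identical(s1$stages, s2$stages)

  badP <- default_transition_matrix(); badP[1, 1] <- badP[1, 1] + 0.01
  expect_error(hypnogram_spec(badP), "sum to 1")
  expect_error(hypnogram_spec(n_epochs = 0), "positive")
  expect_error(hypnogram("NREM4"), "unknown stage")
})

test_that("long-run stage fractions match the eigen-decomposition oracle", {
  P <- default_transition_matrix()
  st <- {
    e <- eigen(t(P)) # oracle: stationary left eigenvector
    v <- Re(e$vectors[, which.min(abs(e$values - 1))]); v / sum(v)
  }
  h <- generate_hypnogram(hypnogram_spec(P, n_epochs = 10000, seed = 12))
  frac <- table(factor(h$stages, levels = names(st))) / 10000
  expect_true(all(abs(as.numeric(frac) - st) < 0.02))
})

test_that("default chain reproduces target macroarchitecture on average", {
  mm <- do.call(rbind, lapply(1:30, function(s)
    compute_macro_metrics(generate_hypnogram(
      hypnogram_spec(n_epochs = 960, seed = 1000 + s)))))
  # generator targets implied by the stationary distribution over 8 h
  st <- stationary_distribution(default_transition_matrix())
  expect_equal(mean(mm$n3_min), 480 * st[["N3"]], tolerance = 0.12)
  expect_equal(mean(mm$tst_min), 480 * (1 - st[["W"]]), tolerance = 0.05)
  # WASO is bounded above by total wake and close to it for a fast-mixing
  # chain (sleep-onset and terminal wake are the small remainder)
  expect_lt(mean(mm$waso_min), 480 * st[["W"]])
  expect_gt(mean(mm$waso_min), 0.7 * 480 * st[["W"]])
})
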