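test_that("zero densities give pure background; no N2/N3 gives no events", {
  hyp <- n2n3_hypnogram(6, seed = 2)
  syn <- synthesize_night(hyp, event_injection_spec(
    so_density_per_min = 0, spindle_density_per_min = 0, seed = 3))
  expect_equal(nrow(syn$events), 0)
  expect_lt(abs(sd(syn$night$signal[, 1]) - 15), 2.5) # background RMS scale

  wake <- hypnogram(rep(c("W", "REM"), 5))
  syn2 <- synthesize_night(wake, event_injection_spec(seed = 4))
  expect_equal(nrow(syn2$events), 0)
})

test_that("injected event counts follow density x minutes with Poisson error", {
  hyp <- n2n3_hypnogram(20, seed = 5) # all epochs N2/N3 -> 10 min
  mins <- sum(stage_minutes(hyp)[c("N2", "N3")])
  counts <- vapply(1:20, function(s) {
    syn <- synthesize_night(hyp, event_injection_spec(
      spindle_density_per_min = 0, seed = 100 + s))
    nrow(syn$events)
  }, numeric(1))
  lambda <- 4.2 * mins
  # mean of 20 Poisson draws: SE = sqrt(lambda/20); allow 4 SE
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 20))
})

test_that("ground-truth events are disjoint, inside N2/N3, and deterministic", {
  hyp <- generate_hypnogram(hypnogram_spec(n_epochs = 30, seed = 6,
                                           initial_stage = "N2"))
  inj <- event_injection_spec(seed = 7)
  syn <- synthesize_night(hyp, inj)
  ev <- syn$events[order(syn$events$onset_s), ]
  if (nrow(ev) > 1) {
    gaps <- ev$onset_s[-1] - (ev$onset_s + ev$duration_s)[-nrow(ev)]
    expect_true(all(gaps > 0))
  }
  ep <- floor(ev$onset_s / 30) + 1
  ep_end <- floor((ev$onset_s + ev$duration_s) / 30) + 1
  expect_true(all(hyp$stages[ep] %in% c("N2", "N3")))
  expect_true(all(hyp$stages[pmin(ep_end, length(hyp$stages))]
                  %in% c("N2", "N3")))

  syn2 <- synthesize_night(hyp, inj)
  expect_identical(syn$night$signal, syn2$night$signal)
  expect_identical(syn$events, syn2$events)
})

test_that("impossible densities raise a budget error", {
  hyp <- hypnogram(rep("N2", 2)) # 1 minute
  expect_error(
    synthesize_night(hyp, event_injection_spec(so_density_per_min = 200,
                                               seed = 8)),
    "budget")
})

test_that("behavioral simulator respects degenerate and bounded cases", {
  sp0 <- behavior_sim_spec(n_participants = 4, n_days = 3, beta0 = 430,
                           var_between = 0, var_within = 0, seed = 1)
  out <- simulate_behavior(sp0)
  expect_true(all(out$outcome == 430))

  spb <- behavior_sim_spec(n_participants = 8, n_days = 6, beta0 = -2.5,
                           var_between = 0.2, var_within = 30,
                           family = "beta", zero_inflation_prob = 0.3,
                           seed = 2)
  outb <- simulate_behavior(spb)
  expect_true(all(outb$outcome >= 0 & outb$outcome <= 1))
  expect_gt(sum(outb$outcome == 0), 0)

  expect_identical(simulate_behavior(spb), simulate_behavior(spb))
  expect_error(behavior_sim_spec(var_between = -1), "non-negative")
})

test_that("fitted ICC recovers the generating components (0.63 scale)", {
  # 2404.27 / (2404.27 + 1440.80) = 0.625 by construction; the moment
  # estimator across seeds should concentrate near it
  iccs <- vapply(1:100, function(s) {
    out <- simulate_behavior(behavior_sim_spec(seed = 5000 + s))
    moment_icc(out$outcome, out$participant)
  }, numeric(1))
  expect_lt(abs(mean(iccs) - 0.63), 0.15)

  icc2 <- vapply(1:100, function(s) {
    out <- simulate_behavior(behavior_sim_spec(var_between = 2 * 2404.27,
                                               seed = 5000 + s))
    moment_icc(out$outcome, out$participant)
  }, numeric(1))
  expect_gt(mean(icc2), mean(iccs)) # monotone in var_between
})
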