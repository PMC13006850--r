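mk_go <- function(rts, correct = TRUE) {
  tibble::tibble(condition = "go", responded = !is.na(rts),
                 correct = correct & !is.na(rts), rt_ms = rts)
}
mk_nogo <- function(n, n_resp) {
  tibble::tibble(condition = "nogo",
                 responded = c(rep(TRUE, n_resp), rep(FALSE, n - n_resp)),
                 correct = c(rep(FALSE, n_resp), rep(TRUE, n - n_resp)),
                 rt_ms = NA_real_)
}

test_that("Go/NoGo scoring filters outliers and counts commissions", {
  tr <- rbind(mk_go(c(400, 450, 150, 950)), mk_nogo(60, 6))
  sc <- score_gonogo(tr)
  expect_equal(sc$gng_rt_ms, 425)          # 150 and 950 excluded
  expect_equal(sc$commission_pct, 10)
  sc0 <- score_gonogo(rbind(mk_go(c(500)), mk_nogo(60, 0)))
  expect_equal(sc0$commission_pct, 0)
  # strictly below/above: boundary RTs are kept
  scb <- score_gonogo(rbind(mk_go(c(200, 900)), mk_nogo(10, 0)))
  expect_equal(scb$gng_rt_ms, 550)
  # no valid go RT -> missing marker
  scna <- score_gonogo(rbind(mk_go(c(100, 950)), mk_nogo(10, 0)))
  expect_true(is.na(scna$gng_rt_ms))
  expect_error(score_gonogo(mk_go(c(400))), "nogo")
})

mk_simon <- function(congruency, switch, rts, correct = TRUE) {
  tibble::tibble(congruency = congruency, switch = switch,
                 responded = !is.na(rts), correct = correct,
                 rt_ms = rts)
}

test_that("Simon/switch effects reproduce printed group-mean arithmetic", {
  # cells whose means equal the group means 816.53 (incongruent) and
  # 718.74 (congruent)
  tr <- rbind(
    mk_simon("incongruent", "nonswitch", c(816.53 - 50, 816.53 + 50)),
    mk_simon("congruent", "nonswitch", c(718.74 - 40, 718.74 + 40)))
  sc <- score_simon_switch(tr)
  expect_equal(sc$simon_effect_rt_ms, 97.79, tolerance = 1e-9)

  # identical cells -> zero effect; swapping cells flips the sign
  sym <- rbind(mk_simon("incongruent", "switch", c(600, 700)),
               mk_simon("congruent", "nonswitch", c(600, 700)))
  expect_equal(score_simon_switch(sym)$simon_effect_rt_ms, 0)

  sw <- rbind(mk_simon("congruent", "switch", c(600)),
              mk_simon("congruent", "nonswitch", c(620)),
              mk_simon("incongruent", "switch", c(600)),
              mk_simon("incongruent", "nonswitch", c(620)))
  expect_equal(score_simon_switch(sw)$switch_effect_rt_ms, -20)
})

test_that("scoring is order-invariant, antisymmetric, and filters RTs", {
  set.seed(9)
  tr <- mk_simon(sample(c("congruent", "incongruent"), 60, TRUE),
                 sample(c("switch", "nonswitch", NA), 60, TRUE),
                 runif(60, 350, 2800))
  a <- score_simon_switch(tr)
  b <- score_simon_switch(tr[sample(nrow(tr)), ])
  expect_equal(a, b)

  flip <- tr
  flip$congruency <- ifelse(tr$congruency == "congruent",
                            "incongruent", "congruent")
  expect_equal(score_simon_switch(flip)$simon_effect_rt_ms,
               -a$simon_effect_rt_ms)

  # outlier bounds are strict: 300 and 3000 are retained
  tb <- rbind(mk_simon("incongruent", "nonswitch", c(300, 3000, 200, 3500)),
              mk_simon("congruent", "nonswitch", c(1650)))
  expect_equal(score_simon_switch(tb)$simon_effect_rt_ms, 0)

  # accuracy orientations: default signs match the expected pattern
  acc <- rbind(mk_simon("incongruent", "switch", rep(500, 10),
                        correct = c(rep(TRUE, 9), FALSE)),
               mk_simon("congruent", "nonswitch", rep(500, 10),
                        correct = TRUE))
  sc <- score_simon_switch(acc)
  expect_lt(sc$simon_effect_acc_pct, 0)  # worse on incongruent
  expect_gt(sc$switch_effect_acc_pct, 0) # better on nonswitch
  sc2 <- score_simon_switch(acc,
    simon_acc_orientation = "congruent_minus_incongruent",
    switch_acc_orientation = "switch_minus_nonswitch")
  expect_equal(sc2$simon_effect_acc_pct, -sc$simon_effect_acc_pct)
})
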