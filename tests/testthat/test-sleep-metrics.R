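test_that("macro metrics match hand-computed examples", {
  allN2 <- compute_macro_metrics(hypnogram(rep("N2", 100)))
  expect_equal(allN2$tst_min, 50)
  expect_equal(allN2$waso_min, 0)
  expect_equal(allN2$sleep_efficiency, 100)

  frag <- compute_macro_metrics(hypnogram(c("W", "N2", "W", "N2", "W")))
  expect_equal(frag$waso_min, 0.5)   # single wake epoch inside the span
  expect_equal(frag$n_awakenings, 1L)
  expect_equal(frag$tst_min, 1.0)

  none <- compute_macro_metrics(hypnogram(rep("W", 10)))
  expect_equal(none$tst_min, 0)
  expect_equal(none$waso_min, 0)
  expect_equal(none$sleep_efficiency, 0)
})

test_that("TST identity holds exactly per night and in cohort means", {
  mm <- do.call(rbind, lapply(1:25, function(s)
    compute_macro_metrics(generate_hypnogram(
      hypnogram_spec(n_epochs = 120, seed = 400 + s)))))
  expect_equal(mm$tst_min,
               tst_from_stages(mm$n1_min, mm$n2_min, mm$n3_min, mm$rem_min))
  # linearity: summed stage means equal the mean TST
  expect_equal(mean(mm$tst_min),
               tst_from_stages(mean(mm$n1_min), mean(mm$n2_min),
                               mean(mm$n3_min), mean(mm$rem_min)))
})

test_that("density arithmetic, doubling, and the zero-minute error", {
  hyp <- hypnogram(rep(c("N2", "N3"), 30)) # 30 min N2+N3
  ev <- tibble::tibble(type = rep("SO", 60))
  expect_equal(compute_density(ev, hyp, "SO"), 2.0)
  expect_equal(compute_density(ev[0, ], hyp, "SO"), 0.0)
  expect_equal(compute_density(rbind(ev, ev), hyp, "SO"), 4.0)
  expect_error(compute_density(ev, hypnogram(rep("W", 10)), "SO"),
               "undefined")
})

test_that("recovered densities track injected densities within 10%", {
  rec <- detection_recovery_study(n_nights = 4, n_epochs = 20, seed = 77)
  rel_so <- sum(rec$so_density_detected * rec$n2n3_min) /
    sum(rec$so_density_true * rec$n2n3_min)
  rel_sp <- sum(rec$spindle_density_detected * rec$n2n3_min) /
    sum(rec$spindle_density_true * rec$n2n3_min)
  expect_lt(abs(rel_so - 1), 0.10)
  expect_lt(abs(rel_sp - 1), 0.10)
})

test_that("exclusion rules drop bad nights then thin participants", {
  nights <- tibble::tibble(
    participant_id = rep(c("A", "B"), each = 5),
    night_index = rep(1:5, 2),
    best_quality = c(0.9, 0.9, 0.9, 0.9, 0.9,   # A: all good
                     0.45, 0.8, 0.45, 0.7, 0.45)) # B: 2 good -> excluded
  res <- apply_exclusions(nights, min_nights = 4, quality_threshold = 0.5)
  expect_equal(unique(res$retained$participant_id), "A")
  expect_equal(sum(res$log$reason == "low_channel_quality"), 3)
  expect_equal(sum(res$log$reason == "too_few_nights"), 2)
  expect_equal(nrow(res$retained) + nrow(res$log), nrow(nights))

  empty <- apply_exclusions(nights[0, ])
  expect_equal(nrow(empty$retained), 0)
  expect_equal(nrow(empty$log), 0)
})
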