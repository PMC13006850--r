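fs <- 250

test_that("SO detector: hand-checked waveform passes, scaled probe fails", {
  hyp <- hypnogram(rep("N3", 4)) # 2 quiet minutes
  x <- numeric(4 * 30 * fs)
  # 40 uV / 400 ms negative + 30 uV / 300 ms positive half-sines at t = 60 s;
  # amplitudes are set on the 0.3-4 Hz detection scale by inverting the
  # filter-chain attenuation of this exact template
  tpl <- so_template(40, 30, 0.4, 0.3, fs)
  probe <- function(scale) {
    xx <- x
    yy <- c(numeric(10 * fs), tpl, numeric(10 * fs))
    g <- {
      f <- fir_bandpass(fir_bandpass(yy, fs, 0.3, 40), fs, 0.3, 4)
      (max(f) - min(f)) / (max(tpl) - min(tpl))
    }
    wv <- tpl * scale / g
    i0 <- 60 * fs
    xx[i0:(i0 + length(wv) - 1)] <- wv
    xb <- fir_bandpass(xx, fs, 0.3, 40)
    detect_slow_oscillations(xb, fs, build_analysis_mask(xb, fs, hyp))
  }
  ev <- probe(1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$p2p_uV, 70, tolerance = 0.05)
  expect_gt(ev$neg_peak_uV, 33)
  # same waveform scaled so p2p = 50 uV fails the 61 uV criterion
  expect_equal(nrow(probe(50 / 70)), 0)
  # all-zero signal and empty mask both yield empty results
  expect_equal(nrow(detect_slow_oscillations(
    numeric(2 * 30 * fs), fs,
    build_analysis_mask(numeric(2 * 30 * fs), fs, hypnogram(c("N2", "N2"))))),
    0)
  wake_mask <- build_analysis_mask(numeric(30 * fs), fs, hypnogram("W"))
  expect_equal(nrow(detect_slow_oscillations(numeric(30 * fs), fs,
                                             wake_mask)), 0)
})

test_that("every detected SO independently re-passes all four criteria", {
  hyp <- n2n3_hypnogram(14, seed = 21)
  syn <- synthesize_night(hyp, event_injection_spec(seed = 22))
  x <- fir_bandpass(syn$night$signal[, 1], fs, 0.3, 40)
  mask <- build_analysis_mask(x, fs, hyp)
  so <- detect_slow_oscillations(x, fs, mask)
  expect_gt(nrow(so), 10)
  trace_so <- fir_bandpass(x, fs, 0.3, 4)
  ok <- vapply(seq_len(nrow(so)), function(i)
    so_criteria_hold(so[i, ], trace_so, fs), logical(1))
  expect_true(all(ok))
  # events lie wholly inside usable epochs
  ep0 <- floor(so$onset_s / 30) + 1
  ep1 <- floor((so$onset_s + so$duration_s) / 30) + 1
  expect_true(all(mask$usable[ep0] & mask$usable[pmin(ep1, nrow(mask))]))
})

test_that("detection counts are invariant to constant offsets", {
  hyp <- n2n3_hypnogram(8, seed = 31)
  syn <- synthesize_night(hyp, event_injection_spec(seed = 32))
  raw <- syn$night$signal[, 1]
  for (off in c(0, 120)) {
    x <- fir_bandpass(raw + off, fs, 0.3, 40)
    mask <- build_analysis_mask(x, fs, hyp)
    so <- detect_slow_oscillations(x, fs, mask)
    sp <- detect_spindles(x, fs, mask)
    if (off == 0) { n_so <- nrow(so); n_sp <- nrow(sp) }
    else { expect_equal(nrow(so), n_so); expect_equal(nrow(sp), n_sp) }
  }
})

test_that("spindle detector recovers a single burst and rejects short ones", {
  hyp <- hypnogram(rep("N2", 4))
  mkx <- function(dur, seed) {
    set.seed(seed)
    x <- pink_noise(4 * 30 * fs, fs)
    bu <- spindle_template(dur, 13, 20, fs)
    i0 <- 60 * fs
    x[i0:(i0 + length(bu) - 1)] <- x[i0:(i0 + length(bu) - 1)] + bu
    fir_bandpass(x, fs, 0.3, 40)
  }
  hits <- 0
  for (s in 1:5) {
    x <- mkx(1.0, 40 + s)
    ev <- detect_spindles(x, fs, build_analysis_mask(x, fs, hyp))
    if (nrow(ev) == 1 && abs(ev$onset_s - (60 * fs - 1) / fs) < 0.5) {
      hits <- hits + 1
      expect_gte(ev$duration_s, 0.5)
      expect_lte(ev$duration_s, 2.0)
    }
  }
  expect_gte(hits, 4) # sensitivity to a 20 uV burst in 15 uV-RMS noise

  # a 0.3 s burst is below the admissible duration range
  x3 <- mkx(0.3, 77)
  expect_equal(nrow(detect_spindles(x3, fs,
                                    build_analysis_mask(x3, fs, hyp))), 0)

  expect_error(detect_spindles(numeric(10), fs,
                               build_analysis_mask(numeric(30 * fs), fs,
                                                   hypnogram("N2"))),
               "longer than the signal")
})

test_that("spindle detector is specific on event-free background", {
  # false-positive rate on pure 1/f background across seeds
  hyp <- hypnogram(rep("N2", 20)) # 10 min
  fp <- 0
  for (s in 1:6) {
    set.seed(600 + s)
    x <- fir_bandpass(pink_noise(20 * 30 * fs, fs), fs, 0.3, 40)
    fp <- fp + nrow(detect_spindles(x, fs, build_analysis_mask(x, fs, hyp)))
  }
  expect_lte(fp, 1) # at most one spurious event per hour of background
  # every reported duration respects the admissible range by construction
})

test_that("event-shape summaries average time-locked traces correctly", {
  hyp <- hypnogram(rep("N3", 10))
  x <- numeric(10 * 30 * fs)
  tpl <- so_template(60, 45, 0.45, 0.35, fs)
  onsets <- c(30, 75, 130, 200, 260)
  for (o in onsets) {
    i0 <- o * fs
    x[i0:(i0 + length(tpl) - 1)] <- x[i0:(i0 + length(tpl) - 1)] + tpl
  }
  xb <- fir_bandpass(x, fs, 0.3, 40)
  so <- detect_slow_oscillations(xb, fs, build_analysis_mask(xb, fs, hyp))
  expect_equal(nrow(so), length(onsets))
  avg <- summarize_event_shapes(so, xb, fs)
  expect_equal(avg$n_events, length(onsets))
  # identical injected events: the average reproduces one event's trace
  one <- summarize_event_shapes(so[1, ], xb, fs)
  expect_equal(avg$mean, one$mean, tolerance = 1e-6)
  expect_true(all(avg$sem < 1e-6))
  # trough at the anchor
  expect_equal(which.min(avg$mean), (length(avg$mean) + 1) / 2,
               tolerance = 3)
  # averaging is invariant to event order
  perm <- summarize_event_shapes(so[sample(nrow(so)), ], xb, fs)
  expect_equal(perm$mean, avg$mean)
  expect_error(summarize_event_shapes(so[0, ], xb, fs), "no events")
})
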