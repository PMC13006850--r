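# Shared fixtures and independent oracles used across test files.

# N2/N3-rich hypnogram for short synthetic nights
n2n3_hypnogram <- function(n_epochs = 20, seed = 1) {
  P <- matrix(0, 5, 5, dimnames = list(c("W","N1","N2","N3","REM"),
                                       c("W","N1","N2","N3","REM")))
  P["W", ] <- c(0.5, 0.5, 0, 0, 0)
  P["N1", ] <- c(0, 0.3, 0.7, 0, 0)
  P["N2", ] <- c(0, 0, 0.88, 0.12, 0)
  P["N3", ] <- c(0, 0, 0.15, 0.85, 0)
  P["REM", ] <- c(0, 0, 0.2, 0, 0.8)
  generate_hypnogram(hypnogram_spec(P, n_epochs = n_epochs,
                                    initial_stage = "N2", seed = seed))
}

# all-usable mask for a clean synthetic trace
usable_mask <- function(x, fs, hyp) build_analysis_mask(x, fs, hyp)

# independent brute-force Benjamini-Hochberg step-up (textbook definition:
# adj_i = min over j >= rank(i) of m * p_(j) / j, capped at 1)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)
    cand <- vapply(r:m, function(j) m * p[o[j]] / j, numeric(1))
    adj[i] <- min(c(cand, 1))
  }
  adj
}

# independent one-way ANOVA moment estimator of variance components,
# used as the recovery oracle for simulated mixed-model outcomes
moment_icc <- function(y, id) {
  id <- as.integer(factor(id))
  k <- max(id)
  n0 <- length(y) / k
  gmeans <- tapply(y, id, mean)
  msb <- n0 * sum((gmeans - mean(y))^2) / (k - 1)
  msw <- sum((y - gmeans[id])^2) / (length(y) - k)
  vb <- max((msb - msw) / n0, 0)
  vb / (vb + msw)
}

# re-check a detected SO against the four amplitude/duration criteria,
# independently of the detector's own bookkeeping, on the 0.3-4 Hz trace
so_criteria_hold <- function(ev, trace_so, fs, p = so_params()) {
  i0 <- round(ev$onset_s * fs) + 1L
  i1 <- round((ev$onset_s + ev$duration_s) * fs) + 1L
  seg <- trace_so[i0:min(i1, length(trace_so))]
  neg_pk <- min(seg); pos_pk <- max(seg)
  zc <- which(seg[-length(seg)] < 0 & seg[-1] >= 0)[1]
  if (is.na(zc)) return(FALSE)
  neg_dur <- zc / fs
  pos_dur <- ev$duration_s - neg_dur
  abs(neg_dur - ev$neg_dur_s) <= 3 / fs && # crossing-index convention slack
    (-neg_pk) >= p$neg_amp_uV &&
    (pos_pk - neg_pk) >= p$p2p_amp_uV &&
    neg_dur >= p$neg_dur_min_ms / 1000 - 1 / fs &&
    neg_dur <= p$neg_dur_max_ms / 1000 + 1 / fs &&
    pos_dur <= p$pos_dur_max_ms / 1000 + 1 / fs
}
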