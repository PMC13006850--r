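#' Slow-oscillation detection parameters
#'
#' Amplitude and duration criteria applied to candidate half-wave pairs
#' on the 0.3-4 Hz bandpassed trace: the negative half-wave peak must
#' reach `neg_amp_uV`, the negative-to-positive peak-to-peak amplitude
#' must reach `p2p_amp_uV`, the negative half-wave must last between
#' `neg_dur_min_ms` and `neg_dur_max_ms`, and the following positive
#' half-wave at most `pos_dur_max_ms`.
#'
#' @param bp_lo,bp_hi detection band edges, Hz.
#' @param neg_amp_uV minimum negative-peak magnitude, uV.
#' @param p2p_amp_uV minimum peak-to-peak amplitude, uV.
#' @param neg_dur_min_ms,neg_dur_max_ms negative half-wave duration
#'   bounds, ms.
#' @param pos_dur_max_ms maximum positive half-wave duration, ms.
#' @param filter_order FIR order for the internal detection bandpass.
#' @return A list of class `so_params`.
#' @export
so_params <- function(bp_lo = 0.3, bp_hi = 4,
                      neg_amp_uV = 33, p2p_amp_uV = 61,
                      neg_dur_min_ms = 125, neg_dur_max_ms = 1500,
                      pos_dur_max_ms = 1000, filter_order = 300L) {
  stopifnot(bp_lo > 0, bp_hi > bp_lo, neg_amp_uV > 0, p2p_amp_uV > 0,
            neg_dur_min_ms > 0, neg_dur_max_ms > neg_dur_min_ms,
            pos_dur_max_ms > 0)
  structure(as.list(environment()), class = "so_params")
}

#' Detect slow oscillations on masked N2/N3 sleep
#'
#' The input trace (already 0.3-40 Hz filtered) is bandpassed to the
#' detection band (0.3-4 Hz by default, zero-phase). Candidates are
#' consecutive negative-then-positive half-waves delimited by zero
#' crossings of the narrowband trace; a candidate is accepted when all
#' four amplitude/duration criteria in [so_params] hold. Events must lie
#' wholly inside usable (artifact-free N2/N3) epochs; events straddling a
#' masked-epoch boundary are discarded. Candidates are disjoint by
#' construction, so returned events never overlap.
#'
#' @param x numeric trace, microvolts, 0.3-40 Hz filtered.
#' @param fs sampling rate, Hz.
#' @param mask an `analysis_mask` from [build_analysis_mask]. An
#'   all-rejected mask yields an empty event table (not an error).
#' @param p an [so_params].
#' @return Tibble of events: `type` ("SO"), `onset_s`, `duration_s`,
#'   `channel` (`NA`; filled by callers that know it), `p2p_uV`,
#'   `neg_peak_uV` (negative-peak magnitude), `neg_dur_s`, `pos_dur_s`,
#'   `stage_at_onset`; sorted by onset.
#' @export
detect_slow_oscillations <- function(x, fs, mask, p = so_params()) {
  stopifnot(inherits(mask, "analysis_mask"))
  empty <- tibble::tibble(type = character(0), onset_s = numeric(0),
                          duration_s = numeric(0), channel = character(0),
                          p2p_uV = numeric(0), neg_peak_uV = numeric(0),
                          neg_dur_s = numeric(0), pos_dur_s = numeric(0),
                          stage_at_onset = character(0))
  if (!any(mask$usable)) return(empty)
  x <- x - mean(x) # detection is offset-invariant by construction
  s <- fir_bandpass(x, fs, p$bp_lo, p$bp_hi, p$filter_order)
  n <- length(s)
  # sign changes of the narrowband trace; crossings indexed at the sample
  # before the change
  pos2neg <- which(s[-n] >= 0 & s[-1] < 0)
  neg2pos <- which(s[-n] < 0 & s[-1] >= 0)
  if (!length(pos2neg) || !length(neg2pos)) return(empty)
  ok_sample <- mask_samples(mask, n, fs)
  ep_len <- attr(mask, "epoch_len_s")
  out <- vector("list", 64L)
  n_out <- 0L
  for (a in pos2neg) {
    b <- neg2pos[neg2pos > a][1]
    if (is.na(b)) break
    cend <- pos2neg[pos2neg > b][1]
    if (is.na(cend)) next
    neg_dur <- (b - a) / fs
    pos_dur <- (cend - b) / fs
    if (neg_dur < p$neg_dur_min_ms / 1000 ||
        neg_dur > p$neg_dur_max_ms / 1000 ||
        pos_dur > p$pos_dur_max_ms / 1000) next
    neg_pk <- min(s[a:b])
    pos_pk <- max(s[b:cend])
    if (-neg_pk < p$neg_amp_uV) next
    if (pos_pk - neg_pk < p$p2p_amp_uV) next
    if (!all(ok_sample[a:cend])) next # strict containment in usable epochs
    onset <- (a - 1) / fs
    n_out <- n_out + 1L
    if (n_out > length(out)) out <- c(out, vector("list", length(out)))
    out[[n_out]] <- c(onset, neg_dur + pos_dur, pos_pk - neg_pk, -neg_pk,
                      neg_dur, pos_dur, floor(onset / ep_len) + 1)
  }
  if (n_out == 0L) return(empty)
  m <- do.call(rbind, out[seq_len(n_out)])
  tibble::tibble(type = "SO", onset_s = m[, 1], duration_s = m[, 2],
                 channel = NA_character_, p2p_uV = m[, 3],
                 neg_peak_uV = m[, 4], neg_dur_s = m[, 5],
                 pos_dur_s = m[, 6],
                 stage_at_onset = mask$stage[m[, 7]])
}
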