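#' Specification for ground-truth event injection
#'
#' Controls the synthetic EEG for one night: the 1/f background, extra
#' delta-band power in N3, and the densities and morphologies of injected
#' slow oscillations (SOs) and sleep spindles. Defaults are set to the
#' scale observed in multi-night in-home recordings of healthy older
#' adults: SO density 4.2/min and spindle density 1.5/min of N2+N3 sleep,
#' mean SO peak-to-peak amplitude ~86.5 uV, and a 15 uV-RMS pink-noise
#' background.
#'
#' SO amplitudes are specified on the detection scale, i.e. as the
#' peak-to-peak amplitude the event exhibits in the 0.3-4 Hz band after
#' the standard filter chain; the injector rescales the raw waveform to
#' compensate the (duration-dependent) attenuation of that chain, exactly
#' as a physiological SO's raw amplitude exceeds its narrowband amplitude.
#'
#' @param so_density_per_min injected SO events per minute of N2+N3.
#' @param spindle_density_per_min injected spindles per minute of N2+N3.
#' @param so_amp_uV mean in-band peak-to-peak SO amplitude, uV.
#' @param so_amp_sd_uV between-event SD of SO amplitude, uV.
#' @param so_neg_frac fraction of the peak-to-peak amplitude carried by
#'   the negative half-wave.
#' @param so_neg_dur_s range (length-2) of negative half-wave durations, s.
#' @param so_pos_dur_s range of positive half-wave durations, s.
#' @param spindle_amp_uV mean spindle peak amplitude, uV.
#' @param spindle_amp_sd_uV between-event SD of spindle amplitude, uV.
#' @param spindle_freq_hz centre spindle frequency, Hz (11-16).
#' @param spindle_freq_jitter_hz half-width of the uniform frequency
#'   jitter around the centre, Hz.
#' @param spindle_dur_s mean spindle duration, s (within 0.5-2.5 for
#'   recoverable events).
#' @param spindle_dur_jitter_s half-width of the uniform duration jitter, s.
#' @param noise_exponent spectral exponent of the 1/f background.
#' @param noise_rms_uV RMS of the background, uV.
#' @param n3_delta_rms_uV extra 0.5-2 Hz noise RMS added during N3, uV.
#' @param min_gap_s minimum gap enforced between injected events, s.
#' @param seed integer seed.
#' @return An object of class `event_injection_spec`.
#' @export
event_injection_spec <- function(so_density_per_min = 4.2,
                                 spindle_density_per_min = 1.5,
                                 so_amp_uV = 86.5,
                                 so_amp_sd_uV = 6,
                                 so_neg_frac = 0.55,
                                 so_neg_dur_s = c(0.35, 0.55),
                                 so_pos_dur_s = c(0.25, 0.40),
                                 spindle_amp_uV = 20,
                                 spindle_amp_sd_uV = 2,
                                 spindle_freq_hz = 13,
                                 spindle_freq_jitter_hz = 1,
                                 spindle_dur_s = 1.0,
                                 spindle_dur_jitter_s = 0.2,
                                 noise_exponent = 1,
                                 noise_rms_uV = 15,
                                 n3_delta_rms_uV = 5,
                                 min_gap_s = 0.5,
                                 seed = 1L) {
  if (so_density_per_min < 0 || spindle_density_per_min < 0)
    stop("event densities must be non-negative")
  if (spindle_freq_hz < 11 || spindle_freq_hz > 16)
    stop("spindle_freq_hz must lie in the sigma band [11, 16] Hz")
  if (noise_rms_uV < 0 || n3_delta_rms_uV < 0)
    stop("noise RMS values must be non-negative")
  structure(as.list(environment()), class = "event_injection_spec")
}

# Canonical SO template: negative half-sine then positive half-sine.
# Exposed so sub-threshold probe waveforms can be built directly.
#' Biphasic slow-oscillation template
#'
#' One negative half-sine followed by one positive half-sine, with
#' independently configurable amplitudes and durations, sampled at `fs`.
#'
#' @param neg_amp_uV,pos_amp_uV half-wave peak amplitudes (positive
#'   numbers; the negative half-wave is emitted with negative sign).
#' @param neg_dur_s,pos_dur_s half-wave durations, s.
#' @param fs sampling rate, Hz.
#' @return Numeric waveform vector.
#' @export
so_template <- function(neg_amp_uV, pos_amp_uV, neg_dur_s, pos_dur_s, fs) {
  tn <- seq(0, neg_dur_s, by = 1 / fs)
  tp <- seq(0, pos_dur_s, by = 1 / fs)
  c(-neg_amp_uV * sin(pi * tn / neg_dur_s),
    pos_amp_uV * sin(pi * tp / pos_dur_s)[-1])
}

#' Hann-windowed sinusoidal spindle template
#'
#' @param dur_s burst duration, s.
#' @param freq_hz oscillation frequency, Hz.
#' @param amp_uV peak amplitude, uV.
#' @param fs sampling rate, Hz.
#' @return Numeric waveform vector.
#' @export
spindle_template <- function(dur_s, freq_hz, amp_uV, fs) {
  t <- seq(0, dur_s, by = 1 / fs)
  amp_uV * sin(2 * pi * freq_hz * t) * 0.5 * (1 - cos(2 * pi * t / dur_s))
}

# attenuation of an SO template through the 0.3-40 Hz + 0.3-4 Hz chain;
# memoised on (neg_dur, pos_dur) rounded to the sample grid
so_chain_gain <- function(neg_dur_s, pos_dur_s, fs, order = 300L,
                          cache = NULL) {
  key <- sprintf("%d_%d", round(neg_dur_s * fs), round(pos_dur_s * fs))
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  wv <- so_template(55, 45, neg_dur_s, pos_dur_s, fs)
  pad <- 3L * (order + 1L) + length(wv)
  x <- c(numeric(pad), wv, numeric(pad))
  y <- fir_bandpass(fir_bandpass(x, fs, 0.3, 40, order), fs, 0.3, 4, order)
  g <- (max(y) - min(y)) / (max(wv) - min(wv))
  if (!is.null(cache)) cache[[key]] <- g
  g
}

#' Construct an EEG night container
#'
#' @param signal numeric matrix, samples x channels (column names are
#'   channel labels), in physical microvolts.
#' @param fs sampling rate, Hz.
#' @param channel_quality named fraction in `[0, 1]` per channel.
#' @param participant_id,night_id identifiers.
#' @return An object of class `eeg_night`.
#' @export
eeg_night <- function(signal, fs, channel_quality,
                      participant_id = NA_character_,
                      night_id = NA_character_) {
  signal <- as.matrix(signal)
  if (is.null(colnames(signal)))
    stop("signal matrix must carry channel names as column names")
  if (!setequal(names(channel_quality), colnames(signal)))
    stop("channel_quality must be named after the signal channels")
  if (any(channel_quality < 0 | channel_quality > 1))
    stop("channel quality must lie in [0, 1]")
  if (fs <= 0) stop("fs must be positive")
  structure(list(signal = signal, fs = fs,
                 channel_quality = channel_quality[colnames(signal)],
                 participant_id = participant_id, night_id = night_id),
            class = "eeg_night")
}

#' @exportS3Method base::print
print.eeg_night <- function(x, ...) {
  cat("<eeg_night> ", nrow(x$signal), " samples @ ", x$fs, " Hz (",
      round(nrow(x$signal) / x$fs / 60, 1), " min), channels: ",
      paste(sprintf("%s[q=%.2f]", colnames(x$signal), x$channel_quality),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Synthesize one night of EEG with ground-truth events
#'
#' Builds a single-channel night of 1/f background EEG aligned to a
#' hypnogram, adds extra delta-band noise during N3 epochs, and injects
#' slow oscillations and spindles only into N2/N3 epochs, uniformly over
#' the eligible samples with rejection sampling so that no two events
#' overlap (a configurable guard gap keeps their detection footprints
#' separable). Event counts are Poisson with mean
#' `density x minutes(N2+N3)`.
#'
#' @param hyp a [hypnogram].
#' @param inj an [event_injection_spec].
#' @param fs sampling rate, Hz (250 by default).
#' @param channel channel label for the synthesized derivation.
#' @param participant_id,night_id identifiers carried into the outputs.
#' @return A list with elements `night` (an [eeg_night]) and `events`
#'   (tibble of ground truth: `onset_s`, `duration_s`, `type`, `channel`,
#'   plus per-type amplitude columns). Deterministic given `inj$seed`.
#' @export
synthesize_night <- function(hyp, inj, fs = 250, channel = "F7-O1",
                             participant_id = "sim", night_id = "n1") {
  stopifnot(inherits(hyp, "hypnogram"), inherits(inj, "event_injection_spec"))
  set.seed(inj$seed)
  n_ep <- length(hyp$stages)
  ep_len <- hyp$epoch_len_s
  n <- round(n_ep * ep_len * fs)
  x <- pink_noise(n, fs, inj$noise_exponent, inj$noise_rms_uV)

  # stage-dependent delta power: extra 0.5-2 Hz noise during N3
  if (inj$n3_delta_rms_uV > 0 && any(hyp$stages == "N3")) {
    d <- pink_noise(n, fs, inj$noise_exponent, 1)
    d <- fir_bandpass(d, fs, 0.5, 2)
    d <- d * inj$n3_delta_rms_uV / sd(d)
    gain <- rep(as.numeric(hyp$stages == "N3"), each = round(ep_len * fs))
    # 0.5 s cosine ramps at stage boundaries avoid step discontinuities
    k <- round(0.5 * fs)
    gain <- as.numeric(stats::filter(gain, rep(1 / k, k), sides = 2))
    gain[is.na(gain)] <- 0
    x <- x + d * gain[seq_len(n)]
  }

  eligible_ep <- which(hyp$stages %in% c("N2", "N3"))
  n2n3_min <- length(eligible_ep) * ep_len / 60
  n_so <- if (n2n3_min > 0) rpois(1, inj$so_density_per_min * n2n3_min) else 0L
  n_sp <- if (n2n3_min > 0) rpois(1, inj$spindle_density_per_min * n2n3_min) else 0L

  # eligible start times: events must lie wholly inside N2/N3 epochs
  ep_start <- (eligible_ep - 1) * ep_len
  occupied <- matrix(numeric(0), ncol = 2)
  gap <- inj$min_gap_s
  place_event <- function(len_s) {
    # events are short relative to an epoch; confine each to one epoch so
    # containment in usable N2/N3 epochs holds by construction
    for (try in 1:400) {
      e0 <- if (length(ep_start) == 1L) ep_start else sample(ep_start, 1L)
      on <- e0 + runif(1, 0, ep_len - len_s)
      if (!nrow(occupied) ||
          all(on > occupied[, 2] + gap | on + len_s < occupied[, 1] - gap)) {
        occupied <<- rbind(occupied, c(on, on + len_s))
        return(on)
      }
    }
    stop("cannot place event of ", round(len_s, 2), " s without overlap: ",
         "requested density exceeds the ", round(n2n3_min, 1),
         " min N2+N3 epoch budget")
  }

  events <- list()
  gain_cache <- new.env(parent = emptyenv())
  if (n_so > 0 && n2n3_min > 0) {
    for (i in seq_len(n_so)) {
      dn <- runif(1, inj$so_neg_dur_s[1], inj$so_neg_dur_s[2])
      dp <- runif(1, inj$so_pos_dur_s[1], inj$so_pos_dur_s[2])
      p2p <- max(rnorm(1, inj$so_amp_uV, inj$so_amp_sd_uV), 1)
      on <- place_event(dn + dp)
      g <- so_chain_gain(dn, dp, fs, cache = gain_cache)
      wv <- so_template(inj$so_neg_frac * p2p / g,
                        (1 - inj$so_neg_frac) * p2p / g, dn, dp, fs)
      i0 <- round(on * fs) + 1L
      idx <- i0:(i0 + length(wv) - 1L)
      x[idx] <- x[idx] + wv
      events[[length(events) + 1L]] <- tibble::tibble(
        onset_s = on, duration_s = dn + dp, type = "SO",
        channel = channel, amp_uV = p2p, freq_hz = NA_real_)
    }
  }
  if (n_sp > 0 && n2n3_min > 0) {
    for (i in seq_len(n_sp)) {
      du <- runif(1, inj$spindle_dur_s - inj$spindle_dur_jitter_s,
                  inj$spindle_dur_s + inj$spindle_dur_jitter_s)
      fr <- runif(1, inj$spindle_freq_hz - inj$spindle_freq_jitter_hz,
                  inj$spindle_freq_hz + inj$spindle_freq_jitter_hz)
      am <- max(rnorm(1, inj$spindle_amp_uV, inj$spindle_amp_sd_uV), 0.5)
      on <- place_event(du)
      wv <- spindle_template(du, fr, am, fs)
      i0 <- round(on * fs) + 1L
      idx <- i0:(i0 + length(wv) - 1L)
      x[idx] <- x[idx] + wv
      events[[length(events) + 1L]] <- tibble::tibble(
        onset_s = on, duration_s = du, type = "spindle",
        channel = channel, amp_uV = am, freq_hz = fr)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    tibble::tibble(onset_s = numeric(0), duration_s = numeric(0),
                   type = character(0), channel = character(0),
                   amp_uV = numeric(0), freq_hz = numeric(0))
  ev <- ev[order(ev$onset_s), , drop = FALSE]

  sig <- matrix(x, ncol = 1, dimnames = list(NULL, channel))
  quality <- channel_quality_from_signal(x, fs, ep_len)
  night <- eeg_night(sig, fs, setNames(quality, channel),
                     participant_id = participant_id, night_id = night_id)
  list(night = night, events = ev)
}

# fraction of 30-s epochs whose demeaned trace stays within +/-200 uV;
# stands in for the recorder's proprietary "scoreable data" percentage
channel_quality_from_signal <- function(x, fs, epoch_len_s = 30,
                                        reject_uV = 200) {
  ns <- round(epoch_len_s * fs)
  n_ep <- floor(length(x) / ns)
  if (n_ep < 1) return(0)
  ok <- vapply(seq_len(n_ep), function(i) {
    seg <- x[((i - 1) * ns + 1):(i * ns)]
    max(abs(seg - mean(seg))) <= reject_uV
  }, logical(1))
  mean(ok)
}
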