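#' Select the best-quality EEG channel for a night
#'
#' Among the candidate frontal-occipital derivations, returns the one
#' with the highest recorded channel quality provided it reaches the
#' quality threshold; ties are broken by candidate order. When no
#' candidate reaches the threshold the night is unusable and `NA` is
#' returned for the caller to discard it.
#'
#' @param night an [eeg_night].
#' @param candidates character vector of channel labels to consider, in
#'   preference order.
#' @param quality_threshold minimum acceptable quality fraction
#'   (default 0.5, i.e. at least 50% scoreable data).
#' @return A channel label, or `NA_character_` when every candidate falls
#'   below the threshold.
#' @export
select_best_channel <- function(night,
                                candidates = c("F7-O1", "F8-O2",
                                               "Fpz-O1", "Fpz-O2"),
                                quality_threshold = 0.5) {
  stopifnot(inherits(night, "eeg_night"), length(candidates) >= 1)
  candidates <- intersect(candidates, candidates) # preserve order, drop dups
  unknown <- setdiff(candidates, names(night$channel_quality))
  if (length(unknown) == length(candidates))
    stop("none of the candidate channels exist in this night: ",
         paste(unknown, collapse = ", "))
  candidates <- setdiff(candidates, unknown)
  q <- night$channel_quality[candidates]
  if (all(q < quality_threshold)) return(NA_character_)
  candidates[which.max(q)] # which.max takes the first maximum: tie rule
}

#' Build the artifact-free N2/N3 analysis mask
#'
#' Divides the (already 0.3-40 Hz filtered) trace into 30-s epochs on a
#' grid anchored at recording start, demeans each epoch, and marks an
#' epoch usable when its stage is N2 or N3 and the demeaned trace never
#' exceeds the rejection threshold in absolute value. Rejected epochs
#' carry a reason code: `not_N2N3` or `amplitude_artifact` (stage gating
#' is applied first, so a noisy REM epoch is reported as `not_N2N3`).
#'
#' @param x numeric filtered trace, microvolts.
#' @param fs sampling rate, Hz.
#' @param hyp a [hypnogram] aligned to the recording start. The signal
#'   must cover all but at most one trailing epoch.
#' @param reject_uV amplitude-artifact threshold on `|demeaned sample|`
#'   (default 200).
#' @return A tibble of class `analysis_mask` with columns `epoch`
#'   (1-based), `stage`, `usable` (logical) and `reason`
#'   (`NA` for usable epochs).
#' @export
build_analysis_mask <- function(x, fs, hyp, reject_uV = 200) {
  stopifnot(inherits(hyp, "hypnogram"), fs > 0)
  ns <- round(hyp$epoch_len_s * fs)
  n_ep <- length(hyp$stages)
  if (length(x) < (n_ep - 1L) * ns)
    stop("signal and hypnogram are misaligned: signal covers ",
         floor(length(x) / ns), " epochs but hypnogram has ", n_ep)
  usable <- logical(n_ep)
  reason <- rep(NA_character_, n_ep)
  for (i in seq_len(n_ep)) {
    if (!hyp$stages[i] %in% c("N2", "N3")) {
      reason[i] <- "not_N2N3"
      next
    }
    i0 <- (i - 1L) * ns + 1L
    i1 <- min(i * ns, length(x))
    if (i0 > length(x)) { # hypnogram one epoch longer than the signal
      reason[i] <- "amplitude_artifact"
      next
    }
    seg <- x[i0:i1]
    if (max(abs(seg - mean(seg))) > reject_uV) {
      reason[i] <- "amplitude_artifact"
    } else {
      usable[i] <- TRUE
    }
  }
  out <- tibble::tibble(epoch = seq_len(n_ep), stage = hyp$stages,
                        usable = usable, reason = reason)
  class(out) <- c("analysis_mask", class(out))
  attr(out, "epoch_len_s") <- hyp$epoch_len_s
  attr(out, "fs") <- fs
  out
}

# sample-level logical vector: TRUE where the sample lies in a usable epoch
mask_samples <- function(mask, n_samples, fs) {
  ep_len <- attr(mask, "epoch_len_s")
  ns <- round(ep_len * fs)
  ok <- rep(rep(mask$usable, each = 1L), times = 1L)
  full <- rep(ok, each = ns)
  length(full) <- n_samples # pad with NA then convert
  full[is.na(full)] <- FALSE
  full
}
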