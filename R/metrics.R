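#' Total sleep time from stage minutes
#'
#' TST is by definition the sum of minutes scored in the four sleep
#' stages (N1 + N2 + N3 + REM); wake does not count. Kept as a separate
#' helper so the identity can be applied directly to stage-duration
#' summaries (per night or to cohort means, by linearity) as well as
#' inside [compute_macro_metrics].
#'
#' @param n1_min,n2_min,n3_min,rem_min stage minutes.
#' @return Total sleep time in minutes.
#' @export
tst_from_stages <- function(n1_min, n2_min, n3_min, rem_min) {
  n1_min + n2_min + n3_min + rem_min
}

#' Macroarchitecture metrics for one night
#'
#' Standard hypnogram summaries: stage minutes (0.5 min per 30-s epoch),
#' total sleep time, wake after sleep onset (wake minutes between the
#' first and last non-wake epoch), number of awakenings (maximal wake
#' runs within that span), and sleep efficiency
#' (100 x TST / time in bed, with time in bed the full hypnogram span).
#' A hypnogram with no sleep epochs yields zero TST, zero WASO and zero
#' efficiency rather than an error.
#'
#' @param hyp a [hypnogram].
#' @return A one-row tibble: `n1_min`, `n2_min`, `n3_min`, `rem_min`,
#'   `tst_min`, `waso_min`, `n_awakenings`, `sleep_efficiency`,
#'   `n2n3_min`, `tib_min`.
#' @export
compute_macro_metrics <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  sm <- stage_minutes(hyp)
  tst <- tst_from_stages(sm[["N1"]], sm[["N2"]], sm[["N3"]], sm[["REM"]])
  tib <- length(hyp$stages) * hyp$epoch_len_s / 60
  sleep_idx <- which(hyp$stages != "W")
  if (length(sleep_idx) == 0L) {
    waso <- 0; nawk <- 0L; eff <- 0
  } else {
    span <- hyp$stages[min(sleep_idx):max(sleep_idx)]
    wake_runs <- rle(span == "W")
    waso <- sum(span == "W") * hyp$epoch_len_s / 60
    nawk <- sum(wake_runs$values)
    eff <- 100 * tst / tib
  }
  tibble::tibble(n1_min = sm[["N1"]], n2_min = sm[["N2"]],
                 n3_min = sm[["N3"]], rem_min = sm[["REM"]],
                 tst_min = tst, waso_min = waso,
                 n_awakenings = as.integer(nawk),
                 sleep_efficiency = eff,
                 n2n3_min = sm[["N2"]] + sm[["N3"]], tib_min = tib)
}

#' Event density per minute of N2+N3 sleep
#'
#' Density is the event count divided by minutes scored as N2 or N3 —
#' the scored stage minutes, not the artifact-free minutes, following
#' the conventional definition (a config switch selects the
#' artifact-free variant).
#'
#' @param events event tibble (from a detector or ground truth) with a
#'   `type` column.
#' @param hyp the night's [hypnogram].
#' @param kind `"SO"` or `"spindle"`.
#' @param mask optional `analysis_mask`; required when
#'   `denominator = "artifact_free"`.
#' @param denominator `"scored"` (default) or `"artifact_free"`.
#' @return Events per minute.
#' @export
compute_density <- function(events, hyp, kind = c("SO", "spindle"),
                            mask = NULL,
                            denominator = c("scored", "artifact_free")) {
  kind <- match.arg(kind)
  denominator <- match.arg(denominator)
  sm <- stage_minutes(hyp)
  mins <- sm[["N2"]] + sm[["N3"]]
  if (denominator == "artifact_free") {
    if (is.null(mask)) stop("mask required for the artifact-free denominator")
    mins <- sum(mask$usable) * hyp$epoch_len_s / 60
  }
  if (mins <= 0)
    stop("density undefined: no N2+N3 minutes in this night")
  sum(events$type == kind) / mins
}

#' Apply night- and participant-level exclusion rules
#'
#' Feasibility screening mirrors the two-stage rule used for in-home
#' recordings: first drop any night whose best candidate channel falls
#' below the quality threshold, then drop participants left with fewer
#' than `min_nights` surviving nights. Every dropped row is logged with
#' a reason code (`low_channel_quality` or `too_few_nights`).
#'
#' @param nights tibble with at least `participant_id`, `night_index` and
#'   `best_quality` (the best candidate-channel quality fraction; `NA`
#'   counts as below threshold).
#' @param min_nights minimum surviving nights per participant (default 4).
#' @param quality_threshold minimum channel quality (default 0.5).
#' @return A list: `retained` (tibble) and `log` (tibble with
#'   `participant_id`, `night_index`, `reason`).
#' @export
apply_exclusions <- function(nights, min_nights = 4L,
                             quality_threshold = 0.5) {
  need <- c("participant_id", "night_index", "best_quality")
  if (nrow(nights) == 0) {
    return(list(retained = nights,
                log = tibble::tibble(participant_id = character(0),
                                     night_index = integer(0),
                                     reason = character(0))))
  }
  stopifnot(all(need %in% names(nights)))
  bad_q <- is.na(nights$best_quality) |
    nights$best_quality < quality_threshold
  log1 <- tibble::tibble(participant_id = nights$participant_id[bad_q],
                         night_index = nights$night_index[bad_q],
                         reason = "low_channel_quality")
  keep <- nights[!bad_q, , drop = FALSE]
  counts <- table(keep$participant_id)
  few <- names(counts)[counts < min_nights]
  bad_p <- keep$participant_id %in% few
  log2 <- tibble::tibble(participant_id = keep$participant_id[bad_p],
                         night_index = keep$night_index[bad_p],
                         reason = "too_few_nights")
  list(retained = keep[!bad_p, , drop = FALSE],
       log = rbind(log1, log2))
}
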