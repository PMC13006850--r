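#' Score one Go/NoGo session
#'
#' Reaction time is the mean RT over correct responses on "go" trials,
#' with responses faster than `rt_min_ms` or slower than `rt_max_ms`
#' excluded as outliers (strictly below/above: boundary values are
#' kept). Hit rate is the percentage of "go" trials answered correctly;
#' commission rate is the percentage of "no go" trials that drew a
#' response (a failure of inhibition). When no valid go RT survives the
#' filter, `gng_rt_ms` is `NA` so the day can be dropped from RT models
#' downstream.
#'
#' @param trials tibble of trials with columns `condition` (`"go"` /
#'   `"nogo"`), `responded` (logical), `correct` (logical), `rt_ms`
#'   (numeric, `NA` when no response).
#' @param rt_min_ms,rt_max_ms outlier bounds, ms (defaults 200 and 900).
#' @return One-row tibble: `gng_rt_ms`, `gng_hit_pct`, `commission_pct`,
#'   `n_go`, `n_nogo`.
#' @export
score_gonogo <- function(trials, rt_min_ms = 200, rt_max_ms = 900) {
  go <- trials[trials$condition == "go", , drop = FALSE]
  nogo <- trials[trials$condition == "nogo", , drop = FALSE]
  if (nrow(go) == 0 || nrow(nogo) == 0)
    stop("a Go/NoGo session needs at least one go and one nogo trial")
  rts <- go$rt_ms[go$correct & go$responded]
  rts <- rts[!is.na(rts) & rts >= rt_min_ms & rts <= rt_max_ms]
  tibble::tibble(
    gng_rt_ms = if (length(rts)) mean(rts) else NA_real_,
    gng_hit_pct = 100 * mean(go$correct),
    commission_pct = 100 * mean(nogo$responded),
    n_go = nrow(go), n_nogo = nrow(nogo))
}

#' Score one Simon switch session
#'
#' Reaction-time cells use correct responses with RT within
#' `[rt_min_ms, rt_max_ms]` (strict below/above exclusion; 300-3000 ms
#' by default). The Simon effect on RT is
#' `mean(incongruent) - mean(congruent)`; the switch effect on RT is
#' `mean(switch) - mean(non-switch)`. Accuracy effects are differences
#' of percent correct, oriented so that the usual pattern (worse
#' accuracy on incongruent trials, better on non-switch trials) gives a
#' negative Simon accuracy effect and a positive switch accuracy effect:
#' `incongruent - congruent` and `non-switch - switch` respectively.
#' Both orientations exist in the literature; flip
#' `simon_acc_orientation` / `switch_acc_orientation` to get the other
#' convention. The first trial of each block carries no switch label
#' (`switch = NA`) and is excluded from switch cells.
#'
#' @param trials tibble with columns `congruency` (`"congruent"` /
#'   `"incongruent"`), `switch` (`"switch"` / `"nonswitch"` / `NA` for
#'   block-initial trials), `responded`, `correct`, `rt_ms`.
#' @param rt_min_ms,rt_max_ms RT outlier bounds, ms.
#' @param rt_correct_only restrict RT cells to correct responses
#'   (default TRUE).
#' @param simon_acc_orientation `"incongruent_minus_congruent"` (default)
#'   or `"congruent_minus_incongruent"`.
#' @param switch_acc_orientation `"nonswitch_minus_switch"` (default) or
#'   `"switch_minus_nonswitch"`.
#' @return One-row tibble: `simon_effect_rt_ms`, `simon_effect_acc_pct`,
#'   `switch_effect_rt_ms`, `switch_effect_acc_pct`. Cells with no valid
#'   trials propagate `NA` (missing-day marker).
#' @export
score_simon_switch <- function(trials, rt_min_ms = 300, rt_max_ms = 3000,
                               rt_correct_only = TRUE,
                               simon_acc_orientation =
                                 c("incongruent_minus_congruent",
                                   "congruent_minus_incongruent"),
                               switch_acc_orientation =
                                 c("nonswitch_minus_switch",
                                   "switch_minus_nonswitch")) {
  simon_acc_orientation <- match.arg(simon_acc_orientation)
  switch_acc_orientation <- match.arg(switch_acc_orientation)
  cell_rt <- function(sel) {
    tt <- trials[sel & trials$responded, , drop = FALSE]
    if (rt_correct_only) tt <- tt[tt$correct, , drop = FALSE]
    r <- tt$rt_ms[!is.na(tt$rt_ms) & tt$rt_ms >= rt_min_ms &
                    tt$rt_ms <= rt_max_ms]
    if (length(r)) mean(r) else NA_real_
  }
  cell_acc <- function(sel) {
    tt <- trials[sel, , drop = FALSE]
    if (nrow(tt)) 100 * mean(tt$correct) else NA_real_
  }
  inc <- trials$congruency == "incongruent"
  con <- trials$congruency == "congruent"
  sw <- !is.na(trials$switch) & trials$switch == "switch"
  ns <- !is.na(trials$switch) & trials$switch == "nonswitch"
  simon_rt <- cell_rt(inc) - cell_rt(con)
  switch_rt <- cell_rt(sw) - cell_rt(ns)
  simon_acc <- cell_acc(inc) - cell_acc(con)
  if (simon_acc_orientation == "congruent_minus_incongruent")
    simon_acc <- -simon_acc
  switch_acc <- cell_acc(ns) - cell_acc(sw)
  if (switch_acc_orientation == "switch_minus_nonswitch")
    switch_acc <- -switch_acc
  tibble::tibble(simon_effect_rt_ms = simon_rt,
                 simon_effect_acc_pct = simon_acc,
                 switch_effect_rt_ms = switch_rt,
                 switch_effect_acc_pct = switch_acc)
}
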