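#' Per-participant means and SDs across nights/days
#'
#' Means characterise between-participant differences; standard
#' deviations across nights characterise within-participant variability.
#' Both are computed over non-missing entries only; a participant with a
#' single observation gets an `NA` SD (flagged missing rather than 0).
#'
#' @param data tibble with a `participant_id` column and numeric metric
#'   columns.
#' @param vars character vector of columns to summarise; defaults to all
#'   numeric columns except identifiers.
#' @return Tibble: one row per participant, `<var>_mean` and `<var>_sd`
#'   columns.
#' @export
summarize_participants <- function(data, vars = NULL) {
  stopifnot("participant_id" %in% names(data))
  if (is.null(vars)) {
    num <- vapply(data, is.numeric, logical(1))
    vars <- setdiff(names(data)[num], c("night_index", "day"))
  }
  ids <- unique(data$participant_id)
  rows <- lapply(ids, function(id) {
    d <- data[data$participant_id == id, , drop = FALSE]
    out <- list(participant_id = id)
    for (v in vars) {
      x <- d[[v]][!is.na(d[[v]])]
      out[[paste0(v, "_mean")]] <- if (length(x)) mean(x) else NA_real_
      out[[paste0(v, "_sd")]] <- if (length(x) > 1) sd(x) else NA_real_
    }
    tibble::as_tibble(out)
  })
  do.call(rbind, rows)
}

#' Two-tailed correlation between participant-level summaries
#'
#' Pearson, or Spearman implemented as the Pearson machinery applied to
#' rank-transformed data (two-tailed t-test on the coefficient in both
#' cases).
#'
#' @param x,y numeric vectors, length >= 3, finite.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r`, `p`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("correlation needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance in input")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-15))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, p = min(p, 1), n = n, method = method)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values (monotone in the
#' ranks; adjusted values never fall below the raw ones).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
fdr_adjust <- function(pvals) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Intraclass correlation from variance components
#'
#' `ICC = var_between / (var_between + var_within)`: the share of total
#' outcome variance attributable to stable between-participant
#' differences. High values favour designs with more participants and
#' fewer repeats; low values the reverse.
#'
#' @param var_between participant random-intercept variance (>= 0).
#' @param var_within residual variance (>= 0).
#' @return ICC in `[0, 1]`.
#' @export
icc_from_variances <- function(var_between, var_within) {
  if (var_between < 0 || var_within < 0)
    stop("variance components must be non-negative")
  if (var_between + var_within == 0)
    stop("ICC undefined when both variance components are zero")
  var_between / (var_between + var_within)
}

#' Latent intraclass correlation for models without a residual variance
#'
#' Zero-inflated beta (and other non-Gaussian) mixed models estimate no
#' residual variance; the latent ICC substitutes a fixed latent-scale
#' residual: `var_between / (var_between + latent_scale)`. The
#' conventional latent logistic scale of 1 is the default; the logistic
#' distribution variance `pi^2 / 3` is offered as an alternative
#' convention.
#'
#' @param var_between random-intercept variance on the latent scale.
#' @param latent_scale latent residual scale (default 1).
#' @return Latent ICC in `[0, 1]`.
#' @export
latent_icc <- function(var_between, latent_scale = 1) {
  stopifnot(var_between >= 0, latent_scale > 0)
  var_between / (var_between + latent_scale)
}
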