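#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of sleep-stage labels for one
#' night, scored in fixed-length epochs (30 s by convention). It is the
#' time base for all macroarchitecture metrics and for event densities.
#'
#' @param stages character vector of stage labels, each one of
#'   `"W"`, `"N1"`, `"N2"`, `"N3"`, `"REM"`.
#' @param epoch_len_s epoch length in seconds (default 30).
#' @return An object of class `hypnogram`: a list with elements `stages`
#'   (character) and `epoch_len_s`.
#' @export
hypnogram <- function(stages, epoch_len_s = 30) {
  stages <- as.character(stages)
  if (length(stages) < 1L)
    stop("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(stages), STAGES)
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, epoch_len_s = epoch_len_s),
            class = "hypnogram")
}

#' @exportS3Method base::print
print.hypnogram <- function(x, ...) {
  mins <- table(factor(x$stages, levels = STAGES)) * x$epoch_len_s / 60
  cat("<hypnogram> ", length(x$stages), " epochs of ", x$epoch_len_s,
      " s (", round(length(x$stages) * x$epoch_len_s / 60, 1), " min)\n",
      sep = "")
  cat("  minutes:", paste(sprintf("%s=%.1f", names(mins), mins),
                          collapse = " "), "\n")
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' Minutes scored in each stage
#'
#' @param hyp a [hypnogram].
#' @return Named numeric vector of minutes per stage (W, N1, N2, N3, REM).
#' @export
stage_minutes <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  cnt <- table(factor(hyp$stages, levels = STAGES))
  m <- as.numeric(cnt) * hyp$epoch_len_s / 60
  names(m) <- STAGES
  m
}

#' Specification for a Markov-chain hypnogram generator
#'
#' Nightly stage sequences are emulated as a first-order Markov chain over
#' the five AASM stages. The default transition matrix (see
#' [default_transition_matrix]) is calibrated so that a full simulated
#' night (960 epochs = 8 h) reproduces, on average, the macro-architecture
#' scale reported for healthy older adults: roughly 64 min of N3,
#' ~48 min of wake after sleep onset, and a total sleep time around
#' 420 min.
#'
#' @param transition_matrix 5x5 row-stochastic matrix with dimnames
#'   `W, N1, N2, N3, REM` (rows: from; columns: to). Each row must sum to
#'   1 within 1e-9.
#' @param n_epochs number of 30-s epochs to generate (> 0).
#' @param initial_stage stage label for the first epoch.
#' @param seed integer seed; the generated sequence is a deterministic
#'   function of the spec including the seed.
#' @param epoch_len_s epoch length in seconds.
#' @return An object of class `hypnogram_spec`.
#' @export
hypnogram_spec <- function(transition_matrix = default_transition_matrix(),
                           n_epochs = 960L,
                           initial_stage = "W",
                           seed = 1L,
                           epoch_len_s = 30) {
  P <- as.matrix(transition_matrix)
  if (!all(dim(P) == c(5L, 5L)))
    stop("transition_matrix must be 5x5 over stages W, N1, N2, N3, REM")
  if (is.null(rownames(P)) || !setequal(rownames(P), STAGES))
    stop("transition_matrix must carry stage dimnames W, N1, N2, N3, REM")
  P <- P[STAGES, STAGES]
  if (any(P < 0))
    stop("transition probabilities must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-9))
    stop("each transition-matrix row must sum to 1 (tolerance 1e-9)")
  if (!is.numeric(n_epochs) || n_epochs < 1)
    stop("n_epochs must be a positive integer")
  if (!initial_stage %in% STAGES)
    stop("initial_stage must be one of ", paste(STAGES, collapse = ", "))
  structure(list(transition_matrix = P, n_epochs = as.integer(n_epochs),
                 initial_stage = initial_stage, seed = as.integer(seed),
                 epoch_len_s = epoch_len_s),
            class = "hypnogram_spec")
}

#' Default sleep-stage transition matrix
#'
#' Constructed from a target stationary distribution `pi` (fractions of
#' time in bed spent per stage) and per-stage persistence probabilities
#' `p` via `P = diag(p) + (1 - p) q'` with jump distribution
#' `q_j` proportional to `pi_j (1 - p_j)`, which makes `pi` the exact
#' stationary distribution while keeping stage bouts geometrically
#' distributed with realistic mean lengths (e.g. wake bouts of a few
#' minutes, long consolidated N2 bouts).
#'
#' @param pi target stationary stage fractions (named, sums to 1).
#' @param persistence per-stage self-transition probabilities (named).
#' @return A 5x5 row-stochastic matrix with stage dimnames.
#' @export
default_transition_matrix <- function(
    pi = c(W = 0.1050, N1 = 0.0742, N2 = 0.4547, N3 = 0.1377, REM = 0.2284),
    persistence = c(W = 0.80, N1 = 0.55, N2 = 0.93, N3 = 0.90, REM = 0.92)) {
  stopifnot(setequal(names(pi), STAGES), setequal(names(persistence), STAGES))
  pi <- pi[STAGES] / sum(pi)
  p <- persistence[STAGES]
  q <- pi * (1 - p)
  q <- q / sum(q)
  P <- diag(p) + (1 - p) %*% t(q)
  dimnames(P) <- list(STAGES, STAGES)
  P
}

#' Stationary distribution of a stage transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalised
#' to sum to 1. Long-run stage fractions of the simulated chain converge
#' to this distribution.
#'
#' @param P row-stochastic transition matrix.
#' @return Named numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  names(v) <- rownames(P)
  v
}

#' Generate a hypnogram from a Markov-chain specification
#'
#' @param spec a [hypnogram_spec].
#' @return A [hypnogram] of `spec$n_epochs` epochs. Deterministic given
#'   the spec's seed.
#' @export
generate_hypnogram <- function(spec) {
  stopifnot(inherits(spec, "hypnogram_spec"))
  P <- spec$transition_matrix
  n <- spec$n_epochs
  out <- character(n)
  out[1] <- spec$initial_stage
  if (n > 1L) {
    # draw all uniforms at once; invert each row's CDF
    cum <- t(apply(P, 1, cumsum))
    set.seed(spec$seed)
    u <- runif(n - 1L)
    for (i in 2:n) {
      out[i] <- STAGES[which(u[i - 1L] <= cum[out[i - 1L], ])[1L]]
    }
  }
  hypnogram(out, epoch_len_s = spec$epoch_len_s)
}
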