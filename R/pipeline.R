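#' Default pipeline configuration
#'
#' All thresholds of the analysis surface here with their standard
#' values: 0.3-40 Hz / 300th-order preprocessing filter, 200 uV epoch
#' rejection, 50% channel-quality threshold, minimum 4 usable nights per
#' participant, SO criteria 33/61 uV and 125/1500/1000 ms, spindle
#' duration 0.5-2.5 s, Go/NoGo RT bounds 200-900 ms, Simon RT bounds
#' 300-3000 ms.
#'
#' @param n_participants,nights_per_participant,n_epochs simulated
#'   cohort size and night length (epochs of 30 s).
#' @param seed master seed.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(n_participants = 3L,
                                    nights_per_participant = 4L,
                                    n_epochs = 10L,
                                    seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      n_participants = as.integer(n_participants),
      nights_per_participant = as.integer(nights_per_participant),
      n_epochs = as.integer(n_epochs),
      fs = 250,
      low_quality_prob = 0,
      write_edf = FALSE),
    filter = list(lo = 0.3, hi = 40, order = 300L),
    reject_uV = 200,
    quality_threshold = 0.5,
    min_nights = 4L,
    candidate_channels = c("F7-O1", "F8-O2", "Fpz-O1", "Fpz-O2"),
    behavior = list(beta0 = 430,
                    betas = list(so_density = 0, spindle_density = 0,
                                 waso = 0),
                    var_between = 2404.27, var_within = 1440.80,
                    family = "gaussian"),
    model = list(outcome = "outcome",
                 predictors = c("so_density", "spindle_density", "waso"),
                 family = "gaussian"))
}

validate_pipeline_config <- function(cfg) {
  fail <- function(...) stop("config schema error: ", ..., call. = FALSE)
  for (k in c("seed", "simulate", "filter", "quality_threshold",
              "min_nights", "behavior", "model"))
    if (is.null(cfg[[k]])) fail("missing key '", k, "'")
  q <- cfg$quality_threshold
  if (!is.numeric(q) || q < 0 || q > 1)
    fail("quality_threshold must lie in [0, 1], got ", q)
  if (cfg$min_nights < 1) fail("min_nights must be >= 1")
  if (cfg$filter$lo <= 0 || cfg$filter$hi <= cfg$filter$lo)
    fail("filter band must satisfy 0 < lo < hi")
  if (!is.null(cfg$reject_uV) && cfg$reject_uV <= 0)
    fail("reject_uV must be positive")
  sim <- cfg$simulate
  if (sim$n_participants < 1 || sim$nights_per_participant < 1 ||
      sim$n_epochs < 1)
    fail("simulate sizes must be positive")
  if (!cfg$model$family %in% c("gaussian", "beta_zi"))
    fail("model family must be 'gaussian' or 'beta_zi'")
  invisible(TRUE)
}

#' Run the full synthetic study pipeline
#'
#' Orchestrates simulate -> preprocess -> detect -> metrics ->
#' exclusions -> behavior -> model as one reproducible run. Each
#' participant-night gets an independent sub-seed derived from the
#' master seed, so identical config + seed gives byte-identical outputs.
#' Stage outputs are written as tidy CSVs under `out_dir`, and a run
#' manifest (JSON) records the config hash, seeds, per-stage row counts
#' and the package version; counts reconcile across stages
#' (simulated = retained + excluded).
#'
#' @param config configuration list (see [default_pipeline_config]) or
#'   path to a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress.
#' @return The manifest list, invisibly; all outputs on disk.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  base <- default_pipeline_config()
  cfg <- utils::modifyList(base, cfg)
  validate_pipeline_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[somnocog] ", ...)

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, cfg_file)
  cfg_hash <- as.character(tools::md5sum(cfg_file))
  unlink(cfg_file)

  sim <- cfg$simulate
  fs <- sim$fs
  inj_args <- sim$injection %||% list()
  night_rows <- list()
  event_rows <- list()
  det_rows <- list()
  gidx <- 0L
  say("simulate + detect: ", sim$n_participants, " participants x ",
      sim$nights_per_participant, " nights")
  for (p in seq_len(sim$n_participants)) {
    pid <- sprintf("P%02d", p)
    for (ni in seq_len(sim$nights_per_participant)) {
      gidx <- gidx + 1L
      sseed <- derive_seed(cfg$seed, gidx)
      hyp <- generate_hypnogram(hypnogram_spec(n_epochs = sim$n_epochs,
                                               initial_stage = "W",
                                               seed = sseed))
      inj <- do.call(event_injection_spec,
                     c(inj_args, list(seed = derive_seed(cfg$seed,
                                                         gidx + 10000L))))
      syn <- synthesize_night(hyp, inj, fs = fs,
                              participant_id = pid,
                              night_id = sprintf("%s_n%02d", pid, ni))
      night <- syn$night
      # optional degraded-quality nights to exercise the exclusion rules
      set.seed(derive_seed(cfg$seed, gidx + 20000L))
      if (runif(1) < sim$low_quality_prob)
        night$channel_quality[] <- runif(1, 0.2, 0.45)
      if (isTRUE(sim$write_edf))
        write_edf(night, file.path(out_dir,
                                   sprintf("%s_n%02d.edf", pid, ni)))
      ch <- select_best_channel(night, cfg$candidate_channels,
                                cfg$quality_threshold)
      best_q <- suppressWarnings(
        max(night$channel_quality[intersect(cfg$candidate_channels,
                                            names(night$channel_quality))],
            na.rm = TRUE))
      macro <- compute_macro_metrics(hyp)
      row <- tibble::tibble(participant_id = pid, night_index = ni,
                            best_quality = best_q, channel = ch)
      if (!is.na(ch)) {
        x <- fir_bandpass(night$signal[, ch], fs, cfg$filter$lo,
                          cfg$filter$hi, cfg$filter$order)
        mask <- build_analysis_mask(x, fs, hyp, cfg$reject_uV)
        so <- detect_slow_oscillations(x, fs, mask)
        sp <- detect_spindles(x, fs, mask)
        so$channel <- ch; sp$channel <- ch
        det <- rbind(so[, c("type", "onset_s", "duration_s", "channel")],
                     sp[, c("type", "onset_s", "duration_s", "channel")])
        det$participant_id <- pid; det$night_index <- ni
        det_rows[[gidx]] <- det
        has_n2n3 <- macro$n2n3_min > 0
        row <- cbind(row, macro,
                     tibble::tibble(
                       so_density = if (has_n2n3)
                         compute_density(so, hyp, "SO") else NA_real_,
                       spindle_density = if (has_n2n3)
                         compute_density(sp, hyp, "spindle") else NA_real_,
                       so_amp_uV = if (nrow(so)) mean(so$p2p_uV) else NA_real_,
                       spindle_dur_s = if (nrow(sp)) mean(sp$duration_s)
                                       else NA_real_,
                       spindle_amp_uV = if (nrow(sp)) mean(sp$env_amp_uV)
                                        else NA_real_))
      } else {
        row <- cbind(row, macro,
                     tibble::tibble(so_density = NA_real_,
                                    spindle_density = NA_real_,
                                    so_amp_uV = NA_real_,
                                    spindle_dur_s = NA_real_,
                                    spindle_amp_uV = NA_real_))
      }
      night_rows[[gidx]] <- row
      gt <- syn$events
      gt$participant_id <- pid; gt$night_index <- ni
      event_rows[[gidx]] <- gt
    }
  }
  nights <- do.call(rbind, night_rows)
  ground_truth <- do.call(rbind, event_rows)
  detections <- do.call(rbind, det_rows)

  say("exclusions")
  excl <- apply_exclusions(nights, cfg$min_nights, cfg$quality_threshold)
  retained <- excl$retained

  say("behavior simulation + model fit on ", nrow(retained), " nights")
  preds <- tibble::tibble(participant = retained$participant_id,
                          day = retained$night_index,
                          so_density = retained$so_density,
                          spindle_density = retained$spindle_density,
                          waso = retained$waso_min)
  # nights with undefined metrics (e.g. no N2/N3 sleep) are excluded from
  # the behavioral model, mirroring listwise day deletion
  preds <- preds[stats::complete.cases(preds), , drop = FALSE]
  beh <- cfg$behavior
  bspec <- behavior_sim_spec(
    n_participants = length(unique(preds$participant)),
    n_days = max(preds$day),
    beta0 = beh$beta0,
    betas = unlist(beh$betas),
    var_between = beh$var_between, var_within = beh$var_within,
    family = if (identical(beh$family, "beta_zi")) "beta" else beh$family,
    seed = derive_seed(cfg$seed, 30000L))
  outcomes <- simulate_behavior(bspec, preds, design = "predictors")

  model <- NULL
  model_days <- 0L
  model_warnings <- character(0)
  if (nrow(outcomes) > 0 &&
      length(unique(outcomes$participant)) >= 2) {
    model <- withCallingHandlers(
      tryCatch(
        fit_glmm(outcomes, cfg$model$outcome, cfg$model$predictors,
                 cfg$model$family),
        error = function(e) {
          say("model stage failed: ", conditionMessage(e))
          NULL
        }),
      warning = function(w) {
        model_warnings <<- c(model_warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    model_days <- nrow(outcomes)
  }

  wr <- function(d, name) {
    write.csv(as.data.frame(d), file.path(out_dir, name), row.names = FALSE)
    name
  }
  files <- c(wr(nights, "night_metrics.csv"),
             wr(excl$log, "exclusion_log.csv"),
             wr(ground_truth, "ground_truth_events.csv"),
             wr(detections, "detected_events.csv"),
             wr(outcomes, "behavior_outcomes.csv"))
  if (!is.null(model)) {
    files <- c(files, wr(model$fixed, "model_fixed_effects.csv"))
    icc_df <- data.frame(var_between = model$var_between,
                         var_within = model$var_within, icc = model$icc)
    files <- c(files, wr(icc_df, "model_icc.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("somnocog")),
    config_hash = cfg_hash,
    seed = cfg$seed,
    files = as.list(files),
    counts = list(
      nights_simulated = nrow(nights),
      nights_excluded = nrow(excl$log),
      nights_retained = nrow(retained),
      participants_retained = length(unique(retained$participant_id)),
      ground_truth_events = nrow(ground_truth),
      detected_events = if (is.null(detections)) 0L else nrow(detections),
      days_modelled = model_days),
    model_warnings = as.list(model_warnings))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: ", out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
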