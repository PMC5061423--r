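# Pipeline orchestration: simulate -> characterize -> correlate ->
# timefreq -> classify -> report, with config validation, stage caching
# and reproducible seeds.

# hold-resample a parameter series onto an arbitrary grid
series_on_grid <- function(p, grid_t) {
  v <- stats::approx(p$timestamps, p$values, xout = grid_t,
                     method = "constant", rule = 2, f = 0)$y
  parameter_series(p$name, grid_t, v)
}

#' Compute all characterizations of a session on its common grid
#'
#' Applies the long-term (Blinkcount, GSRSCL, LFHF, Meditation) and
#' short-term (GSRsiginc, Blinksiginc, medianRRI, alphaAsym)
#' characterizations available for the session's channels, plus the
#' preprocessed lever, and hold-resamples everything onto the session's
#' 10 Hz grid.
#'
#' @param session a [session()].
#' @param set `"all"`, `"short"` or `"long"`.
#' @param detector_cfg [slope_detector_config()] for the GSR encoder.
#' @param alpha_step_s step of the alpha-asymmetry sliding window, s.
#' @return named list of `parameter_series` on a common grid.
#' @export
characterize_session <- function(session, set = c("all", "short", "long"),
                                 detector_cfg = slope_detector_config(),
                                 alpha_step_s = 0.1) {
  set <- match.arg(set)
  st <- session$streams
  grid_t <- if ("gsr" %in% names(st)) st$gsr$timestamps else {
    dur <- max(vapply(st, function(s) max(s$timestamps), numeric(1)))
    seq(0, dur, by = 1 / session$grid_rate)
  }
  out <- list()
  want_long <- set %in% c("all", "long")
  want_short <- set %in% c("all", "short")
  has_eeg <- all(EEG_CHANNELS %in% names(st))
  if (want_long) {
    if ("blink_strength" %in% names(st))
      out$Blinkcount <- blink_count(detect_blink_events(st$blink_strength),
                                    duration = max(grid_t))
    if ("gsr" %in% names(st)) out$GSRSCL <- gsr_scl(st$gsr)
    if ("ibi_event" %in% names(st)) out$LFHF <- lfhf(st$ibi_event)
    if ("meditation" %in% names(st))
      out$Meditation <- meditation_series(st$meditation)
  }
  if (want_short) {
    if ("gsr" %in% names(st))
      out$GSRsiginc <- squarewave_to_grid(gsr_siginc(st$gsr, detector_cfg))
    if ("blink_strength" %in% names(st))
      out$Blinksiginc <- squarewave_to_grid(blink_siginc(st$blink_strength))
    if ("ibi_event" %in% names(st)) out$medianRRI <- median_rri(st$ibi_event)
    if (has_eeg)
      out$alphaAsym <- alpha_asymmetry(st[EEG_CHANNELS],
                                       step_s = alpha_step_s)
  }
  if ("lever" %in% names(st)) out$Lever <- lever_preprocess(st$lever)
  lapply(out, series_on_grid, grid_t = grid_t)
}

CONFIG_SCHEMA <- list(
  seed = 1L, out_dir = "pipeline_out",
  sim = list(n_participants = 3L, trials = 1L, loops = 1L, duration = 240,
             n_events = 4L, min_gap = 10, grid_rate = 10,
             modality = "autonomous", condition = "wide",
             channels = c("gsr", "ibi", "lever", "meditation", "blink",
                          "eeg")),
  detector = list(smooth_window_s = 1.0, slope_threshold_k = 3,
                  min_event_s = 0.5, merge_gap_s = 0.3),
  correlation = list(set = "short", reference = "Lever"),
  timefreq = list(z_rule = "ge2"),
  classification = list(label_sources = "GSRsiginc", intervals = 2,
                        methods = "LDA", modes = "all_channels"))

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], as.list(user[[nm]]),
                                     paste0(path, nm, "$"))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys, fills
#' defaults, and checks the classification grid against the tested
#' (source, interval) combinations. A missing seed gets the deterministic
#' default 1 (logged).
#'
#' @param config path to a YAML file or a named list.
#' @return validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!"seed" %in% names(config))
    message("no seed in config; using deterministic default 1")
  cfg <- merge_config(CONFIG_SCHEMA, config)
  cfg$seed <- as.integer(cfg$seed)
  cfg$sim$modality <- match.arg(cfg$sim$modality,
                                c("autonomous", "self_drive", "rest"))
  cl <- cfg$classification
  if (length(cl$label_sources))
    for (src in cl$label_sources) for (iv in cl$intervals)
      label_spec(src, iv)  # errors on untested (source, interval) pairs
  structure(cfg, class = c("pipeline_config", "list"))
}

config_to_simcfg <- function(cfg) {
  sim_config(n_participants = cfg$sim$n_participants,
             trials = cfg$sim$trials, loops = cfg$sim$loops,
             seed = cfg$seed, duration = cfg$sim$duration,
             n_events = cfg$sim$n_events, min_gap = cfg$sim$min_gap,
             grid_rate = cfg$sim$grid_rate, channels = cfg$sim$channels)
}

stage_hash <- function(obj) {
  f <- tempfile()
  jsonlite::write_json(obj, f, auto_unbox = TRUE, force = TRUE, digits = NA)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes simulate, characterize, correlate, timefreq and classify in
#' order on a synthetic cohort, writing per-stage CSV/JSON artifacts under
#' `config$out_dir` and returning a report with per-file checksums. Stages
#' whose inputs and config section are unchanged since the previous run
#' are resumed from their cached outputs; a failing stage is recorded and
#' its downstream stages skipped.
#'
#' @param config a [validate_config()] result (or anything it accepts).
#' @return list of class `run_report`: per-stage status, output files with
#'   md5 checksums, seed and warnings.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(out_dir, ".cache")
  dir.create(cache_dir, showWarnings = FALSE)
  report <- list(seed = cfg$seed, stages = list(), files = character(),
                 warnings = character())
  failed <- FALSE

  run_stage <- function(name, section, fn) {
    if (failed) {
      report$stages[[name]] <<- "skipped"
      return(NULL)
    }
    h <- stage_hash(list(seed = cfg$seed, section = section))
    hf <- file.path(cache_dir, paste0(name, ".md5"))
    marker <- file.path(cache_dir, paste0(name, ".done"))
    if (file.exists(hf) && file.exists(marker) &&
        readLines(hf, warn = FALSE)[1L] == h) {
      report$stages[[name]] <<- "cached"
      return(readRDS(marker))
    }
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- paste("failed:", conditionMessage(res))
      failed <<- TRUE
      return(NULL)
    }
    writeLines(h, hf)
    saveRDS(res, marker)
    report$stages[[name]] <<- "ok"
    res
  }

  cohort <- run_stage("simulate", cfg$sim, function() {
    sc <- config_to_simcfg(cfg)
    cohort <- simulate_cohort(sc, modality = cfg$sim$modality,
                              condition = cfg$sim$condition)
    sess_dir <- file.path(out_dir, "sessions")
    for (s in cohort) write_session(s, sess_dir)
    cohort
  })

  chars <- run_stage("characterize", cfg$detector, function() {
    dcfg <- do.call(slope_detector_config, cfg$detector)
    chars <- lapply(cohort, characterize_session, detector_cfg = dcfg,
                    alpha_step_s = 0.5)
    for (i in seq_along(cohort)) {
      ch <- chars[[i]]
      df <- data.frame(t = ch[[1L]]$timestamps)
      for (nm in names(ch)) df[[nm]] <- ch[[nm]]$values
      utils::write.csv(df, file.path(out_dir, paste0(
        session_stem(cohort[[i]]$meta), "_characterization.csv")),
        row.names = FALSE, na = "")
    }
    chars
  })

  run_stage("correlate", cfg$correlation, function() {
    keep_short <- c("GSRsiginc", "Blinksiginc", "medianRRI", "alphaAsym",
                    "Lever")
    keep_long <- c("Blinkcount", "GSRSCL", "LFHF", "Meditation", "Lever")
    keep <- if (cfg$correlation$set == "short") keep_short else keep_long
    for (i in seq_along(cohort)) {
      ser <- chars[[i]][intersect(keep, names(chars[[i]]))]
      if (length(ser) < 2L) next
      m <- spearman_map(ser, reference = cfg$correlation$reference)
      render_map(m, out = file.path(out_dir, paste0(
        session_stem(cohort[[i]]$meta), "_map.json")))
    }
    TRUE
  })

  run_stage("timefreq", cfg$timefreq, function() {
    rows <- list()
    for (i in seq_along(cohort)) {
      st <- cohort[[i]]$streams
      if (!all(EEG_CHANNELS %in% names(st))) next
      for (ch in EEG_CHANNELS) {
        bp <- eeg_bandpass(st[[ch]])
        bs <- condense_bands(spectrogram_01hz(bp))
        for (bn in names(TF_BANDS))
          rows[[length(rows) + 1L]] <- data.frame(
            condition = cohort[[i]]$meta$condition, band = bn,
            channel = ch, dataset = session_stem(cohort[[i]]$meta),
            variance = bs[[bn]]$variance)
      }
    }
    if (!length(rows)) return(NULL)
    vdf <- do.call(rbind, rows)
    tab <- variance_count_table(vdf, z_rule = cfg$timefreq$z_rule)
    utils::write.csv(tab, file.path(out_dir, "variance_counts.csv"),
                     row.names = FALSE)
    tab
  })

  run_stage("classify", cfg$classification, function() {
    cl <- cfg$classification
    if (!length(cl$label_sources)) {
      report$warnings <<- c(report$warnings,
                            "classification grid empty; stage skipped")
      return(NULL)
    }
    rows <- list()
    for (i in seq_along(cohort)) {
      st <- cohort[[i]]$streams
      if (!all(EEG_CHANNELS %in% names(st))) next
      eeg <- eeg_preprocess_cls(st[EEG_CHANNELS])
      for (src in cl$label_sources) for (iv in cl$intervals) {
        p <- switch(src,
          GSRsiginc = normalize_series(chars[[i]]$GSRsiginc),
          medianRRI = normalize_series(chars[[i]]$medianRRI),
          GSRSCL = normalize_series(chars[[i]]$GSRSCL),
          Meditation = chars[[i]]$Meditation,
          Joystick = joystick_r2(st$joystick_y))
        labs <- build_labels(p, label_spec(src, iv))
        if (length(unique(labs$label)) < 2L) next
        eps <- epoch_by_labels(eeg, labs)
        for (md in cl$modes) {
          fx <- alpha_ratio_features(eps, mode = md)
          for (me in cl$methods) {
            cv <- crossval_classify(fx$X, fx$y, method = me,
                                    seed = cfg$seed)
            rows[[length(rows) + 1L]] <- data.frame(
              label = src, interval_s = iv, mode = md, method = me,
              trial = cohort[[i]]$meta$trial,
              participant = cohort[[i]]$meta$participant_id,
              accuracy = cv$mean)
          }
        }
      }
    }
    if (!length(rows)) return(NULL)
    res <- do.call(rbind, rows)
    utils::write.csv(res, file.path(out_dir, "cv_results.csv"),
                     row.names = FALSE)
    tab <- build_accuracy_table(res)
    utils::write.csv(tab, file.path(out_dir, "accuracy_table.csv"),
                     row.names = FALSE)
    tab
  })

  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   list.files(cache_dir, full.names = TRUE))
  files <- files[!grepl("\\.cache", files) & basename(files) != "report.json"]
  report$files <- vapply(files, function(f) unname(tools::md5sum(f)),
                         character(1))
  names(report$files) <- sub(paste0("^", out_dir, "/?"), "", files)
  jsonlite::write_json(
    list(seed = report$seed, stages = report$stages,
         files = as.list(report$files), warnings = report$warnings),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "\n")
  for (nm in names(x$stages)) cat(sprintf("  %-12s %s\n", nm, x$stages[[nm]]))
  cat(" ", length(x$files), "output file(s)\n")
  invisible(x)
}
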