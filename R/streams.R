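#' Sensor stream container
#'
#' A `sensor_stream` holds one uniformly- or event-sampled channel: a vector
#' of timestamps (seconds since session start, strictly increasing), the
#' sample values in channel units, and the nominal sampling rate (0 for event
#' series such as inter-beat intervals, where each timestamp is a beat time
#' and each value the preceding RR interval in seconds).
#'
#' @param name channel identifier, e.g. `"gsr"`, `"F3"`.
#' @param timestamps numeric vector, seconds since session start, strictly
#'   increasing.
#' @param values numeric vector, same length as `timestamps`. `NA` marks an
#'   explicitly missing sample; non-finite values other than `NA` are
#'   rejected.
#' @param nominal_rate sampling rate in Hz; 0 for event series.
#' @param units unit string (`"uS"`, `"s"`, `"uV"`, `"au"`, ...).
#' @return an object of class `sensor_stream`.
#' @export
sensor_stream <- function(name, timestamps, values, nominal_rate, units = "au") {
  stopifnot(is.character(name), length(name) == 1L)
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values))
    stop("timestamps and values must have equal length for channel '", name, "'")
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing for channel '", name,
         "' (first offense at index ", which(diff(timestamps) <= 0)[1L] + 1L, ")")
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad))
    stop("non-finite values (use NA for missing) in channel '", name, "'")
  structure(
    list(name = name, timestamps = timestamps, values = values,
         nominal_rate = as.numeric(nominal_rate), units = units),
    class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  dur <- if (length(x$timestamps)) diff(range(x$timestamps)) else 0
  cat(sprintf("<sensor_stream '%s'> %d samples, %.1f s, %s Hz, units %s\n",
              x$name, length(x$values), dur,
              if (x$nominal_rate > 0) format(x$nominal_rate) else "event",
              x$units))
  invisible(x)
}

#' @export
length.sensor_stream <- function(x) length(x$values)

#' Session metadata
#'
#' Identifies one recording: participant, task modality (autonomous riding,
#' self-driving, or rest), corridor condition, trial and loop indices, and
#' per-device clock offsets used by [align_streams()].
#'
#' @param participant_id character id.
#' @param modality one of `"autonomous"`, `"self_drive"`, `"rest"`.
#' @param condition one of `"wide"`, `"narrow"`, `"none"`; rest sessions must
#'   use `"none"`.
#' @param trial,loop positive integers.
#' @param clock_offsets named numeric vector of per-channel clock offsets in
#'   seconds (empty means all zero).
#' @return an object of class `session_meta`.
#' @export
session_meta <- function(participant_id, modality, condition = "none",
                         trial = 1L, loop = 1L, clock_offsets = numeric()) {
  modality <- match.arg(modality, c("autonomous", "self_drive", "rest"))
  condition <- match.arg(condition, c("wide", "narrow", "none"))
  if (modality == "rest" && condition != "none")
    stop("rest sessions must have condition 'none'")
  if (modality != "rest" && condition == "none")
    stop("driving sessions require condition 'wide' or 'narrow'")
  stopifnot(trial >= 1L, loop >= 1L)
  structure(list(participant_id = as.character(participant_id),
                 modality = modality, condition = condition,
                 trial = as.integer(trial), loop = as.integer(loop),
                 clock_offsets = clock_offsets),
            class = "session_meta")
}

#' Aligned multimodal session
#'
#' Bundles all sensor streams of one participant/condition/trial/loop with
#' metadata and the rate of the common analysis grid.
#'
#' @param meta a [session_meta()] object.
#' @param streams named list of [sensor_stream()] objects (names must match
#'   each stream's own name).
#' @param grid_rate common analysis grid rate in Hz (default 10).
#' @param check_channels require the modality's mandatory channels to be
#'   present (set `FALSE` for deliberately partial bundles, e.g. EEG-only).
#' @return an object of class `session`.
#' @export
session <- function(meta, streams, grid_rate = 10, check_channels = TRUE) {
  stopifnot(inherits(meta, "session_meta"), is.list(streams))
  nm <- vapply(streams, function(s) s$name, character(1))
  names(streams) <- nm
  req <- if (check_channels) required_channels(meta$modality) else character()
  missing_ch <- setdiff(req, nm)
  if (length(missing_ch))
    stop("session is missing required channel(s) for modality '",
         meta$modality, "': ", paste(missing_ch, collapse = ", "))
  structure(list(meta = meta, streams = streams, grid_rate = grid_rate),
            class = "session")
}

required_channels <- function(modality) {
  switch(modality,
         autonomous = c("gsr", "ibi_event", "lever"),
         self_drive = c("gsr", "ibi_event", "joystick_y"),
         rest       = c("gsr", "ibi_event"))
}

#' @export
print.session <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<session> %s / %s / %s / trial %d / loop %d, grid %g Hz\n",
              m$participant_id, m$modality, m$condition, m$trial, m$loop,
              x$grid_rate))
  for (s in x$streams) print(s)
  invisible(x)
}

# EEG channel layout used throughout: left and right fronto-central strips.
EEG_LEFT <- c("F3", "FC3", "C3")
EEG_RIGHT <- c("F4", "FC4", "C4")
EEG_CHANNELS <- c(EEG_LEFT, EEG_RIGHT)

session_stem <- function(meta) {
  sprintf("%s_%s_%s_t%d_l%d", meta$participant_id, meta$modality,
          meta$condition, meta$trial, meta$loop)
}

#' Write a session to a directory of CSV files
#'
#' Emits up to three UTF-8 CSV files per session plus a `manifest.json`
#' mapping files to channels:
#' \itemize{
#'   \item `<stem>_grid.csv` — 10 Hz channels (`t`, `gsr`, `lever`,
#'     `joystick_y`, `meditation`, `blink_strength_binned`) plus the IBI
#'     event series stored sparsely (`ibi_event_t` exact beat time,
#'     `ibi_event` RR value, on the rows whose grid bin contains the beat).
#'   \item `<stem>_eeg.csv` — 256 Hz EEG channels F3, FC3, C3, F4, FC4, C4.
#'   \item `<stem>_blink.csv` — native 128 Hz blink strength.
#' }
#' File names are keyed by participant, modality, condition, trial and loop,
#' so two sessions differing only in metadata get distinct files.
#'
#' @param session a [session()].
#' @param root_path output directory (created if absent).
#' @return invisibly, the manifest: a named list mapping file names to the
#'   channels they contain.
#' @export
write_session <- function(session, root_path) {
  stopifnot(inherits(session, "session"))
  if (!dir.exists(root_path))
    dir.create(root_path, recursive = TRUE)
  if (file.access(root_path, 2L) != 0L)
    stop("cannot write to '", root_path, "'")
  stem <- session_stem(session$meta)
  st <- session$streams
  manifest <- list()

  grid_names <- intersect(
    c("gsr", "lever", "joystick_y", "meditation", "blink_strength_binned"),
    names(st))
  has_ibi <- "ibi_event" %in% names(st)
  if (length(grid_names) || has_ibi) {
    # all 10 Hz channels in a session share one grid; use the longest
    base <- if (length(grid_names)) {
      lens <- vapply(st[grid_names], length, integer(1))
      st[[grid_names[which.max(lens)]]]$timestamps
    } else {
      ibi <- st[["ibi_event"]]
      seq(0, max(ibi$timestamps), by = 1 / session$grid_rate)
    }
    df <- data.frame(t = base)
    for (nm in grid_names) {
      v <- rep(NA_real_, length(base))
      idx <- match(round(st[[nm]]$timestamps, 9), round(base, 9))
      if (anyNA(idx))
        stop("grid channel '", nm, "' is not on the session grid; ",
             "resample it before writing")
      v[idx] <- st[[nm]]$values
      df[[nm]] <- v
    }
    if (has_ibi) {
      ibi <- st[["ibi_event"]]
      bin <- findInterval(ibi$timestamps, c(base, Inf))
      if (anyNA(bin) || any(bin < 1L))
        stop("ibi_event beats precede the session grid")
      if (anyDuplicated(bin))
        stop("more than one beat per grid bin; increase grid rate")
      et <- rep(NA_real_, length(base)); ev <- rep(NA_real_, length(base))
      et[bin] <- ibi$timestamps; ev[bin] <- ibi$values
      df$ibi_event_t <- et; df$ibi_event <- ev
    }
    f <- file.path(root_path, paste0(stem, "_grid.csv"))
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     f, row.names = FALSE, quote = FALSE, na = "")
    manifest[[paste0(stem, "_grid.csv")]] <-
      c(grid_names, if (has_ibi) "ibi_event")
  }

  eeg_names <- intersect(EEG_CHANNELS, names(st))
  if (length(eeg_names)) {
    df <- data.frame(t = st[[eeg_names[1L]]]$timestamps)
    for (nm in eeg_names) df[[nm]] <- st[[nm]]$values
    f <- file.path(root_path, paste0(stem, "_eeg.csv"))
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     f, row.names = FALSE, quote = FALSE, na = "")
    manifest[[paste0(stem, "_eeg.csv")]] <- eeg_names
  }

  if ("blink_strength" %in% names(st)) {
    b <- st[["blink_strength"]]
    df <- data.frame(t = b$timestamps, blink_strength = b$values)
    f <- file.path(root_path, paste0(stem, "_blink.csv"))
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     f, row.names = FALSE, quote = FALSE, na = "")
    manifest[[paste0(stem, "_blink.csv")]] <- "blink_strength"
  }

  mpath <- file.path(root_path, "manifest.json")
  all_manifests <- if (file.exists(mpath))
    jsonlite::read_json(mpath, simplifyVector = TRUE) else list()
  all_manifests[names(manifest)] <- manifest
  jsonlite::write_json(all_manifests, mpath, auto_unbox = FALSE, digits = NA)
  invisible(manifest)
}

CHANNEL_UNITS <- c(gsr = "uS", ibi_event = "s", lever = "au",
                   joystick_y = "au", meditation = "au",
                   blink_strength_binned = "au", blink_strength = "au",
                   F3 = "uV", FC3 = "uV", C3 = "uV",
                   F4 = "uV", FC4 = "uV", C4 = "uV")

channel_units <- function(nm) {
  u <- CHANNEL_UNITS[nm]
  ifelse(is.na(u), "au", u)
}

read_channel_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  n0 <- nrow(df)
  ok <- is.finite(df$t)
  if (!all(ok)) {
    message(sum(!ok), " unparseable row(s) skipped in ", basename(path))
    df <- df[ok, , drop = FALSE]
  }
  if (nrow(df) > 1L && any(diff(df$t) <= 0))
    stop("non-monotone timestamps in ", basename(path),
         " (first offense at row ", which(diff(df$t) <= 0)[1L] + 1L, ")")
  df
}

#' Read a session from a directory written by [write_session()]
#'
#' @param root_path directory containing the CSV files.
#' @param meta a [session_meta()] identifying which session to load.
#' @param grid_rate grid rate of the stored 10 Hz channels.
#' @return a [session()], equal to the written one up to float round-trip.
#' @export
read_session <- function(root_path, meta, grid_rate = 10) {
  stem <- session_stem(meta)
  gf <- file.path(root_path, paste0(stem, "_grid.csv"))
  ef <- file.path(root_path, paste0(stem, "_eeg.csv"))
  bf <- file.path(root_path, paste0(stem, "_blink.csv"))
  streams <- list()

  if (file.exists(gf)) {
    df <- read_channel_csv(gf)
    for (nm in setdiff(names(df), c("t", "ibi_event", "ibi_event_t"))) {
      keep <- !is.na(df[[nm]])
      if (!any(keep)) next
      streams[[nm]] <- sensor_stream(nm, df$t[keep], df[[nm]][keep],
                                     grid_rate, channel_units(nm))
    }
    if ("ibi_event" %in% names(df)) {
      keep <- !is.na(df$ibi_event)
      if (any(keep)) {
        tt <- if ("ibi_event_t" %in% names(df)) df$ibi_event_t[keep]
              else df$t[keep]
        streams[["ibi_event"]] <- sensor_stream("ibi_event", tt,
                                                df$ibi_event[keep], 0, "s")
      }
    }
  }
  if (file.exists(ef)) {
    df <- read_channel_csv(ef)
    rate <- 1 / stats::median(diff(df$t))
    for (nm in intersect(EEG_CHANNELS, names(df)))
      streams[[nm]] <- sensor_stream(nm, df$t, df[[nm]], round(rate), "uV")
  }
  if (file.exists(bf)) {
    df <- read_channel_csv(bf)
    rate <- 1 / stats::median(diff(df$t))
    streams[["blink_strength"]] <- sensor_stream("blink_strength", df$t,
                                                 df$blink_strength,
                                                 round(rate), "au")
  }

  req <- required_channels(meta$modality)
  if (!file.exists(gf) && length(req))
    stop("missing mandatory file: ", basename(gf))
  missing_ch <- setdiff(req, names(streams))
  if (length(missing_ch))
    stop("required channel(s) empty or absent: ",
         paste(missing_ch, collapse = ", "))
  session(meta, streams, grid_rate = grid_rate, check_channels = FALSE)
}

#' Resample a stream onto a uniform grid
#'
#' @param stream a [sensor_stream()].
#' @param rate target rate in Hz.
#' @param method `"hold"` (last observation carried forward), `"linear"`
#'   (interpolation), or `"bin_mean"` (mean of the samples falling in each
#'   half-open bin `[t, t + 1/rate)`; empty bins are `NA`).
#' @return a [sensor_stream()] with timestamps `k/rate` spanning the input.
#' @export
resample_to_grid <- function(stream, rate, method = c("linear", "hold", "bin_mean")) {
  method <- match.arg(method)
  stopifnot(rate > 0, length(stream$values) > 0L)
  if (method == "linear" && stream$nominal_rate == 0 && length(stream$values) < 2L)
    stop("linear resampling of an event stream needs at least 2 events")
  t0 <- stream$timestamps[1L]
  tn <- stream$timestamps[length(stream$timestamps)]
  grid <- seq(ceiling(t0 * rate) / rate, tn, by = 1 / rate)
  v <- switch(method,
    hold = {
      idx <- findInterval(grid + 1e-12, stream$timestamps)
      ifelse(idx >= 1L, stream$values[pmax(idx, 1L)], NA_real_)
    },
    linear = stats::approx(stream$timestamps, stream$values, xout = grid,
                           rule = 2)$y,
    bin_mean = {
      bin <- findInterval(stream$timestamps, c(grid, tn + 1 / rate))
      out <- rep(NA_real_, length(grid))
      agg <- tapply(stream$values, bin, mean, na.rm = TRUE)
      ix <- as.integer(names(agg))
      keep <- ix >= 1L & ix <= length(grid)
      out[ix[keep]] <- as.numeric(agg)[keep]
      out
    })
  sensor_stream(stream$name, grid, v, rate, stream$units)
}

#' Align the streams of a session on a common clock
#'
#' Shifts each stream's timestamps by its entry in
#' `meta$clock_offsets` (a positive offset means the device clock ran ahead,
#' so its samples move earlier), then resamples all grid-rate channels onto
#' the session grid. EEG and other high-rate channels are only
#' offset-corrected, and event series keep their event times.
#'
#' @param session a [session()].
#' @return the aligned [session()].
#' @export
align_streams <- function(session) {
  off <- session$meta$clock_offsets
  dur <- max(vapply(session$streams,
                    function(s) max(s$timestamps), numeric(1)))
  if (length(off) && any(abs(off) > dur))
    stop("clock offset exceeds session duration")
  out <- lapply(session$streams, function(s) {
    o <- if (s$name %in% names(off)) off[[s$name]] else 0
    s$timestamps <- s$timestamps - o
    s
  })
  grid_rate <- session$grid_rate
  out <- lapply(out, function(s) {
    if (s$nominal_rate == grid_rate) {
      shifted <- any(abs(s$timestamps * grid_rate -
                         round(s$timestamps * grid_rate)) > 1e-9)
      if (shifted) resample_to_grid(s, grid_rate, "linear") else s
    } else s
  })
  session$streams <- out
  session
}
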