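# Stressor-presence classification: EEG preprocessing, epoching by
# stressor-interval labels, alpha band-power ratio features, and
# stratified ten-fold cross-validation (LDA, linear SVM, logistic
# regression).

#' Preprocess EEG for classification
#'
#' Zero-phase 5th-order Butterworth band-pass between 3 and 50 Hz, followed
#' by a linear detrend of each channel over the whole segment. Per-epoch
#' baseline correction (subtracting the mean of the epoch's first second)
#' is applied later during epoching.
#'
#' @param eeg named list of six 256 Hz EEG [sensor_stream()]s.
#' @param lo,hi band edges, Hz.
#' @return named list of preprocessed [sensor_stream()]s.
#' @export
eeg_preprocess_cls <- function(eeg, lo = 3, hi = 50) {
  lapply(eeg, function(ch) {
    fs <- ch$nominal_rate
    bf <- signal::butter(5, c(lo, hi) / (fs / 2), type = "pass")
    v <- as.numeric(signal::filtfilt(bf, ch$values))
    tt <- ch$timestamps
    v <- stats::residuals(stats::lm.fit(cbind(1, tt), v))
    sensor_stream(ch$name, tt, v, fs, ch$units)
  })
}

#' Cut EEG into labeled stressor-interval epochs
#'
#' One epoch (channels x samples matrix) per label interval, with epoch
#' boundaries at exact multiples of the interval duration from the segment
#' start. Each epoch is baseline-corrected by subtracting the per-channel
#' mean of its first `baseline_s` seconds. Epochs with more than 20%
#' masked (`NA`) samples are dropped together with their labels.
#'
#' @param eeg named list of preprocessed EEG [sensor_stream()]s.
#' @param labels a [build_labels()] result.
#' @param baseline_s baseline-correction span from epoch start, s.
#' @return an object of class `epoch_set`: `epochs` (list of 6 x n
#'   matrices), `labels` (integer vector), `interval_s`, `fs`.
#' @export
epoch_by_labels <- function(eeg, labels, baseline_s = 1) {
  interval_s <- attr(labels, "interval_s")
  fs <- eeg[[1L]]$nominal_rate
  nsmp <- as.integer(round(interval_s * fs))
  t0 <- eeg[[1L]]$timestamps[1L]
  n <- length(eeg[[1L]]$values)
  chm <- do.call(rbind, lapply(eeg[EEG_CHANNELS], function(s) s$values))
  epochs <- list(); labs <- integer()
  nb <- max(1L, as.integer(round(baseline_s * fs)))
  for (i in seq_len(nrow(labels))) {
    s0 <- as.integer(round((labels$interval_start_s[i] - t0) * fs)) + 1L
    s1 <- s0 + nsmp - 1L
    if (s1 > n) break
    ep <- chm[, s0:s1, drop = FALSE]
    if (mean(is.na(ep)) > 0.2) next
    base <- rowMeans(ep[, seq_len(min(nb, ncol(ep))), drop = FALSE],
                     na.rm = TRUE)
    ep <- ep - base
    epochs[[length(epochs) + 1L]] <- ep
    labs <- c(labs, labels$label[i])
  }
  if (!length(epochs)) stop("no surviving epochs")
  structure(list(epochs = epochs, labels = labs, interval_s = interval_s,
                 fs = fs),
            class = "epoch_set")
}

#' Alpha band-power ratio features
#'
#' Per epoch and channel: periodogram power in the alpha band (8-13 Hz)
#' divided by power in 4-30 Hz. `mode = "all_channels"` yields the six
#' per-channel ratios; `mode = "left_minus_right"` the three differences
#' F3-F4, FC3-FC4, C3-C4. Epochs whose denominator is zero (silent) are
#' dropped together with their labels.
#'
#' @param epochs an [epoch_by_labels()] result.
#' @param mode `"all_channels"` or `"left_minus_right"`.
#' @param alpha_band,total_band bands in Hz.
#' @return list with `X` (feature matrix) and `y` (labels).
#' @export
alpha_ratio_features <- function(epochs,
                                 mode = c("all_channels",
                                          "left_minus_right"),
                                 alpha_band = c(8, 13),
                                 total_band = c(4, 30)) {
  mode <- match.arg(mode)
  fs <- epochs$fs
  feat <- matrix(NA_real_, length(epochs$epochs), 6L,
                 dimnames = list(NULL, EEG_CHANNELS))
  drop <- logical(length(epochs$epochs))
  for (i in seq_along(epochs$epochs)) {
    ep <- epochs$epochs[[i]]
    for (j in seq_len(6L)) {
      seg <- ep[j, ]
      if (anyNA(seg)) seg[is.na(seg)] <- mean(seg, na.rm = TRUE)
      tot <- segment_band_power(seg, fs, total_band)
      if (tot <= .Machine$double.eps) { drop[i] <- TRUE; break }
      feat[i, j] <- segment_band_power(seg, fs, alpha_band) / tot
    }
  }
  if (any(drop)) message(sum(drop), " silent epoch(s) dropped")
  feat <- feat[!drop, , drop = FALSE]
  y <- epochs$labels[!drop]
  X <- if (mode == "all_channels") feat
  else {
    m <- feat[, EEG_LEFT, drop = FALSE] - feat[, EEG_RIGHT, drop = FALSE]
    colnames(m) <- paste0(EEG_LEFT, "-", EEG_RIGHT)
    m
  }
  list(X = X, y = as.integer(y))
}

#' Stratified k-fold cross-validated classification
#'
#' Two-class classification of stressor presence with one of Linear
#' Discriminant Analysis (`"LDA"`, MASS), a linear support vector machine
#' (`"SVM"`, e1071, cost 1), or simple logistic regression (`"SLR"`,
#' `stats::glm`). Folds are stratified by class and fixed by `seed`.
#'
#' @param X numeric feature matrix (rows = epochs).
#' @param y integer labels (1 = presence, 2 = absence); both classes must
#'   be present.
#' @param method `"LDA"`, `"SVM"` or `"SLR"`.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return an object of class `cv_result`: `method`, `fold_accuracies`
#'   (percent), `mean`, `sd`, `recall` (per class).
#' @export
crossval_classify <- function(X, y, method = c("LDA", "SVM", "SLR"),
                              k = 10L, seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.integer(y)
  cls <- sort(unique(y))
  if (length(cls) < 2L) stop("degenerate labels: only one class present")
  restore_rng <- local_seed(derive_seed(seed, 37))
  on.exit(restore_rng(), add = TRUE)
  folds <- integer(length(y))
  for (cl in cls) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  acc <- numeric(k)
  pred_all <- integer(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (!any(te)) { acc[f] <- NA_real_; next }
    # guard: a fold's training split can lose a class on tiny data
    if (length(unique(y[tr])) < 2L) { acc[f] <- NA_real_; next }
    pred <- switch(method,
      LDA = {
        fit <- MASS::lda(X[tr, , drop = FALSE], grouping = factor(y[tr]))
        as.integer(as.character(stats::predict(fit,
          X[te, , drop = FALSE])$class))
      },
      SVM = {
        fit <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr]),
                          kernel = "linear", cost = 1, scale = TRUE)
        as.integer(as.character(stats::predict(fit, X[te, , drop = FALSE])))
      },
      SLR = {
        df <- data.frame(X[tr, , drop = FALSE])
        df$.y <- as.integer(y[tr] == cls[2L])
        fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                           family = stats::binomial()))
        pr <- suppressWarnings(
          stats::predict(fit, data.frame(X[te, , drop = FALSE]),
                         type = "response"))
        ifelse(pr > 0.5, cls[2L], cls[1L])
      })
    pred_all[te] <- pred
    acc[f] <- 100 * mean(pred == y[te])
  }
  acc <- acc[!is.na(acc)]
  recall <- vapply(cls, function(cl)
    100 * mean(pred_all[y == cl] == cl), numeric(1))
  structure(list(method = method, fold_accuracies = acc,
                 mean = mean(acc), sd = stats::sd(acc),
                 recall = stats::setNames(recall, paste0("class", cls))),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s> mean %.1f%% (SD %.1f) over %d folds\n",
              x$method, x$mean, x$sd, length(x$fold_accuracies)))
  invisible(x)
}

#' Aggregate per-participant CV results into an accuracy table
#'
#' @param results data frame with columns `label`, `interval_s`, `mode`,
#'   `trial`, `participant`, `accuracy` (one row per participant-level CV
#'   mean).
#' @return data frame of class `accuracy_table`: one row per label x
#'   interval x mode, columns `M_trial<k>` / `SD_trial<k>` holding the
#'   mean and SD over participants.
#' @export
build_accuracy_table <- function(results) {
  key <- unique(results[, c("label", "interval_s", "mode")])
  trials <- sort(unique(results$trial))
  rows <- lapply(seq_len(nrow(key)), function(i) {
    out <- key[i, ]
    for (tr in trials) {
      v <- results$accuracy[results$label == key$label[i] &
                            results$interval_s == key$interval_s[i] &
                            results$mode == key$mode[i] &
                            results$trial == tr]
      out[[paste0("M_trial", tr)]] <- mean(v)
      out[[paste0("SD_trial", tr)]] <- if (length(v) > 1L) stats::sd(v) else 0
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("accuracy_table", "data.frame")
  out
}
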