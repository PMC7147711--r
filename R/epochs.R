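# Epochs container: channels x trials x samples with montage, events and
# per-trial condition labels.

#' Construct an epochs object
#'
#' The package's epoched-EEG container: a numeric array of dimensions
#' channels x trials x samples (microvolts), a common time axis in ms
#' relative to the go-stimulus onset, per-trial condition labels drawn from
#' the stop-signal outcome vocabulary (SG/FG/SS/FS), and per-trial event
#' latencies (stop-signal onset = SSD, response = RT; `NA` where the event
#' did not occur).
#'
#' @param data 3-D numeric array, channels x trials x samples.
#' @param srate Sampling rate in Hz.
#' @param time Time axis in ms (length = number of samples). Alternatively
#'   supply `tmin` and the axis is built from `srate`.
#' @param channels Channel labels (length = dim 1).
#' @param condition Per-trial labels, one of `"SG"`, `"FG"`, `"SS"`, `"FS"`.
#' @param events Data frame with per-trial columns `go_ms`, `stop_ms`,
#'   `response_ms` (NA when absent). Defaults to go onset at 0 and no other
#'   events.
#' @param montage A [montage_1020()]-style montage (optional).
#' @param tmin Start of the time axis in ms when `time` is not given.
#' @return An object of class `"eeg_epochs"`.
#' @export
eeg_epochs <- function(data, srate, time = NULL, channels = NULL,
                       condition = NULL, events = NULL, montage = NULL,
                       tmin = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, srate > 0)
  nch <- dim(data)[1]; ntr <- dim(data)[2]; ns <- dim(data)[3]
  if (is.null(time)) {
    if (is.null(tmin)) tmin <- 0
    time <- tmin + (seq_len(ns) - 1) * 1000 / srate
  }
  if (length(time) != ns) stop("time axis length must equal sample count", call. = FALSE)
  if (is.null(channels)) channels <- paste0("CH", seq_len(nch))
  channels <- toupper(channels)
  if (length(channels) != nch) stop("channel labels must match dim 1", call. = FALSE)
  if (anyDuplicated(channels)) stop("channel labels must be unique", call. = FALSE)
  if (is.null(condition)) condition <- rep("SG", ntr)
  if (length(condition) != ntr) stop("condition labels must match trial count", call. = FALSE)
  bad <- setdiff(unique(condition), c("SG", "FG", "SS", "FS"))
  if (length(bad)) stop("unknown condition labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.null(events)) {
    events <- data.frame(go_ms = rep(0, ntr), stop_ms = NA_real_,
                         response_ms = NA_real_)
  }
  stopifnot(nrow(events) == ntr,
            all(c("go_ms", "stop_ms", "response_ms") %in% names(events)))
  events <- events[, c("go_ms", "stop_ms", "response_ms"), drop = FALSE]
  dimnames(data) <- list(channels, NULL, NULL)
  structure(list(data = data, srate = srate, time = as.numeric(time),
                 channels = channels, condition = as.character(condition),
                 events = events, montage = montage),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("EEG epochs: ", d[1], " channels x ", d[2], " trials x ", d[3],
      " samples @ ", x$srate, " Hz\n", sep = "")
  cat("  time: [", x$time[1], ", ", x$time[length(x$time)], "] ms\n", sep = "")
  tab <- table(factor(x$condition, levels = c("SG", "FG", "SS", "FS")))
  cat("  conditions: ", paste(names(tab), tab, sep = "=", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[2]
n_samples <- function(epochs) dim(epochs$data)[3]

#' Select trials by condition label
#'
#' Filters an epochs object to the trials carrying a given outcome label,
#' preserving trial order. Selecting a label no trial carries is an error
#' (an empty epochs object is never returned silently).
#'
#' @param epochs An [eeg_epochs()] object.
#' @param label One of `"SG"`, `"FG"`, `"SS"`, `"FS"`.
#' @return An `"eeg_epochs"` object containing only the matching trials.
#' @export
select_condition <- function(epochs, label) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  label <- match.arg(label, c("SG", "FG", "SS", "FS"))
  keep <- which(epochs$condition == label)
  if (length(keep) == 0) {
    stop("empty epochs: no trials with condition ", label, call. = FALSE)
  }
  subset_trials(epochs, keep)
}

subset_trials <- function(epochs, idx) {
  out <- epochs
  out$data <- epochs$data[, idx, , drop = FALSE]
  out$condition <- epochs$condition[idx]
  out$events <- epochs$events[idx, , drop = FALSE]
  rownames(out$events) <- NULL
  out
}

#' Pick channels from an epochs object
#'
#' @param epochs An [eeg_epochs()] object.
#' @param channels Channel labels to keep (order preserved as given).
#' @return An `"eeg_epochs"` object with only those channels.
#' @export
select_channels <- function(epochs, channels) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  channels <- toupper(channels)
  idx <- match(channels, epochs$channels)
  if (anyNA(idx)) {
    stop("channels not present: ",
         paste(channels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- epochs
  out$data <- epochs$data[idx, , , drop = FALSE]
  out$channels <- channels
  if (!is.null(out$montage)) {
    out$montage <- tryCatch(montage_1020(channels), error = function(e) NULL)
  }
  out
}

#' Concatenate epochs into a continuous multichannel recording
#'
#' Lays the trials of an epochs object end to end, separated by `gap_ms` of
#' zeros, and returns the continuous signal together with the go-onset
#' latencies of each trial in the concatenated timeline. This is the
#' inverse view used to exercise epoch extraction and to export continuous
#' EDF recordings.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param gap_ms Silent gap inserted between consecutive trials (ms).
#' @return A list with `data` (channels x samples matrix), `srate`,
#'   `channels`, and `events`: a data frame with per-trial `onset_ms` (go
#'   onset in continuous time) plus the trial's condition and event columns.
#' @export
epochs_to_continuous <- function(epochs, gap_ms = 0) {
  stopifnot(inherits(epochs, "eeg_epochs"), gap_ms >= 0)
  ns <- n_samples(epochs); ntr <- n_trials(epochs)
  gap <- round(gap_ms * epochs$srate / 1000)
  total <- ntr * ns + (ntr - 1) * gap
  out <- matrix(0, nrow = length(epochs$channels), ncol = total)
  onset_ms <- numeric(ntr)
  t0 <- epochs$time[1]                       # ms of first sample rel. go onset
  for (i in seq_len(ntr)) {
    a <- (i - 1) * (ns + gap) + 1
    out[, a:(a + ns - 1)] <- epochs$data[, i, ]
    onset_ms[i] <- (a - 1) * 1000 / epochs$srate - t0
  }
  events <- cbind(data.frame(onset_ms = onset_ms,
                             condition = epochs$condition,
                             stringsAsFactors = FALSE),
                  epochs$events)
  list(data = out, srate = epochs$srate, channels = epochs$channels,
       events = events)
}
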