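# Band-pass filtering and epoch extraction.

#' Band-pass filter specification
#'
#' Butterworth IIR band-pass. The default, a 4th-order 1-40 Hz filter
#' applied forward and backward (zero-phase), is the standard EEG broadband
#' choice; zero-phase application protects the phase statistics computed
#' downstream. A causal single-pass option is available.
#'
#' @param low,high Cutoff frequencies in Hz, `0 < low < high`.
#' @param order Filter order (per pass).
#' @param zero_phase Apply forward-backward (`filtfilt`) if `TRUE`,
#'   single-pass causal otherwise.
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(low = 1, high = 40, order = 4, zero_phase = TRUE) {
  if (!(low > 0 && high > low)) {
    stop("invalid filter: need 0 < low < high", call. = FALSE)
  }
  stopifnot(order >= 1)
  structure(list(low = low, high = high, order = as.integer(order),
                 family = "butterworth", zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

filter_series <- function(x, spec, srate) {
  nyq <- srate / 2
  if (spec$high >= nyq) {
    stop("invalid filter: high cutoff must be below the Nyquist frequency",
         call. = FALSE)
  }
  bf <- signal::butter(spec$order, c(spec$low, spec$high) / nyq, type = "pass")
  if (spec$zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Band-pass filter epoched EEG
#'
#' Applies the same Butterworth band-pass to every channel and trial;
#' metadata (time axis, labels, events) is unchanged.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param spec A [filter_spec()]; defaults to the 1-40 Hz zero-phase filter.
#' @return A filtered `"eeg_epochs"` object.
#' @export
bandpass <- function(epochs, spec = filter_spec()) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(spec, "filter_spec"))
  d <- dim(epochs$data)
  out <- epochs
  for (c in seq_len(d[1])) for (i in seq_len(d[2])) {
    out$data[c, i, ] <- filter_series(epochs$data[c, i, ], spec, epochs$srate)
  }
  out
}

#' Extract fixed-length epochs from a continuous recording
#'
#' Cuts one epoch per event from a continuous multichannel signal. Events
#' whose window would overhang a recording edge are dropped with a warning;
#' if all events are dropped this is an error. Extracted samples are exact
#' slices of the continuous data (no resampling or interpolation).
#'
#' @param data Channels x samples numeric matrix, or the list returned by
#'   [epochs_to_continuous()] / [read_edf()].
#' @param events Event (go-onset) latencies in ms from recording start, or
#'   a data frame with an `onset_ms` column (extra per-trial columns
#'   `condition`, `stop_ms`, `response_ms` are carried into the result).
#' @param window `c(start, end)` in ms relative to each event.
#' @param srate Sampling rate in Hz (taken from `data` if it is a list).
#' @param channels Channel labels (taken from `data` if it is a list).
#' @return An [eeg_epochs()] object with one trial per surviving event.
#' @export
extract_epochs <- function(data, events, window = c(-500, 1300),
                           srate = NULL, channels = NULL) {
  if (is.list(data) && !is.null(data$data)) {
    srate <- data$srate
    channels <- data$channels
    data <- data$data
  }
  stopifnot(is.matrix(data), !is.null(srate), length(window) == 2,
            window[1] < window[2])
  if (is.data.frame(events)) {
    ev_df <- events
    onsets <- events$onset_ms
  } else {
    onsets <- as.numeric(events)
    ev_df <- data.frame(onset_ms = onsets)
  }
  ns_total <- ncol(data)
  ns <- round((window[2] - window[1]) * srate / 1000)
  start_idx <- round(onsets * srate / 1000) + round(window[1] * srate / 1000) + 1
  ok <- start_idx >= 1 & (start_idx + ns - 1) <= ns_total
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to a recording edge were dropped",
            call. = FALSE)
  }
  if (!any(ok)) stop("empty epochs: all events fell outside the recording",
                     call. = FALSE)
  keep <- which(ok)
  arr <- array(NA_real_, dim = c(nrow(data), length(keep), ns))
  for (j in seq_along(keep)) {
    a <- start_idx[keep[j]]
    arr[, j, ] <- data[, a:(a + ns - 1)]
  }
  condition <- if ("condition" %in% names(ev_df)) ev_df$condition[keep] else NULL
  ev_out <- data.frame(
    go_ms = rep(0, length(keep)),
    stop_ms = if ("stop_ms" %in% names(ev_df)) ev_df$stop_ms[keep] else NA_real_,
    response_ms = if ("response_ms" %in% names(ev_df))
      ev_df$response_ms[keep] else NA_real_
  )
  eeg_epochs(arr, srate = srate, tmin = window[1], channels = channels,
             condition = condition, events = ev_out)
}
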