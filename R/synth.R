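# Synthetic EEG with controlled phase structure. Each oscillation spec
# injects an event-locked band-limited burst whose phase at onset is drawn
# von Mises across trials (ground-truth ITC = I1(kappa)/I0(kappa)) or copied
# from another channel with an offset and Gaussian jitter (ground-truth PLV
# ~ exp(-sd^2/2)).

#' Oscillatory burst specification
#'
#' Describes one event-locked oscillatory component of the synthetic EEG: a
#' sinusoidal burst at `freq` Hz under a Tukey envelope spanning
#' `[onset, offset]` ms relative to a locking event. Across trials the
#' burst's onset phase is drawn from a von Mises distribution with
#' concentration `kappa` (so the generator's ground-truth inter-trial
#' coherence is the Bessel ratio `I1(kappa)/I0(kappa)`; `kappa = Inf` means
#' identical phase on every trial). Alternatively, `coupled_to` copies the
#' onset phase of a previously generated channel plus a constant offset and
#' Gaussian jitter, creating ground-truth between-channel phase locking.
#'
#' @param channels Target channel label(s); every target receives the same
#'   per-trial phase draw.
#' @param freq Burst centre frequency in Hz, within the 1-40 Hz analysis band.
#' @param amplitude Peak amplitude in microvolts.
#' @param onset,offset Burst window in ms relative to the locking event;
#'   `onset < offset`.
#' @param kappa Von Mises phase concentration across trials (`>= 0`, may be
#'   `Inf`). Ignored when `coupled_to` is given.
#' @param condition Restrict the burst to trials with these outcome labels
#'   (`NULL` = all trials).
#' @param lock Locking event: `"go"` (stimulus onset, t = 0), `"stop"`
#'   (per-trial SSD) or `"response"` (per-trial RT). Trials lacking the
#'   event do not receive the burst.
#' @param coupled_to Optional list `list(channel =, offset =, jitter_sd =)`:
#'   copy that channel's burst phase with a constant offset (radians) plus
#'   zero-mean Gaussian jitter (radians).
#' @return An object of class `"oscillation_spec"`.
#' @export
oscillation_spec <- function(channels, freq, amplitude = 10,
                             onset = 0, offset = 500, kappa = Inf,
                             condition = NULL, lock = c("go", "stop", "response"),
                             coupled_to = NULL) {
  lock <- match.arg(lock)
  if (freq < 1 || freq > 40) {
    stop("burst frequency must lie in the 1-40 Hz analysis band", call. = FALSE)
  }
  if (!(kappa >= 0)) stop("kappa must be non-negative", call. = FALSE)
  if (!(onset < offset)) stop("need onset < offset", call. = FALSE)
  if (!is.null(condition)) {
    condition <- match.arg(condition, c("SG", "FG", "SS", "FS"), several.ok = TRUE)
  }
  if (!is.null(coupled_to)) {
    stopifnot(is.list(coupled_to), !is.null(coupled_to$channel))
    coupled_to$channel <- toupper(coupled_to$channel)
    if (is.null(coupled_to$offset)) coupled_to$offset <- 0
    if (is.null(coupled_to$jitter_sd)) coupled_to$jitter_sd <- 0
    stopifnot(coupled_to$jitter_sd >= 0)
  }
  structure(list(channels = toupper(channels), freq = freq,
                 amplitude = amplitude, onset = onset, offset = offset,
                 kappa = kappa, condition = condition, lock = lock,
                 coupled_to = coupled_to),
            class = "oscillation_spec")
}

#' Synthetic-EEG generation configuration
#'
#' @param montage Channel montage (default: full 32-channel 10-20 cap).
#' @param srate Sampling rate in Hz.
#' @param window Epoch window `c(start, end)` in ms relative to go onset.
#' @param noise_sd White Gaussian background noise SD in microvolts.
#' @param pink_sd SD of an additional 1/f-shaped noise component
#'   (microvolts; 0 disables it).
#' @param specs List of [oscillation_spec()] objects.
#' @param tukey_alpha Taper fraction of the burst envelope (0 = rectangular,
#'   1 = Hann).
#' @return An object of class `"eeg_gen_config"`.
#' @export
eeg_gen_config <- function(montage = montage_1020(), srate = 500,
                           window = c(-500, 1300), noise_sd = 5,
                           pink_sd = 0, specs = list(), tukey_alpha = 0.25) {
  stopifnot(srate > 0, length(window) == 2, window[1] < window[2],
            noise_sd >= 0, pink_sd >= 0, tukey_alpha >= 0, tukey_alpha <= 1)
  if (inherits(specs, "oscillation_spec")) specs <- list(specs)
  for (sp in specs) {
    stopifnot(inherits(sp, "oscillation_spec"))
    unknown <- setdiff(sp$channels, montage$channel)
    if (length(unknown)) {
      stop("oscillation spec targets unknown channels: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (!is.null(sp$coupled_to) &&
        !(sp$coupled_to$channel %in% montage$channel)) {
      stop("coupling source channel not in montage: ", sp$coupled_to$channel,
           call. = FALSE)
    }
  }
  structure(list(montage = montage, srate = srate, window = window,
                 noise_sd = noise_sd, pink_sd = pink_sd, specs = specs,
                 tukey_alpha = tukey_alpha),
            class = "eeg_gen_config")
}

#' Stop-signal tone waveform
#'
#' Pure sinusoid of the given frequency and duration with 5 ms raised-cosine
#' on/off ramps, sampled at `rate` Hz.
#'
#' @param freq Tone frequency in Hz; must be below the Nyquist frequency.
#' @param duration_ms Tone duration in ms.
#' @param rate Sampling rate in Hz.
#' @return Numeric waveform vector (possibly empty for zero duration).
#' @examples
#' tone <- make_stop_tone(750, 100, 44100)
#' @export
make_stop_tone <- function(freq = 750, duration_ms = 100, rate = 44100) {
  if (freq >= rate / 2) {
    stop("tone frequency must be below the Nyquist frequency (rate/2)",
         call. = FALSE)
  }
  n <- round(duration_ms * rate / 1000)
  if (n <= 0) return(numeric(0))
  t <- (seq_len(n) - 1) / rate
  w <- sin(2 * pi * freq * t)
  ramp_n <- min(round(0.005 * rate), floor(n / 2))
  if (ramp_n > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    w[seq_len(ramp_n)] <- w[seq_len(ramp_n)] * ramp
    w[(n - ramp_n + 1):n] <- w[(n - ramp_n + 1):n] * rev(ramp)
  }
  w
}

tukey_window <- function(n, alpha) {
  if (n <= 0) return(numeric(0))
  if (alpha <= 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}

# 1/f-amplitude noise via spectral shaping of white noise, scaled to unit SD.
pink_noise <- function(n) {
  if (n < 4) return(stats::rnorm(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))                      # avoid division by zero at DC
  f <- pmin(f, n - f + 1)                        # mirror for negative freqs
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  as.numeric(scale(y))
}

#' Simulate epoched EEG for a task session
#'
#' Generates one epoch per trial of `session`: Gaussian (optionally plus
#' 1/f) background noise on every channel, with each applicable
#' [oscillation_spec()] burst added on its target channels. Burst phase is
#' defined at burst onset and evolves at the centre frequency; per-trial
#' event latencies (SSD, RT) are copied from the session log, so
#' stop-locked bursts land at each trial's own stop-signal onset.
#'
#' @param config An [eeg_gen_config()].
#' @param session An `"ssrt_session"` from [run_session()].
#' @param seed Integer seed; identical config, session and seed give
#'   byte-identical output.
#' @return An [eeg_epochs()] object.
#' @export
simulate_epochs <- function(config, session, seed = NULL) {
  stopifnot(inherits(config, "eeg_gen_config"), inherits(session, "ssrt_session"))
  tr <- session$trials
  ntr <- nrow(tr)
  if (ntr == 0) stop("session has no trials", call. = FALSE)
  srate <- config$srate
  ns <- round((config$window[2] - config$window[1]) * srate / 1000)
  time <- config$window[1] + (seq_len(ns) - 1) * 1000 / srate
  chans <- config$montage$channel
  nch <- length(chans)
  events <- data.frame(go_ms = rep(0, ntr), stop_ms = tr$ssd_ms,
                       response_ms = tr$rt_ms)
  burst_phase_registry <- list()   # burst onset phases, keyed "CHANNEL.trial"
  dat <- with_seed(seed, {
    x <- array(stats::rnorm(nch * ntr * ns, 0, config$noise_sd),
               dim = c(nch, ntr, ns))
    if (config$pink_sd > 0) {
      for (c in seq_len(nch)) for (i in seq_len(ntr)) {
        x[c, i, ] <- x[c, i, ] + config$pink_sd * pink_noise(ns)
      }
    }
    for (sp in config$specs) {
      ch_idx <- match(sp$channels, chans)
      for (i in seq_len(ntr)) {
        if (!is.null(sp$condition) && !(tr$outcome[i] %in% sp$condition)) next
        lock_ms <- switch(sp$lock, go = events$go_ms[i],
                          stop = events$stop_ms[i],
                          response = events$response_ms[i])
        phi <- if (is.null(sp$coupled_to)) {
          if (is.infinite(sp$kappa)) 0 else rvonmises(1, 0, sp$kappa)
        } else {
          src <- burst_phase_registry[[paste0(sp$coupled_to$channel, ".", i)]]
          if (is.null(src)) src <- 0
          src + sp$coupled_to$offset +
            if (sp$coupled_to$jitter_sd > 0)
              stats::rnorm(1, 0, sp$coupled_to$jitter_sd) else 0
        }
        for (ch in sp$channels) {
          burst_phase_registry[[paste0(ch, ".", i)]] <- phi
        }
        if (is.na(lock_ms)) next        # event absent: draw made, burst skipped
        a_ms <- lock_ms + sp$onset
        b_ms <- lock_ms + sp$offset
        idx <- which(time >= a_ms & time < b_ms)
        if (length(idx) == 0) next
        env <- tukey_window(length(idx), config$tukey_alpha)
        wave <- sp$amplitude * env *
          cos(2 * pi * sp$freq * (time[idx] - a_ms) / 1000 + phi)
        for (ci in ch_idx) x[ci, i, ] <- x[ci, i, ] +
            replace(numeric(ns), idx, wave)
      }
    }
    x
  })
  eeg_epochs(dat, srate = srate, time = time, channels = chans,
             condition = tr$outcome, events = events, montage = config$montage)
}
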