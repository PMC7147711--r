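# Complex Morlet time-frequency decomposition.

morlet_kernel <- function(freq, cycles, srate) {
  sd_t <- cycles / (2 * pi * freq)
  half <- ceiling(3 * sd_t * srate)
  t <- (-half:half) / srate
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sd_t^2))
  w / sqrt(sum(Mod(w)^2))        # unit energy; phase response is zero-centred
}

#' Morlet time-frequency decomposition of epoched EEG
#'
#' Convolves every channel and trial with complex Morlet wavelets on a
#' frequency grid, yielding a complex coefficient per
#' (channel, trial, frequency, time). The number of cycles grows with
#' frequency (`max(3, f/2)` by default) to balance time and frequency
#' resolution across the 1-40 Hz range. Samples closer to an epoch edge
#' than half the wavelet length are flagged invalid in the `valid` mask;
#' downstream significance masking never marks them significant.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param freqs Frequency grid in Hz (strictly increasing, below Nyquist).
#' @param cycles Wavelet cycle count per frequency (recycled).
#' @return An object of class `"tf_decomposition"`: list with `coef`
#'   (complex array channels x trials x freqs x times), `freqs`, `time`,
#'   `cycles`, `valid` (freqs x times logical), `srate`, `channels`.
#' @export
tf_decompose <- function(epochs, freqs = 1:40, cycles = pmax(3, freqs / 2)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  freqs <- as.numeric(freqs)
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing", call. = FALSE)
  if (max(freqs) >= epochs$srate / 2) {
    stop("requested frequency at or above the Nyquist frequency", call. = FALSE)
  }
  if (min(freqs) <= 0) stop("frequencies must be positive", call. = FALSE)
  cycles <- rep_len(cycles, length(freqs))
  d <- dim(epochs$data)
  nch <- d[1]; ntr <- d[2]; ns <- d[3]
  kernels <- mapply(morlet_kernel, freqs, cycles,
                    MoreArgs = list(srate = epochs$srate), SIMPLIFY = FALSE)
  klen <- vapply(kernels, length, integer(1))
  if (max(klen) > ns) {
    stop("epoch shorter than the longest wavelet (", max(klen), " samples)",
         call. = FALSE)
  }
  nfft <- ns + max(klen) - 1
  K <- lapply(kernels, function(k) stats::fft(c(k, rep(0, nfft - length(k)))))
  half <- (klen - 1) / 2
  coef <- array(NA_complex_, dim = c(nch, ntr, length(freqs), ns))
  for (c in seq_len(nch)) for (i in seq_len(ntr)) {
    X <- stats::fft(c(epochs$data[c, i, ], rep(0, nfft - ns)))
    for (fi in seq_along(freqs)) {
      full <- stats::fft(X * K[[fi]], inverse = TRUE) / nfft
      coef[c, i, fi, ] <- full[(half[fi] + 1):(half[fi] + ns)]
    }
  }
  valid <- matrix(TRUE, nrow = length(freqs), ncol = ns)
  for (fi in seq_along(freqs)) {
    h <- half[fi]
    if (h > 0) valid[fi, c(seq_len(min(h, ns)),
                           if (h < ns) (ns - h + 1):ns)] <- FALSE
  }
  structure(list(coef = coef, freqs = freqs, time = epochs$time,
                 cycles = cycles, valid = valid, srate = epochs$srate,
                 channels = epochs$channels),
            class = "tf_decomposition")
}

#' @export
print.tf_decomposition <- function(x, ...) {
  d <- dim(x$coef)
  cat("Morlet TF decomposition: ", d[1], " channels x ", d[2], " trials x ",
      d[3], " freqs x ", d[4], " times\n", sep = "")
  cat("  freqs: ", min(x$freqs), "-", max(x$freqs), " Hz; time ",
      x$time[1], " to ", x$time[length(x$time)], " ms\n", sep = "")
  invisible(x)
}
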