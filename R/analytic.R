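# Analytic signal and band-limited instantaneous phase.

#' Analytic signal via the FFT
#'
#' Computes the discrete analytic signal (the Hilbert-transform
#' construction): negative-frequency components of the spectrum are zeroed
#' and positive ones doubled, so the imaginary part of the result is the
#' Hilbert transform of the input.
#'
#' @param x Real-valued numeric vector.
#' @return Complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0) return(complex(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Band-limited instantaneous phase
#'
#' Band-pass filters each channel and trial into `band` (zero-phase
#' Butterworth) and returns the instantaneous phase of the analytic signal,
#' in (-pi, pi]. Signals whose band-limited envelope is essentially zero
#' have no defined phase and raise an error.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param band A [band_def()] (or any list with `low`/`high` in Hz).
#' @param order Butterworth order used for the band filter.
#' @param amp_tol Minimum mean analytic amplitude below which the phase is
#'   declared undefined.
#' @return Array channels x trials x samples of phases in radians.
#' @export
instantaneous_phase <- function(epochs, band, order = 4, amp_tol = 1e-8) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  nyq <- epochs$srate / 2
  if (!(band$low > 0 && band$high > band$low && band$high < nyq)) {
    stop("band must satisfy 0 < low < high < Nyquist", call. = FALSE)
  }
  spec <- filter_spec(band$low, band$high, order = order, zero_phase = TRUE)
  d <- dim(epochs$data)
  ph <- array(NA_real_, dim = d)
  for (c in seq_len(d[1])) for (i in seq_len(d[2])) {
    z <- analytic_signal(filter_series(epochs$data[c, i, ], spec, epochs$srate))
    if (mean(Mod(z)) < amp_tol) {
      stop("undefined phase: band-limited amplitude is below tolerance",
           call. = FALSE)
    }
    ph[c, i, ] <- Arg(z)
  }
  dimnames(ph) <- list(epochs$channels, NULL, NULL)
  ph
}
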