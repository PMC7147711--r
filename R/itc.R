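# Inter-trial coherence: modulus of the across-trial mean unit phasor,
# with Rayleigh-test significance masks and band summaries.

#' Resultant length of a set of phases
#'
#' The circular resultant `|mean(exp(i*phi))|` taken across the first
#' dimension of `phases`. This is the statistic underlying both the
#' inter-trial coherence (phases across trials at one time-frequency cell)
#' and the phase-locking value (phase differences across time).
#'
#' @param phases Numeric vector, matrix or array of angles in radians; the
#'   mean is taken over the first dimension.
#' @return Resultant length(s) in `[0, 1]`, with the first dimension dropped.
#' @export
itc_resultant <- function(phases) {
  z <- exp(1i * phases)
  if (is.null(dim(z))) return(Mod(mean(z)))
  d <- dim(z)
  m <- colMeans(matrix(z, nrow = d[1]))
  out <- Mod(m)
  if (length(d) > 2) dim(out) <- d[-1]
  out
}

#' Rayleigh critical value for the inter-trial coherence
#'
#' Under the null of uniformly random phases, the resultant length of `n`
#' unit phasors has `P(R > r) = exp(-n r^2)` (large-sample Rayleigh
#' approximation), so the critical resultant at level `alpha` is
#' `sqrt(-log(alpha) / n)`. ITC values at or above this threshold are
#' flagged significant.
#'
#' @param n_trials Number of trials, `>= 2`.
#' @param alpha Significance level in (0, 1).
#' @return Critical ITC value in `[0, 1]`.
#' @examples
#' itc_threshold(60, 0.05)   # ~0.2234
#' @export
itc_threshold <- function(n_trials, alpha = 0.05) {
  if (n_trials < 2) stop("need at least 2 trials", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  sqrt(-log(alpha) / n_trials)
}

#' Inter-trial coherence map
#'
#' Computes, for every (channel, frequency, time) cell, the modulus of the
#' across-trial mean unit phasor of the Morlet coefficients: 0 means phases
#' are unrelated across trials, 1 means a perfectly reproducible phase.
#' Cells are flagged significant when the ITC exceeds the Rayleigh critical
#' value at `alpha`; wavelet edge cells are never significant. An optional
#' Benjamini-Hochberg correction across valid cells is available.
#'
#' @param tf A [tf_decompose()] result.
#' @param alpha Significance level for the per-cell Rayleigh test.
#' @param fdr Apply Benjamini-Hochberg false-discovery-rate correction
#'   across valid cells instead of the per-cell threshold.
#' @return An object of class `"itc_map"`: list with `itc` (channels x
#'   freqs x times), `mask` (logical, same shape), `threshold`, `n_trials`,
#'   `freqs`, `time`, `valid`, `channels`, `alpha`.
#' @export
compute_itc <- function(tf, alpha = 0.05, fdr = FALSE) {
  stopifnot(inherits(tf, "tf_decomposition"))
  d <- dim(tf$coef)
  n <- d[2]
  if (n < 2) stop("ITC is degenerate with a single trial; need >= 2", call. = FALSE)
  a <- Mod(tf$coef)
  ph <- tf$coef / ifelse(a > 0, a, 1)        # unit phasors; zero stays zero
  itc <- Mod(colMeans(aperm(ph, c(2, 1, 3, 4))))
  dim(itc) <- d[c(1, 3, 4)]
  dimnames(itc) <- list(tf$channels, NULL, NULL)
  thr <- itc_threshold(n, alpha)
  valid3 <- aperm(array(tf$valid, dim = c(d[3], d[4], d[1])), c(3, 1, 2))
  if (fdr) {
    p <- exp(-n * itc^2)
    padj <- array(NA_real_, dim = dim(p))
    padj[valid3] <- stats::p.adjust(p[valid3], method = "BH")
    mask <- !is.na(padj) & padj < alpha
  } else {
    mask <- (itc >= thr) & valid3
  }
  structure(list(itc = itc, mask = mask, threshold = thr, n_trials = n,
                 freqs = tf$freqs, time = tf$time, valid = tf$valid,
                 channels = tf$channels, alpha = alpha),
            class = "itc_map")
}

#' @export
print.itc_map <- function(x, ...) {
  d <- dim(x$itc)
  cat("ITC map: ", d[1], " channels x ", d[2], " freqs x ", d[3], " times (",
      x$n_trials, " trials)\n", sep = "")
  cat(sprintf("  threshold %.4f (alpha = %g); %.1f%% of valid cells significant\n",
              x$threshold, x$alpha,
              100 * sum(x$mask) / (d[1] * sum(x$valid))))
  invisible(x)
}

#' Contrast two ITC maps
#'
#' Elementwise difference `a - b` (e.g. successful-stop minus successful-go,
#' isolating phase locking attributable to inhibition). Both inputs must
#' share channels, frequency and time axes; their significance masks are
#' carried along.
#'
#' @param a,b [compute_itc()] results on identical axes.
#' @return An object of class `"itc_contrast"`: list with `diff`, `mask_a`,
#'   `mask_b`, `freqs`, `time`, `channels`.
#' @export
contrast_itc <- function(a, b) {
  stopifnot(inherits(a, "itc_map"), inherits(b, "itc_map"))
  if (!identical(a$channels, b$channels) || !identical(a$freqs, b$freqs) ||
      !isTRUE(all.equal(a$time, b$time))) {
    stop("ITC maps have mismatched axes", call. = FALSE)
  }
  structure(list(diff = a$itc - b$itc, mask_a = a$mask, mask_b = b$mask,
                 freqs = a$freqs, time = a$time, channels = a$channels),
            class = "itc_contrast")
}

#' Band-averaged ITC summaries
#'
#' Averages an ITC map over the frequencies of each named band, per channel
#' and time point, in long format suitable for CSV export.
#'
#' @param map An [compute_itc()] result.
#' @param bands Named list of [band_def()]s (default [standard_bands()]).
#' @param valid_only Average over valid (non-edge) cells only.
#' @return Data frame with columns `channel`, `band`, `time_ms`, `itc`,
#'   `significant` (TRUE when the band-mean ITC clears the threshold).
#' @export
itc_band_summary <- function(map, bands = standard_bands(), valid_only = TRUE) {
  stopifnot(inherits(map, "itc_map"))
  out <- list()
  for (b in bands) {
    fi <- which(map$freqs >= b$low & map$freqs <= b$high)
    if (length(fi) == 0) next
    for (ci in seq_along(map$channels)) {
      sub <- matrix(map$itc[ci, fi, ], nrow = length(fi))
      if (valid_only) {
        sub[!map$valid[fi, , drop = FALSE]] <- NA
        vals <- suppressWarnings(colMeans(sub, na.rm = TRUE))
        vals[is.nan(vals)] <- NA
      } else {
        vals <- colMeans(sub)
      }
      out[[length(out) + 1L]] <- data.frame(
        channel = map$channels[ci], band = b$name, time_ms = map$time,
        itc = vals, significant = !is.na(vals) & vals >= map$threshold,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Plot an ITC map for one channel
#'
#' Time-frequency image of ITC with significant cells outlined.
#'
#' @param x An `"itc_map"`.
#' @param channel Channel label to plot.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.itc_map <- function(x, channel = x$channels[1], ...) {
  ci <- match(toupper(channel), x$channels)
  if (is.na(ci)) stop("channel not in map: ", channel, call. = FALSE)
  z <- t(x$itc[ci, , ])
  graphics::image(x$time, x$freqs, z, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (ms)", ylab = "frequency (Hz)",
                  main = paste0("ITC ", x$channels[ci]), ...)
  m <- t(x$mask[ci, , ])
  if (any(m)) graphics::contour(x$time, x$freqs, m * 1, levels = 0.5,
                                add = TRUE, drawlabels = FALSE, col = "white")
  invisible(x)
}
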