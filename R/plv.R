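# Phase-locking value connectivity over electrode pairs, analysis windows
# resolved against per-trial task events, trial-shuffled surrogate nulls,
# and connectivity-graph construction.

#' Phase-locking value of two phase series
#'
#' The modulus of the mean phasor of the instantaneous phase difference,
#' `|1/N * sum(exp(i * (phi1 - phi2)))|`. Equals 1 when the phase
#' difference is constant over the window (including any constant offset)
#' and tends to 0 for unrelated phases; always lies in `[0, 1]` and is
#' symmetric in its arguments.
#'
#' @param phi1,phi2 Phase series in radians, equal length `>= 2`.
#' @return PLV in `[0, 1]`.
#' @examples
#' t <- seq(0, 1, by = 0.002)
#' compute_plv(2 * pi * 5 * t, 2 * pi * 5 * t + 0.7)  # 1
#' @export
compute_plv <- function(phi1, phi2) {
  if (length(phi1) != length(phi2)) {
    stop("phase series must have equal length", call. = FALSE)
  }
  if (length(phi1) < 2) stop("need at least 2 samples", call. = FALSE)
  Mod(mean(exp(1i * (phi1 - phi2))))
}

#' Analysis window relative to task events
#'
#' A time window whose endpoints are offsets (ms) from per-trial events:
#' the go-stimulus onset, the stop-signal onset (SSD) or the response.
#' Ready-made windows matching the task structure:
#' `window_fixation()` is the 250 ms pre-stimulus fixation `[-250, 0)`;
#' `window_ssd()` spans go onset to the trial's stop-signal onset;
#' `window_ssrt(ssrt)` spans the stop-signal onset to SSD + estimated SSRT
#' (the covert stopping interval); `window_rt()` spans go onset to the
#' response.
#'
#' @param name Window label.
#' @param start_event,end_event `"go"`, `"stop"` or `"response"`.
#' @param start_offset,end_offset Offsets in ms added to the event latencies.
#' @return An object of class `"analysis_window"`.
#' @export
analysis_window <- function(name, start_event = "go", start_offset = 0,
                            end_event = "go", end_offset = 0) {
  ev <- c("go", "stop", "response")
  structure(list(name = name,
                 start_event = match.arg(start_event, ev),
                 start_offset = start_offset,
                 end_event = match.arg(end_event, ev),
                 end_offset = end_offset),
            class = "analysis_window")
}

#' @rdname analysis_window
#' @export
window_fixation <- function() analysis_window("fixation", "go", -250, "go", 0)

#' @rdname analysis_window
#' @export
window_ssd <- function() analysis_window("ssd", "go", 0, "stop", 0)

#' @rdname analysis_window
#' @param ssrt Estimated stop-signal reaction time in ms.
#' @export
window_ssrt <- function(ssrt) analysis_window("ssrt", "stop", 0, "stop", ssrt)

#' @rdname analysis_window
#' @export
window_rt <- function() analysis_window("rt", "go", 0, "response", 0)

# Resolve a window to sample indices for one trial; NULL if unresolvable.
resolve_window <- function(win, events_row, time) {
  ev_ms <- function(ev) switch(ev, go = events_row$go_ms,
                               stop = events_row$stop_ms,
                               response = events_row$response_ms)
  a <- ev_ms(win$start_event) + win$start_offset
  b <- ev_ms(win$end_event) + win$end_offset
  if (is.na(a) || is.na(b) || a >= b) return(NULL)
  idx <- which(time >= a & time < b)
  if (length(idx) < 2) return(NULL)
  idx
}

#' Phase-locking connectivity over electrode pairs
#'
#' For every (pair, band, window) cell: extracts the band-limited Hilbert
#' phase of both channels, resolves the window against each trial's events,
#' concatenates the within-window phase differences across trials and takes
#' the PLV. Significance comes from a trial-shuffling surrogate null: the
#' second channel's trials are re-paired at random `n_surrogates` times
#' (destroying within-trial coupling while preserving each channel's phase
#' dynamics) and an edge is significant when the observed PLV exceeds the
#' surrogate 95th percentile. Trials in which a window cannot be resolved
#' (e.g. no stop signal) are skipped; a cell with no resolvable trials is
#' recorded as `NA` with a warning.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param pairs A [pair_set()] (default: the 11 standard pairs).
#' @param bands Named list of [band_def()]s.
#' @param windows List of [analysis_window()]s.
#' @param n_surrogates Number of trial-shuffling surrogates.
#' @param seed Integer seed for the surrogate permutations.
#' @param per_trial Average per-trial PLVs instead of concatenating samples
#'   across trials (sample-weighted concatenation is the default).
#' @return An object of class `"plv_connectivity"`: list with `plv`
#'   (pairs x bands x windows array), `null_q95`, `null_mean`, `n_samples`,
#'   `edges` (long-format data frame), `pairs`, `bands`, `windows`,
#'   `montage`, `n_surrogates`, `seed`.
#' @export
connectivity <- function(epochs, pairs = pair_set(), bands = standard_bands(),
                         windows = list(window_fixation()),
                         n_surrogates = 200, seed = NULL, per_trial = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (inherits(windows, "analysis_window")) windows <- list(windows)
  if (inherits(bands, "band_def")) bands <- list(bands)
  if (is.null(names(bands))) {
    names(bands) <- vapply(bands, `[[`, character(1), "name")
  }
  chans_needed <- unique(as.vector(unclass(pairs)[, 1:2]))
  missing <- setdiff(chans_needed, epochs$channels)
  if (length(missing)) {
    stop("epochs lack channels required by the pair set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ntr <- n_trials(epochs)
  np <- nrow(pairs); nb <- length(bands); nw <- length(windows)
  wnames <- vapply(windows, `[[`, character(1), "name")
  plabs <- pair_labels(pairs)

  # band-limited phases, channels restricted to the ones used
  ph <- lapply(bands, function(b)
    instantaneous_phase(select_channels(epochs, chans_needed), b))

  # per-trial window sample indices (shared across channels)
  widx <- lapply(windows, function(w)
    lapply(seq_len(ntr), function(i)
      resolve_window(w, epochs$events[i, ], epochs$time)))

  plv <- array(NA_real_, dim = c(np, nb, nw),
               dimnames = list(plabs, names(bands), wnames))
  nsamp <- array(0L, dim = c(np, nb, nw), dimnames = dimnames(plv))
  q95 <- array(NA_real_, dim = c(np, nb, nw), dimnames = dimnames(plv))
  nmean <- array(NA_real_, dim = c(np, nb, nw), dimnames = dimnames(plv))

  perms <- with_seed(seed, {
    lapply(seq_len(max(n_surrogates, 0)), function(s) sample.int(ntr))
  })

  for (wi in seq_len(nw)) {
    wlist <- widx[[wi]]
    lens <- vapply(wlist, function(w) if (is.null(w)) 0L else length(w),
                   integer(1))
    if (all(lens == 0)) {
      warning("window '", wnames[wi], "' unresolvable for every trial",
              call. = FALSE)
      next
    }
    maxlen <- max(lens)
    # Lmin[i, j] = shared sample count when trial i (ch1) is re-paired with
    # trial j (ch2); zero-padding below truncates dot products to this length.
    Lmin <- outer(lens, lens, pmin)
    for (bi in seq_len(nb)) {
      ph_b <- ph[[bi]]
      # zero-padded unit phasors, one column per trial, per channel
      Z <- lapply(seq_along(chans_needed), function(ci) {
        m <- matrix(0 + 0i, nrow = maxlen, ncol = ntr)
        for (i in seq_len(ntr)) if (lens[i] > 0) {
          m[seq_len(lens[i]), i] <- exp(1i * ph_b[ci, i, wlist[[i]]])
        }
        m
      })
      for (pi in seq_len(np)) {
        i1 <- match(pairs[pi, 1], chans_needed)
        i2 <- match(pairs[pi, 2], chans_needed)
        # C[i, j] = sum over shared samples of e^{i(phi1_i - phi2_j)}
        C <- t(Z[[i1]]) %*% Conj(Z[[i2]])
        dg <- seq_len(ntr) + (seq_len(ntr) - 1L) * ntr
        stat <- function(map) {
          idx <- seq_len(ntr) + (map - 1L) * ntr
          n <- sum(Lmin[idx])
          if (per_trial) {
            use <- Lmin[idx] > 0
            if (!any(use)) return(NA_real_)
            mean(Mod(C[idx][use]) / Lmin[idx][use])
          } else {
            if (n < 2) return(NA_real_)
            Mod(sum(C[idx])) / n
          }
        }
        plv[pi, bi, wi] <- stat(seq_len(ntr))
        nsamp[pi, bi, wi] <- sum(Lmin[dg])
        if (n_surrogates > 0 && !is.na(plv[pi, bi, wi])) {
          null_vals <- vapply(perms, stat, numeric(1))
          q95[pi, bi, wi] <- stats::quantile(null_vals, 0.95, na.rm = TRUE,
                                             names = FALSE)
          nmean[pi, bi, wi] <- mean(null_vals, na.rm = TRUE)
        }
      }
    }
  }

  edges <- expand.grid(pair = plabs, band = names(bands), window = wnames,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  edges$plv <- as.vector(plv)
  edges$n_samples <- as.vector(nsamp)
  edges$null_q95 <- as.vector(q95)
  edges$significant <- !is.na(edges$plv) & !is.na(edges$null_q95) &
    edges$plv > edges$null_q95

  structure(list(plv = plv, null_q95 = q95, null_mean = nmean,
                 n_samples = nsamp, edges = edges, pairs = pairs,
                 bands = bands, windows = windows, montage = epochs$montage,
                 n_surrogates = n_surrogates, seed = seed,
                 per_trial = per_trial),
            class = "plv_connectivity")
}

#' @export
print.plv_connectivity <- function(x, ...) {
  d <- dim(x$plv)
  cat("PLV connectivity: ", d[1], " pairs x ", d[2], " bands x ", d[3],
      " windows (", x$n_surrogates, " surrogates)\n", sep = "")
  sig <- x$edges[x$edges$significant, , drop = FALSE]
  cat("  significant edges: ", nrow(sig), " / ", nrow(x$edges), "\n", sep = "")
  invisible(x)
}

#' Stimulus-vs-baseline connectivity graph
#'
#' Builds the edge list of a connectivity graph for one band: edges whose
#' PLV in the stimulus window is significant against the surrogate null
#' *and* exceeds their PLV in the baseline (fixation) window, annotated
#' with the PLV increase.
#'
#' @param result A [connectivity()] result.
#' @param stimulus,baseline Window names present in `result` (e.g. `"ssrt"`
#'   vs `"fixation"`).
#' @param band Band name present in `result`.
#' @return Data frame of class `"plv_graph"` with columns `pair`, `ch1`,
#'   `ch2`, `band`, `window`, `plv`, `baseline_plv`, `delta_plv`,
#'   `null_q95`; one row per retained edge (possibly zero rows).
#' @export
build_graph <- function(result, stimulus, baseline = "fixation",
                        band = "theta") {
  stopifnot(inherits(result, "plv_connectivity"))
  wnames <- dimnames(result$plv)[[3]]
  if (!(stimulus %in% wnames)) stop("window not in result: ", stimulus, call. = FALSE)
  if (!(baseline %in% wnames)) stop("window not in result: ", baseline, call. = FALSE)
  if (!(band %in% dimnames(result$plv)[[2]])) {
    stop("band not in result: ", band, call. = FALSE)
  }
  ps <- result$plv[, band, stimulus]
  pb <- result$plv[, band, baseline]
  qs <- result$null_q95[, band, stimulus]
  keep <- which(!is.na(ps) & !is.na(qs) & ps > qs & !is.na(pb) & ps > pb)
  out <- data.frame(
    pair = pair_labels(result$pairs)[keep],
    ch1 = unclass(result$pairs)[keep, 1], ch2 = unclass(result$pairs)[keep, 2],
    band = rep(band, length(keep)), window = rep(stimulus, length(keep)),
    plv = unname(ps[keep]), baseline_plv = unname(pb[keep]),
    delta_plv = unname(ps[keep] - pb[keep]), null_q95 = unname(qs[keep]),
    stringsAsFactors = FALSE)
  class(out) <- c("plv_graph", "data.frame")
  attr(out, "montage") <- result$montage
  out
}

#' Plot a connectivity graph on the montage layout
#'
#' Draws a schematic head with electrode positions and the graph's edges,
#' line width scaled by the PLV increase over baseline.
#'
#' @param x A [build_graph()] result.
#' @param montage Montage supplying 2-D positions (defaults to the one
#'   stored with the result, else the standard 32-channel cap).
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.plv_graph <- function(x, montage = NULL, ...) {
  if (is.null(montage)) montage <- attr(x, "montage")
  if (is.null(montage)) montage <- montage_1020()
  graphics::plot(montage$x, montage$y, pch = 21, bg = "grey85", cex = 2.2,
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 xlim = c(-1.35, 1.35), ylim = c(-1.25, 1.35))
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(1.1 * cos(th), 1.1 * sin(th), col = "grey60")
  graphics::polygon(c(-0.1, 0, 0.1), c(1.09, 1.2, 1.09), border = "grey60")
  if (nrow(x) > 0) {
    for (i in seq_len(nrow(x))) {
      a <- montage[montage$channel == x$ch1[i], ]
      b <- montage[montage$channel == x$ch2[i], ]
      graphics::segments(a$x, a$y, b$x, b$y, col = "firebrick",
                         lwd = 1 + 8 * x$delta_plv[i])
    }
  }
  graphics::text(montage$x, montage$y, montage$channel, cex = 0.55)
  if (nrow(x) > 0) {
    graphics::title(main = paste0(x$band[1], " band, ", x$window[1],
                                  " window (", nrow(x), " edges)"))
  }
  invisible(x)
}
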