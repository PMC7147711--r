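# Stop-signal task simulation: trial sequencing, SSD staircase, race model,
# SSRT estimation.

#' Stop-signal task configuration
#'
#' Parameters of the auditory stop-signal task: 75%/25% go/stop trial mix
#' (180 go, 60 stop by default), a visual go stimulus shown for 1000 ms
#' after a 250 ms fixation cross, and on stop trials a 750 Hz, 100 ms beep
#' presented after a stop-signal delay (SSD). The SSD starts at 250 ms and
#' is adapted by a 1-up/1-down staircase in 50 ms steps: successful
#' inhibition raises it, failed inhibition lowers it, so it tracks the
#' delay at which stopping succeeds on half the stop trials.
#'
#' @param n_go,n_stop Numbers of go and stop trials.
#' @param ssd_initial Starting SSD (ms).
#' @param ssd_step Staircase step (ms), `> 0`.
#' @param ssd_min,ssd_max Clipping bounds for the staircase (ms).
#' @param fixation_duration Fixation-cross duration (ms).
#' @param go_duration Go-stimulus presentation time (ms).
#' @param stop_tone_freq Stop-signal tone frequency (Hz).
#' @param stop_tone_duration Stop-signal tone duration (ms).
#' @return An object of class `"task_config"`.
#' @examples
#' cfg <- task_config()
#' cfg$n_go + cfg$n_stop  # 240 trials per session
#' @export
task_config <- function(n_go = 180, n_stop = 60,
                        ssd_initial = 250, ssd_step = 50,
                        ssd_min = 50, ssd_max = 1000,
                        fixation_duration = 250, go_duration = 1000,
                        stop_tone_freq = 750, stop_tone_duration = 100) {
  if (n_go < 0 || n_stop < 0) {
    stop("invalid task config: trial counts must be non-negative", call. = FALSE)
  }
  if (ssd_step <= 0) {
    stop("invalid task config: ssd_step must be positive", call. = FALSE)
  }
  if (!(ssd_min >= 0 && ssd_min <= ssd_initial && ssd_initial <= ssd_max)) {
    stop("invalid task config: need 0 <= ssd_min <= ssd_initial <= ssd_max",
         call. = FALSE)
  }
  structure(list(
    n_go = as.integer(n_go), n_stop = as.integer(n_stop),
    ssd_initial = ssd_initial, ssd_step = ssd_step,
    ssd_min = ssd_min, ssd_max = ssd_max,
    fixation_duration = fixation_duration, go_duration = go_duration,
    stop_tone_freq = stop_tone_freq, stop_tone_duration = stop_tone_duration
  ), class = "task_config")
}

#' Race-model subject parameters
#'
#' The independent race model: on every trial a go process with an
#' ex-Gaussian finishing time races, on stop trials, against a stop process
#' that finishes at SSD plus a Gaussian stopping latency. The faster
#' process determines the outcome. These parameters define a simulated
#' subject; `stop_latency_mu` is the true stopping latency that SSRT
#' estimation should recover.
#'
#' @param go_rt_mu,go_rt_sigma Gaussian component of the go finishing time (ms).
#' @param go_rt_tau Exponential-tail mean of the go finishing time (ms).
#' @param stop_latency_mu,stop_latency_sigma Stop-process latency mean and
#'   standard deviation (ms).
#' @param miss_rate Probability of a go omission (no response); such trials
#'   are excluded from go-RT averaging.
#' @return An object of class `"subject_params"`.
#' @export
subject_params <- function(go_rt_mu = 450, go_rt_sigma = 60, go_rt_tau = 60,
                           stop_latency_mu = 200, stop_latency_sigma = 30,
                           miss_rate = 0) {
  if (go_rt_sigma < 0 || go_rt_tau < 0 || stop_latency_sigma < 0) {
    stop("invalid subject params: dispersions must be non-negative", call. = FALSE)
  }
  if (miss_rate < 0 || miss_rate >= 1) {
    stop("invalid subject params: miss_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(list(
    go_rt_mu = go_rt_mu, go_rt_sigma = go_rt_sigma, go_rt_tau = go_rt_tau,
    stop_latency_mu = stop_latency_mu, stop_latency_sigma = stop_latency_sigma,
    miss_rate = miss_rate
  ), class = "subject_params")
}

#' Generate a randomized go/stop trial sequence
#'
#' Shuffles `n_go` go trials and `n_stop` stop trials into uniformly random
#' order and assigns each trial a go shape: square (left-hand response) or
#' circle (right-hand response) with equal probability.
#'
#' @param config A [task_config()].
#' @param seed Integer seed for reproducibility.
#' @return A data frame with columns `index`, `kind` (`"go"`/`"stop"`) and
#'   `shape` (`"square"`/`"circle"`).
#' @examples
#' seq1 <- generate_trial_sequence(task_config(), seed = 1)
#' table(seq1$kind)
#' @export
generate_trial_sequence <- function(config = task_config(), seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  n <- config$n_go + config$n_stop
  with_seed(seed, {
    kind <- sample(rep(c("go", "stop"), c(config$n_go, config$n_stop)))
    shape <- sample(c("square", "circle"), n, replace = TRUE)
    data.frame(index = seq_len(n), kind = kind, shape = shape,
               stringsAsFactors = FALSE)
  })
}

#' Simulate one stop-signal session
#'
#' Runs the race model over a full randomized session. On go trials the
#' subject responds at the go finishing time (unless the trial is a miss).
#' On stop trials the response is inhibited if the stop process (SSD plus
#' stopping latency) finishes before the go process; the SSD is then moved
#' up by `ssd_step` after a successful stop and down after a failed stop,
#' clipped to `[ssd_min, ssd_max]`. Trial outcomes use the standard labels
#' SG/FG (successful/failed go) and SS/FS (successful/failed stop).
#'
#' @param config A [task_config()].
#' @param subject A [subject_params()].
#' @param seed Integer seed.
#' @return An object of class `"ssrt_session"`: a list with the trial log
#'   (`trials` data frame with `index`, `kind`, `shape`, `ssd_ms`, `rt_ms`,
#'   `outcome`), the config, seed, and summary statistics `p_inhibit`,
#'   `mean_ssd`, `mean_go_rt`, `ssrt`.
#' @examples
#' sess <- run_session(task_config(), subject_params(), seed = 7)
#' sess$p_inhibit
#' @export
run_session <- function(config = task_config(), subject = subject_params(),
                        seed = NULL) {
  stopifnot(inherits(config, "task_config"), inherits(subject, "subject_params"))
  seq_df <- generate_trial_sequence(config, seed = seed)
  n <- nrow(seq_df)
  trials <- with_seed(if (is.null(seed)) NULL else seed + 104729L, {
    ssd <- config$ssd_initial
    ssd_ms <- rep(NA_real_, n)
    rt_ms <- rep(NA_real_, n)
    outcome <- character(n)
    for (i in seq_len(n)) {
      go_t <- rexgauss(1, subject$go_rt_mu, subject$go_rt_sigma, subject$go_rt_tau)
      miss <- subject$miss_rate > 0 && stats::runif(1) < subject$miss_rate
      if (seq_df$kind[i] == "go") {
        if (miss) {
          outcome[i] <- "FG"              # omission: no RT recorded
        } else {
          outcome[i] <- "SG"
          rt_ms[i] <- go_t
        }
      } else {
        ssd_ms[i] <- ssd
        stop_t <- ssd + stats::rnorm(1, subject$stop_latency_mu,
                                     subject$stop_latency_sigma)
        if (miss || stop_t < go_t) {
          outcome[i] <- "SS"
          ssd <- min(ssd + config$ssd_step, config$ssd_max)
        } else {
          outcome[i] <- "FS"
          rt_ms[i] <- go_t
          ssd <- max(ssd - config$ssd_step, config$ssd_min)
        }
      }
    }
    cbind(seq_df, data.frame(ssd_ms = ssd_ms, rt_ms = rt_ms, outcome = outcome,
                             stringsAsFactors = FALSE))
  })
  n_ss <- sum(trials$outcome == "SS")
  n_fs <- sum(trials$outcome == "FS")
  go_rts <- trials$rt_ms[trials$kind == "go" & trials$outcome == "SG"]
  mean_ssd <- if (config$n_stop > 0) mean(trials$ssd_ms, na.rm = TRUE) else NA_real_
  mean_go_rt <- if (length(go_rts)) mean(go_rts) else NA_real_
  out <- structure(list(
    trials = trials, config = config, subject = subject, seed = seed,
    p_inhibit = if (n_ss + n_fs > 0) n_ss / (n_ss + n_fs) else NA_real_,
    mean_ssd = mean_ssd, mean_go_rt = mean_go_rt
  ), class = "ssrt_session")
  out$ssrt <- tryCatch(estimate_ssrt(out), error = function(e) NA_real_)
  out
}

#' Estimate the stop-signal reaction time (mean method)
#'
#' SSRT is estimated as the mean go reaction time minus the mean SSD over
#' all stop trials. Under a converged 1-up/1-down staircase the mean SSD
#' approximates the delay at which inhibition succeeds 50% of the time, so
#' this difference estimates the latency of the stopping process.
#'
#' @param session An `"ssrt_session"` from [run_session()].
#' @return SSRT in ms.
#' @export
estimate_ssrt <- function(session) {
  stopifnot(inherits(session, "ssrt_session"))
  tr <- session$trials
  go_rts <- tr$rt_ms[tr$kind == "go" & tr$outcome == "SG"]
  ssds <- tr$ssd_ms[tr$kind == "stop"]
  if (length(go_rts) == 0 || length(ssds) == 0) {
    stop("insufficient data: need at least one responded go trial and one stop trial",
         call. = FALSE)
  }
  mean(go_rts) - mean(ssds)
}

#' @export
print.ssrt_session <- function(x, ...) {
  tab <- table(factor(x$trials$outcome, levels = c("SG", "FG", "SS", "FS")))
  cat("Stop-signal session (", nrow(x$trials), " trials, seed ",
      if (is.null(x$seed)) "none" else x$seed, ")\n", sep = "")
  cat("  outcomes: ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n", sep = "")
  cat(sprintf("  p(inhibit) = %.3f   mean SSD = %.1f ms   mean go RT = %.1f ms   SSRT = %.1f ms\n",
              x$p_inhibit, x$mean_ssd, x$mean_go_rt, x$ssrt))
  invisible(x)
}

#' @export
summary.ssrt_session <- function(object, ...) {
  tr <- object$trials
  structure(list(
    n_trials = nrow(tr),
    n_go = sum(tr$kind == "go"), n_stop = sum(tr$kind == "stop"),
    outcomes = table(factor(tr$outcome, levels = c("SG", "FG", "SS", "FS"))),
    p_inhibit = object$p_inhibit, mean_ssd = object$mean_ssd,
    mean_go_rt = object$mean_go_rt, ssrt = object$ssrt
  ), class = "summary.ssrt_session")
}

#' @export
print.summary.ssrt_session <- function(x, ...) {
  cat("Trials:", x$n_trials, "(", x$n_go, "go /", x$n_stop, "stop )\n")
  print(x$outcomes)
  cat(sprintf("p(inhibit) %.3f | mean SSD %.1f | mean go RT %.1f | SSRT %.1f ms\n",
              x$p_inhibit, x$mean_ssd, x$mean_go_rt, x$ssrt))
  invisible(x)
}

#' Write / read a trial log as CSV
#'
#' Columns: `index`, `kind`, `shape`, `ssd_ms`, `rt_ms`, `outcome`.
#'
#' @param session An `"ssrt_session"` (or its `trials` data frame).
#' @param path Output CSV path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns
#'   the trial-log data frame.
#' @export
write_trials <- function(session, path) {
  tr <- if (inherits(session, "ssrt_session")) session$trials else session
  stopifnot(is.data.frame(tr))
  utils::write.csv(tr[, c("index", "kind", "shape", "ssd_ms", "rt_ms", "outcome")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(index = "integer", kind = "character",
                                       shape = "character", ssd_ms = "numeric",
                                       rt_ms = "numeric", outcome = "character"))
  need <- c("index", "kind", "shape", "ssd_ms", "rt_ms", "outcome")
  if (!all(need %in% names(tr))) {
    stop("trial log is missing columns: ",
         paste(setdiff(need, names(tr)), collapse = ", "), call. = FALSE)
  }
  tr
}
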