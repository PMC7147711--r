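# Shared fixture builders. Everything is generated in code at test time.

# Montage restricted to the channels the connectivity pair set needs.
conn_montage <- function(extra = character(0)) {
  montage_1020(unique(c("F3", "F4", "T7", "T8", "O1", "O2", extra)))
}

# A small go-only session for generator tests.
go_session <- function(n = 50, seed = 101) {
  run_session(task_config(n_go = n, n_stop = 0), subject_params(), seed = seed)
}

# Single-channel epochs carrying one go-locked burst with phase
# concentration kappa across trials.
kappa_epochs <- function(kappa, n_trials = 200, freq = 5, noise_sd = 1,
                         seed = 7, amplitude = 10) {
  cfg <- eeg_gen_config(
    montage = montage_1020("F3"), window = c(-200, 800), noise_sd = noise_sd,
    specs = oscillation_spec("F3", freq = freq, amplitude = amplitude,
                             onset = 100, offset = 700, kappa = kappa))
  simulate_epochs(cfg, go_session(n_trials), seed = seed)
}

# Simple phase unwrapping, for phase-slope checks.
unwrap_test <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

# Scaled-down pipeline configuration used for end-to-end tests.
small_pipeline_config <- function(n_surrogates = 60, seeds = c(task = 11, eeg = 22, plv = 33)) {
  pipeline_config(
    task = task_config(n_go = 45, n_stop = 15),
    eeg = eeg_gen_config(
      montage = montage_1020(c("F3", "FZ", "F4", "T7", "TP8", "T8",
                               "O1", "OZ", "O2")),
      specs = default_oscillations()),
    freqs = seq(2, 30, 2),
    itc_channels = c("F3", "FZ", "F4", "O1"),
    n_surrogates = n_surrogates,
    seeds = seeds)
}
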