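dft_peak_hz <- function(w, rate) {
  # frequency of the largest DFT magnitude bin (oracle for tone content)
  spec <- Mod(stats::fft(w))[1:(length(w) %/% 2)]
  (which.max(spec) - 1) * rate / length(w)
}

test_that("the stop tone is a ramped sinusoid at the requested frequency", {
  w <- make_stop_tone(750, 100, 44100)
  expect_equal(length(w), 4410)
  expect_equal(dft_peak_hz(w, 44100), 750, tolerance = 44100 / 4410 / 750)

  w2 <- make_stop_tone(200, 100, 500)
  expect_equal(length(w2), 50)
  expect_equal(dft_peak_hz(w2, 500), 200, tolerance = 0.05)

  expect_length(make_stop_tone(750, 0, 44100), 0)
  expect_error(make_stop_tone(300, 100, 500), "Nyquist")
})

test_that("epoch simulation is deterministic in config, session and seed", {
  sess <- go_session(10)
  cfg <- eeg_gen_config(montage = montage_1020(c("F3", "F4")),
                        window = c(-100, 400), noise_sd = 2,
                        specs = oscillation_spec("F3", 5, kappa = 2))
  a <- simulate_epochs(cfg, sess, seed = 5)
  b <- simulate_epochs(cfg, sess, seed = 5)
  expect_identical(a$data, b$data)
  c <- simulate_epochs(cfg, sess, seed = 6)
  expect_false(identical(a$data, c$data))
  expect_error(
    eeg_gen_config(montage = montage_1020("F3"),
                   specs = oscillation_spec("NOPE", 5)),
    "unknown channels")
})

test_that("epoch geometry and event bookkeeping follow the session", {
  sess <- run_session(task_config(n_go = 15, n_stop = 5), subject_params(),
                      seed = 31)
  cfg <- eeg_gen_config(montage = montage_1020(c("F3", "F4")), noise_sd = 1)
  ep <- simulate_epochs(cfg, sess, seed = 1)
  expect_equal(dim(ep$data), c(2, 20, 900))   # (-500,1300) ms at 500 Hz
  expect_equal(ep$time[1], -500)
  expect_equal(ep$condition, sess$trials$outcome)
  expect_equal(ep$events$stop_ms, sess$trials$ssd_ms)
  expect_equal(ep$events$response_ms, sess$trials$rt_ms)
})

test_that("measured ITC grows with the generator's phase concentration", {
  plateau_itc <- function(kappa) {
    ep <- kappa_epochs(kappa, n_trials = 150, seed = 11)
    tf <- tf_decompose(ep, freqs = c(4, 5, 6))
    m <- compute_itc(tf)
    ti <- which(m$time >= 300 & m$time <= 500)
    mean(m$itc[1, 2, ti])
  }
  vals <- vapply(c(0.5, 2, 8), plateau_itc, numeric(1))
  expect_true(all(diff(vals) > 0))
  # kappa -> Inf: identical phases, ITC near 1
  ep <- kappa_epochs(Inf, n_trials = 30, noise_sd = 0.2, seed = 12)
  m <- compute_itc(tf_decompose(ep, freqs = 5))
  ti <- which(m$time >= 300 & m$time <= 500)
  expect_gt(mean(m$itc[1, 1, ti]), 0.99)
})

test_that("between-channel coupling sets the ground-truth PLV", {
  couple_epochs <- function(jitter_sd, n = 150) {
    cfg <- eeg_gen_config(
      montage = montage_1020(c("F3", "F4")), window = c(-200, 800),
      noise_sd = 0.5,
      specs = list(
        oscillation_spec("F3", 5, amplitude = 10, onset = 100, offset = 700,
                         kappa = 0),
        oscillation_spec("F4", 5, amplitude = 10, onset = 100, offset = 700,
                         coupled_to = list(channel = "F3", offset = 0.7,
                                           jitter_sd = jitter_sd))))
    simulate_epochs(cfg, go_session(n), seed = 21)
  }
  mean_plv <- function(ep) {
    ph <- instantaneous_phase(ep, standard_bands()$theta)
    idx <- which(ep$time >= 150 & ep$time < 650)
    mean(vapply(seq_len(dim(ph)[2]), function(i)
      compute_plv(ph[1, i, idx], ph[2, i, idx]), numeric(1)))
  }
  expect_gt(mean_plv(couple_epochs(0)), 0.97)
  # near-uniform jitter: phase difference is re-drawn per trial, but within a
  # trial it is constant, so judge at the across-trial level instead
  ep <- couple_epochs(pi)
  ph <- instantaneous_phase(ep, standard_bands()$theta)
  idx <- which(ep$time >= 150 & ep$time < 650)
  d <- ph[1, , idx] - ph[2, , idx]
  across <- Mod(mean(exp(1i * as.vector(d))))
  expect_lt(across, 0.25)
  expect_gt(mean_plv(couple_epochs(0)), mean_plv(couple_epochs(0.8)))
})

test_that("amplitude-free noise keeps the ITC mask at its nominal false-positive level", {
  cfg <- eeg_gen_config(montage = montage_1020("CZ"), window = c(-200, 800),
                        noise_sd = 5, specs = list())
  frac <- vapply(1:30, function(r) {
    ep <- simulate_epochs(cfg, go_session(60, seed = 200 + r), seed = 300 + r)
    m <- compute_itc(tf_decompose(ep, freqs = seq(4, 24, 2)))
    sum(m$mask) / sum(m$valid)
  }, numeric(1))
  expect_lte(mean(frac), 0.06)
})
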