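test_that("PLV attains its bounds, is symmetric and offset-invariant", {
  set.seed(1)
  phi <- cumsum(rnorm(1000, 0, 0.3))
  expect_equal(compute_plv(phi, phi), 1, tolerance = 1e-12)
  expect_equal(compute_plv(phi, phi + 0.7), 1, tolerance = 1e-12)
  for (i in 1:5) {
    a <- runif(200, -pi, pi); b <- runif(200, -pi, pi)
    v <- compute_plv(a, b)
    expect_true(v >= 0 && v <= 1)
    expect_identical(v, compute_plv(b, a))
  }
  expect_error(compute_plv(1:3, 1:4), "equal length")
  expect_error(compute_plv(1, 2), "at least 2")
})

test_that("compute_plv matches a brute-force complex sum", {
  set.seed(2)
  for (n in c(5, 17, 50)) {
    a <- runif(n, -pi, pi); b <- runif(n, -pi, pi)
    z <- 0
    for (k in seq_len(n)) z <- z + exp(1i * (a[k] - b[k]))
    expect_equal(compute_plv(a, b), Mod(z / n), tolerance = 1e-12)
  }
})

test_that("independent phases give near-zero PLV; Gaussian jitter follows exp(-sd^2/2)", {
  set.seed(3)
  expect_lt(compute_plv(runif(1000, -pi, pi), runif(1000, -pi, pi)), 0.09)
  base <- cumsum(rnorm(4000, 0, 0.2))
  for (sd in c(0.5, 1)) {
    v <- compute_plv(base, base + 0.4 + rnorm(4000, 0, sd))
    expect_equal(v, exp(-sd^2 / 2), tolerance = 0.05)
  }
})

test_that("instantaneous phase follows the analytic signal of the band-limited input", {
  srate <- 500; ns <- 2000
  t <- (0:(ns - 1)) / srate
  ep <- eeg_epochs(array(cos(2 * pi * 10 * t), dim = c(1, 1, ns)), srate,
                   tmin = 0, channels = "CZ")
  ph <- instantaneous_phase(ep, standard_bands()$alpha)
  interior <- 300:1700
  slope <- mean(diff(unwrap_test(ph[1, 1, interior]))) * srate
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01 * 2 * pi * 10)

  ep5 <- eeg_epochs(array(cos(2 * pi * 5 * t), dim = c(1, 1, ns)), srate,
                    tmin = 0, channels = "CZ")
  ph5 <- instantaneous_phase(ep5, standard_bands()$theta)
  peaks <- which(abs((t * 5) %% 1) < 1e-9)
  peaks <- peaks[peaks > 300 & peaks < 1700]
  expect_true(all(abs(ph5[1, 1, peaks]) < 0.05))

  zero <- eeg_epochs(array(0, dim = c(1, 1, 600)), srate, tmin = 0,
                     channels = "CZ")
  expect_error(instantaneous_phase(zero, standard_bands()$theta),
               "undefined phase")
  expect_error(instantaneous_phase(ep, band_def("bad", 100, 400)), "Nyquist")
})

test_that("connectivity covers the default 11 pairs and a self-copy attains PLV 1", {
  sess <- run_session(task_config(n_go = 12, n_stop = 6), subject_params(),
                      seed = 41)
  cfg <- eeg_gen_config(montage = conn_montage(), noise_sd = 3)
  ep <- simulate_epochs(cfg, sess, seed = 42)
  conn <- connectivity(ep, bands = standard_bands("theta"),
                       windows = list(window_fixation()), n_surrogates = 0)
  expect_equal(dim(conn$plv)[1], 11)
  expect_equal(pair_labels(conn$pairs)[1], "F3-F4")

  # duplicate channel paired with itself: constant zero phase difference
  dup <- ep
  dup$data[2, , ] <- dup$data[1, , ]   # F4 := F3
  conn2 <- connectivity(dup, pairs = pair_set(rbind(c("F3", "F4"))),
                        bands = standard_bands(c("theta", "alpha")),
                        windows = list(window_fixation(), window_rt()),
                        n_surrogates = 0)
  expect_true(all(abs(conn2$plv - 1) < 1e-9, na.rm = TRUE))
})

test_that("windows resolve against per-trial events and report sample counts", {
  sess <- run_session(task_config(n_go = 10, n_stop = 6), subject_params(),
                      seed = 51)
  ep <- simulate_epochs(eeg_gen_config(montage = conn_montage(), noise_sd = 3),
                        sess, seed = 52)
  ss <- select_condition(ep, "SS")
  conn <- connectivity(ss, pairs = pair_set(rbind(c("F3", "F4"))),
                       bands = standard_bands("theta"),
                       windows = list(window_fixation(), window_ssd()),
                       n_surrogates = 0)
  # fixation: 125 samples per trial at 500 Hz; SSD window: ssd ms per trial
  expect_equal(conn$n_samples[1, 1, "fixation"], 125 * dim(ss$data)[2])
  expected_ssd <- sum(round(ss$events$stop_ms * 500 / 1000))
  expect_equal(conn$n_samples[1, 1, "ssd"], expected_ssd, tolerance = 0.02)
  # a window no trial can resolve yields NA with a warning
  expect_warning(
    conn3 <- connectivity(select_condition(ep, "SG"),
                          pairs = pair_set(rbind(c("F3", "F4"))),
                          bands = standard_bands("theta"),
                          windows = list(window_ssd()), n_surrogates = 0),
    "unresolvable")
  expect_true(all(is.na(conn3$plv)))
})

test_that("the surrogate null calibrates edge significance near 5% under independence", {
  sess <- run_session(task_config(n_go = 0, n_stop = 40), subject_params(),
                      seed = 61)
  ep <- simulate_epochs(eeg_gen_config(montage = conn_montage(), noise_sd = 5),
                        sess, seed = 62)
  ss <- tryCatch(select_condition(ep, "SS"), error = function(e) NULL)
  conn <- connectivity(ss, bands = standard_bands(),
                       windows = list(window_fixation(),
                                      analysis_window("late", "go", 400,
                                                      "go", 900)),
                       n_surrogates = 100, seed = 63)
  frac <- mean(conn$edges$significant)
  expect_lt(frac, 0.15)   # 88 null cells at nominal 5%
})

test_that("graph construction keeps only significant, baseline-exceeding edges", {
  sess <- run_session(task_config(n_go = 8, n_stop = 8), subject_params(),
                      seed = 71)
  ep <- simulate_epochs(eeg_gen_config(montage = conn_montage(), noise_sd = 4),
                        sess, seed = 72)
  conn <- connectivity(ep, bands = standard_bands("theta"),
                       windows = list(window_fixation(), window_rt()),
                       n_surrogates = 30, seed = 73)
  g <- build_graph(conn, "rt", "fixation", band = "theta")
  expect_s3_class(g, "plv_graph")
  edges <- conn$edges
  manual <- edges[edges$window == "rt" & edges$significant, "pair"]
  fix <- edges[edges$window == "fixation", c("pair", "plv")]
  manual <- manual[edges$plv[edges$window == "rt" & edges$significant] >
                     fix$plv[match(manual, fix$pair)]]
  expect_setequal(g$pair, manual)
  # contrasting a window with itself can keep no edge
  g0 <- build_graph(conn, "fixation", "fixation", band = "theta")
  expect_equal(nrow(g0), 0)
  expect_error(build_graph(conn, "nope"), "window not in result")
})
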