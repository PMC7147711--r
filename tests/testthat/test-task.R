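test_that("trial sequences have the configured composition and are seeded", {
  s1 <- generate_trial_sequence(task_config(), seed = 1)
  expect_equal(nrow(s1), 240)
  expect_equal(sum(s1$kind == "go"), 180)
  expect_equal(sum(s1$kind == "stop"), 60)
  expect_true(all(s1$shape %in% c("square", "circle")))

  expect_identical(s1, generate_trial_sequence(task_config(), seed = 1))
  s2 <- generate_trial_sequence(task_config(), seed = 2)
  expect_false(identical(s1$kind, s2$kind))
  expect_equal(table(s2$kind), table(s1$kind))

  all_go <- generate_trial_sequence(task_config(n_stop = 0), seed = 1)
  expect_true(all(all_go$kind == "go"))
  expect_error(task_config(n_go = -1), "non-negative")
  expect_error(task_config(ssd_min = 400), "ssd_min")
})

test_that("the staircase obeys its update rule and bounds", {
  # subject who always stops: zero stop latency, enormous go RTs
  always_stop <- subject_params(go_rt_mu = 1e6, go_rt_sigma = 0, go_rt_tau = 0,
                                stop_latency_mu = 0, stop_latency_sigma = 0)
  sess <- run_session(task_config(), always_stop, seed = 3)
  ssds <- sess$trials$ssd_ms[sess$trials$kind == "stop"]
  expect_equal(ssds[1], 250)
  expect_equal(ssds, pmin(250 + (seq_along(ssds) - 1) * 50, 1000))
  expect_true(all(diff(ssds) >= 0))

  # arbitrary subjects: steps are exactly +-50 unless clipped at a bound
  for (seed in 11:14) {
    s <- run_session(task_config(), subject_params(), seed = seed)
    ssd <- s$trials$ssd_ms[s$trials$kind == "stop"]
    d <- diff(ssd)
    at_bound <- ssd[-length(ssd)] %in% c(50, 1000)
    expect_true(all(abs(d[!at_bound]) == 50))
    expect_true(all(ssd >= 50 & ssd <= 1000))
  }
})

test_that("every trial gets exactly one outcome and stop trials partition into SS/FS", {
  for (seed in 21:25) {
    s <- run_session(task_config(n_go = 60, n_stop = 20),
                     subject_params(miss_rate = 0.05), seed = seed)
    tr <- s$trials
    expect_true(all(tr$outcome %in% c("SG", "FG", "SS", "FS")))
    expect_equal(sum(tr$outcome %in% c("SS", "FS")), 20)
    # ssd present iff stop trial; rt present iff a response occurred
    expect_true(all(is.na(tr$ssd_ms[tr$kind == "go"])))
    expect_true(all(!is.na(tr$ssd_ms[tr$kind == "stop"])))
    expect_true(all(!is.na(tr$rt_ms[tr$outcome %in% c("SG", "FS")])))
    expect_true(all(is.na(tr$rt_ms[tr$outcome %in% c("SS", "FG")])))
  }
})

test_that("sessions are byte-identical under the same seed", {
  a <- run_session(task_config(), subject_params(), seed = 42)
  b <- run_session(task_config(), subject_params(), seed = 42)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ssrt, b$ssrt)
})

test_that("SSRT is mean go RT minus mean SSD and recovers the stopping latency", {
  sess <- run_session(task_config(), subject_params(), seed = 5)
  expect_equal(estimate_ssrt(sess),
               mean(sess$trials$rt_ms[sess$trials$outcome == "SG"]) -
                 mean(sess$trials$ssd_ms[sess$trials$kind == "stop"]))

  # constructed log: mean go RT 500, mean SSD 250 -> SSRT 250
  fake <- structure(list(trials = data.frame(
    index = 1:2, kind = c("go", "stop"), shape = "square",
    ssd_ms = c(NA, 250), rt_ms = c(500, NA), outcome = c("SG", "SS"))),
    class = "ssrt_session")
  expect_equal(estimate_ssrt(fake), 250)

  no_stop <- run_session(task_config(n_go = 10, n_stop = 0),
                         subject_params(), seed = 1)
  expect_error(estimate_ssrt(no_stop), "insufficient data")

  # pooled sessions recover the true stopping latency (200 ms) to +-25 ms
  est <- vapply(1:150, function(s)
    estimate_ssrt(run_session(task_config(), subject_params(), seed = 3000 + s)),
    numeric(1))
  expect_lt(abs(mean(est) - 200), 25)
})

test_that("trial logs round-trip through CSV", {
  sess <- run_session(task_config(n_go = 20, n_stop = 8),
                      subject_params(), seed = 9)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trials(sess, path)
  back <- read_trials(path)
  expect_equal(back, sess$trials)
})
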