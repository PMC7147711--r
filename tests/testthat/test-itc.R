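random_tf <- function(nch = 2, ntr = 8, nf = 3, ns = 10, seed = 1) {
  set.seed(seed)
  coef <- array(complex(real = rnorm(nch * ntr * nf * ns),
                        imaginary = rnorm(nch * ntr * nf * ns)),
                dim = c(nch, ntr, nf, ns))
  structure(list(coef = coef, freqs = seq_len(nf) + 3,
                 time = seq_len(ns), cycles = rep(3, nf),
                 valid = matrix(TRUE, nf, ns), srate = 500,
                 channels = paste0("C", seq_len(nch))),
            class = "tf_decomposition")
}

test_that("compute_itc matches a brute-force phasor loop elementwise", {
  tf <- random_tf()
  m <- compute_itc(tf)
  d <- dim(tf$coef)
  brute <- array(NA_real_, dim = d[c(1, 3, 4)])
  for (c in 1:d[1]) for (f in 1:d[3]) for (t in 1:d[4]) {
    z <- 0
    for (n in 1:d[2]) z <- z + exp(1i * Arg(tf$coef[c, n, f, t]))
    brute[c, f, t] <- Mod(z / d[2])
  }
  expect_equal(unname(m$itc), brute, tolerance = 1e-12)
  expect_true(all(m$itc >= 0 & m$itc <= 1))
})

test_that("ITC is a phase-only statistic, bounded in [0, 1]", {
  tf <- random_tf(seed = 2)
  m1 <- compute_itc(tf)
  tf$coef[, 3, , ] <- tf$coef[, 3, , ] * 7.5   # rescale one trial's amplitude
  m2 <- compute_itc(tf)
  expect_equal(m1$itc, m2$itc, tolerance = 1e-12)

  # identical phases across trials attain the upper bound exactly
  tfc <- random_tf(ntr = 6, seed = 3)
  for (n in 2:6) tfc$coef[, n, , ] <- tfc$coef[, 1, , ]
  expect_equal(max(abs(compute_itc(tfc)$itc - 1)), 0, tolerance = 1e-12)

  single <- random_tf(ntr = 1)
  expect_error(compute_itc(single), "single trial")
})

test_that("the Rayleigh threshold has its closed form and calibrates the mask", {
  expect_equal(itc_threshold(60, 0.05), sqrt(-log(0.05) / 60), tolerance = 1e-12)
  expect_equal(itc_threshold(60, 0.05), 0.2234, tolerance = 1e-3)
  expect_gt(itc_threshold(60, 0.01), itc_threshold(60, 0.05))
  expect_lt(itc_threshold(60, 0.5), itc_threshold(60, 0.05))
  expect_error(itc_threshold(60, 0), "alpha")
  expect_error(itc_threshold(60, 1), "alpha")
  expect_error(itc_threshold(1, 0.05), "trials")

  # Monte-Carlo calibration under uniform phases
  set.seed(4)
  reps <- 400
  r <- itc_resultant(matrix(runif(60 * reps, -pi, pi), nrow = 60))
  expect_lt(abs(mean(r >= itc_threshold(60, 0.05)) - 0.05), 0.025)
})

test_that("uniform-phase ITC stays near zero and von Mises phases hit the Bessel ratio", {
  set.seed(5)
  r <- itc_resultant(matrix(runif(400 * 50, -pi, pi), nrow = 400))
  expect_true(mean(r < 0.12) >= 0.95)

  for (kappa in c(0.5, 2)) {
    th <- matrix(rvonmises(5000 * 8, 0, kappa), nrow = 5000)
    expect_lt(abs(mean(itc_resultant(th)) -
                    besselI(kappa, 1) / besselI(kappa, 0)), 0.02)
  }
})

test_that("the Morlet decomposition localizes frequency and preserves phase", {
  srate <- 500; ns <- 2000
  t <- (0:(ns - 1)) / srate
  # pure 10 Hz sinusoid: power maximal on the 10 Hz row at interior times
  ep <- eeg_epochs(array(sin(2 * pi * 10 * t), dim = c(1, 1, ns)), srate,
                   tmin = 0, channels = "CZ")
  tf <- tf_decompose(ep, freqs = seq(4, 20, 2))
  pow <- Mod(tf$coef[1, 1, , ])^2
  interior <- which(colSums(!tf$valid) == 0)
  expect_true(all(apply(pow[, interior], 2, which.max) == which(tf$freqs == 10)))

  # 5 Hz cosine: coefficient phase ~0 at the waveform's peaks
  ep2 <- eeg_epochs(array(cos(2 * pi * 5 * t), dim = c(1, 1, ns)), srate,
                    tmin = 0, channels = "CZ")
  tf2 <- tf_decompose(ep2, freqs = 5)
  peaks <- which(abs((t * 5) %% 1) < 1e-9)
  peaks <- peaks[tf2$valid[1, peaks]]
  expect_true(all(abs(Arg(tf2$coef[1, 1, 1, peaks])) < 0.05))

  expect_error(tf_decompose(ep, freqs = 300), "Nyquist")
  short <- eeg_epochs(array(rnorm(100), dim = c(1, 1, 100)), srate,
                      tmin = 0, channels = "CZ")
  expect_error(tf_decompose(short, freqs = 2), "shorter than")
})

test_that("ITC contrasts are antisymmetric and validate their axes", {
  tf <- random_tf(seed = 6)
  a <- compute_itc(tf)
  b <- compute_itc(random_tf(seed = 7))
  expect_true(all(contrast_itc(a, a)$diff == 0))
  expect_equal(contrast_itc(a, b)$diff, -contrast_itc(b, a)$diff)
  short <- compute_itc(random_tf(ns = 5, seed = 8))
  expect_error(contrast_itc(a, short), "mismatched axes")
})

test_that("an injected condition difference appears in the ITC contrast", {
  # theta locking only in the "SS-like" set; both sets share the noise model
  ss <- kappa_epochs(4, n_trials = 60, seed = 31)
  sg <- kappa_epochs(0, n_trials = 60, seed = 32)
  freqs <- c(3, 5, 7, 12, 20)
  ctr <- contrast_itc(compute_itc(tf_decompose(ss, freqs = freqs)),
                      compute_itc(tf_decompose(sg, freqs = freqs)))
  burst <- which(ctr$time >= 200 & ctr$time <= 600)
  in_band <- mean(ctr$diff[1, 2, burst])          # 5 Hz row
  off_band <- mean(ctr$diff[1, 5, burst])         # 20 Hz row
  expect_gt(in_band, 0.5)
  expect_lt(abs(off_band), 0.2)
})

test_that("band summaries average the map over each band's rows", {
  tf <- random_tf(nf = 5, seed = 9)
  tf$freqs <- c(2, 5, 6, 10, 20)
  m <- compute_itc(tf)
  s <- itc_band_summary(m)
  th <- s[s$band == "theta" & s$channel == "C1", ]
  expect_equal(th$itc, colMeans(m$itc[1, 2:3, ]))
  expect_setequal(unique(s$band), c("delta", "theta", "alpha", "beta"))
})
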