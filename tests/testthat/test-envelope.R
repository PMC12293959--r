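# Hilbert envelope, slow normalization, burstiness CV, envelope correlation.

test_that("Hilbert envelope tracks constant and modulated amplitudes", {
  fs <- 1000; n <- 20000; t <- (0:(n - 1)) / fs
  tone <- 3 * sin(2 * pi * 20 * t)
  env <- hilbert_envelope(tone, fs)
  core <- 501:(n - 500)
  expect_true(all(abs(env[core] - 3) < 0.03))

  am <- (1 + 0.5 * sin(2 * pi * 1 * t)) * sin(2 * pi * 20 * t)
  env_am <- hilbert_envelope(am, fs)
  target <- 1 + 0.5 * sin(2 * pi * 1 * t)
  rmse <- sqrt(mean((env_am[core] - target[core])^2))
  expect_lt(rmse / mean(target), 0.02)

  expect_error(hilbert_envelope(numeric(100), fs), "zero")
})

trim_mid <- function(x) x[round(length(x) * 0.1):round(length(x) * 0.9)]

test_that("slow normalization removes drift but keeps fast modulation", {
  fs <- 200; n <- 60 * fs; t <- (0:(n - 1)) / fs
  # constant envelope normalizes to 1
  tone <- sin(2 * pi * 20 * t)
  norm <- normalize_envelope(hilbert_envelope(tone, fs), fs)
  expect_true(all(abs(trim_mid(norm) - 1) < 0.02))
  # x2 linear amplitude ramp lives below the 0.1 Hz cutoff: CV < 0.05
  ramp <- (1 + t / max(t)) * sin(2 * pi * 20 * t)
  cv_ramp <- burstiness_cv(normalize_envelope(hilbert_envelope(ramp, fs), fs))
  expect_lt(cv_ramp, 0.05)
  expect_error(normalize_envelope(hilbert_envelope(tone, fs)[1:400], fs),
               "shorter")
})

test_that("burstiness CV matches closed forms and is scale invariant", {
  # two-level envelope {1, 3} in equal halves: population sd/mean = 0.5
  x <- c(rep(1, 50000), rep(3, 50000))
  expect_equal(burstiness_cv(x), 0.5, tolerance = 1e-4)
  expect_equal(burstiness_cv(rep(2, 1000)), 0)
  # unmodulated narrowband Gaussian noise: Rayleigh CV = sqrt(4/pi - 1)
  p <- gen_bursty_beta(duration = 60, seed = 14, burst_amp_scale = 0,
                       noise_sd = 0)
  ea <- envelope_analysis(bandpass_beta(p$meg))
  expect_lt(abs(ea$cv - sqrt(4 / pi - 1)), 0.03)
  # global amplitude scaling leaves CV unchanged
  s10 <- p$meg; s10$samples <- 10 * s10$samples
  ea10 <- envelope_analysis(bandpass_beta(s10))
  expect_equal(ea10$cv, ea$cv, tolerance = 1e-9)
})

test_that("burstiness CV increases with planted burst amplitude", {
  cv_at <- function(scale) mean(sapply(1:6, function(sd) {
    p <- gen_bursty_beta(duration = 40, seed = sd, burst_amp_scale = scale,
                         fs = 500)
    envelope_analysis(bandpass_beta(p$meg))$cv
  }))
  cvs <- sapply(c(0, 1, 2.5), cv_at)
  expect_true(all(diff(cvs) > 0))
})

test_that("envelope correlation is symmetric, affine invariant, and signed correctly", {
  fs <- 200; n <- 50 * fs; t <- (0:(n - 1)) / fs
  e1 <- structure(1 + 0.3 * sin(2 * pi * 0.7 * t), edge = 100L)
  e2 <- structure(1 - 0.3 * sin(2 * pi * 0.7 * t), edge = 100L)
  expect_equal(envelope_correlation(e1, e1), 1)
  expect_lt(envelope_correlation(e1, e2), -0.9)
  set.seed(5)
  a <- structure(runif(n, 0.5, 1.5), edge = 100L)
  b <- structure(runif(n, 0.5, 1.5), edge = 100L)
  expect_equal(envelope_correlation(a, b), envelope_correlation(b, a))
  a2 <- structure(2 * unclass(a) + 1, edge = 100L)
  expect_equal(envelope_correlation(a2, b), envelope_correlation(a, b),
               tolerance = 1e-12)
  expect_error(envelope_correlation(a, b[1:100]), "equal length")
  expect_error(envelope_correlation(a, structure(rep(1, n), edge = 100L)),
               "zero-variance")
})
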