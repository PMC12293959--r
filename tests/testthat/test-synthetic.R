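# Synthetic generators: determinism, known invariants, planted structure.

test_that("generators are bit-identical under a fixed seed and differ across seeds", {
  a <- gen_fbm(2000, hurst = 0.7, seed = 11)
  b <- gen_fbm(2000, hurst = 0.7, seed = 11)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, gen_fbm(2000, hurst = 0.7, seed = 12)$samples))

  p1 <- gen_bursty_beta(duration = 10, seed = 5)
  p2 <- gen_bursty_beta(duration = 10, seed = 5)
  expect_identical(p1$meg$samples, p2$meg$samples)
  expect_identical(p1$emg$samples, p2$emg$samples)
  expect_false(identical(p1$meg$samples, p1$emg$samples))

  expect_identical(gen_ar_linear(500, seed = 3)$samples,
                   gen_ar_linear(500, seed = 3)$samples)
  # generators restore the caller's RNG stream
  set.seed(42); r1 <- rnorm(1)
  set.seed(42); invisible(gen_white_noise(100, seed = 9)); r2 <- rnorm(1)
  expect_identical(r1, r2)
})

test_that("Lorenz trajectory is bounded on the attractor and contracts for rho < 1", {
  s <- gen_lorenz(20000)
  expect_true(all(abs(s$samples) < 25))
  expect_equal(s$fs, 100)
  # stable fixed-point regime: trajectory converges, late variability vanishes
  s2 <- gen_lorenz(5000, rho = 0.5)
  late <- s2$samples[4000:5000]
  expect_lt(sd(late), 1e-6)
  expect_error(lorenz_trajectory(100, dt = -0.01), "dt")
})

test_that("Benettin reference exponent matches the literature value for standard parameters", {
  le <- benettin_lorenz_le(10000)
  expect_gt(le, 0.8)
  expect_lt(le, 1.0)
})

test_that("fBm has the prescribed increment correlation structure", {
  expect_error(gen_fbm(1000, hurst = 1.2), "hurst")
  expect_error(gen_fbm(1000, hurst = 0), "hurst")
  # H = 0.5 is Brownian motion: increments uncorrelated at lag >= 1
  b <- gen_fbm(10000, hurst = 0.5, seed = 21)
  inc <- diff(b$samples)
  ac <- acf(inc, lag.max = 5, plot = FALSE)$acf[-1]
  expect_true(all(abs(ac) < 0.05))
  expect_lt(abs(var(inc) - 1), 0.1)
  # H = 0.8: positively correlated increments (persistent)
  b8 <- gen_fbm(10000, hurst = 0.8, seed = 21)
  ac8 <- acf(diff(b8$samples), lag.max = 1, plot = FALSE)$acf[2]
  expect_gt(ac8, 0.3)
})

test_that("AR generator matches its closed-form variance and spectral peak", {
  expect_error(gen_ar_linear(100, ar = c(0, 1.01)), "unstable")
  ar <- ar2_beta_coefs(20, 1000, 0.98)
  va <- (1 - ar[2]) / ((1 + ar[2]) * ((1 - ar[2])^2 - ar[1]^2))
  vs <- mean(sapply(1:10, function(sd)
    var(gen_ar_linear(10000, ar, seed = sd)$samples)))
  expect_lt(abs(vs / va - 1), 0.1)
  # zero-coefficient AR is white noise
  w <- gen_ar_linear(10000, ar = numeric(0), seed = 2)
  expect_lt(abs(acf(w$samples, lag.max = 1, plot = FALSE)$acf[2]), 0.05)
  # smoothed periodogram peaks near the analytic spectrum argmax
  fgrid <- seq(0.5, 100, by = 0.05)
  S <- 1 / Mod(1 - ar[1] * exp(-2i * pi * fgrid / 1000) -
                 ar[2] * exp(-4i * pi * fgrid / 1000))^2
  f_true <- fgrid[which.max(S)]
  x <- gen_ar_linear(20000, ar, seed = 4)
  sp <- spec.pgram(ts(x$samples, frequency = 1000), spans = 11, plot = FALSE)
  f_emp <- sp$freq[which.max(sp$spec)]
  expect_lt(abs(f_emp - f_true), 2)
  expect_lt(abs(f_true - 20), 1)
})

test_that("bursty-beta channels are beta-band limited with planted modulation", {
  expect_error(gen_bursty_beta(duration = 5, shared_fraction = 1.5),
               "shared_fraction")
  pair <- gen_bursty_beta(duration = 20, seed = 8)
  for (ch in pair) {
    sp <- Mod(fft(ch$samples))^2
    freq <- (seq_along(sp) - 1) * ch$fs / length(sp)
    half <- freq <= ch$fs / 2
    in_band <- half & freq >= 12 & freq <= 31
    expect_gt(sum(sp[in_band]) / sum(sp[half]), 0.85)
  }
})
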