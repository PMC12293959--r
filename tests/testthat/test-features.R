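# Nonlinear feature estimators against ground truth and invariants.

lorenz_embedded <- function(n = 12000) {
  s <- gen_lorenz(n)
  tau <- select_delay(average_mutual_information(s$samples, 100))
  list(signal = s, traj = delay_embed(s, tau = tau, m = 3),
       mp = spectral_mean_period(s))
}

test_that("Rosenstein exponent recovers the Lorenz rate and vanishes for periodic orbits", {
  le_ref <- benettin_lorenz_le(12000)
  lz <- lorenz_embedded(12000)
  le <- rosenstein_le(lz$traj, mean_period = lz$mp)
  expect_rel_error(le$value, le_ref, 0.15)
  expect_gt(le$diagnostics$r2, 0.95)

  # noiseless sinusoid: no divergence (|LE| under 5% of the Lorenz rate);
  # frequency incommensurate with fs so neighbour distances stay finite
  tone <- gen_sine(10000, fs = 100, freq = sqrt(2))
  tr <- delay_embed(tone, tau = 18, m = 2)
  le0 <- rosenstein_le(tr, fs = 100, mean_period = 71)
  expect_lt(abs(le0$value), 0.05 * le_ref)

  # iid noise: no exponential-divergence regime, flagged by low fit R^2
  w <- gen_white_noise(5000, fs = 100, seed = 23)
  trw <- delay_embed(w, tau = 1, m = 3)
  lew <- rosenstein_le(trw, fs = 100, mean_period = 4)
  expect_lt(lew$diagnostics$r2, 0.9)
  expect_error(rosenstein_le(lz$traj[1:100, ], mean_period = 10), "short")
})

test_that("Higuchi dimension is exact for a line and matches 2 - H for fBm", {
  fd_line <- higuchi_fd(seq_len(5000))
  expect_lt(abs(fd_line$value - 1), 0.01)
  for (H in c(0.3, 0.5, 0.7)) {
    fd <- higuchi_fd(gen_fbm(10000, hurst = H, seed = 41))
    expect_lt(abs(fd$value - (2 - H)), 0.1)
  }
  expect_error(higuchi_fd(rep(2, 1000)), "constant|zero")
})

test_that("correlation dimension recovers manifold dimension on known supports", {
  set.seed(7)
  th <- runif(2000, 0, 2 * pi)
  circle <- cbind(cos(th), sin(th))
  cd1 <- grassberger_procaccia_cd(circle, theiler = 0)
  expect_lt(abs(cd1$value - 1), 0.05)
  square <- cbind(runif(2000), runif(2000))
  cd2 <- grassberger_procaccia_cd(square, theiler = 0)
  expect_lt(abs(cd2$value - 2), 0.1)
  expect_error(grassberger_procaccia_cd(circle[1:50, ]), "short")
})

test_that("optimized correlation sums equal the naive double loop exactly", {
  s <- gen_lorenz(500)
  tr <- delay_embed(s, tau = 10, m = 3)
  radii <- exp(seq(log(0.5), log(10), length.out = 10))
  for (th in c(0, 5)) {
    fast <- correlation_sum(tr, radii, theiler = th, max_points = 5000)
    ref <- naive_corr_sum(tr, radii, theiler = th)
    expect_equal(fast$C, ref, tolerance = 1e-14)
  }
})

test_that("FD and CD are amplitude invariant; LE slope is scale free", {
  w <- gen_bursty_beta(duration = 12, seed = 9, fs = 500)$meg
  x <- bandpass_beta(w)$samples[1:5000]
  tr <- delay_embed(x, tau = 6, m = 4)
  tr10 <- delay_embed(10 * x, tau = 6, m = 4)
  mp <- spectral_mean_period(x, 500)
  expect_equal(higuchi_fd(10 * x)$value, higuchi_fd(x)$value,
               tolerance = 1e-6)
  expect_equal(grassberger_procaccia_cd(tr10)$value,
               grassberger_procaccia_cd(tr)$value, tolerance = 1e-6)
  expect_equal(rosenstein_le(tr10, fs = 500, mean_period = mp)$value,
               rosenstein_le(tr, fs = 500, mean_period = mp)$value,
               tolerance = 1e-6)
})

test_that("window feature extraction is deterministic and excludes failing windows", {
  cfg <- run_config(m_max = 6)
  pair <- gen_bursty_beta(duration = 21, seed = 3, fs = 500)
  bp <- bandpass_beta(pair$meg)
  ws <- segment_windows(bp, window_length = 10)
  f1 <- suppressWarnings(features_for_window(ws$windows[[1]], ws$fs, cfg))
  f2 <- suppressWarnings(features_for_window(ws$windows[[1]], ws$fs, cfg))
  expect_identical(f1$LE$value, f2$LE$value)
  expect_identical(f1$FD$value, f2$FD$value)
  expect_identical(f1$CD$value, f2$CD$value)
  expect_true(is.finite(f1$LE$value))
  expect_gte(f1$FD$value, 1)
  expect_lte(f1$FD$value, 2)

  # a constant window fails every estimator and is excluded with a message
  ws_bad <- ws
  ws_bad$windows[[2]] <- rep(1, length(ws_bad$windows[[2]]))
  expect_message(ft <- feature_table(list(ws_bad), cfg), "excluded")
  expect_true(all(ft$window_index != 2))
  expect_false(anyNA(ft$value))
})
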