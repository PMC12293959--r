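# Delay and dimension selection, delay embedding.

test_that("AMI of a sinusoid has its first minimum near a quarter period", {
  # a weakly noisy sinusoid: for a perfectly deterministic signal the
  # dependence is deterministic at every lag and the histogram AMI only
  # carries binning artifacts, so a touch of noise makes the quarter-period
  # minimum the meaningful target
  set.seed(1)
  x <- sin(2 * pi * (0:3999) / 100) + rnorm(4000, sd = 0.05)
  ami <- average_mutual_information(x, max_lag = 60)
  tau <- select_delay(ami)
  expect_gte(tau, 18)
  expect_lte(tau, 30)
  # lag 0 dominates every other lag
  expect_true(all(ami[1] >= ami[-1]))
  # matches the direct plug-in estimate at a spot-check lag
  expect_equal(ami[11], naive_ami_lag(x, 10), tolerance = 1e-12)
})

test_that("AMI of iid noise is near zero at positive lags and collapses under permutation", {
  x <- gen_white_noise(20000, seed = 13)$samples
  ami <- average_mutual_information(x, max_lag = 20)
  # bias bound for a 16-bin histogram estimator: ~ n_bins^2 / (2 N ln 2)
  bias <- 16^2 / (2 * length(x) * log(2)) * 2
  expect_true(all(ami[-1] < 0.05))
  expect_gt(ami[1], 1)  # marginal entropy
  # structured signal loses its lag structure when permuted
  y <- sin(2 * pi * (0:9999) / 100)
  ami_s <- average_mutual_information(y, max_lag = 30)
  set.seed(31)
  yp <- y[sample(seq_along(y))]
  ami_p <- average_mutual_information(yp, max_lag = 30)
  expect_gt(mean(ami_s[-1]), 10 * mean(ami_p[-1]))
  expect_error(average_mutual_information(rep(1, 1000), 20), "constant")
})

test_that("delay selection applies first-minimum, 1/e fallback, and max-lag fallback", {
  curve_min <- c(2, 1.5, 1.0, 0.7, 0.9, 1.1)
  expect_identical(select_delay(curve_min), 3L)
  # monotone decreasing: first lag strictly below AMI(0)/e
  curve_mono <- 2 * exp(-(0:20) / 5)      # equals 2/e at lag 5
  expect_identical(select_delay(curve_mono), 6L)
  curve_flat <- seq(2, 1.9, length.out = 11)
  expect_warning(tau <- select_delay(curve_flat), "max_lag")
  expect_identical(tau, 10L)
})

test_that("FNN separates closed curves, strange attractors, and noise", {
  # closed curve embeds in 2-D (period incommensurate with the sampling so
  # neighbour distances are genuine, not duplicate-sample rounding noise)
  x <- sin(2 * pi * (0:2999) / 100.37)
  fnn <- false_nearest_neighbors(x, tau = 25, m_max = 4)
  expect_lt(fnn[2], 0.01)
  # Lorenz x-coordinate needs m = 3
  s <- gen_lorenz(5000)
  tau <- select_delay(average_mutual_information(s$samples, 100))
  fnn_l <- false_nearest_neighbors(s$samples, tau = tau, m_max = 5)
  expect_identical(as.integer(select_dimension(fnn_l)), 3L)
  # iid noise stays above threshold through m_max
  w <- gen_white_noise(3000, seed = 17)$samples
  fnn_w <- false_nearest_neighbors(w, tau = 1, m_max = 6)
  expect_true(all(fnn_w > 0.01))
  expect_warning(m <- select_dimension(fnn_w), "m_max")
  expect_identical(as.integer(m), 6L)
})

test_that("FNN fractions are insensitive to time reversal", {
  # reversal changes reference subsampling and neighbour ties, so fractions
  # agree only approximately; the selected dimension must agree exactly
  s <- gen_lorenz(4000)
  f1 <- false_nearest_neighbors(s$samples, tau = 17, m_max = 5)
  f2 <- false_nearest_neighbors(rev(s$samples), tau = 17, m_max = 5)
  expect_lt(max(abs(f1 - f2)), 0.1)
})

test_that("dimension selection handles the degenerate and saturated cases", {
  expect_identical(as.integer(select_dimension(c(0.6, 0.005, 0.001))), 2L)
  expect_identical(as.integer(select_dimension(c(0, 0.5, 0.5))), 1L)
  expect_error(select_dimension(numeric(0)), "empty")
})

test_that("delay embedding has the exact row/column construction", {
  tr <- delay_embed(1:100, tau = 5, m = 3)
  expect_identical(dim(tr), c(90L, 3L))
  expect_identical(tr[1, ], c(1, 6, 11))
  expect_identical(tr[90, ], c(90, 95, 100))
  # point i component j equals x[i + (j-1) tau] everywhere
  x <- rnorm(200)
  tr2 <- delay_embed(x, tau = 7, m = 4)
  for (j in 1:4)
    expect_identical(tr2[, j], x[(1 + (j - 1) * 7):((j - 1) * 7 + nrow(tr2))])
  # m = 1: the signal itself as a column
  tr1 <- delay_embed(x, tau = 3, m = 1)
  expect_identical(as.vector(tr1), x)
  expect_error(delay_embed(1:10, tau = 5, m = 3), "too short")
})
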