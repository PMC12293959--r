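# Independent reference implementations used to validate the package's
# optimized paths on small instances.

# Naive O(N^2) correlation sum via stats::dist, no subsampling.
naive_corr_sum <- function(traj, radii, theiler = 0) {
  traj <- as.matrix(traj)
  n <- nrow(traj)
  d <- as.matrix(stats::dist(traj))
  keep <- abs(row(d) - col(d)) > theiler & upper.tri(d)
  dd <- d[keep]
  sapply(radii, function(r) mean(dd < r))
}

# Brute-force Grassberger-Procaccia slope on a state matrix: correlation sum
# on a fine log radius grid, slope over the small-radius half below
# saturation.
naive_gp_dimension <- function(states, theiler = 0, n_radii = 40) {
  states <- as.matrix(states)
  d <- as.matrix(stats::dist(states))
  keep <- abs(row(d) - col(d)) > theiler & upper.tri(d)
  dd <- d[keep]
  qs <- stats::quantile(dd, c(0.001, 0.5))
  radii <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_radii))
  C <- sapply(radii, function(r) mean(dd < r))
  ok <- C > 0 & C < 0.2
  fit <- stats::lm(log(C[ok]) ~ log(radii[ok]))
  unname(stats::coef(fit)[2])
}

# Narrow AMI reference: direct plug-in histogram estimate for one lag.
naive_ami_lag <- function(x, k, n_bins = 16) {
  rng <- range(x)
  ib <- pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins))
  a <- ib[1:(length(x) - k)]
  b <- ib[(1 + k):length(x)]
  tab <- table(factor(a, levels = 1:n_bins), factor(b, levels = 1:n_bins))
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pa, pb)[nz]))
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
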