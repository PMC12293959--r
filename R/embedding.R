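# Phase-space reconstruction: delay from the first minimum of average
# mutual information, dimension from false nearest neighbours.

#' Average mutual information over lags
#'
#' Histogram-based (equal-width bins) mutual information, in bits, between
#' `x(t)` and `x(t + k)` for `k = 0..max_lag`.  Fixed binning keeps the
#' estimate fully deterministic.
#'
#' @param x numeric vector or [beta_signal].
#' @param max_lag largest lag in samples (must be below `length(x)/4`).
#' @param n_bins number of histogram bins per axis (>= 4).
#' @return Numeric vector of length `max_lag + 1`; element `k + 1` is the
#'   mutual information at lag `k`.
#' @examples
#' ami <- average_mutual_information(sin(2 * pi * (0:999) / 100), 50)
#' @export
average_mutual_information <- function(x, max_lag = 100, n_bins = 16) {
  x <- as_signal_samples(x)
  n <- length(x)
  if (max_lag >= n / 4) stop("`max_lag` must be below length(x)/4")
  if (n_bins < 4) stop("`n_bins` must be at least 4")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant signal has zero entropy")
  # bin index in 1..n_bins
  ib <- pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins))
  ami <- numeric(max_lag + 1)
  for (k in 0:max_lag) {
    a <- ib[1:(n - k)]
    b <- ib[(1 + k):n]
    joint <- tabulate(a + n_bins * (b - 1L), nbins = n_bins * n_bins)
    joint <- joint / sum(joint)
    pa <- tabulate(a, nbins = n_bins) / length(a)
    pb <- tabulate(b, nbins = n_bins) / length(b)
    pij <- matrix(joint, n_bins, n_bins)
    nz <- pij > 0
    outer_p <- outer(pa, pb)
    ami[k + 1] <- sum(pij[nz] * log2(pij[nz] / outer_p[nz]))
  }
  ami
}

#' Select the embedding delay from an AMI curve
#'
#' The delay is the first strict local minimum of the AMI curve; if none
#' exists (common for narrowband signals), the first lag where AMI drops
#' below `AMI(0)/e`; as a last resort the largest lag, with a warning.
#' Before minimum detection the curve is smoothed with a centered 3-point
#' moving average (endpoints untouched): histogram AMI estimates carry
#' lag-to-lag quantization wiggles that would otherwise trigger spuriously
#' early minima, while genuine minima are broad and survive the smoothing.
#' The 1/e fallback uses the raw curve.
#'
#' @param ami_curve output of [average_mutual_information()] (lag 0 first).
#' @return Integer delay in samples (>= 1).
#' @export
select_delay <- function(ami_curve) {
  nl <- length(ami_curve)
  if (nl < 3) stop("AMI curve must cover at least 3 lags")
  sm <- as.vector(stats::filter(ami_curve, rep(1 / 3, 3), sides = 2))
  sm[c(1, nl)] <- ami_curve[c(1, nl)]
  for (k in 2:(nl - 1)) {
    if (sm[k] < sm[k - 1] && sm[k] < sm[k + 1])
      return(k - 1L)  # curve index k is lag k-1
  }
  below <- which(ami_curve < ami_curve[1] / exp(1))
  below <- below[below > 1]
  if (length(below) > 0) return(below[1] - 1L)
  warning("AMI curve has no minimum and never drops below AMI(0)/e; ",
          "using max_lag")
  nl - 1L
}

#' False-nearest-neighbour fractions
#'
#' Kennel's test for the minimal embedding dimension: for each candidate
#' dimension `m`, the fraction of nearest neighbours (Theiler-excluded) that
#' are "false" -- flagged by either the distance-ratio test
#' (`> r_tol`) or the attractor-size test (`> a_tol` times the signal SD).
#'
#' @param x numeric vector or [beta_signal].
#' @param tau embedding delay in samples.
#' @param m_max largest candidate dimension (>= 2).
#' @param r_tol,a_tol Kennel tolerances (defaults 15 and 2).
#' @param theiler temporal exclusion window in samples (default `tau`).
#' @param n_ref number of reference points used to estimate each fraction
#'   (evenly strided; neighbours are searched over all points).
#' @return Numeric vector of fractions in [0, 1], one per `m = 1..m_max`.
#' @export
false_nearest_neighbors <- function(x, tau, m_max = 10, r_tol = 15,
                                    a_tol = 2, theiler = tau,
                                    n_ref = 1000L) {
  x <- as_signal_samples(x)
  if (m_max < 2) stop("`m_max` must be at least 2")
  if (length(x) - m_max * tau < 10)
    stop("fewer than 10 usable points at m_max = ", m_max,
         " with tau = ", tau)
  .fnn_cpp(x, as.integer(tau), as.integer(m_max), r_tol, a_tol,
           as.integer(theiler), as.integer(n_ref))
}

#' Select the embedding dimension from FNN fractions
#'
#' @param fnn_fractions output of [false_nearest_neighbors()].
#' @param threshold acceptable false-neighbour fraction (default 0.01).
#' @return Integer dimension: the smallest `m` with fraction at or below the
#'   threshold, or `m_max` (with attribute `saturated = TRUE` and a warning)
#'   if no candidate qualifies.
#' @export
select_dimension <- function(fnn_fractions, threshold = 0.01) {
  if (length(fnn_fractions) == 0) stop("empty FNN fractions")
  ok <- which(fnn_fractions <= threshold)
  if (length(ok) > 0) return(as.integer(ok[1]))
  warning("FNN fraction never fell below ", threshold,
          "; using m_max = ", length(fnn_fractions))
  structure(as.integer(length(fnn_fractions)), saturated = TRUE)
}

#' Delay embedding
#'
#' Builds the reconstructed state-space trajectory: point `i` has components
#' `x[i + (j - 1) * tau]`, `j = 1..m`.
#'
#' @param x numeric vector or [beta_signal].
#' @param tau delay in samples (>= 1).
#' @param m embedding dimension (>= 1).
#' @param fs sampling rate carried on the result (taken from the signal when
#'   `x` is a [beta_signal]).
#' @return A numeric matrix of dimension `(length(x) - (m-1)*tau) x m` with
#'   attributes `tau`, `m`, `fs`.
#' @examples
#' tr <- delay_embed(1:100, tau = 5, m = 3)  # 90 x 3
#' @export
delay_embed <- function(x, tau, m, fs = NULL) {
  if (inherits(x, "beta_signal")) {
    fs <- fs %||% x$fs
    x <- x$samples
  }
  tau <- as.integer(tau); m <- as.integer(m)
  if (tau < 1 || m < 1) stop("`tau` and `m` must be positive integers")
  np <- length(x) - (m - 1L) * tau
  if (np < 1) stop("signal too short to embed: need length > (m-1)*tau")
  traj <- vapply(seq_len(m), function(j) x[(1L + (j - 1L) * tau):
                                             ((j - 1L) * tau + np)],
                 numeric(np))
  traj <- matrix(traj, nrow = np, ncol = m)
  attr(traj, "tau") <- tau
  attr(traj, "m") <- m
  attr(traj, "fs") <- fs
  traj
}

#' Estimate delay and dimension for one window
#'
#' Convenience wrapper chaining [average_mutual_information()],
#' [select_delay()], [false_nearest_neighbors()] and [select_dimension()].
#'
#' @param x numeric vector or [beta_signal].
#' @param max_lag,n_bins AMI parameters.
#' @param m_max,r_tol,a_tol,fnn_threshold,n_ref FNN parameters.
#' @return List with `tau`, `m`, `ami_curve`, `fnn_fractions`.
#' @export
estimate_embedding <- function(x, max_lag = 100, n_bins = 16, m_max = 10,
                               r_tol = 15, a_tol = 2, fnn_threshold = 0.01,
                               n_ref = 1000L) {
  x <- as_signal_samples(x)
  ami <- average_mutual_information(x, max_lag = max_lag, n_bins = n_bins)
  tau <- select_delay(ami)
  fnn <- false_nearest_neighbors(x, tau = tau, m_max = m_max, r_tol = r_tol,
                                 a_tol = a_tol, n_ref = n_ref)
  m <- select_dimension(fnn, threshold = fnn_threshold)
  list(tau = tau, m = m, ami_curve = ami, fnn_fractions = fnn)
}
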