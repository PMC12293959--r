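# Per-window nonlinear features: Rosenstein largest Lyapunov exponent,
# Higuchi fractal dimension, Grassberger-Procaccia correlation dimension.

feature_value <- function(name, value, diagnostics = list()) {
  structure(list(name = name, value = value, diagnostics = diagnostics),
            class = "feature_value")
}

#' @export
print.feature_value <- function(x, ...) {
  cat(sprintf("<feature_value> %s = %.6g", x$name, x$value))
  if (!is.null(x$diagnostics$r2))
    cat(sprintf("  (fit R2 = %.3f)", x$diagnostics$r2))
  cat("\n")
  invisible(x)
}

#' Mean period of a signal from its spectral mean frequency
#'
#' `fs / mean frequency`, with the mean frequency the power-weighted average
#' frequency of the raw periodogram.  Used as the Theiler window and default
#' divergence fit span for the Lyapunov estimator.
#'
#' @param x numeric vector or [beta_signal].
#' @param fs sampling rate in Hz (ignored when `x` is a [beta_signal]).
#' @return Mean period in samples (>= 1).
#' @export
spectral_mean_period <- function(x, fs = 1) {
  if (inherits(x, "beta_signal")) { fs <- x$fs; x <- x$samples }
  n <- length(x)
  spec <- Mod(fft(x - mean(x))[2:(floor(n / 2) + 1)])^2
  freq <- (1:floor(n / 2)) * fs / n
  mf <- sum(freq * spec) / sum(spec)
  max(1, round(fs / mf))
}

#' Largest Lyapunov exponent (Rosenstein's method)
#'
#' For every reference point on the reconstructed trajectory, finds the
#' nearest neighbour outside a Theiler window of `mean_period` samples, then
#' tracks the average log-distance between the pair over `fit_span` forward
#' steps.  The exponent is the least-squares slope of the divergence curve
#' (natural log per sample) over its linear region, multiplied by the
#' sampling rate, i.e. in 1/s (equivalently 1/model-time-unit when
#' `fs = 1/dt`).  The linear region is selected automatically as the
#' contiguous span covering at least half of the curve that maximizes the
#' linear-fit R^2: the first few steps of the curve reflect neighbour
#' alignment rather than exponential divergence, and a fixed full-span fit
#' is biased upward by that transient.  A low fit R^2 in the diagnostics
#' flags the absence of a genuine exponential-divergence regime (e.g. for
#' noise).
#'
#' @param traj trajectory matrix from [delay_embed()].
#' @param fs sampling rate in Hz (default: the trajectory's `fs` attribute).
#' @param mean_period Theiler window in samples; use
#'   [spectral_mean_period()] of the underlying window.
#' @param fit_span number of forward steps for the divergence fit
#'   (default = `mean_period`, Rosenstein's recommendation of about one
#'   mean period).
#' @param n_ref number of reference points (evenly strided).
#' @return A `feature_value` (name `"LE"`), diagnostics: divergence curve,
#'   fit R^2, number of neighbour pairs.
#' @export
rosenstein_le <- function(traj, fs = attr(traj, "fs"), mean_period,
                          fit_span = mean_period, n_ref = 1000L) {
  if (nrow(traj) < 500) stop("trajectory too short (< 500 points)")
  if (mean_period < 1) stop("`mean_period` must be >= 1")
  fit_span <- as.integer(fit_span)
  n <- nrow(traj)
  refs <- unique(as.integer(round(seq(0, n - fit_span - 1,
                                      length.out = min(n_ref, n - fit_span)))))
  res <- .nn_divergence_cpp(traj, refs, as.integer(mean_period), fit_span)
  if (res$n_pairs == 0) stop("no valid neighbour pairs (Theiler window ",
                             "excluded every candidate)")
  curve <- res$curve
  if (all(!is.finite(curve))) stop("non-finite divergence curve")
  fit <- best_linear_region(0:fit_span, curve, min_frac = 0.5,
                            min_len = 5L)
  feature_value("LE", fit$slope * fs,
                diagnostics = list(curve = curve, r2 = fit$r2,
                                   region = c(fit$from, fit$to),
                                   n_pairs = res$n_pairs,
                                   fit_span = fit_span,
                                   mean_period = mean_period))
}

#' Higuchi fractal dimension
#'
#' Higuchi's curve-length construction on the scalar series: for each scale
#' `k = 1..k_max`, the normalized curve length `L(k)` is averaged over the
#' `k` possible offsets; FD is the least-squares slope of `log L(k)` versus
#' `log(1/k)`.  FD is 1 for a smooth curve and approaches 2 for
#' plane-filling noise; values outside [1, 2] trigger a warning.
#'
#' @param x numeric vector or [beta_signal].
#' @param k_max largest scale (default 16; `length(x)` must be at least
#'   `10 * k_max`).
#' @return A `feature_value` (name `"FD"`), diagnostics: `log_k`,
#'   `log_L`, fit R^2.
#' @examples
#' higuchi_fd(seq_len(2000))$value  # straight line: FD = 1
#' @export
higuchi_fd <- function(x, k_max = 16) {
  x <- as_signal_samples(x)
  n <- length(x)
  if (n < 10 * k_max) stop("signal shorter than 10 * k_max")
  L <- numeric(k_max)
  for (k in seq_len(k_max)) {
    # all offsets at once: |x[i+k] - x[i]| assigned to offset (i-1) mod k
    d <- abs(diff(x, lag = k))
    off <- ((seq_len(n - k) - 1L) %% k) + 1L
    sums <- rowsum(d, off)
    nm <- tabulate(off, nbins = k)
    L[k] <- mean(sums * (n - 1) / (nm * k) / k)
  }
  if (any(L == 0)) stop("zero curve length (constant signal?)")
  fit <- ls_slope(log(1 / seq_len(k_max)), log(L))
  fd <- fit$slope
  if (fd < 1 - 1e-6 || fd > 2 + 1e-6)
    warning(sprintf("Higuchi FD = %.3f outside [1, 2]", fd))
  feature_value("FD", fd,
                diagnostics = list(log_k = log(seq_len(k_max)),
                                   log_L = log(L), r2 = fit$r2))
}

#' Correlation sum over a set of radii
#'
#' Fraction of Theiler-admissible point pairs within distance `r` of each
#' other, for each radius.  Pair counting runs in compiled code over an
#' evenly strided subsample of at most `max_points` trajectory points
#' (attractor geometry is preserved by striding; the cap bounds the O(N^2)
#' cost).
#'
#' @param traj trajectory matrix (rows = state vectors).
#' @param radii increasing vector of radii.
#' @param theiler temporal exclusion window in samples (original time
#'   index).
#' @param max_points subsample cap (default 2000).
#' @return List with `C` (correlation sums, one per radius) and `n_pairs`.
#' @export
correlation_sum <- function(traj, radii, theiler = 0, max_points = 2000L) {
  traj <- as.matrix(traj)
  n <- nrow(traj)
  idx <- unique(as.integer(round(seq(1, n, length.out = min(max_points, n)))))
  res <- .corr_sum_cpp(traj, idx - 1L, idx, as.double(radii),
                       as.integer(theiler))
  if (res$n_pairs == 0) stop("Theiler window excluded every pair")
  res
}

# Best contiguous linear region (span >= min_frac of the points) by
# linear-fit R^2; returns the fit over that region with its bounds.
best_linear_region <- function(x, y, min_frac = 1 / 3, min_len = 3L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  nr <- length(x)
  min_len <- min(nr, max(min_len, ceiling(nr * min_frac)))
  if (nr < min_len) stop("too few points for a scaling-region fit")
  best <- NULL
  for (a in 1:(nr - min_len + 1)) {
    for (b in (a + min_len - 1):nr) {
      fit <- ls_slope(x[a:b], y[a:b])
      if (is.null(best) || (is.finite(fit$r2) && fit$r2 > best$r2))
        best <- c(fit, list(from = a, to = b))
    }
  }
  best
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Computes the correlation sum `C(r)` on `n_radii` log-spaced radii
#' between the 0.1th and 50th percentile of pairwise distances, then takes
#' the slope of `log C(r)` versus `log r` over the automatically selected
#' scaling region: radii in the saturation zone (`C(r)` above `c_max`) are
#' excluded, and the scaling region is the contiguous span of at least one
#' third of the remaining radii that maximizes the linear-fit R^2.  The low
#' radius floor is needed to reach the genuine scaling regime of strange
#' attractors; the saturation cutoff keeps the fit away from the bend where
#' `C(r)` approaches 1.
#'
#' @param traj trajectory matrix from [delay_embed()] (or raw states).
#' @param n_radii number of radii (default 24).
#' @param theiler temporal exclusion window in samples (default: the
#'   trajectory's `tau` attribute, else 1).
#' @param max_points subsample cap for pair counting (default 2000).
#' @param c_max saturation cutoff on the correlation sum (default 0.2).
#' @return A `feature_value` (name `"CD"`), diagnostics: radii, correlation
#'   sums, scaling region (indices into the kept radii), fit R^2.
#' @export
grassberger_procaccia_cd <- function(traj, n_radii = 24,
                                     theiler = attr(traj, "tau") %||% 1,
                                     max_points = 2000L, c_max = 0.2) {
  traj <- as.matrix(traj)
  if (nrow(traj) < 200) stop("trajectory too short (< 200 points)")
  # percentile scan on a coarser stride to pick the radius range
  idx <- unique(as.integer(round(seq(1, nrow(traj),
                                     length.out = min(1000L, nrow(traj))))))
  d <- as.vector(stats::dist(traj[idx, , drop = FALSE]))
  d <- d[d > 0]
  qs <- quantile(d, c(0.001, 0.5), names = FALSE)
  radii <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_radii))
  cs <- correlation_sum(traj, radii, theiler = theiler,
                        max_points = max_points)
  keep <- cs$C > 0 & cs$C <= c_max
  if (sum(keep) < 3) keep <- cs$C > 0  # degenerate: everything saturated
  fit <- best_linear_region(log(radii)[keep], log(cs$C)[keep])
  feature_value("CD", fit$slope,
                diagnostics = list(radii = radii, C = cs$C,
                                   region = c(fit$from, fit$to),
                                   r2 = fit$r2, n_pairs = cs$n_pairs))
}

#' Compute the three nonlinear features for one window
#'
#' Estimates the embedding (delay from AMI, dimension from FNN) once per
#' window, then computes the Lyapunov exponent and correlation dimension on
#' the embedded trajectory and the Higuchi fractal dimension on the scalar
#' window.
#'
#' @param window numeric vector (one segment from [segment_windows()]).
#' @param fs sampling rate in Hz.
#' @param config parameter list from [run_config()].
#' @return List with `LE`, `FD`, `CD` (`feature_value`s) and `embedding`
#'   (the [estimate_embedding()] result).
#' @export
features_for_window <- function(window, fs, config = run_config()) {
  out <- list()
  needs_embedding <- any(c("LE", "CD") %in% config$features)
  if (needs_embedding) {
    emb <- estimate_embedding(window, max_lag = config$max_lag,
                              n_bins = config$n_bins, m_max = config$m_max,
                              r_tol = config$r_tol, a_tol = config$a_tol,
                              fnn_threshold = config$fnn_threshold,
                              n_ref = config$fnn_n_ref)
    traj <- delay_embed(window, tau = emb$tau, m = emb$m, fs = fs)
    mp <- spectral_mean_period(window, fs)
    out$embedding <- emb
  }
  if ("LE" %in% config$features)
    out$LE <- rosenstein_le(traj, fs = fs, mean_period = mp,
                            n_ref = config$le_n_ref)
  if ("FD" %in% config$features)
    out$FD <- higuchi_fd(window, k_max = config$k_max)
  if ("CD" %in% config$features)
    out$CD <- grassberger_procaccia_cd(traj, n_radii = config$n_radii,
                                       theiler = emb$tau,
                                       max_points = config$cd_max_points)
  out
}

#' Per-window feature table for a set of signals
#'
#' Runs [features_for_window()] over every window of every (already
#' band-passed) signal and collects the values in tidy long format.
#' Windows where an estimator fails are excluded with a logged reason
#' rather than producing NaN rows.
#'
#' @param window_sets list of `window_set` objects (see
#'   [segment_windows()]).
#' @param config parameter list from [run_config()].
#' @param quiet suppress progress messages.
#' @return data.frame with columns `subject_id`, `modality`,
#'   `window_index`, `feature`, `value`, `fit_r2`.
#' @export
feature_table <- function(window_sets, config = run_config(),
                          quiet = TRUE) {
  if (inherits(window_sets, "window_set")) window_sets <- list(window_sets)
  rows <- list()
  for (ws in window_sets) {
    for (w in seq_along(ws$windows)) {
      fv <- tryCatch(
        suppressWarnings(features_for_window(ws$windows[[w]], ws$fs,
                                             config)),
        error = function(e) e)
      if (inherits(fv, "error")) {
        message(sprintf("excluded %s/%s window %d: %s", ws$subject_id,
                        ws$modality, w, conditionMessage(fv)))
        next
      }
      for (nm in intersect(c("LE", "FD", "CD"), names(fv))) {
        v <- fv[[nm]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = ws$subject_id, modality = ws$modality,
          window_index = w, feature = nm, value = v$value,
          fit_r2 = v$diagnostics$r2 %||% NA_real_,
          stringsAsFactors = FALSE)
      }
      if (!quiet)
        message(sprintf("%s/%s window %d done", ws$subject_id,
                        ws$modality, w))
    }
  }
  if (length(rows) == 0)
    return(data.frame(subject_id = character(), modality = character(),
                      window_index = integer(), feature = character(),
                      value = numeric(), fit_r2 = numeric()))
  do.call(rbind, rows)
}
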