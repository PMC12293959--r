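# Zero-phase FFT-based cosine filtering and fixed-window segmentation.

# Raised-cosine frequency-domain gain.  Each band edge carries a cosine
# flank of width `transition` centred on the edge (gain 0.5 at the edge
# itself), with unity gain in the passband.  `lo = NULL` gives a low-pass,
# `hi = NULL` a high-pass.
cosine_gain <- function(f, lo = NULL, hi = NULL, transition) {
  g <- rep(1, length(f))
  ramp <- function(x) 0.5 * (1 - cos(pi * x))  # 0 -> 1 over x in [0, 1]
  if (!is.null(lo)) {
    a <- lo - transition / 2
    b <- lo + transition / 2
    g <- g * ifelse(f <= a, 0, ifelse(f >= b, 1, ramp((f - a) / transition)))
  }
  if (!is.null(hi)) {
    a <- hi - transition / 2
    b <- hi + transition / 2
    g <- g * ifelse(f <= a, 1, ifelse(f >= b, 0,
                                      1 - ramp((f - a) / transition)))
  }
  g
}

# Zero-phase filter core: reflect-pad 1 s at each end, zero-pad to the next
# 5-smooth FFT length, multiply the spectrum by the (real, symmetric) cosine
# gain, and crop.  A purely real gain leaves the phase untouched, so the
# filter has no group delay by construction.
fft_cosine_filter <- function(x, fs, lo = NULL, hi = NULL, transition) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(round(fs)))
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  np <- length(xp)
  nfft <- nextn(np, c(2, 3, 5))
  xp <- c(xp, numeric(nfft - np))
  f <- c(0:(floor(nfft / 2)), -((ceiling(nfft / 2) - 1):1)) * fs / nfft
  g <- cosine_gain(abs(f), lo = lo, hi = hi, transition = transition)
  y <- Re(fft(fft(xp) * g, inverse = TRUE)) / nfft
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase beta band-pass filter
#'
#' Band-pass filters a signal with a zero-phase FFT-based cosine filter:
#' unity gain in the passband, raised-cosine flanks of width `transition`
#' centred on the band edges (so the gain is exactly 0.5 at `lo` and `hi`),
#' zero elsewhere, and no group delay.  Filtering is applied to the full
#' recording (before any segmentation) to avoid per-window edge artifacts.
#'
#' @param signal a [beta_signal].
#' @param lo,hi band edges in Hz (defaults 13 and 30, the beta band).
#' @param transition flank width in Hz on each edge (default 2).
#' @return A [beta_signal] with filtered samples; the band is recorded in
#'   the `band` element.
#' @examples
#' s <- gen_sine(5000, fs = 1000, freq = 20)
#' f <- bandpass_beta(s)
#' @export
bandpass_beta <- function(signal, lo = 13, hi = 30, transition = 2) {
  stopifnot(inherits(signal, "beta_signal"))
  fs <- signal$fs
  if (lo >= hi) stop("`lo` must be below `hi`")
  if (hi + transition / 2 >= fs / 2)
    stop("upper band edge (plus flank) exceeds the Nyquist frequency")
  if (length(signal$samples) <= 10 * fs / lo)
    stop("signal too short for a meaningful band-pass at ", lo, " Hz")
  out <- signal
  out$samples <- fft_cosine_filter(signal$samples, fs, lo = lo, hi = hi,
                                   transition = transition)
  out$band <- c(lo = lo, hi = hi, transition = transition)
  out
}

#' Segment a signal into fixed non-overlapping windows
#'
#' Cuts the recording into contiguous, non-overlapping windows of
#' `window_length` seconds (default 10), discarding any trailing remainder.
#'
#' @param signal a [beta_signal].
#' @param window_length window length in seconds.
#' @return A `window_set`: list with `windows` (list of equal-length numeric
#'   vectors), `fs`, `window_length`, `subject_id`, `modality`.
#' @examples
#' s <- gen_white_noise(25000, fs = 1000, seed = 1)
#' ws <- segment_windows(s, window_length = 10)  # 2 windows, 5 s discarded
#' length(ws$windows)
#' @export
segment_windows <- function(signal, window_length = 10) {
  stopifnot(inherits(signal, "beta_signal"))
  wl <- as.integer(round(window_length * signal$fs))
  n <- length(signal$samples)
  n_win <- n %/% wl
  if (n_win < 1)
    stop("signal (", n / signal$fs, " s) shorter than one window (",
         window_length, " s)")
  windows <- lapply(seq_len(n_win), function(w)
    signal$samples[((w - 1L) * wl + 1L):(w * wl)])
  structure(list(windows = windows, fs = signal$fs,
                 window_length = window_length,
                 subject_id = signal$subject_id,
                 modality = signal$modality),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %s/%s: %d windows of %g s @ %g Hz\n",
              x$subject_id, x$modality, length(x$windows),
              x$window_length, x$fs))
  invisible(x)
}
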