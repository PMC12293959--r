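# Hilbert amplitude envelope, slow normalization, burstiness CV, and
# cross-modal envelope correlation.

#' Hilbert amplitude envelope
#'
#' Modulus of the analytic signal (FFT construction).  The input is assumed
#' to be band-passed already; the first and last 0.5 s are edge regions
#' where the analytic signal is unreliable, and downstream statistics trim
#' them.
#'
#' @param x numeric vector or [beta_signal] (band-passed samples).
#' @param fs sampling rate in Hz (ignored when `x` is a [beta_signal]).
#' @return Numeric vector of envelope values (non-negative) with attribute
#'   `edge` = number of edge samples (0.5 s) at each end.
#' @examples
#' env <- hilbert_envelope(gen_sine(5000, freq = 20, amp = 3))
#' @export
hilbert_envelope <- function(x, fs = NULL) {
  if (inherits(x, "beta_signal")) { fs <- fs %||% x$fs; x <- x$samples }
  if (is.null(fs)) stop("`fs` required")
  if (all(x == 0)) stop("all-zero input has no meaningful envelope")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- fft(fft(x) * h, inverse = TRUE) / n
  structure(Mod(analytic), edge = as.integer(round(0.5 * fs)))
}

#' Normalize an envelope by its slow component
#'
#' Divides the envelope pointwise by a zero-phase low-pass filtered version
#' of itself (cutoff 0.1 Hz by default), isolating relative amplitude
#' fluctuations and removing slow drifts such as gradual gain changes.
#'
#' @param raw_envelope numeric envelope from [hilbert_envelope()].
#' @param fs sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz (default 0.1).
#' @param transition cosine flank width in Hz (default `cutoff / 2`).
#' @return Normalized envelope (positive, mean near 1 for stationary
#'   input), preserving the `edge` attribute.
#' @export
normalize_envelope <- function(raw_envelope, fs, cutoff = 0.1,
                               transition = cutoff / 2) {
  n <- length(raw_envelope)
  if (n < 3 / cutoff * fs)
    stop("recording shorter than 3/cutoff = ", 3 / cutoff,
         " s; slow normalization is not meaningful")
  slow <- fft_cosine_filter(raw_envelope, fs, hi = cutoff,
                            transition = transition)
  if (any(slow <= 0))
    stop("low-passed envelope is non-positive; pathological input")
  structure(raw_envelope / slow, edge = attr(raw_envelope, "edge"))
}

trim_edges <- function(x, edge = attr(x, "edge") %||% 0L) {
  n <- length(x)
  if (2 * edge >= n) stop("edge trim would remove the whole record")
  x[(edge + 1L):(n - edge)]
}

#' Burstiness: coefficient of variation of the normalized envelope
#'
#' `CV = SD / mean` of the slow-normalized beta envelope over the full task
#' recording (edge regions excluded); higher values reflect more transient
#' burst-like amplitude fluctuations.  For unmodulated narrowband Gaussian
#' noise the envelope is Rayleigh and CV = sqrt(4/pi - 1), about 0.523.
#'
#' @param normalized_envelope output of [normalize_envelope()].
#' @return CV (single non-negative number).
#' @export
burstiness_cv <- function(normalized_envelope) {
  x <- trim_edges(normalized_envelope)
  if (length(x) == 0) stop("empty envelope")
  m <- mean(x)
  if (m == 0) stop("zero-mean envelope")
  sd(x) / m
}

#' Cross-modal envelope correlation
#'
#' Pearson product-moment correlation between two time-aligned normalized
#' envelopes (edge-trimmed), one per modality.
#'
#' @param env_meg,env_emg normalized envelopes of equal length.
#' @return Correlation coefficient in [-1, 1].
#' @export
envelope_correlation <- function(env_meg, env_emg) {
  if (length(env_meg) != length(env_emg))
    stop("envelopes must have equal length")
  a <- trim_edges(env_meg)
  b <- trim_edges(env_emg)
  if (sd(a) == 0 || sd(b) == 0) stop("zero-variance envelope")
  cor(a, b)
}

#' Envelope analysis of a band-passed signal
#'
#' Chains [hilbert_envelope()], [normalize_envelope()] and
#' [burstiness_cv()].
#'
#' @param signal band-passed [beta_signal].
#' @param cutoff slow-normalization cutoff in Hz.
#' @return List with `raw_envelope`, `normalized_envelope`, `cutoff`, `cv`.
#' @export
envelope_analysis <- function(signal, cutoff = 0.1) {
  raw <- hilbert_envelope(signal)
  norm <- normalize_envelope(raw, signal$fs, cutoff = cutoff)
  list(raw_envelope = raw, normalized_envelope = norm, cutoff = cutoff,
       cv = burstiness_cv(norm))
}
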