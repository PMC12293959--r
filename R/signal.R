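#' Construct a single-channel signal object
#'
#' Container for one subject/modality time series.  The pipeline assumes
#' artifact-cleaned input and starts at band-pass filtering, so a
#' `beta_signal` only carries samples, a sampling rate and identifying
#' metadata.
#'
#' @param samples numeric vector of samples (arbitrary units).
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id subject identifier.
#' @param modality `"MEG"`, `"EMG"`, or another label for synthetic inputs.
#' @param kind provenance label (e.g. `"recorded"`, `"lorenz"`,
#'   `"bursty_beta"`).
#' @return An object of class `beta_signal`: a list with elements `samples`,
#'   `fs`, `subject_id`, `modality`, `kind`.
#' @examples
#' s <- beta_signal(sin(2 * pi * 20 * (0:999) / 1000), fs = 1000)
#' s
#' @export
beta_signal <- function(samples, fs, subject_id = NA_character_,
                        modality = NA_character_, kind = "recorded") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  samples <- as.double(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("signal contains NaN/Inf samples")
  structure(
    list(samples = samples, fs = fs,
         subject_id = as.character(subject_id),
         modality = as.character(modality), kind = kind),
    class = "beta_signal")
}

#' @export
print.beta_signal <- function(x, ...) {
  cat(sprintf("<beta_signal> %s/%s [%s]: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$modality, x$kind,
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.beta_signal <- function(x) length(x$samples)

as_signal_samples <- function(x) {
  if (inherits(x, "beta_signal")) x$samples else as.double(x)
}
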