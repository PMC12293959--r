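# Delimited-text signal files and subject manifests.
#
# Signal file format: comment header lines "# key: value" (fs, kind,
# subject_id, modality) followed by one sample per row, printed with 17
# significant digits so that write -> read round-trips bit-exactly.

#' Write a signal to a delimited-text file
#'
#' @param signal a [beta_signal].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "beta_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs: %.17g", signal$fs),
               sprintf("# kind: %s", signal$kind),
               sprintf("# subject_id: %s", signal$subject_id),
               sprintf("# modality: %s", signal$modality)), con)
  writeLines(formatC(signal$samples, digits = 17, format = "g"), con)
  invisible(path)
}

#' Read a signal from a delimited-text file
#'
#' @param path file written by [write_signal()].
#' @param subject_id,modality optional overrides for the header metadata
#'   (used when the manifest, not the file, is authoritative).
#' @return A [beta_signal].
#' @export
read_signal <- function(path, subject_id = NULL, modality = NULL) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  get_hdr <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) == 0) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  fs <- as.numeric(get_hdr("fs"))
  if (!is.finite(fs)) stop("missing or invalid fs header in ", path)
  samples <- as.numeric(lines[!is_hdr])
  if (anyNA(samples))
    stop("non-numeric or NaN samples in ", path)
  beta_signal(samples, fs = fs,
              subject_id = subject_id %||% get_hdr("subject_id"),
              modality = modality %||% get_hdr("modality"),
              kind = get_hdr("kind"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a subject manifest
#'
#' @param df data frame with columns `subject_id`, `modality`, `path`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(df, path) {
  stopifnot(all(c("subject_id", "modality", "path") %in% names(df)))
  write.csv(df[, c("subject_id", "modality", "path")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load all signals referenced by a manifest
#'
#' Reads a manifest CSV (columns `subject_id`, `modality`, `path`; relative
#' paths resolved against the manifest's directory) and loads every signal.
#' Each (subject, modality) pair must be unique and every file must exist
#' and parse cleanly; violations raise an error naming the offending row.
#'
#' @param path manifest CSV path.
#' @param quiet suppress the per-file sample-count log.
#' @return A list of [beta_signal]s (empty, with a warning, for an empty
#'   manifest).
#' @export
load_manifest <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(man) == 0) {
    warning("manifest is empty: ", path)
    return(list())
  }
  stopifnot(all(c("subject_id", "modality", "path") %in% names(man)))
  key <- paste(man$subject_id, man$modality)
  if (anyDuplicated(key))
    stop("duplicate (subject, modality) pair in manifest: ",
         key[duplicated(key)][1])
  base <- dirname(normalizePath(path))
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p))
      stop(sprintf("manifest row %d (%s/%s): file not found: %s",
                   i, man$subject_id[i], man$modality[i], man$path[i]))
    sig <- read_signal(p, subject_id = man$subject_id[i],
                       modality = man$modality[i])
    if (!quiet)
      message(sprintf("loaded %s/%s: %d samples @ %g Hz",
                      sig$subject_id, sig$modality, length(sig$samples),
                      sig$fs))
    out[[i]] <- sig
  }
  out
}
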