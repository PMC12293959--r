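# Study orchestration: configuration, demo cohort generation, and the full
# simulate -> preprocess -> features -> envelope -> surrogates -> stats run.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its default.
#' Defaults follow the analysis conventions this pipeline implements:
#' beta band 13-30 Hz with 2 Hz cosine flanks, 10 s non-overlapping
#' windows, histogram AMI with 16 bins and first-minimum delay selection,
#' Kennel FNN (r_tol 15, a_tol 2, 1 percent threshold), Higuchi k_max 16,
#' 24 log-spaced radii with a 2000-point pair-counting cap for the
#' correlation dimension, 0.1 Hz envelope normalization, and 100 surrogate
#' realizations.
#'
#' @param band_lo,band_hi,band_transition band-pass edges and flank (Hz).
#' @param window_length window length in seconds.
#' @param max_lag,n_bins AMI parameters (samples, bins).
#' @param m_max,r_tol,a_tol,fnn_threshold,fnn_n_ref FNN parameters.
#' @param k_max Higuchi scale cap.
#' @param n_radii,cd_max_points correlation-dimension parameters.
#' @param le_n_ref reference points for the Lyapunov divergence curve.
#' @param envelope_cutoff slow-normalization cutoff (Hz).
#' @param n_surrogates surrogate realizations per signal (0 disables the
#'   surrogate stage).
#' @param features which features to compute (subset of `"LE"`, `"FD"`,
#'   `"CD"`).
#' @param master_seed master seed for every stochastic stage.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(band_lo = 13, band_hi = 30, band_transition = 2,
                       window_length = 10,
                       max_lag = 100, n_bins = 16,
                       m_max = 10, r_tol = 15, a_tol = 2,
                       fnn_threshold = 0.01, fnn_n_ref = 1000L,
                       k_max = 16,
                       n_radii = 24, cd_max_points = 2000L,
                       le_n_ref = 1000L,
                       envelope_cutoff = 0.1,
                       n_surrogates = 100L,
                       features = c("LE", "FD", "CD"),
                       master_seed = 1L) {
  stopifnot(band_lo > 0, band_lo < band_hi, window_length > 0,
            all(features %in% c("LE", "FD", "CD")))
  structure(as.list(environment()), class = "run_config")
}

#' Generate a synthetic demo cohort
#'
#' Writes paired pseudo-MEG/EMG recordings for `n_subjects` subjects with
#' heterogeneous burst parameters (per-subject burst rate and amplitude
#' scale drawn around the generator defaults) and a planted shared-envelope
#' fraction, plus a manifest CSV.
#'
#' @param dir output directory (created if needed).
#' @param n_subjects cohort size (default 17).
#' @param seed master seed.
#' @param duration per-subject recording length in seconds (default 600).
#' @param fs sampling rate in Hz.
#' @param shared_fraction planted shared envelope fraction.
#' @return Path of the manifest CSV, invisibly.
#' @export
make_demo_cohort <- function(dir, n_subjects = 17, seed = 1L,
                             duration = 600, fs = 1000,
                             shared_fraction = 0.3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    pars <- with_seed(child_seed(seed, 100, s), list(
      burst_rate = runif(1, 0.8, 1.6),
      burst_amp_scale = runif(1, 1.0, 2.0)))
    pair <- gen_bursty_beta(fs = fs, duration = duration,
                            seed = child_seed(seed, 200, s),
                            burst_rate = pars$burst_rate,
                            burst_amp_scale = pars$burst_amp_scale,
                            shared_fraction = shared_fraction,
                            subject_id = sid)
    for (mod in c("meg", "emg")) {
      fn <- sprintf("%s_%s.txt", sid, toupper(mod))
      write_signal(pair[[mod]], file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, modality = toupper(mod), path = fn,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  write_manifest(do.call(rbind, rows), manifest)
  invisible(manifest)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full study pipeline
#'
#' Orchestrates the whole flow for a cohort: load signals from the
#' manifest, band-pass to the beta band, segment into windows, compute the
#' per-window nonlinear features, the envelope burstiness and cross-modal
#' envelope correlation, the surrogate comparison, and the group
#' statistics.  All outputs are tidy TSV/JSON files; a rerun with the same
#' manifest and config reproduces them byte-identically.
#'
#' @param manifest path to a manifest CSV (see [load_manifest()]).
#' @param config parameter list from [run_config()].
#' @param out_dir output directory.
#' @return List with the feature table, envelope table, correlation table,
#'   surrogate table (or NULL), and the stats list, invisibly.
#' @export
run_study <- function(manifest, config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  logf("run_study: seed %d, band %g-%g Hz, %g s windows",
       config$master_seed, config$band_lo, config$band_hi,
       config$window_length)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  signals <- load_manifest(manifest, quiet = TRUE)
  if (length(signals) == 0) stop("no signals in manifest")

  # preprocess + features
  bp <- lapply(signals, function(s)
    bandpass_beta(s, lo = config$band_lo, hi = config$band_hi,
                  transition = config$band_transition))
  ws <- lapply(bp, segment_windows, window_length = config$window_length)
  logf("features: %d signals, %d windows each", length(ws),
       length(ws[[1]]$windows))
  ft <- feature_table(ws, config)
  write_tsv(ft, file.path(out_dir, "features.tsv"))

  # envelope / burstiness on the full band-passed record
  env_rows <- list(); envs <- list()
  for (s in bp) {
    ea <- envelope_analysis(s, cutoff = config$envelope_cutoff)
    envs[[paste(s$subject_id, s$modality)]] <- ea$normalized_envelope
    env_rows[[length(env_rows) + 1L]] <- data.frame(
      subject_id = s$subject_id, modality = s$modality, cv = ea$cv,
      stringsAsFactors = FALSE)
  }
  env_tab <- do.call(rbind, env_rows)
  write_tsv(env_tab, file.path(out_dir, "burstiness.tsv"))

  subjects <- unique(env_tab$subject_id)
  r_rows <- list()
  for (sid in subjects) {
    km <- paste(sid, "MEG"); ke <- paste(sid, "EMG")
    if (!is.null(envs[[km]]) && !is.null(envs[[ke]]))
      r_rows[[length(r_rows) + 1L]] <- data.frame(
        subject_id = sid,
        envelope_r = envelope_correlation(envs[[km]], envs[[ke]]),
        stringsAsFactors = FALSE)
  }
  r_tab <- if (length(r_rows)) do.call(rbind, r_rows) else NULL
  if (!is.null(r_tab)) write_tsv(r_tab, file.path(out_dir, "envelope_r.tsv"))
  logf("envelope: %d subjects with paired channels",
       length(r_rows))

  # surrogates
  sur_tab <- NULL
  if (config$n_surrogates > 0) {
    sur_list <- lapply(seq_along(signals), function(i)
      surrogate_features(signals[[i]], config, n = config$n_surrogates,
                         seed = child_seed(config$master_seed, 300, i)))
    sur_tab <- do.call(rbind, sur_list)
    write_tsv(sur_tab, file.path(out_dir, "surrogates.tsv"))
    logf("surrogates: %d realizations per signal", config$n_surrogates)
  }

  stats <- study_statistics(ft, env_tab, r_tab, sur_tab)
  jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  logf("done")
  invisible(list(features = ft, burstiness = env_tab, envelope_r = r_tab,
                 surrogates = sur_tab, stats = stats))
}

#' Group statistics for a completed run
#'
#' Computes the statistics layer from the pipeline tables: paired t tests
#' between modalities for each feature (per-subject means over windows)
#' with Cohen's d and post hoc power; one-sample t tests against zero of
#' the per-subject cross-modal correlations (envelope, and each feature's
#' window series); original-versus-surrogate paired t tests; Pearson
#' correlations between burstiness and each feature across subjects; and
#' the per-subject stability summary.
#'
#' @param ft feature table ([feature_table()]).
#' @param env_tab burstiness table (subject_id, modality, cv).
#' @param r_tab envelope correlation table (subject_id, envelope_r) or
#'   NULL.
#' @param sur_tab surrogate table ([surrogate_features()] rows) or NULL.
#' @return Nested list of results (data frames and scalars), suitable for
#'   JSON serialization.
#' @export
study_statistics <- function(ft, env_tab, r_tab = NULL, sur_tab = NULL) {
  out <- list()
  feats <- unique(ft$feature)
  per <- stability_summary(ft)
  out$stability <- list(
    group = per$group,
    sd_comparison = lapply(per$sd_comparison, as.data.frame))

  # modality comparison on per-subject means
  ps <- per$per_subject
  mods <- unique(ps$modality)
  if (length(mods) == 2) {
    cmp <- list()
    for (f in feats) {
      a <- ps[ps$feature == f & ps$modality == "MEG", ]
      b <- ps[ps$feature == f & ps$modality == "EMG", ]
      common <- intersect(a$subject_id, b$subject_id)
      if (length(common) < 3) next
      cmp[[f]] <- as.data.frame(paired_t(
        a$mean[match(common, a$subject_id)],
        b$mean[match(common, b$subject_id)],
        label = sprintf("%s: MEG vs EMG", f)))
    }
    out$modality_comparison <- cmp

    # cross-modal similarity: per-subject correlation of window series
    sim <- list()
    for (f in feats) {
      rs <- c()
      for (sid in unique(ps$subject_id)) {
        a <- ft[ft$feature == f & ft$modality == "MEG" &
                  ft$subject_id == sid, ]
        b <- ft[ft$feature == f & ft$modality == "EMG" &
                  ft$subject_id == sid, ]
        common <- intersect(a$window_index, b$window_index)
        if (length(common) < 4) next
        rs <- c(rs, cor(a$value[match(common, a$window_index)],
                        b$value[match(common, b$window_index)]))
      }
      if (length(rs) >= 3)
        sim[[f]] <- c(list(mean_r = mean(rs), sd_r = sd(rs)),
                      as.data.frame(one_sample_t(
                        rs, label = sprintf("%s cross-modal r vs 0", f))))
    }
    out$feature_similarity <- sim
  }

  if (!is.null(r_tab) && nrow(r_tab) >= 3)
    out$envelope_similarity <- c(
      list(mean_r = mean(r_tab$envelope_r), sd_r = sd(r_tab$envelope_r)),
      as.data.frame(one_sample_t(r_tab$envelope_r,
                                 label = "envelope r vs 0")))

  # burstiness vs features, per modality
  bf <- list()
  for (mod in unique(env_tab$modality)) {
    cvs <- env_tab[env_tab$modality == mod, ]
    for (f in feats) {
      m <- ps[ps$feature == f & ps$modality == mod, ]
      common <- intersect(cvs$subject_id, m$subject_id)
      if (length(common) < 4) next
      pr <- pearson_across_subjects(
        cvs$cv[match(common, cvs$subject_id)],
        m$mean[match(common, m$subject_id)])
      bf[[paste0(mod, "_", f)]] <- pr
    }
  }
  out$burstiness_correlation <- bf

  if (!is.null(sur_tab)) {
    sv <- list()
    for (mod in unique(sur_tab$modality)) {
      for (f in unique(sur_tab$feature)) {
        g <- sur_tab[sur_tab$modality == mod & sur_tab$feature == f, ]
        if (nrow(g) < 3) next
        res <- tryCatch(
          paired_t(g$original_value, g$surrogate_mean,
                   label = sprintf("%s %s: original vs surrogate", mod, f)),
          error = function(e) NULL)
        if (!is.null(res)) sv[[paste0(mod, "_", f)]] <- as.data.frame(res)
      }
    }
    out$surrogate_comparison <- sv
  }
  out
}
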