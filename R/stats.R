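# Group-level statistics: paired and one-sample t tests, across-subject
# Pearson correlations, Cohen's d, exact noncentral-t post hoc power, and
# per-subject stability summaries.

group_stat_result <- function(label, t, df, p, d = NA_real_,
                              power = NA_real_, n) {
  structure(list(label = label, t = t, df = df, p = p, d = d,
                 power = power, n = n),
            class = "group_stat_result")
}

#' @export
print.group_stat_result <- function(x, ...) {
  cat(sprintf("%s: t(%d) = %.3f, p = %.4g", x$label, x$df, x$t, x$p))
  if (is.finite(x$d)) cat(sprintf(", d = %.3f", x$d))
  if (is.finite(x$power)) cat(sprintf(", power = %.3f", x$power))
  cat(sprintf("  [n = %d]\n", x$n))
  invisible(x)
}

#' @export
as.data.frame.group_stat_result <- function(x, ...) {
  data.frame(label = x$label, t = x$t, df = x$df, p = x$p, d = x$d,
             power = x$power, n = x$n, stringsAsFactors = FALSE)
}

#' Paired-sample t test with effect size and post hoc power
#'
#' Two-sided paired t test on subject-wise differences, with Cohen's d for
#' paired designs (`mean(x - y) / sd(x - y)`) and exact noncentral-t post
#' hoc power at alpha = 0.05.  The identity `|t| = |d| sqrt(n)` holds by
#' construction.
#'
#' @param x,y per-subject values, paired by position (n >= 3).
#' @param label comparison label.
#' @return A `group_stat_result` (fields `t`, `df = n - 1`, `p`, `d`,
#'   `power`, `n`).
#' @examples
#' paired_t(c(2, 1, 3, 0), c(1, 1, 2, 1))
#' @export
paired_t <- function(x, y, label = "paired") {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  d_i <- x - y
  n <- length(d_i)
  if (n < 3) stop("need at least 3 pairs")
  s <- sd(d_i)
  if (!is.finite(s) || s == 0) stop("zero-variance differences")
  t_stat <- mean(d_i) / (s / sqrt(n))
  d <- mean(d_i) / s
  group_stat_result(label, t_stat, n - 1L,
                    2 * pt(-abs(t_stat), n - 1),
                    d, posthoc_power_paired(d, n), n)
}

#' One-sample t test
#'
#' @param x per-subject values (n >= 3, nonzero variance).
#' @param mu0 null value (default 0).
#' @param label comparison label.
#' @return A `group_stat_result` with `d = mean(x - mu0) / sd(x)`.
#' @export
one_sample_t <- function(x, mu0 = 0, label = "one-sample") {
  n <- length(x)
  if (n < 3) stop("need at least 3 values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance")
  t_stat <- (mean(x) - mu0) / (s / sqrt(n))
  d <- (mean(x) - mu0) / s
  group_stat_result(label, t_stat, n - 1L,
                    2 * pt(-abs(t_stat), n - 1),
                    d, posthoc_power_paired(d, n), n)
}

#' Pearson correlation across subjects
#'
#' Product-moment correlation with a two-sided p value from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))`, df = n - 2.
#'
#' @param a,b per-subject values (n >= 4).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_across_subjects <- function(a, b) {
  if (length(a) != length(b)) stop("unequal lengths")
  n <- length(a)
  if (n < 4) stop("need at least 4 subjects")
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance")
  r <- cor(a, b)
  t_stat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(t_stat), n - 2), n = n)
}

#' Cohen's d for paired samples
#'
#' `d = mean(x - y) / sd(x - y)`; the sign follows the direction of the
#' difference.
#'
#' @param x,y paired per-subject values.
#' @return Cohen's d.
#' @export
cohens_d_paired <- function(x, y) {
  d_i <- x - y
  s <- sd(d_i)
  if (!is.finite(s) || s == 0) stop("zero-variance differences")
  mean(d_i) / s
}

#' Post hoc power of a paired (or one-sample) t test
#'
#' Exact power under the noncentral t distribution: with noncentrality
#' `|d| sqrt(n)` and df = n - 1, the power is the probability that |T|
#' exceeds the two-sided central critical value at `alpha`.  At d = 0 the
#' power equals alpha; power is strictly increasing in |d| and in n.
#'
#' @param d Cohen's d (paired).
#' @param n number of pairs (>= 2).
#' @param alpha significance level (default 0.05).
#' @param two_sided logical (default TRUE).
#' @return Power in [0, 1].
#' @examples
#' posthoc_power_paired(1.98, 17)  # well above 0.99
#' @export
posthoc_power_paired <- function(d, n, alpha = 0.05, two_sided = TRUE) {
  if (n < 2) stop("need n >= 2")
  df <- n - 1
  ncp <- abs(d) * sqrt(n)
  if (two_sided) {
    tc <- qt(1 - alpha / 2, df)
    (1 - pt(tc, df, ncp)) + pt(-tc, df, ncp)
  } else {
    tc <- qt(1 - alpha, df)
    1 - pt(tc, df, ncp)
  }
}

#' Per-subject stability summary of windowed features
#'
#' For each subject, modality and feature: the mean and SD of the feature
#' over time windows (the SD measures how stable the feature is across the
#' task).  Group rows aggregate the per-subject values across subjects.
#' When both modalities are present, a paired t test across subjects
#' compares the per-subject SDs between modalities (does one modality
#' fluctuate more over time than the other?).
#'
#' @param ft feature table from [feature_table()].
#' @return List with `per_subject` (data.frame: subject_id, modality,
#'   feature, n_windows, mean, sd), `group` (data.frame: modality, feature,
#'   group_mean, group_sd, mean_within_sd), and `sd_comparison` (list of
#'   `group_stat_result` per feature, or NULL).
#' @export
stability_summary <- function(ft) {
  key <- interaction(ft$subject_id, ft$modality, ft$feature, drop = TRUE)
  per <- do.call(rbind, lapply(split(ft, key), function(g) {
    data.frame(subject_id = g$subject_id[1], modality = g$modality[1],
               feature = g$feature[1], n_windows = nrow(g),
               mean = mean(g$value),
               sd = if (nrow(g) > 1) sd(g$value) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  if (any(per$n_windows < 2)) {
    warning("excluding ", sum(per$n_windows < 2),
            " single-window subject(s) from SD summaries")
  }
  grp <- do.call(rbind, lapply(
    split(per, interaction(per$modality, per$feature, drop = TRUE)),
    function(g) data.frame(modality = g$modality[1], feature = g$feature[1],
                           n_subjects = nrow(g),
                           group_mean = mean(g$mean),
                           group_sd = sd(g$mean),
                           mean_within_sd = mean(g$sd, na.rm = TRUE),
                           stringsAsFactors = FALSE)))
  rownames(grp) <- NULL
  sd_cmp <- NULL
  mods <- unique(per$modality)
  if (length(mods) == 2) {
    sd_cmp <- list()
    for (f in unique(per$feature)) {
      a <- per[per$feature == f & per$modality == mods[1] &
                 per$n_windows >= 2, ]
      b <- per[per$feature == f & per$modality == mods[2] &
                 per$n_windows >= 2, ]
      common <- intersect(a$subject_id, b$subject_id)
      if (length(common) < 3) next
      res <- tryCatch(
        paired_t(a$sd[match(common, a$subject_id)],
                 b$sd[match(common, b$subject_id)],
                 label = sprintf("SD(%s): %s vs %s", f, mods[1], mods[2])),
        error = function(e) NULL)  # zero-variance SDs: no difference
      sd_cmp[[f]] <- res
    }
  }
  list(per_subject = per, group = grp, sd_comparison = sd_cmp)
}
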