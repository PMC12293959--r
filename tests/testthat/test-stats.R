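# Group statistics layer.

test_that("paired t test matches hand computation and stats::t.test", {
  r <- paired_t(c(1, 0, 1, -1), rep(0, 4))
  expect_equal(r$t, 0.522, tolerance = 1e-3)
  expect_identical(r$df, 3L)
  expect_equal(r$d, 0.261, tolerance = 1e-3)

  set.seed(8)
  x <- rnorm(17, 1); y <- rnorm(17)
  r2 <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(r2$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-12)
  expect_error(paired_t(x, x), "zero-variance")
  # |t| = |d| sqrt(n) identity on random inputs
  for (i in 1:10) {
    a <- rnorm(10); b <- rnorm(10)
    rr <- paired_t(a, b)
    expect_equal(abs(rr$t), abs(rr$d) * sqrt(10), tolerance = 1e-12)
    expect_equal(rr$d, cohens_d_paired(a, b), tolerance = 1e-15)
  }
})

test_that("one-sample t test matches hand computation and equals paired on differences", {
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$t, 3.464, tolerance = 1e-3)
  expect_identical(r$df, 2L)
  expect_error(one_sample_t(rep(5, 10), mu0 = 5), "zero")
  set.seed(9)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(one_sample_t(x - y)$t, paired_t(x, y)$t, tolerance = 1e-12)
  expect_equal(one_sample_t(x - y)$p, paired_t(x, y)$p, tolerance = 1e-12)
})

test_that("across-subject Pearson correlation matches cor.test", {
  a <- c(1, 3, 2, 5, 4, 6)
  expect_equal(pearson_across_subjects(a, 2 * a + 1)$r, 1)
  expect_equal(pearson_across_subjects(a, -a)$r, -1)
  set.seed(10)
  x <- rnorm(17); y <- 0.5 * x + rnorm(17)
  r <- pearson_across_subjects(x, y)
  ref <- cor.test(x, y)
  expect_equal(r$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  expect_error(pearson_across_subjects(x[1:3], y[1:3]), "at least 4")
})

test_that("planted across-subject correlation is recovered within Monte-Carlo bounds", {
  rho <- 0.8
  set.seed(12)
  rs <- replicate(200, {
    a <- rnorm(17)
    b <- rho * a + sqrt(1 - rho^2) * rnorm(17)
    pearson_across_subjects(a, b)$r
  })
  expect_lt(abs(mean(rs) - rho), 0.05)
})

test_that("post hoc power follows the noncentral t exactly", {
  # null case: power equals alpha
  expect_equal(posthoc_power_paired(0, 17), 0.05, tolerance = 1e-12)
  # agreement with power.t.test (independent implementation; strict mode
  # counts rejections in both tails, as the two-sided power must)
  for (d in c(0.3, 0.8, 1.5)) {
    ref <- power.t.test(n = 17, delta = d, sd = 1, type = "paired",
                        strict = TRUE)$power
    expect_equal(posthoc_power_paired(d, 17), ref, tolerance = 1e-6)
  }
  # strictly increasing in |d| and n
  ds <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(sapply(ds, posthoc_power_paired, n = 17)) > 0))
  ns <- 3:30
  expect_true(all(diff(sapply(ns, function(n)
    posthoc_power_paired(0.5, n))) > 0))
})

test_that("stability summary computes per-subject window SDs and compares modalities", {
  ft <- expand.grid(window_index = 1:2, modality = c("MEG", "EMG"),
                    subject_id = c("A", "B", "C"),
                    stringsAsFactors = FALSE)
  ft$feature <- "LE"
  # every subject/modality has windows {m, m+2}: per-subject SD = sqrt(2)
  ft$value <- rep(c(1, 3), 6) + rep(0:5, each = 2)
  ss <- stability_summary(ft)
  expect_true(all(abs(ss$per_subject$sd - sqrt(2)) < 1e-12))
  expect_equal(ss$group$group_mean[ss$group$modality == "MEG"],
               mean(c(2, 4, 6)))
  # identical window SDs in both modalities: zero-variance differences are
  # surfaced as "no difference" (NULL), not an error
  expect_null(ss$sd_comparison$LE)

  # make the EMG windows fluctuate more: the SD comparison activates
  ft$value[ft$modality == "EMG"] <- ft$value[ft$modality == "EMG"] *
    rep(c(1, 3), 3)
  ss2 <- stability_summary(ft)
  expect_s3_class(ss2$sd_comparison$LE, "group_stat_result")

  # constant per-window feature gives zero SD
  ftc <- ft; ftc$value <- 1
  expect_true(all(stability_summary(ftc)$per_subject$sd == 0))
})
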