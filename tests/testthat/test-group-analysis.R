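# Welch tests, per-timepoint comparisons, intra-group variability, pipeline.

test_that("welch_t matches the hand-worked example and handles edge cases", {
  w <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(w$t_stat, -1.549, tolerance = 1e-3)
  expect_equal(w$df, 2.941, tolerance = 1e-3)
  expect_lte(w$df, 3 + 3 - 2)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$cohens_d, 0)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("welch_t detects a one-SD shift at n = 200 essentially always", {
  hits <- vapply(1:100, function(i) {
    set.seed(1100 + i)
    welch_t(rnorm(200), rnorm(200, 1))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("per-timepoint comparisons are Welch + Bonferroni per breakpoint", {
  set.seed(16)
  m1 <- matrix(rnorm(32 * 8), 32)
  tp <- timepoint_comparison(m1, m1 + 0)   # identical groups
  expect_equal(nrow(tp), 8L)
  expect_true(all(tp$p_adj >= 0.999))      # identical data: p = 1 each
  m2 <- matrix(rnorm(32 * 8), 32)
  tp2 <- timepoint_comparison(m1, m2)
  expect_equal(tp2$p_adj, pmin(1, tp2$p * 8))
  expect_error(timepoint_comparison(m1, m2[, 1:3]), "breakpoint")
})

test_that("an offset at one breakpoint is localized to that breakpoint", {
  hits <- vapply(1:50, function(i) {
    set.seed(1200 + i)
    g1 <- matrix(rnorm(32 * 8), 32)
    g2 <- matrix(rnorm(32 * 8), 32)
    g2[, 7] <- g2[, 7] + 3              # 3x the within-group SD
    sig <- timepoint_comparison(g1, g2)$p_adj < 0.05
    sum(sig) == 1L && sig[7]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("intra-group variability counts pairs and compares distributions", {
  base <- make_template("cubic", 8) * 20
  same <- matrix(rep(base, 32), 32, byrow = TRUE)
  set.seed(17)
  noisy <- same + matrix(rnorm(32 * 8, 0, 15), 32)
  res <- intragroup_variability(same, noisy)
  expect_equal(res$n_pairs_1, choose(32, 2))   # 496 pairs
  expect_true(all(res$r_1 == 1))               # identical kernels
  expect_equal(res$df, 2 * choose(32, 2) - 2)
  expect_gt(res$mean_1, res$mean_2)
  # Fisher-z variant runs on transformed correlations
  resz <- intragroup_variability(noisy, noisy + rnorm(256), fisher_z = TRUE)
  expect_true(is.finite(resz$t_stat))
})

test_that("higher template dispersion lowers within-group kernel agreement", {
  cfg <- speech_config(100L)
  tight <- make_cohort(cohort_spec("A", 32, template_dispersion = 0.2,
                                   internal_noise_mean = 0.5,
                                   internal_noise_sd = 0, seed = 18), cfg)
  loose <- make_cohort(cohort_spec("B", 32, template_dispersion = 0.8,
                                   internal_noise_mean = 0.5,
                                   internal_noise_sd = 0, seed = 19), cfg)
  km <- function(coh) do.call(rbind, lapply(coh$sessions, function(s)
    estimate_kernel(s)$values))
  res <- intragroup_variability(km(tight), km(loose))
  expect_gt(res$mean_1, res$mean_2)
  expect_lt(res$p_value, 0.05)
})

test_that("session logs round-trip through CSV and re-analysis", {
  cfg <- speech_config(50L)
  sess <- sim_session("cubic", sigma = 1, config = cfg, seed = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_log(sess, path)
  back <- read_session_log(path, cfg)
  expect_equal(back$participant_id, sess$participant_id)
  expect_equal(estimate_kernel(back)$values, estimate_kernel(sess)$values,
               tolerance = 1e-9)
  expect_equal(agreement(back)$agreement, agreement(sess)$agreement)
})

test_that("the pipeline is reproducible and melody skips the quartic ladder", {
  cfg <- pipeline_config(conditions = c("complex_tone", "melody"),
                         group_1 = cohort_spec("ASD", 4, "quartic", seed = 1),
                         group_2 = cohort_spec("non-ASD", 4, "cubic",
                                               seed = 2),
                         seed = 9)
  rep1 <- run_pipeline(cfg)
  rep2 <- run_pipeline(cfg)
  expect_identical(rep1, rep2)
  expect_null(rep1$conditions$melody$shape_selection)
  expect_false(is.null(rep1$conditions$complex_tone$shape_selection))
  expect_false(is.null(rep1$conditions$melody$prototype_r))
  # report completeness: one metric row per participant per condition
  for (res in rep1$conditions) {
    expect_equal(nrow(res$metrics), 8L)
    expect_false(any(duplicated(res$metrics$participant_id)))
    expect_true(all(c("rms", "agreement", "n_scored_trials") %in%
                      names(res$metrics)))
  }
  dir <- withr::local_tempdir()
  write_report(rep1, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "shape_ladder_complex_tone.csv")))
  expect_false(file.exists(file.path(dir, "shape_ladder_melody.csv")))
})

test_that("groups built on different shapes select different group shapes", {
  cfg <- pipeline_config(conditions = "complex_tone",
                         group_1 = cohort_spec("ASD", 8, "quartic",
                                               template_dispersion = 0.15,
                                               internal_noise_mean = 0.5,
                                               internal_noise_sd = 0.1,
                                               seed = 3),
                         group_2 = cohort_spec("non-ASD", 8, "cubic",
                                               template_dispersion = 0.15,
                                               internal_noise_mean = 0.5,
                                               internal_noise_sd = 0.1,
                                               seed = 4),
                         seed = 23)
  rep <- run_pipeline(cfg)
  sel <- rep$conditions$complex_tone$shape_selection
  expect_equal(sel$group_1$best_label, "quartic")
  expect_equal(sel$group_2$best_label, "cubic")
})
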