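# Cohort-level statistics and the end-to-end pipeline: per-timepoint group
# comparisons (Welch + Bonferroni), RMS/agreement group tests, intra-group
# kernel variability, exceptional-sensitivity subgroups, report assembly.

#' Welch two-sample t-test with Cohen's d
#'
#' Welch statistic with Welch-Satterthwaite (fractional) degrees of freedom,
#' two-sided p, and Cohen's d in the pooled-SD form.
#'
#' @param x,y Numeric samples (each length >= 2).
#' @return An object of class `"welch_result"`: `t_stat`, `df`, `p_value`,
#'   `mean_1`, `mean_2`, `sd_1`, `sd_2`, `cohens_d`.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 4, 6)) # t = -1.549, df = 2.941
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs >= 2 observations", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = FALSE)
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  structure(list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_1 = mean(x), mean_2 = mean(y),
                 sd_1 = stats::sd(x), sd_2 = stats::sd(y),
                 cohens_d = if (sp > 0) (mean(x) - mean(y)) / sp else 0),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.3f, df = %.3f, p = %.4g, d = %.2f\n", x$t_stat,
              x$df, x$p_value, x$cohens_d))
  cat(sprintf("  group 1: M = %.3f (SD %.3f); group 2: M = %.3f (SD %.3f)\n",
              x$mean_1, x$sd_1, x$mean_2, x$sd_2))
  invisible(x)
}

# stack a list of kernels into a participants x breakpoints matrix
kernel_matrix <- function(kernels) {
  if (is.matrix(kernels)) return(kernels)
  do.call(rbind, lapply(kernels, function(k)
    if (inherits(k, "kernel")) k$values else as.numeric(k)))
}

#' Per-timepoint group comparison of kernels
#'
#' One Welch test per breakpoint on participants' kernel values, with
#' Bonferroni adjustment over the breakpoints
#' (`p_adj = min(1, p * n_breakpoints)`). This is a fixed-effects
#' approximation to a by-subject random-intercept model: with one kernel
#' value per participant per time point, the group contrast at each time
#' point coincides.
#'
#' @param kernels_g1,kernels_g2 Lists of `"kernel"` objects (or matrices,
#'   participants x breakpoints).
#' @return `data.frame` with one row per breakpoint: means, SDs, `t`, `df`,
#'   `p`, `p_adj`.
#' @export
timepoint_comparison <- function(kernels_g1, kernels_g2) {
  m1 <- kernel_matrix(kernels_g1)
  m2 <- kernel_matrix(kernels_g2)
  if (ncol(m1) != ncol(m2))
    stop("groups have different breakpoint counts", call. = FALSE)
  K <- ncol(m1)
  rows <- lapply(seq_len(K), function(k) {
    w <- welch_t(m1[, k], m2[, k])
    data.frame(breakpoint = k, mean_1 = w$mean_1, sd_1 = w$sd_1,
               mean_2 = w$mean_2, sd_2 = w$sd_2, t = w$t_stat, df = w$df,
               p = w$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * K)    # Bonferroni over breakpoints
  out
}

#' Intra-group kernel variability
#'
#' Computes all pairwise Pearson correlations between participants' kernels
#' within each group, then compares the two correlation distributions with a
#' Student two-sample t-test (`df = m1 + m2 - 2`, matching the convention of
#' reporting pooled-df tests on correlation sets). A Fisher-z variant
#' (t-test on `atanh(r)`) is available since raw correlations are bounded.
#'
#' @param kernels_g1,kernels_g2 Lists of kernels or matrices.
#' @param fisher_z If `TRUE`, run the t-test on Fisher-z transformed
#'   correlations.
#' @return List with `r_1`, `r_2` (pairwise correlation vectors), `n_pairs_1`,
#'   `n_pairs_2`, `dropped_1`, `dropped_2` (pairs excluded for zero-variance
#'   kernels), `mean_1`, `mean_2`, `sd_1`, `sd_2`, `t_stat`, `df`, `p_value`.
#' @export
intragroup_variability <- function(kernels_g1, kernels_g2, fisher_z = FALSE) {
  pairwise_r <- function(m) {
    if (nrow(m) < 3L)
      stop("need >= 3 participants per group", call. = FALSE)
    cm <- suppressWarnings(stats::cor(t(m)))
    r <- cm[upper.tri(cm)]
    list(r = r[is.finite(r)], dropped = sum(!is.finite(r)))
  }
  p1 <- pairwise_r(kernel_matrix(kernels_g1))
  p2 <- pairwise_r(kernel_matrix(kernels_g2))
  x <- if (fisher_z) atanh(pmin(pmax(p1$r, -1 + 1e-12), 1 - 1e-12)) else p1$r
  y <- if (fisher_z) atanh(pmin(pmax(p2$r, -1 + 1e-12), 1 - 1e-12)) else p2$r
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(r_1 = p1$r, r_2 = p2$r, n_pairs_1 = length(p1$r),
       n_pairs_2 = length(p2$r), dropped_1 = p1$dropped,
       dropped_2 = p2$dropped, mean_1 = mean(p1$r), mean_2 = mean(p2$r),
       sd_1 = stats::sd(p1$r), sd_2 = stats::sd(p2$r),
       t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, fisher_z = fisher_z)
}

#' Write / read a session log as CSV
#'
#' Columns: `participant_id`, `group`, `condition`, `trial_index`,
#' `a_bp_1..K`, `b_bp_1..K`, `choice`. Reading rebuilds a `"session_log"`
#' (the stimulus-generation config must be supplied, since CSV carries only
#' the trials).
#'
#' @param session A `"session_log"`.
#' @param path File path.
#' @param config A [noise_config()] matching the logged condition.
#' @return `read_session_log()` returns a `"session_log"`.
#' @export
write_session_log <- function(session, path) {
  df <- cbind(data.frame(participant_id = session$participant_id,
                         group = session$group,
                         condition = session$condition,
                         stringsAsFactors = FALSE),
              session$trials)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path, config) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "condition", "trial_index", "choice")
  if (!all(need %in% names(df)))
    stop("session log is missing required columns", call. = FALSE)
  if (any(df$condition != df$condition[1L]))
    stop("session log mixes conditions", call. = FALSE)
  if (!identical(sort(df$trial_index), seq_len(nrow(df))))
    stop("trial_index must be 1..n without gaps", call. = FALSE)
  K <- config$n_breakpoints
  cols <- c("trial_index", paste0("a_bp_", seq_len(K)),
            paste0("b_bp_", seq_len(K)), "choice")
  if (!all(cols %in% names(df)))
    stop("session log breakpoint columns do not match the config",
         call. = FALSE)
  structure(list(participant_id = df$participant_id[1L],
                 group = df$group[1L], condition = df$condition[1L],
                 seed = NA_integer_, config = config,
                 trials = df[order(df$trial_index), cols]),
            class = "session_log")
}

#' Configuration for the end-to-end pipeline
#'
#' @param conditions Conditions to simulate (subset of `"speech"`,
#'   `"complex_tone"`, `"melody"`).
#' @param group_1,group_2 [cohort_spec()]s for the two groups (seeds inside
#'   them are offsets; the master seed decorrelates conditions).
#' @param seed Master seed.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(conditions = c("speech", "complex_tone",
                                           "melody"),
                            group_1 = cohort_spec("ASD"),
                            group_2 = cohort_spec("non-ASD"),
                            seed = 1L) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  structure(list(conditions = conditions, group_1 = group_1,
                 group_2 = group_2, seed = as.integer(seed)),
            class = "pipeline_config")
}

# group-level pooled shape selection: one observation per participant per
# breakpoint, on the shared normalized grid
pooled_shape_selection <- function(kmat) {
  K <- ncol(kmat)
  tk <- rep((seq_len(K) - 1) / (K - 1), each = nrow(kmat))
  select_shape(as.numeric(kmat), t = tk)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Simulates both cohorts under each condition, estimates kernels, computes
#' per-participant metrics, per-timepoint group comparisons, group-level
#' shape selection (8-breakpoint conditions only), RMS/agreement Welch tests,
#' intra-group variability, exceptional-sensitivity subgroup flags, and (for
#' melody) prototype-contour correlations. Optionally serializes kernels,
#' metrics and the report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return An object of class `"group_report"`: per-condition results plus
#'   the configuration; fully reproducible from the master seed.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  results <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    ncfg <- noise_config(cond)
    s1 <- config$group_1
    s2 <- config$group_2
    s1$seed <- config$seed + 1000L * ci + s1$seed
    s2$seed <- config$seed + 1000L * ci + 500L + s2$seed
    # polynomial base shapes need > degree+1 points; on the 3-note melody the
    # natural base template is the notation-derived prototype contour
    if (ncfg$n_breakpoints < 5L) {
      if (is.character(s1$base_shape) && s1$base_shape != "prototype")
        s1$base_shape <- "prototype"
      if (is.character(s2$base_shape) && s2$base_shape != "prototype")
        s2$base_shape <- "prototype"
    }
    coh1 <- make_cohort(s1, ncfg)
    coh2 <- make_cohort(s2, ncfg)
    kern1 <- lapply(coh1$sessions, estimate_kernel)
    kern2 <- lapply(coh2$sessions, estimate_kernel)
    met <- rbind(do.call(rbind, lapply(coh1$sessions, observer_metrics)),
                 do.call(rbind, lapply(coh2$sessions, observer_metrics)))
    m1 <- kernel_matrix(kern1); m2 <- kernel_matrix(kern2)
    rms1 <- met$rms[met$group == s1$group]
    rms2 <- met$rms[met$group == s2$group]
    agr1 <- met$agreement[met$group == s1$group]
    agr2 <- met$agreement[met$group == s2$group]
    res <- list(
      condition = cond,
      config = ncfg,
      kernels = list(group_1 = m1, group_2 = m2),
      metrics = met,
      timepoints = timepoint_comparison(m1, m2),
      rms_test = welch_t(rms1, rms2),
      agreement_test = welch_t(agr1, agr2),
      intragroup = intragroup_variability(m1, m2),
      subgroup = list(group_1 = exceptional_sensitivity(rms1, rms2),
                      group_2 = exceptional_sensitivity(rms2, rms2)))
    if (ncfg$n_breakpoints >= 6L) {     # ladder needs quartic residual df
      res$shape_selection <- list(group_1 = pooled_shape_selection(m1),
                                  group_2 = pooled_shape_selection(m2))
    }
    if (cond == "melody") {
      res$prototype_r <- list(
        group_1 = prototype_correlation(colMeans(m1)),
        group_2 = prototype_correlation(colMeans(m2)),
        per_participant_1 = apply(m1, 1, prototype_correlation),
        per_participant_2 = apply(m2, 1, prototype_correlation))
    }
    results[[cond]] <- res
  }
  report <- structure(list(conditions = results, config = config,
                           group_labels = c(config$group_1$group,
                                            config$group_2$group)),
                      class = "group_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.group_report <- function(x, ...) {
  cat("group_report:", paste(x$group_labels, collapse = " vs "), "\n")
  for (res in x$conditions) {
    cat(sprintf("\n== %s ==\n", res$condition))
    if (!is.null(res$shape_selection))
      cat(sprintf("  best shape: %s (%s) vs %s (%s)\n",
                  res$shape_selection$group_1$best_label, x$group_labels[1],
                  res$shape_selection$group_2$best_label, x$group_labels[2]))
    cat(sprintf("  RMS: M %.2f vs %.2f cents, Welch t = %.2f, df = %.1f, p = %.3g\n",
                res$rms_test$mean_1, res$rms_test$mean_2, res$rms_test$t_stat,
                res$rms_test$df, res$rms_test$p_value))
    cat(sprintf("  agreement: %.3f vs %.3f, t = %.2f, p = %.3g\n",
                res$agreement_test$mean_1, res$agreement_test$mean_2,
                res$agreement_test$t_stat, res$agreement_test$p_value))
    cat(sprintf("  intra-group r: %.2f vs %.2f, t = %.2f (df %d), p = %.3g\n",
                res$intragroup$mean_1, res$intragroup$mean_2,
                res$intragroup$t_stat, res$intragroup$df,
                res$intragroup$p_value))
    cat(sprintf("  flagged > ref mean + 2 SD: %d (%.2f%%) vs %d (%.2f%%)\n",
                res$subgroup$group_1$flagged_count,
                res$subgroup$group_1$flagged_percent,
                res$subgroup$group_2$flagged_count,
                res$subgroup$group_2$flagged_percent))
    if (!is.null(res$prototype_r))
      cat(sprintf("  prototype r: %.2f vs %.2f\n", res$prototype_r$group_1,
                  res$prototype_r$group_2))
  }
  invisible(x)
}

#' Serialize a group report
#'
#' Writes per-participant kernels and metrics as CSV and a JSON summary of
#' every test in the report.
#'
#' @param report A `"group_report"`.
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(groups = report$group_labels,
                  note = paste("Per-timepoint contrasts are Welch tests with",
                               "Bonferroni correction over breakpoints,",
                               "a fixed-effects stand-in for a by-subject",
                               "random-intercept model."))
  for (res in report$conditions) {
    cond <- res$condition
    K <- ncol(res$kernels$group_1)
    kdf <- data.frame(
      participant_id = c(sprintf("%s_%02d", report$group_labels[1],
                                 seq_len(nrow(res$kernels$group_1))),
                         sprintf("%s_%02d", report$group_labels[2],
                                 seq_len(nrow(res$kernels$group_2)))),
      condition = cond,
      rbind(res$kernels$group_1, res$kernels$group_2))
    names(kdf)[-(1:2)] <- paste0("k_", seq_len(K))
    utils::write.csv(kdf, file.path(out_dir,
                                    sprintf("kernels_%s.csv", cond)),
                     row.names = FALSE)
    utils::write.csv(res$metrics,
                     file.path(out_dir, sprintf("metrics_%s.csv", cond)),
                     row.names = FALSE)
    utils::write.csv(res$timepoints,
                     file.path(out_dir, sprintf("timepoints_%s.csv", cond)),
                     row.names = FALSE)
    summary[[cond]] <- list(
      rms_test = unclass(res$rms_test),
      agreement_test = unclass(res$agreement_test),
      intragroup = res$intragroup[c("n_pairs_1", "n_pairs_2", "mean_1",
                                    "mean_2", "sd_1", "sd_2", "t_stat", "df",
                                    "p_value")],
      subgroup = lapply(res$subgroup, function(s)
        s[c("reference_mean", "reference_sd", "threshold", "flagged_count",
            "flagged_percent")]),
      best_shape = if (!is.null(res$shape_selection))
        list(group_1 = res$shape_selection$group_1$best_label,
             group_2 = res$shape_selection$group_2$best_label),
      prototype_r = if (!is.null(res$prototype_r))
        res$prototype_r[c("group_1", "group_2")])
    if (!is.null(res$shape_selection)) {
      lad <- rbind(cbind(group = report$group_labels[1],
                         res$shape_selection$group_1$ladder),
                   cbind(group = report$group_labels[2],
                         res$shape_selection$group_2$ladder))
      utils::write.csv(lad, file.path(out_dir,
                                      sprintf("shape_ladder_%s.csv", cond)),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
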