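# Per-participant scalar metrics: RMS sensitivity, agreement (internal-noise
# index), exceptional-sensitivity flags, prototype-contour correlation.

#' Root-mean-square of a kernel
#'
#' A scalar index of pitch sensitivity: how strongly the observer weights the
#' breakpoints in either direction. `sqrt(mean(values^2))`, in cents.
#'
#' @param kernel A `"kernel"` or numeric vector of kernel values.
#' @return RMS in cents (>= 0).
#' @export
kernel_rms <- function(kernel) {
  v <- if (inherits(kernel, "kernel")) kernel$values else as.numeric(kernel)
  if (length(v) == 0) stop("empty kernel", call. = FALSE)
  sqrt(mean(v^2))
}

# rowwise Pearson correlation of a matrix with a vector; NA where either
# side has zero variance
row_cor <- function(m, v) {
  vc <- v - mean(v)
  vn <- sqrt(sum(vc^2))
  mc <- m - rowMeans(m)
  mn <- sqrt(rowSums(mc^2))
  r <- (mc %*% vc) / (mn * vn)
  r[mn < 1e-12] <- NA_real_
  if (vn < 1e-12) r[] <- NA_real_
  drop(r)
}

#' Kernel-response agreement (internal-noise index)
#'
#' For each trial, the pair member whose pitch contour correlates more highly
#' (Pearson) with the participant's kernel is the "objectively correct"
#' response; agreement is the fraction of trials where the logged choice
#' matches it. Higher agreement indicates lower internal noise. Trials where
#' either correlation is undefined (a zero-variance contour) or the two
#' correlations tie are excluded from the denominator.
#'
#' @param session A `"session_log"`.
#' @param kernel Kernel to score against; default the session's own
#'   (in-sample) kernel.
#' @param leave_one_out If `TRUE`, score trial `i` against the kernel
#'   recomputed without trial `i` (removes the in-sample optimism of scoring
#'   a noisy observer against their own kernel). Only available with the
#'   default in-sample kernel.
#' @return A list with `agreement` (proportion in `[0, 1]`) and
#'   `n_scored_trials`.
#' @export
agreement <- function(session, kernel = NULL, leave_one_out = FALSE) {
  m <- session_shift_matrices(session)
  n <- nrow(m$a)
  if (leave_one_out) {
    if (!is.null(kernel))
      stop("leave_one_out applies to the in-sample kernel only",
           call. = FALSE)
    diffs <- m$chosen - m$unchosen
    kbar <- colMeans(diffs)
    ra <- numeric(n); rb <- numeric(n)
    for (i in seq_len(n)) {
      ki <- (n * kbar - diffs[i, ]) / (n - 1)
      ra[i] <- suppressWarnings(stats::cor(m$a[i, ], ki))
      rb[i] <- suppressWarnings(stats::cor(m$b[i, ], ki))
    }
  } else {
    kv <- if (is.null(kernel)) estimate_kernel(session)$values
          else if (inherits(kernel, "kernel")) kernel$values
          else as.numeric(kernel)
    if (stats::sd(kv) < 1e-12)
      stop("agreement undefined for a zero-variance kernel", call. = FALSE)
    ra <- row_cor(m$a, kv)
    rb <- row_cor(m$b, kv)
  }
  scored <- is.finite(ra) & is.finite(rb) & ra != rb
  if (!any(scored))
    stop("no scorable trials (all correlations undefined or tied)",
         call. = FALSE)
  correct <- ifelse(ra > rb, "A", "B")
  agree <- mean(session$trials$choice[scored] == correct[scored])
  list(agreement = agree, n_scored_trials = sum(scored))
}

#' Per-participant metric record
#'
#' Computes the RMS and agreement metrics for one session in one call.
#'
#' @param session A `"session_log"`.
#' @param leave_one_out Passed to [agreement()].
#' @return One-row `data.frame`: `participant_id`, `group`, `condition`,
#'   `rms`, `agreement`, `n_scored_trials`.
#' @export
observer_metrics <- function(session, leave_one_out = FALSE) {
  k <- estimate_kernel(session)
  ag <- agreement(session, leave_one_out = leave_one_out)
  data.frame(participant_id = session$participant_id, group = session$group,
             condition = session$condition, rms = kernel_rms(k),
             agreement = ag$agreement,
             n_scored_trials = ag$n_scored_trials,
             stringsAsFactors = FALSE)
}

#' Flag exceptional pitch sensitivity
#'
#' Flags members of a target group whose kernel RMS lies strictly above the
#' reference group's mean plus two sample SDs (n - 1 denominator).
#'
#' @param rms_target RMS values (cents) of the group being screened.
#' @param rms_reference RMS values of the reference group (length >= 2).
#' @return An object of class `"subgroup_result"`: `reference_mean`,
#'   `reference_sd`, `threshold`, `flags` (logical), `flagged_count`,
#'   `flagged_percent`.
#' @examples
#' exceptional_sensitivity(c(30, 20, 10), c(10.7, 10.7))$threshold
#' @export
exceptional_sensitivity <- function(rms_target, rms_reference) {
  if (length(rms_reference) < 2L)
    stop("reference group needs >= 2 values for an SD", call. = FALSE)
  mu <- mean(rms_reference)
  sdev <- stats::sd(rms_reference)
  threshold <- mu + 2 * sdev
  flags <- rms_target > threshold        # strict exceedance
  structure(list(reference_mean = mu, reference_sd = sdev,
                 threshold = threshold, flags = flags,
                 flagged_count = sum(flags),
                 flagged_percent = 100 * sum(flags) / length(flags)),
            class = "subgroup_result")
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat(sprintf(
    "exceptional sensitivity: threshold %.2f cents (ref M = %.2f, SD = %.2f)\n",
    x$threshold, x$reference_mean, x$reference_sd))
  cat(sprintf("  flagged %d of %d (%.2f%%)\n", x$flagged_count,
              length(x$flags), x$flagged_percent))
  invisible(x)
}

#' Correlation of a kernel with the prototypical melodic contour
#'
#' Pearson correlation between a (melody) kernel and the notation-derived
#' prototype contour: note 2 five semitones below note 1, note 3 five
#' semitones above note 2, i.e. `[0, -500, 0]` cents.
#'
#' @param kernel A `"kernel"` or numeric vector.
#' @param prototype Prototype contour in cents.
#' @return Pearson correlation coefficient.
#' @export
prototype_correlation <- function(kernel, prototype = c(0, -500, 0)) {
  v <- if (inherits(kernel, "kernel")) kernel$values else as.numeric(kernel)
  if (length(v) != length(prototype))
    stop("kernel and prototype lengths differ", call. = FALSE)
  if (stats::sd(v) < 1e-12 || stats::sd(prototype) < 1e-12)
    stop("correlation undefined for zero-variance input", call. = FALSE)
  stats::cor(v, prototype)
}
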