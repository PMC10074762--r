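# First-order temporal kernels from 2AFC session logs.

#' Estimate a first-order temporal kernel
#'
#' The kernel is the mean pitch contour of the chosen stimuli minus the mean
#' pitch contour of the unchosen stimuli, computed per breakpoint, in cents.
#'
#' @param session A `"session_log"`.
#' @return An object of class `"kernel"`: list with `values` (cents, length
#'   `n_breakpoints`), `n_trials`, `condition`, `participant_id`.
#' @examples
#' cfg <- noise_config("speech")
#' obs <- observer_spec("p1", template = make_template("cubic", 8), seed = 7)
#' k <- estimate_kernel(simulate_observer_session(obs, cfg))
#' round(k$values, 2)
#' @export
estimate_kernel <- function(session) {
  if (!inherits(session, "session_log"))
    stop("estimate_kernel expects a session_log", call. = FALSE)
  if (nrow(session$trials) < 1L)
    stop("session has no trials", call. = FALSE)
  m <- session_shift_matrices(session)
  values <- colMeans(m$chosen) - colMeans(m$unchosen)
  names(values) <- NULL
  structure(list(values = values, n_trials = nrow(session$trials),
                 condition = session$condition,
                 participant_id = session$participant_id),
            class = "kernel")
}

#' @export
print.kernel <- function(x, ...) {
  cat(sprintf("kernel: %s, %s, %d trials\n", x$participant_id, x$condition,
              x$n_trials))
  print(round(x$values, 2))
  invisible(x)
}

# kernel from the first n trials of a session
prefix_kernel <- function(session, n) {
  sub <- session
  sub$trials <- session$trials[seq_len(n), , drop = FALSE]
  estimate_kernel(sub)
}

#' Subset-vs-full kernel reliability curve
#'
#' For each subset size `n`, the Pearson correlation between the kernel
#' estimated from the first `n` trials and the kernel from all trials (nested
#' prefixes). The pilot criterion for a reliable session is r >= 0.8.
#'
#' @param session A `"session_log"`.
#' @param subset_sizes Integer vector of subset sizes (each in `[2,
#'   n_trials]`).
#' @param random_subsets If `TRUE`, draw each subset at random (without
#'   replacement) instead of taking the first `n` trials.
#' @return An object of class `"reliability_curve"`: data.frame with columns
#'   `subset_size` and `r`.
#' @export
reliability_curve <- function(session, subset_sizes, random_subsets = FALSE) {
  n_total <- nrow(session$trials)
  subset_sizes <- as.integer(subset_sizes)
  if (any(subset_sizes < 2L))
    stop("subset sizes must be >= 2", call. = FALSE)
  if (any(subset_sizes > n_total))
    stop("subset sizes cannot exceed the number of trials", call. = FALSE)
  full <- estimate_kernel(session)$values
  r <- vapply(subset_sizes, function(n) {
    sub <- session
    idx <- if (random_subsets) sort(sample.int(n_total, n)) else seq_len(n)
    sub$trials <- session$trials[idx, , drop = FALSE]
    stats::cor(estimate_kernel(sub)$values, full)
  }, numeric(1))
  structure(data.frame(subset_size = subset_sizes, r = r),
            class = c("reliability_curve", "data.frame"))
}
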