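# Stimulus generation: Gaussian pitch noise on breakpoint contours, 2AFC pairing.

#' Stimulus-generation configuration
#'
#' Builds a validated configuration for one experimental condition. The three
#' named conditions carry the study defaults: speech and complex tone use 8
#' breakpoints linearly interpolated over a 250 ms sound on a 210 Hz base;
#' melody uses 3 note onsets held as plateaus (square breakpoint function,
#' 0.1 s transitions) over 1380 ms on a 260 Hz base. In every condition the
#' per-breakpoint pitch shifts are drawn from a zero-mean normal distribution
#' with `noise_sd` = 70 cents, clipped (winsorized) at `clip_multiple` = 2.2
#' standard deviations.
#'
#' @param condition `"speech"`, `"complex_tone"` or `"melody"`.
#' @param n_breakpoints Number of pitch breakpoints (>= 2).
#' @param noise_sd SD of the pitch noise, in cents (>= 0).
#' @param clip_multiple Clipping bound in multiples of `noise_sd` (> 0).
#' @param base_f0 Base fundamental frequency in Hz.
#' @param duration Stimulus duration in milliseconds.
#' @param interpolation `"linear"` or `"square_bpf"`.
#' @param transition_time Ramp duration in seconds between note plateaus
#'   (square BPF only).
#' @param pool_size Number of stimuli in the pool; must equal `2 * n_trials`.
#' @param n_trials Number of 2AFC trials per session.
#' @return An object of class `"noise_config"`.
#' @examples
#' cfg <- noise_config("speech")
#' cfg$n_breakpoints # 8
#' @export
noise_config <- function(condition = c("speech", "complex_tone", "melody"),
                         n_breakpoints = NULL, noise_sd = 70,
                         clip_multiple = 2.2, base_f0 = NULL, duration = NULL,
                         interpolation = NULL, transition_time = NULL,
                         pool_size = NULL, n_trials = NULL) {
  condition <- match.arg(condition)
  defaults <- switch(condition,
    speech       = list(n_breakpoints = 8L, base_f0 = 210, duration = 250,
                        interpolation = "linear", transition_time = NA_real_,
                        pool_size = 800L, n_trials = 400L),
    complex_tone = list(n_breakpoints = 8L, base_f0 = 210, duration = 250,
                        interpolation = "linear", transition_time = NA_real_,
                        pool_size = 800L, n_trials = 400L),
    melody       = list(n_breakpoints = 3L, base_f0 = 260, duration = 1380,
                        interpolation = "square_bpf", transition_time = 0.1,
                        pool_size = 600L, n_trials = 300L))
  pick <- function(user, def) if (is.null(user)) def else user
  cfg <- list(
    condition       = condition,
    n_breakpoints   = as.integer(pick(n_breakpoints, defaults$n_breakpoints)),
    noise_sd        = as.numeric(noise_sd),
    clip_multiple   = as.numeric(clip_multiple),
    base_f0         = as.numeric(pick(base_f0, defaults$base_f0)),
    duration        = as.numeric(pick(duration, defaults$duration)),
    interpolation   = pick(interpolation, defaults$interpolation),
    transition_time = as.numeric(pick(transition_time, defaults$transition_time)),
    pool_size       = as.integer(pick(pool_size, defaults$pool_size)),
    n_trials        = as.integer(pick(n_trials, defaults$n_trials)),
    clip_mode       = "winsorize")
  validate_noise_config(cfg)
  structure(cfg, class = "noise_config")
}

validate_noise_config <- function(cfg) {
  if (cfg$n_breakpoints < 2L)
    stop("n_breakpoints must be >= 2", call. = FALSE)
  if (is.na(cfg$noise_sd) || cfg$noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$clip_multiple <= 0)
    stop("clip_multiple must be > 0", call. = FALSE)
  if (cfg$base_f0 <= 0)
    stop("base_f0 must be > 0", call. = FALSE)
  if (cfg$duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  if (!cfg$interpolation %in% c("linear", "square_bpf"))
    stop("interpolation must be 'linear' or 'square_bpf'", call. = FALSE)
  if (cfg$pool_size <= 0L)
    stop("pool_size must be > 0", call. = FALSE)
  if (cfg$pool_size != 2L * cfg$n_trials)
    stop("pool_size must equal 2 * n_trials", call. = FALSE)
  if (cfg$interpolation == "square_bpf") {
    if (is.na(cfg$transition_time) || cfg$transition_time <= 0)
      stop("square_bpf interpolation requires transition_time > 0",
           call. = FALSE)
    seg <- cfg$duration / 1000 / cfg$n_breakpoints
    if (cfg$transition_time >= seg)
      stop("transition_time must be shorter than the shortest note segment",
           call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.noise_config <- function(x, ...) {
  cat(sprintf(
    "noise_config: %s | %d breakpoints, noise SD %g cents (clip %g SD)\n",
    x$condition, x$n_breakpoints, x$noise_sd, x$clip_multiple))
  cat(sprintf("  base F0 %g Hz, duration %g ms, %s interpolation\n",
              x$base_f0, x$duration, x$interpolation))
  cat(sprintf("  pool %d stimuli -> %d trials\n", x$pool_size, x$n_trials))
  invisible(x)
}

# n x K matrix of winsorized-normal pitch shifts (cents).
sample_shift_matrix <- function(config, n) {
  bound <- config$noise_sd * config$clip_multiple
  x <- matrix(stats::rnorm(n * config$n_breakpoints, 0, config$noise_sd),
              nrow = n, ncol = config$n_breakpoints)
  x[x > bound] <- bound
  x[x < -bound] <- -bound
  x
}

#' Sample one noise contour
#'
#' Draws `n_breakpoints` pitch shifts i.i.d. from Normal(0, `noise_sd`^2) and
#' winsorizes them at `+/- clip_multiple * noise_sd` (values beyond the bound
#' are set to the bound).
#'
#' @param config A [noise_config()].
#' @param stimulus_id Identifier to attach to the stimulus.
#' @return An object of class `"contour_stimulus"`: a list with `stimulus_id`,
#'   `shifts` (cents) and `condition`.
#' @export
sample_contour <- function(config, stimulus_id = 1L) {
  validate_noise_config(config)
  structure(list(stimulus_id = stimulus_id,
                 shifts = drop(sample_shift_matrix(config, 1L)),
                 condition = config$condition),
            class = "contour_stimulus")
}

#' Analytic SD of the winsorized pitch-noise distribution
#'
#' Closed-form standard deviation of a Normal(0, sd^2) variable winsorized at
#' `+/- clip * sd`: `E[X^2]/sd^2 = (2*Phi(z)-1) - 2*z*phi(z) + 2*z^2*(1-Phi(z))`
#' with `z = clip`.
#'
#' @param sd Nominal SD before clipping (cents).
#' @param clip Clipping bound in SD multiples.
#' @return SD of the clipped distribution, same units as `sd`.
#' @export
winsorized_normal_sd <- function(sd, clip) {
  z <- clip
  f <- (2 * stats::pnorm(z) - 1) - 2 * z * stats::dnorm(z) +
    2 * z^2 * (1 - stats::pnorm(z))
  sd * sqrt(f)
}

#' Build a pool of non-identical noise contours
#'
#' Draws `pool_size` contours; in the (measure-zero) event that two contours
#' share an identical shift vector the duplicate is redrawn, so every stimulus
#' in the pool is unique.
#'
#' @param config A [noise_config()].
#' @return A `data.frame` with columns `stimulus_id`, `condition` and
#'   `bp_1 .. bp_K` (cents), class `"stimulus_pool"`.
#' @export
build_stimulus_pool <- function(config) {
  validate_noise_config(config)
  n <- config$pool_size
  shifts <- sample_shift_matrix(config, n)
  # regenerate exact duplicates (possible when noise_sd = 0 never resolves,
  # so cap redraw attempts for degenerate configs)
  if (config$noise_sd > 0) {
    repeat {
      dup <- duplicated(shifts)
      if (!any(dup)) break
      shifts[dup, ] <- sample_shift_matrix(config, sum(dup))
    }
  }
  pool <- data.frame(stimulus_id = seq_len(n),
                     condition = config$condition,
                     shifts)
  names(pool)[-(1:2)] <- paste0("bp_", seq_len(config$n_breakpoints))
  structure(pool, class = c("stimulus_pool", "data.frame"))
}

# Extract the K shift columns of a pool as a matrix.
pool_shifts <- function(pool) {
  as.matrix(pool[, grep("^bp_", names(pool)), drop = FALSE])
}

#' Pair a stimulus pool into 2AFC trials
#'
#' Randomly pairs the pool without replacement (each stimulus appears in
#' exactly one pair) and randomizes which member is presented as A.
#'
#' @param pool A pool from [build_stimulus_pool()].
#' @param config The [noise_config()] used to build the pool.
#' @param iid_pairs If `TRUE`, pairs are instead drawn i.i.d. with replacement
#'   from the pool (each trial an independent random pair); the default
#'   `FALSE` matches pairing without replacement.
#' @return A `data.frame` with columns `trial_index`, `a_id`, `b_id`, class
#'   `"trial_set"`, carrying the pool and config as attributes.
#' @export
pair_trials <- function(pool, config, iid_pairs = FALSE) {
  n <- nrow(pool)
  if (iid_pairs) {
    n_trials <- config$n_trials
    a <- integer(n_trials); b <- integer(n_trials)
    for (i in seq_len(n_trials)) {
      ab <- sample.int(n, 2L)        # without replacement within a trial
      a[i] <- ab[1L]; b[i] <- ab[2L]
    }
  } else {
    if (n %% 2L != 0L)
      stop("pool size must be even for pairing without replacement",
           call. = FALSE)
    ord <- sample.int(n)
    a <- ord[seq(1L, n, by = 2L)]
    b <- ord[seq(2L, n, by = 2L)]
  }
  trials <- data.frame(trial_index = seq_along(a),
                       a_id = pool$stimulus_id[a],
                       b_id = pool$stimulus_id[b])
  structure(trials, class = c("trial_set", "data.frame"),
            pool = pool, config = config)
}

# Value of the breakpoint contour at arbitrary times (seconds).
# linear: breakpoints at t_k = (k-1)/(K-1) * duration, held outside [t_1, t_K].
# square_bpf: K equal note segments; plateaus with linear ramps of
# transition_time seconds centred on each interior note onset.
contour_at <- function(shifts, config, times_sec) {
  K <- length(shifts)
  dur <- config$duration / 1000
  if (config$interpolation == "linear") {
    tk <- (seq_len(K) - 1) / (K - 1) * dur
    stats::approx(tk, shifts, xout = times_sec, rule = 2)$y
  } else {
    onsets <- (seq_len(K) - 1) / K * dur
    val <- rep(shifts[1L], length(times_sec))
    half <- config$transition_time / 2
    for (k in 2:K) {
      lo <- onsets[k] - half
      hi <- onsets[k] + half
      ramp <- times_sec >= lo & times_sec < hi
      val[ramp] <- shifts[k - 1L] +
        (shifts[k] - shifts[k - 1L]) * (times_sec[ramp] - lo) /
        config$transition_time
      val[times_sec >= hi] <- shifts[k]
    }
    val
  }
}

#' Interpolate a contour to a dense trajectory
#'
#' Evaluates the breakpoint contour at `n_samples` evenly spaced times across
#' the stimulus duration. Linear mode draws straight segments between
#' breakpoints placed at normalized times `(k-1)/(K-1)`; square-BPF mode holds
#' each note's value as a plateau with linear ramps of `transition_time`
#' seconds centred on each interior note onset.
#'
#' @param stimulus A `"contour_stimulus"` or a bare numeric shift vector.
#' @param config The matching [noise_config()].
#' @param n_samples Number of output samples (>= `n_breakpoints`).
#' @return Numeric vector of pitch shifts in cents, length `n_samples`.
#' @export
interpolate_contour <- function(stimulus, config, n_samples) {
  shifts <- if (inherits(stimulus, "contour_stimulus")) stimulus$shifts
            else as.numeric(stimulus)
  if (length(shifts) != config$n_breakpoints)
    stop("shift vector length does not match config$n_breakpoints",
         call. = FALSE)
  if (n_samples < config$n_breakpoints)
    stop("n_samples must be >= n_breakpoints", call. = FALSE)
  times <- seq(0, config$duration / 1000, length.out = n_samples)
  contour_at(shifts, config, times)
}

#' Write / read a stimulus pool as CSV
#'
#' @param pool A stimulus pool.
#' @param path File path.
#' @return `read_pool()` returns the pool `data.frame`.
#' @export
write_pool <- function(pool, path) {
  utils::write.csv(pool, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  pool <- utils::read.csv(path)
  structure(pool, class = c("stimulus_pool", "data.frame"))
}

#' Read a stimulus configuration from JSON or YAML
#'
#' The file holds the [noise_config()] fields by name; `condition` is
#' required, all other fields fall back to the condition defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `"noise_config"`.
#' @export
read_noise_config <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(fields$condition))
    stop("config file must name a condition", call. = FALSE)
  allowed <- setdiff(names(formals(noise_config)), "condition")
  do.call(noise_config, c(list(condition = fields$condition),
                          fields[intersect(names(fields), allowed)]))
}
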