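# Linear template observers: the synthetic-data model standing in for human
# 2AFC listeners. Observer i chooses A on a trial iff
#   d = w . (s_A - s_B) + eps >= 0,  eps ~ N(0, (sigma_int * sigma_ext)^2),
# where w is a unit-norm internal template over breakpoints, sigma_ext is the
# analytic SD of w.(s_A - s_B) under the winsorized stimulus distribution, and
# with probability lambda the choice is replaced by a fair coin flip.

# run expr with a local RNG state seeded at `seed`, restoring the caller's.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

normalize_vec <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm < .Machine$double.eps)
    stop("cannot normalize a zero vector", call. = FALSE)
  x / nrm
}

#' Construct an internal template
#'
#' Named shapes evaluate an orthogonal polynomial of the requested degree on
#' the normalized time grid `t_k = (k-1)/(K-1)`, mean-centre it and scale to
#' unit Euclidean norm; `"prototype"` is the notation-derived melodic contour
#' `[0, -500, 0]` cents (note 2 five semitones below its neighbours),
#' mean-centred and unit-normalized; `"custom"` unit-normalizes `extra` as
#' given.
#'
#' @param shape `"linear"`, `"quadratic"`, `"cubic"`, `"quartic"`,
#'   `"prototype"` or `"custom"`.
#' @param n_points Template length (number of breakpoints).
#' @param extra Numeric vector for `shape = "custom"`, or a replacement
#'   contour for `"prototype"`.
#' @return Unit-norm numeric vector of length `n_points`.
#' @examples
#' make_template("prototype", 3)  # 0.408 -0.816 0.408
#' @export
make_template <- function(shape = c("cubic", "quartic", "linear", "quadratic",
                                    "prototype", "custom"),
                          n_points, extra = NULL) {
  shape <- match.arg(shape)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  if (shape == "custom") {
    if (is.null(extra)) stop("custom shape requires `extra`", call. = FALSE)
    return(normalize_vec(as.numeric(extra)))
  }
  if (shape == "prototype") {
    proto <- if (is.null(extra)) c(0, -500, 0) else as.numeric(extra)
    if (length(proto) != n_points)
      stop("prototype length does not match n_points", call. = FALSE)
    return(normalize_vec(proto - mean(proto)))
  }
  degree <- match(shape, c("linear", "quadratic", "cubic", "quartic"))
  if (n_points <= degree)
    stop(sprintf("%s template needs more than %d points", shape, degree),
         call. = FALSE)
  tk <- (seq_len(n_points) - 1) / (n_points - 1)
  # orthogonal polynomial basis on the grid: column `degree` is mean-centred
  # and orthogonal to all lower degrees by construction
  normalize_vec(stats::poly(tk, degree)[, degree])
}

#' Specify a simulated observer
#'
#' @param participant_id Identifier.
#' @param group Group label (e.g. `"ASD"`, `"non-ASD"`).
#' @param template Unit-norm weight vector over breakpoints (see
#'   [make_template()]).
#' @param internal_noise_ratio `sigma_int`: SD of the late decision noise in
#'   units of the external decision-variable SD (>= 0).
#' @param lapse_rate Probability in `[0, 1]` that a trial's choice is replaced
#'   by a fair coin flip.
#' @param seed Integer seed driving all of this observer's randomness.
#' @return An object of class `"observer_spec"`.
#' @export
observer_spec <- function(participant_id, group = "none", template,
                          internal_noise_ratio = 0, lapse_rate = 0,
                          seed = 1L) {
  template <- as.numeric(template)
  if (abs(sqrt(sum(template^2)) - 1) > 1e-9)
    stop("template must have unit Euclidean norm", call. = FALSE)
  if (internal_noise_ratio < 0)
    stop("internal_noise_ratio must be >= 0", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate > 1)
    stop("lapse_rate must lie in [0, 1]", call. = FALSE)
  structure(list(participant_id = participant_id, group = group,
                 template = template,
                 internal_noise_ratio = internal_noise_ratio,
                 lapse_rate = lapse_rate, seed = as.integer(seed)),
            class = "observer_spec")
}

# Analytic SD of w.(s_A - s_B): shifts are i.i.d. winsorized normal, so
# Var = 2 * sd_win^2 * ||w||^2 and ||w|| = 1.
external_decision_sd <- function(config) {
  sqrt(2) * winsorized_normal_sd(config$noise_sd, config$clip_multiple)
}

#' Simulate a 2AFC session for one observer
#'
#' Applies the linear-template decision rule to every trial of a
#' [pair_trials()] trial set. Ties (`d = 0`) resolve deterministically to A.
#'
#' @param observer An [observer_spec()].
#' @param trials A `"trial_set"` from [pair_trials()].
#' @return An object of class `"session_log"`: a list with participant
#'   metadata, the `noise_config`, and a `trials` data.frame holding
#'   `trial_index`, `a_bp_1..K`, `b_bp_1..K` and `choice` (`"A"`/`"B"`).
#' @export
simulate_session <- function(observer, trials) {
  config <- attr(trials, "config")
  pool <- attr(trials, "pool")
  w <- observer$template
  if (length(w) != config$n_breakpoints)
    stop("template length does not match config$n_breakpoints", call. = FALSE)
  shifts <- pool_shifts(pool)
  a <- shifts[match(trials$a_id, pool$stimulus_id), , drop = FALSE]
  b <- shifts[match(trials$b_id, pool$stimulus_id), , drop = FALSE]
  n <- nrow(trials)
  sigma <- observer$internal_noise_ratio * external_decision_sd(config)
  d <- drop((a - b) %*% w)
  with_seed(observer$seed + 104729L, {       # decision-stage stream
    if (sigma > 0) d <- d + stats::rnorm(n, 0, sigma)
    choice <- ifelse(d >= 0, "A", "B")
    if (observer$lapse_rate > 0) {
      lapse <- stats::runif(n) < observer$lapse_rate
      choice[lapse] <- sample(c("A", "B"), sum(lapse), replace = TRUE)
    }
  })
  df <- data.frame(trial_index = trials$trial_index, a, b,
                   choice = choice, stringsAsFactors = FALSE)
  K <- config$n_breakpoints
  names(df) <- c("trial_index", paste0("a_bp_", seq_len(K)),
                 paste0("b_bp_", seq_len(K)), "choice")
  structure(list(participant_id = observer$participant_id,
                 group = observer$group, condition = config$condition,
                 seed = observer$seed, config = config, trials = df),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("session_log: %s [%s], %s, %d trials\n", x$participant_id,
              x$group, x$condition, nrow(x$trials)))
  invisible(x)
}

# chosen/unchosen shift matrices of a session
session_shift_matrices <- function(session) {
  df <- session$trials
  K <- session$config$n_breakpoints
  a <- as.matrix(df[, paste0("a_bp_", seq_len(K))])
  b <- as.matrix(df[, paste0("b_bp_", seq_len(K))])
  isA <- df$choice == "A"
  chosen <- a; chosen[!isA, ] <- b[!isA, ]
  unchosen <- b; unchosen[!isA, ] <- a[!isA, ]
  list(a = a, b = b, chosen = chosen, unchosen = unchosen)
}

#' Run one observer through stimulus generation, pairing and simulation
#'
#' Convenience wrapper: seeds the stimulus stream from the observer's seed,
#' builds a fresh pool and pairing, and simulates the session.
#'
#' @param observer An [observer_spec()].
#' @param config A [noise_config()].
#' @return A `"session_log"`.
#' @export
simulate_observer_session <- function(observer, config) {
  trials <- with_seed(observer$seed, {
    pool <- build_stimulus_pool(config)
    pair_trials(pool, config)
  })
  simulate_session(observer, trials)
}

#' Specify a simulated cohort
#'
#' Observer `i` receives template `normalize(base + dispersion * z_i)` with
#' `z_i` a standard-normal vector, an internal-noise ratio drawn from a normal
#' distribution truncated at zero, and a lapse rate drawn from a normal
#' distribution truncated to `[0, 1]`.
#'
#' @param group Group label.
#' @param n_observers Number of observers (>= 2).
#' @param base_shape Template shape label passed to [make_template()], or a
#'   numeric base template (used as `extra` with `shape = "custom"`).
#' @param template_dispersion Non-negative dispersion `delta` of individual
#'   templates around the base.
#' @param internal_noise_mean,internal_noise_sd Parameters of the
#'   internal-noise distribution.
#' @param lapse_mean,lapse_sd Parameters of the lapse-rate distribution.
#' @param seed Master seed; every observer's seed derives from it.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(group, n_observers = 32L, base_shape = "cubic",
                        template_dispersion = 0.3, internal_noise_mean = 1,
                        internal_noise_sd = 0.3, lapse_mean = 0, lapse_sd = 0,
                        seed = 1L) {
  if (n_observers < 2L) stop("n_observers must be >= 2", call. = FALSE)
  if (template_dispersion < 0)
    stop("template_dispersion must be >= 0", call. = FALSE)
  structure(list(group = group, n_observers = as.integer(n_observers),
                 base_shape = base_shape,
                 template_dispersion = template_dispersion,
                 internal_noise_mean = internal_noise_mean,
                 internal_noise_sd = internal_noise_sd,
                 lapse_mean = lapse_mean, lapse_sd = lapse_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a whole cohort
#'
#' Draws each observer's template, internal noise and lapse rate from the
#' cohort distributions, then gives every observer a fresh stimulus pool,
#' pairing and simulated session. Fully reproducible from the master seed.
#'
#' @param spec A [cohort_spec()].
#' @param config A [noise_config()].
#' @return A list with `observers` (list of [observer_spec()]) and `sessions`
#'   (list of `"session_log"`), class `"cohort"`.
#' @export
make_cohort <- function(spec, config) {
  K <- config$n_breakpoints
  base <- if (is.numeric(spec$base_shape)) {
    make_template("custom", K, extra = spec$base_shape)
  } else {
    make_template(spec$base_shape, K)
  }
  n <- spec$n_observers
  draws <- with_seed(spec$seed, {
    list(z = matrix(stats::rnorm(n * K), n, K),
         noise = pmax(0, stats::rnorm(n, spec$internal_noise_mean,
                                      spec$internal_noise_sd)),
         lapse = pmin(1, pmax(0, stats::rnorm(n, spec$lapse_mean,
                                              spec$lapse_sd))),
         seeds = sample.int(2147480000L, n))
  })
  observers <- vector("list", n)
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    w <- normalize_vec(base + spec$template_dispersion * draws$z[i, ])
    obs <- observer_spec(
      participant_id = sprintf("%s_%02d", spec$group, i),
      group = spec$group, template = w,
      internal_noise_ratio = draws$noise[i], lapse_rate = draws$lapse[i],
      seed = draws$seeds[i])
    observers[[i]] <- obs
    sessions[[i]] <- simulate_observer_session(obs, config)
  }
  structure(list(observers = observers, sessions = sessions,
                 spec = spec, config = config), class = "cohort")
}
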