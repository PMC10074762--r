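# Shared helpers: compact constructors for simulated sessions.

# speech-style config with an arbitrary trial count (pool = 2 * trials)
speech_config <- function(n_trials = 400L, n_breakpoints = 8L) {
  noise_config("speech", n_breakpoints = n_breakpoints,
               pool_size = 2L * n_trials, n_trials = n_trials)
}

# one simulated observer session under a fresh pool/pairing
sim_session <- function(shape = "cubic", sigma = 0, lapse = 0,
                        config = speech_config(), seed = 1L, extra = NULL) {
  w <- make_template(shape, config$n_breakpoints, extra = extra)
  obs <- observer_spec("obs", template = w, internal_noise_ratio = sigma,
                       lapse_rate = lapse, seed = seed)
  simulate_observer_session(obs, config)
}

# a session whose choices are made uniformly at random (pure guessing)
random_session <- function(config = speech_config(), seed = 1L) {
  sim_session(shape = "custom", extra = c(1, rep(0, config$n_breakpoints - 1)),
              lapse = 1, config = config, seed = seed)
}

# build a session_log directly from shift matrices and choices (for worked
# examples with hand-computable kernels)
manual_session <- function(a, b, choice, config) {
  K <- config$n_breakpoints
  df <- data.frame(trial_index = seq_len(nrow(a)), a, b, choice = choice,
                   stringsAsFactors = FALSE)
  names(df) <- c("trial_index", paste0("a_bp_", seq_len(K)),
                 paste0("b_bp_", seq_len(K)), "choice")
  structure(list(participant_id = "manual", group = "none",
                 condition = config$condition, seed = NA_integer_,
                 config = config, trials = df),
            class = "session_log")
}
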