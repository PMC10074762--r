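# Stimulus noise generation, pooling, pairing and contour interpolation.

test_that("condition defaults carry the study parameters", {
  sp <- noise_config("speech")
  expect_equal(sp$n_breakpoints, 8L)
  expect_equal(sp$noise_sd, 70)
  expect_equal(sp$clip_multiple, 2.2)
  expect_equal(sp$base_f0, 210)
  expect_equal(sp$duration, 250)
  expect_equal(sp$interpolation, "linear")
  expect_equal(sp$pool_size, 800L)
  expect_equal(sp$n_trials, 400L)
  me <- noise_config("melody")
  expect_equal(me$n_breakpoints, 3L)
  expect_equal(me$base_f0, 260)
  expect_equal(me$duration, 1380)
  expect_equal(me$interpolation, "square_bpf")
  expect_equal(me$transition_time, 0.1)
  expect_equal(me$pool_size, 600L)
  expect_equal(me$n_trials, 300L)
})

test_that("invalid configurations are rejected", {
  expect_error(noise_config("speech", noise_sd = -1), "noise_sd")
  expect_error(noise_config("speech", n_breakpoints = 1), "n_breakpoints")
  expect_error(noise_config("speech", pool_size = 801), "2 \\* n_trials")
  expect_error(noise_config("melody", transition_time = 0.5), "transition")
})

test_that("shifts are winsorized normal with zero mean and the clipped SD", {
  cfg <- noise_config("speech")
  expect_equal(sample_contour(noise_config("speech", noise_sd = 0))$shifts,
               rep(0, 8))
  set.seed(101)
  # 1e6 shift values: 125000 contours of 8 breakpoints
  big <- noise_config("speech", pool_size = 125000L, n_trials = 62500L)
  shifts <- as.numeric(as.matrix(build_stimulus_pool(big)[, -(1:2)]))
  bound <- 70 * 2.2
  expect_lte(max(abs(shifts)), bound)
  expect_gt(max(abs(shifts)), bound - 1)    # the bound is actually attained
  # empirical mean within 3 standard errors of zero
  expect_lt(abs(mean(shifts)), 3 * sd(shifts) / sqrt(length(shifts)))
  # empirical SD matches the closed-form winsorized-normal SD (68.25 cents)
  expect_equal(winsorized_normal_sd(70, 2.2), 68.2523, tolerance = 1e-4)
  expect_equal(sd(shifts), winsorized_normal_sd(70, 2.2), tolerance = 3e-3)
})

test_that("pools have the printed sizes and contain no duplicate contours", {
  set.seed(7)
  sp <- build_stimulus_pool(noise_config("speech"))
  expect_equal(dim(sp), c(800L, 2L + 8L))
  expect_false(any(duplicated(sp[, -(1:2)])))
  me <- build_stimulus_pool(noise_config("melody"))
  expect_equal(dim(me), c(600L, 2L + 3L))
  tiny <- build_stimulus_pool(noise_config("speech", n_breakpoints = 2,
                                           pool_size = 2, n_trials = 1))
  expect_equal(nrow(tiny), 2L)
  expect_false(identical(tiny[1, -(1:2)], tiny[2, -(1:2)]))
})

test_that("pairing uses each stimulus exactly once and is seed-reproducible", {
  cfg <- noise_config("speech")
  set.seed(42)
  pool <- build_stimulus_pool(cfg)
  tr <- pair_trials(pool, cfg)
  expect_equal(nrow(tr), 400L)
  expect_setequal(c(tr$a_id, tr$b_id), pool$stimulus_id)
  expect_false(any(tr$a_id == tr$b_id))
  mcfg <- noise_config("melody")
  expect_equal(nrow(pair_trials(build_stimulus_pool(mcfg), mcfg)), 300L)
  expect_error(pair_trials(pool[1:3, ], cfg), "even")
  # bit-identical pools and pairings under the same seed
  set.seed(42)
  pool2 <- build_stimulus_pool(cfg)
  tr2 <- pair_trials(pool2, cfg)
  expect_identical(pool, pool2)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
  # minimal pool
  tiny_cfg <- noise_config("speech", n_breakpoints = 2, pool_size = 2,
                           n_trials = 1)
  tiny <- pair_trials(build_stimulus_pool(tiny_cfg), tiny_cfg)
  expect_setequal(c(tiny$a_id, tiny$b_id), 1:2)
})

test_that("linear interpolation is piecewise linear through the breakpoints", {
  cfg2 <- noise_config("speech", n_breakpoints = 2, pool_size = 2,
                       n_trials = 1)
  traj <- interpolate_contour(c(0, 100), cfg2, 3)
  expect_equal(traj, c(0, 50, 100))
  cfg <- noise_config("speech")
  set.seed(3)
  s <- sample_contour(cfg)
  # n_samples = K puts samples exactly on the breakpoints
  expect_equal(interpolate_contour(s, cfg, 8), s$shifts)
  expect_error(interpolate_contour(s, cfg, 4), "n_samples")
})

test_that("square-BPF contours hold plateaus with linear onset ramps", {
  cfg <- noise_config("melody")
  shifts <- c(0, -500, 0)
  dur <- cfg$duration / 1000
  onsets <- (0:2) / 3 * dur
  grab <- function(t) interpolate_contour(shifts, cfg,
                                          1001)[round(t / dur * 1000) + 1]
  # plateau samples away from any onset take the note value exactly
  expect_equal(grab(onsets[2] + 0.2), -500)
  expect_equal(grab(onsets[3] + 0.2), 0)
  expect_equal(grab(0.1), 0)
  # centre of the note-2 onset ramp is the midpoint of adjacent note values
  n <- 100001L
  traj <- interpolate_contour(shifts, cfg, n)
  t <- seq(0, dur, length.out = n)
  mid <- which.min(abs(t - onsets[2]))
  expect_equal(traj[mid], -250, tolerance = 1)
})

test_that("configs load from JSON and YAML with condition defaults", {
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(condition = "melody", noise_sd = 50),
                       jpath, auto_unbox = TRUE)
  cfg <- read_noise_config(jpath)
  expect_equal(cfg$noise_sd, 50)
  expect_equal(cfg$n_breakpoints, 3L)      # melody default retained
  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("condition: speech", "n_trials: 100", "pool_size: 200"),
             ypath)
  cfg2 <- read_noise_config(ypath)
  expect_equal(cfg2$n_trials, 100L)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(noise_sd = 70), bad, auto_unbox = TRUE)
  expect_error(read_noise_config(bad), "condition")
})

test_that("stimulus pools round-trip through CSV", {
  set.seed(5)
  pool <- build_stimulus_pool(noise_config("melody"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pool(pool, path)
  back <- read_pool(path)
  expect_equal(as.data.frame(back), as.data.frame(pool), tolerance = 1e-12)
})
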