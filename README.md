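# revpitch

Reverse-correlation (classification-image) analysis of pitch-contour mental
representations, for auditory psychophysicists studying how listeners weight
time-varying pitch information in speech and music — including cohort
comparisons such as autistic vs non-autistic groups.

In a reverse-correlation experiment the listener hears many pairs of
randomly pitch-perturbed stimuli and picks, on every trial, the one that
best matches an internal target (a rising tone, a known melody). Each
stimulus is a contour of pitch shifts *s* = (s₁, …, s_K) in cents at K
breakpoints, drawn i.i.d. from N(0, 70²) and clipped at ±2.2 SD (speech and
complex tone: K = 8, linearly interpolated over 250 ms; melody: K = 3 note
plateaus with 0.1 s transitions over 1380 ms). The listener's **first-order
temporal kernel** is

> kernel_k = mean(chosen contours)_k − mean(unchosen contours)_k (cents),

a data-driven image of the mental representation that drove their choices.
From the kernel the package derives:

- **RMS sensitivity** √(mean kernel²) — how strongly pitch is weighted;
- **agreement** — the fraction of trials where the actual choice matches
  the pair member correlating more highly with the listener's own kernel;
  an index of internal noise (in-sample and leave-one-out variants);
- **polynomial shape** — OLS fits of degree 1–4 on normalized time with a
  sequential nested-F selection ladder, plus the y-intercept b₀ and the
  tangent slope at the midpoint t = 0.5;
- **group statistics** — per-breakpoint Welch tests with Bonferroni
  correction, Welch tests on RMS and agreement with Cohen's d, intra-group
  pairwise kernel correlations, and exceptional-sensitivity flags
  (RMS > reference mean + 2 SD).

Because no human data ship with the package, a first-class simulation module
provides **linear template observers**: observer decisions follow
d = w·(s_A − s_B) + ε with a unit-norm template w, late Gaussian noise
ε ~ N(0, (σ_int σ_ext)²) scaled to the analytic external decision-variable
SD, and optional lapses. Cohorts draw templates around a base shape with
controllable dispersion, so every analysis stage is testable end to end.

A small audio module renders stimuli as harmonic complexes (fundamental plus
seven odd harmonics, sine phase) and validates them with an autocorrelation
F0 estimator and minimal WAV I/O.

## Worked example

Simulate two 32-observer cohorts whose mental representations differ in
shape (quartic vs cubic base templates) and heterogeneity (higher template
dispersion in the first group), run the full analysis, and print the report:

```r
library(revpitch)

cfg <- pipeline_config(
  conditions = c("speech", "complex_tone", "melody"),
  group_1 = cohort_spec("ASD", n_observers = 32, base_shape = "quartic",
                        template_dispersion = 0.45, internal_noise_mean = 1.2,
                        internal_noise_sd = 0.4, seed = 1),
  group_2 = cohort_spec("non-ASD", n_observers = 32, base_shape = "cubic",
                        template_dispersion = 0.3, internal_noise_mean = 1.2,
                        internal_noise_sd = 0.4, seed = 2),
  seed = 2026)
report <- run_pipeline(cfg)   # ~2 s
report
```

```
group_report: ASD vs non-ASD

== speech ==
  best shape: quartic (ASD) vs cubic (non-ASD)
  RMS: M 17.03 vs 19.18 cents, Welch t = -3.16, df = 61.9, p = 0.00247
  agreement: 0.699 vs 0.731, t = -2.84, p = 0.00619
  intra-group r: 0.44 vs 0.61, t = -10.24 (df 990), p = 1.83e-23
  flagged > ref mean + 2 SD: 0 (0.00%) vs 1 (3.12%)

== complex_tone ==
  best shape: quartic (ASD) vs cubic (non-ASD)
  RMS: M 18.47 vs 19.05 cents, Welch t = -0.60, df = 57.1, p = 0.548
  agreement: 0.718 vs 0.733, t = -0.91, p = 0.364
  intra-group r: 0.45 vs 0.65, t = -11.52 (df 990), p = 6.34e-29
  flagged > ref mean + 2 SD: 0 (0.00%) vs 1 (3.12%)

== melody ==
  RMS: M 28.32 vs 28.30 cents, Welch t = 0.02, df = 57.8, p = 0.988
  agreement: 0.689 vs 0.692, t = -0.28, p = 0.78
  intra-group r: 0.78 vs 0.89, t = -7.60 (df 990), p = 6.84e-14
  flagged > ref mean + 2 SD: 0 (0.00%) vs 2 (6.25%)
  prototype r: 1.00 vs 1.00
```

Reading the output: the group-level shape ladder recovers the generating
quartic-vs-cubic difference in both 8-breakpoint conditions (melody, with 3
points, is excluded from the quartic ladder). The higher template dispersion
of the first group shows up exactly where it should — lower intra-group
pairwise kernel correlations in every condition — while the matched internal
noise keeps RMS and agreement similar in the tone and melody conditions.
Both groups' mean melody kernels correlate perfectly with the prototypical
contour `[0, -500, 0]` cents (note 2 five semitones below its neighbours),
since both cohorts were built around it. `write_report(report, "out/")`
serializes kernels, metrics, per-timepoint tables, shape ladders and a JSON
summary.

Single-observer workflow:

```r
cfg  <- noise_config("speech")                      # 8 breakpoints, 400 trials
obs  <- observer_spec("p01", template = make_template("cubic", 8),
                      internal_noise_ratio = 1, seed = 11)
sess <- simulate_observer_session(obs, cfg)
k    <- estimate_kernel(sess)                       # cents per breakpoint
observer_metrics(sess)                              # rms, agreement
reliability_curve(sess, c(100, 300, 400))           # subset-vs-full r
select_shape(k)                                     # nested-F shape ladder
```

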