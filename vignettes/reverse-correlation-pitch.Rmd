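---
title: "Reverse correlation for pitch contours: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse correlation for pitch contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revpitch)
```

## The measurement problem

Classical psychoacoustic tasks report a performance score, which confounds
two very different things: how faithfully a listener represents the target
pitch pattern, and how noisy their decisions are from trial to trial.
Reverse correlation separates them. The listener hears pairs of randomly
pitch-perturbed stimuli and picks the better match to an internal target on
each of a few hundred trials; regressing the choices on the random
perturbations exposes the internal template directly (the *classification
image*, here a *temporal kernel* over breakpoints), while the consistency
between the choices and the listener's own kernel indexes internal noise.

## Stimulus model

A stimulus is a vector of pitch shifts in cents at K breakpoints, drawn
i.i.d. from N(0, `noise_sd`² = 70²) and **winsorized** at ±`clip_multiple`
× `noise_sd` = ±154 cents: draws beyond the bound are set to the bound, not
redrawn. Winsorizing vs redrawing is genuinely open for "clipped" noise; we
chose winsorizing because it keeps the analytic variance tractable
(`winsorized_normal_sd()` gives SD 68.25 cents for the study parameters,
against the nominal 70) and record the choice in the config (`clip_mode`)
so a redraw mode can be added without breaking session logs.

Three conditions are built in:

| condition    | K | base F0 | duration | contour                     | pool → trials |
|--------------|---|---------|----------|-----------------------------|---------------|
| speech       | 8 | 210 Hz  | 250 ms   | linear interpolation        | 800 → 400     |
| complex_tone | 8 | 210 Hz  | 250 ms   | linear interpolation        | 800 → 400     |
| melody       | 3 | 260 Hz  | 1380 ms  | square BPF, 0.1 s ramps     | 600 → 300     |

Breakpoints are placed at normalized times (k−1)/(K−1); the field's stimulus
tools do not pin down placement within the sound, and the analysis is
invariant to it because kernels are computed on breakpoint values, not the
dense trajectory. For the square breakpoint function the three notes occupy
equal thirds of the duration (the sung phrase the melody emulates has a
longer final note; equal thirds is the neutral choice absent note
annotations) with linear ramps of 0.1 s centred on each interior onset.

Pools are paired **without replacement** — each stimulus appears in exactly
one 2AFC pair, matching random pairing of a fixed pool — with A/B roles
randomized per participant; an i.i.d. pairing mode is available behind the
`iid_pairs` flag. Duplicate contours in a pool are regenerated; the event
has negligible probability but the uniqueness guarantee is cheap.

## The template observer (synthetic data)

Simulated listeners implement the standard linear-template 2AFC model. On a
trial with contours s_A and s_B the decision variable is

d = w · (s_A − s_B) + ε,  ε ~ N(0, (σ_int × σ_ext)²),

with w the unit-norm internal template, σ_ext the *analytic* SD of
w·(s_A − s_B) under the stimulus distribution (√2 × 68.25 cents — computed
in closed form, not estimated per session), and σ_int the
internal-to-external noise ratio. The observer picks A iff d ≥ 0 (the tie
d = 0 has probability zero and resolves to A for determinism); with lapse
probability λ the choice is replaced by a fair coin flip. Operating on
breakpoint shifts rather than the interpolated trajectory loses nothing:
interpolation is a fixed linear map, so the dense-contour observer is the
same model with a transformed template.

Named template shapes use discrete orthogonal polynomials (`stats::poly`)
on the breakpoint grid, mean-centred and unit-normalized. Orthogonality is
what makes the selection-ladder behaviour interpretable: a quartic template
has, by construction, no quadratic or cubic component, so the ladder's
early rungs are null and the linear-vs-quartic rung carries the effect —
the same signature the group analyses are designed to detect. The melodic
prototype is the notation-derived contour [0, −500, 0] cents (note 2 five
semitones below its neighbours), mean-centred and normalized like the
polynomial shapes; `custom` templates are normalized exactly as supplied.

Cohorts draw observer i's template as normalize(base + δ·z_i) with standard
normal z_i, internal-noise ratios from a zero-truncated normal and lapse
rates from a [0, 1]-truncated normal. The dispersion δ is the lever for
intra-group heterogeneity: higher δ lowers pairwise between-participant
kernel correlations, the package's analogue of diverse perceptual profiles
within a clinical group. Default cohort size is 32 per group, the study
scale. Everything — pools, pairings, decisions — derives from one master
seed, so a cohort is a pure function of its spec.

What the simulation does *not* emulate: serial dependencies between trials,
attention drifts, asymmetric lapses, non-linear (e.g. probability-matching)
decision rules, or any coupling between template shape and internal noise.
Passing tests therefore demonstrate that the estimators recover the
constructs of this model family at realistic trial counts — not that human
data satisfy the model.

## Estimators

**Kernel.** `estimate_kernel()` computes mean(chosen) − mean(unchosen) per
breakpoint, in cents, with no normalization; scale questions live in the
metrics. The estimator is exactly antisymmetric under choice inversion and
homogeneous of degree one in the stimulus scale (both tested).

**Reliability.** `reliability_curve()` correlates the kernel from the first
n trials with the full-set kernel (nested prefixes, matching the
subset-vs-full pilot criterion r ≥ 0.8; a random-subset mode exists behind
a flag). For a pure guesser the nested construction has an analytic noise
floor E[r] ≈ √(n/N) — 0.866 at 300 of 400 — which the test suite confirms
by Monte Carlo; real reliability claims must clear it, which the r ≥ 0.8
criterion does only mildly, a useful caution when interpreting pilot-style
reliability numbers.

**RMS and agreement.** RMS is √(mean kernel²). Agreement scores each trial
by Pearson-correlating both contours with the kernel; the higher-correlated
member is the "objectively correct" choice and agreement is the fraction of
matches. Pearson correlation (not the dot product) follows the field's
usage and stays well defined for 3-point melody kernels (df = 1). Trials
where either correlation is undefined (zero-variance contour) or the two
correlations tie are excluded from the denominator; exclusion biases
neither direction and the scored-trial count is reported. In-sample scoring
— against the participant's own kernel, as the construct is defined — is
optimistically biased for noisy observers: a pure guesser scores ≈ 0.55 at
400 trials, not 0.50, because each trial's choice contributes to the kernel
it is scored against. The `leave_one_out` option removes the shared trial
and re-centres guessers on 0.5 (tested); we keep in-sample as the default
because it is the construct the agreement index is defined as, and the bias
is shared across participants compared under equal trial counts.

**Shape selection.** Degree-1..4 OLS fits on normalized time [0, 1] feed
sequential nested F-tests (the likelihood-ratio-equivalent form for
Gaussian OLS, verified against `stats::anova` and a direct log-likelihood
computation): linear vs quadratic first; if null, linear vs cubic; a
significant cubic is challenged by quartic; if linear vs cubic is also
null, linear vs quartic decides. The one branch the source procedure never
exhibits — a significant quadratic rung — steps up the same way (quadratic
vs cubic, then vs quartic). α = 0.05 throughout. Group-level fits pool one
observation per participant per breakpoint; participant-level fits use that
participant's K points. Melody kernels (3 points) support only the linear
fit and are excluded from the ladder. Shape parameters are b₀ = p(0) and
the analytic derivative p′(0.5) — "midpoint" is defined on the normalized
axis since no other definition is canonical; the ladder itself is invariant
to affine time rescaling (tested).

**Group analyses.** Per-breakpoint group contrasts use Welch tests with
Bonferroni correction over the K breakpoints. This is a deliberate
fixed-effects stand-in for a by-subject random-intercept mixed model: with
exactly one kernel value per participant per breakpoint, the group contrast
at each time point estimates the same quantity, and the substitution is
noted in the serialized report header. RMS and agreement are compared with
Welch tests plus pooled-SD Cohen's d. Intra-group variability compares the
two sets of C(n, 2) pairwise kernel correlations with a Student t
(df = m₁ + m₂ − 2 = 990 for 32-observer groups); because the 496 pairs per
group share participants, these observations are dependent and the test's
nominal size is approximate — a Fisher-z variant is offered since raw
correlations are bounded. Exceptional sensitivity is a strict exceedance of
the reference group's mean + 2 sample SDs (n − 1 denominator; the strict
inequality and the sample SD are conventions chosen once and documented, as
the defining usage does not specify either).

## Numerical and audio choices

Audio is validation only — the pipeline never consumes it. Rendering is
additive synthesis of the fundamental plus seven odd harmonics (partials
1, 3, …, 15) at equal amplitude with sine phase, phase-accumulated so
contours glide continuously; 44.1 kHz, peak-normalized to −3 dBFS (a sound
file has no SPL; the playback level is metadata), 5 ms raised-cosine ramps
against spectral splatter. F0 estimation is frame-wise autocorrelation
(50 ms frames, 25 ms hop) with parabolic peak interpolation, median across
frames; it recovers rendered plateau pitches well within 1%. WAV I/O is
minimal mono PCM16.

## Problem sizes in the test suite

Property tests run at sizes chosen to make their Monte Carlo margins
comfortable: 10⁵–10⁶ draws for distributional checks on the noise
generator, 100 replicates of full 400-trial speech sessions for reliability
and agreement properties, 100 eight-observer cohorts per generating shape
for ladder recovery, 500 replicates for the type-I-error check, and 5000
trials for template-recovery ceilings. These are the package's chosen
verification scales; the full 32-per-group pipeline itself runs in about
two seconds.

## Known limitations

- The observer model is linear with late Gaussian noise; estimator
  behaviour under non-linear or non-stationary human strategies is
  untested by construction.
- In-sample agreement is biased upward for noisy observers (see above);
  compare groups only at matched trial counts, or use `leave_one_out`.
- The intra-group correlation t-test inherits the dependence of pairwise
  correlations; treat its p-values as descriptive.
- The square-BPF note grid assumes equal note durations; melodies with
  strongly unequal notes need a custom config.
- The melody condition's 3 breakpoints support neither the shape ladder
  nor degree > 1 fits; this mirrors the design, not a software limit.
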