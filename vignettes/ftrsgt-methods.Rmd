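---
title: "Models and methods behind ftrsgt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ftrsgt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of **ftrsgt** — the
models, their assumptions, the tunable parameters, the numerical choices,
and what the synthetic-data tests do and do not establish. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The task and the behavioral markers

In the FT-RSGT a metronome tone sounds every 750 ms (800/1600/800 tones in
three blocks); the participant taps in synchrony while choosing the left or
right button as randomly as possible, and thought probes (Likert 1 = clearly
on task … 4 = clearly off task) appear at uniform random intervals of
40–80 s (10/20/10 per block). In the third block roughly every 8–12th tone
is a higher-pitched oddball, never among the first 10 tones after block
start or after a probe.

Two markers are computed over the last `n_back = 25` **tap events** (not
tone trials) before each probe:

* **BV**, the sample SD of the inter-tap intervals. No intervals are
  screened: a missed tap merges two intervals into one long one, a
  double-tap adds a near-zero one; both inflate BV, by construction.
* **AE**, the approximate entropy ApEn(m = 2) of the button sequence, with
  *exact* block matching (tolerance 0 — the Pincus tolerance `r` is
  meaningless for symbols) and self-matches included so no `log 0` occurs.
  On binary sequences ApEn is bounded by `log 2` in the long-run limit; the
  unbounding transform is `AE_trans = −log(log 2 − AE)`, and because a
  25-symbol window can reach the bound, the argument is clamped at
  `log 2 − 1e−10` rather than erroring — no windows are excluded.

Both markers are z-scored across all usable probes of the dataset, and the
`Trial` covariate is the within-block probe index z-scored over the same
rows. These are package-level conventions: the source analyses state only
"z-transformed across subjects" and "Trial (probe number)".

## 2. The ordinal probe-response model

Responses are ordinal, so the model is an ordered probit on a latent
normal scale: `y* = Xβ + u_subject + u_subject:block + ε`, `ε ~ N(0,1)`,
with the response equal to category `k` iff `τ_{k−1} < y* ≤ τ_k`. There is
no intercept and the residual SD is fixed at 1 — the three free cutpoints
absorb location, which identifies the probit scale. Fixed effects are BV,
AE, BV×AE, Trial, Block, Group and Group×Block, treatment-coded (baseline
block, sham group as references).

Priors: `β ~ N(0, 2.5²)`, ordered `τ ~ N(0, 5²)`, half-Normal(1) on both
random-intercept SDs. The sources say only "non-informative"; these are
weakly informative on the probit scale, where effects above 2–3 are
already extreme.

### Sampler

No Stan-style PPL is available in the target environment, so the sampler is
a purpose-built Gibbs scheme in compiled code:

1. **Latent responses** by truncated-normal draws (Albert–Chib data
   augmentation), inverse-CDF method with tail guards.
2. **All coefficients jointly** — fixed effects *and* both random-intercept
   vectors — in one Gaussian block draw from their exact conditional. The
   textbook alternation between β and the intercepts mixes very slowly for
   between-subject terms (Group), because the two are strongly coupled.
3. **Variance components** by random-walk Metropolis on `log σ` (adapted
   during warmup) *plus* an interweaving (ASIS) move: rewrite `u = σv`,
   hold `v`, and redraw `σ` conjugately in the non-centered
   parameterization (the half-Normal prior is the positive half of a
   Normal on the unconstrained coefficient). Without the interweaving step
   the σ-vs-u funnel gives the nested SD an effective sample size an order
   of magnitude too small.
4. **Cutpoints** by per-component collapsed Metropolis steps on the ordinal
   likelihood with the latent responses integrated out (Cowles' remedy for
   the stalling uniform Gibbs update at large n); only the two adjacent
   response categories enter each acceptance ratio. Proposal scales adapt
   toward 44% acceptance during warmup.
5. **Recentering sweeps** along the likelihood-invariant ridges of the
   collapsed posterior: the global location (all cutpoints and subject
   intercepts together), each design column that is constant within
   subject-block cells (Group, Block, Group×Block) against the cell
   intercepts, and each subject intercept against its cells. Along these
   directions the likelihood is flat and the conditional is the Gaussian
   implied by the priors, so the sweep is an exact Gibbs draw. These
   directions are only prior-pinned and are the dominant slow modes
   otherwise.

All adaptation stops at the end of warmup. Convergence is gated at split
R-hat < 1.01 and bulk ESS > 400 (Geyer initial monotone sequence) for every
reported parameter; a failing fit is flagged and the pipeline refuses to
report it. Defaults: 4 chains × 1000 post-warmup draws after 500 warmup.

Posterior summaries are the mean, the 95% HDI (sorted-draws shortest
window), evidence ratios as draw-count ratios (`Inf` when one side is
empty, as printed in the field), and Bayes R² computed per draw as
`Var(η)/(Var(η)+1)` on the latent scale with random effects included.

### Validation

The tests check the sampler against an independent maximum-likelihood
ordered probit (numerical optimization) on a large single-group dataset,
verify cutpoint ordering in every draw, probit sign symmetry, null-data HDI
coverage, and parameter recovery from the generative model at the reference
effect sizes (BV 0.19, AE −0.07, Trial 0.81, stimulation block 0.27,
random-intercept SDs 0.5/0.3, thresholds −0.5/0.5/1.5). The thresholds and
probe layout (20 + 20 for recovery, 10 + 20 for power, matching the task)
are config choices fixed once; recovery tolerance is two posterior SDs.

## 3. Power analysis

`estimate_power()` repeats: draw a two-group dataset from the generative
model with the Group×Block coefficient set to `b` and all nuisance
parameters from the config above; refit; declare success when ≥ 95% of the
retained draws are on the expected side of zero (the boundary counts as
success). The fit-back sampler is a single short chain (300 warmup + 600
draws) with the convergence gate off — a deliberate speed approximation:
the decision only needs the tail fraction around 0.95, for which ~600
draws give a Monte-Carlo error below 1%. The sources drew nuisance
parameters from an earlier study's (unpublished) posterior; here they are
fixed at the reference values, which is why the power target carries a
±10-point band.

The power surface `power(b, N) = 1 − exp(−[m0 + m1 b + m2 b²] N)` is fit by
linearizing — regress `−log(1 − power)/N` on `(1, b, b²)` with weights
∝ `n_sims · N`, dropping saturated cells — which is deterministic;
agreement with nonlinear least squares on noiseless grids is tested
(`nls` needs `scaleOffset` there, its documented zero-residual remedy).
Predictions are clipped to `[0, 1)` and are exactly 0 at `N = 0`.

## 4. Pupillometry

Preprocessing follows the standard chain: per-eye selection by least
missing data; velocity-based blink detection (smoothed derivative crossing
a steep negative onset and recovering past a positive offset, padded by a
margin, with all missing samples always enclosed); merging of intervals
separated by < 100 ms; linear interpolation; 5 Hz low-pass.

There is no IIR filter routine in base R, so the Butterworth low-pass is
applied in the frequency domain as the *squared* magnitude response of the
analog prototype (the magnitude response of a forward–backward filtfilt),
with reflection padding against circular edge effects. It is exactly
zero-phase and its attenuation is checked against the closed-form gain in
the tests.

The tonic/phasic decomposition works at 250 Hz:

1. detect troughs with prominence above `0.2 × MAD` of the high-passed
   trace;
2. interpolate a natural cubic spline through the trough points
   (provisional tonic);
3. solve non-negative least squares (compiled Lawson–Hanson) for PRF
   regressors, `h(t) = (t/t_max)^n e^{n(1−t/t_max)}` with `n = 10`,
   `t_max = 900 ms`, unit peak so coefficients carry diameter units —
   the printed form of this response function in the source is
   typographically garbled, and the unit-max normalization is our choice;
4. subtract the modeled responses, re-detect troughs, re-fit the spline
   (the final tonic — now a lower envelope: at its trough anchors it lies
   at or below the signal because the subtracted responses are
   non-negative);
5. re-estimate coefficients against the final tonic (the sources describe
   the subtraction order but not whether coefficients are refit; refitting
   is this package's choice);
6. per trial: tonic at the tone onset; phasic = sum of coefficients of
   events within ±200 ms of the onset (tap and tone regressors are nearly
   collinear at this pace, so they are pooled per trial); z-scored within
   subject.

Fewer than two troughs triggers a flagged fallback to a global linear
tonic. Missing-data screens: a trial is excluded when more than 20%
(strict) of its feature window is missing, a probe when more than 10 of
its 25 preceding trials are excluded, a dataset when more than half of all
samples are missing.

**Limitation**: tonic content at frequencies near the event rate that is
*not* event-locked can be absorbed into the PRF coefficients when true
amplitudes are near zero; the zero-amplitude test therefore uses a slow
tonic. On event-dense fixtures the traditional baseline (mean over
[−200, 0) ms) correlates near 1 with the envelope tonic while the two
phasic estimates correlate much less — the overlap of 750 ms-spaced
responses is exactly what the deconvolution corrects.

## 5. EEG features

Preprocessing is a 0.5–30 Hz zero-phase band-pass (same frequency-domain
Butterworth) with optional re-referencing to named channels; artifact
screening is a deterministic ±100 µV amplitude criterion (the sources used
visual inspection, which has no numeric criterion to reproduce). Channel
geometry is abstract: channels are named roles (`frontal_midline`,
`posterior_*`), no electrode-position math.

* **MMN**: baseline-correct to [−100, 0) ms, average, difference
  (oddball − standard), grand-average peak = most negative sample in
  [120, 300] ms, mean amplitude over peak ± 20 ms, with a polarity
  inversion check on posterior channels.
* **Alpha**: per 1000 ms epoch, demean, taper with a Tukey window whose
  cosine ramps cover 10% of the epoch ("Hanning window of 10%" in the
  commercial-package convention), FFT, one-sided power normalized so the
  full-band sum equals the tapered epoch's variance, summed over 8–12 Hz.
  A few percent of a band-centered sinusoid's power leaks out of the band
  through the near-rectangular window's sidelobes; the tests allow 5% for
  this and check the full-band Parseval identity exactly.
* **Midfrontal theta**: complex Morlet wavelets (`c = 3` cycles,
  `σ_t = c/(2πf)`, L1-normalized, 30 linear frequency steps on 1–30 Hz),
  power averaged over 4–8 Hz × [−500, 0] ms before each tap. The FFT
  convolution is verified against a direct time-domain convolution oracle.
  Condition splits use a per-subject median split (counts differ by at
  most one).

## 6. The synthetic-data generator

The generator is a forward model with known ground truth, not a replica of
human data. Its stated world:

* **Events**: exact task layout; probe gaps drawn uniform(40, 80) s, with
  draws near the block end constrained to the sub-interval that still lets
  the remaining probes fit (so all gaps respect the bounds; an impossible
  layout errors). Oddball spacing is drawn from {8..12} and pushed past
  exclusion zones when needed — after a probe no spacing in 8–12 may be
  admissible, so gaps can exceed 12 *only* across an exclusion zone
  (the exclusion rule is the binding constraint in the sources).
* **Latent attentional state**: AR(1) on the tone grid plus a linear
  time-on-task drift. Defaults (φ = 0.9995 per tone, innovation SD 0.025,
  stationary SD ≈ 0.8) give episodes that decorrelate over minutes —
  mind-wandering episodes are long relative to a 19 s probe window. This
  calibration matters: it is what makes the fitted |β_BV| and |β_AE| grow
  with `n_back` (longer windows estimate the local state with less noise),
  the robustness signature seen in real data; with fast state dynamics the
  within-window smearing cancels that gain and the signature disappears.
* **Taps**: asynchrony `N(0, σ)` with `σ = 50 ms · exp(0.4 · state)`; 1%
  omissions and 1% double-taps; buttons from a first-order Markov chain
  with repetition probability `plogis(qlogis(0.5) + gain · state)` — a
  continuous dial from deterministic to fair-coin behavior.
* **Probes**: ordered-probit draws from `state_coef · state + u_subject +
  u_subject:block` at the probe time, with the config thresholds.
* **Pupil**: tonic = spline-smoothed random walk (knots every 2 s) +
  optional trend; plus truncated-normal-amplitude PRF responses at every
  tone and tap; plus white noise; blinks as missing gaps flanked by steep
  partial-occlusion ramps, as video trackers produce.
* **EEG**: 1/f-shaped noise plus alpha/theta sinusoids with per-condition
  amplitudes and an optional Gaussian deflection (σ = 60 ms, a realistic
  MMN width) on oddball epochs, polarity-inverted posteriorly.

What a green test establishes: the estimators invert this forward model at
the stated noise levels, the bookkeeping (windows, screens, exclusions) is
exact, and the sampler recovers coefficients from its own generative form.
What it does not establish: performance on real eye-tracker artifacts,
non-stationary EEG noise, or model misspecification of the latent state —
none of which have ground truth here.

## 7. Reproducibility

Every stochastic function takes a `seed` and restores the RNG state on
exit (`withr`); the compiled sampler uses R's own RNG stream, so a seeded
call is bit-reproducible. Pipeline artifacts are written next to a JSON
snapshot of the config that produced them, and `scripts/acceptance.R`
recomputes the acceptance targets from scratch from a single `--seed`.
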