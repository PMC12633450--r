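---
title: "Methods: movement, semantic typicality, and effect-size modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement, semantic typicality, and effect-size modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenokit)
library(dplyr)
```

`phenokit` quantifies behavior from three kinds of interview-derived data —
landmark time-series, answer embeddings, and precomputed behavioral
features — and models all of them with the same multivariate effect-size
machinery. This vignette is the package's account of those methods: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where the underlying procedure
left room.

## The statistical model

Every behavioral metric is analyzed with one robust linear model per
outcome:

$$\text{metric} \sim \text{age} + \text{IQ} + \text{sex} +
\text{ADHD-Inatt} + \text{ADHD-Hyper} + \text{ASD}$$

with age in years, full-scale IQ in points, sex coded female = 1 / male = 0,
and three binary diagnostic *status* flags. A Combined ADHD presentation
sets both status flags, so the inattentive and hyperactive domains carry
separate coefficients; ADHD other/unspecified records are excluded from
every fit. The model assumes the diagnostic effects are additive constant
gaps across development — interactions are deliberately left out of the
main model (power), and an `age x disorder` term is fitted only as a
post-hoc follow-up (`fit_interaction()`), whose p-value is reported
uncorrected.

Fitting is iteratively reweighted least squares with the Tukey bisquare
weight $w(u) = (1 - (u/c)^2)^2$ for $|u| \le c$ (else 0), $c = 4.685$ (95%
Gaussian efficiency), residuals scaled by the MAD-based robust scale
$\hat s = \mathrm{median}(|r|)/0.6745$ re-estimated each iteration.
Iteration stops when the largest coefficient change falls below `tol`
(default `1e-8`, relative for large coefficients) or after `max_iter = 200`
iterations, in which case the fit is returned with `converged = 0` and a
warning rather than an error.

Standard errors use the M-estimation (Huber) covariance with the usual
small-sample correction,

$$\widehat{\mathrm{Cov}}(\hat\beta) = K^2 \,\hat s^2\,
\frac{\sum_i \psi(u_i)^2 / (n-p)}{\big(\tfrac1n\sum_i \psi'(u_i)\big)^2}
\,(X^\top X)^{-1},
\qquad K = 1 + \frac{p}{n}\frac{\mathrm{Var}(\psi')}{\overline{\psi'}^2},$$

the form used by the standard robust-regression implementations. The naive
weighted-least-squares covariance is *not* used: bisquare weights are below
one even for well-behaved residuals, so the weighted residual sum of
squares underestimates the residual variance and inflates every t-statistic
by roughly 15% — enough to break the nominal calibration of the
significance machinery. The test suite cross-checks both coefficients and
standard errors against an independent robust-regression implementation
and verifies empirical type-I control under null simulations.

Two derived quantities drive all reporting:

- **Effect size**, $ES = t/\sqrt{DFE}$ with $DFE = n_\text{used} - p$
  (intercept counted in $p$). This makes effects comparable across
  outcomes whose missingness differs. For a binary predictor with positive
  fraction $\pi$ the quantity approaches
  $d\sqrt{\pi(1-\pi)(1-R^2)}$, where $d$ is the Cohen's d of the group
  contrast and $R^2$ the predictor's collinearity with the rest of the
  design — about $d/2$ for balanced, orthogonal groups. It is this
  definition, not raw Cohen's d, that the package recovers in its
  round-trip tests.
- **Odds ratios**, $OR = e^{\beta}$ from maximum-likelihood logistic fits
  for binary diagnosis outcomes — the multiplicative change in odds per
  unit of the predictor (one year for age). Detected (quasi-)complete
  separation is a hard error; penalized estimation is out of scope.

Missingness is handled listwise *per model*: a participant missing IQ is
dropped from every fit, one missing a single behavioral metric is dropped
only from that metric's model, so `n_used` varies across outcomes and is
reported with every fit. Families of related models (an "analysis block")
are Bonferroni-corrected — $p_\text{adj} = \min(1, m\,p)$ with $m$ the
number of models in the block, applied per predictor — and flagged at
$p_\text{adj} < 0.01$. Exported matrices keep non-significant cells with a
mask flag rather than dropping them.

## Movement quantification

Landmark series are long tables of per-frame 3D coordinates
(image-normalized units: x, y in frame-relative scale, z a unitless
relative depth — documented, not enforced) with a presence flag, sampled at
30 Hz. The chain is:

1. **Missingness mask.** A frame is invalid for a landmark if *any*
   sliding window containing it (nominal length = 2 s of frames, stepping
   one frame) has a missing fraction strictly above 10%.
2. **Jitter mask.** A frame is invalid if any covering 10-frame window has
   a sample standard deviation (ddof = 1) of the x-coordinate, over the
   present frames in that window, above 0.1 for face landmarks or 0.01 for
   pose landmarks. Windows with fewer than two present frames impose no
   exclusion. A landmark-frame must pass **both** masks.
3. **Face alignment.** Per frame, the least-squares affine map from the
   present face landmarks to a canonical template is fitted and applied to
   all face landmarks, removing head rotation, translation, scale, and
   shear. At least four affinely independent present landmarks are
   required; frames with fewer, or with a rank-deficient configuration,
   are marked invalid (their face landmarks set absent) rather than
   crashing. The shipped 13-point template is a synthetic configuration
   asset — any non-coplanar template works and detector-specific canonical
   faces can be supplied.
4. **Body normalization.** Pose coordinates are divided by the frame's
   Euclidean inter-shoulder distance, removing body-size and
   camera-distance scale. Frames missing a shoulder, or with an
   inter-shoulder distance at or below `distance_epsilon = 1e-9`
   (normalized units), are marked invalid.
5. **Displacement.** Movement is the frame-to-frame 3D Euclidean
   displacement per landmark over consecutive valid pairs (both endpoints
   present, passing QC, exactly one frame apart). Gaps are skipped, never
   interpolated — interpolation would fabricate motion. Displacements are
   averaged over time within each landmark first, then across the
   landmarks of a region; the natural log of the region mean is the
   modeling outcome. A region mean of exactly zero yields a missing log
   (with a warning), never $-\infty$.

Numerical decisions worth stating explicitly:

- **Window enumeration.** Sliding windows step by one frame, and a frame
  is excluded if *any* covering window violates — the conservative
  deterministic reading of segment-wise exclusion. Windows are truncated
  at *both* series edges to their actual length, so short prefixes and
  suffixes count as windows; near the edges this is deliberately strict
  (an isolated missing frame invalidates its immediate neighbourhood
  there). The test suite checks both masks against an exhaustive
  all-windows scan on series up to 200 frames, using the same enumeration
  written independently.
- **Averaging order.** Per-landmark temporal means are averaged across
  landmarks, rather than pooling all frame pairs; the two differ when
  landmarks have unequal valid-pair counts, and the chosen order keeps
  every landmark's contribution equal regardless of its missingness.
- Tightening either QC threshold can only shrink the valid set
  (monotonicity), and body summaries are invariant to global scaling
  while post-alignment face summaries are invariant to rigid motion —
  all three properties are under test.

## Semantic typicality

Answers to the 23 scripted interview questions arrive as D-dimensional
text embeddings (the study configuration used D = 768). The normative
reference for each question is the **component-wise median** embedding
over all non-missing answers from typically developing participants aged
14–22 (both the TD definition — an explicit all-negative indicator — and
the band are configurable). Raw embeddings are medianed without unit
normalization; cosine similarity handles scale at scoring time, and
typicality is invariant to positive rescaling of either vector.

Per-question typicality is the cosine similarity between an answer and its
question's reference. Missing answers score missing; a zero-norm answer
vector scores missing with a warning. Question scores are averaged into
conceptual domains over the *available* questions (a domain with all
questions missing is missing), and the Fisher-Z transform
$z = \operatorname{artanh}(s)$ is applied to the domain mean before
regression. Two open choices and their resolutions:

- **Transform order.** Domains average raw similarities, and Fisher-Z is
  applied to the domain mean — averaging happens on the similarity scale,
  the transform is a pre-regression variance-stabilization. The
  alternative (z-transforming per question, then averaging) is a
  one-line change in the chain if a user prefers it.
- **Domain membership.** Only the self-emotion domain's membership
  (questions 14, 17, 20, 23) is attested; the shipped map
  (`default_domains()`) completes the partition of 1–23 as a plausible
  placeholder and is user-overridable everywhere it is consumed.

Similarities are clipped to $[-1+\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-7}$ before artanh, capping $|z|$ at about 8.4 so that
exact-match answers have bounded leverage in regression instead of
infinite values. `select_typical_answer()` returns the participant whose
answer is closest to the reference (exhaustive argmax), breaking exact
ties deterministically by the smallest participant id.

## The synthetic cohort generator

The motivating recordings are available only under a data-use agreement,
so the package ships a generator whose defaults *are* the study
conditions, with stored ground truth for recovery testing:

- **Cohort** (`simulate_cohort()`, default n = 2341): age from a truncated
  normal (mean 10.1, SD 3.39, bounds 5–22), about one third female
  (785/2341). ADHD-Hyperactive status follows a logistic link in age (OR
  0.83 per year); Inattentive status is drawn conditionally on Hyperactive
  with rates implied by the observed presentation counts (so the Combined
  overlap is reproduced); ASD follows a logistic link on the two status
  flags with ORs 2.3 and 1.6. Intercepts are calibrated by root-finding so
  the configured *marginal* prevalences (1278, 718, 349 of 2341) hold
  exactly in the generative model, making the configured ORs the true
  generative parameters that `fit_logistic()` must recover. A configured
  fraction of no-status records carries the other/unspecified label
  (excluded), and a typically-developing indicator is set among
  all-negative records. IQ, clinical scale scores, and interview lengths
  are Gaussian with group shifts chosen to echo the published group means;
  they are descriptive filler, not recovery targets, except the
  hyperactivity trait score, which declines with age by construction.
- **Features** (`simulate_feature_table()`): each metric is
  $y = \sum_k b_k x_k^{(std)} + \varepsilon$ with standardized predictors
  and $\varepsilon \sim N(0, 1)$ by default, so the generative $b_k$ is
  (up to partial-correlation attenuation) exactly the effect size the
  model-fitting stage reports. This is the round-trip oracle behind the
  effect-size recovery tests, which demand agreement within ±0.05.
- **Landmarks** (`simulate_landmarks()`): each landmark is a mean-reverting
  AR(1) trajectory around its rest position with innovation SD
  $\text{step}\cdot\exp(\text{age-slope}(a - 10) + \text{hyper-step}\,h + u)$,
  $u$ a per-participant lognormal variability term (SD 0.3) — so log mean
  displacement is linear in age and hyperactive status by construction.
  Face landmarks additionally share a global head-pose translation that
  alignment must remove. Missing runs and high-variance jitter bursts are
  injected at configured rates and their locations stored, so the QC masks
  can be tested against known artifact positions. Defaults: 30 fps, 270 s
  (the mean interview length), face step 0.004 and pose step 0.0015
  normalized units — small enough that genuine motion stays under the
  jitter thresholds, which only the injected bursts should trip.
- **Embeddings** (`simulate_embeddings()`): per-question prototype vectors
  plus isotropic Gaussian noise whose scale falls with age and rises with
  ASD on narrative-type questions, so typicality decreases in the noise
  scale monotonically (under test over a 5-point grid) and the
  ASD/age structure propagates into the semantic domain scores.

What the generator does **not** emulate: real marginal distributions beyond
the configured moments, non-Gaussian embedding geometry, detector-specific
landmark error structure, linguistic content, or any audio/video. Passing
recovery tests therefore demonstrates that the analysis chain is correct
and calibrated under its own assumptions — not that those assumptions hold
in any particular recording set.

## Problem sizes and determinism

Everything is deterministic given `(config, seed)`. The test and
acceptance runs use deliberately scaled problem sizes chosen to exercise
each property with comfortable statistical margins: effect-size recovery
averages 50 cohorts of n = 2000; odds-ratio recovery 20 cohorts of
n = 5000; null calibration 1000 cohorts of n = 1000; the end-to-end
specificity run uses one cohort of n = 2000 with 6-second landmark series
(10 landmarks at 30 fps) and 32-dimensional embeddings; mask/oracle
equivalence uses 200-frame series. Embedding dimension and series length
only dilate these checks without changing what they establish, so the
smaller sizes are used throughout testing while the generator defaults
retain the study-scale values.

## Known limitations

- The robust fit's p-values use the t reference distribution with
  $n - p$ degrees of freedom; bootstrap alternatives are out of scope.
- Jitter thresholds distinguish only face vs pose landmark classes; hand
  landmarks are not modeled.
- The canonical face template and the non-attested domain memberships are
  configuration assets, not claims about any specific upstream detector
  or interview protocol.
- Anxiety-comorbidity sensitivity analyses are expressible by adding a
  binary predictor column to `predictors`, but are not separately
  implemented.
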