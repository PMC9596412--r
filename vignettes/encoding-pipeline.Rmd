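---
title: "Language-model metrics as fMRI encoders: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Language-model metrics as fMRI encoders: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surpsal)
```

## The problem

During naturalistic listening, the brain continuously predicts upcoming
words. Two quantities derived from an autoregressive language model index
different facets of that process: **surprisal**, the negative log
probability of the observed word given its context, indexes the magnitude
of the prediction error; **saliency**, a gradient-based attribution over
the context words, indexes how much each previous word contributed to the
prediction. This package implements the full chain that turns these
token-level quantities into a group-level statistical map over brain
regions, contrasting intelligible forward (FW) speech against its
time-reversed backward (BW) control — acoustically matched but stripped of
linguistic content.

## Sliding context windows

Every token is a prediction target once. Its context is every preceding
token whose onset lies in the half-open interval `[t - W, t)`, for window
lengths W of 15, 30, 45, 60, 75 and 90 s (15 s spans roughly one
hemodynamic event; 90 s spans paragraphs). Two conventions are deliberate
design choices, since either could be defended:

- membership is decided by token **onset**, not offset, and the target
  itself is excluded (half-open interval);
- windows are anchored at the target's onset minus W.

Targets earlier than W seconds into the narrative get a truncated context
(all available previous tokens) and are flagged `is_full = FALSE`; the
first token, with an empty context, yields NA surprisal and no saliency
vector under the default `truncate` policy (an `error` policy is
available). Contexts are nested across window lengths by construction, a
property the test suite verifies by brute force.

## Metrics

Surprisal uses base-10 logs: `-log10 P(token | context)`. Probabilities
are clamped at 1e-12 before the log — softmax outputs are strictly
positive, so the clamp matters only for distributions reconstructed from
truncated files.

Saliency is gradient × input with an L2 norm: for context token j,
`s_j = ||grad_j ⊙ x_j||₂`, then the vector is divided by its sum so the
weights form a probability vector over the context. The differentiated
score is the **pre-softmax logit** of the predicted token by default (the
common gradient-times-input convention); a log-probability variant is
exposed via `score = "logprob"`. An all-zero raw vector (degenerate
gradient) maps to uniform weights by default rather than an error.

Because one prediction produces a whole vector over its context, a second
step maps saliency back to single tokens before regressor construction:
`aggregate_received_saliency()` assigns each token the **mean** weight it
receives across all full-window predictions whose context contains it
(`mean_received`). This mapping is a configuration point, not a claim —
`sum_received` and `last_prediction` are provided as alternatives, and the
mean was chosen as the scale-stable default (it does not grow mechanically
with the number of containing windows). Only full-window predictions
enter, which is what makes the usable fMRI time range window-dependent.

## The toy language model and its oracle

Tests and simulations need a language model whose behavior is exactly
known. `toy_decay_lm()` pools context embeddings with exponential recency
weights, `g = Σ_j γ^(n-j) x_j`, and maps them linearly to logits `z = Ug`.
This gives closed forms for everything downstream: the gradient of logit c
with respect to context row j is `γ^(n-j) U_c`, and the unnormalized
saliency is `γ^(n-j) ||U_c ⊙ x_j||₂`. A central finite-difference oracle
(`finite_difference_gradient()`) verifies the analytic gradients on
random instances; comparisons use the matrix-level relative error
`max|G - G_fd| / max|G|`, because entries decaying like `γ^(n-j)` fall
below the cancellation noise of differencing an O(1) score long before
they stop being exactly representable analytically.

One behavioral caveat: with γ < 1 the toy model's effective memory is
~`1/(1-γ)` tokens (10 tokens at the default γ = 0.9), so contexts longer
than a 15-s window barely change its predictions. Per-window mean
surprisal on synthetic narratives is therefore nearly flat across window
lengths, and the context-size vs. surprisal correlation computed on
synthetic data is noise-dominated — unlike a transformer, whose
predictions keep improving (and whose uncertainty changes) with longer
real-text context. The correlation reported for the published per-window
table (r = 0.93) is a property of that table, reproduced exactly by
`tokens_vs_surprisal_correlation()`; the synthetic pipeline makes no claim
to reproduce it.

## From tokens to regressors

Token metric values become impulses at token onsets on a 0.1-s grid
(values of co-binned tokens add; NA values contribute nothing). Impulses —
not boxcars over word duration — because word duration enters separately
as a nuisance regressor and would otherwise be encoded twice. The grid is
convolved with a canonical double-gamma HRF (peak 6 s, undershoot 16 s,
undershoot/peak ratio 1/6, 32-s kernel, unit peak; all configurable via
`hrf_spec()`) and sampled at `t = k·TR`, TR = 1 s, for 709 volumes.

For the saliency analysis, the first `ceiling((W + buffer)/TR)` volumes
are dropped. With buffer = 11 s this yields 683, 668, 653, 638, 623, 608
retained volumes for W = 15…90 s — the buffer value is a calibration that
reproduces that published bookkeeping under TR = 1 s, exposed in the
configuration rather than hard-coded as truth.

The design matrix per subject/condition is intercept + metric of interest
+ WD + LF + WS, with non-intercept columns z-scored within the validity
mask. WD (word duration) and LF (log10 occurrences per million; the log is
a conventional scaling choice) go through the same event-to-HRF path; WS
(word sound) is a sampled envelope linearly interpolated onto the scan
grid. Rank deficiency after masking is an error, not a warning.

## The two-level GLM

"Mixed-effects group GLM" is implemented as the standard summary-statistics
two-level procedure: per-subject, per-condition OLS (via `lm.fit`), the
FW − BW difference of the interest beta per ROI, then a one-sample t test
across subjects (dof = S − 1) with Bonferroni correction over ROIs. The
default contrast is one-sided (FW > BW), matching the directional
hypothesis that linguistic predictors explain intelligible speech better;
two-sided is available. Both conditions are fitted as separate runs that
receive the same stimulus-derived regressors, which is what makes the
contrast well-defined for the meaningless BW condition. `n_comparisons`
defaults to the number of ROIs analyzed and can be pinned to 1000 when a
subset of a 1000-region parcellation is used. Optional AR(1) prewhitening
of the first level is available but off by default; the group-level t on
subject contrasts is already robust to first-level autocorrelation, which
the null-FWER study confirms empirically. Zero-variance ROIs yield a
sentinel t (0 if the mean is also 0, ±Inf otherwise, with a warning).

## The synthetic study

The generator's defaults are the emulated study conditions: 2512 tokens
(~63% full words, matching 1589/2512) over a 12-min narrative — a jittered
renewal process rescaled to the narrative span, giving ~52 context tokens
per 15-s window against the published 53.52 ± 7.2 — Zipf-distributed token
identities with internally consistent lexical frequencies, 27 subjects,
709 volumes at TR = 1 s, 100 ROIs (1000 under the `paper-scale` profile;
100 keeps simulation studies tractable on a desktop), AR(1) = 0.3 Gaussian
noise of unit sd, independent across ROIs, and effects of β = 1 (on the
z-scored regressor) planted in 5 designated ROIs of the FW runs only. The
word-sound effect (β = 0.5) is present in **both** conditions and all ROIs,
mirroring the logic that the reversed control preserves auditory
characteristics; since WS is a nuisance regressor, this does not touch the
contrast. The BW run carries no linguistic effect.

What the synthetic data do *not* emulate: spatial correlation between
ROIs, subject-level variability in effect size or HRF shape, scanner
drift, motion artifacts, and — per the toy-model caveat above — the
context-length dependence of a real transformer's uncertainty. Passing
tests therefore demonstrate the correctness and calibration of the
*procedure* (exact recovery without noise, nominal false-positive control,
high sensitivity at the planted effect size), not that real data would
yield any particular map.

## Numerical and testing choices

- Problem sizes: module tests run at toy scale (V ≤ 50, d ≤ 8, contexts
  ≤ 20 tokens); simulation studies use 200 null replicates and 5 planted
  full-pipeline runs at 27 subjects × 100 ROIs × 709 volumes, sizes chosen
  to give stable Monte-Carlo estimates (binomial SE ≈ 0.015 on the FWER)
  at desktop runtimes.
- Saliency vectors are validated to sum to 1 within 1e-9; closed-form
  agreement is required to 1e-10; noiseless GLM recovery to 1e-8
  (normal-equations accuracy); finite-difference gradient agreement to
  1e-4 at step 1e-5.
- Determinism: every simulated artifact is a pure function of the
  `sim_config` including its seed; stage seeds are derived by fixed
  offsets so transcript, model, envelope and noise draws do not interact.
- Errors carry stable kebab-case codes (`oov-token`,
  `unsorted-transcript`, `collinear-design`, …) as condition classes.

## Limitations

The saliency-to-predictor mapping is an explicit configuration point, not
an inferred ground truth. The HRF is fixed across subjects and ROIs. The
toy model's recency decay is a caricature of attention. The 11-s masking
buffer is a calibration. None of these affect the package's guarantees on
synthetic data, but all of them matter when attaching a real language
model (via the three-generic adapter contract) and real BOLD series.
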