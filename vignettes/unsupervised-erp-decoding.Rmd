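---
title: "Unsupervised decoding of auditory ERP spellers: model, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised decoding of auditory ERP spellers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zerotrainbci)
```

## The decoding problem

An auditory ERP speller presents six spatial tones in rapid sequence (stimulus
onset asynchrony 175 ms). The user attends one of the six; a trial consists
of 15 pseudo-randomized iterations of all six tones (90 presentations,
15.75 s). Attended ("target") tones evoke event-related potentials that
differ from unattended ("non-target") tones, and one trial yields a
one-out-of-six decision. Two trials spell one of 36 symbols: the first picks
a group of six symbols, the second a symbol within the group.

The conventional decoder is a supervised classifier trained on a labeled
calibration recording. This package implements the alternative this family
of methods exists for: a decoder that starts from random weights and learns
**without labels**, during usage, from the structure of the paradigm itself.

## The probabilistic model

For epoch $x \in \mathbb{R}^{D+1}$ (interval-mean features plus a constant
bias feature) the model assumes the one-dimensional projection $w^\top x$ is
Gaussian with precision $\lambda$ and a class-dependent mean: $\mu_t$ when
the presented stimulus equals the latent attended stimulus $c$ of the trial,
$\mu_{nt}$ otherwise. The latent $c$ is uniform over the $K = 6$ stimuli,
and $w$ carries a zero-mean isotropic Gaussian prior with precision $\beta$.
Given a trial's feature matrix $X_t$ and presented-stimulus sequence, Bayes's
rule yields a posterior over the six hypotheses; the argmax is the decoded
selection. Working at the level of the attended stimulus — rather than
labeling the 90 epochs independently — shrinks the labeling search from
$2^{90}$ possibilities to 6, which is what makes unsupervised learning
feasible at single-trial SNR.

The class projection means are fixed at $\mu_t = +1$, $\mu_{nt} = -1$
(configurable). With these targets the weight update below coincides with a
ridge regression onto $\pm 1$ labels, which is also why a supervised LDA-like
solution is recoverable in the hard-label limit.

## Training by expectation maximization

All stored trials are refit after every new trial, for
`em_iter = 5` iterations per classifier:

* **E step** — posterior $P(c \mid X_t, w, \lambda)$ for every stored trial,
  computed in log-space with max subtraction.
* **M step, weights** — $w = (X X^\top + (\beta/\lambda) I)^{-1} X \bar y$,
  where $\bar y$ assigns each epoch the posterior expectation of its class
  mean. Under one-hot posteriors this is exactly the ridge solution for the
  implied hard labels; in general it is the posterior-probability-weighted
  sum of all labelings' ridge classifiers.
* **M step, lambda** — inverse of the expected mean squared error between
  projections and class means, floored at `lambda_floor = 1e-10` to avoid
  infinite precision on degenerate exact fits (the analogue, for $\lambda$,
  of the collapse guard the procedure applies to $\beta$).
* **M step, beta** — inverse of the mean squared weight, capped at
  `beta_cap = 200` so the classifier cannot collapse onto the all-zero
  weight vector.

We re-estimate $\beta$ inside every EM iteration (the alternative — once per
trial — was also open; per-iteration re-estimation reads the update equations
as one joint cycle and converged indistinguishably in our synthetic runs).

### What is (and is not) monotone

The quantity every update provably increases is the penalized objective
$\log p(X \mid w, \lambda) + \log \mathcal N(w \mid 0, \beta^{-1} I)$: the
$w$ update is its exact maximizer given the E-step posteriors, the $\lambda$
update its exact maximizer given $w$, and the $\beta$ update (inverse mean
squared weight) its exact maximizer in $\beta$ — the cap and floor only clip
a concave coordinate ascent toward its optimum, so monotonicity survives
them. The bare data log-likelihood — the quantity used for classifier
*selection* — is **not** guaranteed monotone under these updates, because
$w$ is regularized and $\beta$ re-estimated; in practice we observe
occasional dips of order $10^{-3}$ on objective values of order $10^3$.
`em_iterations(trace = TRUE)` records both trajectories
(`objective_trace`, `loglik_trace`); the test suite asserts per-step
monotonicity (tolerance $10^{-6}$) of the objective.

## Sign-flipped classifier pairs

Nothing anchors an unsupervised fit to the correct polarity: a classifier
that swaps target and non-target labels explains the data exactly as well at
the epoch level, but not at the trial-marginal level. The package therefore
initializes `n_pairs = 5` pairs; each pair starts at $+w_0$ and $-w_0$ with
$w_0$ drawn from an isotropic Gaussian (sd $1/\sqrt{D+1}$, so initial
projections have roughly unit scale; the concrete draw scale was an open
choice and is configurable). All ten classifiers are EM-updated after every
trial; the prediction comes from the classifier with the highest data
log-likelihood over all stored trials (ties break to the lowest pair index;
an expected-squared-error criterion is available behind
`bci_config(selection = "mse")`). After the prediction, the weaker member of
each pair is re-initialized with the negated weights of the stronger one;
$\lambda$ and $\beta$ are copied from the kept member so the pair remains a
sign reflection of a single model (the procedure fixes only the weight
negation; copying keeps the pair coupled, re-initializing to the global
defaults would decouple it).

Online predictions are final. The *posthoc* re-analysis re-classifies every
stored trial with the currently best classifier and may revise early,
warm-up-period mistakes; it can run after every trial (a live third-line
display) or once at block end.

## The synthetic study conditions

No recordings ship with the package; a generator stands in for them so every
claim is testable. It emulates:

* the trial structure above (6 stimuli x 15 iterations, SOA 175 ms, 30
  trials per block);
* 31 channels at 100 Hz, epoch window $[-200, 700)$ ms;
* a class difference with a fronto-central negativity (half-sine over
  100–200 ms, peak 150 ms, negative) and a centro-parietal positivity
  (half-sine over 250–600 ms), on top of a small class-shared exogenous
  response;
* structured noise: per-channel AR(1) with coefficient 0.8 (EEG-like
  autocorrelation; white noise available for analytic checks), optional
  spatial covariance, optional slow drift, optional high-variance artifact
  epochs for testing the rejection rule.

The class-difference amplitude defaults to 0.35 noise-SD units. The source
study reports no amplitude or SNR figures for its auditory ERPs, so this
default is a declared calibration: it was chosen (once, from a sweep of
{0.25, 0.30, 0.35} over ten seeds) as the mid-margin setting at which a
30-trial block reproduces the qualitative regime the method is known for —
near-chance early trials, $\ge 0.9$ median accuracy over trials 21–30,
posthoc recovery of $\ge 80\%$ of the block in $\ge 80\%$ of seeds, and a
supervised baseline near ceiling.

What the generator does **not** emulate: volume-conducted channel mixing
from real sources, eye/muscle artifacts with realistic topographies,
inter-subject variability of component latency, overlap of consecutive
epochs at 175 ms SOA (epochs are drawn independently), or fatigue-driven
non-stationarity beyond a linear drift option. Passing tests therefore
demonstrate correctness of the algorithms under controlled conditions, not
performance on real EEG.

## Preprocessing

The online chain is strictly causal: a forward-only order-5 Chebyshev
type-2 low-pass (20 dB stop-band, 40 Hz edge) for continuous data, epoching
to $[-200, 700)$ ms, per-channel baseline subtraction over $[-200, 0)$ ms,
12 interval means per channel (intervals `[100 130] ... [600 700]` ms,
half-open sample selection, features concatenated channel-major: 372
features at 31 channels), then — for the unsupervised path only — per-trial
feature-wise standardization and a constant bias feature (373rd). The
variance-based outlier rule (reject epochs above 2.5 x the 90th-percentile
epoch variance, linear-interpolation percentile, pooled channel-sample
variance with a per-channel-max option) applies to labeled calibration data
only; online, all epochs are kept. The generator emits 100 Hz epochs
directly, so the acquisition chain (1 kHz recording, hardware band-pass,
45 Hz low-pass, downsampling) is treated as upstream of the package. The
acausal 0.5–20 Hz forward-backward band-pass exists only on the
visualization path (`ssauc_map`).

## The supervised baseline

Binary LDA on un-normalized, bias-free features (per-trial normalization and
the bias term exist for the unsupervised model's benefit; a matched-
preprocessing ablation is a config switch away): pooled class-centered
covariance shrunk toward the scaled identity ($\nu$ = mean eigenvalue) with
the analytically estimated Ledoit–Wolf intensity, $w = \Sigma^{-1}(m_t -
m_{nt})$, bias centered between class means. A trial is decoded by summing
epoch decision values per stimulus (with equal epoch counts, summing equals
averaging) and taking the argmax, ties to the lowest id. The model is
trained once on an outlier-rejected calibration block and never adapted.

## Evaluation harnesses

`run_block_protocol` reproduces the online study design: a calibration block
trains the LDA once; evaluation blocks alternate methods; the unsupervised
pool is re-initialized before each of its blocks (the "hard" condition that
makes every block show a fresh warm-up); posthoc trajectories are recorded
after every trial. `run_extended_simulation` concatenates all blocks into
one long session with a single pool initialization, mirroring the
time-extended re-analysis: 180 trials make 18 sub-blocks of 10 trials (5
symbols), and `subblock_ttests` compares methods across simulated subjects
with two-sided paired t-tests at $\alpha = 0.05$, deliberately without
multiple-testing correction, matching the original reporting convention.
"Subjects" are independent generator seeds; a subject-specific amplitude
range reproduces between-subject variability without claiming realism.

Metrics: trial-wise selection accuracy; symbol accuracy (both trials of a
pair correct; a both-wrong pair renders the feedback sentinel `°`);
time-to-control (first trial of the first run of three consecutive correct
selections — the chance probability of such a run is $(1/6)^3$); and
signed scaled AUC maps, $\mathrm{ssAUC} = 2\,\mathrm{AUC} - 1$ per channel
and interval with midrank (Mann–Whitney) AUC.

## Numerical and design choices

* Posteriors and marginals in log-space with max subtraction; the marginal
  data log-likelihood per trial is a log-sum-exp over the 6 hypotheses under
  the uniform prior.
* The Gram matrix of stored features is accumulated incrementally and
  eigendecomposed once per online step; all ten classifiers' ridge solves
  reuse the decomposition.
* Argmax ties (prediction and selection) break to the lowest index —
  documented, deterministic.
* All randomness flows from one session seed through named substreams
  (`sub_seed`), so any run is replayable from `(config, seed)`.
* The original online implementation contained a documented error in the
  Gaussian log-density constant ($-\tfrac14$ instead of $-\tfrac12$ times
  $\log(2\pi\sigma)$). The package implements the correct constant;
  `bci_config(bug_compat = TRUE)` reproduces the erroneous one for
  replication studies. The constant cancels from per-trial posteriors and
  only shifts marginal likelihoods by a per-epoch constant, which is why it
  did not affect the original results.
* Pseudo-randomization draws an independent uniform permutation per
  iteration block; no constraint is imposed at block seams (none is
  specified for the paradigm), but `generate_sequence(permute_hook = )`
  exposes the hook for stricter schedules.

## Problem sizes used by the shipped tests

The test suite and acceptance script run entirely on synthetic data at
sizes chosen to exercise the stated properties: 30-trial blocks at the full
31-channel dimensionality for the chance-level (30 seeds), EM-monotonicity
(20 seeds) and warm-up/recovery (10 seeds) suites; 6 x 30-trial sessions for
the extended-duration harness; and 3-5 seeds for the acceptance script's
summary statistics. Unit tests of the decoder mathematics use small
constructed instances where closed-form oracles exist.

## Known limitations

* Synthetic-only validation; real-data performance claims are out of scope.
* The generator's epochs do not overlap in time, unlike real 175 ms SOA
  recordings; the preprocessing chain would handle overlap, the generator
  just does not produce it.
* The refit-everything-after-every-trial schedule is faithful but
  quadratic in session length; very long sessions would want incremental
  refitting (only the Gram matrix is currently incremental).
* Language-model priors over symbols and transfer-learning initialization
  are hooks only (the prior over the attended stimulus is a parameter;
  non-uniform priors are accepted but no language model ships).
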