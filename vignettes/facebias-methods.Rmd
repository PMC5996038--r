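---
title: "Models and methods behind facebias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind facebias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facebias)
```

`facebias` simulates and analyses a two-alternative anger/fear
categorisation experiment in which three kinds of face–emotion
associations bias observers' decisions: *shared* associations (common to
all observers, carried by facial morphology), *idiosyncratic* associations
(stable but unique to each observer) and *induced* associations (arbitrary
face–emotion pairings created by a short induction period at the start of
each block). This vignette documents the generative model, the estimators,
the numerical choices, and what the test suite does and does not establish
about real data.

## The experimental design

The default `study_design()` is 31 participants, 32 face identities and 8
blocks. Faces are split into two sets of 16; each set is used for four
consecutive blocks. A block opens with 48 induction trials (its 16 faces,
3 repetitions each, always at the maximal morph level 7, each face
expressing only its induced emotion) followed by 112 test trials: per face
and block set, every (emotion, level 1–6) combination twice plus four
neutral presentations, i.e. 28 test trials per face distributed 7 per
block. The per-level composition of the test period is a design choice of
this package — only the totals (112 test trials, levels 1–6 of both
emotions plus neutral, balanced per face) are externally constrained, and
the doubly-balanced scheme is the simplest one meeting them. Induced
labels are drawn 8/8 within each face set (hence 16/16 overall) per
participant, independently across participants.

Evidence is coded linearly and symmetrically: morph level $\ell$ of anger
maps to $x = +\ell/6$, of fear to $x = -\ell/6$, neutral to $0$. Induction
trials (level 7) sit just outside the test range at $|x| = 7/6$. No lapse
or non-response process is modelled: simulated observers always respond
within the deadline, and analysis functions drop any `none` responses they
might meet in imported data.

## The generative observer

An observer cohort is parameterised by shared face values
$s_i \sim \mathcal N(0, \sigma_s^2)$ (one per face, common to everyone)
and idiosyncratic values $\varepsilon_{ij} \sim \mathcal N(0, \sigma_e^2)$
(participant × face), centered per face across participants so the
shared/idiosyncratic split is exact by construction. Responses follow the
probit decision model

$$P(\text{anger}) = \Phi\!\big(w x + b + \beta_s a_s + \beta_i a_i +
\beta_n a_n\big),$$

where the $a$'s are ±1 labels derived from the signs of $s_i$,
$\varepsilon_{ij}$ and the induced assignment. Defaults are $w = 1.5$,
$b = 0$, $\beta_s = 0.35$, $\beta_i = 0.25$, $\beta_n = 0.08$,
$\sigma_s = \sigma_e = 1$: a sensitivity that yields roughly
75–80 % test accuracy and ~95 % induction accuracy, shared and
idiosyncratic criterion shifts of similar, substantial size, and an
induced shift an order of magnitude weaker — the qualitative ordering the
paradigm is designed to expose.

Post-test ratings load on the shared and idiosyncratic components only,

$$r_{ij} = \mathrm{squash}\big(g_s s_i + g_i \varepsilon_{ij} +
\eta_{ij}\big), \qquad \eta \sim \mathcal N(0, \sigma_r^2),$$

with `squash` a clipped identity onto the signed rating scale $[-1, 1]$
(the physical scale of the rating screen is arbitrary; a fixed internal
scale keeps the estimators unit-free). The induced assignment never enters
the ratings, so the mutual information between ratings and induced labels
is zero by construction — the basis of the null checks below. Defaults
$g_s = 0.5$, $g_i = 0.3$, $\sigma_r = 0.2$ give a strong but imperfect
rating consensus (leave-one-out slopes near 1 with clear spread).
Attribute ratings (dominance, trustworthiness) load on $s$ with gains
$+1$ and $-0.8$ and noise SD 1.5, which produces moderate correlations
(|r| around 0.5) of the size typical for trait-rating consensus data.

Every sampling stage takes its own seed; `derive_seeds()` spawns the named
per-stage seeds from one master seed so that any stage can be reproduced
in isolation.

## Leave-one-out decomposition and labelling

For participant $j$, their per-face values $v_{ij}$ (post-test ratings in
the behavioural arm; per-face decision biases in the EEG arm) are
regressed, without intercept, on the mean of everyone else:

$$v_{ij} = \beta_j\, m_{ij} + \varepsilon_{ij}, \qquad
m_{ij} = \tfrac{1}{N-1}\textstyle\sum_{k \ne j} v_{ik}.$$

Values are mean-centered per participant first, so the no-intercept form
is well-behaved; the regression slope measures consensus, the regressor
is the shared component and the OLS residual the idiosyncratic one —
orthogonal within participant by construction (asserted to 1e-8 in the
tests). Faces are labelled *shared anger* when $m_{ij}$ strictly exceeds
its per-participant median (ties fall to fear, the "otherwise" branch) and
*idiosyncratic anger* when $\varepsilon_{ij} > 0$. Two prose descriptions
of the idiosyncratic rule circulate — a median split of the residuals and
the explicit $\varepsilon > 0$ rule; they coincide only when the residual
median is zero, so the package implements the explicit sign rule and
reports the residual median as a diagnostic attribute. Whether inputs
should be normalised per participant before the regression is not
externally fixed; mean-centering (no variance scaling) is used, and the
label-invariance test shows any common positive affine rescaling leaves
all labels unchanged.

For the EEG arm, per-face decision biases come from a joint
maximum-likelihood probit fit per participant,
$P(\text{anger}) = \Phi(w x + b_i)$ with one shared slope and one
intercept per face, bounded $w \in [0, 20]$, $|b_i| \le 5$ (biases landing
on a bound are flagged). The problem is convex, so a single bounded
quasi-Newton run suffices; tests cross-check the estimates against
`glm(..., binomial(probit))` to ~1e-3.

## The psychometric model family and its selection

`psych_model()` spans the family: the base model $\Phi(wx+b)$; *bias*
variants adding $\beta_k a_k$ (criterion shifts, maximal effect at
neutral); *sensitivity* variants adding $\gamma_k c_k x$ with congruence
$c_k = a_k\,\mathrm{sign}(x)$ (zero at neutral, maximal at intermediate
evidence — the coding that makes "increased sensitivity to the congruent
emotion" well-defined); and the full three-way additive bias model.
Labels are coded ±1 rather than 0/1 so $\beta$ is a symmetric criterion
shift in the signal-detection sense.

Fits minimise the Bernoulli negative log-likelihood with analytic
gradients under L-BFGS-B (`factr = 1e7`, i.e. ~1e-9 relative tolerance)
from five jittered starts; probabilities are clipped to
$[10^{-9}, 1-10^{-9}]$. Bounds are $w \in [0,20]$, $|b|, |\beta|,
|\gamma| \le 5$ — box constraints chosen for identifiability and numerical
safety; the box on $\gamma$ (rather than the tighter coupling
$|\gamma| \le w$) keeps the optimiser in standard form, and the clipping
makes a transiently negative effective slope at extreme evidence harmless.

Model evidence is the 10-fold cross-validated log-likelihood: folds are
stratified by displayed emotion × face (so every training set sees every
face), shared across models, and the summed held-out log-likelihood
implicitly penalises complexity. Setting $k$ to the trial count reduces
the procedure to leave-one-out, which the tests verify against brute-force
per-trial GLM refits. Group-level selection is reported both ways:
fixed-effects $\log_{10}$ Bayes factors (summed evidence differences) and
random-effects Bayesian model selection — variational updates
$u_{nk} \propto \exp(\mathrm{ev}_{nk} + \psi(\alpha_k) - \psi(\sum
\alpha))$, $\alpha = \alpha_0 + \sum_n u_n$, uniform Dirichlet prior
$\alpha_0 = 1$, convergence at $\Delta\alpha < 10^{-6}$ — with plain
(unprotected) exceedance probabilities from $10^6$ seeded Dirichlet draws;
the $K = 2$ case is verified against the incomplete-beta closed form.

## Group statistics

One-sample and paired t-tests are classical (`stats::t.test`), two-sided.
The 2×2 repeated-measures interaction is computed as the paired t-test on
the difference-of-differences contrast with $F = t^2$,
$\mathrm{df} = (1, n-1)$ — an algebraic identity for a single-df
interaction, asserted exactly in the tests. The Bayes factor quantifying
evidence *for* a null difference is the JZS/Cauchy default
($\delta \sim \mathrm{Cauchy}(0, \sqrt2/2)$), computed by integrating the
noncentral-t likelihood over the prior and cross-checked against the
Zellner–Siow mixture-of-g quadrature; the exact prior scale used in any
particular published analysis is generally unknowable, so no acceptance
value is pinned to it. Pearson correlations use `stats::cor.test`.

## The EEG forward model and encoding analyses

Synthetic epochs are built additively: each encoding entry contributes
`amplitude × kernel(t) × weight(channel) × covariate(trial)` on top of
white Gaussian noise (default SD 2 a.u. per sample against unit
amplitudes — after averaging the nine centro-parietal channels and
regressing over ~400–900 trials, single-subject beta SNR comfortably
exceeds 5). The kernel is zero before its onset, rises as a half-cosine
to its peak and decays back over 150 ms. The default rise time is 20 ms:
the onset estimator below reads the half-maximum crossing, which for this
kernel sits at onset + rise/2, so a short rise keeps the estimator within
one sample of the true onset — the kernel family was chosen precisely for
its unambiguous onset. Defaults place a shared-association component at
270 ms and an emotion-strength component at 390 ms, sampled at 100 Hz
over −0.1–0.8 s. Artefacts (blinks, drift) and realistic spatial mixing
are deliberately out of scope.

Encoding regressions average the nine centro-parietal channels
(CP1/CP2/CPZ/P1/P2/PZ/PO1/PO2/POZ) first and fit one OLS per timepoint
across trials, all covariates simultaneously with an intercept;
covariates are z-scored per subject (comparable betas across subjects)
except the fixed ±1 congruence regressors, and covariate pairs with
|r| > 0.99 abort the fit. Group inference over time uses cluster-based
permutation: pointwise one-sample t-tests, cluster-forming threshold
two-sided p < 0.05, clusters scored by summed |t|, and a null of 1000
seeded whole-subject sign flips scored by maximal cluster mass. The
calibration test drives the procedure with 500 pure-noise group datasets
(24 subjects, 40 samples, 500 flips each) and requires the family-wise
error to land in [0.03, 0.07].

Onset latencies are read from grand-average time courses as the first
crossing of 50 % of the peak, linearly interpolated between the
bracketing samples (the sub-sample version of the first-sample-above
rule). Differences are tested with the jackknife: latencies re-estimated
on each leave-one-subject-out average, the t statistic over those
estimates divided by $n-1$ to undo the variance shrinkage the jackknife
induces, referred to $t_{n-1}$. The congruence analyses regress the
signal on three ±1 regressors — response congruent/incongruent with the
shared association, the idiosyncratic association, and the participant's
overall response tendency — read out at the sample nearest 500 ms, with
no window averaging.

## Problem sizes and determinism

The test suite exercises the full default design (31 × 32 × 8) where the
check is about design structure, and scaled-down cohorts (4–10
participants, 4–24 EEG subjects, 200–400 trials) where the check is about
estimator behaviour; parameter-recovery suites use $10^4$–$10^5$ trials
and 10–20 Monte-Carlo replicates. These sizes were chosen so the whole
suite and the acceptance script each run in minutes on one core while
keeping Monte-Carlo error far below the tolerances asserted. All
randomness flows from explicit seeds; `run_all()` is bit-reproducible
given its master seed.

## What the tests do and do not show

Passing tests establish that the estimators invert the package's own
generative model: decomposition orthogonality and exactness, probit
parameter recovery, model selection picking the generating model, null
AUCs at chance, cluster-test calibration against Gaussian noise, and
latency recovery under the raised-cosine forward model. They do not
establish anything about real observers: actual rating scales are
bounded and discrete rather than clipped-Gaussian, real EEG noise is
autocorrelated and spatially structured, real criterion shifts need not
be additive or stationary, and the true shared/idiosyncratic split may
not be linear in a group mean. The generator is a testbed for the
analysis pipeline, not a cognitive model of the phenomena themselves.

Known limitations: no lapse-rate or logistic-link variants, no
hierarchical (group-level) fitting, no protected exceedance probabilities
or Bayesian omnibus risk, and cluster correction runs over time only, not
over the scalp.
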