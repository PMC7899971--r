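---
title: "Diagnosing skills and modeling written answers: the methods behind masterytopics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing skills and modeling written answers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`masterytopics` analyzes mixed-format assessments in two linked stages: a
diagnostic classification of examinees' skills from scored items, and a
covariate-aware topic model of their written answers. This vignette
documents the models, the estimation algorithms, the tunable parameters,
the synthetic-data generator, and the numerical and design choices a
maintainer should know about.

## Stage 1: the log-linear cognitive diagnosis model

Each examinee carries a binary mastery profile $\alpha_i \in \{0,1\}^S$
over $S$ skills. A Q-matrix declares which skills each item measures, and
the response probability is logistic in an intercept, non-negative main
effects for the item's flagged skills, and interactions among them:

$$P(Y_{ij}=1 \mid \alpha_i) = \mathrm{logit}^{-1}\Big(\lambda_{j0} +
\textstyle\sum_s \lambda_{js}\,\alpha_{is} q_{js} +
\sum_{s<u} \lambda_{jsu}\,\alpha_{is}\alpha_{iu} q_{js} q_{ju}\Big).$$

`build_effect_structure()` enumerates the admissible terms (all subsets of
an item's flagged skills up to `max_order`, default 2).

**Estimation.** `fit_lcdm()` maximizes the marginal likelihood by EM. The
E step computes each examinee's posterior over the $2^S$ profiles
(response patterns are collapsed first, so cost grows with distinct
patterns, not examinees). The M step updates the saturated profile
distribution in closed form and each item's parameters by L-BFGS-B on the
expected complete-data log-likelihood with a weak ridge ($10^{-3}$, which
keeps degenerate items finite without visibly moving interior optima).
Monotonicity is enforced as in the LCDM convention: main effects are
bounded below at zero, and if an interaction estimate violates the
requirement that gaining any skill never lowers the success probability,
the item is re-maximized under the full linear constraints
(`constrOptim`). Parameters are clamped to $|\lambda| \le 15$; an item is
flagged as a boundary case when a parameter reaches the clamp or a fitted
cell probability saturates beyond $5\times10^{-4}$ of 0 or 1. The EM stops
when the relative log-likelihood change falls below `tol` (default
$10^{-6}$; recovery studies in the tests use $10^{-8}$). The observed-data
log-likelihood is asserted monotone at every iteration.

**Standard errors** come from the numerically computed observed
information of the marginal log-likelihood, jointly over item parameters
and multinomial-logit structural parameters. `wald_tests_and_prune()`
tests each interaction ($z = \hat\lambda/\mathrm{SE}$), drops the least
significant non-significant interaction (highest order first), refits, and
repeats — the backward analogue of testing compensatory structure term by
term. The pruning level defaults to $\alpha = 0.05$; the table also flags
significance at 0.01.

**Classification and summaries.** `classify_examinees()` returns modal
profiles (ties broken toward the lowest profile index, with a warning) and
EAP marginal mastery. Marginal mastery proportions are reported both ways;
the EAP version is the default headline number because modal shares are a
coarsened, threshold-dependent statistic. Attribute correlations implied
by the structural distribution are computed two ways: phi (Pearson on the
binary margins) and tetrachoric (a latent bivariate-normal whose quadrant
probability matches the structural 2×2 cells, solved by quadrature and
root-finding). Tetrachoric is the default report since observed high
skill correlations in this literature are latent-scale quantities.
`attribute_reliability()` is the expected agreement of two independent
classifications drawn from each examinee's marginal posterior, rescaled
from [0.5, 1] to [0, 1]; it is a documented stand-in, since published
"skill reliability" values of this kind rarely state their estimator, and
values near 0 simply mean the items barely update the prior for that
skill.

## Text preprocessing

`tokenize_and_normalize()` lowercases, splits on non-alphabetic
characters, drops single-letter tokens, removes stopwords, and stems with
an in-package implementation of the Porter (1980) algorithm. The stopword
list is vendored (a fixed Snowball-style list) so preprocessing cannot
drift with external resources. Manual typo correction and tense
normalization, which human analysts sometimes apply, are deliberately out
of scope: a fixed algorithmic stemmer is reproducible, at the cost of
stems like "poni" for "ponies".

`build_dtm()` applies the exclusion rules in order: rubric-score-0
documents first (non-scorable answers), then words with corpus frequency
below `min_word_freq` (default 10), then documents with fewer than
`min_doc_length` (default 15) post-filter tokens. Because dropping short
documents can push word frequencies back under the threshold, the two
count filters alternate to a fixed point, which makes the operation
idempotent. Every excluded document is recorded in a ledger with the rule
that removed it, and input count = kept + excluded always holds. Whether
the frequency rule means corpus or document frequency is genuinely
ambiguous in practice; corpus frequency is the default, with
`freq_mode = "document"` available.

## Stage 2: the structural topic model

Documents draw $K-1$ free logits $\eta_d \sim N(X_d\gamma, \Sigma)$, with
topic $K$ as the reference (logit 0) — the standard identifiable
parameterization — then $\theta_d = \mathrm{softmax}(\eta_d, 0)$, and each
token draws a topic from $\theta_d$ and a word from that topic's
distribution $\beta_k$. The prevalence design $X_d$ is an intercept plus
the stage-1 mastery indicators (modal 0/1 by default; EAP probabilities
behind `covariate_mode = "eap"`).

**Inference** is the Laplace variational EM of the STM literature. Per
document the posterior of $\eta_d$ is approximated by a Gaussian at its
mode; the mode is found by damped Newton iteration with analytic gradient
and Hessian, vectorized across documents (all word-sum quantities are
$D \times V$ matrix products; only the small $(K-1)$-dimensional solves
loop over documents). Two numerical guards matter:

* logits are recentred when their row maximum exceeds 30 (overflow);
* each document's Laplace precision is floored at the prior's smallest
  precision, so the Laplace variance never exceeds the prior scale. This
  is exact when the word log-likelihood is concave, and it prevents a
  destructive feedback in which one ill-conditioned document inflates the
  $\Sigma$ update, which loosens every prior, which makes more documents
  ill-conditioned.

The M step is ridge-penalized least squares for $\gamma$ (prior variance
$\sigma_k^2 = 25$ per coefficient, diffuse, configurable — external
defaults used by other software are not reproducible from the outside, so
the package fixes its own documented prior), the mean of Laplace
covariances plus residual outer products for $\Sigma$, and
responsibility-weighted counts with a $1/V$ pseudocount for $\beta$.
Initialization is seeded random noise scaled by corpus word frequencies
(default; a k-means-on-documents init is available, but in recovery
experiments the random init escaped document-cluster local optima more
reliably, because document clusters align with covariate groups rather
than topics when documents are genuine topic mixtures). Convergence is
declared on the relative change of the approximate objective (sum of
per-document Laplace evidence terms) below `tol` = $10^{-5}$ within
`max_iter` = 500; the bound trace is exposed rather than asserted
monotone, since the Laplace objective is an approximation.

**Covariate effects on the proportion scale.** `estimate_effects()` uses
the method of composition: per draw, sample each $\eta_d$ from its Laplace
posterior, map to $\theta$, and regress each topic's $\theta$ on $X$ by
OLS. Estimates are means over draws; squared SEs add the between-draw
variance and the mean within-draw OLS variance; $t$ uses
$df = D - \text{terms}$. Reporting on the proportion scale makes a
coefficient read directly as "mastering the skill changes expected topic
use by this much", and the estimates close over the simplex: intercepts
sum to 1 across topics and covariate effects sum to 0, before any
clipping in `predicted_topic_use()`.

**Topic-count selection.** `search_k()` fits one model per candidate $K$
(same data, design, seed) and tabulates mean semantic coherence (top-$M$
co-occurrence score, always $\le 0$), mean FREX exclusivity (harmonic
blend, weight 0.7, of within-topic ECDF ranks of the word's
topic-share and frequency, averaged over the top $M = 10$ words), and mean
pairwise cosine similarity between $\beta$ rows (lower = more distinct).
$M$ and the FREX weight follow the metric literature's conventions and are
configurable. No winner is chosen automatically: the table flags the
coherence/exclusivity Pareto front, and among front members the cosine
minimizer — the judgment call the selection mimics — as `pick`.

## The synthetic-data generator

`default_sim_config()` emulates the assessment the package was built
around: 2,323 examinees; three reading skills (Idea, Structure,
Integration) with profile probabilities (.139, .127, .063, .671) on
profiles 000, 001, 101, 111 and zero elsewhere, so only four of eight
profiles are populated; the published 4-item Q-matrix with reported item
parameters (non-significant intercepts set to 0, interaction dropped as in
the final published model); $K = 4$ topics over 300 tokenizer-stable
pseudo-words; negative-binomial answer lengths with mean 128.3 and SD 76.4
truncated at 15 ($\mathrm{size} = 2.883$ matches that mean/SD pair); and
215 score-0 documents so 2,108 survive preprocessing. Prevalence
coefficients are chosen on the logit scale so the implied proportion-scale
effects match the reported covariate-effect magnitudes (integration
mastery: about +0.07 on the integrative topic and −0.15 on the everyday
topic). The logit covariance is compound-symmetric,
$\Sigma = \sigma^2(I + \mathbf{1}\mathbf{1}')$ with $\sigma^2 = 0.5$:
equivalent to i.i.d. noise on all $K$ topic logits before fixing the
reference, so every pairwise log-ratio — including against the reference
topic — has the same unit variance. (A diagonal $\Sigma$ would make the
reference topic systematically less dispersed, and therefore
systematically harder to recover, an asymmetry that is a simulation
artifact rather than a feature of real essays.) The $\sigma^2$ value
reproduces the wide within-group spread of observed topic proportions,
where individual answers range from near-zero to majority use of a topic.

Rubric scores are a monotone noisy function of the document's true
integrative-topic proportion (rank mapped to 1–7 with Gaussian noise, SD
0.9), which reproduces the qualitative pattern that heavier integrative
borrowing accompanies higher scores; the exact functional form is a free
choice. Topic-word distributions give each topic a block of anchor words
with Zipf-like weights (75% of mass) plus a shared block (25%), mimicking
prompt-specific vocabulary shared across answer styles. One integer seed
drives deterministic sub-streams per component, so partial reruns
reproduce exactly.

`recovery_sim_config()` is the design used for parameter-recovery checks,
and deliberately differs from the study-scale config: 8 items with at
least two single-attribute items per skill, strongly discriminating main
effects (3.8–4.2, near the top magnitudes seen in operational
calibrations) so classification is sharp, two-attribute items whose cell
probabilities all stay within 0.1–0.9 so interaction terms are
informative, and a profile distribution giving every profile positive
mass. The study-scale design itself cannot support recovery of all
parameters: with four items a single skill is measured by one weak main
effect, and with half the profiles empty the interaction cells never
occur, so those parameters are unidentified — the same reason the
operational analysis reported low skill reliabilities.

**What the generator does not emulate:** real essays' burstiness
(word reuse within a document beyond multinomial sampling), spelling
errors and their manual correction, rater disagreement, polytomous item
scoring, and content (topical-word) covariate effects. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated generative model, not robustness to these real-data features.

## Problem sizes used by the test suite

Simulation-backed checks run at reduced scale so the whole suite stays
fast on one core: LCDM recovery uses 20 seeds at $n = 2000$ and compares
seed-averaged estimates (individual interaction terms have sampling SEs
near 0.2–0.7 even in well-designed 8-item tests, so per-seed bands would
measure sampling noise, not estimator quality); STM recovery uses 5 seeds
at 2,000 documents; the null-calibration study uses 100 replicate corpora
of 500 documents with $K = 2$; the topic-count search uses 4 seeds at
1,000 documents with the study's answer-length distribution. The
acceptance script reruns the study-scale pipeline (2,323 examinees, 2,108
documents) once plus smaller recovery runs, fitting each STM with two
seeded restarts and keeping the higher-objective run — the standard guard
against local optima in mixture likelihoods.

## Known limitations

* The LCDM M step assumes complete binary response matrices; missing
  responses are rejected rather than modeled.
* The Laplace approximate objective is not a true bound, so convergence is
  declared on relative change, and small non-monotonicities in the trace
  are expected and harmless.
* Tetrachoric correlations are undefined when a skill's structural margin
  is degenerate (returned as 1 for perfectly coupled skills, NA
  otherwise).
* With few items, modal classification can collapse to fewer distinct
  profiles than there are skills, making a modal prevalence design
  singular; the pipeline raises an informative error and the EAP mode is
  the practical fallback (the bundled small demo uses it).
* Topic labels are arbitrary: any comparison against generating values
  first aligns topics by cosine similarity of the word distributions.
* Covariate effects in the two-stage pipeline are attenuated when the
  stage-1 items measure a skill weakly: modal mastery indicators then
  carry classification error, which biases the prevalence regression
  toward zero exactly as measurement error does in any regression. The
  recovery tests therefore evaluate the STM stage against the true
  generating profiles; the end-to-end pipeline on the study-scale
  synthetic data shows the same signs and ordering of effects but smaller
  magnitudes, as expected with a weakly measured skill.
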