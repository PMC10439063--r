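---
title: "Norming ordinal ratings on the latent scale: models, simulators and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norming ordinal ratings on the latent scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(latentnorms)
```

## The model

A Likert response on a K-point scale is treated as an ordinal observation
of a continuous latent variable. K − 1 ordered thresholds
τ₁ < … < τ_{K−1} partition the latent axis; a latent value in
(τ_{k−1}, τ_k] is observed as response k (the boundary belongs to the lower
region, a measure-zero choice made deterministic). With a probit link the
latent variable is normal; with a logit link, logistic.

The equal-variance mixed model places random intercepts on the latent mean:

  P(response ≤ k) = F(τ_k − μ_i − μ_j),  μ_i ~ N(0, σ_item²), μ_j ~ N(0, σ_part²).

The latent grand mean is fixed at zero for identifiability, so each item's
conditional mode μ̂_i *is* its latent-mean norm. The distributional variant
adds log-scale discrimination effects acting on the latent SD,

  σ_latent(i, j) = 1 / exp(disc_i + disc_j),

with the disc population intercept fixed at zero (baseline latent SD 1).
Summaries of latent SDs are always computed per posterior draw as
1/exp(disc) and then summarised — medians of a nonlinear transform are not
the transform of medians.

## Response patterns

Five stock threshold sets (K = 5) represent qualitatively different rater
styles: equidistant (−3, −1, 1, 3), left-biased (−1, 1, 3, 5), right-biased
(−5, −3, −1, 1), edge-biased (−1, −0.35, 0.35, 1) and centre-biased
(−4, −1.5, 1.5, 4). The literature the registry emulates shows the patterns
only graphically; these constants are constrained surrogates chosen so that
a latent value of 2.5 recodes to 4, 3, 5, 5 and 4 respectively — the one
numerically published anchor — while preserving each pattern's qualitative
shape. Any replacement must preserve that recoding.

## Maximum-likelihood fitting

The marginal likelihood integrates over all random effects jointly; crossed
factors do not factorise, so the integral is approximated by a Laplace
approximation around the joint conditional mode:

* **Inner loop** — Newton iterations on the stacked effects vector. The
  penalised Hessian is Z′WZ + D⁻¹ with per-observation curvature weights W;
  for two crossed factors it has two diagonal blocks plus a sparse
  item-by-participant block, factorised with `Matrix`. Ordinal probit and
  logit log-likelihoods are concave in the linear predictor, so with the
  ridge from the prior the system is positive definite; step halving guards
  the ascent. Scores and curvatures are capped (|g| ≤ 1e6, w ∈ [1e−10,
  1e12]) so observations whose probability underflows deep in the tails
  cannot inject infinities.
* **Outer loop** — quasi-Newton (`nlminb`) over the first threshold, log
  threshold increments (which enforce ordering) and log random-effect SDs,
  warm-starting the inner mode between evaluations. Box bounds keep the
  optimiser out of degenerate regions (|τ₁| ≤ 30, log increments ≤ log 60,
  σ ∈ [1e−6, 30]); an SD on the 1e−6 floor is flagged as a boundary fit.
* **Tolerances** — inner gradient ∞-norm < 1e−6; outer relative objective
  change < 1e−8; at most 200 outer iterations. The upstream packages this
  mirrors do not publish their tolerances; these are this package's own.
* **Starting values** — thresholds from the intercept-only closed form
  (link-inverse of empirical cumulative proportions, `fit_thresholds_only`),
  RE SDs at 0.5, modes at 0.
* **Degenerate inputs** — all-identical responses are an error; categories
  unobserved at the scale extremes have their adjacent thresholds clamped
  to ±10 with a warning (they are unidentified, and inferring K from the
  data would silently change the model — hence K must always be declared);
  unobserved interior categories are an error.

Conditional SDs of the modes come from the diagonal of the inverse
penalised Hessian at the optimum. The Laplace approximation is validated
against two independent oracles on single-factor data, where the likelihood
factorises per group: adaptive Gauss–Hermite quadrature (nodes centred and
scaled at each group's conditional mode) and naive Monte-Carlo integration.

## Bayesian fitting

No Stan-family backend exists in this environment, so the sampler is part
of the package: Hamiltonian Monte Carlo with analytic gradients of the
unequal-variance ordinal likelihood, non-centred random effects, dual-
averaging step-size adaptation (target acceptance 0.8, the `adapt_delta`
analogue) and a diagonal mass matrix re-estimated in two warmup windows.
Two exact auxiliary updates run after every HMC step, both leaving the
likelihood invariant and hence the posterior exact:

* a Gibbs **translation** along the soft direction in which all thresholds
  and all mean effects of one factor shift together (its conditional is
  Gaussian under the Normal(0, 5) threshold and standard-normal z priors);
* an interweaving **rescale** of each RE SD against its effect vector
  (log-concave 1-D conditional, slice-sampled).

Without these the global parameters mix an order of magnitude more slowly.
Priors — thresholds Normal(0, 5) with an ordering transform, RE SDs
half-Normal(0, 1), effects Normal(0, SD) — stand in for backend defaults
that the reference analyses left unstated; sensitivity to them has not been
tested against the originals. Convergence is monitored by split-chain
R-hat; the fit fails loudly (error by default) if any threshold or RE SD
exceeds 1.05. Test-scale defaults are 4 chains × (500 warmup + 500 draws);
the reference-scale settings (3–6 chains × 6000, thinning) are reachable
through `distributional_spec`. The 89% highest-density interval is the
shortest window containing ⌈0.89 n⌉ sorted draws.

## What the simulators state — and what they do not

The generators reproduce the reference generative worlds: items-only
(L_i = μ_i + e_i, both N(0, 1), 100 items × 25 ratings), crossed
(L_ij = μ_i + μ_j + e_ij, 100 participants rating 25 items each, allocated
pseudo-randomly so nobody rates an item twice), distributional
(L_ij ~ N(μ_i + μ_j, 1/exp(disc_i + disc_j)), disc SDs 0.5), and
non-normal variants with fixed parameterisations: logistic(0, 1),
uniform(−2, 2), an equal mixture of N(−1.5, 0.75) and N(1.5, 0.75), and
half-normal |N(0, 1)| — not recentred, a choice the source leaves open.
Allocation concatenates random item permutations, chunks them into
participant blocks and repairs within-participant duplicates by swapping
(the source says only "pseudo-randomly"). Every generated table stores its
latent ground truth, and responses are exact recodings of it.

A green recovery test therefore establishes that the estimators undo
threshold distortion *within these worlds*: homogeneous response patterns
across participants, no missing data, no per-participant threshold
differences, balanced designs. Real norming data violate all of these to
some degree; the split-half consistency analysis is the only evaluation
here that does not rely on simulated truth.

## Evaluation choices

* Sample SDs use the n − 1 denominator throughout.
* Scaled recovery errors divide both truth and estimates by their own SDs
  across items, making comparisons invariant to shrinkage magnitude.
* Zero-variance participants are excluded from z-score norms (assigning
  them 0 would bias exactly the items they rated).
* Split halves standardise each method's estimates by the SD of its
  estimates pooled over both halves before differencing; the exact
  standardisation used in the reference figure is unspecified, and this is
  the package's own choice. Odd trial counts alternate the extra trial
  between halves by item index.
* LOESS smoothing is not implemented; comparisons use correlations and
  error SDs.
* `run_experiment` scales the reference designs down proportionally
  (with floors) so the full studies fit in test budgets; at scale = 1 the
  designs match the reference settings.

## Known limitations

The Laplace approximation is biased for small groups (visible as mild
underestimation of participant SDs at 25 ratings per participant); the
quadrature oracle quantifies this only for single-factor models. The HMC
sampler uses a fixed-length jittered trajectory, not a dynamic one, and its
priors are stand-ins. Fixed-effect covariates, per-group thresholds,
non-probit/logit links and missing-data mechanisms are out of scope.
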