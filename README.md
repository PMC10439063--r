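# latentnorms

Norming studies collect Likert ratings (e.g. 1–5) of many items from many
participants and publish per-item summaries — traditionally the mean and SD
of the ratings. But a Likert scale is ordinal, not interval: responses arise
by cutting a continuous *latent* dimension at thresholds whose spacing
reflects the raters' response pattern, not the dimension itself. Raw means
and SDs are therefore distorted by whatever response pattern the sample
happened to have (edge-biased raters inflate extreme categories, centre-
biased raters compress them, and so on), and items at the scale floor or
ceiling become indistinguishable.

`latentnorms` computes item norms on the latent scale instead, as random
effects of cumulative link mixed models (CLMMs). For a probit link,

> P(response ≤ k) = Φ(τ_k − μ_i − μ_j)

with thresholds τ_1 < … < τ_{K−1}, item effects μ_i ~ N(0, σ_item²) and
participant effects μ_j ~ N(0, σ_part²). The conditional mode of μ_i is the
item's latent-mean norm: an analogue of the mean rating, but invariant to
the response pattern and shrunken in proportion to how little data the item
has. A Bayesian *distributional* variant additionally gives every item and
participant a discrimination effect disc with latent SD = 1/exp(disc_i +
disc_j), yielding a latent-SD norm — the analogue of the rating SD —
together with posterior medians and 89% highest-density intervals.

The package provides, for R:

- the latent/ordinal machinery: threshold sets, five stock response
  patterns, recoding, response probabilities (`make_pattern`,
  `recode_latent`, `response_probs`);
- simulation generators for items-only, crossed, unequal-variance and
  non-normal rating studies (`simulate_items_only`, `simulate_crossed`,
  `simulate_nonnormal`);
- a maximum-likelihood CLMM with crossed random intercepts, fitted by a
  Laplace approximation with sparse inner Newton steps (`fit_clmm`,
  `ranef`), plus an adaptive Gauss–Hermite oracle
  (`marginal_loglik_quadrature`);
- a Bayesian distributional CLMM fitted by Hamiltonian Monte Carlo with
  analytic gradients (`fit_distributional`, `summarize_posterior_norms`,
  `hdi`, `latent_sd_draws`);
- baseline methods and evaluation procedures: raw means, within-participant
  z-scores, Gaussian LMM norms, recovery errors, split-half consistency and
  a simulation-experiment runner (`raw_norms`, `zscore_norms`, `lmm_norms`,
  `recovery_error`, `split_half_consistency`, `run_experiment`);
- delimited-text IO, a TOML-subset config reader and a CLI
  (`inst/cli/latentnorm`).

## Worked example

Simulate a 40-item × 40-participant study whose raters are edge-biased
(narrow central threshold regions, so 1s and 5s dominate), then norm it:

```r
library(latentnorms)

design <- simulation_design(n_items = 40, n_participants = 40,
                            ratings_per_item = 20, items_per_participant = 20,
                            seed = 2024)
trials <- simulate_crossed(design, pattern = "edge-biased")

fit <- fit_clmm(trials, n_levels = 5)
fit
#> <clmm_fit> probit link, K = 5, n = 800, logLik = -982.851
#>   thresholds: -1.026, -0.2879, 0.423, 1.01
#>   RE SD (item): 1.0582  [40 levels]
#>   RE SD (participant): 1.0768  [40 levels]
```

The fitted thresholds recover the edge-biased pattern (−1, −0.35, 0.35, 1)
and both random-effect SDs recover the simulated value 1. The norm table
puts raw and latent norms side by side (`latent_mean_lo`/`_hi` are ± one
conditional SD):

```r
norms <- clmm_norms(trials, n_levels = 5)
head(norms[, 1:7], 5)
#>   item_id  n raw_mean raw_sd latent_mean latent_mean_lo latent_mean_hi
#> 1 item_01 20     4.40  0.940       1.718         1.4118          2.024
#> 2 item_02 20     3.75  1.446       0.825         0.5411          1.109
#> 3 item_03 20     2.00  0.973      -0.743        -1.0162         -0.471
#> 4 item_04 20     2.75  1.517      -0.490        -0.7678         -0.212
#> 5 item_05 20     3.15  1.694       0.327         0.0469          0.607
```

Against the simulated ground truth, the latent norms track the true item
effects more faithfully than raw means (r = 0.973 vs 0.965 here; the gap
widens with more biased patterns and at the scale bounds), and the latent
parameters predict the full response distribution of any item:

```r
predict_item_probs(norms, "item_03", threshold_set(fit$tau))
#> [1] 0.389 0.287 0.203 0.082 0.040
```

For latent SD norms and credible intervals, fit the distributional model:

```r
post  <- fit_distributional(trials, distributional_spec(seed = 1))
norms <- summarize_posterior_norms(post)   # medians + 89% HDIs, mean and SD
```

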