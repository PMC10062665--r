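# trajmix

Model-based clustering of joint mood–pain symptom-diary trajectories as a
finite mixture of discrete-time Markov chains.

## The problem

Mobile symptom diaries collect daily self-reports of mood and pain
(1–5 Likert scales each) from people living with chronic pain. Mood and
pain interact, but not in one universal way: different subgroups of
participants show different day-to-day dynamics. `trajmix` is for
biostatisticians and epidemiologists who want to discover such subgroups
(candidate behavioural endotypes) from longitudinal categorical
trajectories and reason about what hypothetical symptom-improving
interventions would do to each one.

Each participant's sequence of joint states — the 5×5 Likert grid, or the
reduced four states **GL, GH, BL, BH** (Good/Bad mood × Low/High pain) —
is summarised by its matrix of transition counts between consecutive
reporting days. The cohort is modelled as a mixture of Markov chains: with
probability λ<sub>c</sub> a participant follows the row-stochastic
transition matrix M<sub>c</sub> of cluster c, so the observed-data
log-likelihood is

&nbsp;&nbsp;ℓ = Σ<sub>s</sub> log Σ<sub>c</sub> λ<sub>c</sub>
Π<sub>ij</sub> M<sub>c</sub>[i,j]<sup>C<sub>s</sub>[i,j]</sup>,

maximised by expectation–maximisation with seeded multi-restart, a
smoothing pseudocount ε that keeps fitted chains regular, and BIC
(2·negLL + p·ln T over total transitions T) for choosing the number of
components. Around the fit the package provides:

* **Pearson residual diagnostics** against a "sticky diagonal + uniform
  off-diagonal" null for the pooled counts: R = (Y − E)/√E, with
  |R| > 2 flagging transitions the null cannot explain;
* **stationary distributions** x = xM per cluster (long-run fraction of
  reporting days in each state), via a direct solve with regularity
  checking;
* **intervention transforms**: add a boost β to transitions into improved
  mood (or pain) states in the treated rows, redistribute the remaining
  mass, and compare stationary distributions before and after;
* **cluster characterisation**: log odds ratios (Wald 95% CI,
  Haldane–Anscombe correction) of binary conditions / pain-site flags per
  cluster;
* a **synthetic cohort generator** with latent clusters, ~44-day mean
  trajectories, reporting gaps and cluster-linked covariate prevalences,
  so the whole pipeline is testable without access to cohort data;
* `run_pipeline()`, an end-to-end orchestrator writing tidy CSVs, a model
  JSON and a reproducibility manifest.

All user-facing functions take and return data frames (tibbles), chain
with the pipe, and have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(trajmix)

spec <- cohort_spec(
  S = 400, K = 2, weights = c(0.5, 0.5),
  matrices = list(sticky_matrix(4, 0.9), sticky_matrix(4, 0.5)),
  mean_length = 40, seed = 1
)
cohort <- simulate_cohort(spec)
counts <- transition_counts(cohort$diary)
fit    <- fit_markov_mixture(counts, K = 2, seed = 1)
fit
#> <markov_mixture> K = 2 on 4 states; 400 participants, 15557 transitions
#>   weights: 0.457 0.543
#>   log-likelihood: -13981.15 in 7 iterations (converged)
```

The two recovered components are the sticky chain (stay probability 0.9)
and the mobile one (0.5), with weights near the generating 50/50 split.
Long-run occupancy per cluster:

```r
occupancy_report(fit)
#> # A tibble: 8 × 4
#>   cluster weight state probability
#>     <int>  <dbl> <chr>       <dbl>
#> 1       1  0.457 GL          0.260
#> 2       1  0.457 GH          0.241
#> 3       1  0.457 BL          0.262
#> 4       1  0.457 BH          0.236
#> ...
```

Both chains here have near-uniform stationary distributions — they differ
in *stickiness*, not destination. A hypothetical mood-improving treatment
(boost β = 0.05 toward good-mood states out of bad-mood states) shifts
each cluster's long-run occupancy:

```r
intervention_report(fit, intervention_spec("mood", beta = 0.05))
#> # A tibble: 8 × 5
#>   cluster state x_before x_after   delta
#>     <int> <chr>    <dbl>   <dbl>   <dbl>
#> 1       1 GL       0.260  0.364   0.104
#> 2       1 GH       0.241  0.343   0.101
#> 3       1 BL       0.262  0.218  -0.0438
#> 4       1 BH       0.236  0.0747 -0.162
#> ...
```

The same boost moves the sticky cluster much further (BH mass down 0.162)
than the mobile one (down 0.105) — clusters respond differently to the
same intervention, which is the clinical point of the analysis. Deltas sum
to zero per cluster, and `max_feasible_beta()` gives the largest boost
each matrix can absorb.

See `vignettes/markov-mixture-methods.Rmd` for the model, conventions and
numerical choices in full.

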