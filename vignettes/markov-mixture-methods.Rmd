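---
title: "Clustering mood-pain diary trajectories as a mixture of Markov chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering mood-pain diary trajectories as a mixture of Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmix)
```

## The problem

People living with chronic pain report their mood and pain day by day in
mobile symptom diaries. Mood and pain are known to interact, but the
*individual-level* shape of that interaction varies: some people drift
toward simultaneous low mood and high pain, others recover toward feeling
well, others stay wherever they are. `trajmix` models a cohort of such
diaries as a finite mixture of discrete-time Markov chains: each
participant belongs to one of $K$ latent clusters (candidate behavioural
endotypes), and each cluster $c$ has its own transition matrix $M_c$
governing how the joint mood-pain state evolves from one reporting day to
the next.

## State spaces

Scores arrive on 1-5 Likert scales for both mood (1 worst, 5 best) and
pain (1 none, 5 worst). Two encodings are supported:

* **full** — the raw $5\times5$ grid, 25 states, used for exploratory
  residual diagnostics;
* **reduced** — mood collapsed to Good (4-5) / Bad (1-3), pain to Low
  (1-2) / High (3-5), giving four states in the fixed order
  **GL, GH, BL, BH**. Clustering uses this space: with 25 states each
  component would carry 600 free transition parameters and per-participant
  counts (median a few dozen transitions) could not support them.

The display order of the four reduced states is a package-wide convention;
every matrix, table and plot uses (GL, GH, BL, BH). Note the grouping
splits the 25 cells as GL 4, GH 6, BL 6, BH 9 (2 good-mood levels $\times$
2 low-pain levels, and so on).

Days missing either score are dropped — only complete (mood, pain) pairs
are analysed — and a transition is counted between each pair of
*consecutive reporting days* regardless of the calendar gap between them.
Duplicate reports for the same day are rejected rather than silently
resolved, since the upstream resolution rule is unknown. Participants with
fewer than two complete days contribute no transitions and are excluded
from likelihood fitting with a warning.

## Residual diagnostics

Before clustering, the pooled transition counts $Y$ are screened against a
deliberately simple "sticky diagonal" null: each state $i$ has a stay
probability $\pi_i$, and leaving is uniform over the other $n-1$ states.
Maximum likelihood gives
$$\hat N_i = \sum_k Y_{ik}, \quad \hat\pi_i = Y_{ii}/\hat N_i, \quad
\hat P_{ij} = \begin{cases}\hat\pi_i & i = j\\ (1-\hat\pi_i)/(n-1) & i \ne j\end{cases},
\quad E_{ij} = \hat N_i \hat P_{ij},$$
and the Pearson residuals $R_{ij} = (Y_{ij} - E_{ij})/\sqrt{E_{ij}}$ are
asymptotically standard normal when the null holds; $|R_{ij}| > 2$ flags
transitions happening significantly more or less often than the null
predicts. Two conventions matter:

* diagonal residuals are structurally zero (the null fits each diagonal
  cell exactly), so normality summaries are computed over off-diagonal,
  unflagged cells only;
* cells with zero expected count return residual 0 plus a flag — never
  `NaN` or `Inf` — so downstream summaries stay total. Rows with no counts
  are flagged with an undefined $\hat\pi_i$, a uniform $\hat P$ row and a
  zero $E$ row.

The normality summary uses the sample standard deviation (denominator
$\text{count}-1$).

## The mixture model and EM

For participant $s$ with transition count matrix $C_s$, the likelihood
under component $c$ conditions on the first observed state:
$$\log L_{sc} = \sum_{ij} C_s[i,j] \log M_c[i,j].$$
No initial-state term is included; the likelihood is purely about
transition dynamics, and the code isolates this so an initial-state term
could be added. The observed-data log-likelihood is
$\sum_s \log \sum_c \lambda_c L_{sc}$ with mixing weights $\lambda$.

EM alternates:

* **E-step** — responsibilities
  $\Gamma_{sc} \propto \lambda_c L_{sc}$, normalised per participant with
  log-sum-exp (all likelihood work happens in the log domain; a
  participant impossible under every component gets uniform
  responsibilities and a warning);
* **M-step** — $\lambda_c = \tfrac1S\sum_s \Gamma_{sc}$ and
  $$M_c[i,j] = \frac{\sum_s \Gamma_{sc} C_s[i,j] + \varepsilon}
  {\sum_s \Gamma_{sc} \sum_k C_s[i,k] + n\varepsilon},$$
  with pseudocount $\varepsilon = 10^{-6}$ (default). The smoothing
  prevents EM degeneracies (components collapsing onto zero-probability
  transitions) and guarantees every fitted chain is strictly positive,
  hence regular, so stationary analysis downstream is always well posed.
  Rows with no weighted mass become uniform.

Numerical choices: convergence is declared when the relative
log-likelihood improvement falls below `tol` ($10^{-8}$) or after
`max_iter` (500) iterations; the vectorised E-step represents $\log 0$ by
a large negative sentinel ($-10^{12}$), far below any attainable
log-likelihood yet safe from overflow. The per-iteration log-likelihood
trace is stored and is monotone nondecreasing — the EM guarantee — which
the test suite asserts on every fit it runs.

**Initialisation and restarts.** Responsibilities start from a symmetric
Dirichlet(1) draw per participant (default), or from perturbed pooled-MLE
matrices (`init = "pooled"`). Since EM only finds local optima, the fit
runs `n_restarts` (default 20) seeded restarts and keeps the best final
log-likelihood, ties going to the earliest restart. Restart $r$ uses
`seed + r - 1`, making fits reproducible.

Hard assignments take each participant's argmax responsibility, ties
broken toward the lowest cluster index (reported via a message).

## Choosing K

`model_selection_scan()` fits each candidate $K$ under the same restart
policy and reports the negative log-likelihood, its decrease from
$K-1$, the parameter count $p = (K-1) + Kn(n-1)$, and
$$\mathrm{BIC} = 2\,\mathrm{negLL} + p\ln T,$$
where the sample size $T$ is the total number of observed transitions.
Using $T$ (rather than the number of participants) matches the unit of
observation entering the likelihood; this was a genuinely open choice and
is documented here as the package's convention. Since a $(K{+}1)$-mixture
contains every $K$-mixture, best-of-restarts negLL should be nonincreasing
in $K$ — asserted in tests — and BIC turns upward once extra components
stop paying for their parameters.

## Stationary distributions

Each fitted $M_c$ is checked for regularity (some power strictly positive,
tested on the positivity pattern up to the Wielandt bound $(n-1)^2+1$);
$\varepsilon$-smoothed EM output is always regular. The stationary
distribution solves $x M = x$, $\sum_i x_i = 1$, computed by replacing one
equation of the singular system $(M^\top - I)x = 0$ with the
normalisation row — a deterministic direct solve with no complex
arithmetic — and verified to residual $10^{-10}$. For an ergodic chain
$x_k$ is the modelled long-run fraction of reporting days spent in state
$k$, which is what `occupancy_report()` tabulates per cluster.

## Hypothetical interventions

The intervention transforms ask: if a treatment nudged daily transitions
toward better mood (or less pain), how would each cluster's long-run
occupancy shift? For the mood arm, in each bad-mood row (BL, BH) the
probabilities of the good-mood destinations GL and GH each gain $\beta$;
the two bad-mood destinations then hold $\text{BL}+\text{BH}-2\beta$,
redistributed `split` to BL and $1-\text{split}$ to BH. Good-mood rows are
untouched. The pain arm mirrors this: high-pain rows (GH, BH) boost GL and
BL, with the leftover split between GH and BH. Adding $2\beta$ and
removing $2\beta$ per treated row preserves row sums by construction.

The default `split = 0.8` sends the larger share of leftover mass to the
state that is better on the *untreated* dimension (BL for the mood arm,
GH for the pain arm), consistent with modelling the intervention as
beneficial; the parameter is configurable so the opposite reading is also
runnable. Feasibility is checked per row: $\beta$ may not exceed half the
mass available on the two non-improved destinations, nor any boosted
entry's headroom to 1, and `max_feasible_beta()` returns the exact bound
(0.25 for a uniform matrix). `intervention_report()` tabulates
before/after stationary distributions and their difference per cluster;
the deltas sum to zero by construction.

## Cluster characterisation

Hard cluster membership is crossed with each binary covariate (conditions,
pain sites) in a 2x2 table — in-cluster versus *all other clusters
pooled*, participants missing the covariate excluded — and summarised by
the log odds ratio with a Wald 95% interval,
$\log\mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d}$. A zero cell triggers the
Haldane-Anscombe $+0.5$ correction (flagged); a zero margin makes the
estimate undefined and it is returned as `NA` rather than an error. The
estimator and interval method were unspecified upstream; Wald-on-log-scale
with Haldane correction is the package's documented choice, and no
multiple-testing adjustment is applied (per-covariate intervals only).

## The synthetic cohort generator

Because the original cohort data are not publicly deposited, every
pipeline stage is exercised against `simulate_cohort()`, which generates
exactly the structure the model assumes: cluster drawn from the mixing
weights, a trajectory length from a negative-binomial model (mean 44
reporting days, matching the motivating cohort average; dispersion 8,
minimum 2),
an initial state (uniform by default), then one chain step per reporting
day. Two design points deserve emphasis:

* **Gaps shape day indices, not dynamics.** Consecutive reporting days are
  separated by geometric calendar gaps (`gap_prob`, default 0.15), but the
  chain advances once per *report*. Generated counts therefore follow the
  mixture model exactly, matching the analysis convention that a
  transition spans consecutive reporting days whatever the calendar gap.
  Real data need not obey this: if symptoms evolve on unreported days,
  observed transitions are powers of a daily matrix. Passing recovery
  tests on these cohorts demonstrates correctness of the estimator under
  its own assumptions, not robustness to that misspecification.
* **Missingness is ignorable by construction** (independent of state), as
  the analysis assumes; informative missingness is out of scope.

`simulate_full_scale_states()` refines reduced trajectories to 5x5 Likert
pairs via a per-state refinement distribution (uniform over each reduced
state's cells by default) and can blank one score on a
`single_score_missing` fraction of days (default 0.05), which the ingest
step then drops — emulating incomplete reports. Default rates are chosen
once as plausible for app-based diaries; only the motivating cohort's
mean trajectory length is public, so the other generator defaults are
explicit stand-ins.

The `mhealth_preset()` cohort (S = 9990, weights 0.18/0.16/0.20/0.46)
uses four illustrative regime matrices — attracted to BH, attracted to
GL, attracted to GH, and sticky — not fitted values from any real cohort.
End-to-end runs on this preset check that the pipeline
recovers four clusters with those qualitative regimes
(`chain_regime()` labels a fit "sticky" above a mean-diagonal of 0.5,
otherwise by the state holding most stationary mass).

`recovery_harness()` closes the loop: simulate, fit, align components to
the truth by exhaustive best-permutation matching on L1 matrix distance
(exact for the small $K$ used here), and score mixing-weight error,
maximum absolute transition-probability error, assignment accuracy and
the adjusted Rand index (via `mclust::adjustedRandIndex`).

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations are sized so results are
stable yet quick on a single core: residual calibration pools roughly
10^4 transitions over a 25-state null chain (600 off-diagonal residual
cells); EM recovery uses 800 participants of ~40 reporting days with
well-separated sticky chains (stay 0.9 vs 0.5); BIC selection scans
$K \in 1..6$ on 1000 participants generated from four well-separated
regimes; stationary solvers are checked on 1000 random strictly-positive
matrices; and the full-scale end-to-end run on the cohort preset uses the full S = 9990 with 5
EM restarts.

## Known limitations

* The Markov assumption is first-order on reporting days; longer memory
  and non-reported-day dynamics are not modelled.
* Association only: intervention transforms are hypothetical what-if
  calculations on transition probabilities, not causal estimates.
* The likelihood omits initial-state terms; clusters that differ only in
  their starting state are indistinguishable.
* Ties and label switching: mixture components are identifiable only up
  to permutation; all comparisons to ground truth go through
  best-permutation alignment.

## A minimal worked example

```{r example, eval = FALSE}
spec <- cohort_spec(
  S = 400, K = 2, weights = c(0.5, 0.5),
  matrices = list(sticky_matrix(4, 0.9), sticky_matrix(4, 0.5)),
  mean_length = 40, seed = 1
)
cohort <- simulate_cohort(spec)
counts <- transition_counts(cohort$diary)
fit <- fit_markov_mixture(counts, K = 2, seed = 1)
glance(fit)
occupancy_report(fit)
intervention_report(fit, intervention_spec("mood", beta = 0.05))
```
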