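---
title: "The shift-model CRM for concurrent mono- and combination-therapy dose finding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The shift-model CRM for concurrent mono- and combination-therapy dose finding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmshift)
```

## The problem

A phase I trial wants to find, at the same time, the maximum tolerated dose
(MTD) of a new agent given alone and given on top of a second agent, over a
2 x 7 grid: row 1 is monotherapy, row 2 the combination, columns are the
dose levels of the new agent. Two ordering assumptions are clinically
solid: dose-limiting toxicity (DLT) probability rises with dose within each
row, and adding the second agent can only raise it at a fixed dose, so the
combination's MTD cannot sit above the monotherapy MTD. The MTD in each row
is the level whose true DLT rate is closest to a target (30% throughout
this package; equidistant ties go to the lower, safer level).

Running two separate single-agent designs (3+3 or BOIN per row) ignores
the second assumption and can end in a *reversal* -- recommending a higher
MTD with the second agent than without -- which is clinically incoherent.
The shift-model CRM makes a reversal structurally impossible and borrows
safety information across rows.

## The model

The continual reassessment method (CRM) fits the one-parameter empiric
(power) model: with a skeleton of prior DLT probability guesses $q_{rj}$
over the grid, the DLT probability at row $r$, level $j$ is modeled as
$q_{rj}^{\exp(a)}$ and $a$ is estimated from the accumulated binary
outcomes by maximum likelihood. We parameterize the exponent as $\exp(a)$
and maximize over $a \in [-10, 10]$, so the power stays positive and the
optimization is effectively unconstrained -- standard CRM practice, and
numerically stable.

Uncertainty about *where* the row-2 MTD sits relative to row 1 is coded as
a small set of working models indexed by a shift $s \in \{0, -1\}$: the
two rows' MTDs are either at the same level or the combination's is one
level lower. All models share a single strictly increasing base skeleton
$q_1 < \dots < q_{L+1}$ (length `n_levels + 1` so a shifted row never runs
off the end): row 1 always takes $q_1..q_L$, and the shift-$s$ model's
row 2 takes $q_{1-s}..q_{L-s}$. Pushing row 2 one position up the base
vector places its prior MTD one level lower, which is exactly the
hypothesis that model encodes. Because the row-2 skeleton is everywhere at
or above row 1's, the fitted probability matrix of *any* working model
recommends a row-2 level at or below the row-1 level: the final pair can
never reverse, under any data.

Every model is refitted on all data at each decision; the model with the
largest likelihood is used (the models are treated as equally likely a
priori, so this is pure likelihood comparison; prior weights are exposed
in the design object for generality). Exactly tied likelihoods -- which
occur structurally, e.g. while all data sit in row 1, where the two
skeletons coincide -- are resolved by a fair random draw. The next patient
is then randomized 1:1 between the two rows' recommended levels.

## Skeleton calibration

The base skeleton comes from the indifference-interval recursion
(`lee_cheung_skeleton()`): anchored at the prior MTD position with value
equal to the target $\theta$, each step up solves
$q_{k+1}^{a^*} = \theta + \delta$ where $a^*$ solves
$q_k^{a^*} = \theta - \delta$, and symmetrically downwards. The halfwidth
$\delta$ controls skeleton spread. Defaults: $\delta = 0.05$, prior MTD at
level 4 of 7, base length 8 -- a mid-grid prior guess with moderate
spread; both parameters are exposed in `shift_crm_design()` so an
alternative calibration can be swapped in. Under the defaults the worked
example's interim state (four DLT-free patients on row-1 levels 1-4, a
DLT at level 5) yields recommendations row 1 level 5, row 2 level 4, with
the two models exactly tied in likelihood -- all data sit in row 1, where
the skeletons coincide -- so the estimated shift at that point is the
outcome of the random tie-break.

## Trial conduct

Likelihood CRMs have no MLE until the data contain both a DLT and a
non-DLT, so conduct is two-stage. The initial stage assigns cohorts of one
starting at (row 1, level 1) and escalates along row 1, then -- if row 1
is exhausted DLT-free -- from (row 2, level 1) along row 2. The stage
flips to modeling at the first patient after which both a DLT and a
non-DLT exist. Two edge cases are fixed as follows: if the *first*
patients experience only DLTs, the lowest
combination is repeated (no lower dose exists and the model is
inestimable); if the whole initial path is exhausted DLT-free, the trial
holds at the highest combination.

The design follows model recommendations as-is in the modeling stage,
which may assign a never-tried combination directly;
`escalation_cap = TRUE` optionally restricts recommendations to
one level above the highest tried level per row for conservative use.

Total sample size defaults to $N = 39$ (see the sample-size section). A
configurable safety rule stops the trial when at least 3 patients have been
treated at the lowest combination and the one-sided lower 90%
Clopper-Pearson bound on its DLT rate exceeds the target; confidence level
and minimum exposure are design parameters. A safety-stopped (or still
homogeneous) trial selects no MTD in either row, and counts as incorrect
in both rows when operating characteristics are summarized.

## Comparator designs

`three_plus_three_design()` runs the classic 3+3 independently per row:
cohorts of three, 0/3 escalate, 1/3 expand to six, at most 1/6 escalate,
two or more DLTs stop the row with the next-lower level as MTD (no MTD if
that happens at level 1); clean escalation past the top declares the top
level. This is the simplest canonical variant (no de-escalation
expansion cohorts).

`parallel_boin_design()` runs Bayesian-optimal-interval conduct per row
with cohorts of one and 20 patients per row: escalate when the observed
rate at the current level is at or below $\lambda_e$, de-escalate at or
above $\lambda_d$ (closed-form boundaries from the target and the interval
$(0.6\theta,\ 1.4\theta)$, the method's recommended defaults). A level
with at least 3 patients whose Beta(1,1)-posterior probability of
exceeding the target tops 0.95 is eliminated with everything above it;
eliminating level 1 stops the row. The row MTD minimizes the distance to
the target of isotonically adjusted (weighted PAVA) posterior means under
the quasi-uniform Beta(0.05, 0.05) selection prior -- the method's own
software default. A flat Beta(1,1) selection prior would make a level seen
once without DLT look like a 0.33 estimate, nearly on target, and collapse
selection accuracy; the near-flat prior exists precisely to prevent that.

## Sample size

`crm_sample_size()` returns the design's default size $N = 39$ for a
desired average probability of correct selection (PCS) of 50%, target
30%, 14 test doses and effect size 1.78. The calculation goes through the
complete-information benchmark: scenarios are calibrated so adjacent doses
differ by the odds ratio given as the effect size, with the true MTD at
each position in turn; the benchmark's average PCS (a normal approximation
to the joint law of the empirical toxicity rates at the MTD's neighbors,
continuous in $n$) is solved for its crossing $n^*$ of the PCS goal; and
the CRM, which must learn the curve sequentially rather than observe
complete tolerance profiles, is budgeted twice the benchmark's patients:
$N = \lceil 2 n^* \rceil$. At the default specification $n^* = 19.1$, so
$N = 39$. The returned $N$ is
monotone in every specification field, and a simulation cross-check (a
single-row two-stage ML-CRM at the returned $N$ under the calibrated
scenarios) lands within Monte-Carlo error of the goal.

## Random dose-toxicity curves

`random_scenario()` generates stress-test ensembles of dose-toxicity
curves: valid ordered matrices, MTD locations uniform over the levels
with the row-2 offset uniform over {0, -1} (clipped at level 1), and a
variety of steep and flat shapes. One extended monotone base curve
is built by anchoring the MTD's probability at Uniform(target ± 0.05) and
accumulating positive increments: the two steps adjacent to the MTD are
gamma(shape 2) with mean 0.08, and farther steps are heavy-tailed
lognormal (median 0.05, sdlog 1.2), so most curves have flat stretches
with occasional steep jumps. Row 1 is the base curve; row 2 is the base
displaced by the intended shift plus N(0, 0.03) level-wise jitter and
floored at row 1 -- the two strategies' curves track each other closely,
as in the worked example, where row 2 sits within a few points of the
one-level-shifted row 1. Draws are rejected until all invariants hold
and each row's closest-to-target level equals its intended MTD. All
dispersion controls are exposed as arguments; the defaults above were
fixed once and are the conditions under which the package's ensemble
numbers are computed.

What the generator does *not* emulate: real dose-toxicity relationships
with covariate structure, inter-patient heterogeneity, or late-onset
toxicity -- a passing ensemble check says the designs rank as reported
under curves *like these*, not that any design attains those numbers in a
particular real trial.

## Simulation engine and reproducibility

`run_trial()` draws each patient's DLT as a Bernoulli outcome at the
assigned combination's true probability and applies the design's rules
exactly as in live conduct. Seeds are localized: a trial is a pure
function of (design, scenario, seed). `simulate_ocs()` derives trial
seeds from a base seed by a counter (`base_seed + i`, modulo $2^{31}-1$),
so any single trial is re-runnable in isolation;
`aggregate_over_curves()` offsets curve $c$ by $10^5 c$. Ensembles of
curves are drawn sequentially after a single `set.seed`.

Reported operating characteristics: PCR (per row, percent of trials
selecting that row's true MTD; trials with no selection count as
incorrect), PCA (mean over trials of the fraction of that trial's
enrolled patients treated at a row's true MTD; the overall PCA is the sum
over rows, so the two denominators match), mean sample size, early-stop
percentage (per trial for the shift design, per row for the parallel
designs), reversal percentage, and the zero / one / both correct-selection
partition.

The package's own reference runs use 1,000 trials for single-scenario
summaries and 50 curves x 200 trials per design for ensembles; at those
sizes the Monte-Carlo standard error of a percentage near 40% is about
1.5 points per scenario and under a point for ensemble means.

## Numerical choices and degenerate inputs

* MLE: `stats::optimize` on $a \in [-10, 10]$, tolerance $10^{-6}$; the
  likelihood diverges to $-\infty$ at both ends for heterogeneous data, so
  the interior maximum exists; a property test checks it against a dense
  grid search.
* Tie detection in model selection uses a relative tolerance of $10^{-9}$
  on the log-likelihood, wide enough to catch structural ties computed
  through identical floating-point paths and far below any data-driven
  likelihood difference.
* All closest-to-target argmins break ties to the lower level, on safety
  grounds.
* Scenario probabilities live in $[0, 1)$: exact zeros are allowed (useful
  for pinning the initial-stage path in tests -- a DLT-free trial stays in
  its initial stage and selects no MTD), exact ones are not, since a
  skeleton value of 1 is outside the power model's domain.
* Homogeneous-at-completion trials (all DLT or no DLT) select no MTD;
  under curves anchored near a 30% target this is rare.

## Known limitations

* Only 2-row grids are implemented; the construction generalizes to more
  rows (chains of shifts) but is neither required nor tested here.
* Skeleton behavior is verified against the worked example at its
  interim state; alternative calibrations change the fitted
  recommendations and should be re-examined by simulation before use.
* The safety stopping rule is one reasonable choice among several; its
  confidence level and minimum exposure are design parameters.
* Ensemble operating characteristics are properties of the generator's
  curve distribution as much as of the designs; metrics that are
  sensitive to curve shape (notably the parallel designs' reversal
  rates) shift when the dispersion controls change.
* Bayesian CRM variants (posterior-mean estimation), time-to-event
  outcomes, and efficacy-integrated extensions are out of scope.
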