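---
title: "Choosing state structures by parameter constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing state structures by parameter constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statemerge)
```

## The model and its assumptions

A discrete-time Markov cohort model places every patient in one of a
finite set of health states; each cycle they move according to a fixed
row-stochastic matrix `P`, accrue the cost `c_X` of their state, and
accrue utility `u_X` scaled by the cycle length in years. The
structural question this package addresses is whether two or more
"similar" states should be one state. The consequences of occupying a
state are its exit destinations, the probabilities of reaching them,
its cost and its utility; states whose consequences coincide can be
merged without changing anything the model predicts.

Formally, merging states `A_1, ..., A_n` that share exit states
`E_1, ..., E_m` is equivalent to keeping the split space and imposing

* `P(A_j -> E_i)` equal across `j` for each exit `i`,
* equal costs and equal utilities across the `A_j`.

Transitions *among* the `A_j` stay unconstrained — "reversible"
structures, where patients move back and forth between the candidate
states, are fully covered, because the probability of leaving the
group for any exit does not depend on which member a patient occupies.
Under these constraints the aggregated occupancy of the group in the
split model follows exactly the merged model's recursion (the chain is
lumpable over the partition), so survival, expected costs and QALYs
coincide over any horizon. `check_equivalence()` verifies this
numerically for any supplied pair of models.

The key statistical consequence: because the constrained split model
is fitted to the *same disaggregated data* as the unconstrained one,
maximised likelihoods and AIC compare the structures legitimately,
which is not true of a merged model fitted to aggregated counts. A
positive AIC difference (constrained minus unconstrained) favours
separate parameters; a negative one favours the merge. Ties resolve to
the more parsimonious, constrained model. Different structures may be
adopted for transitions, costs and utilities independently
("partially merged" models): each constraint is assessed on its own.

Assumptions worth keeping in sight: transitions are observed as
complete one-cycle counts (no censoring, no interval ambiguity);
subjects are independent; the process is time-homogeneous Markov; and
the candidate structures are compared on transition evidence alone —
the joint likelihood would also carry cost and utility terms, but
those are assessed separately by `fit_cost_models()` and
`fit_utility_models()`, keeping each comparison interpretable.

## Constrained maximum likelihood

Each origin row of a count table is a multinomial observation. The
log-likelihood includes the multinomial/binomial normalising
coefficient, so *absolute* AICs are meaningful and match what one
obtains from `dbinom()`/`dmultinom()` directly; with the coefficient
dropped, only AIC differences would be interpretable. Zero counts
contribute nothing (`0 log 0 = 0`), and boundary MLEs are accepted.

For the constraint patterns a merge generates — every member of a
group subject to the same destination equalities — the constrained MLE
has a closed form: the common probability for destination `i` over
group `G` is the pooled proportion
`sum_{j in G} x_ji / sum_{j in G} n_j`, and the remaining
probabilities of each row are the observed conditional proportions
rescaled to the leftover mass. This follows from profiling the free
parameters out of the product-multinomial likelihood; the profile
score for the common probability is the pooled binomial score.
Constraint sets that couple rows *asymmetrically* (an origin shared by
two different equality groups for different destinations) have no such
closed form, and `constrained_mle()` falls back to direct numerical
maximisation of the profile likelihood; the tests check both routes
against an independent brute-force maximiser to `1e-8`.

Parameter counting is structural, not data-dependent: a row with `m`
listed destinations contributes `m - 1`; an equality over `g` origins
removes `g - 1`; a structural zero removes 1. Destinations listed with
a zero count therefore still count towards `m` — the support of the
multinomial is part of the model, so tables should list every
transition the model allows.

Two further operations support practice. `per_destination_table()`
assesses one destination at a time (the equality on transitions into
that destination, all else free), which shows *which* exit risk
supports or opposes a merge. Note that these per-destination AIC
differences do not sum to the whole-merge difference when several
constrained destinations share the same origin rows — the likelihood
factorises over origin rows, not over destinations — so the
whole-model comparison from `compare_structures()` remains the
decision criterion; additivity holds only across constraints touching
disjoint origin rows. `derive_counts()` reconstructs integer event
counts from a published estimate with a 95% CI when raw data are
unavailable, using log-scale moment matching: the standard error of
the log risk is taken as the CI width over `2 * 1.96`, the denominator
solved from the delta-method binomial variance `(1 - p) / (n p)`, and
a round-trip check reports how well the reconstructed counts reproduce
the input interval. This is one reasonable reconstruction, not the
only one; packaged fixtures ship the canonical derived count tables
used throughout the documentation, so downstream analyses do not
depend on the reconstruction details.

## Cost and utility comparisons

Costs are modelled as gamma with a log link — the standard
health-economics choice for right-skewed, strictly positive costs —
with a shape parameter shared between groups, so the common-mean and
separate-means models differ only in what is of interest. Because the
group-mean MLEs of a log-link gamma GLM do not depend on the shape,
the GLM fit plus the profiled ML shape is the exact joint MLE.
Utilities are modelled as normal, truncated above at 1 by default
(full health; configurable, with `Inf` giving the plain normal), with
a shared scale, fitted by direct maximisation. Both comparisons report
the same table shape as the transition comparisons:
`delta_aic = AIC(common) - AIC(separate)`, negative favouring the
merge. Under the null the difference concentrates around `LR - 2`
with `LR ~ chi-squared(1)` (mean near −1, merge chosen about 84% of
the time); under a real difference it grows without bound in `n`.

Costs and utilities for a merged state are prevalence-weighted means
of the member values (`merge_costs()`), with weights normalised
internally, so any rescaling of the prevalence gives the same answer.
When no prevalence is supplied, `merge_model()` uses equal weights.

## Selection error

AIC selects by `LR > 2k_diff`; with one true equality the
large-sample selection error — choosing the split model when the
merge is correct — is `P(chi-squared_1 > 2) ≈ 15.7%`. The
`selection_experiment()` generator reproduces this operating
characteristic, and the acceptance suite checks it at 1000 replicates
of 2000 subjects per row, alongside the power side: with risks 0.1
versus 0.4 at 500 per row the merge is essentially never selected.

## Decision consequences and value of information

Even when a structural choice does not change the optimal strategy, it
can change the value of further research. `sample_psa()` propagates
Dirichlet-sampled transition rows (the conjugate choice; in practice
parameterised by observed counts plus one), log-normal state costs and
truncated-normal utilities through the cohort engine for each
strategy, sharing the parameter draws across strategies within a draw.
Net monetary benefit is `wtp * QALY - cost`. From the draw-by-draw
results follow incremental net benefit with central 95% intervals
(`inb()`), the probability of cost effectiveness and the CEAC
(`prob_ce()`, `ceac()`), per-decision and population EVPI (`evpi()`),
and EVPPI by either a per-strategy smooth-regression estimator
(`evppi()`, a generalised additive model of net benefit on the chosen
parameter blocks) or a nested two-level Monte Carlo estimator
(`evppi_two_level()`) kept for validation — the regression route is
orders of magnitude cheaper at comparable accuracy for smooth net
benefits, which cohort models produce.

When a `merge` is attached to the PSA specification, parameters are
sampled at the merged level and expanded to the split space with the
constraints imposed, so the PSA of a constrained split model matches
the merged model's PSA draw for draw under the same seed — the
equivalence extends from point predictions to the full uncertainty
analysis. Every sampler takes an explicit seed and is reproducible
bit for bit.

The packaged `example_strategies()` problem illustrates why structure
matters: two severities share their death risk but differ sharply in
cost and utility, and a treatment shifts patients to the milder state.
The split structure (and the partially merged one, which shares
transitions but keeps state-specific costs) recommends treating; the
fully merged structure, which averages costs and utilities over a
fixed baseline prevalence, cannot see the severity shift and
recommends the cheaper strategy instead.

## Numerical choices

* **Stochasticity tolerances.** Transition matrices must have rows
  summing to 1 within `1e-8` at construction; cohort occupancies are
  conserved to well below `1e-10` over 50 cycles.
* **Equivalence verification.** The merged/split equivalence is exact
  in real arithmetic, but two independent double-precision recursions
  drift apart by a few ulps per cycle, which on currency-scale totals
  is pure rounding noise at the `1e-10` level.
  `check_equivalence()` therefore runs both recursions with
  compensated (double-double) arithmetic — error-free two-sum and
  two-product transformations — so its reported discrepancies reflect
  structural differences between the models, not summation order. The
  user-facing `cohort_trace()` stays in plain doubles. Relatedly,
  `merge_model()` returns the common member value directly when the
  members agree bitwise, rather than computing a weighted mean of
  identical numbers, which would perturb them by an ulp.
* **Degenerate inputs.** Rows with a single destination carry
  probability 1, zero log-likelihood and no parameters. Structural
  zeroes are honoured exactly; observed events at a structural zero
  give a log-likelihood of `-Inf` rather than an error, so an
  impossible candidate loses any comparison it enters. Equality
  constraints that would force a row sum above 1 are rejected.
* **Discounting and half-cycle correction.** Both default off: no
  annual discount rate is silently injected, and cycle sums are plain
  by default with a trapezoidal (half-cycle) flag available. The
  per-cycle discount factor is derived from the annual rate and the
  cycle length.
* **Optimiser settings.** The numerical fall-back for asymmetric
  constraints and the truncated-normal fits start from
  moment/pooled estimates and run quasi-Newton or Nelder–Mead to
  relative tolerances of `1e-12`–`1e-14`; the test suite's independent
  oracles use a different parameterisation (per-row softmax scores)
  precisely so that agreement is informative.

## Design choices on open points

* Only *outbound* probabilities, costs and utilities are constrained
  by a merge; inbound probabilities aggregate by summation and need no
  constraint for the equivalence, so none is imposed.
* Merge groups must have at least two members and may not overlap;
  nested or hierarchical coarsenings are expressed as separate
  candidate merge specifications and compared as alternatives.
* The per-destination assessment profiles the remaining destinations
  out (closed form above) rather than conditioning on them; both
  reduce to the same pooled binomial for a single constrained
  destination.
* Structure comparison tables are transition-only; cost and utility
  evidence enters through the dedicated outcome fits.
* State labels are opaque strings and the state-space order fixes all
  matrix layouts.

## What the synthetic generator does and does not emulate

`simulate_counts()` draws independent subject paths from a known
transition model, one observed transition per subject-cycle, with the
starting cohort allocated deterministically in proportion to the
initial distribution (largest-remainder rounding) so row denominators
are fixed by design. Costs are gamma, utilities upper-truncated
normal. This matches the complete-observation count data the
likelihood machinery assumes. It does *not* emulate censoring or
informative dropout, interval-censored panel observation, covariate
heterogeneity, or time-varying transition probabilities — passing
tests therefore demonstrate correctness of the method under its own
assumptions, not robustness to those complications in real trial
data.

The property tests that exercise the equivalence theorem generate
transition probabilities as dyadic rationals (integer multiples of
`2^-20`), so that generated rows sum to exactly 1 and the equality
constraints hold exactly in double arithmetic; with ordinary floating
draws the constraints would hold only to within rounding, and the
(deliberately accurate) equivalence check would measure that
construction error instead of the theorem.

## Problem sizes used by the test suite

The suite fits every operation at sizes chosen to keep the full run
in the tens of seconds while leaving Monte Carlo error comfortably
inside the asserted bands: 1000 random models for the equivalence
property; 200 random tables against the brute-force MLE oracle; 1000
replicates at 2000 subjects per row for the selection-error
characteristic; 200 replicates for the cost/utility operating
characteristics; and `4 * 10^3`–`10^4` PSA draws for the
value-of-information checks against closed forms.

## Known limitations

Continuous-time and semi-Markov (tunnel-state) structures are out of
scope, as are Bayesian model comparison, interval-censored
likelihoods, patient-level microsimulation and covariate-adjusted
outcome models. The count-derivation procedure is a moment-matching
reconstruction and should be replaced by the actual counts whenever
they are available. EVPPI by regression inherits the usual smoothing
caveats near kinks in the net-benefit surface; the two-level estimator
is available as a cross-check where that is a concern.
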