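# statemerge

Tools for choosing the state structure of a discrete-time Markov
cost-effectiveness model with statistical evidence rather than
convention.

## The problem

Health-economic state-transition models must decide whether similar
disease severities or similar clinical events belong in one state or
two — e.g. whether "medium-risk" and "high-risk" coronary artery
disease deserve separate states. Merging states aggregates the data the
model is fitted to, so naive likelihood or AIC comparisons between a
merged-state and a split-state model are invalid: they are not fitted
to the same dataset.

`statemerge` implements the constraint re-expression that makes the
comparison valid. A model that merges states `A_1, ..., A_n` with exit
states `E_1, ..., E_m` is practically equivalent to the model on the
full split state space with the equality constraints

```
P(A_1 -> E_i) = P(A_2 -> E_i) = ... = P(A_n -> E_i)   for i = 1..m
c(A_1) = ... = c(A_n),    u(A_1) = ... = u(A_n)
```

on the per-cycle exit probabilities, state costs `c` and utilities `u`.
Transitions *among* the merging states remain free, so reversible
models are covered. Under these constraints the split model reproduces
the merged model's cohort occupancy, expected costs and QALYs exactly;
the data stay disaggregated, so maximised likelihoods and AIC
(`2k − 2 log L`, binomial/multinomial coefficients included) compare
the structures legitimately. "Partially merged" structures — shared
transition probabilities with state-specific costs and utilities — are
expressed by applying only a subset of the constraints.

The package covers the full workflow:

- **structures** — state spaces, merge proposals, the constraint sets
  they imply, and the encompassing-model construction when the states
  to be merged have different exit states (`constraints_from_merge()`,
  `validate_mergeability()`, `extend_for_unshared_exits()`);
- **likelihood** — closed-form constrained multinomial maximum
  likelihood, AIC comparison tables, per-destination assessment, and
  back-derivation of implicit event counts from published risk
  summaries (`constrained_mle()`, `compare_structures()`,
  `per_destination_table()`, `derive_counts()`);
- **outcomes** — gamma (log link) cost models and upper-truncated
  normal utility models comparing common versus state-specific means
  (`fit_cost_models()`, `fit_utility_models()`, `merge_costs()`);
- **cohort** — the Markov cohort engine, model merging and a
  high-precision equivalence check (`cohort_trace()`,
  `expected_outcomes()`, `merge_model()`, `check_equivalence()`);
- **voi** — probabilistic sensitivity analysis, incremental net
  benefit, CEAC, EVPI and EVPPI, so the decision consequences of a
  structure choice can be quantified (`sample_psa()`, `inb()`,
  `prob_ce()`, `evpi()`, `evppi()`);
- **synthetic data** — simulation from known truth for validation and
  selection-error experiments (`truth_spec()`, `simulate_counts()`,
  `selection_experiment()`).

## Worked example

One-year death counts for medium- and high-risk coronary artery
disease, derived from published relative risks (126 deaths of 571 at
medium risk, 259 of 754 at high risk), are shipped as a fixture. Should
the two risk states be merged?

```r
library(statemerge)

tab <- cecat_death_counts()
eq <- constraint_set(prob = list(
  list(dest = "dead", origins = c("medium", "high"))))
compare_structures(tab, list(`medium=high` = eq))
#>      constraint loglik k  aic delta_aic   verdict
#> 1 unconstrained   -6.7 2 17.4       0.0 reference
#> 2   medium=high  -18.8 1 39.6      22.2     split
```

The unconstrained model (separate death probabilities, `k = 2`) has AIC
17.4; constraining a single pooled probability (`k = 1`) raises it to
39.6. The AIC difference of +22.2 strongly favours keeping the states
split: the death risks really differ. The same comparison on the
non-fatal myocardial infarction counts (39/1717 vs 62/2159) gives

```r
compare_structures(cecat_mi_counts(), list(`medium=high` =
  constraint_set(prob = list(list(dest = "mi",
                                  origins = c("medium", "high"))))))
#>      constraint loglik k  aic delta_aic   verdict
#> 1 unconstrained   -5.7 2 15.4       0.0 reference
#> 2   medium=high   -6.4 1 14.8      -0.6     merge
```

a difference of −0.6: the MI risks are similar enough that a common
parameter fits better once model complexity is accounted for. The two
verdicts can be combined — a structure may share its MI risk but keep
separate death risks.

The methods vignette (`vignettes/state-structure-selection.Rmd`) walks
through the equivalence theorem, the encompassing-model trick for
unshared exits, cost/utility comparisons, and how structure choice
propagates to net-benefit decisions and value-of-information estimates.

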