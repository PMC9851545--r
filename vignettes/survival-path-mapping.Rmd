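---
title: "Survival path mapping: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival path mapping: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survpath)
```

## The problem and the model

Longitudinal clinical cohorts record each patient at irregular visits; both
the patient's risk-factor profile and the factors that matter for prognosis
drift over the disease course. `survpath` models this with a *survival
path* tree. Each patient's timeline is zeroed at their first record and cut
into slices of `period` days; within a slice a patient contributes at most
one record, carrying the residual survival time from that visit (days from
the visit to death or censoring) and the covariate values current at that
visit. The tree's root is the whole slice-1 cohort; at every node a
feature-selection cascade picks at most one binary covariate, the node
partitions on it, and the members' next-slice records form the child
nodes. A node that selects nothing carries its subgroup forward
unchanged. Every node is annotated with its Kaplan-Meier median residual
survival and survival rate at the `rates` horizon.

The per-node cascade is, in order:

1. univariate log-rank screen at significance `p_value`;
2. pairwise collinearity resolution: pairs with Pearson |r| above
   `degree_of_correlation` are reduced by comparing the AIC of the two
   single-predictor Cox models and keeping the smaller-AIC variable;
3. backward elimination on the multivariable Cox partial likelihood,
   removing the least-significant variable (likelihood-ratio test,
   chi-square with 1 df) while its p-value is at or above `p_value`;
4. the split variable is the remaining covariate with the largest
   importance `Gamma_q = -2 log(L_{h-q}/L_h)`, i.e. the largest change in
   -2 log-likelihood when refit without it.

Two presentational conventions are worth making explicit. Inference at
every step uses the Cox *partial* likelihood: a partial-F formulation of
stepwise elimination has no direct analogue there (a partial likelihood
has neither an intercept nor a residual error term), so elimination and
importance are defined through likelihood-ratio statistics, which agree
with the F-test asymptotically. And in the collinearity step "the
better variable survives" means the variable with the **smaller** AIC —
smaller AIC is the better single-predictor model; the removed variable is
the larger-AIC one.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `period` | 30 (90 in the examples) | days | slice width on each patient's own clock |
| `left_interval`, `right_interval` | 0.5, 0.5 | fraction of `period` | admission window around each slice centre |
| `predict_time` | 365 | days | horizon of the time-dependent ROC used for dichotomization |
| `p_value` | 0.05 | — | screen and elimination significance threshold |
| `minsample` | 15 | patients | smallest node for which a split is attempted |
| `degree_of_correlation` | 0.7 | \|r\| | collinearity threshold |
| `rates` | 365 | days | node survival-rate annotation horizon |
| `time_slices` | — | slices | depth of the modeled tree |

`p_value` controls the balance between path granularity and false
bifurcations: each noise covariate survives backward elimination with
probability close to `p_value`, so with many candidates a stricter value
(0.01) keeps the map clean. `minsample` guards the multivariable Cox fits;
below roughly 15 subjects per node the fits are unstable and the package
refuses to split (reason code `"minsample"`).

## Time slicing semantics

A record at offset `d` days belongs to slice `k` (centre
`c_k = (k-1) * period`) iff `c_k - left_interval*period <= d <
c_k + right_interval*period` — closed on the left, open on the right; with
`left_interval + right_interval <= 1` windows cannot overlap, so
membership is unique. The window edges had to be fixed by convention and
the half-open choice makes the slice-boundary case deterministic. When two
records of a patient fall into one window the record nearest the centre is
kept (tie: the earlier date), since it best represents the slice. Records
in no window are dropped; slice indices with no records are omitted from
the assembled object rather than stored empty.

Missing covariate values can be filled per slice ("the average level"):
continuous covariates take the within-slice mean; binary covariates take
the within-slice majority value, because a fractional fill would break the
0/1 coding the screen and the splits rely on. Complete columns pass
through bit-identical.

## Dichotomization

Continuous markers (more than two distinct values pooled across slices)
are binarized at the threshold maximizing Youden's J on a time-dependent
ROC at `predict_time`. The ROC is the cumulative-case / dynamic-control
form with Kaplan-Meier estimates of the case and control probabilities:
for threshold `c`, `TPR(c) = (1 - S_c(t)) P(X > c) / (1 - S(t))` and
`FPR(c) = S_c(t) P(X > c) / S(t)`, where `S_c` is the KM curve among
subjects with marker above `c`. Estimates are clamped to [0, 1]; AUC is
the trapezoidal integral of the curve anchored at (0,0) and (1,1). Ties in
J resolve to the smallest threshold, and a value exactly equal to the
cutoff codes to 0 (the rule is strictly "greater than").

Cutoffs are estimated on slice-1 data only and applied uniformly to all
slices. Re-estimating per slice would let the *meaning* of a variable
change along a path, destroying the interpretability the method exists
for; the cost is that a cutoff optimal at baseline may be mildly
suboptimal later.

## Tree construction details

* Node ids are assigned in level order (breadth first), root = 1, and the
  child with split-variable value 0 precedes the value-1 child; ids are
  therefore contiguous and deterministic given input and configuration.
* Selection is re-run at every slice even along carry-forward lineages, so
  a subgroup that was homogeneous yesterday can split tomorrow — including
  on the same variable, when members' values have progressed.
* Children live one slice later than their parent and contain exactly the
  parent members with a record at that slice; patients lost to follow-up
  or past their endpoint silently leave the tree, and a parent whose
  members all disappear simply has no children.
* Only binary (two-way) splits are supported; configurations requesting
  more categories are rejected at validation.
* A re-zeroing utility (`match_subgroup`) restarts each patient's clock at
  the first slice where chosen covariates take chosen values; retained
  slices keep their relative offsets, so a cohort already matching at
  slice 1 round-trips unchanged.

## Downstream analyses

Node-versus-node and treatment-arm comparisons are ordinary KM/log-rank
analyses on residual survival at the relevant slice. The transition table
cross-tabulates treatment at a node's slice against the node occupied at
the next slice; "Missing follow-up" pools true dropout with members whose
follow-up ended before the next window — the data cannot distinguish them.

Per-slice discrimination uses Harrell's C on patients pooled from all
same-slice nodes of size at least `min_node_size`. Turning node membership
into a scalar risk requires a choice the method itself does not dictate:
nodes are ranked by median residual survival, an unreached median ranking
as the best prognosis, with ties broken by the annotated survival rate,
and each patient inherits their node's (negated) rank. Since the C-index
depends only on orderings this is equivalent to any monotone score with
the same node ranking; other scoring rules (e.g. model-based risk) would
give different values, which is why cross-implementation parity of
C-indices should not be expected beyond the ordering they induce.

## The synthetic cohort generator

`simulate_cohort()` emulates the target data schema: per-patient visit
dates on a jittered fixed schedule (ISO dates from a 2015-01-01 epoch),
binary covariates evolving by a per-visit Markov transition, continuous
markers by a random walk, outcome-independent treatment flags, and death
times drawn from a piecewise-constant proportional-hazards model whose
hazard is refreshed at each visit (`baseline_hazard * exp(sum(effect *
x))`). Follow-up ends at death, per-visit dropout or administrative
censoring; every emitted row carries the residual time to that endpoint
and a per-patient constant event indicator. The defaults — 300 patients,
90-day visits with 7-day jitter, a one-year-median baseline hazard
(`log(2)/365` per day), 10% per-visit dropout — describe a plausible
advanced-cancer follow-up study and are used as-is by the test suite's
planted-structure checks (with a planted hazard ratio of 3 where a strong
effect is needed).

What the generator deliberately does **not** emulate: informative
censoring, measurement error in markers, calendar effects, correlated
covariates beyond what the planted structure induces, and realistic
marginal distributions of any particular disease. Passing tests therefore
demonstrate that the machinery recovers known structure under clean
proportional-hazards data, not that it will extract signal from any real
cohort.

## Numerical choices

* Cox fits use the Efron approximation for tied event times (day-grained
  clinical data tie heavily; Efron is markedly less biased than Breslow
  there), tolerance 1e-9 on coefficients, at most 100 iterations.
* Monotone likelihood (perfect separation) is flagged via the fitter's
  infinite-coefficient diagnostics; backward elimination drops the
  offending covariate with a warning rather than failing.
* KM medians use the smallest time with S(t) <= 0.5; survival rates are
  right-continuous step evaluations, extending the last estimate beyond
  the final observed time.
* AIC ties in collinearity pruning, J ties in cutoff selection and
  importance ties in split choice all resolve by input order or smallest
  value — stable, seed-free rules, so rebuilt trees are bit-identical.
* Empty Cox models are legal objects (null-model log-likelihood, AIC =
  -2 logL) so that "elimination removed everything" is an ordinary result.

## Problem sizes in the test suite

The suite validates the statistics against hand and brute-force oracles on
toy sets (5–10 subjects), calibrates type-I behaviour at n = 400 over 200
replicates, recovers planted parameters at n = 2000, and checks
planted-structure recovery of the tree over 100 seeded cohorts of 300–400
patients (two slices each). These sizes give the binomial success
thresholds used (e.g. at least 95/100 root-split recoveries) comfortable
margins under the stated effect sizes while keeping a full run around two
minutes.

## Known limitations

* Only right-censored, single-event outcomes; no competing risks, no
  interval censoring, no recurrent events.
* Slicing is purely day-based; calendar-aware schedules (monthly visits of
  varying length) must be approximated by a fixed period.
* Treatment comparisons are descriptive — no confounding adjustment; the
  transition table in particular reflects association, not causation.
* The univariate screen tests dichotomized covariates only; ordinal
  structure beyond two levels is out of scope.
* With small `minsample` and many slices, late nodes hold few patients and
  their annotations (medians, rates) are noisy; read deep paths with the
  sample sizes in view.
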