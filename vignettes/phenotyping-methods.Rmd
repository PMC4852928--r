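---
title: "Deriving and validating EHR phenotyping algorithms with codephen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating EHR phenotyping algorithms with codephen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codephen)
```

## The problem

Primary-care records code everything — diagnoses, prescriptions, test
results — as short hierarchical clinical codes, and the same clinical
fact can surface under many codes (each dosage or formulation of a drug
has its own). A phenotyping algorithm decides, from this bag of coded
events, whether a patient has a condition. `codephen` derives such
algorithms from data instead of expert code lists: a linked
secondary-care system supplies a gold-standard diagnosis for the subset
of patients present in both systems, and the package learns which
primary-care code patterns predict it. Rheumatoid arthritis (RA) is the
worked condition throughout, but nothing in Phases 1–3 is specific to RA.

## Phase 1 — relative-frequency screening

For code $x$, with $N_{x,1}$ RA carriers and $N_{x,2}$ non-RA carriers
among all $N$ labelled patients,
$$\mathrm{rFeq}(x) = p(\mathrm{RA}\mid x) - p(\mathrm{nonRA}\mid x)
 = \frac{N_{x,1} - N_{x,2}}{N}.$$
Codes with $\mathrm{rFeq} > 0$ are selected. Presence means an
occurrence count of at least one; feature values everywhere else in the
pipeline remain counts, because the final decision tree thresholds on
occurrence numbers.

Two readings of the statistic coexist in practice: dividing by the whole
population (as above) or by the code's carriers,
$(N_{x,1}-N_{x,2})/(N_{x,1}+N_{x,2})$. Both are implemented behind the
`denominator` flag of `screen()` (default `"population"`), and both are
positive exactly when $N_{x,1} > N_{x,2}$, so the *selected set* is
identical — a property the test suite verifies by brute force on random
matrices. Note a consequence of the population denominator with
imbalanced classes: a code carried at equal *rates* by cases and controls
has more control carriers in absolute terms and screens strongly
negative, so screening is conservative for common uninformative codes
and lets rare case-enriched codes through. No multiple-testing
correction is applied; screening is deliberately a permissive univariate
filter, and selection strictness comes from the later phases.

## Phase 2 — aggregation and forest ranking

**Aggregation.** Selected codes act as seeds (`expand_seeds()`): a seed
recruits every dataset code sharing its hierarchy prefix, plus every
code with the same active ingredient when an ingredient map is supplied.
The prefix depth defaults to 3 characters for medication codes
(lower-case chapter letter) and 4 for diagnosis codes, reflecting where
those hierarchies converge; both are overridable. Overlapping groups are
merged transitively (`merge_groups()`) into disjoint variables — the
union-find result is tested against graph connected components. The
similarity notion ("same drug at another dose", "tests performed
together") is operationalised here purely as prefix + ingredient; no
code-description text is consulted. `evaluate_expansion()` guards a
proposed regrouping by comparing out-of-bag accuracy before and after,
accepting it only if accuracy does not drop (tolerance 0 by default).

**Forest ranking.** `fit_forest()` grows an ensemble of two-class
Gini-impurity trees. Each tree trains on a uniform random 2/3 subsample
*without replacement* (not a bootstrap); the held-out third provides the
out-of-bag accuracy via majority vote. Splits are threshold tests
`count >= t` with candidate thresholds at midpoints between distinct
observed values; at each node a random `sqrt(p)` feature subset
competes, and ties in impurity decrease break by lower threshold then
feature name. A feature's importance is its summed impurity decrease
weighted by the fraction of training patients reaching the split,
averaged over trees. The trees are implemented natively so that split
enumeration, importance accounting and tie-breaking are fully specified;
the suite checks single-tree importances against exhaustive split
enumeration on small data, and the overall ranking against an
established forest implementation as an independent cross-check only.

Defaults not dictated by the method description are stated in
`forest_config()`: 500 trees, unlimited depth, `min_leaf` 1. The
bundled benchmark and pipeline use 50–100 trees, which the recovery
experiments show is ample at the benchmark's signal strength.

Gini importance is frequency-biased: a rarely recorded dose-variant
code carries little importance on its own even when its group is highly
predictive, while a common noise code can earn small spurious
importance. Ranking is therefore done on the *aggregated* variables, and
the package's recovery guarantees are stated at group level for the
forest (and at raw-code level for screening, which operates before
aggregation).

## Phase 3 — rule induction

`induce_tree()` grows a single binary tree by greedy recursive
partitioning:

* per feature, the best threshold by information gain, charged an MDL
  correction of $(\log_2 c + \log_2 m)/n$ for choosing among $c$
  candidate cuts and $m$ features — the continuous-attribute refinement
  of late C4.5 releases, extended to the attribute choice. Without the
  attribute term, pessimistic pruning alone left spurious structure on
  label-free noise; with it, pure-noise training sets collapse to a
  single leaf in the large majority of runs while recovery of genuine
  rule structure is unaffected (both are measured in the suite);
* candidates with at least average gain compete on gain ratio
  (gain divided by the entropy of the branch-size split), the classic
  admissibility convention that tempers the ratio's preference for
  unbalanced splits;
* ties break deterministically by feature name then lower threshold;
  no randomness is used anywhere in induction;
* nodes become leaves when pure, smaller than `2 * min_leaf`
  (default `min_leaf = 5`), or without an admissible split; a
  single-class input yields a single majority leaf rather than an error.

Pruning is bottom-up pessimistic error pruning: a subtree collapses to a
leaf when the leaf's predicted error count, $N \cdot U_{cf}(E, N)$, does
not exceed the sum over its leaves. $U_{cf}$ is the binomial upper
confidence limit implemented as `qbeta(1 - cf, E + 1, N - E)`, which
reproduces the canonical special cases (e.g. $E = 0$ gives
$1 - cf^{1/N}$); the confidence factor defaults to 0.25, smaller values
pruning harder. Branch grafting is not performed — pruned trees remain
proper subtrees, which keeps the guarantee that unpruned training
accuracy is never below pruned (tested).

`extract_rules()` flattens each root-to-leaf path into one if–then rule;
the ruleset is mutually exclusive and exhaustive, first-match evaluated,
and functionally identical to the tree on every input (verified
exhaustively over small count grids). Rules serialise to a
human-readable text format that round-trips byte-identically.

## The RA rule engine

The eight published predictors are configuration, not code: seven
counted code groups (QOF RA register codes, psoriatic-arthritis and
alternative-arthropathy exclusions, prednisolone, methotrexate,
sulphasalazine, leflunomide) plus `INTENSITY_RA`, a severity class
derived as the lowest-numbered (most severe) matching level — 1
sero-positive, 2 RA classification codes, 3 related conditions, 4
sero-negative, 9 no RA history. The derivation is monotone: adding codes
never moves the class toward 9.

The original publication presents its decision tree only as a figure, so
exact split thresholds are not machine-readable. The engine is therefore
configuration-driven: `ra_default_ruleset()` encodes the stated logic —
psoriatic-arthritis codes exclude RA outright; alternative-arthropathy
codes without RA evidence exclude RA; a QOF code or severe intensity
(class 1–2) plus any DMARD/prednisolone evidence classifies RA — with
all thresholds at presence (`>= 1`), and any transcribed or induced
ruleset can be loaded in its place. The bundled code lists are
*synthetic placeholders* aligned with the simulator's planted prefixes;
real deployments supply locally curated lists via
`read_ra_predictors()`.

## Validation under incomplete linkage

`scenario_analysis()` works on the 3×3 linkage table with cells
$a,b,e$ (predicted RA × reference RA / not RA / no record) and $c,d,f$
(predicted not RA). Worst case treats the unlinked flagged patients $e$
as false positives: sensitivity $a/(a+c)$, PPV $a/(a+b+e)$, specificity
$(d+f)/(d+f+b+e)$. Best case treats them as true positives treated
elsewhere: sensitivity $(a+e)/(a+e+c)$, PPV $(a+e)/(a+b+e)$, specificity
$(d+f)/(d+f+b)$. The no-GP-data row is reported but excluded from all
denominators — the convention recovered by checking which arithmetic
reproduces every published percentage of the comparator tables. One
published table prints a worst-case sensitivity of 80% where the
convention (and the same publication's running text) gives 83.3%; the
text value is taken as authoritative and the table figure treated as a
typo. Another table's worst-case PPV does not match its own printed
cells under any convention tried; it is not reproduced as a target.
The ambiguous published best-case prevalence figure is likewise not
implemented as a named output.

The bracketing guarantee is exactly as strong as the scenarios'
assumption: latent-truth PPV over the flagged patients always lies in
[worst, best], and latent sensitivity does so over the linked patients
plus the unlinked *flagged* stratum (the population the scenarios
impute). Unlinked patients the algorithm did not flag are outside both
scenarios by the table convention, so false negatives hidden there are
not bounded — a genuine limitation of the methodology, made explicit
here and exercised on simulated data with known latent truth.

`prevalence_by_year()` reports, per calendar year, the flagged fraction
of the registered cohort using only events dated up to that year's end.
Under this cumulative definition the curve is non-decreasing for
monotone rulesets; exclusion rules can in principle lower it.

## The synthetic simulator

`simulate_ehr()` emulates exactly the structure the pipeline exploits:
per-patient RA status Bernoulli(prevalence, default 0.17 as observed in
linked rheumatology cohorts of this kind); planted code groups whose
presence probability differs by class, with member codes sharing a
3-character prefix (so prefix aggregation has structure to find) and
occurrence counts Poisson with floor 1 (the simplest count model —
nothing in the method depends on the count distribution beyond
integer-valued features); noise codes drawn identically in both classes
(presence 0.15, mean count 2); and Bernoulli linkage (default 0.8), with
labels emitted only for linked patients while latent truth is echoed for
every patient. Dates are uniform over 2000–2012. Identical seeds give
byte-identical output, and generation does not disturb the caller's RNG
stream.

What the simulator does *not* emulate — and what passing tests therefore
do not establish about real data: longitudinal disease trajectories,
calendar-time drift in coding practice, informative (non-random)
linkage, correlated noise codes, and realistic code-frequency
distributions. The benchmark (`benchmark_sim_config()`: 2,000 patients,
six planted groups at presence 0.6 in cases vs 0.05 in controls, 30
noise codes) is a strong-signal regime chosen to test *recovery
machinery*, not a claim about real-world effect sizes.

## Numerical and design choices

* All name/code ordering uses radix (C-locale) sorting, so output is
  identical across platform locales; every documented tie-break is
  deterministic.
* Floating-point ties in split scores are compared at tolerance 1e-12;
  pruning comparisons at 1e-8.
* Zero denominators in any accuracy metric yield `NA` for that metric
  only, never an error; empty cohorts report a flagged fraction of `NA`.
* Repeat codes on the same date are counted as separate events (the
  source description does not say whether to deduplicate; counting all
  is the documented choice).
* Patients present only in the label file are kept as all-zero rows,
  mirroring the no-GP-data stratum of the linkage tables.
* `run_pipeline()` passes the top 40 ranked variables (capped at the
  number of groups) to rule induction by default.
* Problem sizes in the bundled experiments (2,000-patient benchmark,
  20-seed recovery loops, 100-tree forests, 10-seed bracketing) were
  chosen as the smallest at which the measured properties are stable.

## Known limitations

Single-linkage prefix aggregation can chain unrelated codes through a
shared prefix; the ingredient map is the precise tool where it matters.
The forest does no class weighting, so very low prevalence shifts OOB
accuracy toward the majority class — rely on the importance ranking, not
raw OOB, in that regime. The rule engine implements the prevalence
algorithm only; defining *incident* (new-onset) cases needs different
predictors (medication evidence accumulates with disease duration) and
is out of scope.
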