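---
title: "Phenotype profiles and dose-reduction prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype profiles and dose-reduction prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodose)
library(dplyr)
```

## The problem

When a drug is prescribed for the first time, the dose that works for one
patient can be too high for another. Drugs metabolized by cytochrome P450
enzymes are particularly prone to this inter-individual variability, and a
dose *reduction* shortly after a first prescription is often a proxy for an
adverse or excessive response. `phenodose` implements a pipeline that asks:
can the phenotypic history already present in a patient's electronic health
record — diagnosis codes, conditions mentioned in clinical notes, and
laboratory test orders — predict, before the first prescription, that the
dose will need to be reduced?

The pipeline has four stages, each usable on its own:

1. **Interval extraction** — find pairs of consecutive same-ingredient
   prescriptions and label them reduction / increase / continuation.
2. **Feature construction** — collect every phenotype observed strictly
   before the first prescription of each interval, expanded through the
   is-a hierarchies of the diagnosis and condition vocabularies.
3. **Phenotype profiles** — per drug (or drug class) and outcome, keep the
   features significantly over- or under-represented in case intervals
   relative to continuations, via a hypergeometric filter cascade.
4. **Classification** — balanced random forests over the profile features,
   evaluated by 10-fold cross-validation with per-fold feature selection
   and by holding out the last calendar year.

## Dose-change intervals

An interval is delimited by two prescriptions $d_1$ (at $t_1$) and $d_2$
(at $t_2$) of the same ingredient for the same patient, with the same route
of administration and reported unit, with no other same-ingredient
prescription strictly between, and with $t_2 - t_1 \le 20$ days. Only
*consecutive* prescriptions can form an interval, which enforces the
no-third-prescription condition by construction.

A dose is a (quantity per administration, administrations per day) pair.
The label compares $d_2$ with $d_1$:

* quantity decreases and frequency does not increase (or vice versa) →
  **reduction**; symmetric rule for **increase**;
* both unchanged → **continuation**;
* one component up and the other down → the daily dose
  $\text{quantity}\times\text{frequency}$ decides; an exact tie is a
  continuation. Dose values are entered quantities, not measurements, so
  comparisons are exact with no tolerance.

Outlier trimming removes all intervals shorter than 6 hours, then the
longest intervals until 10% of the pool is gone (if the short side already
reaches 10%, nothing more is removed). The short-first reading keeps the
rule deterministic; ties on the long side are broken by duration, patient
id, then $t_1$. Trimming is applied within each ingredient's pool, because
the downstream analysis is per drug; pools with fewer than ten intervals
get no long-side trimming since a 10% quantile is meaningless there.

Continuation intervals are kept only for (patient, ingredient) pairs that
never experienced a dose change for that ingredient, so the control arm
represents stable dosing; reductions and increases are always kept. We
scope "never changed" per ingredient rather than per patient — a change on
an unrelated drug should not disqualify a patient's stable drugs — and
expose the alternative as a configuration switch.

## Features

For each interval, the feature set is every `(type, id)` pair observed in
the patient's record strictly before $t_1$ — events at exactly $t_1$ are
excluded. Features are binary presence indicators: counts, recency and
temporal order are deliberately not encoded (a documented limitation of
this representation). The lookback window defaults to the entire available
record; `max_lookback_days` can restrict it.

Diagnosis and condition features are *expanded*: an interval associated
with a concept is automatically associated with all of the concept's is-a
ancestors. Laboratory order codes carry no hierarchy and are never
expanded. Expansion lets a specific finding support statistics at every
level of generality; the `elim` step of the profile cascade later removes
the redundant general levels.

## Phenotype profiles

For one subject (a drug or drug set) and outcome, each feature gets a
$2\times2$ interval-level table: $a$/$b$ case intervals with/without the
feature, $c$/$d$ continuation intervals with/without it. The statistics
are:

* **p-value** — exact one-sided hypergeometric tail, upper
  ($P(X \ge a)$) when the risk ratio is $\ge 1$, lower otherwise. The
  direction-consistent one-sided tail is what lets under-represented
  ("NO"-prefixed) features reach significance.
* **risk ratio** — $\mathrm{RR} = \frac{a/(a+b)}{c/(c+d)}$, with the
  Haldane–Anscombe $+0.5$ correction applied to all four cells when $a$ or
  $c$ is zero, so the ratio is always finite and positive.
* **information content** — $\mathrm{IC} = -\log_2 f$ where $f$ is the
  fraction of corpus intervals containing the feature. IC 0 means
  ubiquitous; high IC means rare.

The filter cascade then applies, in order: (1) uncorrected $p < 0.05$;
(2) remove $0.5 < \mathrm{RR} < 2$; (3) remove features whose IC falls in
the first or fourth quartile of the per-type IC distribution (for
conditions a fixed band such as $4.25 < \mathrm{IC} < 12.75$ can be
configured instead); (4) Bonferroni-corrected $p < 0.05/m$; (5) `elim`
pruning: a feature is removed when it is a strict ancestor of another
tested feature with an equal or smaller p-value, decided in a single pass
against the original p-values. Lab features skip `elim` (no hierarchy).
Per-step survivor counts are recorded on every profile. An empty profile
is a valid outcome and means the record holds no usable signal for that
drug.

Two choices here deserve justification, because the cascade's internals
are underdetermined at small scale:

* **Bonferroni $m$** defaults to the number of features *tested* for the
  subject and outcome, not the number surviving the earlier screens.
  Dividing $\alpha$ by a data-dependently shrunken $m$ loosens the
  threshold exactly when earlier screens pass flukes, and measurably
  breaks family-wise error control at a few hundred intervals per arm;
  $m = $ all-tested is the classical bound. The survivor-based count
  (`bonferroni_scope = "post_ic"`) remains available; at corpus scales of
  $10^5$ intervals the two differ little because true effects dominate.
* **The IC quartile band** is computed on the IC distribution of all
  tested features of that type (`ic_reference = "all"`), not on the
  post-RR survivors. With few survivors — the typical desk-scale situation
  — an interquartile filter on the survivors themselves mechanically
  discards half of them regardless of commonness, which defeats the
  filter's purpose (excluding too-common and too-rare features relative to
  the corpus). The band is inclusive so that tied ICs survive; the fixed
  condition band, when configured, is strict as stated.

The reduced profile variant keeps the top 100 features per type by
p-value (ties: $|\log \mathrm{RR}|$ descending, then feature id); display
order is always $|\log \mathrm{RR}|$ descending, with negative
associations prefixed `"NO "`.

## Classification and evaluation

Subjects are eligible with at least 150 case and 150 control intervals, a
non-empty profile, and at most 55,000 total prescriptions (high-volume
drugs would dominate the drug-set analyses). Intervals are encoded as a
binary matrix over exactly the profile's features; class balance is
enforced by seeded undersampling of the majority class. The classifier is
a random forest with 100 trees, unlimited depth and
$\lfloor \log_2 m + 1 \rfloor$ candidate features per split; it is trained
single-threaded so results are bitwise reproducible.

Cross-validation uses 10 stratified folds drawn after balancing
(stratification is nearly neutral on balanced data but prevents degenerate
folds at small $n$; per-fold re-balancing is a config switch). Crucially,
**the entire profile cascade runs inside each fold** on the nine training
folds only — feature selection never sees a test interval, and each
evaluation records the interval ids its profiles were built from so the
no-leakage property is asserted by instrumentation, not assumed. AUC and
the unweighted two-class precision/recall are averaged over folds; the
F-measure is the harmonic mean of the aggregated precision and recall, and
instance counts are reported on training data only.

The temporal validation trains on intervals whose $t_1$ falls before the
cutoff year (default 2014) and tests on the cutoff year, with both sides
balanced independently and the profile built on the training side only. A
subject whose training-side profile is empty is reported as skipped, and
rendered as a dash in result tables.

## The synthetic cohort generator

Real prescription warehouses are proprietary, so the package ships a
seeded generator whose output has recoverable ground truth. It emulates:

* per-patient prescription chains (default 2–4 prescriptions) with
  lognormal gaps calibrated to mean 3.64 days, sd 4.41 days;
* per-pair outcome labels with default probabilities 0.18 (reduction) and
  0.21 (increase) — the observed interval shares in the motivating
  corpus — realized as unambiguous single-component moves on a discrete
  dose grid;
* three feature streams with events placed strictly before each pair's
  $t_1$, drawn with prevalences conditioned on the pair's label: planted
  features have distinct case/control prevalences, noise features a
  label-independent prevalence drawn log-uniformly on $[0.01, 0.6]$ (so
  IC spreads over a wide band);
* toy is-a DAGs (rooted trees with optional shallower cross-links) for
  the diagnosis and condition vocabularies; labs get none;
* ADR condition mentions inside intervals at Poisson rates 1.0 per
  reduction interval and 0.5 per continuation, a planted disproportion of
  2 at a magnitude where the estimator's sampling error is a few percent.

Because history features accumulate over a patient's record, draws planted
for one pair also appear in later pairs' histories within the same chain.
The two fixed validation conditions therefore use two-prescription chains
(one interval per patient): `sim_config_null()` (no signal, 200 noise
features per type, ~500 intervals per arm) and `sim_config_planted()`
(five planted features per stream, ~1,000 intervals per arm; prevalences
0.2 vs 0.05 for the RR-4 recovery condition and 0.3 vs 0.05, RR 6, for the
classifier condition). Planting five features in *each* stream, rather
than five overall, exercises every per-type filter path; it also matters
quantitatively: five independent binary features at the RR-6 prevalences
bound any classifier's AUC at about 0.85 (the Bayes-optimal score is the
count of present features), whereas fifteen support AUC ≈ 0.97, so the
classifier checks test the classifier rather than the generator's
information ceiling.

What the generator does **not** emulate: disease progression, co-written
correlated features, visit structure, coding drift over calendar time, and
informative missingness. Passing the planted-recovery and classifier
checks therefore shows the machinery is correct and leak-free, not that
comparable AUCs are attainable on real EHR data.

## Numerical and degenerate-input choices

* Timestamps are ISO-8601 in files, UTC POSIXct at second resolution in
  memory; all temporal comparisons are strict (`<`, never `<=`) unless a
  window is stated as closed (the ADR mention window $[t_1, t_2]$).
* Feature ids present in events but absent from an ontology are valid
  isolated leaves with no ancestors, reported once per code.
* The hypergeometric implementation is `stats::phyper`; an independent
  exact enumerator (`hypergeom_tail_exact`, 64/128-bit integer
  arithmetic) ships with the package and the test suite sweeps every
  $2\times2$ table with $N \le 60$ against it.
* Constant classifier scores (e.g. from an empty per-fold profile) score
  AUC 0.5 by convention; undefined precision counts as 0.
* All randomness (simulation, balancing, folds, forests) flows from
  explicit integer seeds; two runs with the same seeds are bitwise
  identical, including serialized outputs.

## Validation problem sizes

The shipped validation (tests and `scripts/acceptance.R`) uses: an
exhaustive oracle sweep of ~635,000 contingency tables; 200 random DAGs
(≤ 50 nodes) for `elim`; 100 null corpora at ~500 intervals/arm for the
family-wise error rate; 20 planted corpora at ~1,000 pairs/arm for
recovery and RR fidelity; and 10 seeds of the strong-signal corpus for
cross-validation, permutation-null, leakage and temporal-holdout checks.
These sizes make each property a stable statistical statement rather than
a single-seed anecdote while keeping a full run in a few minutes.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_config_planted(seed = 42))
intervals <- extract_intervals(sim$prescriptions)
features <- build_feature_dataset(intervals, sim$events, sim$ontologies)
profile <- build_profile(intervals, features, sim$ontologies,
                         subject = "drugA")
glance(profile)
cv <- cross_validate_10fold(intervals, features, sim$ontologies,
                            seed = 42, subject = "drugA")
glance(cv)
autoplot(profile)
```

## Known limitations

Drug discontinuations and switches are not detected; co-administration is
not a feature; lab *results* (as opposed to orders) are unused; the
temporal order of history features is not encoded; Holm–Bonferroni is not
implemented (the correction step is a single configurable Bonferroni).
These reflect the scope of the underlying design rather than accidents of
implementation.
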