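---
title: "Machine reading of the fossil record: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Machine reading of the fossil record: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

paleomine is a desk-scale machine-reading pipeline for paleontological
literature. It takes token-level documents, finds mentions of taxa, geologic
formations, time intervals and places, proposes relation candidates between
co-located mentions, scores every candidate and every aggregated entity-level
assertion with a probability from a learned factor-graph model, assembles the
accepted assertions into a probabilistic fossil-occurrence database, and
computes the macroevolutionary statistics used to compare such a database
against a reference: range-through diversity, per-capita origination and
extinction rates, genus range offsets, and detrended rank correlations.

This vignette records the model, its assumptions, the tunable parameters, and
the numerical and design decisions a maintainer needs.

## The probabilistic model

Every extraction decision is a Boolean random variable in a factor graph with
two variable strata:

* **mention-level** variables, one per relation candidate (a type-compatible
  pair of entity mentions in one sentence or one table row), and
* **entity-level** variables, one per distinct (relation, subject, object)
  tuple, aggregating its mentions across all documents.

Factors contribute log-linear potentials, each tied to a weight shared across
all factors with the same identity:

* a **unary feature** factor per (candidate, feature): $w_f \cdot x_v$, with
  one weight per distinct feature string;
* an **OR-style aggregation** factor per entity tuple linking it to all its
  mention variables: $w_a \cdot \mathbf{1}\{x_e = \max(x_{m_1},\dots,x_{m_k})\}$
  — an entity assertion should be true exactly when some mention of it is;
* a **hierarchy implication** factor for each pair of entity-level age
  assignments of one formation whose intervals are nested (the Carboniferous
  contains the Namurian): $w_r \cdot \mathbf{1}\{x_a = 0 \lor x_b = 1\}$ from
  the coarse interval to the fine one. The implication is statistical, not
  logical; its single shared weight is estimated from data when entity-level
  evidence exists.

The unnormalised log-probability of a full assignment is the sum of the
log-potentials, i.e. an exponential-family model. The three functional forms
are the package's own minimal realisation — indicator potentials linear in a
tied weight — chosen so that the model stays in the classical exponential
family and the unary-only case collapses to logistic regression.

We deliberately realise the narrative "three layers" as two variable strata
plus aggregation factors: per-document relation candidates are the mention
variables themselves, and the cross-document layer is the entity stratum.

## Distant supervision

Labels come from a seed knowledge base rather than hand annotation. A
variable's entity tuple is labelled:

* **positive** if it is in the seed KB, or, for formation ages, if the seed
  holds the same formation with a hierarchically related interval (ancestor
  or descendant);
* **negative** if the subject appears in the seed KB for that relation with
  only disjoint objects (closed world per subject), or — for the two
  taxonomic-opinion relations — if the exact pair is asserted in the seed
  under the *other* opinion relation, since a nested placement and a
  synonymy between the same pair of names are mutually exclusive;
* otherwise **unlabeled**: it participates in inference but not in the
  learning objective.

Labels are decided once per entity tuple and applied to the entity variable
and all of its mention variables, so aggregation and implication factors can
become fully observed and their rule weights learnable. Negative subsampling
(`negative_rate`, default 1) is likewise per entity tuple.

## Learning

Weights maximise the L2-penalised pseudo-likelihood of the evidence
variables: the sum over evidence variables of the log conditional probability
of the observed value given the rest, restricted to factors whose entire
scope is evidence. Each conditional is logistic in the weights, so the
objective is concave; it is maximised by L-BFGS from a zero start and is
exactly penalised logistic regression when only unary factors touch the
evidence (the unit tests cross-check this case against an independent ridge
logistic fit). Rule weights with no fully observed factor keep their
defaults: 4 for aggregation (an entity follows its mentions with odds
$e^4 \approx 55$) and 1 for the interval implication.

The penalty `l2` (default 0.1) is applied to the summed log-likelihood, not
the mean; `l2 = 0.01` is used in the recovery experiments. If supervision
yields only one label class — a complete seed KB over a noise-free corpus
produces no negatives — `learn_weights()` refuses, and the pipeline records
the condition, keeps the default weights, and relies on evidence clamping,
which is exact in that situation.

## Inference

Marginals come from single-site Gibbs sampling in fixed variable order with
evidence clamped, compiled in C++. Two unbiased estimators of each marginal
are accumulated over the post-burn-in sweeps:

* `rao_blackwell` (default): the average of the full-conditional probability
  used each time the variable is resampled;
* `frequency`: the plain fraction of sweeps with value 1.

Both target the same distribution; the Rao-Blackwellised average has much
smaller Monte Carlo variance (for an isolated unary variable it is exact in
one sweep), which matters because the validation suite demands max-absolute
agreement of 0.01 with exact enumeration across hundreds of marginals. An
enumeration oracle (`exact_marginals()`, up to 20 free variables) computes
the same exponential-family marginals by direct summation and serves as the
reference in tests.

The sampler-validation ensemble (`random_factor_graph()`) draws sparse
simple hypergraphs — about 1.2 factors per variable, no repeated factor
scopes — with unary weights uniform on $[-2, 2]$ and rule couplings uniform
on $[0, 1]$. Rule couplings are kept non-negative and moderate deliberately:
the model family the pipeline constructs only ever uses monotone,
non-negative rule couplings, and a single 20,000-sweep chain cannot estimate
marginals of strongly coupled or frustrated systems to 0.01; the
strong-coupling limit (weights at ±2, frustrated unaries) is exercised
separately with 200,000-sweep chains, where both estimators agree with
enumeration.

## From marginals to an occurrence database

Entity tuples with probability at or above `tau` (default 0.95 — a
deliberately conservative, essentially arbitrary operating point) enter the
database. Occurrences then follow two editorial rules:

* **best age**: each formation's age is the accepted interval with the
  shortest duration in Myr (our operationalisation of "most precise"), ties
  broken by most recent publication year, then higher probability, then
  name; occurrences carry this formation-level age rather than per-document
  stated ages;
* **formal unit**: a taxon only yields an occurrence if it is tied to a
  formation that has an accepted age; taxa in documents without a dated,
  formally named unit yield nothing.

Age inference conditions on the unit only, not on (unit, location) pairs;
at this scale formations are not homonymous across regions, and the choice
is recorded here because it is genuinely open.

Taxonomic opinions are resolved before range building: for each name the
governing opinion is the most recent (ties: majority, then lexicographic),
synonym chains resolve transitively to a senior name, and synonym cycles are
broken by dropping the most recent cycle-closing opinion, logged in the
result's `dropped` attribute and never fatal.

## Time, bins and range statistics

The packaged interval table is an ICS-style Phanerozoic hierarchy
(eon → era → period → epoch → stage, boundary ages in Ma) plus the regional
stage Namurian parented directly to the Carboniferous; regional stages may
overlap standard epochs, so sibling-overlap validation applies only within
(parent, rank) groups. Default analysis bins are the 34 epoch-level spans
(mean duration ≈ 15.8 Myr); an explicit bin file can replace them, e.g. with
a finer 52-bin scheme, since published bin sets are rarely enumerated.

Interval and bin membership is half-open in age: a bin covers
$(t_{young}, t_{old}]$ Ma, so a point age on a shared boundary belongs to
the younger bin, with age 0 assigned to the youngest bin. An occurrence is
binned only if its interval overlaps exactly one bin; multi-bin occurrences
(e.g. period-level ages under epoch bins) are dropped from range building
and counted, a conservative alternative to spreading them across bins. The
resolution filter (`min_rank`, default epoch) additionally removes coarse
records before ranging.

Per-capita rates use boundary crossers: for bin $i$, with $N_{bt}$ the
ranges crossing both boundaries, $N_b$ those crossing the bottom and $N_t$
those crossing the top, origination is $p = -\ln(N_{bt}/N_t)$ and extinction
$q = -\ln(N_{bt}/N_b)$, per interval (a `per_myr` switch divides by bin
duration). Rates are undefined (NA) where $N_{bt}$ or a denominator is 0;
singletons count in diversity but in neither rate. Range offsets between
two databases difference bin-midpoint ages in Ma for shared genera, with a
configurable sign convention (default: first database minus second).
Detrended comparisons take first differences over bins where both series
are defined and correlate them by Spearman rank with the asymptotic
p-value.

## The synthetic corpus

`generate_world()` builds the study world: formations with one true age
(60% stage, 30% epoch, 10% period-level — the latter exercising the
resolution filter), one location and a set of genera; genus ranges anchored
on formation bins; genus → family placements and junior-synonym pairs; and
documents rendering every gold tuple at least once through five or more
sentence templates per relation or as table rows (a quarter of occurrence
facts, default). Noise channels, all drawn from one RNG stream seeded once:

* `corruption_rate` (default 0.02): per-token character substitution or
  deletion, the OCR-style recall-loss mechanism;
* `distractor_rate` (default 0.3): sentences that co-locate entities without
  asserting the relation ("overlies", "is absent from", "is not a synonym
  of") and must come out negative;
* `synonym_rate` (default 0.15): genera carrying a junior synonym that
  repeat mentions sometimes use, forcing the taxonomy-resolution path;
* `coarse_age_rate` (default 0.2): repeat renditions of a formation age
  stating an ancestor interval, feeding the hierarchy implication factors
  and the best-age rule.

The reference conditions are 40 formations, 120 genera and 150 documents —
sizes at which a full run takes seconds while every mechanism (tables,
synonyms, hierarchy, distractors) is well represented. What the generator
does *not* emulate: natural-language grammar, parse ambiguity, layout and
table-detection errors, multilingual text, homonymous formation names, and
document-matching noise. Passing tests therefore demonstrate the
statistical machinery end to end, not robustness to real OCR/NLP output.

Gazetteers for mention extraction are built from the entity vocabulary plus
the seed KB; the vocabulary plays the role of the comprehensive name
dictionaries available to a production reader, which is why candidate
recall does not collapse at small seed fractions — only supervision
shrinks. Extraction is longest-match with leftmost/type-priority
tie-breaks, with a binomial pattern (known genus followed by a lowercase
epithet outside the template stop-list) attaching species epithets.
Taxon-taxon candidate pairs are rank-typed by nomenclature: names in
*-idae* are family-group names, so genus-family pairs are placement
candidates only.

## Validation suite and problem sizes

The shipped tests and the acceptance script recompute, from scratch:

* Gibbs vs enumeration on 100 random graphs of up to 12 free variables at
  20,000 sweeps (burn-in 2,000), max |difference| ≤ 0.01;
* recovery of 6 planted unary weights from 5,000 labelled candidates at
  `l2 = 0.01`: sign agreement for all |w*| ≥ 0.5 and max error ≤ 0.2;
* calibration of 5,000 scored candidates whose 50 template reliabilities
  span the unit interval: every decile's empirical accuracy within ±0.05 of
  its centre;
* brute-force oracles for diversity and rates on 1,000 random range sets,
  plus threshold-monotonicity and conservation identities;
* a zero-noise corpus with the full seed KB read back at precision =
  recall = 1 at `tau = 0.95`, with the assembled occurrences equal to the
  gold set;
* the training-size experiment on the reference corpus: seed-KB fractions
  {0.02, 0.1, 0.5, 1} × 5 replicates, median detrended Spearman rho
  non-decreasing in the fraction — little supervision already buys most of
  the signal, and more buys the rest.

These sizes were chosen so the full suite runs in well under two minutes on
one core while leaving the statistical margins comfortable.

## Known limitations

* Feature templates substitute for dependency-parse features; there is no
  coreference and no part-of-speech tagging, so the feature universe is the
  generator's template vocabulary.
* The learning objective ignores unlabeled variables (no semi-supervised
  term); with very small seed KBs the rule weights may stay at defaults.
* Cross-document aggregation is a hard OR indicator; graded alternatives
  (noisy-OR, counts) were not explored and the choice is flagged for
  sensitivity analysis.
* `infer_unit_age` conditions on the unit name only; homonymous formations
  would need (unit, location) keys.
* Multi-bin occurrences are dropped, not apportioned; with coarse timescales
  this biases ranges toward well-resolved taxa.
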