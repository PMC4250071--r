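# paleomine

Desk-scale machine reading of the fossil record: extract
taxon–formation–age–location assertions from token-level documents with a
distantly supervised factor-graph model, assemble them into a probabilistic
fossil-occurrence database, and validate the result with the standard
macroevolutionary statistics.

The package is aimed at two audiences. Paleobiologists get a complete,
inspectable pipeline for turning literature-style statements ("the Waldron
Formation is Silurian in age", "*Acroceras minor* occurs in the Waldron
Formation", taxon/unit table rows) into occurrence data with per-fact
probabilities, plus the downstream diversity and turnover machinery.
Methodologists get a compact, fully tested implementation of
distant-supervision relation extraction over a Boolean factor graph — tied
weights, penalised-likelihood learning, Gibbs marginals with an exact
enumeration oracle, calibration reports — small enough to read end to end.

## The model

Each candidate assertion is a Boolean variable in a two-strata factor graph:
mention-level variables (one per relation candidate in a sentence or table
row) and entity-level variables (one per distinct subject–relation–object
tuple, aggregated across documents). Factors contribute log-linear indicator
potentials with tied weights *w*:

| factor | scope | log-potential |
|---|---|---|
| unary feature | one mention variable | w·x |
| aggregation (OR) | entity e and its mentions m₁…mₖ | w·1{e = max(mᵢ)} |
| hierarchy implication | nested ages a → b of one formation | w·1{a = 0 ∨ b = 1} |

exp(Σ log-potentials) defines an exponential-family joint. Distant
supervision labels variables against a seed knowledge base (closed world per
subject, hierarchy-aware for ages); weights maximise the L2-penalised
conditional likelihood of the evidence (exactly ridge logistic regression in
the unary case); marginal probabilities come from single-site Gibbs sampling
(compiled, Rao-Blackwellised) checked against exact enumeration. Tuples with
probability ≥ τ (default 0.95) enter the database under two editorial rules:
each formation carries its **best age** (shortest accepted interval, then
most recent publication), and occurrences require a dated, formally named
unit.

Downstream, genus ranges over the analysis bins give range-through diversity
and per-capita, per-interval rates from boundary crossers — origination
p = −ln(N_bt/N_t), extinction q = −ln(N_bt/N_b) — plus genus range offsets
in Myr between two databases and Spearman correlations of first-differenced
series.

A synthetic-corpus generator (`generate_world()`) provides the gold worlds
used throughout testing: formations with true ages and locations, a genus
taxonomy with junior synonyms, and noisy documents (token corruption,
distractor sentences, coarse repeat ages, table rendering) in which every
gold fact is expressed at least once.

## A worked example

```r
library(paleomine)

tab <- load_interval_table()   # packaged Phanerozoic hierarchy + epoch bins
tab
#> <interval_table: 149 intervals, 34 bins (538.8 to 0 Ma)>
interval_contains(tab, "Carboniferous", "Namurian")
#> [1] TRUE
interval_midpoint(tab, "Namurian")
#> [1] 324.5

cfg <- pipeline_config(
  world_config = world_config(n_formations = 20, n_taxa = 50, n_documents = 70),
  seed = 42)
run <- run_pipeline(cfg, table = tab)
run
#> <pipeline_run: 70 docs -> 802 mentions -> 421 candidates -> 307 tuples (205 accepted) -> 81 occurrences, 34 genera>
#>   precision 0.922, recall 0.964 vs gold
```

The run report says the 70 noisy documents yielded 421 relation candidates,
307 distinct entity tuples, and 205 tuples at probability ≥ 0.95, of which
92.2% are gold-consistent while 96.4% of the gold facts were recovered.
The accepted tuples become occurrence records carrying each formation's best
age and location:

```r
head(run$occurrences[, c("genus", "formation", "interval", "location", "probability")], 3)
#>   genus        formation          interval       location   probability
#> 1 Goniopecten  Casthorp Sandstone Holocene       Harfordia            1
#> 2 Neopecten    Dunford Limestone  Early Jurassic Fenvikia             1
#> 3 Stegatherium Fardon Limestone   Asselian       Vercombeia           1

run$diversity[14:17, c("bin", "N_bt", "N_b", "N_t", "diversity", "p_rate", "q_rate")]
#>     bin  N_bt   N_b   N_t diversity p_rate q_rate
#> 1    14     8     8     9        10  0.118  0
#> 2    15     9     9     9         9  0      0
#> 3    16     9     9     9         9  0      0
#> 4    17     7     9     9        14  0.251  0.251
```

In bin 17, nine genera cross the bottom boundary but only seven range all
the way through, so the per-capita extinction rate is −ln(7/9) ≈ 0.251.
Comparing the machine diversity history against the gold one, detrended by
first differences:

```r
gd <- gold_diversity(run$world, tab)
rd <- rangethrough_diversity(run$ranges, nrow(tab$bins))
keep <- gd$diversity + rd$diversity > 0
first_difference_spearman(ifelse(keep, rd$diversity, NA),
                          ifelse(keep, gd$diversity, NA))
#>     rho  p_value     n
#> 1 0.848 9.18e-10    32
```

so interval-to-interval diversity changes in the extracted database track
the gold signal at rho ≈ 0.85 under these noise conditions.
`training_size_curve()` repeats learning and inference across seed-KB
fractions to show how little supervision the model needs; `autoplot()`
methods draw the diversity/turnover panels, reliability diagrams and the
training curve, and `tidy()`/`glance()` expose learned weights and fit
summaries. A thin CLI (`exec/paleomine`) wraps generate/run/experiment for
shell use.

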