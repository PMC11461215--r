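# hlaimpute

Quantifying the error that haplotype-frequency-based HLA genotype
imputation introduces into molecular mismatch scores, under correct,
incorrect, broad, and pooled ancestry assumptions.

## The problem

Epitope-level histocompatibility algorithms — T-cell epitope counters
(PIRCHE-II style) and surface-exposed amino-acid mismatch counters (Snow
style) — require two-field ("high resolution") HLA genotypes at HLA-A, -C,
-B, -DRB1 and -DQB1, while much clinical typing exists only at the
allele-group level (e.g. `DRB1*15`). Imputation fills the gap: all
haplotype pairs consistent with the observed first-field genotype are looked
up in a population haplotype-frequency table and weighted by the product of
their frequencies,

```
P(h1, h2 | g) ∝ f(h1) · f(h2)   for all pairs with reduce(g(h1, h2)) = g,
```

with the weighted candidate set either kept (multiple imputation, truncated
to the top 99% of cumulative mass), collapsed to its argmax (single
imputation), or restricted to natural haplotypes only (strict imputation;
otherwise a penalized stepwise linkage-relaxation fallback assembles
candidates from locus-block marginals). Epitope scores of a transplant pair
are then frequency-weighted averages over the candidate cross-product, and
imputation error is measured as the log-delta

```
Δ = ln(score_truth + 1) − ln(score_imputed + 1),   noticeable iff |Δ| > 0.1
```

grouped by the individual's true population × the population table assumed
during imputation (matched / mismatched / pooled "SUPER"). The package is
aimed at transplant immunogenetics researchers who want to test imputation
strategies and ancestry assumptions end to end: it ships the full pipeline —
HLA nomenclature layer, frequency-table handling and pooling, cohort
simulation, imputation, both scorer families, and the deviation/metric
evaluation layer — with synthetic-data generators standing in for licensed
frequency tables and production scoring engines, and brute-force oracles
verifying every algorithmic step at desk scale.

## Worked example

Impute one simulated individual under three ancestry assumptions and watch
the mismatched assumption distort the T-cell epitope score:

```r
library(hlaimpute)

freqs  <- generate_frequency_tables(n_populations = 2, n_haplotypes = 40,
                                    alleles_per_locus = 9, sharing = 0.5, seed = 42)
tabs   <- build_scheme_tables(freqs)          # POP01, POP02, SUPER
cohort <- simulate_cohort(freqs[freqs$population == "POP01", ], n = 20, seed = 7)

g_true <- as_genotype(cohort[20, genotype_cols()])
g_low  <- reduce_to_first_field(g_true)

db    <- generate_sequence_db(unique(unlist(strsplit(tabs$haplotype, "~"))), seed = 9)
donor <- as_genotype(cohort[3, genotype_cols()])
pirche_score(g_true, donor, db)
#> [1] 21

for (pop in c("POP01", "POP02", "SUPER")) {
  res <- impute(g_low, prepare_frequency_table(tabs, pop))
  agg <- aggregate_score(res, donor, "pirche", db)
  cat(pop, "imputed pirche:", round(agg$value, 3),
      " log_delta:", round(log_delta(21, agg$value), 4), "\n")
}
#> POP01 imputed pirche: 21  log_delta: 0
#> POP02 imputed pirche: 12  log_delta: 0.5261
#> SUPER imputed pirche: 21  log_delta: 0
```

The individual was simulated from POP01: imputing with the matched table
(or the pooled SUPER table, which contains POP01's haplotypes) recovers the
true genotype and the exact score, while the mismatched POP02 table imputes
a wrong genotype whose score deviates noticeably (|Δ| = 0.53 > 0.1).

The same question at cohort scale is one call:

```r
study <- run_study(n_populations = 2, n_haplotypes = 40,
                   n_per_population = 30, seed = 5)
t(glance(study))
#> n_pairs                         60.0000
#> n_assumptions                    3.0000
#> failure_rate_matched             0.0000
#> failure_rate_mismatched          0.0000
#> mean_allele_mismatch_matched     0.0000
#> mean_allele_mismatch_mismatched  6.7667
#> noticeable_matched               0.0000
#> noticeable_mismatched            0.6625
```

Matched-ancestry imputation recovers every genotype in this small study
(0 of 10 alleles wrong, no noticeable score deviations), while a wrong
ancestry assumption miscalls 6.8 of 10 alleles on average and perturbs 66%
of the epitope scores noticeably. `autoplot(study)` draws the
true-population × assumption heatmaps and `autoplot(study, "reliability")`
the cumulative-percentile deviation curves; `tidy(study)` returns the
per-pair deviation records.

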