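# strainshare

Strain-level analysis of mother-to-infant oral microbiota transmission.

`strainshare` is for microbiome researchers who have an amplicon sequence
variant (ASV) count table from paired mother-infant samples and want to
quantify vertical transmission. Because ASVs resolve single-nucleotide
differences, "the same strain in mother and child" becomes operational: an
ASV detected (count ≥ 1) in both members of a pair is a **shared ASV**. The
package computes, per infant:

- the number of shared ASVs, their percentage of the infant's observed
  ASVs, and their cumulative relative abundance in the infant;
- the same statistics against every *unrelated* mother
  (`n_infants × n_mothers − n_links` profiles), the null that separates
  transmission from cosmopolitan strains, compared by two-sided
  Mann-Whitney U;
- a per-OTU **sharing index**: among pairs where mother or infant carries
  an OTU (ASVs grouped by reference sequence at ≥ 98.5 % identity), the
  fraction of pairs sharing a member ASV — counted at pair level so twin
  mothers enter once per pair;
- a nonparametric clinical-factor screen: Kruskal-Wallis with the rank
  effect size η²\_H = (H − k + 1)/(n − k), Benjamini-Hochberg FDR across
  factors, Steel-Dwass or Mann-Whitney follow-ups;
- origin-aware community profiles: each OTU split into maternally-shared
  and nonshared components, square-root Bray-Curtis distances, PCoA, and
  UPGMA clustering of infant microbiota into `k` profiles.

All rank statistics (Mann-Whitney with exact small-sample path,
Kruskal-Wallis + η², BH step-up, Steel-Dwass via the studentized range),
Bray-Curtis, PCoA and the rarefaction expectation
E[S_d] = Σₐ [1 − C(N−nₐ, d)/C(N, d)] are implemented in the package and
verified against independent oracles (exhaustive enumeration, brute-force
closed forms, `vegan`, `ape`, `wilcox.test`) in the test suite.

A seeded synthetic-cohort generator (`simulate_cohort()`) plants
covariate-dependent transmission — each infant acquires its own mother's
strain of each adult OTU with probability τ, any other strain with
background probability β — and records full ground truth, so estimator
recovery, null calibration and clustering are all testable. See the
methods vignette (`vignettes/transmission-methods.Rmd`) for the model and
every numerical choice.

## Worked example

```r
library(strainshare)

sim   <- simulate_cohort(sim_config(n_pairs = 100, seed = 1))
prof  <- related_profiles(sim$table, sim$metadata)
unrel <- unrelated_pair_profiles(sim$table, sim$metadata)  # 9,800 rows

median(prof$shared_abundance)   # 0.0917
median(unrel$shared_abundance)  # 0.0125
compare_related_vs_unrelated(prof, unrel)$p_value  # 2.44e-47
```

Infants share a median 9.2 % of their community with their own mother at
the generator's default τ₀ = 0.10, versus 1.3 % with unrelated mothers
(background β = 0.02 matched by strain-pool collisions) — strong evidence
of transmission, which is exactly what was planted. The factor screen
finds the planted feeding effect and nothing else:

```r
factor_screen(prof, sim$metadata,
              c("feeding", "sex", "delivery", "smoking"))$screen
#     factor k   n      H eta_squared    p_raw    p_fdr
# 1  feeding 3 100 30.101     0.28970 2.91e-07 1.16e-06
# 2      sex 2 100  1.763     0.00779 1.84e-01 3.68e-01
# 3 delivery 2 100  0.511     0.00000 4.75e-01 6.33e-01
# 4  smoking 2 100  0.105     0.00000 7.46e-01 7.46e-01
```

Per-OTU transmissibility:

```r
m  <- collapse_to_otus(sim$table, sim$taxonomy)
si <- sharing_index(sim$table, sim$metadata, m$mapping)
head(si[order(-si$index), ], 3)
#     otu_id n_pairs_shared n_union     index
# 34 OTUA034             26     100 0.260
# 42 OTUA042             21      99 0.212
# 41 OTUA041             21     100 0.210
```

A command-line interface covers the same pipeline
(`inst/scripts/strainshare`): `simulate`, `share`, `sharing-index`,
`ordinate`, `cluster`, `stats`, `summarize`.

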