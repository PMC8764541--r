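---
title: "Methods: quantifying mother-to-infant oral strain transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mother-to-infant oral strain transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainshare)
```

## The problem

An infant's oral microbiota assembles rapidly after birth, and the mother's
mouth is its most plausible chronic source. With full-length 16S rRNA
amplicon sequence variants (ASVs) — exact denoised sequences that resolve
single-nucleotide differences — "the same strain in mother and infant"
becomes an operational, testable notion: an ASV detected (count ≥ 1) in both
members of a mother-infant pair. `strainshare` implements the complete
analysis around that notion:

1. **Shared-ASV statistics** per pair: the number of shared ASVs, their
   percentage of the infant's observed ASVs, and their cumulative relative
   abundance in the infant (`related_profiles()`).
2. **An unrelated-pair null**: the same three statistics for every
   infant × non-own-mother combination (`unrelated_pair_profiles()`), giving
   `n_infants × n_mothers − n_links` profiles. Some sharing arises without
   transmission — cosmopolitan strains — so related-pair statistics are only
   interpretable against this null (two-sided Mann-Whitney U).
3. **A per-OTU sharing index**: among pairs in which either member carries
   an OTU (a group of ASVs assigned to the same reference sequence at
   ≥ 98.5 % identity), the fraction of pairs sharing at least one member
   ASV (`sharing_index()`). Counting is at *pair* level, so a mother of
   twins enters once per pair; this resolves the ambiguity in the verbal
   definition of the denominator, since "dual entry of twin mothers" is
   meaningful only for pair-level sets.
4. **A nonparametric factor screen**: Kruskal-Wallis with η² effect size per
   clinical factor, Benjamini-Hochberg FDR across the screened factors, and
   Steel-Dwass (≥ 3 levels) or Mann-Whitney (2 levels) follow-ups
   (`factor_screen()`).
5. **Origin-aware community profiling**: each OTU's abundance in an infant
   split into maternally-shared and nonshared components
   (`build_modified_otu_table()`), square-root Bray-Curtis distances, PCoA,
   and UPGMA clustering into `k` groups (`cluster_infants()`).

## Statistical machinery

All rank tests are implemented in this package (not delegated), because the
test battery is part of the deliverable and is dual-checked against
independent oracles in the test suite.

**Mann-Whitney U.** `U = R_x − n_x(n_x+1)/2`. Exact enumeration of all
`choose(n, n_x)` rank placements when both groups have ≤ 8 tie-free
observations; otherwise a normal approximation with midrank tie correction
`σ² = n₁n₂/12 · [(n+1) − Σ(t³−t)/(n(n−1))]` and an optional 0.5 continuity
correction (on by default, toggleable).

**Kruskal-Wallis and η².** Tie-corrected `H` referred to χ²(k−1), with the
rank effect size `η²_H = (H − k + 1)/(n − k)`. The literature names η²
without fixing a variant; this is the standard rank-based choice, and the
raw (possibly negative) value is kept alongside the value clipped to [0,1].
At k = 2, `H` equals the square of the uncorrected Mann-Whitney z — checked
numerically in the tests.

**Benjamini-Hochberg.** The step-up adjustment
`q_(i) = min_{j≥i} p_(j)·n/j`, capped at 1. One property sometimes claimed
for BH — that applying it twice is idempotent — is false in general (the
reference implementation `p.adjust` agrees); the tests assert the true
properties instead: dominance over raw p, order preservation, the cap, and
exact agreement with `p.adjust`.

**Steel-Dwass.** For each pair of groups, ranks are recomputed within the
pair; the standardized rank sum (same tie-corrected variance as above) is
referred to the studentized range distribution with `k` groups and ∞
degrees of freedom via `q = t√2`. At k = 2 this reduces *exactly* to the
two-sided Mann-Whitney normal approximation without continuity correction,
which the tests verify to 1e-6. Exact permutation Steel-Dwass is out of
scope.

**Bray-Curtis and PCoA.** `BC(x,y) = Σ|xₐ−yₐ| / Σ(xₐ+yₐ)` on square-root
transformed relative abundances (transform toggleable). PCoA is classical
scaling: eigendecomposition of the double-centered `−½D²`; negative
eigenvalues are reported, not corrected (no Lingoes/Cailliez), matching the
default of standard ecology software. On Euclidean distance inputs the
embedding reproduces the distances to 1e-9.

**Rarefaction.** Expected richness under uniform subsampling without
replacement, `E[S_d] = Σₐ [1 − C(N−nₐ, d)/C(N, d)]`, computed with
log-binomials. Rarefaction is used only as saturation evidence; no
downstream statistic rarefies — all abundance analyses use relative
abundances of full counts.

## The synthetic cohort: a stated world

Real validation data would require the study's deposited reads plus an
upstream pipeline (CCS, demultiplexing, DADA2, BLAST) that is out of scope,
so the package ships a generator whose defaults *are* the cohort it
emulates: 200 pairs by default (448 reproduces the study's bookkeeping,
with a twin fraction of 8/448 giving 444 mothers), read depth
Normal(5493.4, 1730.2) truncated at 500, feeding frequencies 57.2/29.4/13.5 %
(breast/mixed/formula), and the remaining covariates drawn at the study's
published marginal frequencies.

**Strain pools.** 60 adult OTUs × 12 strains each, plus 15 infant-specific
OTUs (never present in mothers; these stand in for the infancy-specific
streptococci). Each mother carries one strain per adult OTU with lognormal
OTU weights (σ = 1.2, chosen a priori so the top OTU averages ~13 % of the
community, matching observed dominance). 12 strains per OTU is a desk-scale
stand-in for the ~40 ASVs/OTU of the real data.

**Acquisition.** For each adult OTU an infant acquires its own mother's
strain with probability τᵢ = clip(τ₀ + feeding shift) and *every other
strain of that OTU* with probability β (default 0.02). Acquired strains of
an OTU split the mother's OTU weight equally — the infant samples the
maternal oral environment, whichever strain variant colonizes. The
remainder `max(0, 1 − τᵢ − β)` of raw mass goes to the infant-specific
pool. Reads are multinomial.

This per-strain design was chosen over the more obvious
"copy a τ-fraction of abundance from the mother" because only it makes the
null scenario exact: at τ₀ = β the acquisition probabilities no longer
distinguish the biological mother, the process is exchangeable across
mothers, and related and unrelated sharing coincide in distribution (up to
a second-order correlation between maternal weight and maternal detection).
Under a mass-copy design, related sharing ≈ τ + background strictly exceeds
unrelated sharing at τ₀ = β, and the type-I-error criterion is structurally
unachievable. A side effect worth knowing: because background strains are
by construction *not* the own mother's strains, the related-pair estimator
has no false-positive channel in this world — estimated shared abundance
equals the planted fraction essentially exactly, and recovery and
identifiability checks pass with large margins. Real data are harsher
(sequencing error, shared environment); a green recovery test here
establishes correctness of the bookkeeping, not field performance.

The default τ₀ = 0.10 with feeding shifts (breast 0, mixed +0.05, formula
+0.15) reproduces the qualitative findings being emulated: a related-pair
median shared abundance near 10 %, an unrelated mean near 2 %, and
formula-fed infants with the highest acquisition. Under the per-strain
semantics the *realized* unrelated-pair sharing at these defaults — mass
`(maternal + background)/strains_per_otu` plus detection effects — happens
to land near β itself; the test suite checks this at the default scenario,
but it is a property of the scenario, not a structural guarantee.

**Truth ledger.** For each infant the generator records τᵢ, the covariate
draws used, and the planted transmitted ASVs (own-mother strains acquired
*and* detected in the mother's realized reads, so the ledger never claims a
transmission the data cannot show). `planted_shared_fraction()` converts
the ledger to the realized recovery target.

**What the generator does not emulate.** No sequence-level error model, no
chimeras, no longitudinal dynamics, no shared household environment
(background is i.i.d. across infants), no abundance correlation between
mother and infant beyond the copied weights, and covariates are drawn
independently of each other (twins also draw covariates independently).
Only the feeding effect is planted; the weight effects the field reports
are not, so the factor screen's null factors are genuinely null here.

## Numerical and design choices

- **Detection threshold**: count ≥ 1. Denoised tables carry no floor, and
  any larger threshold would need a justification the source material does
  not provide.
- **OTU membership**: reference identity ≥ 98.5 %; below that, ASVs group
  under `unassigned:<taxon_label>` (genus-level fallback). Collapsing
  conserves the grand read total exactly.
- **Unrelated null**: the full cross-product, never a subsample, matching
  the published pair count (198,464 from 448 infants × 444 mothers − 448
  links); deterministic infant-major, mother-ascending order.
- **Linkage**: UPGMA (average) by default — unstated in the source
  material; average linkage is the community standard with Bray-Curtis and
  avoids Ward's Euclidean assumption. Exposed as a parameter, as is `k`
  (default 8, a parameter rather than an inference: no cluster-selection
  criterion is given).
- **Weight categories**: strictly below mean − 1 SD is `low`, strictly
  above mean + 1 SD `high`, the ±1 SD band inclusive at both ends (the
  printed strict thresholds imply inclusive boundaries). Kaup index
  `weight(g)/height(cm)² × 10` with bands <16, [16,18), ≥18.
- **Rounding**: summary percentages round half-up to one decimal;
  percentage denominators are per-variable non-missing counts.
- **Null calibration bound**: "rejects at ≤ nominal 5 %" is asserted as an
  observed rate over 200 replicates of at most 0.05 + 2·SE(0.05, 200) ≈
  0.081 — a point bound at 5 % would fail about half the time for a
  perfectly calibrated test.
- **Ties**: dendrogram and rank tie handling are deterministic (midranks;
  `hclust`'s fixed merge order), so fixed seeds give bit-identical results.

## A small worked run

```{r worked, eval = FALSE}
sim <- simulate_cohort(sim_config(n_pairs = 50, seed = 7))
prof <- related_profiles(sim$table, sim$metadata)
unrel <- unrelated_pair_profiles(sim$table, sim$metadata)
median(prof$shared_abundance)   # ~0.095 at tau0 = 0.10
mean(unrel$shared_abundance)    # ~0.021 at beta = 0.02
compare_related_vs_unrelated(prof, unrel)$p_value  # << 0.001
```

## Known limitations

- The generator's exchangeable-at-null design means the related-pair
  estimator is exact in simulation; power and calibration results should
  be read as validating the statistics, not as forecasts for field data.
- The sharing index is reported per OTU without a confidence interval; the
  source analysis reports none, and pair-level dependence (twins) makes a
  naive binomial interval wrong.
- Steel-Dwass uses the ∞-df studentized-range approximation; for very
  small groups (n < ~7 per group) exact permutation would be preferable.
- `pct_shared` uses the infant's observed richness as denominator, so
  shallowly sequenced infants have noisier percentages; no coverage
  correction is applied.
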