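---
title: "Scanning multi-population cohorts for region-specific allele patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning multi-population cohorts for region-specific allele patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionscan)
```

## The two allele classes

`regionscan` catalogues two opposite extremes of geographic allele
structure at common SNPs. An *abundant region-specific allele* (ARSA) is
common — above an 18% frequency cutoff — in exactly one continental
region (Africa, the Americas, East Asia, Europe or Oceania) and at least
40-fold rarer in the pooled rest of the world. A *regional absence of a
common allele* (RACA) is the mirror image: an allele carried by more
than 1000 chromosomes worldwide that is nevertheless nearly missing
(fewer than 10 copies) from one region. Neighbouring admixed populations
are deliberately grouped into one geographical region, so the catalogue
captures between-region contrasts rather than fine population structure.

Working at a high frequency cutoff (~20% rather than the conventional 5%
"common variant" line) selects old, drift- or selection-amplified
alleles and keeps the catalogue robust in small panels; 18% specifically
is the largest value that the smallest panels can realise with minimal
between-region spread (see below).

## Threshold arithmetic

All abundance rules operate on allele copies out of the `2N` chromosomes
of an `N`-person diploid panel. The minimal count for a fraction `f` is

```
k = ceiling(f × 2N),
```

with an inclusive boundary: when `f × 2N` is an exact integer that count
already qualifies ("k or more"). Small panels make only discrete
cutoffs realisable; `implied_frequency_pct()` reports the percentage a
panel actually enforces:

```{r}
panels <- c(AFR = 47, AMR = 8, OCE = 19, EAS = 22, EUR = 41)
min_count_threshold(panels)
round(implied_frequency_pct(panels), 2)
```

At 18% the five discovery panels land between 18.09% and 18.75% — the
minimal spread achievable across panels of such unequal size, which is
why 18% (not 20%) is the base fraction default.

Validation panels are admixed, which dilutes a region-specific allele in
proportion to the non-native ancestry fraction `a`. The cutoff is
therefore relaxed multiplicatively:

```{r}
adjusted_threshold(0.18, 0.40) # 40% admixture: 18% becomes 10.8%
```

The multiplicative form (rather than subtracting percentage points) was
chosen because it generalises smoothly to `a = 1`, where a fully
replaced panel can constrain nothing. The adjustment uses the
count-weighted mean admixture of the pooled regional panel; a
per-population variant would be possible, but the pooled panel is what
the frequency is measured on, so the pooled mean is the consistent
choice.

Floating-point note: `ceiling()` is applied after subtracting 1e-9 so
that products like `0.18 × 50 = 9` (not exactly representable in
binary) stay at the inclusive boundary instead of rounding up to 10.

## The three-stage ARSA filter

* **Stage 1 (discovery).** Small panels of minimally admixed populations.
  Rule: in-region count ≥ `k`, and at most `step1_world_max_count`
  (default **1**) allele copies pooled across the other panels. A
  frequency-ratio test is meaningless when the "world" holds a few dozen
  chromosomes, so a hard copy ceiling stands in for near-absence at this
  stage; the 40× rule takes over downstream.
* **Stage 2 (validation).** A large cohort. Rules: in-region frequency ≥
  the admixture-adjusted cutoff, and pooled rest-of-world frequency at
  least `world_ratio` (default **40**) times lower. The rest-of-world
  pool is the *aggregate* frequency over non-excluded regions (total
  copies / total chromosomes), not the maximum over regions — pooling is
  the size-robust reading when panels differ 10-fold in size. The ratio
  is compared by cross-multiplication, so a world count of zero passes
  trivially and no division is ever performed.
* **Stage 3 (re-validation).** A second independent cohort, same
  contract.

Supporting conventions, each of which matters in corner cases:

* *Exclusion policies.* When testing region R, regions that share heavy
  recent admixture with R are removed from R's world pool, otherwise
  leaked copies defeat the ratio rule. Defaults: European targets
  exclude South Asia and the Americas; African targets exclude the
  Americas. Policies are plain tibbles (`exclusion_policy()`) and can
  express alternative rosters, e.g. excluding individual
  African-diaspora populations from the African validation panel instead
  — panels are defined by the manifest, so that variant is a manifest
  edit, not a code change.
* *Unsampled regions.* A region absent from a validation cohort (Oceania
  in 1000-Genomes-style panels) cannot be frequency-tested there;
  instead a strict whole-cohort ceiling applies: fewer than 7 copies
  (`oceania_world_max_count = 6`) across all individuals. The in-region
  frequency requirement is then enforced at the next stage, where the
  region is sampled.
* *Untestable sites fail.* A candidate absent from a validation cohort,
  or whose allele matches neither REF nor ALT there, is dropped and
  logged (`"absent"` / `"allele_mismatch"`), never passed silently.
* *Alleles are matched by base*, not by REF/ALT role, because the role
  can swap between call sets. Both alleles of every site are tested —
  a region-specific allele may be the reference base.

RACA detection is a single pass over the large cohort:
`in_region_count ≤ 9` and `world_count ≥ 1001` after exclusions. The
thresholds are *counts*, not frequencies — a world pool smaller than
1001 chromosomes can never yield a call. The parenthetical frequency
glosses sometimes attached to these counts (0.1%, 25%) are not
self-consistent for panels of a few hundred individuals, so the counts
are authoritative here. Absence is only assertable against large
panels, and heavily admixed regional panels cannot support it at all:
targets outside Africa, Europe and East Asia are refused unless
`force = TRUE`.

## Counting conventions in the VCF scanner

`scan_sites()` tallies biallelic SNVs only; multi-allelic records,
non-SNVs and (by default) sex chromosomes and mitochondria are skipped
into an itemised log — the `2N` diploid arithmetic above presumes
autosomes. Missing genotypes (`./.`) reduce the denominator: all
frequencies use *called* chromosomes, because counting missing calls as
reference would systematically deflate regional frequencies. Half-calls
(`0/.`) and haploid calls contribute their one called copy plus one
missing copy. Phased and unphased separators are equivalent. Records
with malformed genotype tokens are skipped with a warning rather than
guessed at.

Ancestral states come from the `AA=` INFO subfield. Only the first
pipe-delimited token is read (the extended `AA=a|||` dialect), case
encodes annotation confidence (uppercase high, lowercase low), and
`"."`, `"-"`, `"N"` or a missing subfield mean unknown. In polarity
summaries a call is *ancestral* if its called allele equals the
ancestral base, *derived* if the ancestral base is the site's other
allele, and *unknown* otherwise — including the case of an ancestral
base matching neither allele. Percentages are over known calls,
rounded half-up to integers, and the derived percentage is reported as
the complement so the pair always sums to 100.

For very small informative call sets the ancestral-vs-derived imbalance
is tested with the exact one-sided binomial tail rather than by
simulation: `exact_binomial_tail(8, 7, 0.5)` is exactly 9/256 ≈ 0.0352.
Note that rounding this quantity to two decimals (0.03, as summary
tables tend to print) loses the third significant digit; the package
always reports the exact value.

## Clustering, genes, and intersection statistics

Neighbouring calls are often in linkage disequilibrium. As an LD proxy,
`cluster_by_gap()` chains calls per chromosome by single linkage:
consecutive sorted positions strictly less than `cluster_gap_bp`
(default 5000 bp) apart join one cluster. Distance is the difference of
1-based positions; chaining never crosses chromosomes; the clusters
partition the call set and the partition is order-invariant.

Gene assignment is plain interval overlap of call positions against
gene bodies — a deliberate simplification of transcript-aware
annotation that will differ at gene boundaries and does not classify
effects. BED input is converted to 1-based inclusive coordinates on
import (0-based half-open `[100, 200)` becomes `[101, 200]`, so a
variant at 1-based position 200 does overlap); GFF3 is 1-based already
and is filtered to `type == "gene"` records.

Gene lists from several regions are compared two ways: exclusive
combination counts (`combination_counts()`, UpSet semantics — every
gene counted in exactly the combination of lists containing it, so
counts sum to the union) and plain joint intersections tested by Monte
Carlo (`mc_intersection_pvalue()`). The null replaces each list by a
uniform random draw of the same size, without replacement, independent
across lists, from a universe defaulting to 25,000 genes (a
conventional human gene count; configurable). The p-value uses the
add-one estimator `(1 + #{perm ≥ obs})/(n_perm + 1)`, which can never
report zero: at 10^4 permutations the floor is ~10^-4. The product-form
expectation `U·Π(nᵢ/U)` reduces to the hypergeometric mean
`n₁·n₂/U` for two lists (100 and 6400 genes in 25,000 give 25.6).

## The synthetic three-cohort generator

`synth_config()`/`generate_cohorts()` emulate the three-cohort study
design at desk scale: a discovery cohort of small, pure panels
(47/8/19/22/41 individuals for AFR/AMR/OCE/EAS/EUR plus 25 South
Asians), a large validation cohort in 1000-Genomes style
(600/347/504/503/489 for AFR/AMR/EAS/EUR/SAS, with the American panels
30–45% admixed, South Asian panels 30% admixed, and no Oceania panel),
and a medium second cohort in EGDP style (402 individuals including 51
Oceanians). Each haplotype originates from its own population with
probability `1 − a` and from a donor region otherwise, then carries the
alternative allele with the origin region's nominal frequency —
Hardy–Weinberg genotypes from two independent haplotype draws, matching
the `2N` count arithmetic, with sites independent (no LD) unless
`ld_twins` copies genotype columns to nearby positions for clustering
tests. One cohort is written phased, the others unphased, and every
seventh site swaps REF/ALT roles in the second validation cohort, so
the scanner's separator handling and base-matching are exercised on
every run. Two deliberately non-conforming records (a multi-allelic
site and an indel) exercise the skip log.

Planted site kinds and their default frequency regimes:

| kind | in target region | elsewhere |
|---|---|---|
| `arsa_plant` | 0.70 (EUR: 0.45) | 0 |
| `raca_plant` | 0 | 0.60 |
| `decoy_discovery_only` | 0.25 (discovery only) | 0 / 0.05 in validation |
| `cosmopolitan` | 0.05–0.50 | same everywhere |
| `monomorphic` | 0 | 0 |

The defaults are a power calculation, fixed at design time. Exact
planted-signal recovery is only a fair deterministic assertion if every
plant sits several binomial standard deviations clear of every
threshold it meets. The binding case is the 8-person American discovery
panel, where the count threshold is 3 of 16 chromosomes: at an
in-region frequency of 0.25 a true plant *misses* that threshold about
20% of the time, and even at 0.5 about 0.2% — too often for a
multi-seed exact-recovery test. At 0.70 the miss probability is below
10^-6. Symmetrically, a plant must not drift *into* the opposite
catalogue: a European plant at 0.70 would place ~700 copies in the
large European panel plus ~340 leaked copies in the admixed South Asian
and American panels, landing within ~2 SD of the 1000-copy
regional-absence rule for African/East-Asian targets; at 0.45 it clears
that rule by >5 SD while still clearing its own thresholds (the
European discovery panel has 82 chromosomes) by >5 SD. Hence the
region-specific default. RACA plants use world frequency 0.60 so the
smallest post-exclusion world pool (European target: 2208 chromosomes)
exceeds 1000 copies by >10 SD.

`truth_table()` converts the nominal design into expected labels by
evaluating *every* rule margin, for both alleles of every site against
every target region, in expected allele copies — admixture leakage is
propagated exactly. Sites whose smallest margin falls within ±2 copies
of a threshold are flagged borderline and excluded from hard
assertions; a structurally zero expected count (all contributing
frequencies exactly 0) is deterministic and is treated as an infinite
margin, not a borderline one. With the default design no site is
borderline, a plant can satisfy the regional-absence rules for more
than one region (labels are comma-separated lists), and decoys pass
stage 1 but are always eliminated at validation.

What the generator does *not* emulate — and therefore what passing
tests do not show about real data: realistic allele-frequency spectra
and site-frequency correlations, linkage disequilibrium beyond the
optional perfect-copy twins, recombination and mutation processes,
genotyping error and missingness structure, and ancestral
misassignment. The generator verifies the *filter logic*; sensitivity
on real cohorts is governed by panel composition and admixture
estimates, which enter through the manifest.

## Problem sizes in the shipped tests

The test suite runs the full pipeline on 20 seeded cohorts of 200 sites
with discovery panels at the canonical sizes and validation panels of
at least 300 individuals per region (the second cohort is raised from
its EGDP-like default to 300/region for these runs: a 15-person
admixed American panel re-tests a plant at threshold 5 of 30 copies,
within ~2 SD of its expectation, which would make exact recovery flaky
— panels of ≥300 put every margin beyond 5 SD). Monte-Carlo
cross-checks use 10^4 permutations against exact hypergeometric
enumeration on small universes, and brute-force oracles (union-find
clustering, per-genotype tallies, all-pairs interval overlap,
membership-mask combination counts) are re-derived on 20 random
fixtures each. These sizes keep the whole suite to a couple of minutes
while leaving no assertion dependent on luck.

## Known limitations

* Gene assignment is interval overlap, not effect annotation; boundary
  and regulatory relationships are out of scope.
* Admixture fractions are inputs (via the manifest), not estimated.
* No genotype likelihoods, imputation or phasing; genotypes are taken
  at face value from `GT`.
* The X/Y/MT exclusion is a default, not a hard rule — the thresholds'
  diploid arithmetic would need haploid-aware denominators before
  lifting it.
* Catalogue sizes on real cohorts depend on the exclusion policy
  roster; the defaults encode one defensible reading of the admixture
  structure, and alternatives (e.g. dropping African-diaspora
  populations from the African validation panel) are expressible but
  not the default.
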