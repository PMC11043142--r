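---
title: "Cross-population rare-variant overload: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-population rare-variant overload: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varburden)
library(dplyr)
```

varburden asks a population-genetic question about a single candidate gene:
does a disease cohort carry more rare missense alleles than reference
populations do, are individual variants enriched in particular populations
(a signature of founder effects), where along the coding sequence do the
variants sit relative to the gene's mutational constraint, and are any of
the cohort's variants in linkage disequilibrium with one another. Every
stage operates on ordinary tables — one row per variant or per gene — and
returns tibbles, so a full analysis is a short pipe chain.

## Data model

A *variant table* carries one row per biallelic variant with per-population
allele frequency (AF), alternate allele count (AC) and allele number (AN)
columns, plus optional cohort counts (`cohort_ac` out of `cohort_an`
alleles). Genomic positions are 1-based; the only 0-based half-open
coordinates in the package are BED exports. A population in which a variant
has never been observed is frequency zero, not missing: depletion in a
population is part of the signal.

Whichever of AF/AC/AN is absent is back-filled on read. AC is reconstructed
from a frequency as `round(AF * AN)`: published frequencies are rounded to a
few significant digits, and the nearest integer is the only count consistent
with the printed value. Consistency between a supplied AF and AC/AN is
enforced up to the larger of the counting resolution (`0.5/AN`) and the
half-ulp of a three-significant-digit frequency, because a printed AF cannot
be more precise than its own last digit.

The default reference panel is the gnomAD v2.1 exome panel — NFE (N =
56,885), AFR (8,128), EAS (9,197), SAS (15,308), AMR (17,296) and the global
total (125,748) — with AN = 2N per population. Per-site AN overrides on the
table are honoured when present.

## Per-variant enrichment

For each variant and ordered population pair, a 2×2 allele-count table
contrasts alt/ref alleles in the two groups. The point estimate is the
sample (cross-product) odds ratio; the enrichment rule is the conventional
one: OR ≥ 1 with a two-sided exact p below `alpha` (default 0.05) flags
enrichment in population 1, and symmetrically OR < 1 with p < `alpha` flags
depletion.

Two numerical decisions matter here.

**The point OR is computed on the frequency scale.** The cross-product OR of
integer cells `round(AF * AN)` is not invariant to the rounding of the
published frequency when a count is small: a frequency of 1.48E−4 at
AN = 16,256 becomes 2 alleles (observed frequency 1.23E−4), which distorts
the OR by 20%. The odds ratio of the frequencies themselves — equivalently
the cross-product on the unrounded cells `AF * AN`, in which AN cancels —
reproduces published odds ratios to well under 1% and is the default
(`or_scale = "frequency"`). The exact test always runs on the
nearest-integer counts, which is where a discrete test is defined.

**The p-value is a two-sided Fisher exact test** by the minimum-likelihood
rule (the `stats::fisher.test` convention), implemented over the
hypergeometric mass function and verified in the test suite against full
enumeration of all tables with total ≤ 40. The source analysis does not
name its test; Fisher's exact test is the field standard for sparse allele
tables. Confidence intervals are Woolf (log-OR normal) by default, computed
on the Haldane-corrected table when a cell is zero; the conditional exact
interval from inverting the exact test is available with
`ci_method = "exact"`. Published intervals of this kind are often far wider
than Woolf intervals and their construction is rarely stated, so interval
agreement is not asserted anywhere — point estimates are the comparable
quantity. Zero cells follow `zero_policy = "none"` by default (OR of 0 or
infinity, matching the dashes and zero entries of published tables);
Haldane's +0.5 is a flag away. Per-variant p-values are reported raw, as is
conventional for these tables; `adjust = TRUE` adds Benjamini–Hochberg
q-values.

## Gene-level burden

Burden collapses at the allele level: the aggregated AC is the sum of
per-variant alt counts against the single population AN as denominator, and
the burden OR contrasts cohort aggregated odds with population aggregated
odds (same frequency-scale/count-scale split as above). Carrier-level
collapsing is deliberately not the default because the aggregated-AF
formulation is frequency-based. With one variant the burden OR reduces
exactly to that variant's OR — a property the tests pin down.

Control genes are matched on CDS length (default tolerance ±439 bp around
an 8,778-bp focal CDS, roughly a 5% band), which controls the mutational
target size. Percentile ranking of the focal gene's variant count among
controls uses midrank ties over the panel plus the focal gene:
`100 * (n_below + 0.5 * n_ties) / (n_panel + 1)`. No convention is standard
here; midrank is the symmetric choice and is monotone and order-invariant.
BH adjustment treats the focal gene plus its selected controls (per
population) as the family — the only family under which a per-gene "FDR"
label is meaningful.

Note that published gene-level burden ORs computed by other association
frameworks need not equal the aggregated-count cross-product OR; on the
packaged cohort table the two differ (≈3.99 here against the NFE
population). Tests therefore assert that our estimate falls inside the
published confidence interval rather than reproducing another method's
point value.

## Variant density along the CDS

Density is the count of distinct variant sites (AC > 0 in the chosen
population, each site once regardless of frequency) in a sliding window of
`2 * halfwidth + 1` bp (201 bp by default, step 1 bp), divided by the
window length. Windows are clipped at the CDS ends and divided by the
clipped length — the alternative (fixed 201-bp denominator) manufactures
spurious low density at the termini. Density lives in concatenated CDS
coordinates; introns are invisible.

A position is a low-density region (LDR, the constrained state) when its
window density is strictly below a population-scaled threshold:
`expected_total * scale / cds_length`. The per-population `scale` is a
"direct proportion" of the overall expected count, and the proportionality
variable is genuinely ambiguous: the package implements both readings —
allele-number share (`an_share`, the default) and observed-variant-site
share (`count_share`) — and asserts neither as canonical. Per-position
labels merge into maximal runs that partition `[0, cds_length)`;
cross-population similarity is the percentage of CDS positions whose
LDR/HDR label agrees.

Reproducing published similarity percentages for a real gene requires the
full per-population variant list from the frequency database (thousands of
sites, not just the cohort's variants) plus the database's expected-variant
counts; with those two inputs, `density_profile()` +
`population_threshold()` + `call_regions()` + `profile_similarity()` is the
complete recipe. The package ships no such extract, so its tests exercise
the density stack on synthetic data with planted constraint instead.

## Linkage disequilibrium

With phased haplotypes, `r2 = D^2 / (p_A q_A p_B q_B)` with
`D = p_AB − p_A p_B`. From unphased dosages the four haplotype frequencies
are estimated by EM: all genotype configurations except the double
heterozygote resolve deterministically; the double heterozygote splits
between coupling and repulsion phase by the current frequency estimates.
Initialisation is at linkage equilibrium, tolerance 1e-10 on the largest
frequency change, 1000 iterations maximum — the two-locus likelihood is
well behaved and convergence takes a handful of iterations. When the sample
contains no double heterozygote the EM estimate equals the phased closed
form exactly (property-tested). Monomorphic sites give `NA`, never 0: an
undefined correlation is not an absent one. Missing dosages are rejected
rather than imputed.

## The synthetic-data generator

The generator exists so every estimator can be scored against known truth
offline. Its defaults are the study conditions: gnomAD-scale population
sizes, an 8,778-bp CDS, 400 candidate sites (about one rare missense site
per 22 bp, typical of a large exome panel), baseline true AFs log-uniform
in (1e-5, 1e-3), a 100-proband cohort at 200 alleles, 64 control genes
within ±439 bp.

- *Frequencies*: `AC ~ Binomial(AN, true AF)` per population; global counts
  are sums. Enrichment is planted on the odds scale
  (`odds_target = OR * odds_baseline`) so the planted OR is exactly the
  estimand of the sample OR.
- *Positions*: a thinned uniform point process; inside a planted segment the
  intensity is multiplied by a factor in [0, 1), which is precisely the
  structure the density caller must detect.
- *Cohort*: planted counts where specified, otherwise binomial at the
  reference frequency, with an optional odds multiplier to plant a
  gene-level aggregated burden.
- *Genotypes*: each planted pair gets the four-haplotype table achieving its
  target r2 at the pair's allele frequencies (feasibility is checked and
  the feasible maximum reported on violation); haplotypes are sampled
  independently per individual — no recombination, no population structure,
  because only pairwise r2 is consumed downstream.

What the generator does *not* emulate: site-specific AN variation and
coverage dropout, consequence annotation error, relatedness within the
cohort, linkage between the frequency-table variants, and any demographic
realism in the allele-frequency spectrum. Passing recovery tests therefore
demonstrates estimator correctness under the stated sampling model, not
robustness to those real-data artefacts.

One master seed drives everything; per-stage substreams use fixed offsets,
so regenerating one stage never perturbs another.

## Problem sizes and tolerances in the checks

The recovery experiments run at sizes chosen to make their Monte-Carlo error
comfortably smaller than the asserted tolerance: planted-OR recovery with
500 variants (binomial sampling error a few percent of an OR of 9);
planted burden over 300 replicates against a 10% band; LD r2 recovery as
the mean of 200 replicates at 5,000 individuals against a ±0.03 band;
low-density-segment recovery over 50 seeds with 2,000 candidate sites
against a median-Jaccard bound of 0.8 (window smearing alone caps Jaccard
near 0.92 for a 1,500-bp segment under a 201-bp window, which the planted
configuration clears with margin); Woolf coverage on 2,000 variants at
AN = 20,000, where cell counts are large enough for the log-normal
approximation the interval assumes.

## Limitations

- Consequence annotation is consumed, never computed; the package trusts the
  `consequence` column.
- No covariate adjustment, ancestry inference or kernel/variance-component
  burden tests; the burden statistic is the aggregated-count OR only.
- Coordinates are stored as given; no liftover, and no reconciliation
  between genome builds if the cohort and the frequency database disagree.
- LDR/HDR calls carry no significance measure — the threshold rule is
  deterministic, as in the analyses this package systematises.
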