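# varburden

Population-genetic analysis of rare missense variant overload in a candidate
gene. Given a disease cohort's variant list and gnomAD-style per-population
frequency tables, varburden answers four questions a gene-discovery study
asks once a candidate gene keeps turning up in families:

1. **Enrichment** — is each variant over- or under-represented in a
   population relative to another (a founder-effect signature)?
2. **Burden** — does the cohort carry more rare missense alleles of the gene
   than reference populations, benchmarked against CDS-length-matched
   control genes?
3. **Constraint** — where along the coding sequence do the cohort's variants
   sit, relative to regions of depleted (LDR) versus ordinary (HDR) variant
   density?
4. **Linkage** — which of the variants travel together on a haplotype
   (pairwise r²)?

A seeded synthetic-data generator with known ground truth makes every stage
testable offline, with no database download.

## The statistics

For two populations with allele frequencies `p1`, `p2`, the per-variant
enrichment statistic is the sample odds ratio

    OR = [p1 / (1 - p1)] / [p2 / (1 - p2)]

with a Woolf (log-OR normal) or conditional-exact 95% CI and a two-sided
Fisher exact p on the reconstructed allele-count 2×2 table; a variant is
*enriched* when OR ≥ 1 and p < 0.05. Gene-level burden applies the same OR
to allele counts aggregated over the gene's rare variants (cohort vs
population), with Benjamini–Hochberg adjustment across the tested family.
Variant density along the CDS is computed in a 201-bp sliding window (step
1 bp); positions whose density falls below a population-scaled
expected-count threshold, `expected × scale / cds_length`, form low-density
(constrained) regions. Pairwise linkage is `r² = D² / (pA qA pB qB)`,
estimated from phased haplotypes directly or from unphased dosages by EM
over the four haplotype frequencies.

## Worked example

The package ships the frequency table of 13 rare (`AF_NFE < 0.01`) missense
variants of *OTOG* observed in a familial Meniere disease cohort of 100
probands, with gnomAD v2.1 per-population frequencies:

```r
library(varburden)
library(dplyr)

tab <- read_variant_table(system.file("extdata", "otog_fmd_variants.tsv",
                                      package = "varburden"))
cohort <- filter_rare_missense(tab, reference = "NFE", af_threshold = 0.01)
cohort
#> # cohort_table: 13 variants (reference NFE, AF < 0.01, 100 probands)

enr <- enrich_variants(cohort, pop1 = "NFE")
enr %>% filter(variant_id == "NC_000011.10:g.17553211G>A") %>%
  select(pop2, or_point, ci_low, ci_high, p_value, enriched)
#>   pop2  or_point ci_low ci_high  p_value enriched
#> 1 AFR      9.06   2.69   43.9   5.43e- 7 TRUE
#> 2 EAS    Inf      3.07  793.    1.92e-10 TRUE
#> 3 SAS     15.1    4.35   42.8   1.82e-12 TRUE
#> 4 AMR      0.716  0.531   0.950 2.43e- 2 FALSE
```

The first variant (p.Val141Met) is ~9-fold enriched in the non-Finnish
European population over the African and ~15-fold over the South Asian
population, absent from East Asians (infinite OR, finite exact CI), and not
enriched over Latino/Admixed Americans. Summarising all 52 comparisons and
the gene-level burden:

```r
glance(enr)
#>   n_comparisons n_variants n_enriched n_depleted n_variants_enriched
#> 1            52         13         29         11                  10

gene_burden(cohort, populations = c("NFE", "GLOBAL")) %>%
  select(population, cohort_agg_ac, cohort_an, pop_agg_af, or_point, q_value)
#>   population cohort_agg_ac cohort_an pop_agg_af or_point    q_value
#> 1 NFE                   22       200     0.0301     3.99    2.21e-7
#> 2 GLOBAL                22       200     0.0266     4.53    5.20e-8
```

The cohort carries 22 of 200 alleles across the 13 sites (aggregated AF
0.11) against an aggregated NFE frequency of 0.030 — a ~4-fold overload of
rare missense alleles. Density profiling, region calling and LD follow the
same pattern (`density_profile()` → `population_threshold()` →
`call_regions()` → `annotate_variant_region()`; `ld_matrix()` on a dosage
matrix), each with an `autoplot()` method; `run_pipeline()` chains every
stage from one configuration list or YAML file, and the synthetic generator
(`sim_config()`, `simulate_*()`) provides inputs with planted truth.

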