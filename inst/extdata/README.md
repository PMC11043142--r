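# Packaged fixtures

`otog_fmd_variants.tsv` — the 13 rare (AF_NFE < 0.01) missense variants of
*OTOG* observed in a familial Meniere disease cohort of 100 unrelated
probands (cohort allele counts out of 200 alleles), with gnomAD v2.1 exome
per-population allele frequencies (NFE/AFR/EAS/SAS/AMR/global) and panel
allele numbers AN = 2N. Allele counts are left absent (`.`) and are
reconstructed on read as `round(AF * AN)`; a `0` frequency means the variant
is unobserved in that population. The `cds_pos` column is synthetic in the
narrow sense that it is derived from each variant's protein position
(`3 * aa - 2`, CDS 8778 bp) rather than taken from a transcript annotation;
frequencies, positions and cohort counts are as published.
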