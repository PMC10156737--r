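# famseg

Family-based discovery of rare, high-impact coding variants under an
autosomal dominant model with incomplete penetrance.

## What problem this solves, and for whom

Multiplex families — several relatives affected across generations, a
pattern mimicking dominant inheritance — are how statistical geneticists
localize rare coding variants of large effect for late-onset diseases such
as age-related macular degeneration, where genome-wide association signals
are mostly common and non-coding. `famseg` is for analysts running that
family-based discovery loop: take multi-sample genotypes (VCF), pedigree
structure with affection status (PED), and an ANNOVAR-style annotation
table, and produce a ranked list of candidate genes plus cohort-level
carrier statistics.

The pipeline is:

1. **Filter** variants to functional categories `exonic`/`splicing`, CADD
   phred ≥ 15, and reference allele frequency ≤ 1% — with missing CADD/AF
   (the `.` sentinel) always retained, so novel variants are never lost.
2. **Segregate**: per family, among genotyped affected members (n, of whom
   c carry the variant), retain when `n − c ≤ t` and `c ≥ 1`, tolerance
   `t = 1` by default ("all affected individuals or all but one").
   Missing genotypes shrink n rather than count as discordant.
3. **Collapse and rank**: passing variants are pooled per gene across
   families (distinct variants in the same gene in different families
   support the same hit); genes are ranked by supporting families, then
   total affected carriers, then symbol.
4. **Burden**: for variants of interest, carrier counts in a case cohort
   versus a reference cohort are compared in a 2×2 table with a two-sided
   Fisher exact test (probability-ordering definition, log-scale
   accumulation, exact at any cohort size) and chi-squared expected
   counts. `cooccurrence_rate()` reports two-locus phenotype co-occurrence
   as k/n and an integer percentage.
5. **Follow-up quantification**: co-IP band intensities normalized to
   input, scaled so wild type = 1, compared with an exact Wilcoxon
   rank-sum test (full enumeration at triplicate scale).

A gene-dropping simulator (`simulate_family_study()`, `emit_fixture()`)
generates fully synthetic studies — multigenerational pedigrees,
multiplex-ascertained dominant causal variants with incomplete penetrance,
an annotated neutral background, and a Hardy–Weinberg reference cohort —
used throughout the tests to validate the pipeline against known truth.
See `vignettes/famseg-methods.Rmd` for the models, assumptions, and
design decisions.

## Worked example

Simulate a four-family study (three generations, mean sibship 3,
penetrance 0.95, phenocopy rate 0.01, 2,000 annotated background
variants), run the discovery analysis, and compare affected carriers
against the simulated 60,706-exome reference cohort:

```r
library(famseg)

sim <- simulate_family_study(sim_config(), seed = 42)
sim
#> famseg_sim: 4 families, 72 members, 2001 variants (causal gene GENE_CAUSAL)

res <- run_prioritization(sim, known_genes = c("CFH", "CFI", "ARMS2", "C9"))
res
#> famseg_prioritization: 2001 variants -> 4 ranked gene(s)
#>   rank        gene n_families n_variants total_affected_carriers
#> 1    1 GENE_CAUSAL          3          1                      13
#> 2    2    GENE0036          1          2                       5
#> 3    3    GENE0063          1          1                       5
#> 4    4    GENE0149          1          1                       4

res$stage_counts
#>  vcf_variants     annotated    functional          cadd           maf
#>          2001          2001          1101           279           209
#>        joined passing_pairs         genes
#>           209             7             4
```

The causal gene tops the ranking with three supporting families; in the
fourth family a phenocopy left two discordant affecteds, exceeding the
tolerance — exactly the behavior the one-discordant rule is meant to
absorb when it happens once. `nrow(res$known_gene_hits)` is 0: no
qualifying segregating variant in the previously reported genes, reported
separately from discovery. The filter chain's record counts (2001 → 1101 →
279 → 209) are logged per stage, and `write_report()` emits the ranked
table as a deterministic TSV.

Carrier burden of the causal variant among genotyped affected members:

```r
aff <- affected_members(sim$ped, genotyped_only = TRUE, sample_ids = sim$vs$samples)
vs_aff <- variant_set(sim$vs$variants[, 1:4], sim$vs$genotypes[, aff, drop = FALSE])
run_burden(vs_aff, sim$reference, variants_of_interest = sim$truth$causal_keys)
#>        variant case_carriers case_genotyped case_carrier_freq ref_carriers
#> 1 1:500000:G:A            23             25              0.92          147
#>   ref_genotyped     fisher_p odds_ratio
#> 1         60706 1.207538e-57   4737.609
```

23 of 25 genotyped affecteds carry the variant (the ascertained families
are saturated with it) against a reference carrier frequency of ~0.24%,
giving an overwhelming exact p-value — the single-variant analogue of the
carrier-frequency comparison the burden module implements.

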