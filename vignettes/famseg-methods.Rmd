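---
title: "Family-based rare-variant segregation analysis: models and methods"
author: "famseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based rare-variant segregation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
```

## The problem

Genome-wide association studies of late-onset complex diseases such as
age-related macular degeneration (AMD) identify mostly common, mostly
non-coding risk alleles. Multiplex families — several affected relatives
across generations, a pattern mimicking autosomal dominant inheritance —
offer a complementary route: a rare coding variant of large effect that
co-segregates with disease in such families points directly at a causal
gene. `famseg` implements that discovery analysis as a reusable, tested
pipeline: annotation-driven variant filtering, per-family dominant
segregation testing with a discordance tolerance, cross-family gene-level
collapsing and ranking, carrier-frequency burden comparison against a
reference cohort, two-locus phenotype co-occurrence, and quantification of
co-immunoprecipitation follow-up experiments. A gene-dropping simulator
generates fully synthetic studies with the same statistical structure, so
every stage can be validated against known truth.

## Phenotype model

Individuals are graded on a 5-level fundus scale from structured findings
(per-eye maximum drusen diameter, geographic atrophy, choroidal
neovascularization): grade 1 — none or drusen < 63 µm; grade 2 — drusen
63–124 µm; grade 3 — drusen ≥ 125 µm (the large and very large bins share
one grade); grade 4 — GA or CNV in one eye; grade 5 — GA or CNV in both
eyes. The worse eye determines the individual's category; GA/CNV overrides
drusen size; an eye with both GA and CNV counts once toward the
one-eye/both-eyes distinction. Grades 4–5 are "Advanced AMD". Grading here
is from structured findings only — image grading and the role of medical
history in adjudicating a photographic grade are out of scope.

Affection status in the segregation analysis is the binary
affected/unaffected flag of the PED file; individuals coded unknown are
never counted on either side of any rule.

## Variant retention rules

Three filters precede segregation testing, each with the boundary semantics
stated and with *missing annotation values always retained*:

* **Functional category**: keep `exonic` and `splicing`
  (case-insensitive); composite categories such as `exonic;splicing` are
  split on `;` (also the escaped `\x3b` ANNOVAR writes) and kept if any
  component matches.
* **CADD**: keep `cadd_phred >= 15` or missing. The threshold is inclusive.
* **Allele frequency**: keep `exac_all_af <= 0.01` or missing. Inclusive.

Retaining missing scores is deliberate: a novel variant absent from
reference databases is exactly the kind of variant a family study exists to
find, and the `.` sentinel must never silently become zero (the annotation
reader parses it to `NA`). The filters are idempotent, commute, and are
monotone in their thresholds; the test suite asserts all three properties
on randomized annotation tables.

A *known-gene screen* — the same chain restricted to a user-supplied list
of previously reported disease genes — runs before genome-wide discovery
and is reported separately, so "no qualifying segregating variant in known
genes" is an explicit, reportable result.

## Segregation rule

For one variant in one family, let $n$ be the number of genotyped affected
members and $c$ the number of those carrying the variant (dominant model:
heterozygous or homozygous alternate). The variant segregates when

$$ n - c \le t \quad\text{and}\quad c \ge 1, $$

with tolerance $t = 1$ by default ("all affected individuals or all but
one"). Two design choices deserve justification:

* **The $c \ge 1$ guard.** With $t = 1$, a family with a single genotyped
  affected would otherwise "pass" with the variant entirely absent. The
  rule presupposes the variant is observed in the family.
* **Missing genotypes shrink the denominator.** An affected member whose
  genotype is missing is excluded from $n$ (and reported separately), not
  counted as discordant: absence of data is not evidence of non-carriage.

Unaffected members are ignored by default. The disease modeled is
late-onset with incomplete penetrance, so an elderly unaffected carrier is
expected, not contradictory. A strict mode
(`require_absent_in_unaffected = TRUE`) additionally vetoes variants
carried by any genotyped unaffected member, for diseases where that
assumption is appropriate.

Passing (family, variant) pairs are collapsed per gene across families:
the families supporting a gene are the union over all its passing
variants, so one variant in three families and a different variant in a
fourth family both count toward the same gene (this is the evidence
structure the analysis is designed to detect). Genes are ranked by number
of supporting families, ties broken by total affected carriers, then
alphabetically — deterministic and invariant under input order. No
gene-level p-value is attached: the discovery output is an evidence
ranking, not a hypothesis test.

## Carrier burden versus a reference cohort

For variants of interest, case genotypes are tallied into heterozygous
carriers, homozygous carriers and non-carriers (a carrier is a *person*
with ≥ 1 alternate allele, counted once regardless of zygosity), and
compared against reference carrier counts supplied as a small table —
never fetched from a network. The 2×2 table (rows case/reference, columns
carrier/non-carrier) is evaluated two ways:

* **Fisher's exact test**, two-sided by probability ordering: $p$ is the
  sum of hypergeometric probabilities of all tables with the same margins
  at most as probable as the observed one. Probabilities are accumulated
  on the log scale, so reference cohorts of tens of thousands are handled
  without underflow. Because two-sided definitions vary between software
  packages, ours is pinned by an exhaustive test: for every 2×2 table with
  $N \le 40$ the implementation matches a from-scratch enumeration oracle
  to within $10^{-12}$ relative error. Tables at (floating-point) equality
  with the observed probability are included via a relative inclusion
  tolerance of $10^{-12}$. A degenerate margin returns $p = 1$ with a
  flag.
* **Chi-squared expected counts** (no continuity correction, df = 1). The
  expected counts are the primary output — how many carriers each cohort
  would contribute under independence — with the Pearson statistic
  alongside.

The exact test is the headline statistic because rare-variant carrier
counts are small; the expected counts contextualize them.

## Two-locus co-occurrence

`cooccurrence_rate()` reports, among individuals satisfying two genotype
predicates (for example: homozygous for a common risk allele at one locus
*and* carrying a rare variant at another), the fraction with a given
outcome, as $k/n$ and an integer percentage (rounded half away from zero,
so $5/6 \to 83$). No test statistic is attached: at the
handful-of-patients scale where this summary is meaningful, a p-value
would be noise.

## Co-IP quantification

Band intensities from co-immunoprecipitation are first normalized to the
input control (total protein produced), then scaled by the mean of the
wild-type condition so WT sits at 1 and variants read directly as
fold-change. Scaling uses the WT *mean*, not per-replicate pairing, and is
scale-invariant. Conditions are compared with an exact two-sample Wilcoxon
rank-sum test: for combined sample sizes up to 12 the permutation
distribution of the rank-sum statistic is enumerated in full (ties handled
by midranks, which the enumeration respects) and the smaller tail is
doubled, capped at 1; larger samples use the normal approximation with tie
correction. At triplicate scale the most extreme configuration gives
$p = 2/\binom{6}{3} = 0.1$ — worth knowing before powering such an
experiment. A signed-rank wrapper is exposed for paired designs; the
rank-sum test is the default because transfection conditions are
independent experiments.

## The synthetic study generator

`simulate_family_study()` produces the structure the analysis assumes:

* **Pedigrees**: one founder couple per family; sibships of
  $1 + \mathrm{Poisson}(\bar{s} - 1)$; children in non-terminal
  generations marry in founder spouses (at least one per couple, so the
  configured generation depth is always realized).
* **Causal variant**: one founder per family is seeded heterozygous and
  the allele is gene-dropped — each child inherits it from a carrier
  parent with probability 1/2. By default all families share one variant;
  `distinct_causal_variants = TRUE` gives each family its own variant in
  the same gene, reproducing the several-variants-one-gene evidence
  structure.
* **Phenotypes**: carriers are affected with probability `penetrance`
  (default 0.95), non-carriers with probability `phenocopy_rate` (default
  0.01) — incomplete penetrance plus the background prevalence expected
  for a common late-onset disease.
* **Multiplex ascertainment**: each family's gene-drop and phenotype draw
  are repeated until the family presents at least `min_affected_carriers`
  (default 3) affected carriers. This models recruitment: families enter a
  segregation study *because* several relatives are affected. Unascertained
  drops frequently lose the variant lineage after the founder, and such a
  family would never be enrolled. The default of 3 matches the scale of
  sequenced affecteds per family in the study design this emulates.
* **Background variants** (default 2000): allele frequencies from
  Beta(0.3, 30) (mean ≈ 1%, right-skewed toward rare); founders drawn
  under Hardy–Weinberg, then gene-dropped; functional categories from a
  weighted table; CADD from a damaging/benign normal mixture; the true AF
  is written to the annotation with probability 0.98, otherwise the `.`
  sentinel (novel-variant simulation). Genes are assigned round-robin from
  a synthetic pool (~10 variants per gene) excluding the causal gene.
* **Genotype missingness** (default 2%) is applied to the emitted matrix
  only — phenotypes always derive from true carrier status.
* **Reference cohort**: carrier counts for 60,706 exomes drawn as
  $\mathrm{Binomial}(n,\ 1 - (1 - \mathrm{af})^2)$ and split het/hom in
  Hardy–Weinberg proportions.

`emit_fixture()` writes the study as plain-text VCF 4.2, 6-column PED,
ANNOVAR-style annotation TSV, a carrier table, and a truth manifest
(causal gene, causal variant keys, per-family carrier lists); identical
seeds give byte-identical files, and the files round-trip through the
package's readers exactly.

**What the generator does not model** — and therefore what passing tests
do *not* demonstrate about real data: linkage disequilibrium between
background variants (they are dropped independently), realistic exome
site-frequency spectra, age-of-onset liability, genotyping error (only
missingness), pedigree errors, or population stratification. The
generator validates the *logic* of filtering, segregation and collapsing,
not the error modes of real exome data.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle, and the
acceptance script (`scripts/acceptance.R`) recomputes the headline numbers
from scratch at fixed problem sizes chosen to make the checks exact or
tightly bounded while remaining desk-scale:

* Fisher: exhaustive equivalence with an enumeration oracle over *all*
  2×2 tables with $N \le 40$ (≈ 135,000 tables).
* Segregation: exhaustive truth-table agreement over all
  carrier/non-carrier/missing configurations for up to 6 genotyped
  affecteds, at tolerances 0–2.
* Wilcoxon: full-enumeration agreement for all sample-size pairs with
  $n + m \le 10$, including ties.
* Parameter recovery: 100 replicate synthetic studies at the default
  design; the causal gene must rank first in at least 95.
* Tolerance behavior: 20 replicate studies with exactly one affected
  carrier per family knocked down to non-carrier; the causal variant must
  pass every family at tolerance 1 and fail every family at tolerance 0.
* Null calibration: 200 replicates with case and reference carrier
  probabilities equal (0.002) at cohort sizes 2,451 vs 60,706; the Fisher
  rejection rate at 0.05 must not exceed 0.08 (the discrete exact test is
  conservative, so the observed rate sits below the nominal level).
* Mendelian consistency: every simulated genotype matrix passes an
  independent trio-consistency checker; gene-drop transmission frequency
  over 10,000 drops is within 3 standard errors of 1/2.

No empirical number is claimed in this document that those suites do not
themselves compute.

## Numerical and degenerate-input choices

* Fisher: log-scale accumulation; inclusion tolerance $10^{-12}$
  relative; degenerate margins → $p = 1$, flagged.
* Chi-squared: zero-margin cells contribute expected 0; the statistic is
  flagged when undefined.
* Wilcoxon: midranks for ties; exact enumeration up to $n + m = 12$; an
  all-tied comparison returns $p = 1$ with a flag.
* Co-occurrence and carrier frequency with empty denominators return
  flagged `NA`, never an exception.
* Genotype normalization: phase is discarded; any `.` allele (including
  half-calls) is missing; haploid calls are treated as diploid homozygous
  (dominance is modeled autosomally; sex chromosomes are read but treated
  diploid).
* Multiallelic sites are split per alt allele by dosage, so a sample
  carrying only *other* alt alleles is `hom_ref` with respect to the
  split allele and per-sample dosage is conserved across split records.
* Ranking tie-breaks (families ↓, carriers ↓, symbol ↑) make reports
  byte-reproducible.

## Known limitations

* The segregation rule operates on whoever is genotyped; it does not
  distinguish discovery genotyping from validation genotyping of
  additional relatives — load the genotypes you want tested.
* No likelihood-based linkage (LOD scores), no X-linked or recessive
  models, no haplotype sharing.
* Burden comparison is single-variant and unadjusted: no covariates, no
  population-stratification correction, no weighted gene-based
  collapsing tests.
* The VCF reader targets GT-bearing small-variant records; structural
  variants and FORMAT fields beyond GT are out of scope, as is
  streaming/indexing of genome-scale files.
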