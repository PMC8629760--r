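---
title: "Auditing a panel-based genome diagnostic pipeline"
author: "crsaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a panel-based genome diagnostic pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crsaudit)
```

## The problem

National-scale clinical genome sequencing programmes prioritize variants with
automated, virtual-panel-based pipelines: candidate variants are filtered by
population frequency, protein consequence and family segregation, then
intersected with disease-specific gene panels whose entries carry a
confidence rating (Green = diagnostic-grade, Amber, Red) and a mode of
inheritance. Clinical review is mandatory only for the top categories
("Tier 1/2" for small variants, "Tier A" for copy-number calls); the long
Tier 3 list is reviewed at the clinic's discretion, and untiered variants
are effectively invisible.

This package reconstructs that tiering logic for a craniosynostosis cohort
of 114 families in which an expert research group re-analysed every genome
and returned candidate diagnoses to the clinics, producing a rare
commodity: a cohort where the *complete* set of confirmed molecular
diagnoses (34, plus two variants of uncertain significance) is known, so the
clinical pipeline's diagnostic sensitivity — the fraction of those
diagnoses its own workflow surfaced — can be measured, decomposed by
failure mechanism, and projected under alternative detection strategies.

`crsaudit` provides four connected layers:

1. **Tiering engines** (`assign_small_tier()`, `tier_family()`,
   `assign_cnv_tier()`, `sv_breakpoint_review()`) that implement the
   prioritization rules, with the production pipeline's historical defects
   switchable on and off.
2. **A synthetic cohort generator** (`simulate_cohort()`) that plants each
   audited causal-variant archetype into configurable family structures and
   emits standard files (PED, VCF, panels, BED) plus a truth table.
3. **The embedded audited cohort** (`crs_fixture()`): the 36 case records
   with the attributes the audit reported.
4. **Strategy and audit engines** (`found_set()`, `combine_strategies()`,
   `audit_cohort()`) that compute the sensitivity decomposition, the
   overall diagnostic yield, the syndromic comparison with a one-tailed
   Fisher exact test, and the missed-diagnosis classification.

## The tiering model

For each variant allele in a family the small-variant engine evaluates, in
order:

* **Legacy quality filter.** In legacy mode, an indel changing length by
  ≥ 3 nt, or a delins, in a flagged low-complexity region is dropped before
  tiering. This models the production-era quality settings that removed
  three causal multinucleotide indels; the audit reports only that those
  calls were "filtered out based on quality settings", so the precise rule
  here is a reconstruction calibrated to drop exactly that mechanism while
  keeping SNVs untouched.
* **Consequence class.** Loss-of-function → high impact; missense and
  in-frame indel → moderate impact; synonymous/non-coding → excluded.
  Consequences are gene-level; transcript-level nuance is out of scope.
* **Segregation.** De novo calls require reference parental genotypes plus
  read-level support: in legacy mode any alternate read in a parent vetoes
  the call (the mechanism that discarded a causal variant over a single
  mis-called maternal read among 32), while improved mode tolerates a
  parental alternate-read fraction up to `parental_alt_fraction_max`
  (default 0.05, chosen so one stray read in ~30 passes while a true
  heterozygous parent, at ~0.5, never does). Dominant inheritance requires
  all affected members to carry the variant and, under complete penetrance,
  no unaffected member; incomplete penetrance relaxes only the latter.
  Biallelic genotypes are confirmed by homozygosity from carrier parents or
  by a compound-heterozygous partner (both alleles must survive the
  filters; a surviving singleton in a Green biallelic gene remains a
  recessive *candidate*, capped at Tier 3). Hemizygous X variants in
  affected males accept a carrier mother. Under the `shared_variant`
  sibship model a variant absent from any affected sibling fails outright —
  the assumption that cost the cohort a de novo diagnosis in a discordant
  three-brother family; `per_individual` analyses each affected child on
  their own merits.
* **Frequency.** Population allele-frequency ceilings of 0.1 %
  (monoallelic and X-linked) and 1 % (biallelic). The audit states that
  frequency filtering existed but not its thresholds; these defaults are
  the package's own, exposed in `tier_config()`. A missing frequency
  annotation is read as 0 so novel variants are never frequency-filtered.
* **Panel intersection.** If the gene is Green on at least one applied
  panel (multiple panels merge by maximum rating) with a mode of
  inheritance compatible with the observed segregation: Tier 1 for
  high-impact or de novo protein-altering variants, Tier 2 for inherited
  moderate-impact variants. Otherwise a variant that passed every upstream
  rule is Tier 3. The Tier 1/Tier 2 boundary is not printed in the audit;
  placing de novo protein-altering changes in Tier 1 is the reconstruction
  that reproduces the published tier assignments of the biallelic
  splice/missense pair (Tier 1; Tier 2).

The copy-number path reports DEL/DUP calls strictly longer than 10 kb with
quality strictly above 10, and assigns Tier A iff the call interval
intersects (≥ 1 base) the span of a Green gene on an applied panel,
ignoring mode of inheritance. "Pathogenic region in a Green gene" is
modelled as the gene's full coding span; reciprocal-overlap fractions are
not required. Balanced inversions produce no copy-number call at all, so
the audited inversion whose breakpoints flanked a Green gene is missed
mechanically, not by annotation; `sv_breakpoint_review()` models the
researcher-grade breakpoint-aware review that catches it, and is provably a
superset of the Tier A detector.

Two operating points bundle these choices: `mode_config("legacy")`
(zero-tolerance parental reads, indel filter active, shared-variant
sibships, original panel versions) and `mode_config("improved")` (tolerant
parental support, no indel filter, per-individual sibships, updated
panels). Relaxing from legacy to improved never demotes a variant's tier —
a property the test suite asserts over generated cohorts.

## The synthetic cohort generator

`simulate_cohort()` emulates the audited cohort's *statistical structure*,
not its sequences: 114 families (72 trios, 15 multiplex families, the
remainder duos and singletons pro rata — the audit gives only the total for
non-trio structures), 72 % syndromic probands, one planted causal
archetype per hosting family, and 50 benign background variants per genome.
The twelve archetypes reproduce each audited mechanism: de novo
loss-of-function in a Green gene, a biallelic pair, de novo variants in
non-panel and updated-panel genes, a compound heterozygote whose indel the
legacy filter removes, a de novo call shadowed by one parental read (1 of
32, exactly as audited), a discordant multiplex sibship, a Tier A deletion,
a balanced inversion flanking a Green gene, a non-panel mosaic duplication,
a non-coding duplication, and a proband without parental genomes.

Background variants are placed only in filler genes (never panel or
archetype genes), inherited from one unaffected parent, with a 70/30
mixture of rare (< 0.08 %) and common (2–20 %) population frequencies.
This is deliberate: under complete penetrance an inherited heterozygote
from an unaffected parent can never reach Tier 1/2, giving a clean type-I
control for the filter chain, while singletons and non-Green recessive
candidates still contribute a realistic Tier 3 long list. Fifty variants
per genome is desk scale — real genomes carry millions of variants, but
only filter-surviving candidates matter for the audit, and the count is
configurable.

`expected_tier()` is the generator's oracle: a direct rule-table lookup of
the tier each archetype must receive under each mode, never computed
through the engine. The test suite requires 100 % agreement between engine
and oracle on every planted variant across five seeds and both modes, plus
agreement of the engine with an independent brute-force rule evaluator on
whole generated cohorts.

What passing these tests does *not* show: performance on real read-level
data (no alignment, no caller artefacts beyond the modelled ones), on
population structure, on phasing, or on consequence annotation errors —
the generator plants annotations, it does not derive them.

## The embedded cohort and the decomposition

`crs_fixture()` embeds the 36 audited cases. The 22 researcher-submitted
cases are transcribed field-for-field; the 12 further clinician-confirmed
diagnoses and 2 additional diagnoses are *schematic* records (placeholder
gene symbols `GMC23`–`GMC33`, a synthetic Tier 1/2/A split of 8/2/1)
constrained by every published aggregate: 16 clinician-confirmed cases, 13
of them from Tier 1/2/A data, 34 confirmed diagnoses, 29 identifiable by
the combined national-guidance strategy, 14 researcher-only diagnoses in
validated developmental-disorder genes, and 32 syndromic diagnoses. Which
two diagnosed cases are non-syndromic is not printed; the fixture assigns
the two research-classified structural cases, and any choice of two
reproduces the published rates. Similarly, which single schematic case
brings the national-guidance count to 29 is inferred (the X-linked deletion
case), not printed.

Each detection strategy is a predicate over case attributes
(`found_set()`); combined strategies union their found-sets with the
baseline and report sensitivity as a nearest-integer percent. One rounding
rule — half away from zero — reproduces every published percentage
(47/76/85/88 and the +18/+12/+29/+9 increments); base R's round-half-even
would not. The missed-diagnosis number-letter codes are reverse-engineered
from the published per-case codes: structural class takes precedence over
research gene, then non-Green gene, then legacy filtering (the audited
codes force this order — the research-gene structural case is coded as a
structural miss, and the parental-read case as a panel miss). The letter
"E" (discordant multiplex) is attested by a single case; its definition is
inferred.

The syndromic comparison uses the unique integer contingency table
consistent with the published stratum rates (39.0 % of 82 → 32 diagnosed
syndromic; 6.25 % of 32 → 2), and the one-tailed Fisher exact test is the
hypergeometric tail in the direction of the observed association, tested
against exhaustive enumeration over all tables with fixed margins.

## Numerical and degenerate-input choices

* Reportability thresholds are strict (`> 10 kb`, `> 10`), read literally
  from the stated rule.
* Coordinates are 1-based inclusive internally and in VCF; conversion to
  0-based half-open happens only at the BED boundary.
* VCF genotypes cannot express mosaicism, so mosaic carriers travel in a
  dedicated `MOSAIC` FORMAT key (allele fraction; 0 = constitutional).
* A parent with zero sequencing depth rejects a de novo call with reason
  `no_parental_coverage` rather than passing silently.
* Multi-allelic sites are decomposed into one record per ALT allele;
  per-allele read depths follow the AD field.
* Empty inputs (header-only VCFs, zero-background configurations) are
  legal and round-trip.
* Ties in panel ratings resolve by maximum (green > amber > red).

## Problem sizes

The test suite runs generated cohorts of 14 families with 3–8 background
variants per genome for the multi-seed property checks, and one full-scale
114-family, 50-background run end-to-end (generation, tiering, audit),
which completes in well under a minute on a single CPU. The acceptance
script regenerates and re-tiers a full-scale cohort, verifies archetype
recovery in both modes, and then recomputes every headline figure from the
embedded cohort.

## Known limitations

* The schematic records for the clinician-confirmed cases are constrained
  by aggregates, not transcribed; a future release of the underlying
  per-case table should be checked against them.
* The combined national-guidance strategy is flag-driven (the
  identifiability column is itself audited data), not derived from a rule,
  because the guidance it reflects was draft and unpublished.
* Box 1/Box 2 rule text is reconstructed from outcomes, not quoted
  definitions; the Tier 1/2 boundary and the indel-filter shape are
  calibrated reconstructions and are documented as configurable.
* No in-silico pathogenicity scores, no phasing, no mitochondrial logic,
  no live panel-registry client, and no re-implementation of external
  phenotype-driven rankers (ranks are annotations).
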