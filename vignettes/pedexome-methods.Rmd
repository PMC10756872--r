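---
title: "Family-based exome variant prioritization with pedexome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based exome variant prioritization with pedexome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedexome)
```

## The problem and the pipeline

Non-syndromic tooth agenesis (TA) is the congenital absence of permanent
teeth without involvement of other tissues.  Small family-based whole-exome
studies of such phenotypes face a characteristic analysis problem: a handful
of affected individuals, heterogeneous family structures (a few multiplex
families with several affected relatives, plus sporadic single-patient
families), and thousands of candidate alleles that survive variant calling.
pedexome implements the prioritization strategy such studies use, as a
tested, reusable pipeline:

1. **Subgrouping.** Sequenced affected individuals from the same family form
   one subgroup per multiplex family; all sporadic patients are pooled into a
   single subgroup.  This concentrates the within-family inheritance signal
   while still letting sporadic cases contribute jointly.
2. **Allele association.** For every variant and subgroup, a 2x2 table of
   alt/ref allele counts (two alleles per genotyped patient) against an
   external control cohort is tested with a two-sided Fisher exact test; a
   variant passes the screen when some subgroup has `p < alpha` (default
   0.05) and allele odds ratio `OR > 1`.
3. **Annotation cascade.** HIGH-impact (SnpEff class) variants pass; MODERATE
   variants pass only when predicted damaging by any per-transcript
   SIFT/PolyPhen call or rarer than 0.1 in the Asian reference panel;
   LOW/MODIFIER fail.  Genes must additionally appear in at least one of the
   configured gene-phenotype lists (Open Targets tooth agenesis, GO
   odontogenesis, HPO oligodontia).
4. **Segregation.** Multiplex subgroups are scored under an autosomal
   dominant model (affected het or hom-alt carriers), the sporadic pool
   under a recessive model (hom-alt only).
5. **Evidence annotation.** Retained variants are joined with LOEUF
   constraint scores and an ortholog-alignment conservation score; prediction
   calls are summarized per tool.
6. **Enrichment.** The retained gene set is expanded one hop in a
   protein-protein interaction network (STRING-style scores, confidence
   >= 700) and tested term-by-term with the hypergeometric
   over-representation test, Benjamini-Hochberg adjusted (threshold 0.01).

A variant is retained iff every stage passes; every gate decision is
recorded in a per-variant *filter trace* so exclusions are auditable.

## Statistical details and conventions

**Fisher exact test.** The two-sided p-value is computed by the
point-probability method: with margins fixed, all hypergeometric table
probabilities not exceeding the observed one are summed (ties compared with
the customary `1 + 1e-7` relative tolerance).  A zero margin gives `p = 1`.
The implementation builds the full conditional distribution with `dhyper`;
the test suite checks it against an independent log-choose enumeration for
every 2x2 table with total at most 60, and against `stats::fisher.test`.

**Odds ratio.** The allele-count cross-product ratio, with the
Haldane-Anscombe correction (0.5 added to all four cells) whenever a cell is
zero, so the `OR > 1` gate is always evaluable.  The OR gate only encodes
directionality (alt allele more frequent in patients); significance is
carried entirely by the p-value.

**No multiple-testing correction at the association stage.**  The screen
reproduces a raw `p < 0.05` filter and is documented as a screen, not an
inference; correction is applied where the downstream analysis makes claims
(enrichment).

**Subgrouping convention.**  A variant passes association when *any*
subgroup passes.  Whether each multiplex family should be tested separately
or jointly is ambiguous in the underlying design; per-family tests plus an
any-subgroup rule retains both readings in the trace and is the adopted
convention.

**Fail-closed MODERATE variants.**  A MODERATE variant with neither
prediction calls nor an Asian MAF has no rescue route and fails with reason
"insufficient evidence".  The rescue threshold is strict (`< 0.1`), and
"possibly damaging" PolyPhen calls count as damaging — both choices match
the retention pattern of the published candidates (an in-frame insertion
rescued by MAF alone; a missense variant carried only by `P` calls).

**Segregation is support counting, not strict co-segregation.**  Published
family tables show affected non-carriers in multiplex families and
heterozygous sporadic carriers under a nominally recessive model.  Requiring
perfect co-segregation would discard the published candidates; the pipeline
instead counts model-consistent affected carriers (default threshold:
support >= 1 in some subgroup), reports heterozygous carriers in recessive
subgroups as *model-inconsistent carriers*, and emits the full genotype
matrix for human review.

**LOEUF is annotation only.**  Constraint scores (flagged when LOEUF < 1)
inform interpretation but never gate retention, since no LOEUF cutoff is
part of the filtering design.

**Conservation.**  The scorer maps an ungapped human residue position to its
alignment column and reports the fraction of non-gap ortholog residues
matching the human residue (the human row is excluded; ortholog gaps leave
the denominator).  The conservation call threshold defaults to 0.8 — the
design intent is "well conserved across mammals", and 0.8 means at most one
mismatch among the eight orthologs typically aligned.  Shipped alignments
are deterministic synthetic stand-ins (named `*_synthetic.fasta`) built to
satisfy the qualitative conservation claim; they are not biological
sequences.

**Enrichment.**  The universe defaults to the union of all term sets (an
explicit universe can be supplied).  Adjustment is Benjamini-Hochberg; the
g:SCS procedure used by the g:Profiler service depends on its term ensemble
and is not reproducible offline, so adjusted p-values are not comparable to
service output and the method name is recorded in the result metadata.
Neighbor expansion is strictly one hop — expanding an expanded set may grow
it further, which is documented behavior, not idempotence.

## The synthetic cohort generator

`simulateCohort()` emulates the study design so the whole pipeline is
testable without data access: 3 multiplex + 6 sporadic families (defaults),
family sizes 3-6, a 100-individual diploid control cohort, dominant causal
variants planted in multiplex families and recessive ones in sporadic
families, full penetrance by default, and planted alleles at control
frequency 0.005 (rare, consistent with their annotated panel MAFs).
Genotypes are stored as unphased allele-pair strings (`"C/CGCT"`), with
`"./."` for unsequenced relatives, and all downstream counting skips
missing genotypes.  Transmission follows the law of segregation; a
Mendelian-consistency checker (`mendelianConsistent()`) verifies that no
child carries an allele absent from both parents.

Each decoy variant is constructed to fail **exactly one** named gate while
passing all others, enabling stage-level unit tests:

* *association*: a single affected het carrier against a common control
  allele frequency (drawn from 0.25-0.45 and floored at AN/20), which makes
  `OR <= 1` or `p >= 0.05` certain — a zero-carrier variant would also fail
  segregation, so one carrier is required;
* *impact*: a LOW-impact allele carried by a multiplex family;
* *prediction/MAF*: MODERATE with tolerated calls and Asian MAF 0.35, i.e.
  both rescue routes closed;
* *ontology*: a gene excluded from every phenotype list;
* *segregation*: heterozygous in every sporadic case and absent from
  multiplex families — no subgroup has a model-consistent carrier.

What the generator does **not** emulate: linkage and haplotype structure,
sequencing error, population stratification between patients and controls,
phenocopies, or annotation noise.  Passing recovery tests therefore
demonstrates the pipeline's logic under clean Mendelian signal, not its
robustness to real-data artifacts.

## The built-in study fixture

`taFixture()` transcribes the published nine-family cohort: 14 sequenced
affected individuals and the five candidate variants (MAST4 in-frame
insertion, ITGA6 frameshift, PITX2 stop-gain, CACNA1S and CDON missense)
with their printed genotypes, impact classes, per-transcript predictions,
MAFs and LOEUF scores.  Because no per-variant control counts were
published, the fixture scales each printed Asian MAF to the AN = 200
control allele number (MAST4 3, CACNA1S 8, CDON 13) and assigns counts of 1
and 2 to the two HIGH-impact variants without printed MAFs (ITGA6, a novel
frameshift; PITX2) — a fixture convention, documented here, not study data.
LOEUF is likewise available only for the three genes it was printed for.

```{r fixture}
coh <- taFixture(decoysPerGate = 4)
res <- runCascade(coh, taGeneLists(4))
variants(coh)[res$retained, c("gene", "impact", "protein_change")]
carrierCount(coh, "5:65892764:C:CGCT")        # MAST4 risk-allele carriers
carrierCount(coh, "4:111542154:G:A", "het")   # PITX2 heterozygotes
```

## Numerical choices and problem sizes

* Fisher tie comparison uses relative tolerance `1 + 1e-7`; the oracle
  sweep covers all tables with total <= 60 and requires agreement within
  `1e-9`.
* The hypergeometric test is checked against closed-form log-choose
  summation on every configuration with universe <= 25 and against literal
  draw enumeration on small cases.
* Recovery is measured over 200 seeded cohort replicates (requirement:
  >= 95% of planted variants retained, 100% of decoys excluded).
* The enrichment null calibration uses 1000 replicates of 40 random terms
  (sizes 400-800) against random 250-gene queries in a 2000-gene universe;
  that geometry keeps overlap counts large enough that the discrete
  hypergeometric null is near-continuous, so the achieved size of the
  nominal 5% test is interpretable (the test is conservative by
  construction and sits slightly below 5%).
* Report rows are ordered by (chrom, pos, alt) with radix sorting, and all
  generators derive their randomness from the spec seed, so reruns are
  byte-identical.

## Known limitations

* Published enrichment p-values and the pre-filter variant count are
  database-version dependent and are not reproduced; enrichment output is
  validated structurally and statistically instead.
* Only autosomal dominant/recessive models are scored; no X-linked model,
  no de-novo calling (no unaffected relatives were sequenced), and no
  formal linkage/LOD computation.
* Gene symbols are the join key throughout; no identifier mapping service
  is consulted.
* The association screen uses raw p-values by design; its output is a
  candidate list, not a set of significant associations.
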