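---
title: "Predicting canine coat color and ear carriage from a 16-site variant panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting canine coat color and ear carriage from a 16-site variant panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canidmorph)
```

## The problem

Externally visible dog morphology — coat color, patterning, white
markings, ear carriage — is controlled by a small number of well-mapped
Mendelian loci with strong epistatic structure. Given diploid genotypes at
those loci, the phenotype is largely computable; conversely, two
populations that share a phenotype but not the underlying alleles cannot
owe that phenotype to shared ancestry. `canidmorph` implements both
directions: a deterministic genotype-to-phenotype rule engine, and a
cross-population allele-concordance report. The worked system is the
Australian Kelpie (both conformation and working varieties) compared with
the Dingo.

## The panel

The default panel (`default_panel()`) holds sixteen CanFam3.1 sites:

* **E-locus (*MC1R*)**: the recessive ginger stop variant `e`
  (CFA5:63694334 G>A, p.R306\*) and the melanistic-mask variant
  (CFA5:63694460). The mask allele is the *reference* C — an example of
  why the panel never equates "reference" with "wild-type"; each site
  instead records which allele causes the phene and under which
  inheritance mode.
* **B-locus (*TYRP1*)**: four brown variants (p.C41S, p.Tyr185\*,
  p.Q331X, p.345delP). Any two brown alleles — including compound
  heterozygotes across different sites — give a brown eumelanin.
* **K-locus (*CBD103*)**: the 3-base deletion is dominant black
  (self-color); the insertion, which is the reference, permits A-locus
  colors.
* **A-locus (*RALY*/*ASIP*)**: the RALY 16-bp duplication, the ASIP
  239-base insertion, and three ASIP exonic SNVs, following the published
  per-site decomposition; haplotype interpretation (A^y vs a^t vs a) is
  the engine's job, not the panel's.
* **S-locus (*MITF*)**: the SINE insertion upstream of the
  melanocyte-specific promoter (piebald/extreme white when homozygous;
  again phenotype-on-reference) and the promoter length polymorphism whose
  alleles are written in run-length notation.
* **Ear sites**: the intergenic *MSRB3*–*HMGA2* SNP (CFA10:8085469; drop
  ears are C/C) and the *MSRB3* 3′UTR insertion polymorphism
  (CFA10:8038433; a 10-base insertion in Kelpies, a 5-base insertion in
  the Dingo, none in drop-eared dogs).

Coordinates are 1-based; multi-base records store an inclusive end.
Indels keep their published orientation (no left-alignment of the panel
definition itself; VCF anchoring is handled by the I/O layer). Panels
round-trip through a YAML schema (`write_panel()`/`load_panel()`), and the
compiled-in default is unit-tested field by field.

The D-locus (*MLPH* dilution) site is *not* part of the default panel:
the published matrix has no dilution row because the region's high GC
content defeats short-read coverage. It is available as `mlph_site()` via
`extend_panel()` for cohorts that do carry D-locus calls, and the
simulator uses the extended panel so the coverage-dropout artifact has a
target. When the panel lacks a D site, coat predictions report dilution
`"unknown"` rather than guessing.

## Run-length allele codec

Length-polymorphism alleles are written as maximal (count, base) runs:
`"12C9A2G12A"` decodes to the 35-base reference allele, labelled `35A`.
Labels are the decoded length plus a letter awarded in order of
discovery; the packaged registry ships exactly the attested labels
(`35A`, `35B`, `33C`, `31A`), and `label_allele()` extends it by
continuing past the highest letter already used for a length (a novel
33-base allele becomes `33D`, not `33A`). Non-canonical codes such as
`"2A3A"` are accepted with a warning and canonicalized (tolerant reader);
whitespace is stripped before decoding because published expansions
contain typesetting spaces. `decode` and `encode` are exact inverses,
enforced property-style in the tests.

## Genotype I/O and call semantics

Calls are unphased; heterozygotes are canonicalized reference-first, and
every comparison in the package treats (x, y) and (y, x) as equal. Three
statuses are distinguished:

* `called` — both alleles observed;
* `missing` — no call at all (`"0 0"` in tables, `./.` in VCF);
* `low_coverage` — a call exists but read support was thin; it "does not
  exclude heterozygosity", so downstream predictions are only flagged
  `provisional`, never changed.

The distinction matters: a single supporting read is evidence worth
keeping, but not evidence worth asserting a genotype from. Claims that
would require read-level data are represented in this package *only*
through these semantics.

VCF input follows two dialects, differing in what an absent record means:
`all-sites` files assert homozygous reference at absent panel sites;
`sites-only` files leave them missing. The writer emits plain-text VCF
with a `DP` field (low-coverage calls get `DP` below the reader's
threshold, default 4 reads — the conventional minimum per-allele support)
and preserves sample metadata in header lines so cohorts round-trip
exactly. Where the panel does not define an insertion's literal sequence
(the CBD103/TYRP1 3-base indels, the MITF SINE), the writer uses a
synthetic placeholder of the correct length; the reader matches by
sequence where known and by inserted length otherwise, so placeholder
content can never alter a genotype.

## The phenotype engine

Rule precedence, applied in order with every fired rule recorded in the
prediction's `rationale`:

1. `e/e` at *MC1R* → ginger/cream; eumelanin loci reported as carriers;
   mask invisible on this background.
2. Else K-locus dominant black → solid coat, tan points suppressed, hue
   from the B-locus.
3. Else A-locus: a^t/a^t → tan points; A^y → sable/fawn; a/a → recessive
   solid color. A^y calls require the deletion haplotype at both indels
   *and* A^y-consistent exonic alleles; a^t calls require homozygous
   insertion at both indels. Combinations that fit neither haplotype —
   which can arise from imputation or genotyping error — degrade to
   `unknown` with a note, never to a silent choice.
4. B-locus brown needs two brown alleles across the four *TYRP1* sites;
   two heterozygous sites count as a compound heterozygote under an
   assumed-trans phasing, flagged `phase unknown` (unphased short-read
   genotypes cannot exclude cis).
5. Mask visibility is reported as a boolean conditioned on base color, so
   carrier information survives even when the mask cannot show.
6. Dilution: `unknown` when the panel has no D site or its call is
   low-coverage.
7. White extent: homozygous SINE → piebald/extreme; otherwise graded by
   the two promoter allele lengths against the 35-base reference (both
   ≥ 35 → modest, both < 35 → minimal, mixed → intermediate, reported as
   modest with a note since the alleles act co-dominantly).

Missing calls are imputed homozygous-reference with
`provisional = TRUE`. This imputation is a deliberate design choice: it
is what a geneticist does implicitly when predicting "brown with tan
points" for a dog whose ginger-site call failed, and it is required to
reproduce the published per-dog predictions. The flag preserves honesty
about it.

Ear predictions combine the two sites: the SNP calls prick (T/T), drop
(C/C) or possibly semi-erect (C/T); the UTR insertion calls prick
(insertion on both haplotypes) or drop (del/del). The consensus is
`discordant` only when both are informative and conflict; a low-coverage
UTR call becomes `unknown` and flags the prediction provisional.

The engine's verdicts are genotype-level predictions, not guarantees of
appearance: hue-modifier loci (the unexplained variation in brown
intensity), brindle, and grizzle are outside the panel and outside scope.

One representational choice deserves note: predictions need a sable/fawn
base color (the A^y coat on the reference haplotype), so `base_color`
ranges over black, brown, sable_fawn, ginger_cream and unknown.

## Concordance reporting

`allele_counts()` counts called alleles only; missing calls leave the
denominator (counts always sum to `2 × (n_samples − n_missing)`), which
is how locus-constrained records — samples sequenced at a few genes only —
contribute exactly where they have data. A **fixed difference** is a site
where two populations' called allele sets are disjoint. A locus is
**diverged** when any of its sites is a fixed difference, or when the two
populations achieve the same phene through different loci; the yellow-coat
mechanism check compares the E-locus `e` frequency against the proportion
of A^y A-locus states per population. Single-sample populations are
legal and reported with their n; no confidence intervals are attached at
n = 1 rather than suppressing the row. Formal introgression statistics
(D/f-statistics, admixture models) are deliberately out of scope: the
report mirrors an allele-sharing argument, nothing more.

On the packaged cohorts the report flags *MITF*, *RALY*, *ASIP*, the
*MSRB3* 3′UTR, and (via the mechanism rule) *MC1R* — the
Kelpie-vs-Dingo divergence verdict.

## Packaged cohorts and the simulator

`load_paper_fixture("tables")` is the 14 × 16 segregation matrix
(12 Kelpies, 1 Dingo, 1 Labrador; the Labrador enters only through the
ear sites). `load_paper_fixture("dingo_panel")` is the 26-Dingo set: one
whole-genome animal plus 25 locus-constrained records. The published
ASIP exon-4 tallies are internally inconsistent (itemized counts 16+6+1
sum to 23 against a stated total of 22); both readings ship, itemized by
default, and every test that touches them uses ratios robust to the
difference.

`simulate_cohort()` draws genotypes per site under Hardy–Weinberg
proportions at configured frequencies — except the A-locus, which is
sampled as two-allele haplotypes (A^y vs a^t) because independent per-site
sampling would fabricate contradictory A-locus states that real dogs never
show. Default frequencies are the empirical frequencies of the packaged
cohorts (illustrative of the study populations, not breed-wide
estimates); the MLPH dilution-allele frequency defaults to 0.10 in
Kelpies, a token nonzero value reflecting that dilute dogs occur in the
working variety. Missingness is injected per site (default 2%), and
sites listed as low-coverage regions (default: the MLPH site, emulating
the GC-rich dropout) have calls flagged `low_coverage` at the dropout
rate (default 0.8). A seed is mandatory; identical configurations give
byte-identical outputs.

What the simulator does *not* emulate: linkage beyond the A-locus,
genotyping error, allele-specific dropout, population structure, or
read-level artifacts. Passing tests on simulated cohorts therefore
demonstrate pipeline correctness — round-trips, conservation, rule
invariants, frequency recovery — not robustness to every failure mode of
real sequencing data.

## Numerical and testing choices

Frequency-recovery checks use binomial sampling theory: at n diploids the
estimate should fall within 3 standard errors
(`3·sqrt(p(1−p)/2n)`) of the configured frequency; the test suite checks
this at n = 1000 and a mean absolute error below 0.02 over 100
seeded replicates at n = 500 on a single-site panel (sizes chosen to keep
the default suite fast while leaving the binomial bounds meaningful).
Property-style tests run the codec round-trip on randomized sequences,
table/VCF round-trips on simulated cohorts, the two epistasis invariants
(`e/e` never yields a eumelanin base; dominant black never yields tan
points) on randomized genotype vectors, and fixed-difference symmetry.
All randomized tests fix their seeds.

## Known limitations

* Genotypes are unphased throughout; compound-heterozygote brown is an
  assumption, flagged as such.
* The panel is CanFam3.1-specific; no coordinate lift-over is provided —
  panels for other assemblies are user-supplied YAML.
* The a^t call requires both the RALY duplication and the ASIP insertion;
  published descriptions conflate the two, and dogs carrying only one
  would classify `unknown`.
* Declared-color matching (`coat_matches_declared()`) understands the
  registry vocabulary (Brown, Black and Tan, …) only.
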