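---
title: "Star-allele calling and phenotype translation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-allele calling and phenotype translation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxkit)
```

This vignette is the package's account of its science: the calling model
and its assumptions, the knowledge-base design, the phenotype rules, what
the synthetic-data generator does and does not emulate, and the places
where the design was genuinely open and a choice had to be made.

## The knowledge base

The catalog is a single TSV with one `record_type = "allele"` row per
defining variant per star allele (plus one row per gene for the reference
allele `*1`, whose defining set is empty) and one `record_type =
"diplotype"` row per gene x drug x diplotype with the clinical
interpretation. Each defining variant carries both GRCh37 and GRCh38
coordinates, so the same catalog drives either build; an absent position
is an empty field and excludes the gene from that build's regions.

Structural invariants are enforced at load time: `*1` present per gene
with an empty set, unique star names, no two alleles of a gene with
identical defining sets, `(gene, drug, diplotype)` unique after alias
normalization, and every interpretation prefixed with one of the four
CPIC evidence strengths (`Strong`, `Moderate`, `Optional`,
`No recommendation`) in brackets. The catalog *content* — which alleles,
which variants, which activity values — is data, curated from
CPIC/PharmVar-published definitions, and is deliberately not hard-coded:
amending the TSV is the supported way to track guideline updates.

Two content choices deserve explanation:

* **IL28B** is carried under that legacy symbol (with the variant
  rs12979860 that predicts interferon response); the current HGNC symbol
  is IFNL3, and the symbol is purely a label here.
* **Compound haplotypes are not co-packaged with both of their parts.**
  Under unphased short-read data, a catalog containing TPMT `*3A`
  (= c.460G>A + c.719A>G) *and* `*3B` (c.460G>A alone) *and* `*3C`
  (c.719A>G alone) makes the common `*1/*3A` carrier indistinguishable
  from the trans configuration `*3B/*3C`: both imply the same dosage
  vector. Rather than pretend to resolve what the data cannot, the
  packaged catalog keeps `*2`, `*3A`, and `*3C` (a set whose diplotypes
  are all uniquely decodable — verified by exhaustive enumeration in the
  tests) and omits `*3B`; CYP2B6 similarly carries `*6` without the
  single-SNP `*4`/`*9` sub-haplotypes. Partially overlapping sets whose
  diplotypes remain decodable (SLCO1B1 `*5` ⊂ `*15`) are kept.

Diplotype aliases are normalized by sorting the two star names by numeric
value, then suffix (`*2` < `*2A` < `*10`), so lookup is order-insensitive
and reports are deterministic.

## The calling model

Calling is **dosage-based and unphased**. The sample's VCF is restricted
to the catalog regions, multi-allelic records are split with per-allele
dosage, and each catalog locus receives a state: `hom_ref`, `het`,
`hom_alt`, or `no_call`. A pair of alleles is consistent with the
observations iff at every *observed* locus the dosage implied by the pair
(how many of the two alleles contain that variant) equals the observed
dosage. No-call loci are excluded from the check — they carry no
information, so removing an observation can only grow the candidate set
(a monotonicity property the tests assert).

All unordered pairs over the gene's alleles are enumerated (gene panels
here are small — at most 7 alleles, 28 pairs — so exhaustive enumeration
is exact and fast). Among consistent candidates the reported pair
maximizes the number of observed alt-bearing loci explained, then
minimizes the number of non-reference alleles (parsimony: `*1/*2` beats
an exotic pair explaining the same data), then falls back to
normalized-alias lexicographic order. The ranking exists purely to make
clinical reports deterministic; the *quality flag* is what carries the
epistemic state:

* `exact` — one candidate, all of its defining loci observed;
* `ambiguous` — several candidates (all listed in the report's caveats);
* `incomplete` — the winner rests on at least one no-call defining locus;
* `no_call` — every catalog locus of the gene is no-call;
* `unresolved` — no pair fits (e.g. contradictory dosages); reported,
  never raised.

When several candidates coexist with missing data, `incomplete` takes
precedence over `ambiguous`: a conclusion resting on unobserved loci is
the stronger caveat.

Two VCF-interpretation policies are explicit parameters rather than
baked-in assumptions, because both input styles occur in practice:

* `genotype_complete` — whether the absence of a record at a catalog
  locus means homozygous reference (typical for genotyped WGS VCFs) or
  no-call (typical for sparse targeted call sets, and for alignment
  dropouts). Default `FALSE`: the conservative reading.
* `include_filtered` — whether records failing FILTER contribute
  genotypes. Default `FALSE`: a conservative clinical posture.

A REF mismatch between VCF and catalog at the same position warns and
yields no-call — never silent acceptance; an rsid match at a different
position (e.g. lifted-over coordinates) is used as a logged fallback.

## Phenotype translation

CYP2D6 uses the activity-score path: score(\*a/\*b) = v(\*a) + v(\*b)
with packaged values \*1 = 1.0, \*3 = \*4 = \*6 = 0, \*10 = 0.25
(the consensus-revised value), \*17 = 0.5, \*41 = 0.25, and bins
UM > 2.25 < NM ≥ 1.25 > IM > 0 = PM. The bin edges at 1.25 and 2.25 are
inclusive to Normal because Ultrarapid is defined strictly above 2.25;
score 0 is Poor, reading the Intermediate range as the open interval
(0, 1.25). The reference value 1.0 per \*1 allele is the standard CPIC
convention. The mechanism is data-driven: any gene whose alleles all
carry activity values opts in (`activity_genes()`), with an override
argument for custom configurations.

Every other gene uses table lookup: the diplotype row's summary column
carries the phenotype category, and the interpretation/dosing text rides
along into reports. CYP2C19 \*1/\*17 is catalogued as **Rapid
metabolizer** — guidelines have historically disagreed (ultrarapid in the
2015 SSRI guideline, normal per DPWG), but the \*17 and \*1 alleles do
differ in pharmacokinetic parameters, and since CPIC recommendations for
normal and rapid CYP2C19 metabolizers coincide, the choice does not
affect dosing. `*17/*17` remains Ultrarapid.

An uncatalogued diplotype of an unscored gene yields an *indeterminate*
assignment — a value, not an error — and is flagged in reports.

## Reports

Three formats mirror the operator workflow (choose gene(s), then
drug(s)): `single_gene_drug` with full interpretation; `summary` with one
row per gene and **no** interpretation or dosing (information hiding the
tests assert literally: no catalog dosing string appears anywhere in a
serialized summary); and `full`, per-gene blocks at single-pair detail.
Non-exact calls are listed in a caveats section, never dropped.
Timestamps are injectable so golden-file comparisons are byte-exact; TSV,
JSON, and plain-text serializations are deterministic given a fixed
timestamp.

## The concordance harness

Per-gene concordance is **sample-level exact set equality** of
catalog-locus variant calls (or of normalized diplotype aliases): the
notion "samples with variants reported correctly" admits no partial
credit here, and percentages are reported to 2 decimals. Genes absent
from a consensus truth panel are skipped with a note rather than counted
against either side. Discordance triage assigns each adjudicated variant
to one of five categories (caller-only correct, truth-only correct, both,
neither, no contig) with percentages to 1 decimal — recomputed from
counts on every call, so rounding can make totals fall just short of
100%. Percentage rounding is half-up, matching how printed tables round.

## The fixture generator

`generate_sample_vcf()` emits exactly the alternate records implied by a
chosen diplotype per gene (shared variants at dosage 2, private ones at
1), on either build — GRCh38 fixtures use `chr`-prefixed contigs and
GRCh37 fixtures bare ones, deliberately exercising contig normalization.
Noise is applied in a documented order with a single seeded generator
(dropout per record, then at most one spurious non-catalog record per
gene region, then genotype no-calls per surviving record), so identical
specs give byte-identical VCFs on any platform. Spurious records are
placed only *inside* catalog regions: outside they would be invisible to
the pipeline and would test nothing.

What the generator emulates: genotyped VCF input, allele dropout,
missing genotypes, off-catalog contamination, both builds' naming
conventions. What it does not: read-level errors, alignment artifacts,
multi-sample VCFs with cohort-level genotype likelihoods, structural
variation, and phasing. Passing round-trip tests therefore demonstrate
the correctness of the catalog/caller/report machinery on well-formed
variant calls — not robustness to upstream alignment or calling error,
which is the province of the secondary-analysis tools that produce the
VCF.

Cohort generation draws per-gene diplotypes uniformly over the catalog's
unordered pairs (or from a user weight table), derives per-sample seeds
from the master seed, and writes both truth-set kinds alongside the VCFs.

## Verification strategy and problem sizes

The test suite asserts, among others: equivalence of the caller's
candidate sets with an independent brute-force enumerator (indicator-
matrix arithmetic, a separate code path) over 1000 random synthetic
catalogs of up to 8 alleles over up to 6 loci; 100% exact round-trip
recovery of **every** diplotype constructible from the packaged catalog
(97 diplotypes across the 13 genes) through fixture → VCF → extraction →
calling; binomial behavior of dropout noise across 60 seeds; the
no-call safety property (noise may downgrade a call's quality but never
flips it to a different exact diplotype); and byte-level determinism of
fixtures and reports. These sizes keep the default suite under a minute
while covering the full combinatorial space the packaged catalog can
express.

## Known limitations

* No CYP2D6 copy-number events (`*5`, duplications, hybrids) and no HLA
  typing; variants without rsIDs are not representable in the catalog
  schema.
* Unphased input means genuinely phase-dependent distinctions are out of
  reach by design; the caller's job is to say so (`ambiguous`), not to
  guess.
* The catalog is a snapshot; activity values and interpretations must be
  re-curated as guidelines are amended.
* Drug–drug interaction phenoconversion is not modeled.
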