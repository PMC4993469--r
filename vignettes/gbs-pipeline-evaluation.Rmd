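---
title: "Evaluating GBS SNP-calling pipelines: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating GBS SNP-calling pipelines: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbseval)
```

## The problem

Genotyping-by-sequencing (GBS) reduces a genome to restriction fragments
— here the methylation-sensitive enzyme ApeKI, recognition site `GCWGC`
(W = A or T) — and sequences barcoded, multiplexed samples on those
fragments. Many bioinformatics pipelines turn such reads into SNP
genotypes, and on identical input they disagree substantially: in the
number of loci called, the amount of missing data, the heterozygosity
they report, and above all the fraction of genotype calls that are
actually correct. `gbseval` implements the evaluation methodology needed
to compare pipelines rigorously when a deep-resequencing truth set is
available for the same samples, and ships a fully labelled synthetic GBS
study generator so that every stage of the methodology can be validated
by recovering planted parameters.

The package evaluates *call sets*; it deliberately does not re-implement
any SNP-calling pipeline, aligner or demultiplexer. Real pipelines enter
either as VCFs (plus optional alignment-evidence tables) or as
parametric error profiles inside the generator.

## Genotype representation

Calls live in a long tibble — one row per site × sample — with a
categorical state (`hom_ref`, `het`, `hom_alt`, `missing`) and optional
read depth. Only biallelic records are kept; multi-allelic VCF records
are dropped and counted in a load report so that
`loaded + dropped = total` always holds. Phased and unphased separators
are equivalent, genotype order is ignored (`1/0` is `het`), and
half-missing diploid calls (`./1`) are missing.

A locus is identified by (chromosome, 1-based position, variant class).
Alleles are deliberately excluded from the site key because catalogues
from different pipelines — including *de novo* pipelines whose tags were
anchored to the reference after the fact — are compared positionally. An
indel and a SNP anchored at the same coordinate remain distinct sites.
Chromosome names are compared after stripping an optional `chr` prefix
(configurable), and sites sort naturally: numeric chromosome names by
value, then others lexicographically.

## Site filtering

Four shared filters are applied to every pipeline's calls before any
accuracy claim, in a fixed order:

1. **Depth mask** (`min_depth`, default 2): calls supported by fewer
   reads become missing. No site is removed.
2. **Missing rate** (`max_missing`, default 0.80): sites whose missing
   fraction *exceeds* 80% are removed (≤ 80% retained — it is a
   *maximum*).
3. **Minor allele frequency** (`min_maf`, default 0.05): MAF is computed
   from called genotypes only (two alleles per call, one of each for a
   het); sites *below* 0.05 are removed (≥ 0.05 retained — a
   *minimum*).
4. **Heterozygous-locus purge** (`het_locus_threshold`, default 0.50):
   sites with *strictly more than* 50% heterozygous calls among called
   genotypes are removed. In a panel of inbred lines, which are
   essentially homozygous, such loci are the signature of two collapsed
   paralogous loci masquerading as one heterozygous locus.

The order matters and is fixed by the package: depth masking changes
both missingness and allele counts, so it must run first; the het purge
runs last because it removes loci from the otherwise-final catalogue.
All-missing sites always fall to the missing-rate rule, never to MAF.
Each removed site is logged with the first rule it failed and the
measured value, and filtering is idempotent.

## Concordance with the truth set

Accuracy is the fraction of non-missing GBS calls equal to the truth
genotype at the same locus and sample. Missing GBS calls leave the
denominator but are counted in the missing-data percentage;
heterozygosity is reported as the share of called genotypes that are
heterozygous; a het against either homozygote is a plain mismatch — no
half-credit for a shared allele.

One genuine ambiguity is what to do with catalogue sites absent from the
truth callset. A deep-resequencing truth set covers most but not all of
the genome, and a site it does not list may be invariant (so the truth
is implicitly `hom_ref`) or simply uncallable. The package implements
both conventions — *complete* (absent ⇒ `hom_ref`) and *partial*
(absent ⇒ excluded) — reports both denominators in every summary, and
lets the `truth_set()` carry the headline choice. The default is
*complete*, appropriate when the truth covers ~95% or more of the
genome; note that for a fully synthetic study the two coincide, since
every simulated catalogue site exists in the simulated truth.

Percentages throughout the package are rounded half *up* (not half to
even) to the printed precision — one decimal by default, with integer
variants alongside where published comparisons use whole percentages —
and every percentage is recomputable from counts written to the same
report file; counts are authoritative.

## Catalogue overlap

`pairwise_overlap()` is plain positional set arithmetic with the margins
`common + only_a = total_a` and `common + only_b = total_b` guaranteed
by construction. `nway_partition()` assigns every site of the union of
up to 10 catalogues to the cell for the exact subset of catalogues
containing it (the Venn cells); cell disjointness, union coverage, and
per-catalogue marginal sums are asserted on every call.
`partition_accuracy()` pools compared/matching genotype counts over each
cell's sites in the catalogues containing them and reports weighted
mean accuracy over shared cells (subset size ≥ 2) and unique cells
(size 1), weighting each cell by its compared-genotype count. Overlap
tables count SNP loci; indels are excluded by default.

## Attribution of unique inaccurate SNPs

Inaccurate sites (by default: any mismatching compared genotype) that
are unique to a single pipeline expose that pipeline's specific
weaknesses. Each such site runs through a decision tree over the
read-alignment evidence of its supporting reads:

1. **Mapping multiplicity.** A read is multi-hit when its hits on the
   normal reference span ≥ 2 distinct loci, where *distinct* means
   non-overlapping target intervals after merging overlaps (the package
   defines this precisely since informal usage never does). A site is
   `multiple_positions` as soon as *any* supporting read is multi-hit
   (a majority rule is available); single-locus sites are attributed to
   **caller error**.
2. **Masked-reference remap.** Multi-position sites whose reads have no
   hits at all on the hard-masked reference vanished under masking:
   **repetitive**. Sites with surviving masked hits are retained.
3. **Paralogy rule.** A retained site is **paralogous** when some
   supporting read has at least 2 hits, each with 100% query coverage
   and ≥ 96% identity (all three thresholds configurable via
   `paralogy_rule()`); the qualifying hit count feeds the
   mean-hits-per-paralogous-site statistic, using the maximum over a
   site's supporting reads (on synthetic data all reads of a site carry
   the planted copy number, so any aggregate agrees).
4. Multi-position sites failing both structural tests get an explicit
   **unresolved** terminal, so the tree is a true partition — published
   summaries leave this remainder implicit.

Two evidence conventions deserve note. Coverage is the aligned fraction
of the read *query* (so "100% coverage" is a property of the read, not
the target). And the package distinguishes "masked remapping was never
performed" (no masked rows anywhere in the evidence — such sites are
`unresolved_no_evidence`) from "the remap produced zero hits for this
site" (repetitive); the flag lives on the evidence object.

Evidence is consumed from tables (BLAST outfmt-6 dialect via
`read_blast_hits()`, or the package's own TSV) rather than by invoking
aligners, which keeps the stage hermetic and testable; the synthetic
generator emits evidence consistent with its planted causes.

## Demultiplexing evaluation

A read is assigned to a sample when its prefix matches the sample's
barcode within `max_mismatch` substitutions (default 0 — the strictest
reading) and the enzyme remnant follows immediately, IUPAC-aware and
exact: ApeKI leaves `CWGC` after the cut. With variable-length barcodes
the longest match wins; ties at the longest length are unassigned, never
arbitrarily resolved, and the loader rejects barcode tables in which one
barcode + remnant could be mistaken for the prefix of another.
Assignment is per-read, hence deterministic and order-independent, and
every input read lands in exactly one output bin — conservation is
exact, which is what makes measured *loss* interpretable.
`demux_delta()` compares two demultiplexers on the same reads and
reports recovered percentage points.

## The synthetic study generator

The generator's defaults are a stated world, fixed once:

- **Genome**: 1 Mb over 2 chromosomes of uniform random sequence — a
  deliberately scaled-down stand-in for a medium-sized (~1 Gb) diploid
  genome; all feature counts scale linearly with genome length.
- **Paralogs**: 12 segmental-duplication families, copy number
  2 + Poisson(0.4) (mean 2.4, matching the observed mean hit count of
  paralogous reads), inter-copy identity uniform on 0.94–1.00, segments
  of 1.5 kb placed on a non-overlapping slot grid. Families below the
  0.96 paralogy-rule threshold are *intended* to end up `unresolved` —
  the attribution-recovery checks use an explicit 0.96–1.00 range, the
  well-separated regime.
- **Repeats**: 3 families × 8 dispersed copies of a 500 bp unit (~1%
  per-copy divergence); the hard-masked genome replaces exactly these
  intervals with N.
- **Digest**: `GCWGC` scan (the motif equals its own reverse complement,
  so one forward scan suffices); fragments run from one motif start to
  the base before the next and are retained at 100–400 bp, a typical
  size-selection window.
- **Truth**: 5,000 polymorphic sites (10% short insertions) placed
  uniformly on retained fragments, avoiding the 5 bp restriction motif
  itself (a variant there would destroy the cut site); per-site minor
  allele frequency uniform on 0.05–0.5, so the MAF filter is a boundary
  condition rather than a guess; 24 inbred lines, homozygous except for
  residual heterozygosity at 1% — the realistic order for true-breeding
  inbred lines.
- **Pipelines** are parametric profiles (sensitivity, per-cell genotype
  error, paralog-collapse and repeat-mismap probabilities, missingness,
  indel capability). Three presets ship: `fast` (sensitive, very
  accurate, calls indels), `short_tag` (aggressive, paralog-collapse
  0.85 — the signature of very short alignment tags), `sparse`
  (conservative, heavy missingness). When a paralog site collapses, its
  cells read heterozygous at a per-site intensity drawn from 0.2–1.0:
  high intensities push the site past the > 50%-het purge (collapsed
  loci really are removed by filtering), lower ones leave it in the
  catalogue as an inaccurate site for the attribution tree — both fates
  occur in real data, and a single fixed intensity could not produce
  both. Repeat-mismapped cells are rescrambled at rate 0.6. Depth is
  negative-binomial (mean 6, dispersion 2), a standard GBS coverage
  model, with non-missing calls floored at depth 2 so the depth mask and
  the planted missingness stay consistent.
- **Reads**: barcode + genomic sequence from the cut site (the `CWGC`
  remnant arises from the genome itself), fixed 100 bp at 0.1% per-base
  substitution error, or variable 50–135 bp at 1% with occasional
  single-base indels — the two published read regimes. Barcodes default
  to fixed length 6 with pairwise Hamming distance ≥ 2, so a single
  sequencing error can never reassign a read to another sample; a
  configurable fraction of reads receives one barcode substitution for
  demultiplexing-loss experiments. Line genomes carry the SNP alleles;
  indel truth alleles are not spliced into reads (nothing in scope
  re-aligns reads — evidence tables are generated directly).

Everything is deterministic under the seed; sub-generators use fixed
small offsets from it so they are also reproducible when called
standalone.

### What a green test does and does not establish

The generator emits evidence *consistent with its planted causes*: a
collapsed paralog site really does get multi-locus, full-coverage,
high-identity hits; a repeat site's hits really do vanish under masking.
Recovery tests therefore establish that the evaluation machinery —
filters, concordance accounting, partition arithmetic, the decision tree
— is correct, not that real aligners produce such tidy evidence. Real
data add mapping noise, PCR duplicates, allele-biased coverage and
incomplete masking, none of which the generator models; conclusions
about any particular real pipeline require real evidence tables. The
generator also treats non-collapsed paralog sites as unique-mapping
(reads align best to their true copy), a simplification of a continuum.

## Numerical and degenerate-input choices

- Percentages: round half up; one decimal, plus integer columns where
  whole-percent comparisons are conventional.
- Boundary semantics: missing ≤ threshold retained, MAF ≥ threshold
  retained, het > threshold removed; `count_het_loci()` is strictly
  greater-than.
- Sites with no called genotypes report MAF 0 and het fraction 0, and
  are removed by the missing-rate rule.
- Sites with no compared genotypes count as accurate in
  `split_accurate()` (no evidence of error).
- Empty matrices and empty catalogues flow through: header-only VCFs
  round-trip via the samples attribute, concordance returns a zero
  report, and `cross_platform_compare()` flags `no_comparison`.
- `nway_partition()` refuses > 10 catalogues (2^k − 1 cell explosion).
- Ties in demultiplexing are unassigned rather than resolved by input
  order, keeping assignment order-independent.

## Orchestration

`run_config()` + `run_study()` run the whole evaluation from one
configuration (a synthetic parameter block or real input paths) and
write the report tables — catalogue summary, concordance, pairwise
overlap anchored on a reference pipeline (first listed by default),
overlap partition with per-cell accuracy, attribution summary, and
demultiplexing when reads are supplied — plus a JSON manifest of every
parameter and the seed. Each stage runs exactly once per call; no
on-disk caching is attempted. `validate_tables()` re-derives every
cross-table identity from the written files alone, so a tampered or
corrupted report is caught without re-running the pipeline. The
configuration is an R list serialised as JSON; the package exposes no
shell entry point since its users drive it from R.

## Known limitations

- Attribution stops at *unique* inaccurate SNPs; shared inaccurate sites
  are labelled but not causally attributed.
- Positional site identity means an allele-swapped call at the right
  position still matches its truth site (allele-aware matching is
  available as a strict option at comparison time via the genotype
  states themselves, since a wrong allele produces mismatching
  genotypes).
- The generator does not model PCR duplicates, paired-end reads,
  base-quality realism, or linkage between sites.
- BCF, genotype likelihoods, multi-allelic decomposition and phasing are
  out of scope at the VCF layer.
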