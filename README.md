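# gbseval

Evaluation toolkit for genotyping-by-sequencing (GBS) SNP-calling
pipelines, written for researchers who need to decide *which* variant
caller to trust on reduced-representation data — and to understand *why*
a caller gets genotypes wrong.

GBS sequences a reproducible subset of a genome: restriction fragments
(here ApeKI, recognition site `GCWGC`) from multiplexed, inline-barcoded
samples. Different bioinformatics pipelines applied to the very same
reads can report anywhere from ~13k to ~54k SNPs at genotype accuracies
from ~76% to ~99%, so the evaluation methodology matters as much as the
callers themselves. `gbseval` implements that methodology end to end:

- **Uniform genotype model** — per-pipeline VCFs and a resequencing truth
  set are loaded into a tidy sites × samples call table
  (`hom_ref`/`het`/`hom_alt`/`missing`, optional depth); multi-allelic
  records are dropped and accounted for. Sites are identified
  positionally as (chromosome, position, variant class).
- **Shared site filters** — per-call depth `DP ≥ 2`, per-site missing
  rate ≤ 80%, minor allele frequency ≥ 0.05, and a purge of loci with
  > 50% heterozygous calls (in inbred lines these flag collapsed
  paralogs), with a full per-site audit log.
- **Concordance** — accuracy = fraction of non-missing GBS calls equal
  to the truth genotype at the same locus and sample, with missing-data
  and heterozygosity rates; truth-absent sites are scored `hom_ref`
  under the *complete* convention or excluded under *partial* (both
  denominators always reported).
- **Catalogue overlap** — pairwise overlap tables and full 2^k − 1
  membership partitions across up to 10 catalogues, with per-cell pooled
  accuracy and compared-genotype-weighted means for shared
  (≥ 2 catalogues) vs unique cells.
- **Error attribution** — a systematic decision tree over unique
  inaccurate SNPs: reads mapping to one genomic locus ⇒ *caller error*;
  multi-locus reads whose hits vanish on the hard-masked reference ⇒
  *repetitive*; remaining reads with ≥ 2 hits at 100% coverage and
  ≥ 96% identity ⇒ *paralogous*.
- **Demultiplexing evaluation** — strict barcode + enzyme-remnant read
  assignment (IUPAC-aware, longest barcode first, ties unassigned) with
  exact read conservation, to quantify demultiplexer losses.
- **Synthetic study generator** — a fully labelled, seed-deterministic
  GBS study: random genome with planted segmental duplications
  (mean ~2.4 copies, 94–100% identity) and repeat families, ApeKI
  digest, 24 highly homozygous lines with ~1% residual heterozygosity,
  parametric per-pipeline error profiles, barcoded reads in fixed-100 bp
  or variable 50–135 bp regimes. Every planted error traces to one cause
  label, so the whole methodology can be validated by parameter
  recovery.

## Worked example

```r
library(gbseval)

params <- sim_params(seed = 42, genome_length = 3e5, n_sites = 1500)
study  <- simulate_gbs_study(params)

f <- apply_filters(study$calls$short_tag)
f$summary
#>   n_input n_removed_missing n_removed_maf n_removed_het n_retained
#> 1    1223                 0            38           111       1074

compare_to_truth(f$genotypes, study$truth,
                 het_loci_purged = f$summary$n_removed_het)
#> GBS genotype concordance (complete truth convention)
#>   sites: 1074  samples: 24  genotype cells: 25776
#>   missing: 28.7%  heterozygous (of called): 4.3%
#>   accuracy: 95.6% (17582 of 18391 compared)
```

The `short_tag` profile discovered 1,223 of the planted sites; 38 fell
below MAF 0.05 and 111 loci were purged as > 50% heterozygous — the
signature of its high paralog-collapse rate. Of the 25,776 genotype
cells at retained sites, 28.7% are missing and 95.6% of the compared
calls match the truth genotypes.

```r
cats <- lapply(study$calls, function(g)
  site_keys(catalogue_sites(apply_filters(g)$genotypes, "SNP")))
pairwise_overlap(cats$short_tag, cats$fast, names = c("short_tag", "fast"))
#>   total_a total_b common pct_common_of_a pct_common_of_b
#> 1    1074    1198    985            91.7            82.2
```

91.7% of the `short_tag` catalogue is shared with the `fast` catalogue.
`nway_partition()` + `partition_accuracy()` extend this to the full
membership partition with per-cell accuracy; `attribute_errors()` runs
the cause-attribution tree; `run_study()` orchestrates everything from
one config and writes the TSV report tables; `validate_tables()`
re-checks every cross-table identity from the files alone. Results carry
`tidy()`/`glance()`/`autoplot()` methods.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Simulates the default-scale synthetic study (1 Mb genome, 24 lines,
5,000 sites, three pipeline profiles, reads included) at the given seed,
runs the complete evaluation — filtering, concordance, overlap
partition, attribution, demultiplexing — through `run_study()`, fails if
any report identity is violated, prints the headline numbers and writes
the results JSON.
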