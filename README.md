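# spatgeno

Spatial–genomic distance analysis for multiregion tumor biopsies.

## What it does, and for whom

When several image-guided biopsies are taken from one glioma, the samples
differ molecularly — in their somatic mutations, copy-number profile and
methylation state — and the divergence tends to grow with the physical
separation of the biopsy sites. `spatgeno` is for analysts of multiregion
biopsy studies who want that relationship quantified. For every intra-patient
sample pair it computes:

* the **Euclidean distance** `d_ij = sqrt((x_i−x_j)² + (y_i−y_j)² + (z_i−z_j)²)`
  between recorded 3D biopsy coordinates (mm), with a fixed 5 mm convention
  for the shallow/deep halves of a split needle core;
* a **mutation distance** from somatic calls filtered by five retention
  criteria (exonic; protein-altering; ref reads ≥ 10; alt reads ≥ 8;
  alternate allele frequency ≥ 0.1): both the continuous Jaccard (Tanimoto)
  distance `Σ(P_i−Q_i)² / (ΣP_i² + ΣQ_i² − ΣP_iQ_i)` on allele-frequency
  profiles and the mutation **count distance** (mutations private to one
  sample of the pair);
* a **CNV distance**: segment breakpoints of all the patient's samples are
  unified into a common event list, and pairs are compared by the Canberra
  distance `Σ |P_i−Q_i| / (|P_i|+|Q_i|)` on event-level log2 copy ratios;
* a **methylation distance**: the L1 total variation `Σ|P_i−Q_i|` over the
  500 most variable beta-value probes within the patient.

Each modality's pooled pairs are then summarized by Pearson correlation and
an OLS best-fit line `genomic = a + b·mm`, from which the package derives the
expected divergence per 10 mm (`10·b`) and the physical separation equivalent
to one genomic unit (`1/b`).

Because individual-level multiregion genomics are rarely shareable, the
package includes a seed-reproducible synthetic cohort generator
(`simulate_cohort()`) whose mutation, CNV and methylation outputs have
genomic distances that grow linearly with site separation at configurable
slopes — every pipeline stage and every calibration test runs with no
external data.

## Worked example

```r
library(spatgeno)

cfg <- simulation_config(seed = 42, n_patients = 8)
sim <- simulate_cohort(cfg)

pairs <- enumerate_pairs(sim$sites)
head(pairs, 3)
#> # A tibble: 3 × 5
#>   patient_id sample_a sample_b euclidean_mm pair_kind
#>   <chr>      <chr>    <chr>           <dbl> <chr>
#> 1 P01        P01S1    P01S2            30.7 coordinate
#> 2 P02        P02S1    P02S2            36.3 coordinate
#> 3 P03        P03S1    P03S2             5   shallow_deep_needle

calls <- filter_variants(sim$calls)
mut <- dplyr::bind_rows(lapply(unique(calls$patient_id), function(pid)
  mutation_pair_distances(build_af_matrix(calls[calls$patient_id == pid, ]))))
meth <- methylation_pair_distances(qc_filter(sim$beta), sim$sample_meta)

records <- assemble_records(pairs, mutation = mut, methylation = meth)
assoc <- associate(records)
a <- assoc$mutation
sprintf("n=%d pairs, r=%.2f, slope=%.2f mutations/mm, per 10 mm=%.1f, mm per unit=%.1f",
        a$n_pairs, a$pearson_r, a$slope, a$per_10mm_rounded, a$mm_per_unit_rounded)
#> "n=65 pairs, r=0.97, slope=1.73 mutations/mm, per 10 mm=17.3, mm per unit=0.6"
```

Read: across 65 intra-patient pairs the mutation count distance rises by
about 1.7 mutations per mm of separation — roughly 17 additional distinct
mutations per centimeter, or 0.6 mm per mutation — and correlates strongly
with physical distance (r = 0.97; the synthetic cohort is cleaner than real
data by design). The methylation association from the same run gives
`slope = 0.170` L1 units/mm (generator target 0.18).

File-based workflows use `write_cohort()` / `run_config()` /
`run_pipeline()`, which read coordinate TSVs, variant tables (TSV or VCF via
`read_variant_vcf()`), CNVkit-style `.cns` segment files and beta-value
matrices, and write pair tables, per-modality distance TSVs, per-patient
Newick mutation-sharing trees and an `association.json` report. The same
workflow is scriptable from a shell:

```sh
Rscript inst/cli/spatgeno.R simulate --outdir cohort --seed 2 --patients 3
Rscript inst/cli/spatgeno.R run --coordinates cohort/coordinates.tsv \
  --variants cohort/variants.tsv --cns-manifest cohort/cns_manifest.tsv \
  --beta cohort/beta.csv --sample-meta cohort/sample_meta.tsv --outdir out
#> mutation     n=21 r=0.98 p=1.34e-15 slope=1.873 per10mm=18.7
#> cnv          n=21 r=1.00 p=1.33e-21 slope=7.126 per10mm=71.3
#> methylation  n=21 r=0.99 p=9.34e-17 slope=0.181 per10mm=1.8
```

See `vignettes/spatial-genomic-distance.Rmd` for the model, conventions
(Canberra magnitude denominators, QC ordering, probe-selection rules,
hypermutation flagging) and the generator's design.

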