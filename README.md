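# sigregulon

Tools for defining overlapping **ECF sigma-factor regulons** in
*Corynebacterium* and related Actinobacteria from stranded RNA-seq data.

## The scientific problem

The extracytoplasmic-function sigma factors sigma-H and sigma-E of
*Corynebacterium glutamicum* direct RNA polymerase to near-identical
stress promoters. Deleting a sigma factor's cognate **anti-sigma gene**
(e.g. *cseE* for sigma-E, *rshA* for sigma-H) constitutively activates
that sigma factor, so differential RNA-seq of deletion versus reference
strain exposes every responsive gene (the *stimulon*). The genes under
**direct** control — the *regulon* — are those carrying a recognizable
promoter upstream of a mapped transcription start site (TSS).

The promoter grammar the package implements is bipartite:

```
   -35 element         spacer          -10 element
   G G A A C/T      N x 18-19          (c) G T T        ...  +1 (TSS)
           ^
        position -31
```

* the −35 core is a `GGAA` pentamer whose **fifth base sits at position
  −31**: C there makes the promoter recognizable by *both* sigma-H and
  sigma-E (class `dual_sigHE`), any other base restricts it to sigma-H
  (`sigH_only`);
* the −10 core is an exact `GTT` trimer, often preceded by C at −11 in
  dual promoters;
* the spacer between pentamer end and the G of `GTT` is 18–19 nt.

A TSS is called at +1 when its 5′ read-start count is ≥ 10× the count at
−1 (with an absolute floor). Housekeeping (sigma-A-like) promoters are
recognized by a `TANAAT`-family −10 element. Element sets are summarized
as position-frequency matrices with per-column information content
(`2 + Σ f log2 f` bits) and case-encoded consensus strings.

## What is in the package

| Stage | Functions |
|---|---|
| formats / coordinates | `read_fasta`, `read_gff3`, `read_bedgraph_pair`, `write_bed_tss`, `parse_motif_notation`, ... |
| synthetic data with ground truth | `generate_genome`, `simulate_read_starts`, `simulate_counts`, `write_synthetic_dataset` |
| differential expression | `normalize_median_of_ratios`, `compute_ma`, `nb_wald_test`, `bh_adjust`, `run_dge` |
| TSS calling | `call_tss`, `deduplicate_tss`, `associate_tss`, `run_tss_stage` |
| promoter matching | `extract_window`, `find_bipartite`, `match_from_record`, `classify_promoter`, `match_sigA`, `scan_promoters` |
| consensus | `anchor_align`, `element_align`, `information_content`, `consensus_string`, `element_consensus` |
| cross-species survey | `scan_upstream`, `scan_species_set`, `summarize_presence` |
| orchestration | `pipeline_config`, `run_pipeline`, `run_fixture_mode` |

Two motif tables (the 16 dual sigma-H/sigma-E promoter records and the 6
exclusively sigma-H records, in the printed `HEXAMER-Nk-TAIL` notation)
ship under `inst/extdata/`, together with the documented *amtR* override.

## Worked example

Classify the shipped promoter tables and derive their consensus:

```r
library(sigregulon)
fx <- run_fixture_mode()

fx$n_gate_pass_dual
#> [1] 16            # all dual-table records pass the candidate gate
fx$n_regulon_genes
#> [1] 15            # distinct genes (one gene has two promoters)
fx$control_classes
#>         mca       uvrD3        mshC        sufR
#> "sigH_only" "sigH_only" "sigH_only" "sigH_only"
fx$dual$consensus$m35; fx$dual$consensus$m10
#> [1] "GGAAC"
#> [1] "cGTT"
fx$dual$consensus$detail$per_column[5:6, ]
#>    column coverage base frequency letter  ic_bits
#> 5   m35_5       16    C    0.9375      C 1.662710
#> 6 m10_m11       16    C    0.8750      c 1.456436
```

The −31 column (`m35_5`) is C in 15/16 records (≥ 0.9, printed upper
case); the −11 column is C in 14/16 (printed lower case) — the dual-class
consensus `GGAAC ... cGTT`. The sigma-H-only table gives `GGAAt ... GTT`.

A full synthetic run with ground truth:

```r
d <- tempfile()
sfx <- write_synthetic_dataset(d, seed = 1)
cfg <- pipeline_config(
  genome = sfx$paths$genome, gff = sfx$paths$gff,
  starts_fwd = sfx$paths$starts_fwd, starts_rev = sfx$paths$starts_rev,
  counts = sfx$paths$counts, conditions = sfx$paths$conditions,
  out_dir = file.path(d, "out"))
rep <- run_pipeline(cfg)
#> [sigregulon] stage dge: 18 up, 4 down of 60 genes
#> [sigregulon] stage tss: 52 TSS calls, 52 genes with a TSS
#> [sigregulon] stage promoters: 14 dual, 17 sigH-only, 14 sigA-like
#> [sigregulon] done: 12 regulon genes
```

Every reported regulon gene is a planted dual-promoter DE gene; the
stage outputs (`dge.tsv`, `tss.bed`, `promoters.tsv`, `consensus.txt`,
`regulon_report.tsv`) land in the output directory.

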