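---
title: "Defining overlapping ECF sigma-factor regulons from dRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining overlapping ECF sigma-factor regulons from dRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigregulon)
```

## The problem and the model

Extracytoplasmic-function (ECF) sigma factors reprogram bacterial RNA
polymerase toward stress promoters. In *Corynebacterium glutamicum*, the
two ECF factors sigma-H and sigma-E recognize strikingly similar bipartite
promoters: a −35 element built on a `GGAA` core pentamer and a −10 element
centered on a `GTT` trimer, separated by an 18–19 nt spacer. The operative
difference between the two regulons is a single base: the fifth pentamer
letter, which sits at promoter position −31 in the canonical placement.
Sigma-H tolerates any base there (T is most frequent); sigma-E requires C.
A promoter with C at −31 is therefore recognized by both holoenzymes
("dual" class), while any other base restricts it to sigma-H.

`sigregulon` turns that biology into a staged, testable pipeline:

1. **Differential expression** between a reference strain and an anti-sigma
   deletion strain (in which the cognate sigma factor is constitutively
   active) defines the *stimulon* — every gene that responds directly or
   indirectly.
2. **TSS calling** from a primary 5′-end read-start profile locates +1
   positions upstream of the responsive genes.
3. **Promoter matching** in the −50..−1 window upstream of each TSS finds
   the bipartite element and applies the −31 discriminator, separating the
   *regulon* (direct targets with a dual promoter) from sigma-H-only and
   housekeeping (sigma-A-like) promoters.
4. **Consensus derivation** aligns the matched elements and emits
   case-encoded consensus strings with per-column information content.
5. **Cross-species scanning** surveys user-supplied upstream regions of
   orthologous genes for the same promoter architecture.

## Coordinate and notation conventions

All internal coordinates are 1-based inclusive; bedGraph/BED boundaries
are converted at the file layer and nowhere else. Promoter-local numbering
puts the TSS at +1 with no position 0, so a 50-nt window covers −50..−1
and index *i* of the window string maps to position −(51−*i*).
Minus-strand windows are reported reverse-complemented, i.e. read 5′→3′ in
transcription orientation, which is the orientation in which published
motif tables are written.

Printed motif records use the `HEXAMER-Nk-TAIL` notation, e.g.
`GGAACT-N16-CGTT`. We interpret the hexamer as pentamer + the −30 base and
the tail as (optionally) the −11 base + `GTT`. The spacer — counted
strictly between the pentamer's 3′ end and the G of `GTT` — is then
`k + 2` for four-letter tails and `k + 1` for bare `GTT` tails. This
mapping is forced by internal consistency of the published records: the
`cseE` record `GGAACT-N16-CGTT` is printed alongside the statement that
its elements are `GGAAC` and `GTT` separated by 18 nt, and `18 = 16 + 2`.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| TSS ratio threshold | 10 | a position is +1 if its read-start count is ≥ 10× the count at −1; a zero at −1 passes the clause (otherwise noise-free data could never yield a call) |
| TSS minimum starts | 10 | absolute floor replacing the manual curation of false positives in the original protocol |
| dedup window | 3 nt | clustered calls < 3 nt apart collapse to the strongest, ties toward the 5′ position |
| TSS–gene distance | ≤ 500 nt | the largest published TSS-to-start-codon distance in these regulons is 397 nt; 0 marks leaderless transcripts |
| GTT placement | G at −13..−7 | covers canonical −10-to-TSS geometry, including the observed 7-nt offset cases |
| spacer range | 18–19 nt | the published stress-promoter spacing |
| core mismatch budget | 1 over `GGAA` | admits the published `GCAAC` and `GGAAA` deviations while keeping the gate tight; −31 is never a mismatch because it is the class discriminator |
| sigma-A −10 budget | ≤ 2 mismatches vs `TANAAT` | all three published sigma-A −10 variants upstream of *sigE* (`CAAAAT`, `TAATCT`, `TATAGT`) then qualify |
| consensus case thresholds | 0.9 / 0.4 | chosen so that a 15/16 column prints upper case and a 14/16 column lower case, reproducing the published case pattern `GGAAC`/`cGTT`; ties print `n` |
| DGE cutoffs | padj ≤ 0.01, \|M\| ≥ 1 | the stricter of the two published cutoff pairs; both are configurable |
| pseudocount | 0.5 | keeps M and A finite for zero-count groups |
| dispersion floor | 1e-8 | numerical guard for the method-of-moments estimate |

Where a placement is ambiguous, `find_bipartite()` resolves ties
deterministically: fewest core mismatches, then spacer closest to 18, then
G of GTT closest to −8, then C at −31, then the most upstream placement.
The first three steps prefer the canonical geometry; the C preference
means that when two biologically indistinguishable placements exist we
report the one that would matter for the sigma-E call; the final step is a
pure determinism guarantee.

## The differential-expression stage

This stage is a deliberately simple, self-contained analysis — not a
re-implementation of a large DE framework. Size factors are
median-of-ratios over genes with all-positive counts; M and A are
pseudocounted log2 statistics; the test is a per-gene Wald test with a
method-of-moments negative-binomial dispersion (pooled within conditions
with degrees-of-freedom weights, no shrinkage across genes) and two-sided
standard-normal p-values, followed by Benjamini–Hochberg adjustment via
`stats::p.adjust`.

Two calibration facts matter for interpretation. With three replicates per
condition the Wald statistic is heavy-tailed relative to the normal
reference (it behaves like a t statistic with ~4 degrees of freedom), so
*raw* p-values are anti-conservative — roughly 0.12 of null genes fall
below p = 0.05 in simulation. The *stage decision*, however, requires both
padj ≤ 0.01 and |M| ≥ 1, and its simulated false-positive rate on all-null
data is far below 2× the nominal level (≈ 0.07% in the shipped
simulation), while planted four-fold effects at typical depths are
recovered with > 95% sign-correct power. Genes with zero counts everywhere
get p = 1 by definition. Normalization is invariant to rescaling any one
library only up to a single global factor — a property shared by every
median-of-ratios implementation — so tests assert proportionality rather
than identity.

## What the synthetic generator emulates — and what it does not

`generate_genome()` lays out gene cassettes (50-nt promoter window, 5′
UTR of 20–120 nt, 300-nt body) on both strands of one contig with ≥ 120 nt
motif-free intergenic spacing, so windows never overlap the upstream gene.
Promoter classes are planted with exact coordinates recorded: dual
promoters get `GGAAC`, a C at −11 and a spacer of 18 or 19; sigma-H-only
promoters a non-C fifth base (T-biased); sigma-A-like promoters a
`TANAAT`-family hexamer ending at −7 plus an upstream `TTG`. A configurable
fraction of genes are operon members with no TSS or promoter of their own,
emulating the genes that respond without a proximal promoter. Dual genes
always carry a planted log2 fold change in [1, 3] (the regulon is active
in the deletion strain); 10% of the remaining genes are differentially
expressed in either direction. Read starts are negative-binomial peaks
(mean 100) on Poisson background (0.1 per position); counts follow the
3 + 3 replicate design with NB dispersion 0.05.

The generator does **not** model sequencing error, mapping artifacts,
transcription-unit read-through, internal or antisense TSSs, promoter
islands with overlapping elements, or correlated biological replicates.
Passing tests therefore demonstrate that the *rules are implemented
correctly and are recoverable under the stated noise model* — not that
the thresholds are optimal for any particular real library.

Default problem sizes (60-gene genomes for end-to-end runs, 6,600-gene
count matrices for calibration, 1,000-window oracle sweeps) were chosen as
the smallest sizes at which the stochastic assertions are stable across
seeds.

## Numerical and degenerate-input choices

* A count of zero at −1 satisfies the TSS ratio clause; the reported
  ratio uses `max(starts_minus1, 1)` to stay finite.
* Windows running past a contig edge are skipped with a warning, not an
  error; windows containing `N` simply cannot match the exact `GTT`/core
  letters at those positions.
* Zero-coverage consensus columns (e.g. the −11 column of a record set
  with bare `GTT` tails) are dropped from the consensus string and
  reported as missing in the per-column table.
* Information content is `2 + Σ f log2 f` bits; the small-sample
  correction `3/(2 ln2 · n)` is available but off by default, since the
  published logos were generated with an external tool whose correction is
  not reproduced bit-exactly.
* Experimental-evidence overrides (the *amtR* promoter, dual despite A at
  −31) are an explicit input table, never inferred; an override for a gene
  without a qualifying match is an error.
* The survey scanner (`scan_upstream()`) uses exact pentamer matching, no
  mismatch budget, per the consensus-motif wording of the original
  species survey; the upstream window length (500 nt by default) is a
  package choice — the original survey does not state one.

## Open design points resolved here

* Start codons are anchored on the annotation's `gene` (configurable to
  `CDS`) start field; published distance-to-start values are assumed to
  use the CDS start.
* The published text calls all dual promoters `GGAAC`-bearing although one
  printed record reads `GCAAC`; the gate admits both (one core mismatch)
  and the discrepancy surfaces in the match table rather than being
  resolved silently.
* Both printed DGE cutoff pairs (padj ≤ 0.01 with |M| ≥ 1; FDR < 0.05 with
  |M| > 1) are supported; the stricter pair is the default.
* The command-line surface of the pipeline is the exported function layer
  (`run_pipeline()`, `run_fixture_mode()`, per-stage functions); all
  outputs are plain TSV/BED/FASTA so they compose with shell tooling.

## Known limitations

The regulon definition is promoter-proximal: operon members driven by an
upstream dual promoter are counted in the no-TSS bin, not attributed to
the regulon, because operon inference is out of scope. The DE stage's raw
p-values should not be interpreted at face value at n = 3 (see above);
decisions are made on the adjusted-p + fold-change pair. Cross-species
presence counts depend entirely on the upstream regions the user supplies;
the package neither fetches genomes nor identifies orthologs.
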