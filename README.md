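# isoswitch

Detection of coding-to-noncoding major-isoform switching from RNA-seq
transcript catalogues.

## The problem

Most protein-coding genes express several isoforms, and a large fraction of
those isoforms — retained-intron (RI), processed-transcript and
NMD-substrate forms — do not encode protein. Under cellular stress such as
tumour hypoxia, and across tumour cohorts, the *major* isoform of a gene
(the most abundant transcript in a given sample) can switch from a coding
to a noncoding form, silencing protein output without any visible change
in gene-level expression. Gene-level differential expression is blind to
this. `isoswitch` is written for transcriptomicists who want to detect and
quantify these switches from standard transcript-level quantifications
(FPKM tables), in either a replicated time-course design or a large
tumour/normal cohort.

## What the package computes

* **Augmented catalogue construction** — merge novel transcript models
  into a reference annotation (deduplicated by intron chain, genes
  assigned by exonic overlap), then apply two stringent filters: every
  junction of a novel transcript needs ≥ 2 supporting reads in ≥ 2
  samples, and every transcript needs FPKM > 0.5 in ≥ 3 samples. Junctions
  are classified `complete` / `partial` / `novel` against the reference.
* **Alternative-splicing events** — pairwise classification of isoforms
  into SE, MXE, RI, A5SS, A3SS, AFE, ALE with inclusion levels
  `psi = sum FPKM(inclusion) / sum FPKM(inclusion + exclusion)` and a
  rank-sum shift test between conditions.
* **Major-isoform switches** — per sample and per gene, the major isoform
  is `argmax_t FPKM(t)`; its biotype reduces to coding/noncoding. A
  cohort gene is a switch gene when the fraction of tumour samples whose
  status deviates from the normal-tissue baseline class is ≥ 5%. The
  per-sample *noncoding proportion* (fraction of expressed genes with a
  noncoding major isoform) is the outcome statistic, compared between
  patient groups by Wilcoxon rank-sum; switch-set overlaps use the exact
  hypergeometric upper tail P(X ≥ k), X ~ Hypergeom(N, K, n).
* **Intron retention** — per-intron read densities (reads/kb over the
  merged-exon complement), log2 fold-change profiles
  `log2((d_test + eps)/(d_base + eps))`, and a catalogue-wide
  retained-intron expression shift test.
* **Statistics** — log-space hypergeometric tail, Benjamini–Hochberg
  step-up adjustment, exact-enumeration Wilcoxon rank-sum/signed-rank
  tests (exact for total n ≤ 12, normal approximation with tie and
  continuity correction beyond), GO-style term enrichment with an
  ancestor/descendant redundancy filter.
* **Synthetic data** — a seeded generator that emulates both designs with
  a ground-truth ledger (which genes switch, which introns are retained,
  planted sample clusters), so every stage is testable offline.

## Worked example

```r
library(isoswitch)

cfg <- sim_config(n_genes = 100, switch_gene_fraction = 0.1)
sc  <- simulate_catalogue(cfg, seed = 7)
sc$catalogue
#> <gene_catalogue> 664 transcripts, 100 genes, 1006 junctions
#>   biotypes: nmd=47 other_noncoding=37 processed_transcript=78
#>             protein_coding=372 retained_intron=130

tc <- simulate_timecourse(sc, cfg, seed = 8)
sw <- timecourse_switches(sc$catalogue, tc$quant,
                          baseline_samples = tc$meta[condition == "t0", sample],
                          test_samples     = tc$meta[condition == "t24", sample])
sw[direction == "coding_to_noncoding"]
#>     gene_id     design           direction switch_fraction  driver_biotype
#>  1:   G0022 timecourse coding_to_noncoding               1 retained_intron
#>  2:   G0025 timecourse coding_to_noncoding               1 retained_intron
#>  ...
#> 10:   G0099 timecourse coding_to_noncoding               1 retained_intron

truth <- sc$truth$genes[is_switch_gene == TRUE, gene_id]
mean(truth %in% sw[direction == "coding_to_noncoding", gene_id])
#> [1] 1
switch_set_overlap(sw[direction == "coding_to_noncoding", gene_id],
                   truth, sc$truth$genes$gene_id)$p.value
#> [1] 5.78e-14
```

Reading: the generator planted 10 switch genes among 100 (noncoding
isoform up-weighted 4-fold at the late time point, gene totals conserved);
`timecourse_switches` recovers all 10, 9 of them driven by a
retained-intron isoform, and the hypergeometric overlap of the called set
with the planted set is p ≈ 6e-14.

The same analysis runs end to end, deterministically, with

```r
run_pipeline(run_config(seed = 17, design = "cohort"), "out/")
```

which writes the filtered catalogue (GTF), the event table, per-sample
major-isoform calls, switch genes, noncoding proportions, sample clusters
and a hash manifest. A CLI wrapper is installed at
`inst/scripts/isoswitch`.

## Documentation

The methods vignette (`vignettes/isoform-switching.Rmd`) describes the
model and its assumptions, all tunable thresholds with their defaults, the
design of the synthetic-data generator and exactly what a green test does
and does not establish.
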