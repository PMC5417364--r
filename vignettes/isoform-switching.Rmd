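---
title: "Detecting coding-to-noncoding major-isoform switches: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coding-to-noncoding major-isoform switches: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoswitch)
library(data.table)
```

## The model

A gene expresses a set of isoforms $t \in T_g$ with per-sample abundances
$a_{t,s}$ (FPKM). The *major isoform* of gene $g$ in sample $s$ is
$\arg\max_{t \in T_g} a_{t,s}$, and its biotype reduces to a binary
status: `protein_coding` is *coding*; `retained_intron`,
`processed_transcript`, NMD-substrate and other noncoding biotypes are
*noncoding*. The analysis rests on three observations:

1. In multi-isoform genes the identity of the major isoform is a
   per-sample property, assignable independently in every sample — which
   also makes the calls robust to cross-sample batch effects, since no
   cross-sample normalisation enters the argmax.
2. A condition can shift expression *within* a gene from the coding major
   isoform toward a noncoding one (frequently a retained-intron form)
   while the gene's total output barely changes, so gene-level
   differential expression misses it.
3. Aggregated over genes, the per-sample *noncoding proportion* — the
   fraction of expressed genes whose major isoform is noncoding — is a
   sample-level statistic that can be compared between patient groups.

Two designs are supported. In the **time course**, each condition has
replicates; the condition-level major isoform is the argmax on the
condition-mean abundance, and a switch record is emitted when it changes
between baseline and test, with direction (`coding_to_noncoding`,
`noncoding_to_coding`, `within_class`) and the biotype of the gained
isoform (so retention-driven switches are separable). In the **cohort**,
each gene has a baseline class (the modal status among normal samples,
falling back to the reference annotation's class of the longest coding
transcript); the *switch fraction* is the share of tumour samples whose
status deviates from that baseline, with `not_expressed` samples removed
from the denominator, and genes at or above a 5% switch fraction are
reported.

## Catalogue construction and filtering

Novel transcript models are merged into the reference by structural
identity: two transcripts are the same model iff they share chromosome,
strand and intron chain (single-exon models, whose chain is empty, are
compared by their exon interval instead — otherwise all mono-exonic models
would collapse together). A surviving novel model inherits the gene id of
the reference gene with maximal exonic overlap on the same strand
(deterministic tie-break: lexicographically smallest gene id), else a
fresh `NOVELG_` id in a structural sort order that makes the merge
independent of input order.

Two filters then apply:

* **Junction support**: a novel transcript is kept only if *every* one of
  its junctions has ≥ `min_reads` (2) reads in ≥ `min_samples` (2)
  samples. Reference-origin transcripts bypass this filter: it exists to
  remove assembly artefacts, and reference models are externally
  validated. Missing support rows count as zero.
* **Expression**: any transcript is kept only if FPKM is *strictly*
  greater than `min_fpkm` (0.5) in ≥ `min_samples` (3) samples — the
  strictness at the boundary is deliberate and tested. The three samples
  may fall anywhere in the design; restricting them to one condition
  would penalise condition-specific isoforms, which are precisely the
  objects of interest.

Both filters are idempotent and removal-only; genes left without
transcripts disappear. Junctions classify against the reference as
`complete` (donor–acceptor pair known), `partial` (exactly one boundary
known) or `novel` — including the corner case where both boundaries are
known individually but never paired, which we class as novel because no
single reference junction explains it.

## Splicing-event classification

Events are defined *pairwise* between two isoforms of a gene and then
deduplicated by (type, coordinates) across all pairs, rather than derived
from a splice graph: each rule stays independently testable, and the
union-over-pairs with transcript-set aggregation reproduces the gene-level
event list. All rules are evaluated in genomic coordinates with 5′/3′
resolved by strand, so a minus-strand gene behaves as the exact mirror of
a plus-strand one:

* **SE** — an internal exon of one isoform whose flanking splice sites are
  joined by a single junction of the other.
* **RI** — an exon of one isoform spanning an intron of the other with
  both outer edges matching the other's flanking exons.
* **A5SS / A3SS** — two junctions sharing an acceptor (donor) with
  different donors (acceptors), alternative-side exons overlapping;
  on the minus strand the genomic roles swap, which the labels follow.
* **MXE** — two internal, mutually non-overlapping exons, each private to
  one isoform, with shared outer flanking splice sites.
* **AFE / ALE** — differing, non-overlapping terminal exons whose inner
  splice site is shared. These are structural stand-ins: terminal-exon
  usage is really a promoter/poly-A phenomenon that quantification tables
  cannot fully resolve.

A note on the mirror property: because the rules are transcript-oriented,
reflecting all coordinates *and* flipping the strand yields the identical
event types (the structure is unchanged in transcript orientation), while
relabelling the strand alone swaps A5SS↔A3SS and AFE↔ALE. Both facts are
asserted in the property suite against an independently written
brute-force oracle.

Inclusion levels are abundance shares,
$\psi = \sum_{inc} a / (\sum_{inc} a + \sum_{exc} a)$, undefined when the
denominator is zero. This is a deliberate deviation from junction-read
PSI estimation: the package consumes quantification tables, and the test
suite validates parameter *recovery*, not equivalence with read-level
tools. Likewise the event shift test is a Wilcoxon rank-sum on per-sample
inclusion levels with BH control at 1%, replacing likelihood-ratio
machinery that would need read-level input.

## Statistical choices

* **Hypergeometric upper tail** $P(X \ge k)$ is summed in log space
  (log-binomials with a log-sum-exp reduction) so tails near machine zero
  remain accurate; correctness is checked against direct enumeration for
  every parameter combination with $N \le 15$.
* **Rank tests**: exact by full enumeration when total $n \le 12$
  (rank-sum: all $\binom{n}{n_x}$ assignments of pooled mid-ranks;
  signed-rank: all $2^n$ sign patterns), normal approximation with tie
  and continuity correction beyond. At the crossover boundary the
  per-tail approximation error is below 0.02 on untied data; with heavy
  ties the exact distribution is lumpy and the approximation degrades —
  which is precisely why small samples always take the exact path.
  Wilcoxon (not the t-test) is the default for the noncoding proportion
  because it is a bounded share with no variance model attached; both are
  ordinary R options for a user who disagrees.
* **BH adjustment** is the step-up rule applied in-place,
  order-preserving and capped at 1.
* **Enrichment** is a plain hypergeometric per term over
  ancestor-propagated annotations with BH at 1%. Transcript-length bias
  weighting is intentionally not implemented: the enrichment consumer
  here is synthetic data with no length bias to correct. Redundancy
  reduction replaces semantic-similarity clustering with a deterministic
  rule — among enriched ancestor/descendant pairs keep the smaller p,
  ties to the descendant — because no information-content corpus is
  bundled and the rule is exactly testable.

## Thresholds and defaults

| parameter | default | units | why |
|---|---|---|---|
| `min_junc_reads` / `min_junc_samples` | 2 / 2 | reads, samples | stringent novel-junction support |
| `min_fpkm` / `min_fpkm_samples` | 0.5 / 3 | FPKM, samples | strict `>` at the boundary |
| expression `floor` | 1 | FPKM (gene total) | below it a gene is `not_expressed`; prevents noise-driven major-isoform calls entering the noncoding proportion |
| `switch_min_fraction` | 0.05 | fraction of tumour samples | cohort reporting threshold |
| event `fdr`, enrichment `q` | 0.01 | BH-adjusted | 1% FDR |
| `de_fold` | 2.0 | fold | gene-level DE surrogate |
| pseudocount `eps` | 0.1 | reads/kb or FPKM | finite log fold-changes on zero coverage |
| `cluster_k` | 3 | clusters | cohort clustering default |
| `exact_max` | 12 | total n | exact/approximate rank-test crossover |

Ties in the major-isoform argmax break in favour of coding transcripts,
then lexicographic transcript id: conservative for the headline
coding-to-noncoding statistic (a tie can never manufacture a switch call).
Sample clustering is agglomerative with average linkage on Jaccard
distances between binarised (noncoding = 1) status vectors; "unsupervised
clustering" admits many choices and this one is deterministic, metric and
cheap, with $k$ exposed.

The `de_fold_filter` deserves a caveat: its FDR clause (BH q < 0.01 from
the rank-sum test) cannot fire with 3 replicates per condition, where the
smallest attainable exact two-sided p is 0.1. Count-model DE testing is
out of scope by design, so with small replicate numbers the fold criterion
is the live filter (`q_max = 1` disables the clause explicitly).

## The synthetic-data generator

`simulate_catalogue()` builds genes as base protein-coding chains of 4–10
exons (80–500 bp) and introns (200–5000 bp), and derives isoforms by
applying SE/RI/A5SS/A3SS edits to the base so that every generated event
is classifiable and ledgered. Isoform counts are 1 + Geometric(0.13)
capped at 12 (median 5); biotypes are assigned to realise a 44% noncoding
transcript fraction, with RI edits always `retained_intron`. A configured
fraction of genes is designated as switch genes, preferring an RI isoform
as the switch target, mirroring the predominance of retention-driven
switching.

Expression is simulated directly at the FPKM level: gene totals are
log-normal (median 50 FPKM), the coding major isoform carries 60% of the
gene's output and the designated noncoding target 25% (the remainder
shared). These shares were fixed a priori from one requirement — the major
isoform must be unambiguous under negative-binomial noise at dispersion
0.1 with 3 replicates (log-abundance gap ≈ 0.88 against a replicate-mean
s.d. ≈ 0.29) — and were not tuned against any test outcome. Noise is NB
multiplicative: expected counts at `depth` (50) fragments per FPKM unit
with per-sample log-normal library factors, back-converted to FPKM;
dispersion 0 short-circuits to exact expectations for noise-free designs.
Switching multiplies the target's expected share by the switch fold (4)
and renormalises, *conserving the gene total* — which makes "switching
does not change overall locus output" a designed property of the
generator, testable as a null, with `change_totals` providing the
positive control that breaks it. Intron coverage is Poisson at 2 reads/kb
with the retained intron of RI switch genes elevated 4-fold in the test
condition; junction support is Poisson in proportion to the summed
abundance of the isoforms carrying the junction (≈ 5 reads per FPKM unit,
i.e. about a tenth of the fragments covering a position span the
junction).

What the generator does *not* emulate: sequence-level realism (splice-site
motifs, GC/length biases in library preparation), positional coverage
structure within exons, correlated isoform noise within a gene, and
annotation errors. A green recovery test therefore establishes that the
estimators invert the generative model they were pointed at — switch
detection at fold 4/dispersion 0.1, cluster recovery in the noise-free
planted partition, proportion-shift power at Δ = 0.05 — not that they
would perform identically on data with biases the generator omits. The
exact-statistics and oracle-equivalence suites, by contrast, are
distribution-free.

## Numerical and degenerate-input conventions

GTF coordinates (1-based inclusive) convert to 0-based half-open at a
single I/O site; the round trip is exact and tested. Missing rows in
support/quantification/coverage tables are zeros with a logged warning.
Zero denominators yield explicit `NA`/`Inf` flags (event inclusion,
exon/intron ratio) rather than silent values. A constant status matrix
clusters into one cluster with a warning. All simulation randomness flows
through a single seed argument per call (`withr::with_seed`), leaving the
caller's RNG state untouched; re-running the pipeline with the same
configuration reproduces byte-identical files, and the manifest records
md5 hashes to make that auditable.

## Known limitations

* AFE/ALE calls are structural stand-ins; promoter- or poly-A-level
  evidence is out of scope.
* Inclusion levels from FPKM shares inherit quantifier biases that
  junction-read PSI would not.
* The ORF-based biotype rules (NMD 50-nt rule, ≥ 100-codon ORF) need a
  genome FASTA; the sequence-free default classifies non-RI novels as
  `processed_transcript`, which undercounts novel coding isoforms.
* The cohort baseline falls back to the reference annotation when a gene
  is unexpressed in all normal samples; with very few normals the modal
  baseline is itself noisy.
* Enrichment assumes the annotation DAG is small enough for in-memory
  ancestor closure; no OBO parsing beyond a child–parent edge list.
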