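# Per-intron expression, intron log2 fold-change profiles across
# conditions, and the catalogue-wide shift in retained-intron transcript
# expression.

#' Intron intervals of a gene
#'
#' The complement of the merged exons of the gene's reference
#' protein-coding transcripts within the gene span (retained introns are
#' defined relative to the coding structure), ordered 5' to 3' in
#' transcript orientation.
#'
#' @param cat a [gene_catalogue].
#' @param gene one gene id.
#' @return `data.table` with `gene_id`, `intron_index` (5'->3'), `chrom`,
#'   `strand`, `start`, `end`.
#' @export
gene_introns <- function(cat, gene) {
  tx <- cat$transcripts[gene_id == gene &
                          biotype == "protein_coding" & origin == "reference"]
  if (!nrow(tx))   # fall back to all transcripts of the gene
    tx <- cat$transcripts[gene_id == gene]
  if (!nrow(tx)) stop_is("unknown gene '%s'", gene)
  ex <- cat$exons[transcript_id %chin% tx$transcript_id][order(start)]
  merged <- ex[, {             # merge overlapping/adjacent exons
    e <- cummax(end); new <- c(TRUE, start[-1L] > e[-.N]); grp <- cumsum(new)
    .(start = tapply(start, grp, min), end = tapply(end, grp, max))
  }]
  if (nrow(merged) < 2L) {
    return(data.table(gene_id = character(), intron_index = integer(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer()))
  }
  intr <- data.table(gene_id = gene, chrom = tx$chrom[1L], strand = tx$strand[1L],
                     start = as.integer(merged$end[-nrow(merged)]),
                     end = as.integer(merged$start[-1L]))
  if (tx$strand[1L] == "-") intr <- intr[rev(seq_len(.N))]
  intr[, intron_index := seq_len(.N)]
  intr[, .(gene_id, intron_index, chrom, strand, start, end)]
}

#' Per-intron read density
#'
#' Reads per kilobase for every intron of a gene in the selected samples,
#' matched to the coverage table by (gene, start, end). Introns missing
#' from the table get density 0 with a warning.
#'
#' @param cat a [gene_catalogue].
#' @param coverage coverage table from [read_coverage()]: `gene_id`,
#'   `chrom`, `start`, `end`, then per-sample read counts.
#' @param gene gene id.
#' @param samples samples to report (default all count columns).
#' @return `data.table` with `gene_id`, `intron_index`, `start`, `end`,
#'   `sample`, `reads`, `density` (reads/kb).
#' @export
intron_density <- function(cat, coverage, gene, samples = NULL) {
  intr <- gene_introns(cat, gene)
  cov <- as.data.table(coverage)[gene_id == gene]
  sample_cols <- setdiff(names(cov), c("gene_id", "chrom", "start", "end"))
  if (is.null(samples)) samples <- sample_cols
  long <- melt(cov, id.vars = c("gene_id", "chrom", "start", "end"),
               measure.vars = intersect(samples, sample_cols),
               variable.name = "sample", value.name = "reads",
               variable.factor = FALSE)
  out <- merge(intr, long[, .(start, end, sample, reads)],
               by = c("start", "end"), all.x = TRUE)
  out <- out[CJ(intron_index = intr$intron_index, sample = samples),
             on = c("intron_index", "sample")]
  if (anyNA(out$reads)) {
    warn_is("%d intron/sample coverage value(s) missing; density set to 0",
            sum(is.na(out$reads)))
    out[is.na(reads), reads := 0]
  }
  out[, `:=`(gene_id = gene,
             start = intr$start[match(intron_index, intr$intron_index)],
             end = intr$end[match(intron_index, intr$intron_index)])]
  out[, density := reads / ((end - start) / 1000)]
  setorder(out, intron_index, sample)
  out[, .(gene_id, intron_index, start, end, sample, reads, density)]
}

#' Per-intron log2 fold-change between conditions
#'
#' `log2((mean test density + eps) / (mean baseline density + eps))` for
#' every intron of the gene, ordered 5' to 3'; the pseudocount keeps the
#' values finite on zero-coverage introns.
#'
#' @inheritParams intron_density
#' @param baseline_samples,test_samples sample ids per condition.
#' @param eps pseudocount in reads/kb (default 0.1).
#' @return `data.table` with `gene_id`, `intron_index`, `start`, `end`,
#'   `mean_baseline`, `mean_test`, `log2fc`.
#' @export
intron_log2fc <- function(cat, coverage, gene, baseline_samples, test_samples,
                          eps = 0.1) {
  if (!length(baseline_samples) || !length(test_samples))
    stop_is("each condition needs at least one sample")
  d <- intron_density(cat, coverage, gene,
                      samples = unique(c(baseline_samples, test_samples)))
  mb <- d[sample %chin% baseline_samples,
          .(mean_baseline = mean(density)), by = .(intron_index, start, end)]
  mt <- d[sample %chin% test_samples,
          .(mean_test = mean(density)), by = .(intron_index, start, end)]
  fc <- merge(mb, mt, by = c("intron_index", "start", "end"))
  fc[, log2fc := log2((mean_test + eps) / (mean_baseline + eps))]
  fc[, gene_id := gene]
  setorder(fc, intron_index)
  fc[, .(gene_id, intron_index, start, end, mean_baseline, mean_test, log2fc)]
}

#' Global shift in retained-intron transcript expression
#'
#' Sums retained-intron transcript FPKM per gene and sample, compares the
#' two groups gene-wise and reports a signed shift statistic (median
#' per-gene log2 ratio of group means, with pseudocount) and a rank test:
#' signed-rank over per-gene deltas for paired/time-course designs,
#' rank-sum on per-sample totals otherwise.
#'
#' @param quant FPKM matrix.
#' @param cat a [gene_catalogue] supplying biotypes.
#' @param group_a,group_b sample id vectors (A = baseline).
#' @param paired use the per-gene signed-rank design (default TRUE).
#' @param eps pseudocount FPKM (default 0.1).
#' @return list with `shift` (median per-gene log2 ratio, positive = up in
#'   B), `p.value`, `n_genes`.
#' @export
global_ri_shift <- function(quant, cat, group_a, group_b, paired = TRUE,
                            eps = 0.1) {
  ri <- cat$transcripts[biotype == "retained_intron"]
  if (!nrow(ri)) stop_is("no retained_intron transcripts in the catalogue")
  assert_matrix_samples(quant, c(group_a, group_b))
  ids <- intersect(ri$transcript_id, rownames(quant))
  per_gene <- rowsum(quant[ids, c(group_a, group_b), drop = FALSE],
                     ri$gene_id[match(ids, ri$transcript_id)])
  ma <- rowMeans(per_gene[, group_a, drop = FALSE])
  mb <- rowMeans(per_gene[, group_b, drop = FALSE])
  delta <- log2((mb + eps) / (ma + eps))
  p <- if (paired) {
    signed_rank_test(delta)$p.value
  } else {
    rank_sum_test(colSums(per_gene[, group_a, drop = FALSE]),
                  colSums(per_gene[, group_b, drop = FALSE]))$p.value
  }
  list(shift = median(delta), p.value = p, n_genes = nrow(per_gene))
}

#' Expression contrast of coding->noncoding switch genes
#'
#' A null-confirmation report: for genes that switch to a noncoding major
#' isoform, compares total gene-level expression between two groups. The
#' per-gene delta is the log2 ratio of group-mean totals; the group test
#' is a signed-rank of the deltas against zero.
#'
#' @param genes CoNCo gene set (character vector).
#' @param quant FPKM matrix.
#' @param cat a [gene_catalogue] (maps transcripts to genes).
#' @param group_a,group_b sample id vectors.
#' @param eps pseudocount FPKM (default 0.1).
#' @return list with `deltas` (named per-gene log2 differences),
#'   `p.value`.
#' @export
switch_gene_expression_contrast <- function(genes, quant, cat, group_a, group_b,
                                            eps = 0.1) {
  if (!length(genes)) stop_is("empty switch gene set")
  tx <- cat$transcripts[gene_id %chin% genes]
  ids <- intersect(tx$transcript_id, rownames(quant))
  totals <- rowsum(quant[ids, c(group_a, group_b), drop = FALSE],
                   tx$gene_id[match(ids, tx$transcript_id)])
  ma <- rowMeans(totals[, group_a, drop = FALSE])
  mb <- rowMeans(totals[, group_b, drop = FALSE])
  deltas <- log2((mb + eps) / (ma + eps))
  list(deltas = deltas, p.value = signed_rank_test(deltas)$p.value)
}
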