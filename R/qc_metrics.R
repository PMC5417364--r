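# Read-distribution QC across genomic feature classes and the per-kb
# exon/intron ratio used to check sequencing-platform consistency.

#' @noRd
.in_any <- function(pos, chrom, starts, ends, chroms) {
  vapply(seq_along(pos), function(i) {
    any(chroms == chrom[i] & starts <= pos[i] & pos[i] < ends)
  }, logical(1))
}

#' Assign reads to genomic region classes
#'
#' Each read is assigned by its midpoint to exactly one category with
#' fixed precedence `exon_cds > utr > promoter > intron > intergenic`.
#' CDS intervals come from the catalogue's `CDS` features; exonic
#' midpoints outside any CDS are `utr`. When the annotation carries no CDS
#' features at all, exonic midpoints count as `exon_cds`. The promoter is
#' a fixed window upstream of each transcript start (strand-aware).
#'
#' @param reads `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open read intervals).
#' @param cat a [gene_catalogue].
#' @param promoter_span upstream window in bp (default 1000).
#' @return list with `counts` (named integer vector over the five
#'   categories), `fractions` (summing to 1) and `category` (per-read
#'   assignment).
#' @export
assign_regions <- function(reads, cat, promoter_span = 1000) {
  reads <- as.data.table(reads)
  mid <- (reads$start + reads$end) %/% 2L
  ex <- merge(cat$exons, cat$transcripts[, .(transcript_id, chrom, strand, gene_id)],
              by = "transcript_id")
  has_cds <- !is.null(cat$cds) && nrow(cat$cds)
  cds <- if (has_cds)
    merge(cat$cds, cat$transcripts[, .(transcript_id, chrom)], by = "transcript_id")
  # promoter: window upstream of each transcript's 5' end
  tss <- ex[, .(start = min(start), end = max(end)), by = .(transcript_id, chrom, strand)]
  prom <- tss[, .(chrom,
                  start = fifelse(strand == "+", pmax(0L, start - as.integer(promoter_span)), end),
                  end = fifelse(strand == "+", start, end + as.integer(promoter_span)))]
  genes <- ex[, .(start = min(start), end = max(end)), by = .(gene_id, chrom)]
  n <- length(mid)
  category <- rep("intergenic", n)
  in_gene <- .in_any(mid, reads$chrom, genes$start, genes$end, genes$chrom)
  category[in_gene] <- "intron"
  in_prom <- .in_any(mid, reads$chrom, prom$start, prom$end, prom$chrom)
  category[in_prom & !in_gene] <- "promoter"
  in_exon <- .in_any(mid, reads$chrom, ex$start, ex$end, ex$chrom)
  if (has_cds) {
    in_cds <- .in_any(mid, reads$chrom, cds$start, cds$end, cds$chrom)
    category[in_exon & !in_cds] <- "utr"
    category[in_cds] <- "exon_cds"
  } else {
    category[in_exon] <- "exon_cds"
  }
  lv <- c("exon_cds", "utr", "promoter", "intron", "intergenic")
  counts <- table(factor(category, levels = lv))
  list(counts = setNames(as.integer(counts), lv),
       fractions = setNames(as.numeric(counts) / max(1L, n), lv),
       category = category)
}

#' Exon/intron read-density ratio per kb
#'
#' Ratio of exonic reads-per-kb to intronic reads-per-kb for one sample.
#'
#' @param exon_reads,intron_reads read counts in each compartment.
#' @param exon_kb,intron_kb compartment sizes in kilobases (must be > 0).
#' @return list with `exon_density`, `intron_density`, `ratio` (`Inf`,
#'   flagged, when no intronic reads).
#' @export
exon_intron_ratio <- function(exon_reads, intron_reads, exon_kb, intron_kb) {
  if (exon_kb <= 0 || intron_kb <= 0) stop_is("compartment sizes must be > 0")
  ed <- exon_reads / exon_kb
  id <- intron_reads / intron_kb
  list(exon_density = ed, intron_density = id,
       ratio = if (id > 0) ed / id else Inf,
       infinite = id == 0)
}

#' Compare exon/intron ratios between sequencing platforms
#'
#' Reports the median ratio per platform and, when at least two platforms
#' have two or more samples each, a rank-sum comparison of the first two
#' platforms.
#'
#' @param ratios numeric vector of per-sample exon/intron ratios.
#' @param platforms character vector of platform labels, same length.
#' @return list with `medians` (named) and `p.value` (`NA` when untestable).
#' @export
platform_consistency <- function(ratios, platforms) {
  stopifnot(length(ratios) == length(platforms))
  med <- tapply(ratios, platforms, median)
  pl <- names(med)
  p <- NA_real_
  if (length(pl) >= 2L) {
    x <- ratios[platforms == pl[1L]]
    y <- ratios[platforms == pl[2L]]
    if (length(x) >= 2L && length(y) >= 2L) p <- rank_sum_test(x, y)$p.value
  }
  list(medians = med, p.value = p)
}
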