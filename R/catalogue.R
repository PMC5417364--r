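# The gene_catalogue container: transcript models (strand-aware exon
# chains with biotype and provenance) grouped by gene, plus a junction
# index derived from the intron boundaries of every transcript.

#' Construct a gene catalogue
#'
#' The central container of the package: a table of transcript models (one
#' row per transcript: gene, chromosome, strand, biotype, origin), a long
#' exon table in 0-based half-open coordinates, optional CDS intervals, and
#' a derived junction index. Exons are sorted and validated
#' (non-overlapping, at least one per transcript); transcript ids must be
#' unique.
#'
#' @param transcripts `data.frame` with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `biotype`, `origin`.
#' @param exons `data.frame` with columns `transcript_id`, `start`, `end`
#'   (0-based half-open).
#' @param cds optional `data.frame` like `exons` restricted to coding
#'   intervals.
#' @return an object of class `gene_catalogue` with elements `transcripts`,
#'   `exons`, `cds` and `junctions` (the junction index:
#'   `chrom`, `strand`, `donor`, `acceptor`, `origin`).
#' @export
gene_catalogue <- function(transcripts, exons, cds = NULL) {
  tx <- as.data.table(transcripts)
  ex <- as.data.table(exons)
  need <- c("transcript_id", "gene_id", "chrom", "strand", "biotype", "origin")
  if (!all(need %in% names(tx)))
    stop_is("transcripts table must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(tx$transcript_id))
    stop_is("duplicated transcript_id in catalogue")
  if (!all(tx$strand %chin% c("+", "-")))
    stop_is("strand must be '+' or '-'")
  if (!all(tx$biotype %chin% .BIOTYPES))
    stop_is("unknown biotype value(s): %s",
            paste(setdiff(tx$biotype, .BIOTYPES), collapse = ", "))
  ex <- ex[, .(transcript_id, start = as.integer(start), end = as.integer(end))]
  if (any(ex$end <= ex$start)) stop_is("exon with end <= start")
  if (!all(ex$transcript_id %chin% tx$transcript_id))
    stop_is("exon rows reference unknown transcript ids")
  if (!all(tx$transcript_id %chin% ex$transcript_id))
    stop_is("transcript(s) without exons")
  setorder(ex, transcript_id, start)
  if (ex[, any(start[-1L] < end[-.N]), by = transcript_id][, any(V1)])
    stop_is("overlapping exons within a transcript")
  if (!is.null(cds)) {
    cds <- as.data.table(cds)[, .(transcript_id, start = as.integer(start),
                                  end = as.integer(end))]
    setorder(cds, transcript_id, start)
  }
  obj <- structure(list(transcripts = tx[], exons = ex[], cds = cds),
                   class = "gene_catalogue")
  obj$junctions <- .build_junction_index(obj)
  obj
}

#' @noRd
.build_junction_index <- function(cat) {
  j <- transcript_junctions(cat)
  if (!nrow(j)) {
    return(data.table(chrom = character(), strand = character(),
                      donor = integer(), acceptor = integer(),
                      origin = character()))
  }
  j[, .(origin = if (any(origin == "reference")) "reference" else "novel"),
    by = .(chrom, strand, donor, acceptor)]
}

#' Per-transcript junction table
#'
#' One row per intron of every multi-exon transcript: `donor` is the
#' half-open end of the upstream (genomically left) exon, `acceptor` the
#' start of the downstream exon, so `donor < acceptor` always holds in
#' genomic coordinates regardless of strand.
#'
#' @param cat a [gene_catalogue].
#' @return `data.table` with columns `transcript_id`, `chrom`, `strand`,
#'   `origin`, `donor`, `acceptor`.
#' @export
transcript_junctions <- function(cat) {
  ex <- cat$exons
  j <- ex[, if (.N > 1L) .(donor = end[-.N], acceptor = start[-1L]),
          by = transcript_id]
  if (!nrow(j)) {
    return(data.table(transcript_id = character(), chrom = character(),
                      strand = character(), origin = character(),
                      donor = integer(), acceptor = integer()))
  }
  merge(j, cat$transcripts[, .(transcript_id, chrom, strand, origin)],
        by = "transcript_id", sort = FALSE)[
          , .(transcript_id, chrom, strand, origin, donor, acceptor)]
}

#' @noRd
.junction_key <- function(chrom, strand, donor, acceptor) {
  sprintf("%s:%s:%d-%d", chrom, strand, donor, acceptor)
}

#' @export
print.gene_catalogue <- function(x, ...) {
  cat(sprintf("<gene_catalogue> %d transcripts, %d genes, %d junctions\n",
              nrow(x$transcripts), uniqueN(x$transcripts$gene_id),
              nrow(x$junctions)))
  bt <- table(x$transcripts$biotype)
  cat("  biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = " "), "\n")
  invisible(x)
}

#' Exon chains of selected transcripts
#'
#' @param cat a [gene_catalogue].
#' @param ids transcript ids (default all).
#' @return named list of 2-column integer matrices (`start`, `end`), exons
#'   sorted by genomic start.
#' @export
tx_exon_list <- function(cat, ids = cat$transcripts$transcript_id) {
  ex <- cat$exons[transcript_id %chin% ids]
  lapply(split(ex, by = "transcript_id", keep.by = FALSE)[ids],
         function(d) cbind(start = d$start, end = d$end))
}

#' Restrict a catalogue to a transcript set
#'
#' Drops all other transcripts, removes genes left empty, and rebuilds the
#' junction index.
#'
#' @param cat a [gene_catalogue].
#' @param ids transcript ids to keep.
#' @return a [gene_catalogue].
#' @export
subset_catalogue <- function(cat, ids) {
  gene_catalogue(cat$transcripts[transcript_id %chin% ids],
                 cat$exons[transcript_id %chin% ids],
                 cds = if (!is.null(cat$cds)) cat$cds[transcript_id %chin% ids])
}

#' Classify junctions against a reference catalogue
#'
#' A junction is `complete` when its (donor, acceptor) pair matches a
#' reference junction on the same chromosome and strand; `partial` when
#' exactly one of the two boundaries occurs anywhere in the reference
#' junction index on that chromosome/strand; `novel` otherwise (including
#' the rare case where both boundaries are known individually but never as
#' a pair).
#'
#' @param junctions `data.frame` with columns `chrom`, `strand`, `donor`,
#'   `acceptor`.
#' @param ref a reference [gene_catalogue].
#' @return character vector in `{complete, partial, novel}`, one per row.
#' @export
classify_junction <- function(junctions, ref) {
  q <- as.data.table(junctions)
  rj <- ref$junctions
  pair_keys <- .junction_key(rj$chrom, rj$strand, rj$donor, rj$acceptor)
  donor_keys <- sprintf("%s:%s:%d", rj$chrom, rj$strand, rj$donor)
  acc_keys <- sprintf("%s:%s:%d", rj$chrom, rj$strand, rj$acceptor)
  qp <- .junction_key(q$chrom, q$strand, q$donor, q$acceptor)
  qd <- sprintf("%s:%s:%d", q$chrom, q$strand, q$donor)
  qa <- sprintf("%s:%s:%d", q$chrom, q$strand, q$acceptor)
  complete <- qp %chin% pair_keys
  d_known <- qd %chin% donor_keys
  a_known <- qa %chin% acc_keys
  out <- rep("novel", nrow(q))
  out[xor(d_known, a_known)] <- "partial"
  out[complete] <- "complete"
  out
}

#' Filter novel transcripts on junction read support
#'
#' A novel-origin transcript is retained only if every one of its junctions
#' has at least `min_reads` reads in at least `min_samples` samples of the
#' support matrix; junctions missing from the matrix count as unsupported.
#' Reference-origin transcripts always pass: the filter targets assembly
#' artefacts, and reference models are externally validated (the
#' expression filter, by contrast, applies to all transcripts).
#'
#' @param cat a [gene_catalogue].
#' @param support junction support table as returned by
#'   [read_junction_support()]: columns `chrom`, `strand`, `donor`,
#'   `acceptor`, then one integer column per sample.
#' @param min_reads minimum reads per junction per sample (default 2).
#' @param min_samples minimum number of samples meeting `min_reads`
#'   (default 2).
#' @return the filtered, re-indexed [gene_catalogue].
#' @export
filter_junction_support <- function(cat, support, min_reads = 2, min_samples = 2) {
  novel_ids <- cat$transcripts[origin == "novel", transcript_id]
  if (!length(novel_ids)) return(cat)
  sup <- as.data.table(support)
  sample_cols <- setdiff(names(sup), c("chrom", "strand", "donor", "acceptor"))
  if (!nrow(sup) || !length(sample_cols)) {
    warn_is("empty junction support matrix: dropping all %d novel transcripts",
            length(novel_ids))
    return(subset_catalogue(cat, setdiff(cat$transcripts$transcript_id, novel_ids)))
  }
  counts <- as.matrix(sup[, ..sample_cols])
  if (any(counts < 0)) stop_is("negative junction read counts")
  ok_key <- .junction_key(sup$chrom, sup$strand, sup$donor, sup$acceptor)[
    rowSums(counts >= min_reads) >= min_samples]
  tj <- transcript_junctions(cat)[transcript_id %chin% novel_ids]
  tj[, supported := .junction_key(chrom, strand, donor, acceptor) %chin% ok_key]
  # single-exon novels have no junctions and pass vacuously
  bad <- tj[, .(fail = any(!supported)), by = transcript_id][fail == TRUE, transcript_id]
  subset_catalogue(cat, setdiff(cat$transcripts$transcript_id, bad))
}

#' Filter transcripts on expression level
#'
#' Keeps a transcript only if its FPKM is strictly greater than `min_fpkm`
#' in at least `min_samples` samples. Applies to reference and novel
#' transcripts alike; transcripts absent from the matrix are treated as
#' all-zero (with a warning) and dropped; genes left without transcripts
#' disappear.
#'
#' @param cat a [gene_catalogue].
#' @param quant numeric FPKM matrix, rownames = transcript ids, one column
#'   per sample.
#' @param min_fpkm strict FPKM threshold (default 0.5).
#' @param min_samples minimum number of samples exceeding it (default 3).
#' @return the filtered, re-indexed [gene_catalogue].
#' @export
filter_expression <- function(cat, quant, min_fpkm = 0.5, min_samples = 3) {
  quant <- as.matrix(quant)
  if (ncol(quant) < min_samples)
    stop_is("expression filter unsatisfiable: %d sample column(s) < min_samples = %d",
            ncol(quant), min_samples)
  if (any(quant < 0)) stop_is("negative FPKM values")
  ids <- cat$transcripts$transcript_id
  missing <- setdiff(ids, rownames(quant))
  if (length(missing))
    warn_is("%d transcript(s) missing from quantification; treated as zero",
            length(missing))
  present <- intersect(ids, rownames(quant))
  nhit <- rowSums(quant[present, , drop = FALSE] > min_fpkm)
  keep <- present[nhit >= min_samples]
  subset_catalogue(cat, keep)
}

#' Merge novel transcript models into a reference catalogue
#'
#' Transcripts are deduplicated by identical (chromosome, strand, intron
#' chain); single-exon transcripts, which have an empty chain, are
#' deduplicated by their exon interval instead. Each surviving novel
#' transcript is assigned the gene id of the reference gene with maximal
#' exonic overlap on the same strand (ties broken by the lexicographically
#' smallest gene id); novels overlapping no reference gene receive fresh
#' `NOVELG_` gene ids, numbered in a deterministic structural order so the
#' result does not depend on the order of `novel_sets`.
#'
#' @param reference reference [gene_catalogue].
#' @param novel_sets list of novel-origin [gene_catalogue] objects (e.g.,
#'   one per sample).
#' @return the merged [gene_catalogue].
#' @export
merge_catalogues <- function(reference, novel_sets) {
  if (inherits(novel_sets, "gene_catalogue")) novel_sets <- list(novel_sets)
  struct_key <- function(cat) {
    tj <- transcript_junctions(cat)
    chain <- tj[, .(chain = paste(sprintf("%d-%d", donor, acceptor), collapse = ";")),
                by = transcript_id]
    tx <- merge(cat$transcripts, chain, by = "transcript_id", all.x = TRUE, sort = FALSE)
    single <- cat$exons[, .N, by = transcript_id][N == 1L, transcript_id]
    se <- cat$exons[transcript_id %chin% single]
    tx[is.na(chain), chain := {
      m <- se[match(transcript_id, se$transcript_id)]
      sprintf("mono:%d-%d", m$start, m$end)
    }]
    tx[, key := sprintf("%s:%s:%s", chrom, strand, chain)]
    tx
  }
  ref_keys <- struct_key(reference)$key
  ntx <- rbindlist(lapply(novel_sets, function(cs) {
    k <- struct_key(cs)
    k[, src_exons := list(split(cs$exons[, .(transcript_id, start, end)],
                                by = "transcript_id", keep.by = FALSE)[transcript_id])]
    k
  }), use.names = TRUE)
  if (!nrow(ntx)) return(reference)
  setorder(ntx, key, transcript_id)          # deterministic survivor choice
  ntx <- ntx[!duplicated(key)][!key %chin% ref_keys]
  if (!nrow(ntx)) return(reference)
  # unique transcript ids against the reference
  clash <- ntx$transcript_id %in% reference$transcripts$transcript_id
  ntx[clash, transcript_id := paste0(transcript_id, "_novel")]
  nex <- ntx[, rbindlist(setNames(src_exons, transcript_id), idcol = "transcript_id")]
  # gene assignment by maximal exonic overlap, same chrom + strand
  rex <- merge(reference$exons,
               reference$transcripts[, .(transcript_id, gene_id, chrom, strand)],
               by = "transcript_id")[, .(chrom, strand, gene_id, start, end)]
  qex <- merge(nex, ntx[, .(transcript_id, chrom, strand)], by = "transcript_id")
  setkey(rex, chrom, strand, start, end)
  hits <- foverlaps(qex, rex, by.x = c("chrom", "strand", "start", "end"),
                    type = "any", nomatch = NULL)
  assign <- if (nrow(hits)) {
    hits[, ov := pmin(end, i.end) - pmax(start, i.start)]
    per <- hits[ov > 0, .(ov = sum(ov)), by = .(transcript_id, gene_id)]
    setorder(per, transcript_id, -ov, gene_id)   # tie -> smallest gene_id
    per[!duplicated(transcript_id), .(transcript_id, gene_id)]
  } else data.table(transcript_id = character(), gene_id = character())
  ntx[, assigned := assign$gene_id[match(transcript_id, assign$transcript_id)]]
  orphan <- which(is.na(ntx$assigned))
  if (length(orphan)) {
    orph <- ntx[orphan][order(key)]
    fresh <- setNames(sprintf("NOVELG_%05d", seq_along(unique(orph$key))),
                      unique(orph$key))
    ntx[orphan, assigned := fresh[key]]
  }
  gene_catalogue(
    transcripts = rbind(
      reference$transcripts,
      ntx[, .(transcript_id, gene_id = assigned, chrom, strand,
              biotype, origin = "novel")]),
    exons = rbind(reference$exons, nex),
    cds = reference$cds)
}
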