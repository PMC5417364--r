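# Pairwise alternative-splicing event classification between transcript
# models of one gene, in seven categories: SE (skipped/cassette exon),
# MXE (mutually exclusive exons), RI (retained intron), A5SS/A3SS
# (alternative 5'/3' splice sites, transcript-oriented), AFE/ALE
# (alternative first/last exons). Rules are evaluated in genomic
# coordinates; 5'/3' and first/last are then resolved by strand, so a
# minus-strand gene behaves as the mirror image of a plus-strand one.

#' @noRd
.junc_pairs <- function(ex) {
  n <- nrow(ex)
  if (n < 2L) return(matrix(integer(), ncol = 2L,
                            dimnames = list(NULL, c("d", "a"))))
  cbind(d = ex[-n, "end"], a = ex[-1L, "start"])
}

#' @noRd
.has_junc <- function(j, d, a) any(j[, "d"] == d & j[, "a"] == a)

#' @noRd
.exon_key <- function(ex) paste(ex[, "start"], ex[, "end"], sep = "-")

#' @noRd
.ev <- function(type, chrom, strand, coords, start, end, inc, exc) {
  data.table(event_type = type, chrom = chrom, strand = strand,
             coords = coords, start = start, end = end,
             inclusion_tx = list(inc), exclusion_tx = list(exc))
}

# Core pairwise classifier on exon matrices; ids name the two transcripts.
#' @noRd
.classify_pair_core <- function(ex_a, ex_b, chrom, strand, id_a, id_b) {
  out <- list()
  ja <- .junc_pairs(ex_a); jb <- .junc_pairs(ex_b)
  keys_a <- .exon_key(ex_a); keys_b <- .exon_key(ex_b)
  na <- nrow(ex_a); nb <- nrow(ex_b)

  # --- SE: internal exon of one, spliced around by the other ------------
  se_scan <- function(exi, ji, jo, keys_o, inc, exc) {
    n <- nrow(exi)
    if (n < 3L) return()
    for (i in 2:(n - 1L)) {
      d1 <- exi[i - 1L, "end"]; a2 <- exi[i + 1L, "start"]
      if (.has_junc(jo, d1, a2) &&
          !(.exon_key(exi[i, , drop = FALSE]) %in% keys_o)) {
        out[[length(out) + 1L]] <<- .ev(
          "SE", chrom, strand,
          sprintf("%d-%d", exi[i, "start"], exi[i, "end"]),
          exi[i, "start"], exi[i, "end"], inc, exc)
      }
    }
  }
  se_scan(ex_a, ja, jb, keys_b, id_a, id_b)
  se_scan(ex_b, jb, ja, keys_a, id_b, id_a)

  # --- RI: one exon spans an intron of the other, outer edges match -----
  ri_scan <- function(exi, exo, inc, exc) {
    n_o <- nrow(exo)
    if (n_o < 2L) return()
    for (i in seq_len(nrow(exi))) {
      s <- exi[i, "start"]; e <- exi[i, "end"]
      for (k in seq_len(n_o - 1L)) {
        if (exo[k, "start"] == s && exo[k + 1L, "end"] == e &&
            s < exo[k, "end"] && exo[k + 1L, "start"] < e) {
          out[[length(out) + 1L]] <<- .ev(
            "RI", chrom, strand,
            sprintf("%d-%d", exo[k, "end"], exo[k + 1L, "start"]),
            exo[k, "end"], exo[k + 1L, "start"], inc, exc)
        }
      }
    }
  }
  ri_scan(ex_a, ex_b, id_a, id_b)   # A retains an intron of B
  ri_scan(ex_b, ex_a, id_b, id_a)

  # --- alternative splice-site pairs ------------------------------------
  # shared right coordinate (genomic acceptor), differing left: A5SS on +,
  # A3SS on -; the alternative-side exons must overlap.
  if (nrow(ja) && nrow(jb)) {
    for (i in seq_len(nrow(ja))) for (k in seq_len(nrow(jb))) {
      d1 <- ja[i, "d"]; a1 <- ja[i, "a"]; d2 <- jb[k, "d"]; a2 <- jb[k, "a"]
      if (a1 == a2 && d1 != d2) {
        exl_a <- ex_a[ex_a[, "end"] == d1, , drop = FALSE][1L, ]
        exl_b <- ex_b[ex_b[, "end"] == d2, , drop = FALSE][1L, ]
        if (max(exl_a["start"], exl_b["start"]) < min(d1, d2)) {
          longer <- if (d1 > d2) id_a else id_b
          shorter <- if (d1 > d2) id_b else id_a
          out[[length(out) + 1L]] <- .ev(
            if (strand == "+") "A5SS" else "A3SS", chrom, strand,
            sprintf("%d-%d", min(d1, d2), max(d1, d2)),
            min(d1, d2), max(d1, d2), longer, shorter)
        }
      }
      if (d1 == d2 && a1 != a2) {
        exr_a <- ex_a[ex_a[, "start"] == a1, , drop = FALSE][1L, ]
        exr_b <- ex_b[ex_b[, "start"] == a2, , drop = FALSE][1L, ]
        if (max(a1, a2) < min(exr_a["end"], exr_b["end"])) {
          longer <- if (a1 < a2) id_a else id_b
          shorter <- if (a1 < a2) id_b else id_a
          out[[length(out) + 1L]] <- .ev(
            if (strand == "+") "A3SS" else "A5SS", chrom, strand,
            sprintf("%d-%d", min(a1, a2), max(a1, a2)),
            min(a1, a2), max(a1, a2), longer, shorter)
        }
      }
    }
  }

  # --- MXE: mutually exclusive internal exons with shared outer flanks --
  if (na >= 3L && nb >= 3L) {
    for (i in 2:(na - 1L)) for (k in 2:(nb - 1L)) {
      ea <- ex_a[i, ]; eb <- ex_b[k, ]
      if (.exon_key(ex_a[i, , drop = FALSE]) %in% keys_b) next
      if (.exon_key(ex_b[k, , drop = FALSE]) %in% keys_a) next
      if (min(ea["end"], eb["end"]) > max(ea["start"], eb["start"])) next  # overlap
      L_a <- ex_a[i - 1L, "end"]; R_a <- ex_a[i + 1L, "start"]
      L_b <- ex_b[k - 1L, "end"]; R_b <- ex_b[k + 1L, "start"]
      if (L_a == L_b && R_a == R_b) {
        first <- if (xor(ea["start"] < eb["start"], strand == "-")) id_a else id_b
        second <- if (first == id_a) id_b else id_a
        lo <- if (ea["start"] < eb["start"]) ea else eb
        hi <- if (ea["start"] < eb["start"]) eb else ea
        out[[length(out) + 1L]] <- .ev(
          "MXE", chrom, strand,
          sprintf("%d-%d|%d-%d", lo["start"], lo["end"], hi["start"], hi["end"]),
          lo["start"], hi["end"], first, second)
      }
    }
  }

  # --- AFE / ALE: differing terminal exons, shared inner splice site ----
  if (na >= 2L && nb >= 2L) {
    # genomic-left terminal exons
    fa <- ex_a[1L, ]; fb <- ex_b[1L, ]
    if (!identical(unname(fa), unname(fb)) &&
        ex_a[2L, "start"] == ex_b[2L, "start"] &&
        min(fa["end"], fb["end"]) <= max(fa["start"], fb["start"]) &&
        fa["end"] != fb["end"]) {
      distal <- if (fa["start"] < fb["start"]) id_a else id_b
      proximal <- if (distal == id_a) id_b else id_a
      lo <- if (fa["start"] < fb["start"]) fa else fb
      hi <- if (fa["start"] < fb["start"]) fb else fa
      out[[length(out) + 1L]] <- .ev(
        if (strand == "+") "AFE" else "ALE", chrom, strand,
        sprintf("%d-%d|%d-%d", lo["start"], lo["end"], hi["start"], hi["end"]),
        lo["start"], hi["end"], distal, proximal)
    }
    # genomic-right terminal exons
    la <- ex_a[na, ]; lb <- ex_b[nb, ]
    if (!identical(unname(la), unname(lb)) &&
        ex_a[na - 1L, "end"] == ex_b[nb - 1L, "end"] &&
        min(la["end"], lb["end"]) <= max(la["start"], lb["start"]) &&
        la["start"] != lb["start"]) {
      distal <- if (la["end"] > lb["end"]) id_a else id_b
      proximal <- if (distal == id_a) id_b else id_a
      lo <- if (la["start"] < lb["start"]) la else lb
      hi <- if (la["start"] < lb["start"]) lb else la
      out[[length(out) + 1L]] <- .ev(
        if (strand == "+") "ALE" else "AFE", chrom, strand,
        sprintf("%d-%d|%d-%d", lo["start"], lo["end"], hi["start"], hi["end"]),
        lo["start"], hi["end"], distal, proximal)
    }
  }

  if (!length(out)) {
    return(data.table(event_type = character(), chrom = character(),
                      strand = character(), coords = character(),
                      start = integer(), end = integer(),
                      inclusion_tx = list(), exclusion_tx = list()))
  }
  res <- rbindlist(out)
  unique(res, by = c("event_type", "coords"))
}

#' Classify alternative-splicing events between two isoforms
#'
#' Compares the exon chains of two transcripts of the same gene and
#' returns every event of the seven categories (SE, MXE, RI, A5SS, A3SS,
#' AFE, ALE) that distinguishes them. `classify_pair(cat, t, t)` is empty,
#' and swapping the arguments returns the same events with
#' inclusion/exclusion roles swapped consistently.
#'
#' @param cat a [gene_catalogue].
#' @param tx_a,tx_b transcript ids of the same gene.
#' @return `data.table` with columns `gene_id`, `event_type`, `chrom`,
#'   `strand`, `coords` (canonical event coordinates, 0-based half-open),
#'   `start`, `end` (event span) and list columns `inclusion_tx`,
#'   `exclusion_tx`.
#' @export
classify_pair <- function(cat, tx_a, tx_b) {
  a <- cat$transcripts[transcript_id == tx_a]
  b <- cat$transcripts[transcript_id == tx_b]
  if (!nrow(a) || !nrow(b)) stop_is("unknown transcript id(s)")
  if (a$gene_id != b$gene_id || a$strand != b$strand || a$chrom != b$chrom)
    stop_is("transcripts must share gene, chromosome and strand")
  if (tx_a == tx_b) {
    ev <- .classify_pair_core(matrix(integer(), 0, 2,
                                     dimnames = list(NULL, c("start", "end"))),
                              matrix(integer(), 0, 2,
                                     dimnames = list(NULL, c("start", "end"))),
                              a$chrom, a$strand, tx_a, tx_b)
  } else {
    exl <- tx_exon_list(cat, c(tx_a, tx_b))
    ev <- .classify_pair_core(exl[[tx_a]], exl[[tx_b]], a$chrom, a$strand,
                              tx_a, tx_b)
  }
  ev[, gene_id := a$gene_id]
  setcolorder(ev, "gene_id")
  ev[]
}

#' Enumerate the splicing events of a gene (or catalogue)
#'
#' Union of [classify_pair()] over all transcript pairs of each gene with
#' at least two isoforms, deduplicated by (event type, coordinates) with
#' inclusion/exclusion transcript sets aggregated across pairs (a
#' transcript claimed by both roles stays in the inclusion set).
#'
#' @param cat a [gene_catalogue].
#' @param gene_ids genes to process (default: all multi-isoform genes).
#' @return event `data.table` as in [classify_pair()], plus `event_id`.
#' @export
enumerate_events <- function(cat, gene_ids = NULL) {
  counts <- cat$transcripts[, .N, by = gene_id]
  genes <- counts[N >= 2L, gene_id]
  if (!is.null(gene_ids)) genes <- intersect(gene_ids, genes)
  evs <- lapply(genes, function(g) {
    ids <- cat$transcripts[gene_id == g, transcript_id]
    prs <- utils::combn(ids, 2L, simplify = FALSE)
    rbindlist(lapply(prs, function(p) classify_pair(cat, p[1L], p[2L])))
  })
  res <- rbindlist(evs)
  if (!nrow(res)) return(res)
  res <- res[, .(
    chrom = chrom[1L], strand = strand[1L],
    start = start[1L], end = end[1L],
    inclusion_tx = list(sort(unique(unlist(inclusion_tx)))),
    exclusion_tx = list(sort(setdiff(unique(unlist(exclusion_tx)),
                                     unique(unlist(inclusion_tx)))))),
    by = .(gene_id, event_type, coords)]
  res[, event_id := sprintf("%s|%s|%s", gene_id, event_type, coords)]
  res[]
}

#' Abundance-based inclusion level of events
#'
#' Inclusion level = sum of inclusion-transcript FPKM over the summed FPKM
#' of inclusion and exclusion transcripts (a PSI analogue computed from
#' quantifications rather than junction reads). `NA` when the denominator
#' is zero.
#'
#' @param events event table from [enumerate_events()].
#' @param quant FPKM matrix (transcripts x samples).
#' @param samples sample columns to use (default all).
#' @return numeric matrix events x samples of inclusion levels, rownames =
#'   `event_id`.
#' @export
event_inclusion <- function(events, quant, samples = colnames(quant)) {
  assert_matrix_samples(quant, samples, "quantification")
  m <- matrix(NA_real_, nrow(events), length(samples),
              dimnames = list(events$event_id, samples))
  for (i in seq_len(nrow(events))) {
    inc <- intersect(events$inclusion_tx[[i]], rownames(quant))
    exc <- intersect(events$exclusion_tx[[i]], rownames(quant))
    num <- colSums(quant[inc, samples, drop = FALSE])
    den <- num + colSums(quant[exc, samples, drop = FALSE])
    m[i, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  m
}

#' Test events for an inclusion shift between two groups
#'
#' Wilcoxon rank-sum test on per-sample inclusion levels; direction from
#' the difference of group means (`inclusion_up` means group B above group
#' A). Events with an undefined inclusion level in any sample, or with
#' `q >= fdr`, are reported with direction `none`.
#'
#' @param events event table from [enumerate_events()].
#' @param quant FPKM matrix.
#' @param group_a,group_b sample id vectors.
#' @param fdr BH threshold for calling a direction (default 0.01).
#' @return the event table with `mean_a`, `mean_b`, `p`, `q`, `direction`.
#' @export
event_shift_test <- function(events, quant, group_a, group_b, fdr = 0.01) {
  if (!length(group_a) || !length(group_b)) stop_is("empty sample group")
  inc <- event_inclusion(events, quant, c(group_a, group_b))
  res <- copy(as.data.table(events))
  stats <- lapply(seq_len(nrow(res)), function(i) {
    xa <- inc[i, group_a]; xb <- inc[i, group_b]
    if (anyNA(c(xa, xb)))
      return(list(mean_a = NA_real_, mean_b = NA_real_, p = NA_real_))
    p <- if (length(xa) >= 2L && length(xb) >= 2L)
      rank_sum_test(xa, xb)$p.value else NA_real_
    list(mean_a = mean(xa), mean_b = mean(xb), p = p)
  })
  res[, `:=`(mean_a = vapply(stats, `[[`, 0, "mean_a"),
             mean_b = vapply(stats, `[[`, 0, "mean_b"),
             p = vapply(stats, `[[`, 0, "p"))]
  res[, q := NA_real_]
  ok <- !is.na(res$p)
  if (any(ok)) res[ok, q := bh_adjust(p[ok])]
  res[, direction := "none"]
  res[!is.na(q) & q < fdr & mean_b > mean_a, direction := "inclusion_up"]
  res[!is.na(q) & q < fdr & mean_b < mean_a, direction := "inclusion_down"]
  res[]
}

#' Export an event table as TSV
#'
#' Flattens the transcript-set list columns to comma-separated strings.
#'
#' @param events event table (optionally with shift-test columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- copy(as.data.table(events))
  out[, inclusion_tx := vapply(inclusion_tx, paste, "", collapse = ",")]
  out[, exclusion_tx := vapply(exclusion_tx, paste, "", collapse = ",")]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
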