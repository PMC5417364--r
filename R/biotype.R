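# Structural biotype assignment for novel transcripts.
#
# Reference transcripts keep their annotated biotype. Novel transcripts are
# classified by structure alone:
#   (a) retained_intron  — an exon completely spans an intron of a
#       protein-coding reference peer (both splice sites strictly internal);
#   (b) nmd              — a qualifying ORF whose stop codon lies more than
#       50 nt upstream of the final exon-exon junction (the canonical
#       50-nt rule); needs genome sequence;
#   (c) processed_transcript — no qualifying ORF (or sequence-free mode);
#   (d) protein_coding   — qualifying ORF, rules (a)/(b) fail.
# A qualifying ORF is the longest ATG-initiated open reading frame on the
# spliced transcript sequence with >= 100 codons. Without a genome FASTA
# the package runs in sequence-free mode: rules (b)/(d) are skipped and
# every non-RI novel becomes processed_transcript.

#' Classify the biotype of one transcript against its gene peers
#'
#' @param tx_id transcript id within `cat`.
#' @param cat a [gene_catalogue]; peers are the other transcripts of the
#'   same gene.
#' @param genome optional named character vector of chromosome sequences
#'   (or a `Biostrings::DNAStringSet`); enables the ORF-based rules.
#' @param min_codons minimum ORF length in codons (default 100).
#' @param nmd_rule_nt premature-stop distance for the NMD rule (default 50).
#' @return a biotype string.
#' @export
classify_biotype <- function(tx_id, cat, genome = NULL,
                             min_codons = 100, nmd_rule_nt = 50) {
  tx <- cat$transcripts[transcript_id == tx_id]
  if (!nrow(tx)) stop_is("unknown transcript '%s'", tx_id)
  if (tx$origin == "reference" && tx$biotype != "novel_unclassified")
    return(tx$biotype)
  peers <- cat$transcripts[gene_id == tx$gene_id & transcript_id != tx_id &
                             origin == "reference" & biotype == "protein_coding",
                           transcript_id]
  ex <- tx_exon_list(cat, tx_id)[[1L]]
  if (length(peers)) {
    pj <- transcript_junctions(cat)[transcript_id %chin% peers]
    if (nrow(pj)) {
      for (i in seq_len(nrow(ex))) {
        if (any(pj$donor > ex[i, "start"] & pj$acceptor < ex[i, "end"]))
          return("retained_intron")
      }
    }
  }
  if (is.null(genome)) return("processed_transcript")
  orf <- .longest_orf(.spliced_sequence(ex, tx$chrom, tx$strand, genome))
  if (is.null(orf) || orf$codons < min_codons) return("processed_transcript")
  if (nrow(ex) > 1L) {
    # transcript-coordinate position of the last junction, 5'->3'
    cum <- cumsum(ex[, "end"] - ex[, "start"])
    last_junc <- if (tx$strand == "+") cum[nrow(ex) - 1L] else {
      lens <- rev(ex[, "end"] - ex[, "start"])
      cumsum(lens)[length(lens) - 1L]
    }
    if (last_junc - orf$stop_end > nmd_rule_nt) return("nmd")
  }
  "protein_coding"
}

#' Assign biotypes to every novel transcript of a catalogue
#'
#' Applies [classify_biotype()] to all novel-origin (or
#' `novel_unclassified`) transcripts and returns the updated catalogue.
#'
#' @inheritParams classify_biotype
#' @return the catalogue with novel biotypes filled in.
#' @export
assign_biotypes <- function(cat, genome = NULL, min_codons = 100,
                            nmd_rule_nt = 50) {
  todo <- cat$transcripts[origin == "novel" | biotype == "novel_unclassified",
                          transcript_id]
  if (!length(todo)) return(cat)
  bt <- vapply(todo, classify_biotype, character(1), cat = cat,
               genome = genome, min_codons = min_codons,
               nmd_rule_nt = nmd_rule_nt)
  tx <- copy(cat$transcripts)
  tx[match(todo, transcript_id), biotype := bt]
  gene_catalogue(tx, cat$exons, cat$cds)
}

#' Coding status of a biotype
#'
#' `protein_coding` is coding; `retained_intron`, `processed_transcript`,
#' `nmd` and `other_noncoding` are noncoding; `novel_unclassified` is
#' treated as noncoding until classified.
#'
#' @param biotype character vector of biotypes.
#' @return character vector in `{coding, noncoding}`.
#' @export
coding_status <- function(biotype) {
  ifelse(biotype == "protein_coding", "coding", "noncoding")
}

#' @noRd
.spliced_sequence <- function(ex, chrom, strand, genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (!chrom %in% names(genome)) stop_is("chromosome '%s' not in genome", chrom)
  seqs <- substring(genome[[chrom]], ex[, "start"] + 1L, ex[, "end"])
  s <- toupper(paste(seqs, collapse = ""))
  if (strand == "-") s <- .revcomp(s)
  s
}

#' @noRd
.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# Longest ATG-initiated ORF terminated by a stop codon, scanning all three
# frames on the given (already strand-oriented) sequence. Returns NULL when
# no terminated ORF exists; stop_end is the 1-based transcript coordinate
# of the last base of the stop codon.
#' @noRd
.longest_orf <- function(s) {
  n <- nchar(s)
  if (n < 6L) return(NULL)
  codons <- function(from) {
    k <- (n - from + 1L) %/% 3L
    if (k < 2L) return(NULL)
    substring(s, from + 3L * (seq_len(k) - 1L), from + 3L * seq_len(k) - 1L)
  }
  best <- NULL
  for (frame in 0:2) {
    cc <- codons(frame + 1L)
    if (is.null(cc)) next
    starts <- which(cc == "ATG")
    stops <- which(cc %in% c("TAA", "TAG", "TGA"))
    for (st in starts) {
      after <- stops[stops > st]
      if (!length(after)) next
      sp <- after[1L]
      len <- sp - st            # codons excluding the stop
      if (is.null(best) || len > best$codons) {
        best <- list(codons = len,
                     start = frame + 1L + 3L * (st - 1L),
                     stop_end = frame + 3L * sp)
      }
    }
  }
  best
}
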