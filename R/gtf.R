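# GTF reading/writing for the exon/CDS dialect the catalogue uses.
# GTF is 1-based inclusive; everything internal is 0-based half-open, and
# this file is the single conversion site.

.BIOTYPES <- c("protein_coding", "retained_intron", "processed_transcript",
               "nmd", "other_noncoding", "novel_unclassified")

#' @noRd
.normalise_biotype <- function(x) {
  x <- tolower(x)
  out <- rep("other_noncoding", length(x))
  out[x %in% .BIOTYPES] <- x[x %in% .BIOTYPES]
  out[x %in% c("nonsense_mediated_decay", "nmd")] <- "nmd"
  out[is.na(x) | x == ""] <- "novel_unclassified"
  out
}

#' @noRd
.gtf_attr <- function(attrs, key) {
  pat <- paste0(key, '\\s+"([^"]*)"')
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(v) if (length(v) == 2L) v[2L] else NA_character_,
         character(1))
}

#' Parse a GTF annotation into a gene catalogue
#'
#' Reads `exon` (and, when present, `CDS`) features carrying `gene_id` and
#' `transcript_id` attributes. The optional `transcript_biotype` attribute
#' is normalised onto the internal biotype vocabulary
#' (`protein_coding`, `retained_intron`, `processed_transcript`, `nmd`,
#' `other_noncoding`); transcripts without a biotype attribute become
#' `novel_unclassified`. GTF 1-based inclusive coordinates are converted to
#' 0-based half-open.
#'
#' @param path path to a GTF file (or a character vector of GTF lines via
#'   `text`).
#' @param text optional GTF content as a single string or vector of lines;
#'   overrides `path`.
#' @param origin provenance flag for every transcript, `"reference"` or
#'   `"novel"`.
#' @return a [gene_catalogue] object.
#' @examples
#' gtf <- c(
#'   'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
#'   'chr1\tx\texon\t501\t600\t.\t+\t.\tgene_id "g1"; transcript_id "t1";')
#' cat1 <- read_gtf(text = gtf)
#' cat1$exons
#' @export
read_gtf <- function(path = NULL, text = NULL, origin = c("reference", "novel")) {
  origin <- match.arg(origin)
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    readLines(path)
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop_is("GTF input contains no feature lines")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop_is("malformed GTF line %d: expected 9 tab-separated fields, found %d",
            lineno[bad], nf[bad])
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 9L, byrow = TRUE)
  dt <- data.table(
    chrom = m[, 1L], feature = m[, 3L],
    start = suppressWarnings(as.integer(m[, 4L])),
    end = suppressWarnings(as.integer(m[, 5L])),
    strand = m[, 7L], attrs = m[, 9L], line = lineno)
  dt <- dt[feature %chin% c("exon", "CDS")]
  if (!nrow(dt)) stop_is("GTF input has no exon features")
  if (anyNA(dt$start) || anyNA(dt$end)) {
    bad <- dt$line[which(is.na(dt$start) | is.na(dt$end))[1L]]
    stop_is("malformed GTF line %d: non-numeric coordinates", bad)
  }
  # to 0-based half-open
  dt[, start := start - 1L]
  bad <- dt$end <= dt$start
  if (any(bad)) {
    warn_is("rejected %d GTF record(s) with end <= start (lines %s)",
            sum(bad), paste(head(dt$line[bad], 5L), collapse = ", "))
    dt <- dt[!bad]
  }
  dt[, `:=`(transcript_id = .gtf_attr(attrs, "transcript_id"),
            gene_id = .gtf_attr(attrs, "gene_id"),
            biotype_raw = .gtf_attr(attrs, "transcript_biotype"))]
  if (anyNA(dt$transcript_id) || anyNA(dt$gene_id)) {
    bad <- dt$line[which(is.na(dt$transcript_id) | is.na(dt$gene_id))[1L]]
    stop_is("malformed GTF line %d: missing gene_id/transcript_id attribute", bad)
  }
  ex <- dt[feature == "exon"]
  tx <- ex[, .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
               biotype = .normalise_biotype(biotype_raw[1L])),
           by = transcript_id]
  tx[, origin := origin]
  cds <- dt[feature == "CDS", .(transcript_id, start, end)]
  gene_catalogue(
    transcripts = tx[, .(transcript_id, gene_id, chrom, strand, biotype, origin)],
    exons = ex[, .(transcript_id, start, end)],
    cds = if (nrow(cds)) cds else NULL)
}

#' Write a gene catalogue as GTF
#'
#' Inverse of [read_gtf()]: emits one `exon` line per exon (and `CDS` lines
#' when the catalogue carries CDS intervals) with `gene_id`,
#' `transcript_id` and `transcript_biotype` attributes, converting back to
#' 1-based inclusive coordinates. `read_gtf(write_gtf(cat))` reproduces the
#' catalogue exactly.
#'
#' @param cat a [gene_catalogue].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(cat, path) {
  stopifnot(inherits(cat, "gene_catalogue"))
  ex <- merge(cat$exons, cat$transcripts, by = "transcript_id", sort = FALSE)
  fmt <- function(d, feature) {
    sprintf('%s\tisoswitch\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
            d$chrom, feature, d$start + 1L, d$end, d$strand,
            d$gene_id, d$transcript_id, d$biotype)
  }
  out <- fmt(ex, "exon")
  if (!is.null(cat$cds) && nrow(cat$cds)) {
    cd <- merge(cat$cds, cat$transcripts, by = "transcript_id", sort = FALSE)
    out <- c(out, fmt(cd, "CDS"))
  }
  writeLines(out, path)
  invisible(path)
}
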