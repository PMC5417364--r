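# Readers/writers for the plain-text table dialects the pipeline exchanges:
# FPKM TSV (transcript_id + sample columns), junction support TSV
# (chrom/strand/donor/acceptor + sample columns), intron coverage TSV
# (gene_id/chrom/start/end + sample columns), sample metadata TSV, and a
# BED6 export of classified junctions.

#' Read a transcript FPKM matrix
#'
#' @param path TSV with a `transcript_id` column followed by one numeric
#'   column per sample.
#' @return numeric matrix, rownames = transcript ids.
#' @export
read_fpkm <- function(path) {
  dt <- fread(path, sep = "\t")
  if (names(dt)[1L] != "transcript_id")
    stop_is("FPKM table must start with a transcript_id column")
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt$transcript_id
  if (any(m < 0)) stop_is("negative FPKM values in %s", path)
  m
}

#' Write a transcript FPKM matrix
#' @param quant numeric matrix with transcript rownames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fpkm <- function(quant, path) {
  fwrite(data.table(transcript_id = rownames(quant), quant), path, sep = "\t")
  invisible(path)
}

#' Read a junction read-support table
#'
#' @param path TSV with columns `chrom`, `strand`, `donor`, `acceptor`,
#'   then one integer column per sample.
#' @return `data.table` in the same layout.
#' @export
read_junction_support <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("chrom", "strand", "donor", "acceptor")
  if (!all(need %in% names(dt)))
    stop_is("junction support table must have columns %s", paste(need, collapse = ", "))
  dt
}

#' @rdname read_junction_support
#' @param support table as returned by [read_junction_support()].
#' @export
write_junction_support <- function(support, path) {
  fwrite(support, path, sep = "\t")
  invisible(path)
}

#' Read a per-intron read-coverage table
#'
#' @param path TSV with columns `gene_id`, `chrom`, `start`, `end`, then
#'   one read-count column per sample.
#' @return `data.table` in the same layout.
#' @export
read_coverage <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(dt)))
    stop_is("coverage table must have columns %s", paste(need, collapse = ", "))
  dt
}

#' @rdname read_coverage
#' @param coverage table as returned by [read_coverage()].
#' @export
write_coverage <- function(coverage, path) {
  fwrite(coverage, path, sep = "\t")
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample`, `condition` (time point or
#'   patient group) and optionally `platform`.
#' @return `data.table`.
#' @export
read_metadata <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "sample"))
  if (!all(c("sample", "condition") %in% names(dt)))
    stop_is("metadata must have 'sample' and 'condition' columns")
  dt
}

#' Export classified junctions as BED6
#'
#' One BED line per junction in the catalogue's index, with the junction
#' class from [classify_junction()] as the feature name.
#'
#' @param cat a [gene_catalogue] whose junctions to export.
#' @param ref reference [gene_catalogue] used for classification.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
export_junctions_bed <- function(cat, ref, path) {
  j <- cat$junctions
  cls <- classify_junction(j, ref)
  fwrite(data.table(j$chrom, j$donor, j$acceptor, cls, 0L, j$strand),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}
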