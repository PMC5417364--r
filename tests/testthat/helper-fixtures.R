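# Fixture builders used across the suite. Everything is constructed in
# code; no binary data.

# Compact catalogue builder: `spec` is a list of transcripts, each
# list(id, gene, strand, exons = rbind(c(s, e), ...), biotype, origin).
make_cat <- function(spec, chrom = "chr1") {
  tx <- data.table::rbindlist(lapply(spec, function(s) data.table::data.table(
    transcript_id = s$id, gene_id = s$gene, chrom = s$chrom %||% chrom,
    strand = s$strand %||% "+",
    biotype = s$biotype %||% "protein_coding",
    origin = s$origin %||% "reference")))
  ex <- data.table::rbindlist(lapply(spec, function(s) data.table::data.table(
    transcript_id = s$id, start = s$exons[, 1], end = s$exons[, 2])))
  gene_catalogue(tx, ex)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Three-transcript single-gene fixture used by catalogue tests: introns are
# t1: (200,500), (600,900); t2: (200,500); t3: (200,700).
fixture_gene3 <- function() {
  make_cat(list(
    list(id = "t1", gene = "g1",
         exons = rbind(c(100, 200), c(500, 600), c(900, 1000))),
    list(id = "t2", gene = "g1", exons = rbind(c(100, 200), c(500, 620))),
    list(id = "t3", gene = "g1", exons = rbind(c(100, 200), c(700, 1000)),
         biotype = "processed_transcript")))
}

# Quantification matrix from a named list of per-sample rows.
make_quant <- function(rows, samples) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), samples)
  m
}

# Calls table shortcut for switch tests.
make_calls <- function(gene_id, sample, status, transcript_id = NA_character_) {
  data.table::data.table(gene_id = gene_id, sample = sample,
                         transcript_id = transcript_id, status = status)
}

# Tiny ontology: root -> {A, B}; A -> A1; annotation over 20 genes.
#   A1: g1..g4; A: g1..g8 (propagation adds A, root); B: g9..g14.
fixture_ontology <- function() {
  edges <- data.table::data.table(
    child = c("A", "B", "A1"), parent = c("root", "root", "A"))
  ann <- data.table::data.table(
    gene_id = c(sprintf("g%d", 1:4), sprintf("g%d", 5:8), sprintf("g%d", 9:14)),
    term_id = c(rep("A1", 4), rep("A", 4), rep("B", 6)))
  ontology_dag(edges, ann)
}
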