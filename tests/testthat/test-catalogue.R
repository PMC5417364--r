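# catalogue construction, GTF I/O, junction classification, filters, merge

test_that("GTF parsing converts coordinates and groups transcripts", {
  gtf <- c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t501\t600\t.\t+\t.\tgene_id "g1"; transcript_id "t1";')
  cat1 <- read_gtf(text = gtf)
  expect_equal(cat1$exons$start, c(100L, 500L))
  expect_equal(cat1$exons$end, c(200L, 600L))
  expect_equal(nrow(cat1$transcripts), 1L)
  expect_equal(nrow(cat1$junctions), 1L)
  expect_equal(cat1$junctions$donor, 200L)
  expect_equal(cat1$junctions$acceptor, 500L)
  expect_equal(cat1$transcripts$biotype, "novel_unclassified")
})

test_that("GTF errors carry line numbers and bad records are rejected", {
  bad <- c('chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g"; transcript_id "t";',
           "chr1\tsrc\texon\t101")
  expect_error(read_gtf(text = bad), "line 2")
  rej <- c('chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g"; transcript_id "t";',
           'chr1\tsrc\texon\t300\t250\t.\t+\t.\tgene_id "g"; transcript_id "t2";')
  expect_warning(cat1 <- read_gtf(text = rej), "end <= start")
  expect_equal(nrow(cat1$exons), 1L)
})

test_that("junction index of a 3-transcript gene is the union of its introns", {
  cat1 <- fixture_gene3()
  # hand count: t1 gives (200,500),(600,900); t2 gives (200,500); t3 (200,700)
  expect_equal(nrow(cat1$junctions), 3L)
  got <- cat1$junctions[order(donor, acceptor), .(donor, acceptor)]
  expect_equal(got, data.table::data.table(
    donor = c(200L, 200L, 600L), acceptor = c(500L, 700L, 900L)))
})

test_that("GTF round-trips exactly, including CDS and biotypes", {
  cat1 <- fixture_gene3()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(cat1, path)
  back <- read_gtf(path)
  expect_equal(back$transcripts[order(transcript_id)],
               cat1$transcripts[order(transcript_id)])
  expect_equal(back$exons[order(transcript_id, start)],
               cat1$exons[order(transcript_id, start)])
})

test_that("classify_junction handles complete/partial/novel and partitions", {
  ref <- fixture_gene3()
  q <- data.table::data.table(
    chrom = "chr1", strand = "+",
    donor = c(200L, 200L, 333L, 600L, 200L),
    acceptor = c(500L, 550L, 444L, 750L, 900L))
  cls <- classify_junction(q, ref)
  expect_equal(cls[1], "complete")          # identity
  expect_equal(cls[2], "partial")           # known donor only
  expect_equal(cls[3], "novel")             # both ends unknown
  expect_equal(cls[4], "partial")           # donor 600 known, acceptor 750 not
  # donor 200 and acceptor 900 both occur in reference but never paired:
  # spec post-condition makes this novel (both boundaries known)
  expect_equal(cls[5], "novel")
  expect_equal(sum(cls %in% c("complete", "partial", "novel")), nrow(q))
  # wrong strand is never complete
  q2 <- data.table::data.table(chrom = "chr1", strand = "-",
                               donor = 200L, acceptor = 500L)
  expect_equal(classify_junction(q2, ref), "novel")
})

test_that("junction class frequencies recover injected perturbation rates", {
  cfg <- sim_config(n_genes = 150)
  sc <- simulate_catalogue(cfg, seed = 11)
  q <- simulate_junction_queries(sc$catalogue, seed = 12,
                                 one_end = 0.10, both_end = 0.02)
  cls <- classify_junction(q, sc$catalogue)
  # realised class must match the intended class except for rare boundary
  # collisions of the +-7/13 offsets
  expect_gt(mean(cls == q$true_class), 0.98)
  n <- nrow(q)
  p_hat <- mean(cls == "partial")
  expect_lt(abs(p_hat - 0.10), 3 * sqrt(0.1 * 0.9 / n) + 0.01)
  expect_lt(abs(mean(cls == "novel") - 0.02), 3 * sqrt(0.02 * 0.98 / n) + 0.01)
})

test_that("junction-support filter applies the >=2 reads in >=2 samples rule", {
  spec <- list(
    list(id = "ref1", gene = "g1", exons = rbind(c(100, 200), c(500, 600))),
    list(id = "nv1", gene = "g1", origin = "novel",
         exons = rbind(c(100, 200), c(700, 800))),
    list(id = "nv2", gene = "g1", origin = "novel",
         exons = rbind(c(100, 200), c(900, 1000))))
  cat1 <- make_cat(spec)
  sup <- data.table::data.table(
    chrom = "chr1", strand = "+", donor = 200L,
    acceptor = c(700L, 900L),
    s1 = c(2L, 1L), s2 = c(2L, 1L), s3 = c(0L, 1L))
  out <- filter_junction_support(cat1, sup)
  expect_setequal(out$transcripts$transcript_id, c("ref1", "nv1"))
  # reference transcripts bypass the filter even with no support rows
  expect_true("ref1" %in% out$transcripts$transcript_id)
  # idempotence and removal-only
  again <- filter_junction_support(out, sup)
  expect_equal(again$transcripts, out$transcripts)
  expect_true(all(out$transcripts$transcript_id %in%
                    cat1$transcripts$transcript_id))
  # empty support drops all novels with a warning
  expect_warning(
    none <- filter_junction_support(cat1, sup[0]),
    "empty")
  expect_equal(none$transcripts$transcript_id, "ref1")
})

test_that("expression filter uses strict inequality and sample minimum", {
  spec <- lapply(1:4, function(i)
    list(id = paste0("t", i), gene = "g1",
         exons = rbind(c(100, 200), c(500, 600))))
  cat1 <- make_cat(spec)
  q <- make_quant(list(
    t1 = c(0.6, 0.6, 0.6, 0.0),   # keep: 3 samples > 0.5
    t2 = c(0.5, 0.5, 0.5, 0.5),   # drop: strict inequality at the boundary
    t3 = c(0.6, 0.6, 0.0, 0.0),   # drop: only 2 samples
    t4 = c(10, 10, 10, 10)),      # keep
    paste0("s", 1:4))
  out <- filter_expression(cat1, q)
  expect_setequal(out$transcripts$transcript_id, c("t1", "t4"))
  expect_equal(filter_expression(out, q)$transcripts, out$transcripts)
  expect_error(filter_expression(cat1, q[, 1:2]), "unsatisfiable")
})

test_that("filters drop genes left without transcripts", {
  spec <- list(
    list(id = "a1", gene = "gA", exons = rbind(c(100, 200))),
    list(id = "b1", gene = "gB", exons = rbind(c(5000, 6000))))
  cat1 <- make_cat(spec)
  q <- make_quant(list(a1 = c(1, 1, 1), b1 = c(0, 0, 0)), paste0("s", 1:3))
  out <- filter_expression(cat1, q)
  expect_equal(unique(out$transcripts$gene_id), "gA")
})

test_that("merge deduplicates by intron chain and assigns genes by overlap", {
  ref <- fixture_gene3()
  # novel duplicate of t2's chain -> collapses; novel mono-exon inside g1
  nov <- make_cat(list(
    list(id = "n1", gene = "x1", origin = "novel",
         exons = rbind(c(90, 200), c(500, 650))),       # chain == t2 -> dup
    list(id = "n2", gene = "x2", origin = "novel",
         exons = rbind(c(520, 580))),                   # inside g1 span
    list(id = "n3", gene = "x3", origin = "novel",
         exons = rbind(c(50000, 50100)))))              # no overlap -> fresh
  out <- merge_catalogues(ref, list(nov))
  expect_equal(nrow(out$transcripts), 3L + 2L)
  expect_false("n1" %in% out$transcripts$transcript_id)
  expect_equal(out$transcripts[transcript_id == "n2", gene_id], "g1")
  expect_match(out$transcripts[transcript_id == "n3", gene_id], "^NOVELG_")
})

test_that("merge is order-insensitive over novel sets", {
  ref <- fixture_gene3()
  nv <- function(id, s) make_cat(list(list(id = id, gene = "x", origin = "novel",
                                           exons = rbind(c(s, s + 100)))))
  a <- nv("na", 150); b <- nv("nb", 510); c3 <- nv("nc", 60000)
  m1 <- merge_catalogues(ref, list(a, b, c3))
  m2 <- merge_catalogues(ref, list(c3, a, b))
  expect_equal(m1$transcripts[order(transcript_id)],
               m2$transcripts[order(transcript_id)])
})

test_that("random merge bookkeeping matches generator truth", {
  cfg <- sim_config(n_genes = 100, n_isoforms = 2)
  sc <- simulate_catalogue(cfg, seed = 21)
  ref <- sc$catalogue
  # novel set: 25 structural duplicates of reference transcripts plus 25
  # fresh variants (shift of one internal boundary), ledgered by design
  ids <- ref$transcripts$transcript_id
  set.seed(22)
  dup_ids <- sample(ids, 25)
  fresh_ids <- sample(setdiff(ids, dup_ids), 25)
  exl <- tx_exon_list(ref, c(dup_ids, fresh_ids))
  mk <- function(i, id) {
    ex <- exl[[id]]
    fresh <- i > 25
    if (fresh) ex[1, "end"] <- ex[1, "end"] - 11L   # new donor -> new chain
    tr <- ref$transcripts[transcript_id == id]
    list(id = paste0("nv", i), gene = paste0("x", i), strand = tr$strand,
         chrom = tr$chrom, origin = "novel", exons = ex)
  }
  nov <- make_cat(lapply(seq_along(c(dup_ids, fresh_ids)),
                         function(i) mk(i, c(dup_ids, fresh_ids)[i])))
  out <- merge_catalogues(ref, list(nov))
  expect_equal(nrow(out$transcripts), nrow(ref$transcripts) + 25L)
  kept <- grep("^nv", out$transcripts$transcript_id, value = TRUE)
  expect_setequal(kept, paste0("nv", 26:50))
})
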