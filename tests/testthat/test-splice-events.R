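# pairwise event classification, enumeration, inclusion, shift test

two_tx_cat <- function(ex_a, ex_b, strand = "+") {
  make_cat(list(
    list(id = "a", gene = "g", strand = strand, exons = ex_a),
    list(id = "b", gene = "g", strand = strand, exons = ex_b)))
}

test_that("canonical SE, RI and A5SS pairs classify with exact coordinates", {
  se <- classify_pair(two_tx_cat(rbind(c(100, 200), c(300, 400), c(500, 600)),
                                 rbind(c(100, 200), c(500, 600))), "a", "b")
  expect_equal(se$event_type, "SE")
  expect_equal(se$coords, "300-400")
  expect_equal(se$inclusion_tx[[1]], "a")
  expect_equal(se$exclusion_tx[[1]], "b")

  ri <- classify_pair(two_tx_cat(rbind(c(100, 600)),
                                 rbind(c(100, 200), c(500, 600))), "a", "b")
  expect_equal(ri$event_type, "RI")
  expect_equal(ri$coords, "200-500")
  expect_equal(ri$inclusion_tx[[1]], "a")   # the retaining transcript

  a5 <- classify_pair(two_tx_cat(rbind(c(100, 250), c(500, 600)),
                                 rbind(c(100, 200), c(500, 600))), "a", "b")
  expect_equal(a5$event_type, "A5SS")
  expect_equal(a5$coords, "200-250")        # the two alternative donors
  expect_equal(a5$inclusion_tx[[1]], "a")   # longer exon form
})

test_that("identity pairs yield no events and cross-gene pairs error", {
  cat1 <- fixture_gene3()
  expect_equal(nrow(classify_pair(cat1, "t1", "t1")), 0L)
  cat2 <- make_cat(list(
    list(id = "x", gene = "gX", exons = rbind(c(100, 200))),
    list(id = "y", gene = "gY", exons = rbind(c(100, 200)))))
  expect_error(classify_pair(cat2, "x", "y"), "share gene")
})

test_that("MXE and AFE/ALE structures are recognised", {
  mxe <- classify_pair(two_tx_cat(
    rbind(c(100, 200), c(300, 400), c(700, 800)),
    rbind(c(100, 200), c(500, 600), c(700, 800))), "a", "b")
  expect_equal(mxe$event_type, "MXE")
  expect_equal(mxe$coords, "300-400|500-600")
  expect_equal(mxe$inclusion_tx[[1]], "a")  # 5'-most exon on + strand

  afe <- classify_pair(two_tx_cat(
    rbind(c(100, 200), c(700, 800)),
    rbind(c(400, 500), c(700, 800))), "a", "b")
  expect_equal(afe$event_type, "AFE")
  ale <- classify_pair(two_tx_cat(
    rbind(c(100, 200), c(300, 400)),
    rbind(c(100, 200), c(600, 700))), "a", "b")
  expect_equal(ale$event_type, "ALE")
  # same structures on the minus strand swap the labels
  afe_m <- classify_pair(two_tx_cat(
    rbind(c(100, 200), c(700, 800)),
    rbind(c(400, 500), c(700, 800)), strand = "-"), "a", "b")
  expect_equal(afe_m$event_type, "ALE")
})

test_that("symmetry: swapping arguments swaps inclusion/exclusion roles", {
  cfg <- sim_config(n_genes = 60, n_isoforms = 2)
  sc <- simulate_catalogue(cfg, seed = 41)
  tx <- sc$catalogue$transcripts
  for (g in unique(tx$gene_id)[1:30]) {
    ids <- tx[gene_id == g, transcript_id]
    ab <- classify_pair(sc$catalogue, ids[1], ids[2])
    ba <- classify_pair(sc$catalogue, ids[2], ids[1])
    expect_equal(event_keys(ab), event_keys(ba))
    if (nrow(ab)) {
      data.table::setorder(ab, event_type, coords)
      data.table::setorder(ba, event_type, coords)
      expect_equal(ab$inclusion_tx, ba$inclusion_tx)
      expect_equal(ab$exclusion_tx, ba$exclusion_tx)
    }
  }
})

test_that("reflecting coordinates and flipping strand preserves event types", {
  # transcript-oriented rules: the mirrored gene is structurally identical,
  # so types are preserved; relabelling the strand alone swaps 5'/3'.
  cfg <- sim_config(n_genes = 50, n_isoforms = 2)
  sc <- simulate_catalogue(cfg, seed = 43)
  tx <- sc$catalogue$transcripts
  M <- 2000000L
  mirror <- function(ex) {
    out <- cbind(start = M - ex[, "end"], end = M - ex[, "start"])
    out[order(out[, "start"]), , drop = FALSE]
  }
  swap53 <- c(SE = "SE", RI = "RI", MXE = "MXE",
              A5SS = "A3SS", A3SS = "A5SS", AFE = "ALE", ALE = "AFE")
  for (g in unique(tx$gene_id)) {
    ids <- tx[gene_id == g, transcript_id]
    strand <- tx[gene_id == g, strand][1]
    exl <- tx_exon_list(sc$catalogue, ids)
    ev <- classify_pair(sc$catalogue, ids[1], ids[2])
    flipped <- if (strand == "+") "-" else "+"
    refl <- two_tx_cat(mirror(exl[[ids[1]]]), mirror(exl[[ids[2]]]),
                       strand = flipped)
    ev_refl <- classify_pair(refl, "a", "b")
    expect_equal(sort(ev_refl$event_type), sort(ev$event_type))
    # strand relabel only: donor/acceptor roles reverse
    same <- two_tx_cat(exl[[ids[1]]], exl[[ids[2]]], strand = flipped)
    ev_rel <- classify_pair(same, "a", "b")
    expect_equal(sort(unname(swap53[ev_rel$event_type])),
                 sort(ev$event_type))
  }
})

test_that("enumeration deduplicates shared events and aggregates tx sets", {
  cat1 <- make_cat(list(
    list(id = "i1", gene = "g", exons = rbind(c(100, 200), c(300, 400), c(500, 600))),
    list(id = "x1", gene = "g", exons = rbind(c(100, 200), c(500, 600))),
    list(id = "x2", gene = "g", exons = rbind(c(100, 200), c(500, 650))),
    list(id = "r1", gene = "g", exons = rbind(c(100, 400), c(500, 600)))))
  ev <- enumerate_events(cat1)
  se <- ev[event_type == "SE"]
  expect_equal(nrow(se), 1L)                 # two pairs, one skipped exon
  expect_equal(se$inclusion_tx[[1]], "i1")
  expect_setequal(se$exclusion_tx[[1]], c("x1", "x2"))
  expect_true(all(lengths(ev$inclusion_tx) > 0 & lengths(ev$exclusion_tx) > 0))
  # multi-event gene: r1 retains i1's first intron and shifts a donor
  expect_setequal(unique(ev$event_type), c("SE", "RI", "A5SS"))
  expect_equal(ev[event_type == "RI", coords], "200-300")
})

test_that("inclusion levels are FPKM shares with NA on zero denominators", {
  cat1 <- make_cat(list(
    list(id = "i1", gene = "g", exons = rbind(c(100, 200), c(300, 400), c(500, 600))),
    list(id = "x1", gene = "g", exons = rbind(c(100, 200), c(500, 600)))))
  ev <- enumerate_events(cat1)
  q <- make_quant(list(i1 = c(8, 0), x1 = c(2, 0)), c("s1", "s2"))
  m <- event_inclusion(ev, q)
  expect_equal(unname(m[1, "s1"]), 0.8)
  expect_true(is.na(m[1, "s2"]))
})

test_that("event shift test matches exact enumeration and flags direction", {
  cat1 <- make_cat(list(
    list(id = "i1", gene = "g", exons = rbind(c(100, 200), c(300, 400), c(500, 600))),
    list(id = "x1", gene = "g", exons = rbind(c(100, 200), c(500, 600)))))
  ev <- enumerate_events(cat1)
  mk_q <- function(inc_levels) {
    n <- length(inc_levels)
    make_quant(list(i1 = 10 * inc_levels, x1 = 10 * (1 - inc_levels)),
               paste0("s", seq_len(n)))
  }
  # identical levels in both groups -> p = 1, none
  q0 <- mk_q(rep(0.5, 6))
  r0 <- event_shift_test(ev, q0, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(r0$p, 1)
  expect_equal(r0$direction, "none")
  # {0.9, 0.8, 0.85} vs {0.1, 0.2, 0.15}: exact two-sided p = 2/20
  q1 <- mk_q(c(0.9, 0.8, 0.85, 0.1, 0.2, 0.15))
  r1 <- event_shift_test(ev, q1, paste0("s", 1:3), paste0("s", 4:6), fdr = 0.2)
  expect_equal(r1$p, 0.1)
  expect_equal(r1$direction, "inclusion_down")
})

test_that("classifier agrees with the brute-force oracle on random pairs", {
  cfg <- sim_config(n_genes = 200, n_isoforms = 2)
  sc <- simulate_catalogue(cfg, seed = 47)
  tx <- sc$catalogue$transcripts
  for (g in unique(tx$gene_id)) {
    ids <- tx[gene_id == g, transcript_id]
    exl <- tx_exon_list(sc$catalogue, ids)
    got <- event_keys(classify_pair(sc$catalogue, ids[1], ids[2]))
    want <- oracle_events(exl[[1]], exl[[2]], tx[gene_id == g, strand][1])
    expect_equal(got, want, info = g)
  }
})
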