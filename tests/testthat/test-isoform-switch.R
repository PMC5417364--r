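# major-isoform calls, switch detection, proportions, overlap, clustering

simple_cat <- function() {
  make_cat(list(
    list(id = "A", gene = "g1", exons = rbind(c(100, 200), c(500, 600))),
    list(id = "B", gene = "g1", biotype = "retained_intron",
         exons = rbind(c(100, 600)))))
}

test_that("major-isoform calls use argmax, coding-first ties and the floor", {
  cat1 <- simple_cat()
  q <- make_quant(list(A = c(10, 2, 5, 0.2), B = c(2, 10, 5, 0.3)),
                  paste0("s", 1:4))
  calls <- call_major_isoforms(cat1, q)
  expect_equal(calls[sample == "s1", .(transcript_id, status)],
               data.table::data.table(transcript_id = "A", status = "coding"))
  expect_equal(calls[sample == "s2", status], "noncoding")
  expect_equal(calls[sample == "s3", transcript_id], "A")   # tie -> coding
  expect_equal(calls[sample == "s4", status], "not_expressed")
  expect_true(is.na(calls[sample == "s4", transcript_id]))
  expect_error(call_major_isoforms(cat1, q[1, , drop = FALSE]), "absent")
})

test_that("calls are per-sample independent and scale-invariant", {
  cfg <- sim_config(n_genes = 25)
  sc <- simulate_catalogue(cfg, seed = 61)
  co <- simulate_cohort(sc, cfg, seed = 62, n_normal = 4, n_tumour = 8)
  calls <- call_major_isoforms(sc$catalogue, co$quant)
  # permuting sample columns permutes calls identically
  perm <- rev(colnames(co$quant))
  calls_p <- call_major_isoforms(sc$catalogue, co$quant[, perm])
  expect_equal(data.table::setorder(data.table::copy(calls), gene_id, sample),
               data.table::setorder(data.table::copy(calls_p), gene_id, sample))
  # scaling one sample leaves its calls unchanged
  q2 <- co$quant; q2[, 3] <- q2[, 3] * 17
  calls_s <- call_major_isoforms(sc$catalogue, q2)
  s3 <- colnames(co$quant)[3]
  expect_equal(calls_s[sample == s3, status], calls[sample == s3, status])
})

test_that("timecourse switches report direction and driver biotype", {
  cat1 <- simple_cat()
  q <- make_quant(list(A = c(10, 9, 11, 3, 2, 2), B = c(2, 2, 3, 9, 10, 11)),
                  c(paste0("b", 1:3), paste0("t", 1:3)))
  sw <- timecourse_switches(cat1, q, paste0("b", 1:3), paste0("t", 1:3))
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$direction, "coding_to_noncoding")
  expect_equal(sw$driver_biotype, "retained_intron")
  # same major isoform in both conditions -> no record
  q2 <- make_quant(list(A = rep(10, 6), B = rep(2, 6)), colnames(q))
  expect_equal(nrow(timecourse_switches(cat1, q2, paste0("b", 1:3),
                                        paste0("t", 1:3))), 0L)
  expect_error(timecourse_switches(cat1, q, character(0), paste0("t", 1:3)),
               "at least one")
})

test_that("cohort switch fraction and threshold follow the 5% rule", {
  genes <- "g1"
  normal <- make_calls("g1", paste0("n", 1:5), rep("coding", 5))
  mk_tum <- function(n_dev) {
    st <- c(rep("noncoding", n_dev), rep("coding", 100 - n_dev))
    make_calls("g1", paste0("t", 1:100), st)
  }
  r6 <- cohort_switch_genes(rbind(normal, mk_tum(6)), paste0("n", 1:5),
                            paste0("t", 1:100))
  expect_equal(r6$switch_fraction, 0.06)
  expect_equal(r6$direction, "coding_to_noncoding")
  r4 <- cohort_switch_genes(rbind(normal, mk_tum(4)), paste0("n", 1:5),
                            paste0("t", 1:100))
  expect_equal(nrow(r4), 0L)
  # not_expressed samples leave the denominator
  tum <- rbind(mk_tum(5), make_calls("g1", paste0("x", 1:50),
                                     rep("not_expressed", 50)))
  r5 <- cohort_switch_genes(rbind(normal, tum), paste0("n", 1:5),
                            c(paste0("t", 1:100), paste0("x", 1:50)))
  expect_equal(r5$switch_fraction, 0.05)
  expect_equal(r5$n_expressed, 100L)
})

test_that("min_fraction edge cases: 0 reports any deviant, >1 reports none", {
  calls <- rbind(make_calls("g1", "n1", "coding"),
                 make_calls("g1", paste0("t", 1:100),
                            c("noncoding", rep("coding", 99))))
  r0 <- cohort_switch_genes(calls, "n1", paste0("t", 1:100), min_fraction = 0)
  expect_equal(r0$gene_id, "g1")
  r2 <- cohort_switch_genes(calls, "n1", paste0("t", 1:100), min_fraction = 1.5)
  expect_equal(nrow(r2), 0L)
  expect_error(cohort_switch_genes(calls, character(0), paste0("t", 1:100)),
               "no normal samples")
})

test_that("group class switches are modal and direction-specific", {
  calls <- rbind(
    make_calls("flip", paste0("a", 1:3), rep("coding", 3)),
    make_calls("flip", paste0("b", 1:3), c("noncoding", "noncoding", "coding")),
    make_calls("stay", paste0("a", 1:3), rep("coding", 3)),
    make_calls("stay", paste0("b", 1:3), rep("coding", 3)),
    make_calls("rev", paste0("a", 1:3), rep("noncoding", 3)),
    make_calls("rev", paste0("b", 1:3), rep("coding", 3)))
  expect_equal(group_class_switches(calls, paste0("a", 1:3), paste0("b", 1:3)),
               "flip")
})

test_that("injected class flips are recovered exactly without noise", {
  cfg <- sim_config(n_genes = 80, switch_gene_fraction = 0.25, dispersion = 0,
                    libsize_spread = 0, prevalence = 1)
  sc <- simulate_catalogue(cfg, seed = 63)
  co <- simulate_cohort(sc, cfg, seed = 64, n_normal = 10, n_tumour = 10)
  calls <- call_major_isoforms(sc$catalogue, co$quant)
  got <- group_class_switches(calls, co$meta[condition == "normal", sample],
                              co$meta[condition == "tumour", sample])
  want <- sc$truth$genes[is_switch_gene == TRUE, gene_id]
  expect_setequal(got, want)
})

test_that("noncoding proportion counts expressed genes only", {
  calls <- rbind(make_calls(sprintf("g%d", 1:10), "s1",
                            c(rep("noncoding", 3), rep("coding", 7))),
                 make_calls("g11", "s1", "not_expressed"))
  prof <- noncoding_proportion(calls)
  expect_equal(prof$proportion, 0.3)
  expect_equal(prof$n_expressed, 10L)
  expect_equal(prof$n_noncoding_major + (prof$n_expressed - 3L), 10L)
  allnot <- make_calls("g1", "s2", "not_expressed")
  expect_error(noncoding_proportion(allnot), "zero expressed")
})

test_that("switch-set overlap equals exact hypergeometric enumeration", {
  u <- sprintf("g%d", 1:10)
  r <- switch_set_overlap(u[1:5], u[1:5], u)
  expect_equal(r$p.value, 1 / 252, tolerance = 1e-12)
  r2 <- switch_set_overlap(u[1:5], u[3:7], u)
  expect_equal(r2$overlap, 3L)
  expect_equal(r2$p.value, 0.5, tolerance = 1e-12)
  # disjoint sets in a large universe: p near 1
  u2 <- sprintf("h%d", 1:200)
  r3 <- switch_set_overlap(u2[1:5], u2[100:104], u2)
  expect_gt(r3$p.value, 0.85)
  expect_error(switch_set_overlap("zz", u[1:2], u), "contained")
  # brute-force property over small universes
  set.seed(65)
  for (i in 1:20) {
    N <- sample(5:15, 1)
    uu <- sprintf("u%d", 1:N)
    a <- sample(uu, sample(1:N, 1)); b <- sample(uu, sample(1:N, 1))
    k <- length(intersect(a, b))
    expect_equal(switch_set_overlap(a, b, uu)$p.value,
                 oracle_hyper_tail(k, length(b), length(a), N),
                 tolerance = 1e-10)
  }
})

test_that("clustering metric behaves at its bounds and warns on constants", {
  m <- matrix(c("noncoding", "coding", "noncoding", "coding",
                "coding", "noncoding"), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  cl <- cluster_samples(m, k = 2)
  d <- as.matrix(cl$distance)
  expect_equal(d["s1", "s2"], 0)            # identical noncoding sets? no:
  # s1 = (1,0), s2 = (1,0) after binarisation -> distance 0
  expect_equal(d["s1", "s3"], 1)            # complementary sets
  expect_equal(cl$clusters[["s1"]], cl$clusters[["s2"]])
  const <- matrix("coding", 2, 3,
                  dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expect_warning(c2 <- cluster_samples(const), "one cluster")
  expect_equal(unname(c2$clusters), rep(1L, 3))
})

test_that("planted three-cluster cohorts are recovered exactly at k = 3", {
  cfg <- sim_config(n_genes = 60, switch_gene_fraction = 0.5, dispersion = 0,
                    libsize_spread = 0, n_clusters = 3)
  sc <- simulate_catalogue(cfg, seed = 66)
  co <- simulate_cohort(sc, cfg, seed = 67, n_normal = 0, n_tumour = 24)
  calls <- call_major_isoforms(sc$catalogue, co$quant)
  cl <- cluster_samples(calls, k = 3)
  planted <- co$meta$cluster
  names(planted) <- co$meta$sample
  got <- cl$clusters[names(planted)]
  # same partition up to label permutation
  co_mat <- outer(got, got, "==")
  pl_mat <- outer(planted, planted, "==")
  expect_true(all(co_mat == pl_mat))
})
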