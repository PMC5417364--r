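# Seeded synthetic-data generator with a ground-truth ledger. Emulates the
# two designs the pipeline targets: a hypoxia-style time course (replicate
# groups, an isoform-composition switch of expression from the coding
# major isoform toward a designated noncoding isoform at the late time
# point, elevated intron coverage for retained-intron switches) and a
# tumour/normal cohort (per-sample switching at a configured prevalence,
# optional group-level noncoding-proportion shift, optional planted
# cluster blocks). FPKM is simulated directly as expected abundance with
# negative-binomial multiplicative noise; all stochastic draws flow
# through one seed per call.

#' Simulation configuration
#'
#' Defaults encode the catalogue structure the generator emulates: a
#' geometric-like isoform-count distribution with median 5, a 44%
#' noncoding biotype fraction, exons of 80-500 bp in chains of 4-10,
#' introns of 200-5000 bp. Expression defaults: gene totals log-normal
#' around 50 FPKM, NB dispersion 0.1, a dominant coding isoform carrying
#' 60% of the gene's output and a designated (noncoding) switch target
#' carrying 25%, switch fold 4 with gene totals conserved.
#'
#' @param n_genes number of genes.
#' @param n_isoforms fixed isoform count per gene, or `NULL` to draw
#'   1 + Geometric(p = 0.13), capped at 12 (median 5).
#' @param noncoding_fraction realised catalogue-wide noncoding transcript
#'   fraction target (default 0.44).
#' @param switch_gene_fraction fraction of genes designated as switch
#'   genes (default 0.1).
#' @param switch_fold expression fold applied to the designated noncoding
#'   isoform in the test condition / flipped samples (default 4).
#' @param prevalence per-tumour-sample probability that a switch gene is
#'   flipped in the cohort design (default 0.2).
#' @param dispersion NB dispersion of the expression noise; 0 gives
#'   noise-free expectations (default 0.1).
#' @param libsize_spread sdlog of the per-sample library-size factor
#'   (default 0.1).
#' @param depth expected fragments per FPKM unit (default 50).
#' @param n_reps replicates per time-course condition (default 3).
#' @param major_weight,target_weight baseline expression shares of the
#'   coding major isoform and the designated noncoding isoform.
#' @param total_fpkm_meanlog,total_fpkm_sdlog log-normal gene totals.
#' @param background_flip_prob cohort-wide per-gene per-sample baseline
#'   probability of a noncoding-major flip (drives the per-sample
#'   noncoding proportion; default 0).
#' @param proportion_shift additive noncoding-proportion shift of cohort
#'   group B over group A (default 0).
#' @param n_clusters planted sample clusters in the cohort design (0 =
#'   none).
#' @param change_totals multiply switch-gene totals by this factor in the
#'   test condition (default 1 = totals conserved, the designed null).
#' @param ri_intron_fold coverage fold on the retained intron of RI switch
#'   genes in the test condition (default 4).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 100, n_isoforms = NULL,
                       noncoding_fraction = 0.44, switch_gene_fraction = 0.1,
                       switch_fold = 4, prevalence = 0.2, dispersion = 0.1,
                       libsize_spread = 0.1, depth = 50, n_reps = 3,
                       major_weight = 0.6, target_weight = 0.25,
                       total_fpkm_meanlog = log(50), total_fpkm_sdlog = 0.5,
                       background_flip_prob = 0, proportion_shift = 0,
                       n_clusters = 0, change_totals = 1, ri_intron_fold = 4) {
  cfg <- as.list(environment())
  stopifnot(cfg$noncoding_fraction >= 0, cfg$noncoding_fraction <= 1,
            cfg$switch_gene_fraction >= 0, cfg$switch_gene_fraction <= 1,
            cfg$switch_fold > 0, cfg$prevalence >= 0, cfg$prevalence <= 1,
            cfg$dispersion >= 0, cfg$major_weight + cfg$target_weight < 1 ||
              cfg$target_weight == 0)
  class(cfg) <- "sim_config"
  cfg
}

# NB multiplicative noise around expected FPKM: counts at `depth` fragments
# per FPKM unit, back-converted. dispersion = 0 returns the expectation.
#' @noRd
.nb_noise <- function(expected, dispersion, depth = 50, libfactor = 1) {
  if (dispersion == 0) return(expected)
  mu <- expected * depth * libfactor
  counts <- rnbinom(length(mu), size = 1 / dispersion, mu = mu)
  counts / (depth * libfactor)
}

#' Simulate a transcript catalogue with ground truth
#'
#' Builds genes as base protein-coding exon chains and derives isoforms by
#' applying SE / RI / A5SS / A3SS edits to the base transcript, so every
#' generated event is classifiable and recorded in the truth ledger.
#' Biotypes are assigned to realise the configured noncoding fraction
#' exactly (up to rounding and eligibility): RI isoforms are always
#' `retained_intron`; further noncoding labels (`processed_transcript`,
#' `nmd`, `other_noncoding`) are spread over the remaining non-base
#' isoforms. A deterministic subset of genes with a noncoding isoform is
#' designated as switch genes (preferring RI targets, mirroring
#' retention-driven switching).
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (mandatory).
#' @return list with `catalogue` (a [gene_catalogue], origin
#'   `"reference"`) and `truth` (`transcripts` ledger with per-isoform
#'   `edit`, `edit_coords`, `role`; `genes` ledger with `is_switch_gene`,
#'   `driver_biotype`, `target_tx`, retained-intron coordinates).
#' @export
simulate_catalogue <- function(cfg = sim_config(), seed) {
  stopifnot(inherits(cfg, "sim_config"), !missing(seed))
  with_seed_if(seed, {
    txs <- list(); exs <- list(); ledger <- list()
    cursor <- 0L
    for (g in seq_len(cfg$n_genes)) {
      gid <- sprintf("G%04d", g)
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(4:10, 1L)
      ex_len <- sample(80:500, n_ex, replace = TRUE)
      in_len <- sample(200:5000, n_ex - 1L, replace = TRUE)
      starts <- cursor + cumsum(c(0L, ex_len[-n_ex] + in_len))
      base <- cbind(start = starts, end = starts + ex_len)
      cursor <- max(base[, "end"]) + 10000L
      K <- if (is.null(cfg$n_isoforms)) min(12L, 1L + rgeom(1L, 0.13))
           else cfg$n_isoforms
      iso <- list(list(ex = base, edit = "none", coords = NA_character_))
      seen <- paste(base[, 1L], base[, 2L], collapse = ";")
      tries <- 0L
      while (length(iso) < K && tries < 50L) {
        tries <- tries + 1L
        type <- sample(c("SE", "RI", "A5SS", "A3SS"), 1L)
        ed <- .apply_edit(base, type, strand)
        if (is.null(ed)) next
        key <- paste(ed$ex[, 1L], ed$ex[, 2L], collapse = ";")
        if (key %in% seen) next
        seen <- c(seen, key)
        iso[[length(iso) + 1L]] <- ed
      }
      for (i in seq_along(iso)) {
        tid <- sprintf("%s.T%02d", gid, i)
        txs[[length(txs) + 1L]] <- data.table(
          transcript_id = tid, gene_id = gid, chrom = "chr1", strand = strand,
          biotype = "protein_coding", origin = "reference")
        exs[[length(exs) + 1L]] <- data.table(
          transcript_id = tid, start = iso[[i]]$ex[, "start"],
          end = iso[[i]]$ex[, "end"])
        ledger[[length(ledger) + 1L]] <- data.table(
          gene_id = gid, transcript_id = tid, edit = iso[[i]]$edit,
          edit_coords = iso[[i]]$coords,
          role = if (i == 1L) "base" else "alt")
      }
    }
    tx <- rbindlist(txs); led <- rbindlist(ledger)
    # biotypes: RI isoforms always retained_intron, then top up to the
    # configured noncoding fraction among remaining alt isoforms
    ri_ids <- led[edit == "RI", transcript_id]
    tx[transcript_id %chin% ri_ids, biotype := "retained_intron"]
    target_nc <- round(cfg$noncoding_fraction * nrow(tx))
    eligible <- led[role == "alt" & edit != "RI", transcript_id]
    need <- max(0L, target_nc - length(ri_ids))
    extra <- if (need > 0L && length(eligible))
      sample(eligible, min(need, length(eligible))) else character()
    if (length(extra)) {
      lab <- sample(c("processed_transcript", "nmd", "other_noncoding"),
                    length(extra), replace = TRUE, prob = c(0.5, 0.25, 0.25))
      tx[match(extra, transcript_id), biotype := lab]
    }
    led[, biotype := tx$biotype[match(transcript_id, tx$transcript_id)]]
    # switch-gene designation: genes with a noncoding isoform, RI preferred
    nc <- led[role == "alt" &
                biotype %chin% c("retained_intron", "processed_transcript",
                                 "nmd", "other_noncoding")]
    nc[, non_ri := biotype != "retained_intron"]
    setorder(nc, gene_id, non_ri, transcript_id)
    cand <- nc[!duplicated(gene_id)]
    n_switch <- round(cfg$switch_gene_fraction * cfg$n_genes)
    sw_genes <- if (n_switch > 0L && nrow(cand))
      sort(sample(cand$gene_id, min(n_switch, nrow(cand)))) else character()
    genes <- data.table(gene_id = sprintf("G%04d", seq_len(cfg$n_genes)))
    genes[, is_switch_gene := gene_id %chin% sw_genes]
    genes[, target_tx := cand$transcript_id[match(gene_id, cand$gene_id)]]
    genes[, driver_biotype := cand$biotype[match(gene_id, cand$gene_id)]]
    genes[is_switch_gene == FALSE, driver_biotype := NA_character_]
    # retained-intron coordinates for RI targets (for coverage injection)
    ri_led <- led[match(genes$target_tx, transcript_id)]
    genes[, ri_coords := ifelse(!is.na(target_tx) & ri_led$edit == "RI",
                                ri_led$edit_coords, NA_character_)]
    catalogue <- gene_catalogue(tx, rbindlist(exs))
    list(catalogue = catalogue,
         truth = list(transcripts = led[], genes = genes[]))
  })
}

# One structural edit of a base exon chain. Returns NULL when inapplicable.
#' @noRd
.apply_edit <- function(base, type, strand) {
  n <- nrow(base)
  if (type == "SE") {
    if (n < 3L) return(NULL)
    i <- sample(2:(n - 1L), 1L)
    list(ex = base[-i, , drop = FALSE], edit = "SE",
         coords = sprintf("%d-%d", base[i, "start"], base[i, "end"]))
  } else if (type == "RI") {
    if (n < 2L) return(NULL)
    i <- sample(seq_len(n - 1L), 1L)
    ex <- base
    ex[i, "end"] <- ex[i + 1L, "end"]
    list(ex = ex[-(i + 1L), , drop = FALSE], edit = "RI",
         coords = sprintf("%d-%d", base[i, "end"], base[i + 1L, "start"]))
  } else if (type == "A5SS" || type == "A3SS") {
    if (n < 2L) return(NULL)
    # A5SS moves a donor (transcript 5' splice site), A3SS an acceptor;
    # map to the genomic side through the strand
    genomic_left <- (type == "A5SS") == (strand == "+")
    i <- sample(seq_len(n - 1L), 1L)
    delta <- sample(20:60, 1L)
    ex <- base
    if (genomic_left) {
      ex[i, "end"] <- ex[i, "end"] - delta
      coords <- sprintf("%d-%d", ex[i, "end"], base[i, "end"])
    } else {
      ex[i + 1L, "start"] <- ex[i + 1L, "start"] + delta
      coords <- sprintf("%d-%d", base[i + 1L, "start"], ex[i + 1L, "start"])
    }
    list(ex = ex, edit = type, coords = coords)
  } else NULL
}

#' @noRd
.baseline_weights <- function(cat, genes_truth, cfg) {
  tx <- copy(cat$transcripts)
  tx[, role := "other"]
  tx[tx[, .I[1L], by = gene_id]$V1, role := "base"]
  tx[transcript_id %chin% stats::na.omit(genes_truth$target_tx), role := "target"]
  tx[, w := NA_real_]
  tx[, n_iso := .N, by = gene_id]
  tx[, has_target := any(role == "target"), by = gene_id]
  tx[role == "base" & has_target == TRUE, w := cfg$major_weight]
  tx[role == "target", w := cfg$target_weight]
  tx[role == "other" & has_target == TRUE,
     w := (1 - cfg$major_weight - cfg$target_weight) / pmax(1L, n_iso - 2L)]
  # genes without a designated target: base dominates, rest share
  tx[has_target == FALSE & role == "base", w := cfg$major_weight]
  tx[has_target == FALSE & role != "base",
     w := (1 - cfg$major_weight) / pmax(1L, n_iso - 1L)]
  tx[n_iso == 1L, w := 1]
  tx[, w := w / sum(w), by = gene_id]
  tx
}

#' Simulate a time-course experiment over a catalogue
#'
#' Two conditions (`t0`, `t24`) with `cfg$n_reps` replicates each. Switch
#' genes have the designated noncoding isoform's expected share multiplied
#' by `cfg$switch_fold` at `t24` with the gene total held constant (an
#' isoform-composition switch; set `cfg$change_totals != 1` for the
#' positive control that also changes totals). NB noise at
#' `cfg$dispersion`; per-intron coverage with the retained intron of RI
#' switch genes elevated `cfg$ri_intron_fold`-fold at `t24`; junction read
#' support drawn consistent with isoform abundance.
#'
#' @param sim output of [simulate_catalogue()].
#' @param cfg the [sim_config()] used for the catalogue.
#' @param seed integer seed.
#' @return list with `quant` (FPKM matrix), `meta` (`sample`,
#'   `condition`), `coverage`, `support`, `truth` (the catalogue truth
#'   plus per-sample expectations).
#' @export
simulate_timecourse <- function(sim, cfg = sim_config(), seed) {
  stopifnot(!missing(seed))
  cat <- sim$catalogue; genes <- sim$truth$genes
  with_seed_if(seed, {
    samples <- c(sprintf("t0_r%d", seq_len(cfg$n_reps)),
                 sprintf("t24_r%d", seq_len(cfg$n_reps)))
    cond <- rep(c("t0", "t24"), each = cfg$n_reps)
    tx <- .baseline_weights(cat, genes, cfg)
    totals <- setNames(rlnorm(nrow(genes), cfg$total_fpkm_meanlog,
                              cfg$total_fpkm_sdlog), genes$gene_id)
    lib <- rlnorm(length(samples), 0, cfg$libsize_spread)
    W0 <- tx$w
    W1 <- tx$w
    sw <- tx$gene_id %chin% genes[is_switch_gene == TRUE, gene_id]
    W1[sw & tx$role == "target"] <- W1[sw & tx$role == "target"] * cfg$switch_fold
    # renormalise switch genes so totals are conserved
    dt <- data.table(gene_id = tx$gene_id, w1 = W1)
    dt[, w1 := w1 / sum(w1), by = gene_id]
    W1 <- dt$w1
    tot1 <- totals
    tot1[genes[is_switch_gene == TRUE, gene_id]] <-
      tot1[genes[is_switch_gene == TRUE, gene_id]] * cfg$change_totals
    expected <- vapply(seq_along(samples), function(s) {
      if (cond[s] == "t0") totals[tx$gene_id] * W0 else tot1[tx$gene_id] * W1
    }, numeric(nrow(tx)))
    quant <- vapply(seq_along(samples), function(s)
      .nb_noise(expected[, s], cfg$dispersion, cfg$depth, lib[s]),
      numeric(nrow(tx)))
    dimnames(quant) <- list(tx$transcript_id, samples)
    meta <- data.table(sample = samples, condition = cond)
    coverage <- .simulate_coverage(cat, genes, samples, cond, cfg)
    support <- .simulate_support(cat, quant)
    list(quant = quant, meta = meta, coverage = coverage, support = support,
         truth = c(sim$truth, list(expected_t0 = W0, expected_t24 = W1,
                                   totals = totals)))
  })
}

#' @noRd
.simulate_coverage <- function(cat, genes, samples, cond, cfg,
                               base_density = 2) {
  intr <- rbindlist(lapply(genes$gene_id, function(g) gene_introns(cat, g)))
  if (!nrow(intr)) return(data.table())
  ri <- genes[!is.na(ri_coords) & is_switch_gene == TRUE]
  intr[, injected := FALSE]
  if (nrow(ri)) {
    key_g <- paste(intr$gene_id, sprintf("%d-%d", intr$start, intr$end))
    intr[key_g %chin% paste(ri$gene_id, ri$ri_coords), injected := TRUE]
  }
  len_kb <- (intr$end - intr$start) / 1000
  counts <- vapply(seq_along(samples), function(s) {
    lambda <- base_density * len_kb *
      ifelse(intr$injected & cond[s] == "t24", cfg$ri_intron_fold, 1)
    stats::rpois(nrow(intr), lambda)
  }, numeric(nrow(intr)))
  out <- data.table(gene_id = intr$gene_id, chrom = intr$chrom,
                    start = intr$start, end = intr$end)
  out[, (samples) := as.data.table(counts)]
  out
}

#' @noRd
.simulate_support <- function(cat, quant, reads_per_fpkm = 5) {
  tj <- transcript_junctions(cat)
  if (!nrow(tj)) return(data.table())
  abund <- rowsum(quant[tj$transcript_id, , drop = FALSE],
                  .junction_key(tj$chrom, tj$strand, tj$donor, tj$acceptor))
  key <- rownames(abund)
  j <- unique(tj[, .(chrom, strand, donor, acceptor)])
  jkey <- .junction_key(j$chrom, j$strand, j$donor, j$acceptor)
  counts <- matrix(stats::rpois(length(abund), abund * reads_per_fpkm),
                   nrow = nrow(abund), dimnames = dimnames(abund))
  out <- j[match(key, jkey)]
  out[, colnames(quant) := as.data.table(counts)]
  out
}

#' Simulate a tumour/normal cohort over a catalogue
#'
#' Normal samples are drawn at baseline composition. In each tumour
#' sample, every switch gene independently flips to its designated
#' noncoding major isoform with probability `cfg$prevalence` (the
#' coding-major and target weights are swapped, conserving the total).
#' Optionally every gene with a noncoding isoform also flips at a
#' background rate calibrated so the expected per-sample noncoding-major
#' proportion equals `cfg$background_flip_prob`, with
#' `cfg$proportion_shift` added for tumour group B; optionally samples are
#' partitioned into `cfg$n_clusters` planted clusters, each flipping its
#' own block of switch genes deterministically.
#'
#' @param sim output of [simulate_catalogue()].
#' @param cfg the [sim_config()].
#' @param seed integer seed.
#' @param n_normal,n_tumour cohort sizes (defaults 20 / 100).
#' @return list with `quant`, `meta` (`sample`, `condition` =
#'   normal/tumour, `group` = A/B for tumour samples, `cluster` planted
#'   id or `NA`), `truth` (catalogue truth plus the realised flip ledger).
#' @export
simulate_cohort <- function(sim, cfg = sim_config(), seed,
                            n_normal = 20, n_tumour = 100) {
  stopifnot(!missing(seed))
  cat <- sim$catalogue; genes <- sim$truth$genes
  with_seed_if(seed, {
    samples <- c(sprintf("N%03d", seq_len(n_normal)),
                 sprintf("T%03d", seq_len(n_tumour)))
    is_tum <- c(rep(FALSE, n_normal), rep(TRUE, n_tumour))
    group <- rep(NA_character_, length(samples))
    group[is_tum] <- rep(c("A", "B"), length.out = n_tumour)
    tx <- .baseline_weights(cat, genes, cfg)
    totals <- setNames(rlnorm(nrow(genes), cfg$total_fpkm_meanlog,
                              cfg$total_fpkm_sdlog), genes$gene_id)
    lib <- rlnorm(length(samples), 0, cfg$libsize_spread)
    eligible <- genes[!is.na(target_tx), gene_id]
    sw_genes <- genes[is_switch_gene == TRUE, gene_id]
    G <- nrow(genes)
    p_bg <- if (cfg$background_flip_prob > 0 && length(eligible))
      min(1, cfg$background_flip_prob * G / length(eligible)) else 0
    p_shift <- if (cfg$proportion_shift > 0 && length(eligible))
      min(1, cfg$proportion_shift * G / length(eligible)) else 0
    cluster <- rep(NA_integer_, length(samples))
    block <- NULL
    if (cfg$n_clusters > 0) {
      cluster[is_tum] <- rep(seq_len(cfg$n_clusters),
                             length.out = sum(is_tum))
      block <- split(sw_genes,
                     rep(seq_len(cfg$n_clusters), length.out = length(sw_genes)))
    }
    flips <- matrix(FALSE, length(eligible), length(samples),
                    dimnames = list(eligible, samples))
    for (s in seq_along(samples)) {
      if (is_tum[s]) {
        flips[, s] <- runif(length(eligible)) < p_bg +
          (group[s] == "B") * p_shift
        if (cfg$n_clusters > 0) {
          flips[eligible %chin% block[[cluster[s]]], s] <- TRUE
        } else {
          hit <- eligible %chin% sw_genes & (runif(length(eligible)) < cfg$prevalence)
          flips[hit, s] <- TRUE
        }
      } else if (p_bg > 0) {
        flips[, s] <- runif(length(eligible)) < p_bg
      }
    }
    W <- matrix(tx$w, nrow(tx), length(samples),
                dimnames = list(tx$transcript_id, samples))
    base_row <- tx$role == "base"
    targ_row <- tx$role == "target"
    for (s in seq_along(samples)) {
      fg <- eligible[flips[, s]]
      if (!length(fg)) next
      bi <- which(base_row & tx$gene_id %chin% fg)
      ti <- which(targ_row & tx$gene_id %chin% fg)
      tmp <- W[bi, s]
      W[bi, s] <- W[ti, s][match(tx$gene_id[bi], tx$gene_id[ti])]
      W[ti, s] <- tmp[match(tx$gene_id[ti], tx$gene_id[bi])]
    }
    expected <- totals[tx$gene_id] * W
    quant <- vapply(seq_along(samples), function(s)
      .nb_noise(expected[, s], cfg$dispersion, cfg$depth, lib[s]),
      numeric(nrow(tx)))
    dimnames(quant) <- list(tx$transcript_id, samples)
    meta <- data.table(sample = samples,
                       condition = ifelse(is_tum, "tumour", "normal"),
                       group = group, cluster = cluster)
    list(quant = quant, meta = meta,
         truth = c(sim$truth, list(flips = flips, cluster = cluster,
                                   totals = totals)))
  })
}

#' Write a simulated data set to disk
#'
#' Emits exactly the dialects the readers consume: `catalogue.gtf`,
#' `fpkm.tsv`, `meta.tsv`, plus `support.tsv` / `coverage.tsv` when
#' present, and the truth ledger as `truth.json`.
#'
#' @param sim list from [simulate_timecourse()] or [simulate_cohort()].
#' @param cat the [gene_catalogue] the simulation ran on.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, cat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(cat, file.path(dir, "catalogue.gtf"))
  write_fpkm(sim$quant, file.path(dir, "fpkm.tsv"))
  fwrite(sim$meta, file.path(dir, "meta.tsv"), sep = "\t")
  if (!is.null(sim$support) && nrow(sim$support))
    write_junction_support(sim$support, file.path(dir, "support.tsv"))
  if (!is.null(sim$coverage) && nrow(sim$coverage))
    write_coverage(sim$coverage, file.path(dir, "coverage.tsv"))
  truth <- sim$truth
  truth$flips <- NULL   # matrix ledger stays in memory; JSON keeps gene flags
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null", digits = NA)
  invisible(dir)
}

#' Perturb reference junctions with known class rates
#'
#' Draws query junctions from the catalogue's index and shifts one end
#' (rate `one_end`) or both ends (rate `both_end`) by a small offset,
#' recording the intended [classify_junction()] class of every query in
#' the truth ledger.
#'
#' @param cat a [gene_catalogue].
#' @param seed integer seed.
#' @param one_end,both_end perturbation rates (defaults 0.10 / 0.02).
#' @return `data.table` of query junctions with a `true_class` column.
#' @export
simulate_junction_queries <- function(cat, seed, one_end = 0.10,
                                      both_end = 0.02) {
  j <- copy(cat$junctions)
  with_seed_if(seed, {
    u <- runif(nrow(j))
    cls <- ifelse(u < both_end, "novel",
                  ifelse(u < both_end + one_end, "partial", "complete"))
    off <- function(n) sample(c(-13L, -7L, 7L, 13L), n, replace = TRUE)
    ip <- which(cls == "partial")
    side <- runif(length(ip)) < 0.5
    j[ip[side], donor := donor + off(sum(side))]
    j[ip[!side], acceptor := acceptor + off(sum(!side))]
    inv <- which(cls == "novel")
    j[inv, `:=`(donor = donor + off(length(inv)),
                acceptor = acceptor + off(length(inv)))]
    j[, true_class := cls]
    j[, origin := NULL]
    j[]
  })
}
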