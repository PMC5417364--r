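# End-to-end orchestration: simulate or ingest, build the filtered
# catalogue, enumerate events, call switches, quantify introns, run
# enrichment and QC, and leave a manifest that makes re-runs auditable and
# reproducible.

#' Default pipeline configuration
#'
#' All thresholds of the analysis in one place: junction support (>= 2
#' reads in >= 2 samples), expression (FPKM > 0.5 in >= 3 samples), cohort
#' switch fraction (5%), event FDR (1%), enrichment q (1%), differential
#' expression fold (2). Stages can be toggled off individually.
#'
#' @param seed integer seed for the simulation stage.
#' @param ... overrides for any default field.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    design = "timecourse",
    min_junc_reads = 2, min_junc_samples = 2,
    min_fpkm = 0.5, min_fpkm_samples = 3,
    expression_floor = 1,
    switch_min_fraction = 0.05,
    event_fdr = 0.01, enrichment_q = 0.01, de_fold = 2.0,
    pseudocount = 0.1,
    cluster_k = 3,
    stages = c("catalogue", "events", "switches", "introns", "qc"),
    sim = list(n_genes = 60))
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$min_fpkm > 0, cfg$de_fold > 0, cfg$event_fdr > 0)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with any subset of [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Fold-change + rank-test differential expression filter
#'
#' Flags genes whose absolute log2 fold-change of mean total expression
#' exceeds `log2(fold)` and whose rank-sum BH q-value is below `q_max`.
#' A deliberately simple surrogate for count-model differential
#' expression testing; the fold criterion is the primary filter.
#'
#' @param totals gene x sample matrix of gene-level totals.
#' @param baseline_samples,test_samples sample columns per condition.
#' @param fold fold-change threshold (default 2).
#' @param q_max BH threshold (default 0.01).
#' @param eps pseudocount (default 0.1).
#' @return `data.table` with `gene_id`, `log2fc`, `p`, `q`, `flagged`.
#' @export
de_fold_filter <- function(totals, baseline_samples, test_samples,
                           fold = 2.0, q_max = 0.01, eps = 0.1) {
  ma <- rowMeans(totals[, baseline_samples, drop = FALSE])
  mb <- rowMeans(totals[, test_samples, drop = FALSE])
  lfc <- log2((mb + eps) / (ma + eps))
  p <- vapply(seq_len(nrow(totals)), function(i)
    rank_sum_test(totals[i, baseline_samples], totals[i, test_samples])$p.value,
    numeric(1))
  res <- data.table(gene_id = rownames(totals), log2fc = lfc, p = p,
                    q = bh_adjust(p))
  res[, flagged := abs(log2fc) > log2(fold) & q < q_max]
  res[]
}

#' Run the pipeline end to end
#'
#' Simulates a data set (deterministically from `config$seed`), builds and
#' filters the catalogue, and executes the enabled stages in dependency
#' order, writing one TSV per stage plus a `manifest.json` recording the
#' configuration, stage record counts and output file hashes. Re-running
#' with an identical configuration reproduces byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- do.call(sim_config, config$sim)
  simc <- simulate_catalogue(scfg, seed = config$seed)
  sim <- if (config$design == "cohort")
    simulate_cohort(simc, scfg, seed = config$seed + 1L)
  else simulate_timecourse(simc, scfg, seed = config$seed + 1L)
  write_simulation(sim, simc$catalogue, file.path(out_dir, "sim"))
  manifest <- list(config = unclass(config), stages = list())
  # record counts only: timings would break byte-identical re-runs
  log_stage <- function(name, n) {
    manifest$stages[[name]] <<- list(records = n)
  }

  cat0 <- simc$catalogue
  if ("catalogue" %in% config$stages) {
    if (!is.null(sim$support) && nrow(sim$support))
      cat0 <- filter_junction_support(cat0, sim$support,
                                      config$min_junc_reads,
                                      config$min_junc_samples)
    cat0 <- filter_expression(cat0, sim$quant, config$min_fpkm,
                              config$min_fpkm_samples)
    write_gtf(cat0, file.path(out_dir, "catalogue.gtf"))
    log_stage("catalogue", nrow(cat0$transcripts))
  }
  quant <- sim$quant[rownames(sim$quant) %in% cat0$transcripts$transcript_id, ,
                     drop = FALSE]

  if ("events" %in% config$stages) {
    ev <- enumerate_events(cat0)
    if (nrow(ev) && config$design == "timecourse") {
      grp <- split(sim$meta$sample, sim$meta$condition)
      ev <- event_shift_test(ev, quant, grp[[1L]], grp[[2L]],
                             fdr = config$event_fdr)
    }
    write_events(ev, file.path(out_dir, "events.tsv"))
    log_stage("events", nrow(ev))
  }

  calls <- call_major_isoforms(cat0, quant, floor = config$expression_floor)
  sw <- NULL
  if ("switches" %in% config$stages) {
    fwrite(calls, file.path(out_dir, "calls.tsv"), sep = "\t")
    if (config$design == "cohort") {
      nm <- sim$meta[condition == "normal", sample]
      tm <- sim$meta[condition == "tumour", sample]
      sw <- cohort_switch_genes(calls, nm, tm,
                                min_fraction = config$switch_min_fraction,
                                cat = cat0)
      prof <- noncoding_proportion(calls)
      fwrite(prof, file.path(out_dir, "noncoding_proportion.tsv"), sep = "\t")
      cl <- cluster_samples(calls[sample %chin% tm], k = config$cluster_k)
      fwrite(data.table(sample = names(cl$clusters), cluster = cl$clusters),
             file.path(out_dir, "clusters.tsv"), sep = "\t")
    } else {
      grp <- split(sim$meta$sample, sim$meta$condition)
      sw <- timecourse_switches(cat0, quant, grp[[1L]], grp[[2L]],
                                floor = config$expression_floor)
    }
    fwrite(sw, file.path(out_dir, "switches.tsv"), sep = "\t")
    log_stage("switches", nrow(sw))
  }

  if ("introns" %in% config$stages && config$design == "timecourse" &&
      !is.null(sim$coverage) && nrow(sim$coverage)) {
    grp <- split(sim$meta$sample, sim$meta$condition)
    fc <- rbindlist(lapply(unique(cat0$transcripts$gene_id), function(g)
      intron_log2fc(cat0, sim$coverage, g, grp[[1L]], grp[[2L]],
                    eps = config$pseudocount)))
    fwrite(fc, file.path(out_dir, "intron_log2fc.tsv"), sep = "\t")
    log_stage("introns", nrow(fc))
  }

  if ("qc" %in% config$stages) {
    tj <- cat0$junctions
    qc <- data.table(n_transcripts = nrow(cat0$transcripts),
                     n_genes = uniqueN(cat0$transcripts$gene_id),
                     n_junctions = nrow(tj))
    fwrite(qc, file.path(out_dir, "qc.tsv"), sep = "\t")
    log_stage("qc", nrow(qc))
  }

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE,
                                   full.names = TRUE),
                        file.path(out_dir, "manifest.json")))
  manifest$files <- data.frame(
    path = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)), row.names = NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
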