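# Per-sample major-isoform assignment and coding->noncoding switch
# detection. Major isoforms are called independently in every sample (the
# per-sample independence is itself a batch-effect mitigation), reduced to
# a coding/noncoding status, and compared across time-course conditions or
# tumour/normal cohorts.

#' Call the major isoform of every gene in every sample
#'
#' The major isoform is the highest-FPKM transcript of the gene in that
#' sample; ties are broken in favour of coding transcripts, then by
#' lexicographic transcript id (conservative for the coding->noncoding
#' statistic). Genes whose total FPKM falls below `floor` are
#' `not_expressed` in that sample.
#'
#' @param cat a [gene_catalogue] with assigned biotypes.
#' @param quant FPKM matrix (transcripts x samples).
#' @param samples samples to call (default all columns).
#' @param floor minimum per-sample gene total FPKM to count as expressed
#'   (default 1).
#' @return `data.table` with columns `gene_id`, `sample`, `transcript_id`
#'   (`NA` when not expressed), `status` in
#'   `{coding, noncoding, not_expressed}`.
#' @export
call_major_isoforms <- function(cat, quant, samples = colnames(quant), floor = 1) {
  assert_matrix_samples(quant, samples, "quantification")
  tx <- cat$transcripts
  missing <- setdiff(tx$transcript_id, rownames(quant))
  if (length(missing))
    stop_is("%d catalogue transcript(s) absent from quantification (e.g. %s)",
            length(missing), missing[1L])
  q <- quant[tx$transcript_id, samples, drop = FALSE]
  long <- data.table(
    transcript_id = rep(tx$transcript_id, times = length(samples)),
    gene_id = rep(tx$gene_id, times = length(samples)),
    coding = rep(tx$biotype == "protein_coding", times = length(samples)),
    sample = rep(samples, each = nrow(tx)),
    fpkm = as.vector(q))
  setorder(long, gene_id, sample, -fpkm, -coding, transcript_id)
  calls <- long[, .(transcript_id = transcript_id[1L],
                    coding = coding[1L], total = sum(fpkm)),
                by = .(gene_id, sample)]
  calls[, status := ifelse(total < floor, "not_expressed",
                           ifelse(coding, "coding", "noncoding"))]
  calls[status == "not_expressed", transcript_id := NA_character_]
  calls[, .(gene_id, sample, transcript_id, status)]
}

#' @noRd
.status_of_tx <- function(cat, ids) {
  coding_status(cat$transcripts$biotype[match(ids, cat$transcripts$transcript_id)])
}

#' Detect major-isoform switches across a time course
#'
#' The condition-level major isoform of a gene is the argmax transcript on
#' mean FPKM within the condition's replicates (same tie rule as
#' [call_major_isoforms()]). A switch record is emitted whenever the
#' condition-level transcript differs between baseline and test;
#' `direction` reduces the change to coding/noncoding classes and
#' `driver_biotype` is the biotype of the gained major isoform (so
#' RI-driven switches are distinguishable).
#'
#' @param cat a [gene_catalogue].
#' @param quant FPKM matrix.
#' @param baseline_samples,test_samples replicate sample ids per condition.
#' @param floor expression floor on the condition-mean gene total; genes
#'   below it in either condition are skipped (default 1).
#' @return `data.table` with `gene_id`, `design = "timecourse"`,
#'   `direction` in `{coding_to_noncoding, noncoding_to_coding,
#'   within_class}`, `switch_fraction = 1`, `driver_biotype`,
#'   `baseline_tx`, `test_tx`.
#' @export
timecourse_switches <- function(cat, quant, baseline_samples, test_samples,
                                floor = 1) {
  if (!length(baseline_samples) || !length(test_samples))
    stop_is("each condition needs at least one sample")
  assert_matrix_samples(quant, c(baseline_samples, test_samples))
  cond_major <- function(smps) {
    m <- rowMeans(quant[cat$transcripts$transcript_id, smps, drop = FALSE])
    d <- data.table(transcript_id = cat$transcripts$transcript_id,
                    gene_id = cat$transcripts$gene_id,
                    coding = cat$transcripts$biotype == "protein_coding",
                    fpkm = m)
    setorder(d, gene_id, -fpkm, -coding, transcript_id)
    d[, .(transcript_id = transcript_id[1L], total = sum(fpkm)), by = gene_id]
  }
  b <- cond_major(baseline_samples)
  t <- cond_major(test_samples)
  m <- merge(b, t, by = "gene_id", suffixes = c("_b", "_t"))
  m <- m[total_b >= floor & total_t >= floor & transcript_id_b != transcript_id_t]
  if (!nrow(m)) {
    return(data.table(gene_id = character(), design = character(),
                      direction = character(), switch_fraction = numeric(),
                      driver_biotype = character(), baseline_tx = character(),
                      test_tx = character()))
  }
  sb <- .status_of_tx(cat, m$transcript_id_b)
  st <- .status_of_tx(cat, m$transcript_id_t)
  m[, direction := fifelse(sb == "coding" & st == "noncoding", "coding_to_noncoding",
                    fifelse(sb == "noncoding" & st == "coding", "noncoding_to_coding",
                            "within_class"))]
  m[, driver_biotype := cat$transcripts$biotype[
      match(transcript_id_t, cat$transcripts$transcript_id)]]
  m[, .(gene_id, design = "timecourse", direction, switch_fraction = 1,
        driver_biotype, baseline_tx = transcript_id_b, test_tx = transcript_id_t)]
}

#' @noRd
.modal_status <- function(status) {
  s <- status[status != "not_expressed"]
  if (!length(s)) return(NA_character_)
  tab <- sort(table(s), decreasing = TRUE)
  # tie -> coding (conservative for the switch statistic)
  if (length(tab) > 1L && tab[1L] == tab[2L]) "coding" else names(tab)[1L]
}

#' Cohort-mode switch genes
#'
#' Each gene's baseline class is its modal coding/noncoding status among
#' normal samples (falling back to the reference annotation's class of the
#' longest protein-coding transcript when no normal sample expresses the
#' gene). The switch fraction is the fraction of tumour samples whose
#' status deviates from that baseline, with `not_expressed` samples
#' excluded from the denominator; genes at or above `min_fraction` are
#' reported.
#'
#' @param calls output of [call_major_isoforms()].
#' @param normal_samples,tumour_samples sample id vectors.
#' @param min_fraction reporting threshold on the switch fraction
#'   (default 0.05).
#' @param cat optional [gene_catalogue] for the reference fallback.
#' @return `data.table` with `gene_id`, `design = "cohort"`, `direction`,
#'   `switch_fraction`, `driver_biotype` (modal biotype of the gained
#'   major isoform among deviant samples, when `cat` is given),
#'   `baseline_class`, `n_deviant`, `n_expressed`.
#' @export
cohort_switch_genes <- function(calls, normal_samples, tumour_samples,
                                min_fraction = 0.05, cat = NULL) {
  calls <- as.data.table(calls)
  if (!length(normal_samples) && is.null(cat))
    stop_is("no normal samples and no reference catalogue fallback")
  base <- calls[sample %chin% normal_samples,
                .(baseline = .modal_status(status)), by = gene_id]
  if (is.null(cat)) {
    base <- base[!is.na(baseline)]
  } else {
    ref_fallback <- function(gids) {
      # class of the longest protein-coding transcript, else noncoding
      tx <- cat$transcripts[gene_id %chin% gids]
      len <- cat$exons[, .(len = sum(end - start)), by = transcript_id]
      tx <- merge(tx, len, by = "transcript_id")
      setorder(tx, gene_id, -len)
      fb <- tx[, .(baseline = if (any(biotype == "protein_coding"))
        "coding" else "noncoding"), by = gene_id]
      fb$baseline[match(gids, fb$gene_id)]
    }
    all_genes <- unique(calls$gene_id)
    base <- merge(data.table(gene_id = all_genes), base,
                  by = "gene_id", all.x = TRUE)
    nofb <- is.na(base$baseline)
    if (any(nofb)) base[nofb, baseline := ref_fallback(gene_id)]
  }
  tum <- calls[sample %chin% tumour_samples & status != "not_expressed"]
  tum <- merge(tum, base, by = "gene_id")
  res <- tum[, .(n_expressed = .N, n_deviant = sum(status != baseline),
                 baseline_class = baseline[1L],
                 deviant_tx = list(transcript_id[status != baseline])),
             by = gene_id]
  res[, switch_fraction := n_deviant / n_expressed]
  res[, direction := fifelse(baseline_class == "coding",
                             "coding_to_noncoding", "noncoding_to_coding")]
  res[, driver_biotype := NA_character_]
  if (!is.null(cat)) {
    res[n_deviant > 0, driver_biotype := vapply(deviant_tx, function(ids) {
      bt <- cat$transcripts$biotype[match(ids, cat$transcripts$transcript_id)]
      names(sort(table(bt), decreasing = TRUE))[1L]
    }, character(1))]
  }
  res[, deviant_tx := NULL]
  out <- res[switch_fraction >= min_fraction & n_deviant > 0L]
  out[, design := "cohort"]
  setorder(out, -switch_fraction, gene_id)
  out[, .(gene_id, design, direction, switch_fraction, driver_biotype,
          baseline_class, n_deviant, n_expressed)]
}

#' Genes whose modal major-isoform class flips between two groups
#'
#' Direction-specific: reports genes whose modal status is coding in group
#' A and noncoding in group B.
#'
#' @param calls output of [call_major_isoforms()].
#' @param group_a,group_b sample id vectors.
#' @return character vector of gene ids.
#' @export
group_class_switches <- function(calls, group_a, group_b) {
  calls <- as.data.table(calls)
  if (!length(group_a) || !length(group_b)) stop_is("empty sample group")
  ma <- calls[sample %chin% group_a, .(s = .modal_status(status)), by = gene_id]
  mb <- calls[sample %chin% group_b, .(s = .modal_status(status)), by = gene_id]
  m <- merge(ma, mb, by = "gene_id", suffixes = c("_a", "_b"))
  sort(m[s_a == "coding" & s_b == "noncoding", gene_id])
}

#' Per-sample noncoding major-isoform proportion
#'
#' The cohort-level outcome statistic: among genes expressed in the
#' sample, the fraction whose major isoform is noncoding.
#'
#' @param calls output of [call_major_isoforms()].
#' @param samples samples to profile (default all in `calls`).
#' @return `data.table` with `sample`, `n_expressed`, `n_noncoding_major`,
#'   `proportion`.
#' @export
noncoding_proportion <- function(calls, samples = NULL) {
  calls <- as.data.table(calls)
  if (!is.null(samples)) calls <- calls[sample %chin% samples]
  prof <- calls[status != "not_expressed",
                .(n_expressed = .N, n_noncoding_major = sum(status == "noncoding")),
                by = sample]
  empty <- setdiff(unique(calls$sample), prof$sample)
  if (length(empty))
    stop_is("sample(s) with zero expressed genes: %s", paste(empty, collapse = ", "))
  prof[, proportion := n_noncoding_major / n_expressed]
  prof[]
}

#' Hypergeometric overlap of two switch-gene sets
#'
#' Upper-tail probability of observing at least the realised overlap when
#' drawing `|set_a|` genes from the universe containing `|set_b|` marked
#' genes.
#'
#' @param set_a,set_b gene sets (character vectors), both inside
#'   `universe`.
#' @param universe background gene set.
#' @return list with `overlap` and `p.value`.
#' @export
switch_set_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop_is("switch sets must be contained in the universe")
  k <- length(intersect(set_a, set_b))
  list(overlap = k,
       p.value = hypergeom_upper_tail(k, length(set_b), length(set_a),
                                      length(universe)))
}

#' Cluster samples on major-isoform class
#'
#' Binarises the gene x sample status matrix (noncoding = 1, anything
#' else = 0), computes Jaccard distances between samples and performs
#' average-linkage agglomerative clustering; the tree is cut at `k`
#' clusters.
#'
#' @param status_matrix character matrix genes x samples with entries in
#'   `{coding, noncoding, not_expressed}` (or the `calls` table from
#'   [call_major_isoforms()]).
#' @param k number of clusters to cut (default 3).
#' @return list with `hclust` (the dendrogram), `clusters` (named integer
#'   vector) and `distance` (the Jaccard `dist`).
#' @export
cluster_samples <- function(status_matrix, k = 3) {
  if (is.data.frame(status_matrix)) {
    calls <- as.data.table(status_matrix)
    status_matrix <- as.matrix(dcast(calls, gene_id ~ sample,
                                     value.var = "status"),
                               rownames = "gene_id")
  }
  if (ncol(status_matrix) < 2L) stop_is("need at least 2 samples to cluster")
  b <- (status_matrix == "noncoding") * 1L
  if (all(b == b[, 1L])) {
    warn_is("constant status matrix: all samples fall in one cluster")
    cl <- setNames(rep(1L, ncol(b)), colnames(b))
    return(list(hclust = NULL, clusters = cl, distance = NULL))
  }
  n <- ncol(b)
  inter <- crossprod(b)
  sums <- colSums(b)
  union <- outer(sums, sums, "+") - inter
  jac <- ifelse(union > 0, 1 - inter / union, 0)
  d <- as.dist(jac)
  hc <- hclust(d, method = "average")
  list(hclust = hc, clusters = cutree(hc, k = min(k, n)), distance = d)
}
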