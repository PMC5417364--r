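# Minimal GO-style ontology support: an acyclic child->parent edge list,
# gene->term annotation propagated to ancestors, hypergeometric term
# enrichment with BH adjustment, and an ancestor/descendant redundancy
# filter standing in for semantic-similarity reduction.

#' Build an ontology DAG with propagated annotation
#'
#' @param edges `data.frame` with columns `child`, `parent` (is_a edges).
#' @param annotation `data.frame` with columns `gene_id`, `term_id`
#'   (direct annotations; propagated to all ancestors on construction).
#' @return object of class `ontology_dag` with `parents` (adjacency list),
#'   `terms`, and `gene2terms` (propagated, a named list of term sets).
#' @export
ontology_dag <- function(edges, annotation) {
  edges <- as.data.table(edges)
  annotation <- as.data.table(annotation)
  stopifnot(all(c("child", "parent") %in% names(edges)),
            all(c("gene_id", "term_id") %in% names(annotation)))
  terms <- sort(unique(c(edges$child, edges$parent, annotation$term_id)))
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(t, seen = character()) {
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    if (t %in% seen) stop_is("ontology edge list contains a cycle at '%s'", t)
    ps <- parents[[t]]
    out <- if (!length(ps)) character() else
      unique(c(ps, unlist(lapply(ps, ancestors, seen = c(seen, t)))))
    anc_cache[[t]] <- out
    out
  }
  for (t in terms) ancestors(t)
  g2t <- lapply(split(annotation$term_id, annotation$gene_id), function(ts) {
    unique(c(ts, unlist(lapply(unique(ts), function(t) anc_cache[[t]]))))
  })
  structure(list(terms = terms, parents = parents,
                 ancestors = as.list(anc_cache), gene2terms = g2t),
            class = "ontology_dag")
}

#' Read an ontology from edge-list and annotation TSVs
#'
#' @param edges_path TSV with columns `child`, `parent`.
#' @param annotation_path TSV with columns `gene_id`, `term_id`.
#' @return an [ontology_dag].
#' @export
read_ontology <- function(edges_path, annotation_path) {
  ontology_dag(fread(edges_path, sep = "\t"), fread(annotation_path, sep = "\t"))
}

#' GO term enrichment by hypergeometric test
#'
#' One upper-tail hypergeometric test per term with at least one annotated
#' universe gene, BH adjustment across all tested terms, and an `enriched`
#' flag at `q < q_threshold`.
#'
#' @param gene_set character vector of genes of interest (subset of
#'   `universe`).
#' @param universe character vector of background genes.
#' @param dag an [ontology_dag].
#' @param q_threshold BH-adjusted significance threshold (default 0.01).
#' @return `data.table` with columns `term_id`, `k`, `K`, `n`, `N`, `p`,
#'   `q`, `enriched`, ordered by `p`.
#' @export
go_enrichment <- function(gene_set, universe, dag, q_threshold = 0.01) {
  if (!all(gene_set %in% universe))
    stop_is("gene_set contains genes outside the universe")
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  g2t <- dag$gene2terms[intersect(names(dag$gene2terms), universe)]
  term_genes <- split(rep(names(g2t), lengths(g2t)), unlist(g2t, use.names = FALSE))
  N <- length(universe); n <- length(gene_set)
  res <- rbindlist(lapply(names(term_genes), function(t) {
    Kg <- term_genes[[t]]
    k <- sum(gene_set %in% Kg)
    data.table(term_id = t, k = k, K = length(Kg), n = n, N = N,
               p = hypergeom_upper_tail(k, length(Kg), n, N))
  }))
  if (!nrow(res)) return(res)
  res[, q := bh_adjust(p)]
  res[, enriched := q < q_threshold]
  setorder(res, p, term_id)
  res[]
}

#' Drop redundant enriched terms along ancestor chains
#'
#' Among any ancestor-descendant pair that are both flagged enriched, only
#' the smaller-p term is kept (ties go to the more specific, descendant
#' term); applied transitively. Non-enriched rows pass through untouched.
#'
#' @param results output of [go_enrichment()].
#' @param dag the [ontology_dag] the results were computed on.
#' @return the filtered results table.
#' @export
reduce_redundant <- function(results, dag) {
  res <- as.data.table(results)
  if (!all(res$term_id %in% dag$terms))
    stop_is("result term(s) missing from the ontology: %s",
            paste(setdiff(res$term_id, dag$terms), collapse = ", "))
  enr <- res[enriched == TRUE]
  if (nrow(enr) < 2L) return(res)
  drop <- character()
  for (i in seq_len(nrow(enr))) {
    ti <- enr$term_id[i]
    anc <- intersect(dag$ancestors[[ti]], enr$term_id)
    for (ta in anc) {
      pa <- enr[term_id == ta, p]
      # descendant wins ties; ancestor only survives with strictly smaller p
      if (pa < enr$p[i]) drop <- c(drop, ti) else drop <- c(drop, ta)
    }
  }
  res[!(term_id %in% unique(drop))]
}
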