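## Per-cluster GO over-representation: one-sided hypergeometric tail test per
## term, BH adjustment within each (cluster, namespace), clusterProfiler-style
## GeneRatio/BgRatio output columns.

#' Hypergeometric upper-tail p-value
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K` are
#' annotated: `p = sum_{x=k}^{min(K,n)} C(K,x) C(N-K,n-x) / C(N,n)`.
#'
#' @param k observed overlap.
#' @param K annotated genes in the universe.
#' @param n drawn genes (cluster size).
#' @param N universe size.
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N || k > min(K, n))
    stop("invalid hypergeometric configuration: k=", k, " K=", K,
         " n=", n, " N=", N, call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation test of one cluster against a gene universe
#'
#' Terms are intersected with the universe, filtered to sizes in
#' `[min_set, max_set]`, tested one-sided hypergeometrically, and BH-adjusted
#' within each namespace.  Duplicate cluster gene ids are removed before
#' testing.
#'
#' @param cluster_genes genes of one cluster (must be a subset of `universe`).
#' @param universe background gene ids.
#' @param sets a `gene_set_collection`.
#' @param min_set,max_set term size bounds after universe intersection
#'   (defaults 10 and 500).
#' @return data.frame with `term_id`, `name`, `namespace`, `GeneRatio`,
#'   `BgRatio`, `k`, `pvalue`, `padj`, `genes` (comma-separated overlap),
#'   sorted by `padj` then `pvalue`.
#' @export
enrich_cluster <- function(cluster_genes, universe, sets, min_set = 10,
                           max_set = 500) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  cluster_genes <- unique(cluster_genes)
  missing <- setdiff(cluster_genes, universe)
  if (length(missing) > 0L)
    stop("cluster gene(s) absent from universe: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  N <- length(universe)
  n <- length(cluster_genes)
  rows <- lapply(names(sets), function(id) {
    s <- sets[[id]]
    members <- intersect(s$genes, universe)
    K <- length(members)
    if (K < min_set || K > max_set) return(NULL)
    overlap <- intersect(cluster_genes, members)
    k <- length(overlap)
    data.frame(term_id = id, name = s$name, namespace = s$namespace,
               GeneRatio = paste0(k, "/", n), BgRatio = paste0(K, "/", N),
               k = k, pvalue = hypergeom_tail(k, K, n, N), padj = NA_real_,
               genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), name = character(),
                      namespace = character(), GeneRatio = character(),
                      BgRatio = character(), k = integer(), pvalue = numeric(),
                      padj = numeric(), genes = character(),
                      stringsAsFactors = FALSE))
  for (ns in unique(out$namespace)) {
    sel <- out$namespace == ns
    out$padj[sel] <- bh_adjust(out$pvalue[sel])
  }
  out[order(out$padj, out$pvalue, out$term_id), , drop = FALSE]
}

#' Over-representation analysis of every cluster
#'
#' Maps [enrich_cluster()] over the clusters of an assignment; BH adjustment
#' is scoped within each (cluster, namespace), so p-values in one cluster
#' never affect another's adjusted values.  The top 10 terms per namespace in
#' each cluster are flagged.
#'
#' @param assignment a [assign_clusters()] result.
#' @param universe background gene ids (e.g. the analyzed DEGs that appear in
#'   at least one gene set).
#' @param sets a `gene_set_collection`.
#' @inheritParams enrich_cluster
#' @return data.frame (`enrichment_table`) with a leading `cluster` column
#'   and a logical `top10` flag.
#' @export
enrich_clusters <- function(assignment, universe, sets, min_set = 10,
                            max_set = 500) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  out <- do.call(rbind, lapply(seq_len(assignment$K), function(cl) {
    genes <- intersect(names(assignment$labels)[assignment$labels == cl], universe)
    if (length(genes) == 0L) return(NULL)
    tab <- enrich_cluster(genes, universe, sets, min_set, max_set)
    if (nrow(tab) == 0L) return(NULL)
    cbind(cluster = cl, tab, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(cluster = integer(), term_id = character(),
                      name = character(), namespace = character(),
                      GeneRatio = character(), BgRatio = character(),
                      k = integer(), pvalue = numeric(), padj = numeric(),
                      genes = character(), top10 = logical(),
                      stringsAsFactors = FALSE))
  out$top10 <- FALSE
  for (cl in unique(out$cluster)) for (ns in unique(out$namespace)) {
    sel <- which(out$cluster == cl & out$namespace == ns)
    keep <- sel[order(out$padj[sel], out$pvalue[sel])][seq_len(min(10, length(sel)))]
    out$top10[keep] <- TRUE
  }
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Default enrichment universe
#'
#' The default background is every annotated gene (the union of all gene-set
#' members), matching the convention of the standard over-representation
#' tools; conditioning the background on the analyzed DEG set is available
#' but starves small clusters of power when few genes carry annotations.
#'
#' @param genes analyzed gene ids (e.g. the selected DEGs).
#' @param sets a `gene_set_collection`.
#' @param mode `"all_annotated"` (default: union of all set members),
#'   `"degs_in_sets"` (analyzed genes appearing in at least one set) or
#'   `"all_genes"` (analyzed genes as-is).
#' @return character vector of universe gene ids.
#' @export
enrichment_universe <- function(genes, sets,
                                mode = c("all_annotated", "degs_in_sets",
                                         "all_genes")) {
  mode <- match.arg(mode)
  annotated <- unique(unlist(lapply(sets, `[[`, "genes"), use.names = FALSE))
  switch(mode,
         degs_in_sets = intersect(genes, annotated),
         all_genes = unique(genes),
         all_annotated = annotated)
}
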