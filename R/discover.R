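## The functional-gene-discovery rule: designate functional clusters (known
## genes present AND a target term enriched), cross-reference the known-gene
## list, and promote unannotated members (zero literature hits, positive
## expression evidence) to candidate functional genes.

#' Designate functional clusters
#'
#' A cluster qualifies iff it contains at least one known gene AND at least
#' one target term is enriched in it below `alpha` (BH-adjusted).  An
#' optional rising-trend filter additionally requires the cluster's mean
#' postnatal z-score to exceed its mean embryonic z-score.
#'
#' @param assignment a [assign_clusters()] result.
#' @param known known functional gene ids.
#' @param enrichment an [enrich_clusters()] table computed on the same
#'   assignment.
#' @param target_terms term ids defining the target function; every id must
#'   exist in `sets` (or, if `sets` is NULL, in the enrichment table).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param sets the `gene_set_collection` used for enrichment, for validating
#'   `target_terms` (optional).
#' @param rising_only apply the rising-trend filter (default FALSE).
#' @param profiles,meta z-score profile matrix and sample metadata; required
#'   when `rising_only = TRUE`.
#' @return data.frame with `cluster`, `triggering_terms`, `n_known`,
#'   `known_genes`; zero rows when no cluster qualifies.
#' @export
designate_functional_clusters <- function(assignment, known, enrichment,
                                          target_terms, alpha = 0.05,
                                          sets = NULL, rising_only = FALSE,
                                          profiles = NULL, meta = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  pool <- if (!is.null(sets)) names(sets) else unique(enrichment$term_id)
  missing <- setdiff(target_terms, pool)
  if (length(missing) > 0L)
    stop("target term(s) not in the gene-set collection: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(assignment$K), function(cl) {
    members <- names(assignment$labels)[assignment$labels == cl]
    kn <- sort(intersect(members, known))
    if (length(kn) == 0L) return(NULL)
    hits <- enrichment[enrichment$cluster == cl &
                         enrichment$term_id %in% target_terms &
                         !is.na(enrichment$padj) & enrichment$padj < alpha, ]
    if (nrow(hits) == 0L) return(NULL)
    data.frame(cluster = cl,
               triggering_terms = paste(hits$term_id, collapse = ","),
               n_known = length(kn),
               known_genes = paste(kn, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster = integer(), triggering_terms = character(),
                      n_known = integer(), known_genes = character(),
                      stringsAsFactors = FALSE)
  if (rising_only && nrow(out) > 0L) {
    if (is.null(profiles) || is.null(meta))
      stop("rising_only = TRUE requires profiles and meta", call. = FALSE)
    meta <- validate_sample_metadata(meta)
    cond_of <- vapply(colnames(profiles), function(tp)
      meta$condition[match(tp, meta$timepoint)], "")
    keep <- vapply(out$cluster, function(cl) {
      members <- names(assignment$labels)[assignment$labels == cl]
      prof <- colMeans(profiles[members, , drop = FALSE])
      mean(prof[cond_of == "postnatal"]) > mean(prof[cond_of == "embryonic"])
    }, TRUE)
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Cross-reference cluster members against the known-gene list
#'
#' @param assignment a [assign_clusters()] result.
#' @param known known functional gene ids.
#' @return data.frame with one row per cluster: `cluster`, `n_members`,
#'   `n_known`, `known_genes` (sorted, comma-separated); total matched count
#'   in `attr(, "total_known")`.
#' @export
cross_reference_known <- function(assignment, known) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  rows <- lapply(seq_len(assignment$K), function(cl) {
    members <- names(assignment$labels)[assignment$labels == cl]
    kn <- sort(intersect(members, known))
    data.frame(cluster = cl, n_members = length(members),
               n_known = length(kn), known_genes = paste(kn, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "total_known") <- sum(out$n_known)
  out
}

#' Predict novel functional gene candidates
#'
#' Candidates are members of designated functional clusters that are absent
#' from the known list, have zero literature hits and positive expression
#' evidence.  Genes missing from the evidence table are conservatively
#' treated as documented and excluded (with a message listing them).
#'
#' @param functional_clusters a [designate_functional_clusters()] table.
#' @param assignment the cluster assignment.
#' @param known known functional gene ids.
#' @param evidence evidence table (see [read_evidence()]).
#' @return list of class `candidate_report`: `functional_clusters`,
#'   `candidates` (data.frame gene_id/cluster/literature_hits/
#'   expression_evidence), `missing_evidence`, `summary`.
#' @export
predict_candidates <- function(functional_clusters, assignment, known, evidence) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  cand <- NULL
  missing_all <- character()
  for (cl in functional_clusters$cluster) {
    members <- names(assignment$labels)[assignment$labels == cl]
    members <- setdiff(members, known)
    idx <- match(members, evidence$gene_id)
    miss <- members[is.na(idx)]
    missing_all <- c(missing_all, miss)
    ok <- !is.na(idx) & evidence$literature_hits[idx] == 0 &
      evidence$expression_evidence[idx]
    if (any(ok)) {
      cand <- rbind(cand, data.frame(
        gene_id = members[ok], cluster = cl,
        literature_hits = evidence$literature_hits[idx[ok]],
        expression_evidence = evidence$expression_evidence[idx[ok]],
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(cand))
    cand <- data.frame(gene_id = character(), cluster = integer(),
                       literature_hits = integer(),
                       expression_evidence = logical(),
                       stringsAsFactors = FALSE)
  if (length(missing_all) > 0L)
    message("gene(s) without evidence rows treated as documented: ",
            paste(utils::head(sort(unique(missing_all)), 20), collapse = ", "))
  stopifnot(!any(cand$gene_id %in% known))
  structure(list(functional_clusters = functional_clusters,
                 candidates = cand,
                 missing_evidence = sort(unique(missing_all)),
                 summary = list(n_functional_clusters = nrow(functional_clusters),
                                n_known_in_functional = sum(functional_clusters$n_known),
                                n_candidates = nrow(cand))),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("candidate_report:", x$summary$n_functional_clusters,
      "functional cluster(s),", x$summary$n_known_in_functional,
      "known gene(s) matched,", x$summary$n_candidates, "candidate(s)\n")
  if (nrow(x$candidates) > 0L) print(x$candidates)
  invisible(x)
}

#' Rank candidates by postnatal expression peak
#'
#' Default score: each candidate's maximum z-score over postnatal timepoints,
#' descending; ties broken by gene id.  The ranking criterion is a package
#' choice (flagged in the output column name) and can be replaced via
#' `score_fun`.
#'
#' @param report a [predict_candidates()] result.
#' @param profiles z-score profile matrix covering every candidate.
#' @param meta sample metadata (maps timepoints to conditions).
#' @param score_fun optional function(z_row, condition_per_timepoint) ->
#'   scalar score.
#' @return the report with `candidates` gaining `score` and `rank` columns,
#'   ordered best first.
#' @export
rank_candidates <- function(report, profiles, meta, score_fun = NULL) {
  stopifnot(inherits(report, "candidate_report"))
  cand <- report$candidates
  if (nrow(cand) == 0L) return(report)
  missing <- setdiff(cand$gene_id, rownames(profiles))
  if (length(missing) > 0L)
    stop("candidate(s) missing from profiles: ",
         paste(missing, collapse = ", "), call. = FALSE)
  meta <- validate_sample_metadata(meta)
  cond_of <- vapply(colnames(profiles), function(tp)
    meta$condition[match(tp, meta$timepoint)], "")
  if (is.null(score_fun))
    score_fun <- function(z, cond) max(z[cond == "postnatal"])
  cand$score <- vapply(cand$gene_id, function(g)
    score_fun(profiles[g, ], cond_of), 0)
  ord <- order(-cand$score, cand$gene_id)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  report$candidates <- cand
  report
}
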