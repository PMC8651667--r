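# small hand-built world: 3 clusters, one carrying known genes + an enriched
# target term
make_world <- function() {
  genes <- sprintf("g%03d", 1:90)
  labels <- stats::setNames(rep(1:3, each = 30), genes)
  asg <- structure(list(labels = labels, K = 3L, method = "fixed",
                        metadata = list()), class = "cluster_assignment")
  known <- genes[1:5]
  enrichment <- data.frame(
    cluster = c(1L, 2L, 3L),
    term_id = c("GO:T1", "GO:T1", "GO:T2"),
    name = "t", namespace = "CC", GeneRatio = "5/30", BgRatio = "10/90",
    k = 5L, pvalue = c(1e-6, 0.5, 1e-6), padj = c(1e-5, 0.6, 1e-5),
    genes = "", stringsAsFactors = FALSE)
  evidence <- data.frame(
    gene_id = genes,
    literature_hits = ifelse(genes %in% genes[c(6, 7)], 0L, 5L),
    expression_evidence = genes != genes[7],
    stringsAsFactors = FALSE)
  # g006: zero hits + expression -> candidate; g007: zero hits but no
  # expression evidence -> excluded
  list(asg = asg, known = known, enrichment = enrichment, evidence = evidence,
       genes = genes)
}

test_that("functional clusters require both known members and an enriched term", {
  w <- make_world()
  fc <- designate_functional_clusters(w$asg, w$known, w$enrichment,
                                      target_terms = "GO:T1", alpha = 0.05)
  # cluster 1: known + enriched -> in; cluster 2: known absent -> out;
  # cluster 3: enriched for a non-target term only -> out
  expect_identical(fc$cluster, 1L)
  expect_identical(fc$n_known, 5L)
  expect_match(fc$triggering_terms, "GO:T1")

  none <- designate_functional_clusters(w$asg, character(), w$enrichment,
                                        target_terms = "GO:T1")
  expect_identical(nrow(none), 0L)

  expect_error(designate_functional_clusters(w$asg, w$known, w$enrichment,
                                             target_terms = "GO:NOPE"),
               "GO:NOPE")
})

test_that("known-gene cross-reference partitions counts over clusters", {
  w <- make_world()
  xr <- cross_reference_known(w$asg, w$known)
  expect_identical(xr$n_known, c(5L, 0L, 0L))
  expect_identical(attr(xr, "total_known"), 5L)
  empty <- cross_reference_known(w$asg, character())
  expect_true(all(empty$n_known == 0L))
})

test_that("candidate prediction applies the zero-hits + expression rule", {
  w <- make_world()
  fc <- designate_functional_clusters(w$asg, w$known, w$enrichment, "GO:T1")
  rep <- predict_candidates(fc, w$asg, w$known, w$evidence)
  expect_identical(rep$candidates$gene_id, "g006")
  expect_identical(rep$summary$n_candidates, 1L)
  expect_length(intersect(rep$candidates$gene_id, w$known), 0L)

  # a known gene with zero hits is never a candidate
  ev2 <- w$evidence
  ev2$literature_hits[1] <- 0L
  rep2 <- predict_candidates(fc, w$asg, w$known, ev2)
  expect_false(w$known[1] %in% rep2$candidates$gene_id)

  # genes missing evidence rows are conservatively excluded, with a message
  ev3 <- w$evidence[w$evidence$gene_id != "g006", ]
  expect_message(rep3 <- predict_candidates(fc, w$asg, w$known, ev3),
                 "g006")
  expect_identical(nrow(rep3$candidates), 0L)
})

test_that("shrinking the enrichment threshold never adds candidates", {
  w <- make_world()
  prev_n <- Inf
  for (alpha in c(0.1, 0.05, 0.01, 1e-6)) {
    fc <- designate_functional_clusters(w$asg, w$known, w$enrichment, "GO:T1",
                                        alpha = alpha)
    rep <- predict_candidates(fc, w$asg, w$known, w$evidence)
    expect_lte(rep$summary$n_candidates, prev_n)
    prev_n <- rep$summary$n_candidates
  }
})

test_that("candidates are ranked by postnatal z-score peak", {
  w <- make_world()
  fc <- designate_functional_clusters(w$asg, w$known, w$enrichment, "GO:T1")
  ev <- w$evidence
  ev$literature_hits[8] <- 0L        # a second candidate: g008
  rep <- predict_candidates(fc, w$asg, w$known, ev)
  expect_identical(sort(rep$candidates$gene_id), c("g006", "g008"))

  tps <- c("E11", "E16", "P0", "P14")
  profiles <- matrix(0, length(w$genes), 4,
                     dimnames = list(w$genes, tps))
  profiles["g006", ] <- c(-1, -1, 0, 2.0)
  profiles["g008", ] <- c(-1, -1, 0, 1.0)
  meta <- make_meta(paste0("s", 1:4), rep("B1", 4), tps,
                    c("embryonic", "embryonic", "postnatal", "postnatal"))
  ranked <- rank_candidates(rep, profiles, meta)
  expect_identical(ranked$candidates$gene_id, c("g006", "g008"))
  expect_identical(ranked$candidates$rank, 1:2)
  expect_equal(ranked$candidates$score, c(2, 1))

  expect_error(rank_candidates(rep, profiles[-6, ], meta), "missing from profiles")
})
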