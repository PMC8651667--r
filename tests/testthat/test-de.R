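test_that("size factors follow the median-of-ratios definition", {
  # identical columns -> both factors 1
  m <- cbind(s1 = c(10, 20, 30), s2 = c(10, 20, 30))
  rownames(m) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m)), c(1, 1))

  # pure depth: second column = 2x first
  m2 <- tiny_counts()
  s <- size_factors(m2)
  expect_equal(unname(s[2] / s[1]), 2)
  # hand computation: geometric means (141.42, 14.14, 56.57); every ratio in
  # column 1 is 1/sqrt(2), in column 2 sqrt(2)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  mm <- m2; mm[1, 1] <- 0
  mm[2, 1] <- 0; mm[3, 2] <- 0
  expect_error(size_factors(mm), "filter")
})

test_that("dispersion estimation matches the moment formula and handles limits", {
  # single gene, one condition: (var - mean) / mean^2 applied exactly
  y <- c(44, 50, 56, 38, 62, 50)   # mean 50
  counts <- matrix(y, 1, 6, dimnames = list("g1", paste0("s", 1:6)))
  meta <- make_meta(paste0("s", 1:6), rep("B1", 6), rep("P0", 6),
                    rep("postnatal", 6))
  sf <- stats::setNames(rep(1, 6), paste0("s", 1:6))
  a <- estimate_dispersion(counts, sf, meta)
  expect_equal(unname(a), (stats::var(y) - mean(y)) / mean(y)^2, tolerance = 1e-12)

  # constant gene -> floored at the minimum
  cc <- matrix(7, 1, 6, dimnames = list("g1", paste0("s", 1:6)))
  expect_equal(unname(estimate_dispersion(cc, sf, meta)), 1e-8)

  # Poisson-simulated genes -> dispersion near the floor
  pois <- withr::with_seed(1, matrix(stats::rpois(200 * 6, 60), 200, 6,
                                     dimnames = list(sprintf("g%03d", 1:200),
                                                     paste0("s", 1:6))))
  ap <- estimate_dispersion(pois, sf, meta)
  expect_lt(stats::median(ap), 0.005)
})

test_that("BH adjustment matches hand step-up and is monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- withr::with_seed(2, stats::runif(50))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Wald DE has the documented degenerate and symmetry behavior", {
  sim <- simulate_dataset(flat_config(seed = 21, n_genes = 300, reps = 4))
  de <- wald_de(sim$counts, sim$meta)
  expect_true(all(de$pvalue[de$tested] >= 0 & de$pvalue[de$tested] <= 1))
  expect_true(all(de$padj[de$tested] >= de$pvalue[de$tested] - 1e-12))
  expect_setequal(de$rank[de$tested], seq_len(sum(de$tested)))

  # equal condition means -> log2FC 0, p = 1
  m <- matrix(c(5, 5, 5, 5), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  meta <- make_meta(paste0("s", 1:4), rep("B1", 4),
                    c("E11", "E11", "P0", "P0"),
                    rep(c("embryonic", "postnatal"), each = 2))
  de1 <- wald_de(m, meta)
  expect_equal(de1$log2FoldChange, 0)
  expect_equal(de1$pvalue, 1)

  # swapping condition labels negates log2FC and preserves p-values
  meta2 <- sim$meta
  meta2$condition <- ifelse(meta2$condition == "embryonic", "postnatal",
                            "embryonic")
  de_sw <- wald_de(sim$counts, validate_sample_metadata(meta2))
  expect_equal(de_sw$log2FoldChange, -de$log2FoldChange, tolerance = 1e-9)
  expect_equal(de_sw$pvalue, de$pvalue, tolerance = 1e-9)
})

test_that("normalized quantities are invariant to per-sample depth scaling", {
  sim <- simulate_dataset(flat_config(seed = 22, n_genes = 200, reps = 3))
  counts2 <- sim$counts
  counts2[, 1] <- counts2[, 1] * 3
  s1 <- size_factors(sim$counts)
  s2 <- size_factors(counts2)
  # the scaled sample's factor grows by exactly 3 relative to every other
  # sample; the common geometric-mean shift cancels in all relative sizes
  expect_equal(unname((s2[1] / s2[2]) / (s1[1] / s1[2])), 3, tolerance = 1e-12)
  expect_equal(unname(s2[-1] / s1[-1]), rep(3^(-1 / 6), 5), tolerance = 1e-12)
  # normalized counts shift by a common factor only, so fold changes and
  # p-values move only through the 0.5 pseudo-count
  de1 <- wald_de(sim$counts, sim$meta)
  de2 <- wald_de(counts2, sim$meta)
  expect_lt(max(abs(de2$log2FoldChange - de1$log2FoldChange)), 0.05)
  expect_lt(max(abs(de2$pvalue - de1$pvalue)), 0.05)
})

test_that("top DEG selection filters, ranks and breaks ties as documented", {
  tab <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    baseMean = 10, log2FoldChange = c(3, 1, -2, 0.5), lfcSE = 1,
    stat = 0, pvalue = c(0.001, 0.001, 0.01, 0.2),
    padj = c(0.004, 0.004, 0.02, 0.2), rank = 1:4, tested = TRUE,
    stringsAsFactors = FALSE)
  # tie at p = 0.001 broken by |log2FC| descending
  expect_identical(top_degs(tab, n = 2, alpha = 0.05), c("g1", "g2"))
  expect_identical(top_degs(tab, n = 10, alpha = 0.05), c("g1", "g2", "g3"))
  expect_message(top_degs(tab, n = 10, alpha = 0.05), "only 3")
})

test_that("size factors and fold changes agree with DESeq2 on the same data", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_dataset(step_config(seed = 30, n_genes = 400, n_de = 50,
                                      reps = 4))
  sf <- size_factors(sim$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)

  de <- wald_de(sim$counts, sim$meta)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      round(sim$counts),
      S4Vectors::DataFrame(condition = factor(sim$meta$condition,
                                              levels = c("embryonic", "postnatal"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref_res <- DESeq2::results(dds)
  })
  keep <- de$tested & !is.na(ref_res$log2FoldChange)
  expect_gt(stats::cor(de$log2FoldChange[keep], ref_res$log2FoldChange[keep]),
            0.95)
})
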