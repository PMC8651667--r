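test_that("simulation is deterministic under a fixed seed and differs across seeds", {
  cfg <- simulate_config(n_genes = 120, seed = 7,
                         module_spec = c(rising = 20, falling = 20,
                                         transient = 20, flat = 60))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$evidence, b$evidence)
  expect_identical(a$gene_sets, b$gene_sets)
  cfg2 <- simulate_config(n_genes = 120, seed = 8,
                          module_spec = c(rising = 20, falling = 20,
                                          transient = 20, flat = 60))
  c <- simulate_dataset(cfg2)
  expect_identical(dim(c$counts), dim(a$counts))
  expect_false(identical(c$counts, a$counts))
})

test_that("generated counts match negative-binomial moments (mu = 50, alpha = 0.1)", {
  # one flat gene observed over 10,000 replicate samples
  cfg <- simulate_config(
    n_genes = 1, timepoints = "P0", conditions = "postnatal",
    replicates_per_timepoint = 10000, n_batches = 1,
    batch_mean_factor = 1, batch_disp_factor = 1,
    patterns = list(flat = pattern_flat("P0", "postnatal")),
    module_spec = c(flat = 1),
    functional_module = list(pattern = "flat", n_known = 0, n_candidates = 0),
    base_mean_meanlog = log(50), base_mean_sdlog = 0,
    dispersion = 0.1, seed = 42)
  y <- as.numeric(simulate_dataset(cfg)$counts)
  mu <- 50; v <- mu + 0.1 * mu^2          # NB variance mu + alpha mu^2 = 300
  se_mean <- sqrt(v / length(y))
  expect_lt(abs(mean(y) - mu), 3 * se_mean)
  expect_lt(abs(stats::var(y) - v) / v, 0.10)
})

test_that("null batch factors leave no systematic between-batch mean ratio", {
  cfg <- flat_config(seed = 5, n_genes = 500, reps = 6, batches = 2,
                     batch_mean = c(1, 1), batch_disp = c(1, 1))
  sim <- simulate_dataset(cfg)
  b1 <- sim$meta$sample_id[sim$meta$batch == "B1"]
  b2 <- sim$meta$sample_id[sim$meta$batch == "B2"]
  ratio <- rowMeans(sim$counts[, b2]) / pmax(rowMeans(sim$counts[, b1]), 0.5)
  expect_lt(abs(log2(stats::median(ratio))), 0.1)
})

test_that("planted roles, evidence and gene sets are mutually consistent", {
  sim <- simulate_dataset(simulate_config(seed = 3))
  truth <- sim$truth
  expect_identical(nrow(truth), nrow(sim$counts))
  cand <- truth$gene_id[truth$role == "planted_candidate"]
  expect_length(cand, 3L)
  expect_length(intersect(cand, sim$known), 0L)
  ev <- sim$evidence[match(cand, sim$evidence$gene_id), ]
  expect_true(all(ev$literature_hits == 0 & ev$expression_evidence))
  evk <- sim$evidence[match(sim$known, sim$evidence$gene_id), ]
  expect_true(all(evk$literature_hits > 0))
  expect_setequal(sim$gene_sets[["GO:F0001"]]$genes, c(as.character(sim$known), cand))
})

test_that("planted modules are recoverable in the near-noiseless limit", {
  cfg <- simulate_config(n_genes = 60, dispersion = 1e-6,
                         batch_mean_factor = c(1, 1), batch_disp_factor = c(1, 1),
                         module_spec = c(rising = 20, falling = 20, flat = 20),
                         functional_module = list(pattern = "rising",
                                                  n_known = 0, n_candidates = 0),
                         base_mean_meanlog = 5, base_mean_sdlog = 0, seed = 9)
  sim <- simulate_dataset(cfg)
  med <- median_profiles(tpm(sim$counts, sim$annotation), sim$meta)
  z <- zscore_profiles(med)
  labels <- hierarchical_cluster(unclass(z), 3)
  expect_gt(adjusted_rand(labels, sim$truth$pattern), 0.95)
})

test_that("fixture directories round-trip through the package readers", {
  sim <- simulate_dataset(simulate_config(n_genes = 120, seed = 11,
                                          module_spec = c(rising = 30, flat = 90)))
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim, dir)
  expect_length(paths, 7L)
  expect_identical(read_count_matrix(paths["counts"]), sim$counts)
  meta <- read_sample_metadata(paths["meta"])
  expect_identical(meta$sample_id, sim$meta$sample_id)
  expect_identical(read_gene_sets(paths["gene_sets"]), sim$gene_sets)
  expect_identical(as.character(read_known_genes(paths["known"])),
                   as.character(sim$known))
  ev <- read_evidence(paths["evidence"])
  expect_identical(ev$literature_hits, sim$evidence$literature_hits)
  expect_identical(ev$expression_evidence, sim$evidence$expression_evidence)
  # truth bookkeeping: exactly the configured number of planted candidates
  truth <- utils::read.delim(paths["truth"])
  expect_identical(sum(truth$role == "planted_candidate"), 3L)
})

test_that("infeasible module specs are rejected", {
  expect_error(simulate_config(n_genes = 100,
                               module_spec = c(rising = 10, flat = 80)),
               "sum to 90")
  expect_error(simulate_config(n_genes = 100,
                               module_spec = c(rising = 5, flat = 95),
                               functional_module = list(pattern = "rising",
                                                        n_known = 10,
                                                        n_candidates = 3)),
               "functional module")
})
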