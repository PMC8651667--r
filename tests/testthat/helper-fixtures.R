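# Shared fixture builders; everything is generated in code at test time.

tiny_counts <- function() {
  m <- matrix(c(100, 200,
                10, 20,
                40, 80), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  m
}

make_meta <- function(samples, batch, timepoint, condition,
                      replicate = seq_along(samples)) {
  validate_sample_metadata(data.frame(
    sample_id = samples, batch = batch, timepoint = timepoint,
    condition = condition, replicate = replicate, stringsAsFactors = FALSE))
}

# two-timepoint 6v6 design used by the DE and batch criteria
flat_config <- function(seed, n_genes = 2000, reps = 6, batches = 1,
                        batch_mean = 1, batch_disp = 1) {
  tp <- c("E14", "P10"); cond <- c("embryonic", "postnatal")
  simulate_config(n_genes = n_genes, timepoints = tp, conditions = cond,
                  replicates_per_timepoint = reps, n_batches = batches,
                  batch_mean_factor = rep_len(batch_mean, batches),
                  batch_disp_factor = rep_len(batch_disp, batches),
                  patterns = list(flat = pattern_flat(tp, cond)),
                  module_spec = c(flat = n_genes),
                  functional_module = list(pattern = "flat", n_known = 0,
                                           n_candidates = 0),
                  dispersion = 0.1, seed = seed)
}

step_config <- function(seed, n_genes = 2000, n_de = 200, reps = 6,
                        batches = 1, batch_mean = 1, fold = 4) {
  tp <- c("E14", "P10"); cond <- c("embryonic", "postnatal")
  simulate_config(n_genes = n_genes, timepoints = tp, conditions = cond,
                  replicates_per_timepoint = reps, n_batches = batches,
                  batch_mean_factor = rep_len(batch_mean, batches),
                  batch_disp_factor = rep_len(1, batches),
                  patterns = list(step = pattern_step(tp, cond, fold = fold),
                                  flat = pattern_flat(tp, cond)),
                  module_spec = c(step = n_de, flat = n_genes - n_de),
                  functional_module = list(pattern = "step", n_known = 0,
                                           n_candidates = 0),
                  dispersion = 0.1, seed = seed)
}

# O(m^2) step-up oracle: padj_i = min over p_(i') >= p_i of p_(i') * m / i'
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) ps[j] * m / j, 0)
    adj[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive-enumeration oracle for the hypergeometric upper tail: draw every
# n-subset of an N-universe whose first K elements are annotated
hypergeom_oracle <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k == 0))
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# pairwise-distance form of the within-cluster dispersion
within_dispersion_pairwise <- function(X, labels) {
  total <- 0
  for (l in unique(labels)) {
    idx <- which(labels == l)
    if (length(idx) == 1L) next
    D <- as.matrix(stats::dist(X[idx, , drop = FALSE]))^2
    total <- total + sum(D) / (2 * length(idx))
  }
  total
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
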