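## Seeded generator of multi-batch temporal negative-binomial count datasets
## with planted pattern modules, planted known/candidate genes, matching
## evidence and gene-set tables, and full ground truth.
##
## NB parameterization: mean mu, dispersion alpha, variance mu + alpha*mu^2
## (the convention the DE stage uses); batch effects are multiplicative on the
## mean and on the dispersion, giving the batch-correction stage both moments
## to remove.

#' Temporal pattern builders
#'
#' Each builder returns a vector of multiplicative mean factors, one per
#' timepoint, describing a temporal expression trajectory:
#' `pattern_flat()` is constant; `pattern_rising()` is a sigmoid that starts
#' rising at the condition boundary and saturates (peaks) at `peak`;
#' `pattern_falling()` is its mirror image; `pattern_transient()` is a
#' Gaussian bump centred on `center`; `pattern_step()` multiplies all
#' postnatal timepoints by `fold` (a pure condition effect).
#'
#' @param timepoints character vector of ordered timepoint labels.
#' @param conditions condition (`embryonic`/`postnatal`) per timepoint.
#' @param fold maximum fold change of the pattern relative to baseline.
#' @param peak,center timepoint label where the pattern peaks/centres.
#' @param width width (in timepoint index units) of the transient bump.
#' @return numeric vector of positive factors, one per timepoint.
#' @name patterns
NULL

#' @rdname patterns
#' @export
pattern_flat <- function(timepoints, conditions) rep(1, length(timepoints))

#' @rdname patterns
#' @export
pattern_rising <- function(timepoints, conditions, peak = "P10", fold = 6) {
  i <- seq_along(timepoints)
  i_peak <- match(peak, timepoints)
  if (is.na(i_peak)) stop("peak timepoint '", peak, "' not in timepoints")
  i_start <- match("postnatal", conditions)     # rise begins at birth
  if (is.na(i_start)) i_start <- ceiling(length(i) / 2)
  mid <- (i_start + i_peak) / 2
  sc <- max((i_peak - i_start) / 4, 0.5)
  1 + (fold - 1) / (1 + exp(-(i - mid) / sc))
}

#' @rdname patterns
#' @export
pattern_falling <- function(timepoints, conditions, fold = 6) {
  r <- pattern_rising(timepoints, conditions, peak = timepoints[
    which(conditions == "postnatal")[min(3, sum(conditions == "postnatal"))]],
    fold = fold)
  (fold + 1) - r
}

#' @rdname patterns
#' @export
pattern_transient <- function(timepoints, conditions, center = NULL, width = 1.5,
                              fold = 5) {
  i <- seq_along(timepoints)
  ic <- if (is.null(center)) match("postnatal", conditions)
        else match(center, timepoints)
  if (is.na(ic)) stop("center timepoint not in timepoints")
  1 + (fold - 1) * exp(-(i - ic)^2 / (2 * width^2))
}

#' @rdname patterns
#' @export
pattern_step <- function(timepoints, conditions, fold = 4) {
  ifelse(conditions == "postnatal", fold, 1)
}

#' Build a simulation configuration
#'
#' Defaults emulate the combined mouse retinal development design the
#' pipeline was built around: 12 timepoints (E11--E16 embryonic, P0--P28
#' postnatal), 2 replicates per timepoint, 2 batches crossing the conditions,
#' NB dispersion 0.1, modest multiplicative batch effects, and a functional
#' module of rising genes peaking at P10--P14 that carries known genes plus
#' planted unannotated candidates.
#'
#' @param n_genes total number of genes; module gene counts must sum to it.
#' @param timepoints ordered timepoint labels.
#' @param conditions condition label per timepoint (`embryonic`/`postnatal`).
#' @param replicates_per_timepoint replicates at each timepoint.
#' @param n_batches number of batches; replicate r is assigned to batch
#'   `((r-1) %% n_batches) + 1`, so batches cross timepoints and conditions.
#' @param batch_mean_factor multiplicative batch effect on the NB mean, one
#'   per batch.
#' @param batch_disp_factor multiplicative batch effect on the NB dispersion.
#' @param patterns named list of pattern factor vectors (see [patterns]); by
#'   default rising/falling/transient/flat trajectories over `timepoints`.
#' @param module_spec named integer vector: genes per pattern; must sum to
#'   `n_genes`.
#' @param functional_module list with `pattern` (a name in `patterns`),
#'   `n_known` and `n_candidates`: known and planted-candidate genes inside
#'   that pattern module.
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of the
#'   per-gene baseline mean.
#' @param dispersion per-gene NB dispersion alpha (scalar, recycled).
#' @param length_meanlog,length_sdlog log-normal parameters of gene length in
#'   bp (floored at 200).
#' @param n_decoy_sets,decoy_set_size decoy gene sets drawn at random from all
#'   genes, to exercise enrichment specificity.
#' @param seed global seed; per-stream sub-seeds are derived from it.
#' @return object of class `sim_config`.
#' @export
simulate_config <- function(n_genes = 500,
                            timepoints = c("E11", "E12", "E14", "E16", "P0", "P2",
                                           "P4", "P6", "P10", "P14", "P21", "P28"),
                            conditions = rep(c("embryonic", "postnatal"), c(4, 8)),
                            replicates_per_timepoint = 2,
                            n_batches = 2,
                            batch_mean_factor = c(1, 1.5),
                            batch_disp_factor = c(1, 1.25),
                            patterns = NULL,
                            module_spec = NULL,
                            functional_module = list(pattern = "rising",
                                                     n_known = 10, n_candidates = 3),
                            base_mean_meanlog = 4, base_mean_sdlog = 1,
                            dispersion = 0.1,
                            length_meanlog = 7.5, length_sdlog = 0.6,
                            n_decoy_sets = 15, decoy_set_size = 30,
                            seed = 1) {
  stopifnot(length(conditions) == length(timepoints),
            all(conditions %in% c("embryonic", "postnatal")),
            replicates_per_timepoint >= 1, n_batches >= 1,
            length(batch_mean_factor) == n_batches,
            length(batch_disp_factor) == n_batches,
            all(batch_mean_factor > 0), all(batch_disp_factor > 0),
            all(dispersion >= 0))
  if (is.null(patterns)) {
    patterns <- list(
      rising    = pattern_rising(timepoints, conditions, peak = "P10", fold = 6),
      falling   = pattern_falling(timepoints, conditions, fold = 6),
      transient = pattern_transient(timepoints, conditions, fold = 5),
      flat      = pattern_flat(timepoints, conditions))
  }
  if (is.null(module_spec)) {
    base <- c(rising = 60, falling = 100, transient = 80)
    base <- base[names(base) %in% names(patterns)]
    module_spec <- c(base, flat = n_genes - sum(base))
  }
  if (sum(module_spec) != n_genes)
    stop("module_spec gene counts sum to ", sum(module_spec),
         ", expected n_genes = ", n_genes, call. = FALSE)
  if (!all(names(module_spec) %in% names(patterns)))
    stop("module_spec names must be pattern names", call. = FALSE)
  if (!functional_module$pattern %in% names(module_spec))
    stop("functional_module pattern '", functional_module$pattern,
         "' not in module_spec", call. = FALSE)
  n_fun <- functional_module$n_known + functional_module$n_candidates
  if (n_fun > module_spec[[functional_module$pattern]])
    stop("functional module needs ", n_fun, " genes but its pattern module has ",
         module_spec[[functional_module$pattern]], call. = FALSE)
  bad <- vapply(patterns, function(p)
    length(p) != length(timepoints) || any(p <= 0), TRUE)
  if (any(bad))
    stop("pattern(s) with wrong length or non-positive factors: ",
         paste(names(patterns)[bad], collapse = ", "), call. = FALSE)
  structure(list(n_genes = n_genes, timepoints = timepoints,
                 conditions = conditions,
                 replicates_per_timepoint = replicates_per_timepoint,
                 n_batches = n_batches,
                 batch_mean_factor = batch_mean_factor,
                 batch_disp_factor = batch_disp_factor,
                 patterns = patterns, module_spec = module_spec,
                 functional_module = functional_module,
                 base_mean_meanlog = base_mean_meanlog,
                 base_mean_sdlog = base_mean_sdlog,
                 dispersion = dispersion,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 n_decoy_sets = n_decoy_sets, decoy_set_size = decoy_set_size,
                 seed = seed),
            class = "sim_config")
}

# NB draws in the (mu, alpha) parameterization; alpha = 0 falls back to Poisson.
rnbinom_mu_alpha <- function(n, mu, alpha) {
  out <- numeric(n)
  pois <- alpha <= 1e-12
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                               size = 1 / alpha[!pois])
  out
}

#' Simulate a complete multi-batch temporal dataset with ground truth
#'
#' Counts are drawn as `NB(mean = mu_g * f_pattern(t) * b_mean(batch),
#' dispersion = alpha_g * b_disp(batch))`.  The functional module's known
#' genes receive positive literature hits; its planted candidates receive
#' zero hits with positive expression evidence; a gene set containing exactly
#' the module's known + candidate genes is emitted alongside random decoy
#' sets.
#'
#' @param config a [simulate_config()] object.
#' @return list of class `fundisc_sim` with elements `counts`, `meta`,
#'   `annotation`, `gene_sets`, `known`, `evidence`, `truth` (data.frame with
#'   per-gene pattern, role, `is_de`) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tp <- config$timepoints
  cond <- config$conditions
  R <- config$replicates_per_timepoint

  meta <- do.call(rbind, lapply(seq_along(tp), function(i) {
    data.frame(sample_id = sprintf("%s_r%d", tp[i], seq_len(R)),
               batch = sprintf("B%d", ((seq_len(R) - 1L) %% config$n_batches) + 1L),
               timepoint = tp[i], condition = cond[i], replicate = seq_len(R),
               stringsAsFactors = FALSE)
  }))
  meta <- validate_sample_metadata(meta)

  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  pattern_of <- rep(names(config$module_spec), config$module_spec)

  role <- rep("background", n)
  fun_idx <- which(pattern_of == config$functional_module$pattern)
  kn <- config$functional_module$n_known
  nc <- config$functional_module$n_candidates
  role[fun_idx[seq_len(kn)]] <- "known"
  if (nc > 0) role[fun_idx[kn + seq_len(nc)]] <- "planted_candidate"

  mu0 <- with_seed(stream_seed(config$seed, "basemean"), {
    m <- stats::rlnorm(n, config$base_mean_meanlog, config$base_mean_sdlog)
    # the planted functional module mimics highly expressed structural genes
    # (photoreceptor OS genes are among the most abundant retinal transcripts)
    planted <- role != "background"
    m[planted] <- stats::rlnorm(sum(planted), config$base_mean_meanlog + 2, 0.5)
    m
  })
  alpha <- rep_len(config$dispersion, n)
  lengths_bp <- with_seed(stream_seed(config$seed, "lengths"),
                          pmax(200L, as.integer(round(
                            stats::rlnorm(n, config$length_meanlog,
                                          config$length_sdlog)))))

  tp_index <- match(meta$timepoint, tp)
  batch_index <- as.integer(sub("^B", "", meta$batch))
  pattern_mat <- do.call(rbind, config$patterns)   # pattern x timepoint

  counts <- with_seed(stream_seed(config$seed, "counts"), {
    m <- matrix(0, n, nrow(meta), dimnames = list(genes, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      fac <- pattern_mat[pattern_of, tp_index[j]]
      mu <- mu0 * fac * config$batch_mean_factor[batch_index[j]]
      m[, j] <- rnbinom_mu_alpha(n, mu, alpha * config$batch_disp_factor[batch_index[j]])
    }
    m
  })

  # a gene is DE if its pattern shifts the condition means by >= 1.5x
  de_pattern <- vapply(config$patterns, function(p) {
    r <- mean(p[cond == "postnatal"]) / mean(p[cond == "embryonic"])
    r >= 1.5 || r <= 1 / 1.5
  }, TRUE)
  truth <- data.frame(gene_id = genes, pattern = pattern_of, role = role,
                      is_de = de_pattern[pattern_of], stringsAsFactors = FALSE)

  annotation <- data.frame(gene_id = genes, symbol = toupper(genes),
                           length_bp = lengths_bp, stringsAsFactors = FALSE)

  known <- structure(genes[role == "known"], provenance = "simulated")
  candidates <- genes[role == "planted_candidate"]

  evidence <- with_seed(stream_seed(config$seed, "evidence"), {
    hits <- integer(n); expr <- logical(n)
    bg <- role == "background"
    documented <- stats::runif(n) < 0.8
    hits[bg & documented] <- stats::rpois(sum(bg & documented), 3) + 1L
    expr[bg] <- documented[bg]            # undocumented background lacks
    hits[role == "known"] <- stats::rpois(sum(role == "known"), 10) + 1L
    expr[role == "known"] <- TRUE         # expression evidence, so it never
    hits[role == "planted_candidate"] <- 0L   # qualifies as a candidate
    expr[role == "planted_candidate"] <- TRUE
    data.frame(gene_id = genes, literature_hits = hits,
               expression_evidence = expr, stringsAsFactors = FALSE)
  })

  sets <- list("GO:F0001" = list(name = "outer segment module",
                                 namespace = "CC",
                                 genes = c(known, candidates)))
  decoys <- with_seed(stream_seed(config$seed, "decoys"), {
    lapply(seq_len(config$n_decoy_sets), function(i)
      sort(sample(genes, min(config$decoy_set_size, n))))
  })
  ns_cycle <- c("BP", "CC", "MF")
  for (i in seq_along(decoys)) {
    sets[[sprintf("GO:D%04d", i)]] <- list(
      name = sprintf("decoy set %d", i),
      namespace = ns_cycle[(i - 1L) %% 3L + 1L],
      genes = decoys[[i]])
  }

  structure(list(counts = counts, meta = meta, annotation = annotation,
                 gene_sets = structure(sets, class = "gene_set_collection"),
                 known = known, evidence = evidence, truth = truth,
                 config = config),
            class = "fundisc_sim")
}

#' @export
print.fundisc_sim <- function(x, ...) {
  cat("fundisc_sim:", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      length(unique(x$meta$timepoint)), "timepoints,",
      length(unique(x$meta$batch)), "batches\n")
  cat("  roles:", paste(names(table(x$truth$role)), as.integer(table(x$truth$role)),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated dataset as a fixture directory
#'
#' Emits the seven plain-text files the pipeline readers consume plus the
#' ground truth: `counts.tsv`, `meta.tsv`, `annotation.tsv`, `gene_sets.gmt`,
#' `known_genes.txt`, `evidence.tsv`, `truth.tsv`.
#'
#' @param sim a `fundisc_sim` object.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "fundisc_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    meta = file.path(dir, "meta.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    known = file.path(dir, "known_genes.txt"),
    evidence = file.path(dir, "evidence.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_count_matrix(sim$counts, paths["counts"])
  write_tsv(sim$meta, paths["meta"])
  write_tsv(sim$annotation, paths["annotation"])
  write_gene_sets(sim$gene_sets, paths["gene_sets"])
  writeLines(as.character(sim$known), paths["known"])
  write_tsv(data.frame(gene_id = sim$evidence$gene_id,
                       literature_hits = sim$evidence$literature_hits,
                       expression_evidence = tolower(sim$evidence$expression_evidence)),
            paths["evidence"])
  write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Simulate z-score temporal profiles with a planted cluster number
#'
#' Generates gene-by-timepoint profile matrices for validating cluster-number
#' selection: `k_true` well-separated base trajectories (z-scored), plus iid
#' Gaussian noise of standard deviation `noise_sd` per timepoint.
#'
#' @param n_genes number of profiles.
#' @param k_true number of planted clusters (2--6).
#' @param n_timepoints profile length.
#' @param noise_sd per-coordinate noise standard deviation; the planted
#'   trajectories are separated by pairwise distances well above `4 * noise_sd`.
#' @param seed RNG seed.
#' @return list with `X` (matrix) and `labels` (true cluster per gene).
#' @export
simulate_profiles <- function(n_genes = 300, k_true = 5, n_timepoints = 12,
                              noise_sd = 0.25, seed = 1) {
  stopifnot(k_true >= 2, k_true <= 6, n_timepoints >= 4)
  t <- seq(0, 1, length.out = n_timepoints)
  shapes <- list(
    t,                                    # rising ramp
    1 - t,                                # falling ramp
    exp(-(t - 0.25)^2 / 0.02),            # early transient
    exp(-(t - 0.75)^2 / 0.02),            # late transient
    sin(2 * pi * t),                      # one oscillation
    abs(t - 0.5))                         # V shape
  zshape <- function(v) (v - mean(v)) / stats::sd(v)
  centers <- do.call(rbind, lapply(shapes[seq_len(k_true)], zshape))
  labels <- rep(seq_len(k_true), length.out = n_genes)
  X <- with_seed(seed, centers[labels, , drop = FALSE] +
                   matrix(stats::rnorm(n_genes * n_timepoints, sd = noise_sd),
                          n_genes, n_timepoints))
  rownames(X) <- sprintf("g%05d", seq_len(n_genes))
  list(X = X, labels = labels)
}
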