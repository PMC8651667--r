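## End-to-end orchestration: batch correction -> DE -> top DEGs -> TPM ->
## median/z profiles -> gap statistic -> clustering -> enrichment ->
## discovery, with per-stage TSV artifacts and a deterministic run manifest.

#' Build a pipeline configuration
#'
#' Inputs may be in-memory objects or file paths (loaded through the package
#' readers at run time).
#'
#' @param counts count matrix or path to a counts TSV.
#' @param meta sample metadata or path.
#' @param annotation gene annotation or path.
#' @param gene_sets `gene_set_collection` or GMT path.
#' @param known known-gene vector or path.
#' @param evidence evidence table or path.
#' @param target_terms term ids defining the target function for discovery.
#' @param out_dir artifact directory.
#' @param skip_batch_correction pass counts through unadjusted (for
#'   single-batch or already-corrected data).
#' @param include_condition keep condition as a covariate in the batch model.
#' @param n_top,de_alpha,rank_by DEG selection (defaults 3000, 0.05, pvalue).
#' @param K fixed cluster number; when NULL it is selected by the gap
#'   statistic.
#' @param kmax,gap_B,gap_rule,gap_clusterer gap-statistic parameters
#'   (defaults 100, 50, tibshirani_1se, kmeans).
#' @param cluster_method final assignment method (default hierarchical).
#' @param universe_mode,set_min,set_max,enrich_alpha enrichment parameters.
#' @param rising_only restrict functional clusters to rising temporal trends.
#' @param seed global seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, meta, annotation, gene_sets, known,
                            evidence, target_terms, out_dir,
                            skip_batch_correction = FALSE,
                            include_condition = TRUE,
                            n_top = 3000, de_alpha = 0.05,
                            rank_by = c("pvalue", "padj"),
                            K = NULL, kmax = 100, gap_B = 50,
                            gap_rule = c("tibshirani_1se", "global_max"),
                            gap_clusterer = c("kmeans", "hierarchical"),
                            cluster_method = c("hierarchical", "kmeans"),
                            universe_mode = c("all_annotated", "degs_in_sets",
                                              "all_genes"),
                            set_min = 10, set_max = 500, enrich_alpha = 0.05,
                            rising_only = FALSE, seed = 1) {
  structure(list(counts = counts, meta = meta, annotation = annotation,
                 gene_sets = gene_sets, known = known, evidence = evidence,
                 target_terms = target_terms, out_dir = out_dir,
                 skip_batch_correction = isTRUE(skip_batch_correction),
                 include_condition = isTRUE(include_condition),
                 n_top = n_top, de_alpha = de_alpha,
                 rank_by = match.arg(rank_by),
                 K = K, kmax = kmax, gap_B = gap_B,
                 gap_rule = match.arg(gap_rule),
                 gap_clusterer = match.arg(gap_clusterer),
                 cluster_method = match.arg(cluster_method),
                 universe_mode = match.arg(universe_mode),
                 set_min = set_min, set_max = set_max,
                 enrich_alpha = enrich_alpha,
                 rising_only = isTRUE(rising_only), seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; relative input paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return `pipeline_config` with path-valued inputs.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || !is.character(p)) return(p)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (key in c("counts", "meta", "annotation", "gene_sets", "known",
                "evidence"))
    y[[key]] <- resolve(y[[key]])
  if (!is.null(y$out_dir)) y$out_dir <- resolve(y$out_dir)
  do.call(pipeline_config, y)
}

load_input <- function(x, reader) if (is.character(x) && length(x) == 1L) reader(x) else x

md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

write_matrix_tsv <- function(m, path, id_column = "gene_id", digits = 6) {
  df <- data.frame(rownames(m), signif(m, digits), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(m))
  write_tsv(df, path)
}

#' Run the full discovery pipeline
#'
#' Executes every stage in order and writes one artifact file per stage plus
#' `manifest.json` (config hash, seed, per-file checksums; byte-identical
#' across reruns with the same configuration and seed) and `run.log`.  A
#' stage failure aborts with the stage name and leaves a `FAILED` marker next
#' to the partial artifacts.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results of every stage and
#'   the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(line)
    cat(line, "\n", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    say("stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  artifacts <- character()
  emit <- function(name, path) artifacts[[name]] <<- path

  inputs <- stage("load_inputs", {
    counts <- load_input(config$counts, read_count_matrix)
    validate_count_matrix(counts)
    meta <- validate_sample_metadata(load_input(config$meta, read_sample_metadata))
    check_paired(counts, meta)
    list(counts = counts, meta = meta,
         annotation = load_input(config$annotation, read_gene_annotation),
         gene_sets = load_input(config$gene_sets, read_gene_sets),
         known = load_input(config$known, read_known_genes),
         evidence = load_input(config$evidence, read_evidence))
  })

  adjusted <- stage("batch_correction", {
    if (config$skip_batch_correction ||
        length(unique(inputs$meta$batch)) == 1L) {
      say("  batch correction skipped")
      inputs$counts
    } else {
      model <- fit_batch_model(inputs$counts, inputs$meta,
                               include_condition = config$include_condition)
      adjust_counts(inputs$counts, model)
    }
  })
  p <- file.path(config$out_dir, "adjusted_counts.tsv")
  write_count_matrix(adjusted, p); emit("adjusted_counts", p)

  de <- stage("differential_expression", wald_de(adjusted, inputs$meta))
  p <- file.path(config$out_dir, "de_results.tsv")
  write_tsv(format(de, digits = 8, scientific = TRUE, trim = TRUE), p)
  emit("de_results", p)

  top <- stage("top_degs",
               top_degs(de, n = config$n_top, alpha = config$de_alpha,
                        rank_by = config$rank_by))
  p <- file.path(config$out_dir, "top_degs.txt")
  writeLines(top, p); emit("top_degs", p)
  say("  ", length(top), " DEGs selected")

  profs <- stage("normalize_profiles", {
    tpm_all <- tpm(adjusted, inputs$annotation)
    tpm_top <- tpm_all[top, , drop = FALSE]
    med <- median_profiles(tpm_top, inputs$meta)
    z <- zscore_profiles(med)
    list(tpm = tpm_top, median = med, z = z)
  })
  p <- file.path(config$out_dir, "tpm.tsv")
  write_matrix_tsv(profs$tpm, p); emit("tpm", p)
  p <- file.path(config$out_dir, "profiles_median_tpm.tsv")
  write_matrix_tsv(profs$median, p); emit("profiles_median", p)
  p <- file.path(config$out_dir, "profiles_zscore.tsv")
  write_matrix_tsv(unclass(profs$z), p); emit("profiles_zscore", p)

  gap <- NULL
  K <- config$K
  if (is.null(K)) {
    gap <- stage("gap_statistic",
                 gap_statistic(profs$z,
                               gap_config(kmax = config$kmax, B = config$gap_B,
                                          clusterer = config$gap_clusterer,
                                          rule = config$gap_rule,
                                          seed = config$seed)))
    K <- select_k(gap, rule = config$gap_rule)
    say("  selected K = ", K)
  } else say("  using user-supplied K = ", K)
  if (!is.null(gap)) {
    p <- file.path(config$out_dir, "gap_curve.tsv")
    write_tsv(format(gap, digits = 8, trim = TRUE), p); emit("gap_curve", p)
  }

  assignment <- stage("clustering",
                      assign_clusters(profs$z, K, method = config$cluster_method,
                                      seed = config$seed))
  p <- file.path(config$out_dir, "cluster_assignment.tsv")
  write_tsv(data.frame(gene_id = names(assignment$labels),
                       cluster = as.integer(assignment$labels)), p)
  emit("cluster_assignment", p)
  p <- file.path(config$out_dir, "cluster_profiles.tsv")
  write_matrix_tsv(cluster_profiles(assignment, profs$z), p, id_column = "cluster")
  emit("cluster_profiles", p)

  enr <- stage("enrichment", {
    universe <- enrichment_universe(rownames(profs$z), inputs$gene_sets,
                                    mode = config$universe_mode)
    enrich_clusters(assignment, universe, inputs$gene_sets,
                    min_set = config$set_min, max_set = config$set_max)
  })
  p <- file.path(config$out_dir, "enrichment.tsv")
  write_tsv(format(enr, digits = 8, scientific = TRUE, trim = TRUE), p)
  emit("enrichment", p)

  report <- stage("discovery", {
    fc <- designate_functional_clusters(assignment, inputs$known, enr,
                                        target_terms = config$target_terms,
                                        alpha = config$enrich_alpha,
                                        sets = inputs$gene_sets,
                                        rising_only = config$rising_only,
                                        profiles = profs$z, meta = inputs$meta)
    rep <- predict_candidates(fc, assignment, inputs$known, inputs$evidence)
    rank_candidates(rep, profs$z, inputs$meta)
  })
  p <- file.path(config$out_dir, "functional_clusters.tsv")
  write_tsv(report$functional_clusters, p); emit("functional_clusters", p)
  p <- file.path(config$out_dir, "known_matches.tsv")
  write_tsv(cross_reference_known(assignment, inputs$known), p)
  emit("known_matches", p)
  p <- file.path(config$out_dir, "candidates.tsv")
  write_tsv(report$candidates, p); emit("candidates", p)
  say("  ", nrow(report$candidates), " candidate(s) predicted from ",
      nrow(report$functional_clusters), " functional cluster(s)")

  manifest <- list(
    tool = "fundisc",
    seed = config$seed,
    config_hash = md5_of_object(config[setdiff(names(config), "out_dir")]),
    selected_K = as.integer(K),
    files = as.list(vapply(artifacts, function(f) unname(tools::md5sum(f)), "")))
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  say("pipeline complete: ", length(artifacts) + 1L, " artifacts in ",
      config$out_dir)

  invisible(list(inputs = inputs, adjusted = adjusted, de = de, top = top,
                 profiles = profs, gap = gap, K = K, assignment = assignment,
                 enrichment = enr, report = report,
                 artifacts = c(artifacts, manifest = mp)))
}
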