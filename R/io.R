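## Readers and writers for every external table the pipeline touches.
## All tables are TSV with a header row, UTF-8, no quoting (featureCounts/GEO
## matrix conventions).  Gene identity is matched case-sensitively on gene_id;
## symbols are display-only.

split_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  strsplit(lines, "\t", fixed = TRUE)
}

#' Validate a gene-by-sample count matrix
#'
#' Checks the count-matrix contract: a numeric matrix of non-negative
#' integer-valued counts with unique, non-missing gene row names and sample
#' column names.
#'
#' @param counts matrix to validate.
#' @return the matrix, invisibly, with storage mode coerced to integer-valued
#'   numeric; an error describes the first violated invariant.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integer-valued", call. = FALSE)
  invisible(counts)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' The file has a header row of sample identifiers and a first column of gene
#' identifiers; every remaining cell must be a non-negative integer.  Row and
#' column order is preserved.
#'
#' @param path path to a tab-separated count matrix.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  rows <- split_tsv_lines(path)
  header <- rows[[1]]
  samples <- header[-1]
  if (length(samples) == 0L) stop("count matrix has no sample columns", call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample ids in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  body <- rows[-1]
  genes <- vapply(body, `[`, "", 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  mat <- matrix(0, nrow = length(body), ncol = length(samples),
                dimnames = list(genes, samples))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1]
    if (length(cells) != length(samples))
      stop("row ", i + 1L, " (", genes[i], ") has ", length(cells),
           " cells, expected ", length(samples), call. = FALSE)
    bad <- !grepl("^[0-9]+$", cells)
    if (any(bad))
      stop("non-integer count at gene '", genes[i], "', sample '",
           samples[which(bad)[1]], "': '", cells[which(bad)[1]], "'",
           call. = FALSE)
    mat[i, ] <- as.numeric(cells)
  }
  validate_count_matrix(mat)
  mat
}

#' Write a count matrix as TSV
#'
#' @param counts validated count matrix.
#' @param path output file path.
#' @param id_column name for the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, id_column = "gene_id") {
  validate_count_matrix(counts)
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write_tsv(df, path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, required) {
  rows <- split_tsv_lines(path)
  header <- rows[[1]]
  missing <- setdiff(required, header)
  if (length(missing) > 0L)
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  body <- rows[-1]
  if (length(body) == 0L) stop("no data rows in ", path, call. = FALSE)
  cells <- lapply(seq_along(header), function(j)
    vapply(body, function(r) if (length(r) >= j) r[[j]] else NA_character_, ""))
  df <- as.data.frame(cells, col.names = header, stringsAsFactors = FALSE,
                      check.names = FALSE)
  df
}

#' Read and validate a sample metadata table
#'
#' Expects TSV columns `sample_id`, `batch`, `timepoint`, `condition`,
#' `replicate`.  Conditions are restricted to `embryonic`/`postnatal`, each
#' timepoint must map to exactly one condition, and every field must be
#' non-empty.  Timepoints keep their order of first appearance (developmental
#' order in well-formed inputs).
#'
#' @param path path to the metadata TSV.
#' @return data.frame with the five columns; `replicate` integer; timepoint
#'   level order stored in `attr(, "timepoints")`.
#' @export
read_sample_metadata <- function(path) {
  df <- read_tsv(path, c("sample_id", "batch", "timepoint", "condition", "replicate"))
  df <- df[c("sample_id", "batch", "timepoint", "condition", "replicate")]
  validate_sample_metadata(df)
}

#' Validate sample metadata
#'
#' @param meta data.frame with columns `sample_id`, `batch`, `timepoint`,
#'   `condition`, `replicate`.
#' @return the validated data.frame (replicate coerced to integer).
#' @export
validate_sample_metadata <- function(meta) {
  req <- c("sample_id", "batch", "timepoint", "condition", "replicate")
  missing <- setdiff(req, colnames(meta))
  if (length(missing) > 0L)
    stop("metadata missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  for (cl in req) {
    v <- meta[[cl]]
    if (anyNA(v) || any(!nzchar(as.character(v))))
      stop("metadata column '", cl, "' has missing values", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(meta$condition), c("embryonic", "postnatal"))
  if (length(bad) > 0L)
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (expected embryonic/postnatal)", call. = FALSE)
  tab <- unique(meta[c("timepoint", "condition")])
  dup <- tab$timepoint[duplicated(tab$timepoint)]
  if (length(dup) > 0L)
    stop("timepoint(s) mapped to two conditions: ", paste(dup, collapse = ", "),
         call. = FALSE)
  rep_num <- suppressWarnings(as.integer(as.character(meta$replicate)))
  if (anyNA(rep_num)) stop("replicate must be integer", call. = FALSE)
  meta$replicate <- rep_num
  attr(meta, "timepoints") <- unique(as.character(meta$timepoint))
  meta
}

# Check that a count matrix and metadata describe the same samples.
check_paired <- function(counts, meta) {
  if (!setequal(colnames(counts), meta$sample_id))
    stop("count matrix samples and metadata sample_id differ: counts-only {",
         paste(setdiff(colnames(counts), meta$sample_id), collapse = ", "),
         "}, metadata-only {",
         paste(setdiff(meta$sample_id, colnames(counts)), collapse = ", "), "}",
         call. = FALSE)
  invisible(TRUE)
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `symbol`, `length_bp` (union-exon length in
#' base pairs, used for TPM).
#'
#' @param path path to the annotation TSV.
#' @return data.frame with unique `gene_id` and integer `length_bp >= 1`.
#' @export
read_gene_annotation <- function(path) {
  df <- read_tsv(path, c("gene_id", "symbol", "length_bp"))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
         call. = FALSE)
  len <- suppressWarnings(as.numeric(df$length_bp))
  if (anyNA(len) || any(len < 1) || any(len != round(len)))
    stop("length_bp must be a positive integer for every gene", call. = FALSE)
  df$length_bp <- as.integer(len)
  df[c("gene_id", "symbol", "length_bp")]
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' The namespace (BP/CC/MF) is encoded as a `NS|name` description prefix.
#' Terms with no member genes are dropped with a warning.
#'
#' @param path path to the GMT file.
#' @return a `gene_set_collection`: named list of `list(name, namespace, genes)`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      stop("malformed GMT line ", i, ": fewer than 2 fields", call. = FALSE)
    term <- f[1]
    if (term %in% names(sets))
      stop("duplicate term_id '", term, "' at GMT line ", i, call. = FALSE)
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(genes) == 0L) {
      warning("dropping gene set '", term, "' (no member genes)", call. = FALSE)
      next
    }
    desc <- f[2]
    ns <- "BP"
    name <- desc
    if (grepl("^(BP|CC|MF)\\|", desc)) {
      ns <- sub("\\|.*$", "", desc)
      name <- sub("^(BP|CC|MF)\\|", "", desc)
    }
    sets[[term]] <- list(name = name, namespace = ns, genes = genes)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write gene sets to GMT
#'
#' @param sets a `gene_set_collection`.
#' @param path output path; descriptions are written as `NS|name`.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    s <- sets[[id]]
    paste(c(id, paste0(s$namespace, "|", s$name), s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  ns <- table(vapply(x, `[[`, "", "namespace"))
  cat("gene_set_collection:", length(x), "terms (",
      paste(names(ns), as.integer(ns), sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Read a known functional gene list
#'
#' One gene identifier per line; duplicates removed, case preserved.
#'
#' @param path path to the plain-text list.
#' @return character vector of unique gene ids with a `provenance` attribute.
#' @export
read_known_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  genes <- unique(lines[nzchar(lines)])
  if (length(genes) == 0L) stop("empty known-gene list: ", path, call. = FALSE)
  structure(genes, provenance = basename(path))
}

#' Read a literature/expression evidence table
#'
#' TSV with columns `gene_id`, `literature_hits` (non-negative integer) and
#' `expression_evidence` (true/false).  One row per gene.  Genes absent from
#' the table are treated downstream as documented (never candidates).
#'
#' @param path path to the evidence TSV.
#' @return data.frame with integer `literature_hits` and logical
#'   `expression_evidence`.
#' @export
read_evidence <- function(path) {
  df <- read_tsv(path, c("gene_id", "literature_hits", "expression_evidence"))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in evidence table: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
         call. = FALSE)
  hits <- suppressWarnings(as.numeric(df$literature_hits))
  if (anyNA(hits) || any(hits < 0) || any(hits != round(hits)))
    stop("literature_hits must be a non-negative integer", call. = FALSE)
  flag <- tolower(as.character(df$expression_evidence))
  if (!all(flag %in% c("true", "false", "1", "0")))
    stop("expression_evidence must be true/false", call. = FALSE)
  data.frame(gene_id = df$gene_id,
             literature_hits = as.integer(hits),
             expression_evidence = flag %in% c("true", "1"),
             stringsAsFactors = FALSE)
}
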