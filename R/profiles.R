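## Temporal profile construction: TPM, per-timepoint medians over replicates,
## and per-gene z-scores.

#' Transcripts per million
#'
#' `TPM_gj = (c_gj / L_g) / sum_h (c_hj / L_h) * 1e6` with `L_g` the
#' union-exon gene length in bp; every column sums to one million.
#'
#' @param counts count matrix.
#' @param annotation gene annotation with `gene_id` and `length_bp` covering
#'   every gene in `counts`.
#' @return gene x sample numeric matrix.
#' @export
tpm <- function(counts, annotation) {
  validate_count_matrix(counts)
  idx <- match(rownames(counts), annotation$gene_id)
  if (anyNA(idx))
    stop("gene(s) missing from annotation: ",
         paste(utils::head(rownames(counts)[is.na(idx)], 10), collapse = ", "),
         call. = FALSE)
  len <- annotation$length_bp[idx]
  rate <- counts / len
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  sweep(rate, 2, tot, "/") * 1e6
}

#' Collapse replicates to per-timepoint medians
#'
#' @param tpm_matrix gene x sample matrix (typically TPM).
#' @param meta sample metadata; columns are grouped by `timepoint` and
#'   ordered by the timepoint order recorded in the metadata.
#' @return gene x timepoint matrix of medians.
#' @export
median_profiles <- function(tpm_matrix, meta) {
  meta <- validate_sample_metadata(meta)
  if (!all(colnames(tpm_matrix) %in% meta$sample_id))
    stop("sample(s) missing from metadata: ",
         paste(setdiff(colnames(tpm_matrix), meta$sample_id), collapse = ", "),
         call. = FALSE)
  tps <- attr(meta, "timepoints")
  meta <- meta[match(colnames(tpm_matrix), meta$sample_id), ]
  tps <- tps[tps %in% meta$timepoint]
  if (length(tps) == 0L) stop("no timepoint has any sample", call. = FALSE)
  out <- vapply(tps, function(tp) {
    j <- which(meta$timepoint == tp)
    apply(tpm_matrix[, j, drop = FALSE], 1, stats::median)
  }, numeric(nrow(tpm_matrix)))
  dimnames(out) <- list(rownames(tpm_matrix), tps)
  out
}

#' Z-score temporal profiles per gene
#'
#' Each gene's profile is centred by its mean and divided by its sample
#' standard deviation (n - 1).  Constant profiles are flagged and set to
#' all-zero rather than dropped, so cluster membership accounting still
#' covers every selected gene.
#'
#' @param profiles gene x timepoint matrix (>= 2 timepoints).
#' @return matrix of class `profile_matrix` with attributes `center`,
#'   `scale` (pre-z mean and sd) and `constant` (logical flag per gene).
#' @export
zscore_profiles <- function(profiles) {
  if (ncol(profiles) < 2L) stop("need >= 2 timepoints to z-score", call. = FALSE)
  ctr <- rowMeans(profiles)
  scl <- apply(profiles, 1, stats::sd)
  constant <- scl < 1e-12
  z <- (profiles - ctr) / ifelse(constant, 1, scl)
  z[constant, ] <- 0
  structure(z, center = ctr, scale = scl, constant = constant,
            class = c("profile_matrix", class(z)))
}
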