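## Two-group differential expression: median-of-ratios size factors, pooled
## within-condition method-of-moments NB dispersion, delta-method Wald test on
## the log2 fold change (postnatal vs embryonic), Benjamini-Hochberg
## adjustment, and top-N DEG selection.
##
## This is a deliberately simple NB Wald pipeline with the baseMean /
## log2FoldChange / lfcSE / pvalue / padj output contract of the standard DE
## tools: no dispersion shrinkage, no outlier filtering, no independent
## filtering.

ALPHA_MIN <- 1e-8

#' Median-of-ratios size factors
#'
#' `s_j = median over reference genes g of c_gj / geomean(c_g.)`, the
#' reference genes being those with positive counts in every sample.
#'
#' @param counts count matrix.
#' @return named positive numeric vector, one per sample.
#' @export
size_factors <- function(counts) {
  validate_count_matrix(counts)
  ref <- rowSums(counts == 0) == 0
  if (!any(ref))
    stop("no gene has positive counts in all samples; filter low-count genes ",
         "or samples before normalization", call. = FALSE)
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  s <- apply(logc, 2, function(col) exp(stats::median(col - loggeo)))
  stopifnot(all(s > 0))
  s
}

#' Pooled within-condition method-of-moments NB dispersion
#'
#' For each condition with at least two replicates, `alpha_c = (var - mean) /
#' mean^2` on size-factor-normalized counts; the per-gene estimate is the
#' degrees-of-freedom-weighted mean over conditions.  Because the gene-wise
#' moment estimator is very noisy at typical replicate numbers (which makes a
#' plug-in Wald test anticonservative), it is moderated toward the
#' across-gene mean dispersion with `prior_df` pseudo-degrees of freedom
#' before flooring at `1e-8`; `prior_df = 0` gives the raw gene-wise
#' estimate.
#'
#' @param counts count matrix.
#' @param sf size factors from [size_factors()].
#' @param meta sample metadata.
#' @param prior_df weight (in degrees of freedom) of the across-gene mean
#'   dispersion in the moderated estimate (default 40).
#' @return named per-gene dispersion vector (>= 1e-8).
#' @export
estimate_dispersion <- function(counts, sf, meta, prior_df = 40) {
  meta <- validate_sample_metadata(meta)
  check_paired(counts, meta)
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  norm <- sweep(counts, 2, sf, "/")
  conds <- split(seq_len(ncol(norm)), meta$condition)
  conds <- conds[vapply(conds, length, 1L) >= 2L]
  if (length(conds) == 0L)
    stop("need >= 2 replicates in at least one condition", call. = FALSE)
  num <- 0; den <- 0
  for (j in conds) {
    m <- rowMeans(norm[, j, drop = FALSE])
    v <- apply(norm[, j, drop = FALSE], 1, stats::var)
    a <- ifelse(m > 0, (v - m) / m^2, 0)
    w <- length(j) - 1L
    num <- num + w * a
    den <- den + w
  }
  raw <- num / den
  abar <- mean(raw)
  alpha <- pmax(ALPHA_MIN, (den * raw + prior_df * abar) / (den + prior_df))
  names(alpha) <- rownames(counts)
  alpha
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH over a p-value vector; rejects inputs outside `[0, 1]`.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values (elementwise `>=` input, `<= 1`).
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Wald test for differential expression between conditions
#'
#' Tests postnatal against embryonic samples, pooling timepoints as
#' replicates.  Per gene, `log2FC = log2((m_post + 0.5) / (m_emb + 0.5))` on
#' mean normalized counts; its standard error comes from the delta method
#' with NB variance `mu + alpha * mu^2` on the raw scale; the Wald statistic
#' is referred to a standard normal, and BH adjustment is applied over tested
#' genes.
#'
#' @param counts count matrix.
#' @param meta sample metadata with both conditions present.
#' @param sf size factors; computed from `counts` when NULL.
#' @param dispersions per-gene dispersions; estimated when NULL.
#' @return data.frame (`de_result`) with columns `gene_id`, `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`, `rank`, `tested`.
#'   Genes with no counts anywhere are flagged `tested = FALSE` and carry NA
#'   test fields.
#' @export
wald_de <- function(counts, meta, sf = NULL, dispersions = NULL) {
  validate_count_matrix(counts)
  meta <- validate_sample_metadata(meta)
  check_paired(counts, meta)
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  jA <- which(meta$condition == "embryonic")
  jB <- which(meta$condition == "postnatal")
  if (length(jA) == 0L || length(jB) == 0L)
    stop("both conditions must have at least one sample", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(counts, sf, meta)
  eps <- 0.5

  norm <- sweep(counts, 2, sf, "/")
  mA <- rowMeans(norm[, jA, drop = FALSE])
  mB <- rowMeans(norm[, jB, drop = FALSE])
  baseMean <- rowMeans(norm)
  tested <- baseMean > 0

  # delta-method variance of the mean normalized count per condition, with
  # fitted raw-scale means mu_hat_gj = s_j * m_cond
  var_mean <- function(m, j) {
    muh <- outer(m, sf[j])                       # gene x sample fitted means
    v <- muh + dispersions * muh^2
    rowSums(sweep(v, 2, sf[j]^2, "/")) / length(j)^2
  }
  vA <- var_mean(mA, jA)
  vB <- var_mean(mB, jB)
  log2fc <- log2((mB + eps) / (mA + eps))
  ln2sq <- log(2)^2
  lfcSE <- sqrt(vA / ((mA + eps)^2 * ln2sq) + vB / ((mB + eps)^2 * ln2sq))
  stat <- ifelse(lfcSE > 0, log2fc / lfcSE, 0)
  pvalue <- 2 * stats::pnorm(-abs(stat))

  res <- data.frame(gene_id = rownames(counts), baseMean = baseMean,
                    log2FoldChange = log2fc, lfcSE = lfcSE, stat = stat,
                    pvalue = pvalue, padj = NA_real_, rank = NA_integer_,
                    tested = tested, stringsAsFactors = FALSE)
  res$log2FoldChange[!tested] <- NA_real_
  res$lfcSE[!tested] <- NA_real_
  res$stat[!tested] <- NA_real_
  res$pvalue[!tested] <- NA_real_
  res$padj[tested] <- bh_adjust(res$pvalue[tested])
  ord <- order(res$pvalue[tested], -abs(res$log2FoldChange[tested]),
               res$gene_id[tested])
  res$rank[tested][ord] <- seq_len(sum(tested))
  class(res) <- c("de_result", "data.frame")
  res
}

#' Select the top-ranked significant DEGs
#'
#' Keeps genes below the significance threshold on the ranking column
#' (default raw p-value, as in a "top 3000 DEGs, p < 0.05" selection), sorts
#' ascending with ties broken by |log2FC| descending then gene id, and
#' truncates to `n`.
#'
#' @param table a [wald_de()] result.
#' @param n maximum number of genes (default 3000).
#' @param alpha significance threshold (default 0.05).
#' @param rank_by `"pvalue"` or `"padj"`.
#' @return character vector of gene ids, best first.
#' @export
top_degs <- function(table, n = 3000, alpha = 0.05, rank_by = c("pvalue", "padj")) {
  rank_by <- match.arg(rank_by)
  tab <- table[table$tested & !is.na(table[[rank_by]]) & table[[rank_by]] < alpha, ]
  ord <- order(tab[[rank_by]], -abs(tab$log2FoldChange), tab$gene_id)
  tab <- tab[ord, ]
  if (nrow(tab) < n)
    message("only ", nrow(tab), " genes pass ", rank_by, " < ", alpha,
            " (requested ", n, ")")
  utils::head(tab$gene_id, n)
}
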