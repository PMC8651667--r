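## Negative-binomial batch correction by quantile mapping.
##
## Per gene, sample means are modelled by a log-link regression on batch and
## (by default) biological condition; per-(gene, batch) NB dispersions are
## fitted by maximum likelihood with a method-of-moments fallback.  Each
## observed count is then mapped through its fitted batch NB CDF (midpoint
## percentile) onto a batch-free target NB whose batch coefficients are
## replaced by a sample-count-weighted pooled offset and whose dispersion is
## the sample-count-weighted pooled batch dispersion.  The mapping is
## deterministic, monotone, integer-preserving and exactly the identity on
## single-batch data.

#' Fit the per-gene per-batch negative-binomial batch model
#'
#' @param counts validated count matrix (genes x samples).
#' @param meta sample metadata paired with `counts` (see
#'   [read_sample_metadata()]).
#' @param include_condition include the embryonic/postnatal condition as a
#'   covariate so biological signal is not absorbed into batch terms
#'   (default TRUE).
#' @return object of class `batch_model`: fitted per-sample means `mu`,
#'   target means `mu_star`, per-(gene, batch) dispersions `alpha`, pooled
#'   target dispersions `alpha_star`, excluded-gene flags and fit
#'   diagnostics.
#' @details Genes with all-zero counts in any batch have an unidentifiable
#'   batch distribution and are flagged `excluded`; [adjust_counts()] passes
#'   them through unchanged.  Every batch must contain at least two samples,
#'   otherwise its dispersion is unestimable.
#' @export
fit_batch_model <- function(counts, meta, include_condition = TRUE) {
  validate_count_matrix(counts)
  meta <- validate_sample_metadata(meta)
  check_paired(counts, meta)
  meta <- meta[match(colnames(counts), meta$sample_id), ]

  batches <- unique(meta$batch)
  nb <- table(factor(meta$batch, levels = batches))
  if (any(nb < 2))
    stop("batch(es) with a single sample (dispersion unestimable): ",
         paste(names(nb)[nb < 2], collapse = ", "), call. = FALSE)

  batch_f <- factor(meta$batch, levels = batches)
  cond_f <- factor(meta$condition, levels = c("embryonic", "postnatal"))
  use_cond <- include_condition && nlevels(droplevels(cond_f)) > 1L
  mm <- if (length(batches) > 1L && use_cond)
    stats::model.matrix(~ batch_f + cond_f)
  else if (length(batches) > 1L) stats::model.matrix(~ batch_f)
  else if (use_cond) stats::model.matrix(~ cond_f)
  else stats::model.matrix(~ 1, data = meta)
  batch_cols <- grep("^batch_f", colnames(mm))

  n_g <- nrow(counts)
  by_batch <- lapply(batches, function(b) which(meta$batch == b))
  names(by_batch) <- batches

  zero_in_batch <- vapply(by_batch, function(j)
    rowSums(counts[, j, drop = FALSE]) == 0, logical(n_g))
  if (is.null(dim(zero_in_batch))) zero_in_batch <- matrix(zero_in_batch, nrow = n_g)
  excluded <- rowSums(zero_in_batch) > 0

  mu <- matrix(NA_real_, n_g, ncol(counts),
               dimnames = dimnames(counts))
  mu_star <- mu
  alpha <- matrix(NA_real_, n_g, length(batches),
                  dimnames = list(rownames(counts), batches))
  converged <- rep(NA, n_g)
  mom_fallback <- matrix(FALSE, n_g, length(batches),
                         dimnames = list(rownames(counts), batches))

  w_b <- as.numeric(nb) / sum(nb)           # sample-count batch weights

  for (g in which(!excluded)) {
    y <- counts[g, ]
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(mm, y, family = stats::poisson())),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$fitted.values)) ||
        any(fit$fitted.values <= 0)) {
      # fallback: saturated cell means over batch x condition
      cell <- interaction(batch_f, cond_f, drop = TRUE)
      cm <- tapply(y, cell, mean)
      mug <- pmax(as.numeric(cm[as.character(cell)]), 1e-8)
      converged[g] <- FALSE
      coefs_batch <- vapply(seq_along(batches), function(bi) {
        if (bi == 1L) 0 else {
          log(mean(y[by_batch[[bi]]]) / mean(y[by_batch[[1L]]]))
        }
      }, 0)
    } else {
      mug <- fit$fitted.values
      converged[g] <- fit$converged
      coefs_batch <- c(0, fit$coefficients[batch_cols])
    }
    mu[g, ] <- mug

    # batch-free target mean: replace each batch offset by the pooled offset
    pooled_off <- sum(w_b * coefs_batch)
    bi <- as.integer(batch_f)
    mu_star[g, ] <- mug * exp(pooled_off - coefs_batch[bi])

    for (b in seq_along(batches)) {
      j <- by_batch[[b]]
      a <- nb_dispersion(y[j], mug[j])
      alpha[g, b] <- a$alpha
      mom_fallback[g, b] <- a$mom
    }
  }
  alpha_star <- as.numeric(alpha %*% w_b)

  structure(list(genes = rownames(counts), samples = colnames(counts),
                 batches = batches, batch_of = as.character(meta$batch),
                 mu = mu, mu_star = mu_star,
                 alpha = alpha, alpha_star = alpha_star,
                 excluded = excluded, converged = converged,
                 mom_fallback = mom_fallback,
                 include_condition = use_cond),
            class = "batch_model")
}

# NB dispersion for one gene in one batch: ML (theta.ml) with a
# method-of-moments fallback; alpha floored at 0 (Poisson).
nb_dispersion <- function(y, mu) {
  mom <- max(0, sum((y - mu)^2 - mu) / sum(mu^2))
  if (stats::var(y) <= mean(y) || mean(y) == 0)
    return(list(alpha = mom, mom = TRUE))
  th <- tryCatch(
    suppressWarnings(MASS::theta.ml(y, mu, limit = 25)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(th) || !is.finite(th) || th <= 0)
    list(alpha = mom, mom = TRUE)
  else list(alpha = 1 / as.numeric(th), mom = FALSE)
}

#' @export
print.batch_model <- function(x, ...) {
  cat("batch_model:", length(x$genes), "genes,", length(x$batches), "batch(es);",
      sum(x$excluded), "gene(s) excluded (all-zero in some batch)\n")
  invisible(x)
}

# Discrete CDF / quantile in the (mu, alpha) NB parameterization.
pnb <- function(q, mu, alpha) {
  if (alpha <= 1e-12) stats::ppois(q, mu) else stats::pnbinom(q, mu = mu, size = 1 / alpha)
}
qnb <- function(p, mu, alpha) {
  if (alpha <= 1e-12) stats::qpois(p, mu) else stats::qnbinom(p, mu = mu, size = 1 / alpha)
}

#' Map counts to their batch-free distribution
#'
#' Each modelled count `y` in batch `b` is assigned the midpoint percentile
#' `p = (F_gb(y-1) + F_gb(y)) / 2` under its fitted batch NB, and replaced by
#' the smallest integer `q` with `F_g*(q) >= p` under the gene's target NB.
#' Excluded genes are returned unchanged.
#'
#' @param counts the count matrix the model was fitted on.
#' @param model a [fit_batch_model()] object for the same genes and samples.
#' @return adjusted count matrix (non-negative integers, same dimnames).
#' @export
adjust_counts <- function(counts, model) {
  validate_count_matrix(counts)
  stopifnot(inherits(model, "batch_model"))
  if (!identical(rownames(counts), model$genes) ||
      !identical(colnames(counts), model$samples))
    stop("count matrix and batch model cover different genes/samples",
         call. = FALSE)
  adj <- counts
  bi <- match(model$batch_of, model$batches)
  for (g in which(!model$excluded)) {
    a_star <- model$alpha_star[g]
    for (j in seq_along(model$samples)) {
      y <- counts[g, j]
      a_b <- model$alpha[g, bi[j]]
      mu_b <- model$mu[g, j]
      p <- (pnb(y - 1, mu_b, a_b) + pnb(y, mu_b, a_b)) / 2
      p <- min(max(p, 1e-12), 1 - 1e-12)
      adj[g, j] <- qnb(p, model$mu_star[g, j], a_star)
    }
  }
  storage.mode(adj) <- "double"
  adj[adj < 0] <- 0
  validate_count_matrix(adj)
  adj
}
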