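# Morphological intratumor heterogeneity (MITH) of tumor nuclei.

#' Normalize features across all tumor nuclei of all samples
#'
#' Per-feature z-score over the pooled nuclei (global mean 0, unit
#' population variance, so a two-point feature {0, 2} maps to {-1, +1}).
#' Zero-variance features are dropped with a warning. A robust variant
#' (median/MAD) is available.
#'
#' @param mat Nuclei x features numeric matrix.
#' @param method "zscore" (default) or "robust" (median/MAD scaling).
#' @return Matrix of the same rows with normalized (possibly fewer) columns.
#' @export
normalize_global <- function(mat, method = c("zscore", "robust")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2)
  if (method == "zscore") {
    ctr <- colMeans(mat)
    scl <- apply(mat, 2, pop_sd)
  } else {
    ctr <- apply(mat, 2, stats::median)
    scl <- apply(mat, 2, stats::mad)
  }
  zv <- scl < 1e-12
  if (any(zv)) {
    warning("dropping ", sum(zv), " zero-variance features: ",
            paste(utils::head(colnames(mat)[zv]), collapse = ", "))
    mat <- mat[, !zv, drop = FALSE]
    ctr <- ctr[!zv]; scl <- scl[!zv]
  }
  sweep(sweep(mat, 2, ctr), 2, scl, "/")
}

#' MITH of one sample
#'
#' Mean over features of the population standard deviation (divide by M,
#' not M-1) of the globally normalized feature values across the M tumor
#' nuclei of the sample:
#' MITH = (1/N) sum_i sqrt( sum_j (x_ij - xbar_i)^2 / M ).
#'
#' @param normalized Nuclei x features matrix from
#'   \code{\link{normalize_global}} (all samples pooled).
#' @param sample_ids Sample id per nucleus row.
#' @param sample The sample to score.
#' @return MITH (>= 0), or NA when the sample has fewer than 2 nuclei.
#' @export
compute_mith <- function(normalized, sample_ids, sample) {
  x <- normalized[sample_ids == sample, , drop = FALSE]
  if (nrow(x) < 2) {
    warning("sample ", sample, " has fewer than 2 tumor nuclei; MITH is NA")
    return(NA_real_)
  }
  mean(apply(x, 2, pop_sd))
}

#' Per-sample MITH table
#'
#' Normalizes a pooled tumor-nucleus feature matrix globally and computes
#' MITH for every sample.
#'
#' @param mat Pooled tumor-nuclei x features matrix (morphology plus
#'   texture where available; all-NA columns are excluded first).
#' @param sample_ids Sample id per nucleus row.
#' @param method Normalization method, see \code{\link{normalize_global}}.
#' @return data.frame(sample_id, MITH, M, N).
#' @export
mith_table <- function(mat, sample_ids, method = "zscore") {
  mat <- as.matrix(mat)
  usable <- colSums(!is.finite(mat)) == 0
  if (!all(usable))
    message("MITH restricted to ", sum(usable),
            " features without missing values")
  nm <- normalize_global(mat[, usable, drop = FALSE], method = method)
  samples <- unique(sample_ids)
  mith <- vapply(samples, function(s) {
    if (sum(sample_ids == s) < 2) NA_real_
    else compute_mith(nm, sample_ids, s)
  }, numeric(1))
  data.frame(sample_id = samples, MITH = mith,
             M = as.integer(table(factor(sample_ids, levels = samples))),
             N = ncol(nm), stringsAsFactors = FALSE)
}
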