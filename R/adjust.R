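#' Adjust L1 RNA estimates for intronic rate
#'
#' Log2-transformed TPM (with a 0.5 pseudocount) is regressed on the RNA-seq
#' intronic rate by OLS and the residuals are returned as the adjusted
#' estimates. Tumor and normal samples are fitted jointly in one model: pass
#' them together. The log2 transform precedes residualization (residuals can
#' be negative, so the reverse order is not defined).
#'
#' @param tpm Numeric vector (or loci-by-samples matrix, adjusted row-wise
#'   against the shared covariate) of TPM values.
#' @param intronic_rate Numeric vector, one value per sample, in `[0, 1]`.
#' @param pseudocount Added before log2 (default 0.5).
#' @return Adjusted values (residuals, log2 scale), same shape as `tpm`
#'   (matrix input is adjusted per row).
#' @export
adjust_rna <- function(tpm, intronic_rate, pseudocount = 0.5) {
  n <- if (is.matrix(tpm)) ncol(tpm) else length(tpm)
  if (length(intronic_rate) != n) abort("tpm and intronic_rate lengths differ")
  if (n < 3) abort("need at least 3 samples")
  if (sd(intronic_rate) == 0) {
    warn("intronic rate is constant; adjustment degenerates to centering")
  }
  y <- log2p(tpm, pseudocount)
  if (is.matrix(y)) t(residualize(t(y), intronic_rate)) else residualize(y, intronic_rate)
}

#' Adjust L1 RT counts for WGS quality metrics
#'
#' Log2-transformed counts (0.5 pseudocount) are regressed jointly on the ten
#' WGS quality covariates -- mean read length, coverage, mean base quality,
#' chimeric read fraction, and clipped base fraction, each for the tumor and
#' the paired normal -- and the residuals are returned as the adjusted RT
#' estimates.
#'
#' @param count Numeric vector (or loci-by-samples matrix) of RT counts.
#' @param covariates Data frame or matrix with one row per sample (any
#'   number of numeric columns; ten in the standard design).
#' @param pseudocount Added before log2 (default 0.5).
#' @return Adjusted values (residuals, log2 scale).
#' @export
adjust_rt <- function(count, covariates, pseudocount = 0.5) {
  X <- as.matrix(covariates)
  n <- if (is.matrix(count)) ncol(count) else length(count)
  if (nrow(X) != n) abort("count and covariates dimensions differ")
  if (n <= ncol(X) + 1) abort("need more samples than covariates")
  if (qr(cbind(1, scale(X, scale = FALSE)))$rank < ncol(X) + 1) {
    warn("collinear covariates; using minimum-norm fit")
  }
  y <- log2p(count, pseudocount)
  if (is.matrix(y)) t(residualize(t(y), X)) else residualize(y, X)
}
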