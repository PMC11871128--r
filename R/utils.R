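#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join row_number n across all_of if_else pull rename
#' @importFrom stats lm coef resid quantile rnorm runif rbinom rpois qbeta
#'   median sd var cor wilcox.test t.test p.adjust setNames complete.cases
#'   hclust cutree dist confint pnorm pt
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

# uniform random DNA string(s); vectorised over n via a single sample() call
rand_dna <- function(len, n = 1L) {
  total <- len * n
  chars <- sample(BASES, total, replace = TRUE)
  if (n == 1L) {
    paste(chars, collapse = "")
  } else {
    vapply(split(chars, rep(seq_len(n), each = len)), paste, "", collapse = "")
  }
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# log2 with the pseudocount used throughout (counts and TPMs both hit zero)
log2p <- function(x, pseudocount = 0.5) log2(x + pseudocount)

# substring by 0-based half-open interval; vectorised over all arguments
# (substring(), unlike substr(), recycles to the longest argument)
substr0 <- function(x, start, end) substring(x, start + 1L, end)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == round(x)

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a probability in [0, 1]", name))
  }
}

# residualise columns of y (vector or matrix) on covariate matrix x by OLS;
# returns residuals with attributes dropped. Rank-deficient designs fall back
# to the minimum-norm solution via the pivoted QR that lm.fit uses.
residualize <- function(y, x) {
  y <- as.matrix(y)
  X <- cbind(`(Intercept)` = 1, as.matrix(x))
  fit <- stats::lm.fit(X, y)
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(y)
  if (ncol(res) == 1L) drop(res) else res
}
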