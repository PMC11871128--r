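#' Per-type locus activity matrix
#'
#' For each locus, the mean adjusted log2 RNA and TRT per tumor type. Global
#' locus means weight each tumor type equally (the mean of per-type means),
#' so large cohorts do not dominate.
#'
#' @param rna_adj,trt_adj Loci-by-samples matrices of adjusted log2 values
#'   (see [cohort_adjust()]).
#' @param tumor_type Character vector, one type per sample.
#' @return List of class `l1_activity_matrix`: `rna` / `trt`
#'   (loci-by-types mean matrices), `n_per_type`, `locus_mean_rna`,
#'   `locus_mean_trt` (equal-weight means across types).
#' @export
build_activity_matrix <- function(rna_adj, trt_adj, tumor_type) {
  stopifnot(ncol(rna_adj) == length(tumor_type), all(dim(rna_adj) == dim(trt_adj)))
  counts <- table(tumor_type)
  types <- names(counts)[counts > 0]
  if (length(types) < length(unique(tumor_type))) warn("dropping empty tumor types")
  per_type <- function(m) {
    out <- vapply(types, function(tt) rowMeans(m[, tumor_type == tt, drop = FALSE]),
                  numeric(nrow(m)))
    matrix(out, nrow = nrow(m), dimnames = list(rownames(m), types))
  }
  rna_m <- per_type(rna_adj); trt_m <- per_type(trt_adj)
  structure(list(
    rna = rna_m, trt = trt_m,
    n_per_type = as.integer(counts[types]),
    locus_mean_rna = rowMeans(rna_m),
    locus_mean_trt = rowMeans(trt_m)
  ), class = "l1_activity_matrix")
}

#' Cluster loci by RNA and TRT profiles across tumor types
#'
#' Two dendrograms are built (average-linkage, Euclidean) on the rows of the
#' RNA and TRT activity matrices and cut at a fraction of their height; a
#' third annotation flags loci whose mean TRT falls below
#' `low_trt_threshold`. Loci sharing all three annotations form one final
#' cluster.
#'
#' @param am An [build_activity_matrix()] object.
#' @param low_trt_threshold Mean TRT per sample below which a locus is
#'   flagged low-TRT (default 0.0018, on the adjusted log2 scale).
#' @param cut_frac Dendrogram cut height as a fraction of tree height.
#' @param method Linkage method for [hclust()].
#' @return Tibble of class `l1_locus_clusters`: `locus`, `rna_label`,
#'   `trt_label`, `low_trt`, `cluster` (final id).
#' @export
cluster_loci <- function(am, low_trt_threshold = 0.0018, cut_frac = 0.5,
                         method = "average") {
  if (nrow(am$rna) < 2) abort("need at least 2 loci")
  cut_labels <- function(m) {
    d <- dist(m)
    if (max(d) == 0) {
      warn("all locus profiles identical; single cluster")
      return(rep(1L, nrow(m)))
    }
    hc <- hclust(d, method = method)
    cutree(hc, h = cut_frac * max(hc$height))
  }
  rna_label <- cut_labels(am$rna)
  trt_label <- cut_labels(am$trt)
  low <- am$locus_mean_trt < low_trt_threshold
  key <- paste(rna_label, trt_label, low)
  out <- tibble(
    locus = rownames(am$rna),
    rna_label = rna_label, trt_label = trt_label, low_trt = low,
    cluster = match(key, unique(key))
  )
  structure(out, class = c("l1_locus_clusters", class(out)))
}

#' Long sample-by-locus table for the efficiency model
#'
#' @param cohort A QC-adjusted `l1_cohort` (see [cohort_adjust()]).
#' @return Tibble with one row per sample and locus: `sample_id`, `locus`,
#'   `trt` and `rna` (adjusted log2), `tumor_type`, `p53_mut`.
#' @export
cohort_long <- function(cohort) {
  if (is.null(cohort$adj)) cohort <- cohort_adjust(cohort)
  s <- cohort$samples
  L <- nrow(cohort$rna); n <- ncol(cohort$rna)
  tibble(
    sample_id = rep(s$sample_id, each = L),
    locus = rep(rownames(cohort$rna), n),
    trt = as.vector(cohort$adj$trt),
    rna = as.vector(cohort$adj$rna),
    tumor_type = rep(s$tumor_type, each = L),
    p53_mut = rep(s$p53_mut, each = L)
  )
}

# design pieces for the efficiency model: shared covariates X0 and the
# per-locus RNA slope block S (one column per locus, rna where the row's
# locus matches, 0 elsewhere)
efficiency_design <- function(long, loci = sort(unique(long$locus))) {
  type <- factor(long$tumor_type)
  X0 <- cbind(`(Intercept)` = rep(1, nrow(long)),
              if (nlevels(type) > 1) {
                stats::model.matrix(~ type)[, -1, drop = FALSE]
              },
              if (length(unique(long$p53_mut)) > 1) {
                cbind(p53_mut = long$p53_mut)
              })
  S <- matrix(0, nrow(long), length(loci),
              dimnames = list(NULL, paste0("eff_", loci)))
  S[cbind(seq_len(nrow(long)), match(long$locus, loci))] <- long$rna
  list(X0 = X0, S = S, loci = loci)
}

#' Fit the locus-efficiency regression
#'
#' A single OLS over all sample-by-locus observations:
#' `locus TRT ~ efficiency_i * locus RNA + tumor type + p53 + const`,
#' with a separate RNA slope (the efficiency) per locus and tumor-type/p53
#' coefficients shared across loci.
#'
#' @param long A [cohort_long()]-style tibble (adjusted log2 `trt` and
#'   `rna`, `locus`, `tumor_type`, `p53_mut`).
#' @return Object of class `l1_efficiency_fit`: `efficiencies` tibble
#'   (`locus`, `estimate`, `se`, `lower`, `upper`, `p_value`), `shared`
#'   tibble of covariate coefficients, `sigma`, `df_residual`, `n_obs`.
#' @export
fit_efficiency_model <- function(long) {
  if (length(unique(long$locus)) < 1) abort("no loci")
  if (all(long$rna == 0)) abort("locus RNA is all zero")
  des <- efficiency_design(long)
  X <- cbind(des$X0, des$S)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(paste("rank-deficient design; collinear columns:",
                paste(bad, collapse = ", ")))
  }
  fit <- stats::lm.fit(X, long$trt)
  dfres <- nrow(X) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / dfres
  inv_perm <- chol2inv(qr.R(qx))
  XtX_inv <- matrix(0, ncol(X), ncol(X))
  XtX_inv[qx$pivot, qx$pivot] <- inv_perm
  se <- sqrt(diag(XtX_inv) * sigma2)
  names(se) <- colnames(X)
  est <- fit$coefficients
  tcrit <- stats::qt(0.975, dfres)
  eff_idx <- grep("^eff_", colnames(X))
  effs <- tibble(
    locus = sub("^eff_", "", colnames(X)[eff_idx]),
    estimate = unname(est[eff_idx]), se = unname(se[eff_idx]),
    lower = unname(est[eff_idx] - tcrit * se[eff_idx]),
    upper = unname(est[eff_idx] + tcrit * se[eff_idx]),
    p_value = 2 * pt(abs(est[eff_idx] / se[eff_idx]), dfres, lower.tail = FALSE)
  )
  shared <- tibble(
    term = colnames(X)[-eff_idx],
    estimate = unname(est[-eff_idx]), se = unname(se[-eff_idx])
  )
  structure(list(efficiencies = effs, shared = shared,
                 sigma = sqrt(sigma2), df_residual = dfres, n_obs = nrow(X)),
            class = "l1_efficiency_fit")
}

#' Permutation background for locus efficiencies
#'
#' The locus label of every observation is randomly permuted and the
#' efficiency model refitted, `n_resamplings` times, over the given locus
#' subset (in the source analysis, loci with TRTs in at least 2 samples).
#' The pooled resampled efficiencies define the empirical null; the
#' per-resampling variances define the null for efficiency heterogeneity.
#'
#' @param long A [cohort_long()]-style tibble.
#' @param loci_subset Loci to include (default: all in `long`).
#' @param n_resamplings Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List of class `l1_background`: `pool` (flat vector of resampled
#'   efficiencies), `per_var` (variance within each resampling),
#'   `n_resamplings`.
#' @export
efficiency_background <- function(long, loci_subset = NULL, n_resamplings = 1000,
                                  seed = 1L) {
  loci_subset <- loci_subset %||% sort(unique(long$locus))
  if (!length(loci_subset)) abort("loci_subset is empty")
  if (n_resamplings < 100) warn("fewer than 100 resamplings: empirical p unstable")
  long <- filter(long, .data$locus %in% loci_subset)
  withr::local_seed(seed)
  des <- efficiency_design(long, loci_subset)
  n <- nrow(long)
  L <- length(loci_subset)
  pool <- matrix(NA_real_, L, n_resamplings)
  for (b in seq_len(n_resamplings)) {
    # permute only the locus label; each observation keeps its (TRT, RNA) pair
    perm <- sample.int(n)
    S <- matrix(0, n, L)
    S[cbind(seq_len(n), match(long$locus[perm], loci_subset))] <- long$rna
    fit <- stats::lm.fit(cbind(des$X0, S), long$trt)
    pool[, b] <- fit$coefficients[(ncol(des$X0) + 1):(ncol(des$X0) + L)]
  }
  structure(list(pool = as.vector(pool), per_var = apply(pool, 2, var),
                 n_resamplings = n_resamplings),
            class = "l1_background")
}

#' Categorize loci against a resampled background
#'
#' One-sided empirical p-values -- rank of the fitted value in the pooled
#' background with `(r + 1) / (N + 1)` smoothing, in the observed direction
#' -- are Bonferroni-corrected over `n_hypotheses`. Non-significant values
#' outside the background interquartile range are `slightly_high` /
#' `slightly_low`; the rest are `typical`.
#'
#' @param fit An [fit_efficiency_model()] object, or a tibble with `locus`
#'   and `estimate` columns.
#' @param background An [efficiency_background()]-style object.
#' @param alpha Corrected significance threshold (default 0.05).
#' @param n_hypotheses Number of hypotheses for the correction (default: the
#'   number of loci in `fit`).
#' @return Tibble: `locus`, `estimate`, `p_high`, `p_low`, `p_corrected`,
#'   `category`.
#' @export
categorize_loci <- function(fit, background, alpha = 0.05, n_hypotheses = NULL) {
  effs <- if (inherits(fit, "l1_efficiency_fit")) fit$efficiencies else fit
  pool <- background$pool
  if (!length(pool)) abort("empty background pool")
  n_hypotheses <- n_hypotheses %||% nrow(effs)
  N <- length(pool)
  p_high <- (vapply(effs$estimate, function(x) sum(pool >= x), 0) + 1) / (N + 1)
  p_low <- (vapply(effs$estimate, function(x) sum(pool <= x), 0) + 1) / (N + 1)
  p_emp <- pmin(p_high, p_low)
  p_corr <- pmin(1, p_emp * n_hypotheses)
  q <- quantile(pool, c(0.25, 0.75))
  category <- dplyr::case_when(
    p_corr < alpha & p_high < p_low ~ "significantly_high",
    p_corr < alpha & p_low <= p_high ~ "significantly_low",
    effs$estimate > q[2] ~ "slightly_high",
    effs$estimate < q[1] ~ "slightly_low",
    TRUE ~ "typical"
  )
  tibble(locus = effs$locus, estimate = effs$estimate,
         p_high = p_high, p_low = p_low, p_corrected = p_corr,
         category = category)
}

# closed-form simple-regression slopes of y on each row of M
row_slopes <- function(M, y) {
  yc <- y - mean(y)
  Mc <- M - rowMeans(M)
  ss <- rowSums(Mc^2)
  slope <- unname(as.vector(Mc %*% yc)) / ss
  slope[ss == 0] <- NA_real_
  unname(slope)
}

#' Per-locus total-RT regressions with a resampling background
#'
#' One simple OLS per locus, `total RT burden ~ coef * locus RNA + const`,
#' associating every locus (not only transduction-bearing ones) with total
#' RT activity. The background resamples observations with replacement and
#' permutes the locus assignment of the RNA, refitting all models per
#' resampling; categorization reuses [categorize_loci()].
#'
#' @param total_rt Adjusted log2 total RT burden, one value per sample.
#' @param rna_adj Loci-by-samples adjusted log2 RNA matrix.
#' @param n_resamplings Background resamplings (default 1000).
#' @param seed Integer seed.
#' @param alpha,n_hypotheses Passed to [categorize_loci()].
#' @return List of class `l1_total_rt_fit`: `coefficients` tibble (`locus`,
#'   `estimate`, `r`, `p_value`, `category`, ...), `background`.
#' @export
fit_total_rt_models <- function(total_rt, rna_adj, n_resamplings = 1000,
                                seed = 1L, alpha = 0.05, n_hypotheses = NULL) {
  n <- length(total_rt)
  stopifnot(ncol(rna_adj) == n)
  L <- nrow(rna_adj)
  slope <- row_slopes(rna_adj, total_rt)
  if (any(is.na(slope))) warn("constant locus RNA: coefficient undefined for some loci")
  r <- suppressWarnings(as.vector(cor(t(rna_adj), total_rt)))
  tstat <- r * sqrt((n - 2) / pmax(1e-12, 1 - r^2))
  p_value <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)

  withr::local_seed(seed)
  pool <- matrix(NA_real_, L, n_resamplings)
  per_var <- numeric(n_resamplings)
  grp <- rep(seq_len(L), each = n)
  for (b in seq_len(n_resamplings)) {
    # resample observations with replacement across any sample and locus,
    # then permute the locus assignment of the RNA: each background model
    # sees pairs drawn from the pooled (total RT, locus RNA) cloud
    i <- sample.int(n, L * n, replace = TRUE)
    l <- sample.int(L, L * n, replace = TRUE)
    x <- rna_adj[cbind(l, i)]
    y <- total_rt[i]
    sx <- rowsum(x, grp); sy <- rowsum(y, grp)
    sxy <- rowsum(x * y, grp); sxx <- rowsum(x * x, grp)
    pool[, b] <- (sxy - sx * sy / n) / (sxx - sx^2 / n)
    per_var[b] <- var(pool[, b], na.rm = TRUE)
  }
  background <- structure(list(pool = as.vector(pool[!is.na(pool)]),
                               per_var = per_var,
                               n_resamplings = n_resamplings),
                          class = "l1_background")
  cats <- categorize_loci(
    tibble(locus = rownames(rna_adj), estimate = slope),
    background, alpha = alpha, n_hypotheses = n_hypotheses %||% L
  )
  coefs <- left_join(
    tibble(locus = rownames(rna_adj), estimate = slope, r = r, p_value = p_value),
    select(cats, -"estimate"), by = "locus"
  )
  structure(list(coefficients = coefs, background = background),
            class = "l1_total_rt_fit")
}

#' Aggregate locus RNA into cluster RNA
#'
#' Sums TPM over the loci of each cluster per sample and log2-transforms
#' (0.5 pseudocount).
#'
#' @param rna_tpm Loci-by-samples TPM matrix.
#' @param clusters An [cluster_loci()] tibble (or vector of cluster ids in
#'   locus order).
#' @return Clusters-by-samples matrix of log2 summed TPM.
#' @export
aggregate_cluster_rna <- function(rna_tpm, clusters) {
  cl <- if (is.data.frame(clusters)) clusters$cluster[match(rownames(rna_tpm), clusters$locus)] else clusters
  sums <- rowsum(rna_tpm, group = cl)
  rownames(sums) <- paste0("cluster_", rownames(sums))
  log2p(sums)
}

#' Total RT on summed cluster RNA
#'
#' Multivariate OLS: `total RT burden ~ sum_clusters c_i * cluster_i RNA +
#' const`, where cluster RNA is the per-sample sum of locus RNA over the
#' cluster's loci (log2, adjusted).
#'
#' @param total_rt Adjusted log2 total RT burden per sample.
#' @param cluster_rna Clusters-by-samples matrix (see
#'   [aggregate_cluster_rna()], optionally QC-adjusted).
#' @return Object of class `l1_cluster_model`: `coefficients` tibble with
#'   95% CIs, `fit_correlation` (Pearson r of observed vs fitted),
#'   `fitted`, `lm` (the underlying fit).
#' @export
fit_cluster_model <- function(total_rt, cluster_rna) {
  X <- t(cluster_rna)
  keep <- apply(X, 2, function(col) sd(col) > 0)
  if (!any(keep)) abort("no cluster with varying aggregate RNA")
  X <- X[, keep, drop = FALSE]
  if (qr(cbind(1, X))$rank < ncol(X) + 1) warn("collinear cluster sums; minimum-norm fit")
  df <- as.data.frame(X)
  fit <- lm(total_rt ~ ., data = df)
  ci <- suppressWarnings(confint(fit))
  sm <- summary(fit)$coefficients
  coefs <- tibble(
    term = rownames(sm), estimate = unname(sm[, 1]), se = unname(sm[, 2]),
    lower = unname(ci[, 1]), upper = unname(ci[, 2]), p_value = unname(sm[, 4])
  )
  structure(list(coefficients = coefs,
                 fit_correlation = cor(total_rt, fitted(fit)),
                 fitted = fitted(fit), lm = fit),
            class = "l1_cluster_model")
}
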