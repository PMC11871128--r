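std_factor <- function(coef_sd_x, coef_sd_y, standardization) {
  if (standardization == "conventional") coef_sd_x / coef_sd_y else coef_sd_y / coef_sd_x
}

fast_ols <- function(X, y) .lm.fit(cbind(1, X), y)$coefficients

#' p53 dual-regulation mediation decomposition
#'
#' Decomposes the total effect of p53 mutation on L1 RT burden into a
#' component mediated by L1 RNA and a direct component, via five OLS fits:
#'
#' 1. `RT ~ tau * p53 + c1` (total effect)
#' 2. `RT ~ beta * RNA + c2`
#' 3. `RNA ~ alpha * p53 + c3`
#' 4. `RT ~ beta' * RNA + tau' * p53 + c4`
#' 5. `RNA ~ beta* * RT + alpha* * p53 + c5`
#'
#' The mediated effect is `alpha * beta'` (algebraically equal to
#' `tau - tau'`); the mediated and unmediated fractions are `alpha*beta' /
#' tau` and `tau' / tau`. Coefficients are also reported standardized;
#' `"conventional"` multiplies each coefficient by sd(predictor)/sd(outcome)
#' (invariant to affine rescaling of any variable), `"as-quoted"` uses the
#' reciprocal ratio. Percentile bootstrap confidence intervals are computed
#' for the standardized effects and the fractions by resampling samples with
#' replacement.
#'
#' @param data Data frame containing the three columns.
#' @param rt,rna,p53 Column names: adjusted log2 RT burden, adjusted log2
#'   RNA, and the 0/1 p53 mutation indicator.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param standardization `"conventional"` or `"as-quoted"`.
#' @return Object of class `l1_mediation` with `coefficients` (term,
#'   estimate, std_estimate, se, p_value), `effects` (mediated/unmediated
#'   effects and fractions with bootstrap CIs), `n`, `boot` (the bootstrap
#'   draws).
#' @export
fit_mediation <- function(data, rt = "rt", rna = "rna", p53 = "p53",
                          n_boot = 1000, seed = 1L,
                          standardization = c("conventional", "as-quoted")) {
  standardization <- rlang::arg_match(standardization)
  y <- data[[rt]]; m <- data[[rna]]; x <- data[[p53]]
  if (length(unique(x)) < 2) abort("p53 indicator is constant", class = "l1rt_degenerate")
  n <- length(y)

  eq1 <- lm(y ~ x); eq2 <- lm(y ~ m); eq3 <- lm(m ~ x)
  eq4 <- lm(y ~ m + x); eq5 <- lm(m ~ y + x)
  pull_coef <- function(fit, term, sx, sy) {
    sm <- summary(fit)$coefficients
    c(est = sm[term, 1], se = sm[term, 2], p = sm[term, 4],
      std = sm[term, 1] * std_factor(sx, sy, standardization))
  }
  sy <- sd(y); sm_ <- sd(m); sx <- sd(x)
  co <- rbind(
    tau = pull_coef(eq1, "x", sx, sy),
    beta = pull_coef(eq2, "m", sm_, sy),
    alpha = pull_coef(eq3, "x", sx, sm_),
    beta_prime = pull_coef(eq4, "m", sm_, sy),
    tau_prime = pull_coef(eq4, "x", sx, sy),
    beta_star = pull_coef(eq5, "y", sy, sm_),
    alpha_star = pull_coef(eq5, "x", sx, sm_)
  )
  coefficients <- tibble(
    term = rownames(co), estimate = co[, "est"], std_estimate = co[, "std"],
    se = co[, "se"], p_value = co[, "p"]
  )
  intercepts <- vapply(list(eq1, eq2, eq3, eq4, eq5),
                       function(f) unname(coef(f)[1]), 0)

  est <- setNames(co[, "est"], rownames(co))
  stdv <- setNames(co[, "std"], rownames(co))
  mediated <- unname(est["alpha"] * est["beta_prime"])
  mediated_std <- unname(stdv["alpha"] * stdv["beta_prime"])

  withr::local_seed(seed)
  boot <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("mediated_std", "tau_prime_std",
                                         "mediated_frac", "unmediated_frac")))
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, replace = TRUE)
    yb <- y[i]; mb <- m[i]; xb <- x[i]
    if (length(unique(xb)) < 2) next
    c4 <- fast_ols(cbind(mb, xb), yb)        # (int, beta', tau')
    a <- fast_ols(cbind(xb), mb)[2]          # alpha
    t1 <- fast_ols(cbind(xb), yb)[2]         # tau
    med <- a * c4[2]
    f_med <- std_factor(sd(xb), sd(yb), standardization)
    boot[b, ] <- c(med * f_med, c4[3] * f_med, med / t1, c4[3] / t1)
  }
  boot <- boot[complete.cases(boot), , drop = FALSE]
  qs <- function(v) unname(quantile(v, c(0.025, 0.975)))
  effects <- tibble(
    effect = c("mediated", "unmediated"),
    estimate = c(mediated, unname(est["tau_prime"])),
    std_estimate = c(mediated_std, unname(stdv["tau_prime"])),
    fraction = c(mediated / est[["tau"]], est[["tau_prime"]] / est[["tau"]]),
    std_lower = c(qs(boot[, "mediated_std"])[1], qs(boot[, "tau_prime_std"])[1]),
    std_upper = c(qs(boot[, "mediated_std"])[2], qs(boot[, "tau_prime_std"])[2]),
    frac_lower = c(qs(boot[, "mediated_frac"])[1], qs(boot[, "unmediated_frac"])[1]),
    frac_upper = c(qs(boot[, "mediated_frac"])[2], qs(boot[, "unmediated_frac"])[2])
  )
  structure(list(coefficients = coefficients, effects = effects,
                 intercepts = intercepts, n = n, boot = as_tibble(boot),
                 standardization = standardization),
            class = "l1_mediation")
}

#' @export
print.l1_mediation <- function(x, ...) {
  cat("L1 mediation decomposition (n =", x$n, ")\n")
  print(x$coefficients)
  print(x$effects)
  invisible(x)
}

#' RNA-quintile-stratified p53 vs RT tests
#'
#' Samples are split into five equal-size quintiles of RNA; within each, a
#' two-sided Mann-Whitney U test compares RT between p53 mutant and
#' wild-type samples, Bonferroni-corrected over the five tests.
#'
#' @param data Data frame.
#' @param rt,rna,p53 Column names as in [fit_mediation()].
#' @return Tibble: `quintile`, `n_mut`, `n_wt`, `median_diff`, `p_value`,
#'   `p_adjusted`, `testable`.
#' @export
quintile_stratified_test <- function(data, rt = "rt", rna = "rna", p53 = "p53") {
  y <- data[[rt]]; m <- data[[rna]]; x <- data[[p53]]
  n <- length(y)
  if (n < 50) abort("need at least 50 samples for quintile stratification")
  q <- dplyr::ntile(m, 5)
  out <- purrr::map_dfr(1:5, function(k) {
    yi <- y[q == k]; xi <- x[q == k]
    n_mut <- sum(xi == 1); n_wt <- sum(xi == 0)
    if (n_mut == 0 || n_wt == 0) {
      return(tibble(quintile = k, n_mut = n_mut, n_wt = n_wt,
                    median_diff = NA_real_, p_value = NA_real_, testable = FALSE))
    }
    wt <- wilcox.test(yi[xi == 1], yi[xi == 0], exact = FALSE)
    tibble(quintile = k, n_mut = n_mut, n_wt = n_wt,
           median_diff = median(yi[xi == 1]) - median(yi[xi == 0]),
           p_value = wt$p.value, testable = TRUE)
  })
  mutate(out, p_adjusted = pmin(1, .data$p_value * 5))
}

#' Bootstrap comparison of LFS vs matched non-LFS tumors
#'
#' Each of `n_resamplings` resamplings draws, per tumor type, as many
#' non-LFS TP53-mutant samples (with replacement) as the LFS cohort has of
#' that type, preserving the LFS type composition exactly. The bootstrap
#' distribution of resampled means is compared with the true LFS values by
#' a two-sided t-test.
#'
#' @param values Numeric vector (e.g. adjusted log2 RT or RNA).
#' @param lfs 0/1 LFS flag per sample.
#' @param tumor_type Character vector per sample.
#' @param p53_mut 0/1 TP53 alteration flag per sample.
#' @param n_resamplings Default 10000.
#' @param seed Integer seed.
#' @return List of class `l1_lfs_comparison`: `lfs_mean`, `boot_means`,
#'   `ci` (95% of bootstrap means), `p_value`, `n_lfs`, `n_resamplings`.
#' @export
lfs_bootstrap_compare <- function(values, lfs, tumor_type, p53_mut,
                                  n_resamplings = 10000, seed = 1L) {
  lfs_idx <- which(lfs == 1)
  if (!length(lfs_idx)) abort("no LFS samples")
  pool_ok <- lfs == 0 & p53_mut == 1
  comp <- table(tumor_type[lfs_idx])
  missing_types <- names(comp)[!names(comp) %in% unique(tumor_type[pool_ok])]
  if (length(missing_types)) {
    abort(paste("LFS tumor type(s) absent from the non-LFS pool:",
                paste(missing_types, collapse = ", ")))
  }
  withr::local_seed(seed)
  n_lfs <- length(lfs_idx)
  totals <- numeric(n_resamplings)
  for (tt in names(comp)) {
    pool <- values[pool_ok & tumor_type == tt]
    k <- comp[[tt]]
    draws <- matrix(sample(pool, k * n_resamplings, replace = TRUE), nrow = k)
    totals <- totals + colSums(draws)
  }
  boot_means <- totals / n_lfs
  tt <- t.test(boot_means, values[lfs_idx])
  structure(list(
    lfs_mean = mean(values[lfs_idx]),
    boot_means = boot_means,
    ci = unname(quantile(boot_means, c(0.025, 0.975))),
    p_value = tt$p.value,
    n_lfs = n_lfs, n_resamplings = n_resamplings
  ), class = "l1_lfs_comparison")
}

#' Gene-mutation association tests for L1 RNA and RT
#'
#' Pass 1: for every gene, two-sided Mann-Whitney U tests of the RNA and RT
#' endpoints in mutant vs wild-type samples (2G comparisons). Pass 2: the
#' remaining genes (all but TP53) are stratified by p53 status, four tests
#' each. Bonferroni correction is applied within the full family; a
#' comparison passes if its corrected p-value is below `alpha` and its
#' effect size (absolute difference of medians) is at least the overall
#' standard deviation of the endpoint.
#'
#' @param data Data frame with 0/1 gene columns and the two endpoints.
#' @param genes Character vector of gene column names.
#' @param rna,rt Endpoint column names (adjusted log2).
#' @param p53 Column name of the TP53 indicator used for stratification;
#'   excluded from pass 2 if it appears in `genes`.
#' @param alpha Corrected significance threshold (default 0.01).
#' @return Tibble of class `l1_gene_tests`: `gene`, `stratum`, `endpoint`,
#'   `n_mut`, `n_wt`, `statistic`, `p_value`, `p_adjusted`, `effect_size`,
#'   `pass`, `skipped`, `skip_reason`.
#' @export
gene_stratified_tests <- function(data, genes, rna = "rna", rt = "rt",
                                  p53 = "p53_mut", alpha = 0.01) {
  endpoints <- c(RNA = rna, RT = rt)
  sds <- vapply(endpoints, function(cn) sd(data[[cn]]), 0)
  plan <- bind_rows(
    tidyr::expand_grid(gene = genes, stratum = "all", endpoint = names(endpoints)),
    tidyr::expand_grid(gene = setdiff(genes, p53), stratum = c("p53_mut", "p53_wt"),
                       endpoint = names(endpoints))
  )
  res <- purrr::pmap_dfr(plan, function(gene, stratum, endpoint) {
    rows <- switch(stratum, all = rep(TRUE, nrow(data)),
                   p53_mut = data[[p53]] == 1, p53_wt = data[[p53]] == 0)
    g <- data[[gene]][rows]; v <- data[[endpoints[[endpoint]]]][rows]
    base <- tibble(gene = gene, stratum = stratum, endpoint = endpoint,
                   n_mut = sum(g == 1), n_wt = sum(g == 0))
    if (base$n_mut == 0 || base$n_wt == 0) {
      return(mutate(base, statistic = NA_real_, p_value = NA_real_,
                    effect_size = NA_real_, skipped = TRUE,
                    skip_reason = "empty mutant or wild-type group"))
    }
    wt <- wilcox.test(v[g == 1], v[g == 0], exact = FALSE)
    mutate(base, statistic = unname(wt$statistic), p_value = wt$p.value,
           effect_size = abs(median(v[g == 1]) - median(v[g == 0])),
           skipped = FALSE, skip_reason = NA_character_)
  })
  n_tests <- sum(!res$skipped)
  res <- res |>
    mutate(p_adjusted = pmin(1, .data$p_value * n_tests),
           pass = !.data$skipped & .data$p_adjusted < alpha &
             .data$effect_size >= sds[.data$endpoint])
  structure(res, class = c("l1_gene_tests", class(res)))
}

#' Does normal-tissue L1 RNA predict tumor TP53 mutation?
#'
#' Linear probability model
#' `tumor p53 mutation status ~ normal RNA + tumor type + const` with tumor
#' type categorical; the standardized RNA coefficient and its p-value are
#' returned. Types with a uniform p53 outcome are dropped with a warning.
#'
#' @param data Data frame.
#' @param normal_rna Column of adjusted log2 normal-tissue RNA.
#' @param tumor_p53 Column of the 0/1 tumor TP53 indicator.
#' @param tumor_type Column of tumor type labels.
#' @param standardization `"conventional"` (coef * sd(x)/sd(y), rescaling
#'   invariant) or `"as-quoted"`.
#' @return Tibble: `estimate`, `std_estimate`, `se`, `p_value`, `n`.
#' @export
normal_rna_to_p53 <- function(data, normal_rna = "normal_rna",
                              tumor_p53 = "tumor_p53", tumor_type = "tumor_type",
                              standardization = c("conventional", "as-quoted")) {
  standardization <- rlang::arg_match(standardization)
  y <- data[[tumor_p53]]; x <- data[[normal_rna]]
  tt <- factor(data[[tumor_type]])
  uniform <- tapply(y, tt, function(v) length(unique(v)) == 1)
  if (any(uniform)) {
    warn(paste("dropping tumor type(s) with uniform p53 outcome:",
               paste(names(uniform)[uniform], collapse = ", ")))
    keep <- !tt %in% names(uniform)[uniform]
    y <- y[keep]; x <- x[keep]; tt <- droplevels(tt[keep])
  }
  fit <- if (nlevels(tt) > 1) lm(y ~ x + tt) else lm(y ~ x)
  sm <- summary(fit)$coefficients
  tibble(
    estimate = sm["x", 1],
    std_estimate = sm["x", 1] * std_factor(sd(x), sd(y), standardization),
    se = sm["x", 2], p_value = sm["x", 4], n = length(y)
  )
}
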