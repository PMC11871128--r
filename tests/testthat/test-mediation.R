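test_that("the OLS mediation identity holds on arbitrary inputs", {
  for (s in 1:3) {
    withr::local_seed(s)
    n <- 150
    d <- tibble::tibble(
      p53 = rbinom(n, 1, 0.4),
      rna = rexp(n) + 0.6 * p53,
      rt = 0.5 * rna + 0.3 * p53 + rnorm(n)
    )
    fit <- fit_mediation(d, n_boot = 50, seed = s)
    est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
    expect_lt(abs(est["tau"] - est["tau_prime"] - est["alpha"] * est["beta_prime"]),
              1e-10)
    fr <- fit$effects$fraction
    expect_equal(sum(fr), 1, tolerance = 1e-10)   # fractions sum to one
  }
  expect_error(fit_mediation(tibble::tibble(rt = rnorm(9), rna = rnorm(9),
                                            p53 = rep(1, 9))),
               class = "l1rt_degenerate")
})

test_that("standardized coefficients are invariant to affine rescaling", {
  withr::local_seed(11)
  n <- 400
  d <- tibble::tibble(p53 = rbinom(n, 1, 0.5))
  d$rna <- rnorm(n) + d$p53
  d$rt <- 0.4 * d$rna + 0.3 * d$p53 + rnorm(n)
  f1 <- fit_mediation(d, n_boot = 50, seed = 1)
  d2 <- dplyr::mutate(d, rt = 7 * rt, rna = rna / 100, p53 = 3 * p53)
  f2 <- fit_mediation(d2, n_boot = 50, seed = 1)
  expect_equal(f1$coefficients$std_estimate, f2$coefficients$std_estimate,
               tolerance = 1e-9)
  expect_equal(f1$effects$fraction, f2$effects$fraction, tolerance = 1e-9)
  # the as-quoted direction is available but is not rescaling invariant
  f3 <- fit_mediation(d, n_boot = 50, seed = 1, standardization = "as-quoted")
  expect_false(isTRUE(all.equal(f1$coefficients$std_estimate,
                                f3$coefficients$std_estimate)))
})

test_that("quintile stratification is balanced and localizes a planted high-RNA effect", {
  withr::local_seed(12)
  n <- 1000
  rna <- rnorm(n)
  p53 <- rbinom(n, 1, 0.5)
  rt <- rnorm(n) + ifelse(rna > quantile(rna, 0.6) & p53 == 1, 1.2, 0)
  d <- tibble::tibble(rt = rt, rna = rna, p53 = p53)
  res <- quintile_stratified_test(d)
  expect_true(all(abs(res$n_mut + res$n_wt - n / 5) <= 1))
  expect_true(all(res$p_adjusted[4:5] < 0.05))
  expect_true(all(res$p_adjusted[1:2] > 0.05))
  expect_error(quintile_stratified_test(d[1:30, ]), "50")
})

test_that("quintile tests are calibrated under the null", {
  flags <- vapply(1:100, function(s) {
    withr::local_seed(300 + s)
    d <- tibble::tibble(rt = rnorm(300), rna = rnorm(300),
                        p53 = rbinom(300, 1, 0.5))
    all(quintile_stratified_test(d)$p_adjusted >= 0.05, na.rm = TRUE)
  }, TRUE)
  expect_gte(mean(flags), 0.90)
})

test_that("LFS bootstrap preserves type composition and defaults to 10000 resamplings", {
  expect_equal(eval(formals(lfs_bootstrap_compare)$n_resamplings), 10000)
  # values coded by tumor type: type A near 0, type B near 100; the LFS set
  # is 2 A + 1 B, so every composition-preserving resampled mean is ~100/3
  withr::local_seed(13)
  n <- 300
  type <- rep(c("A", "B"), each = n / 2)
  vals <- ifelse(type == "A", rnorm(n, 0, 0.1), rnorm(n, 100, 0.1))
  lfs <- integer(n); lfs[c(1, 2, n / 2 + 1)] <- 1L
  p53 <- rep(1L, n)
  cmp <- lfs_bootstrap_compare(vals, lfs, type, p53, n_resamplings = 500, seed = 2)
  expect_true(all(abs(cmp$boot_means - 100 / 3) < 1))
  expect_equal(cmp$n_lfs, 3)

  expect_error(
    lfs_bootstrap_compare(vals, lfs, type, ifelse(type == "B", 0L, 1L)),
    "absent")
})

test_that("LFS comparison is calibrated when LFS values come from the pool itself", {
  flags <- vapply(1:60, function(s) {
    withr::local_seed(500 + s)
    n <- 240
    type <- sample(c("A", "B"), n, replace = TRUE)
    vals <- rnorm(n)
    lfs <- integer(n); lfs[sample.int(n, 8)] <- 1L
    cmp <- lfs_bootstrap_compare(vals, lfs, type, rep(1L, n),
                                 n_resamplings = 400, seed = s)
    cmp$p_value > 0.05
  }, TRUE)
  expect_gte(mean(flags), 0.9)
})

test_that("gene tests attempt 164 unstratified comparisons for 82 genes", {
  withr::local_seed(14)
  n <- 200
  genes <- sprintf("G%02d", 1:82)
  d <- tibble::tibble(rt = rnorm(n), rna = rnorm(n),
                      p53_mut = rbinom(n, 1, 0.5))
  for (g in genes) d[[g]] <- rbinom(n, 1, 0.3)
  res <- gene_stratified_tests(d, genes)
  expect_equal(sum(res$stratum == "all"), 164)
  expect_equal(nrow(res), 164 + 4 * 82)
  expect_true(all(!res$pass, na.rm = TRUE))   # null genes pass nowhere
})

test_that("a gene shifting RT by 2 SD in the p53-mutant stratum passes there only", {
  withr::local_seed(15)
  n <- 600
  d <- tibble::tibble(rt = rnorm(n), rna = rnorm(n),
                      p53_mut = rbinom(n, 1, 0.5))
  genes <- sprintf("G%d", 1:5)
  for (g in genes) d[[g]] <- rbinom(n, 1, 0.3)
  hit <- d$G1 == 1 & d$p53_mut == 1
  d$rt[hit] <- d$rt[hit] + 2 * sd(d$rt)
  res <- gene_stratified_tests(d, genes)
  passing <- res[which(res$pass), ]
  expect_true(all(passing$gene == "G1"))
  expect_true(any(passing$stratum == "p53_mut" & passing$endpoint == "RT"))
  expect_false(any(passing$stratum == "p53_wt"))
})

test_that("normal-tissue RNA model is calibrated, invariant, and powered", {
  # null: noise RNA gives a near-zero standardized coefficient
  withr::local_seed(16)
  ps <- vapply(1:40, function(s) {
    d <- tibble::tibble(normal_rna = rnorm(400),
                        tumor_p53 = rbinom(400, 1, 0.4),
                        tumor_type = sample(c("A", "B", "C"), 400, TRUE))
    normal_rna_to_p53(d)$p_value
  }, 0)
  expect_gt(mean(ps), 0.3); expect_lt(mean(ps), 0.7)

  # rescaling RNA by 1000 leaves the standardized coefficient unchanged
  d <- tibble::tibble(normal_rna = rnorm(400), tumor_p53 = rbinom(400, 1, 0.4),
                      tumor_type = sample(c("A", "B"), 400, TRUE))
  f1 <- normal_rna_to_p53(d)
  f2 <- normal_rna_to_p53(dplyr::mutate(d, normal_rna = normal_rna * 1000))
  expect_equal(f1$std_estimate, f2$std_estimate, tolerance = 1e-10)

  # power: a 0.2-per-SD shift in mutation probability is detected at n = 600
  hits <- vapply(1:30, function(s) {
    withr::local_seed(700 + s)
    z <- rnorm(600)
    pr <- pmin(0.95, pmax(0.05, 0.4 + 0.2 * z))
    d <- tibble::tibble(normal_rna = z, tumor_p53 = rbinom(600, 1, pr),
                        tumor_type = sample(c("A", "B", "C"), 600, TRUE))
    normal_rna_to_p53(d)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("tidy and glance methods expose the fitted quantities", {
  withr::local_seed(17)
  n <- 300
  d <- tibble::tibble(p53 = rbinom(n, 1, 0.5))
  d$rna <- rnorm(n) + d$p53
  d$rt <- 0.4 * d$rna + 0.3 * d$p53 + rnorm(n)
  fit <- fit_mediation(d, n_boot = 100, seed = 1)
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("tau", "beta", "alpha", "beta_prime",
                             "tau_prime", "beta_star", "alpha_star"))
  gl <- generics::glance(fit)
  expect_equal(gl$mediated_fraction + gl$unmediated_fraction, 1,
               tolerance = 1e-10)
})
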