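#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.l1_mediation <- function(x, ...) x$coefficients

#' @export
glance.l1_mediation <- function(x, ...) {
  e <- x$effects
  tibble(
    n = x$n,
    mediated_fraction = e$fraction[e$effect == "mediated"],
    unmediated_fraction = e$fraction[e$effect == "unmediated"],
    mediated_std = e$std_estimate[e$effect == "mediated"],
    tau_prime_std = e$std_estimate[e$effect == "unmediated"],
    standardization = x$standardization
  )
}

#' @export
tidy.l1_efficiency_fit <- function(x, ...) {
  rename(x$efficiencies, term = "locus")
}

#' @export
glance.l1_efficiency_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_loci = nrow(x$efficiencies),
         sigma = x$sigma, df_residual = x$df_residual)
}

#' @export
tidy.l1_cluster_model <- function(x, ...) x$coefficients

#' @export
glance.l1_cluster_model <- function(x, ...) {
  tibble(fit_correlation = x$fit_correlation,
         r_squared = summary(x$lm)$r.squared,
         n = length(x$fitted))
}

#' @export
tidy.l1_total_rt_fit <- function(x, ...) {
  rename(x$coefficients, term = "locus")
}

#' @export
tidy.l1_lfs_comparison <- function(x, ...) {
  tibble(lfs_mean = x$lfs_mean, boot_mean = mean(x$boot_means),
         ci_lower = x$ci[1], ci_upper = x$ci[2],
         p_value = x$p_value, n_lfs = x$n_lfs,
         n_resamplings = x$n_resamplings)
}
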