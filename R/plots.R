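#' Histogram of inserted lengths for canonical calls
#'
#' @param calls An `l1_calls` tibble.
#' @param binwidth Histogram bin width (nt).
#' @return A ggplot object.
#' @export
plot_insertion_lengths <- function(calls, binwidth = 250) {
  df <- filter(calls, .data$class == "canonical", !is.na(.data$inserted_length))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$inserted_length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::labs(x = "Inserted L1 length (nt)", y = "Calls",
                  title = "Canonical insertion lengths") +
    ggplot2::theme_minimal()
}

#' Inversion rate per group with exact confidence intervals
#'
#' @param data Tibble with one row per group: `group`, `k` (inversions),
#'   `n` (total calls).
#' @param level Confidence level (default 0.99, Clopper-Pearson).
#' @return A ggplot object.
#' @export
plot_inversion_rates <- function(data, level = 0.99) {
  ci <- inversion_rate_ci(data$k, data$n, level)
  df <- dplyr::bind_cols(data, ci)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = "Inversion fraction") +
    ggplot2::theme_minimal()
}

#' Mediated vs unmediated contribution of p53 to RT burden
#'
#' @param x An [fit_mediation()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.l1_mediation <- function(x, ...) {
  df <- x$effects
  ggplot2::ggplot(df, ggplot2::aes(x = .data$std_estimate, y = .data$effect)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$effect), show.legend = FALSE) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$std_lower, xmax = .data$std_upper), height = 0.2) +
    ggplot2::labs(x = "Standardized effect on RT burden", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of locus activity across tumor types
#'
#' @param am An [build_activity_matrix()] object.
#' @param which `"rna"` or `"trt"`.
#' @return A ggplot object.
#' @export
plot_locus_activity <- function(am, which = c("rna", "trt")) {
  which <- rlang::arg_match(which)
  m <- am[[which]]
  df <- as_tibble(m, rownames = "locus") |>
    tidyr::pivot_longer(-"locus", names_to = "tumor_type", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tumor_type, y = .data$locus,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = paste("mean log2", toupper(which))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
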