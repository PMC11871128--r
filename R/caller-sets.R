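#' Intersect two call sets
#'
#' Calls from the same sample and chromosome with positions within `window`
#' bp of each other are considered shared. Matching is greedy
#' nearest-neighbor (smallest offset first, then lowest coordinate), each
#' call matched at most once; the operation is symmetric up to swapping the
#' `a_only`/`b_only` outputs.
#'
#' @param set_a,set_b Call tibbles with `call_id`, `sample_id`, `chrom`,
#'   `pos` columns.
#' @param window Maximum position offset considered shared (bp, default 50).
#' @return List with `shared` (tibble of matched `a_id`, `b_id`, `offset`),
#'   `a_only`, and `b_only` (the unmatched rows of each input).
#' @export
intersect_callsets <- function(set_a, set_b, window = 50L) {
  if (anyDuplicated(set_a$call_id) || anyDuplicated(set_b$call_id)) {
    abort("duplicate call ids")
  }
  cand <- dplyr::inner_join(
    set_a |> select(all_of(c("call_id", "sample_id", "chrom", "pos"))) |>
      rename(a_id = "call_id", a_pos = "pos"),
    set_b |> select(all_of(c("call_id", "sample_id", "chrom", "pos"))) |>
      rename(b_id = "call_id", b_pos = "pos"),
    by = c("sample_id", "chrom"), relationship = "many-to-many"
  ) |>
    mutate(offset = abs(.data$a_pos - .data$b_pos)) |>
    filter(.data$offset <= window) |>
    arrange(.data$offset, pmin(.data$a_pos, .data$b_pos))
  used_a <- used_b <- character()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!cand$a_id[i] %in% used_a && !cand$b_id[i] %in% used_b) {
      keep[i] <- TRUE
      used_a <- c(used_a, cand$a_id[i]); used_b <- c(used_b, cand$b_id[i])
    }
  }
  shared <- cand[keep, c("a_id", "b_id", "sample_id", "chrom", "offset")]
  list(
    shared = shared,
    a_only = filter(set_a, !.data$call_id %in% shared$a_id),
    b_only = filter(set_b, !.data$call_id %in% shared$b_id)
  )
}

#' Exact Clopper-Pearson confidence interval for a proportion
#'
#' Exact binomial tail-inversion interval, used for inversion rates across
#' cancer subtypes at the 99% level.
#'
#' @param k Number of successes (e.g. inversion-containing calls).
#' @param n Number of trials (total calls, >= 1).
#' @param level Confidence level (default 0.99).
#' @return Tibble: `estimate` (k/n), `lower`, `upper`.
#' @export
inversion_rate_ci <- function(k, n, level = 0.99) {
  if (any(n < 1)) abort("n must be >= 1", class = "l1rt_undefined")
  if (any(k < 0 | k > n)) abort("k must satisfy 0 <= k <= n")
  alpha <- 1 - level
  lower <- if_else(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  upper <- if_else(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  tibble(estimate = k / n, lower = lower, upper = upper)
}

#' Write calls as TSV
#'
#' Fixed column order; list-columns are dropped.
#'
#' @param calls An `l1_calls` tibble.
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  cols <- c("call_id", "sample_id", "chrom", "pos", "class", "inserted_length",
            "second_priming", "length_lower_bound", "tsd_len", "tsd_deletion",
            "strand", "polyA_support", "clip_support", "discordant_support",
            "td_source", "td_chrom", "td_start", "td_end", "td_multimap",
            "status")
  readr::write_tsv(calls[intersect(cols, names(calls))], path)
  invisible(path)
}

#' Write calls as a minimal VCF
#'
#' Emits INS records with INFO keys CLASS, SVLEN, TSD, POLYA, TDSRC, STATUS.
#'
#' @param calls An `l1_calls` tibble.
#' @param path Output path.
#' @param ref Optional reference object for contig header lines.
#' @export
write_calls_vcf <- function(calls, path, ref = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=INS:ME:LINE1,Description=\"LINE-1 mobile element insertion\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"canonical or inversion\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Inserted length\">",
    "##INFO=<ID=TSD,Number=1,Type=Integer,Description=\"Target site duplication length\">",
    "##INFO=<ID=POLYA,Number=0,Type=Flag,Description=\"Poly(A) tail support\">",
    "##INFO=<ID=TDSRC,Number=1,Type=String,Description=\"Transduction source id\">",
    "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"somatic, pseudo-germline, or unresolved\">"
  )
  if (!is.null(ref)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(ref$genome), nchar(unname(ref$genome))))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- paste0(
    "CLASS=", calls$class,
    if_else(is.na(calls$inserted_length), "", paste0(";SVLEN=", calls$inserted_length)),
    if_else(is.na(calls$tsd_len), "", paste0(";TSD=", calls$tsd_len)),
    if_else(calls$polyA_support, ";POLYA", ""),
    if_else(is.na(calls$td_source), "", paste0(";TDSRC=", calls$td_source)),
    ";STATUS=", calls$status
  )
  body <- sprintf("%s\t%d\t%s\tN\t<INS:ME:LINE1>\t.\tPASS\t%s",
                  calls$chrom, calls$pos, calls$call_id, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
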