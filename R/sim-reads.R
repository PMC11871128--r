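#' Read-simulation parameters
#'
#' @param read_len Read length in nt (>= 100; shorter reads map split reads
#'   unreliably).
#' @param frag_mean,frag_sd Fragment length distribution (Normal, truncated
#'   below at `2 * read_len`).
#' @param coverage Fold coverage of the haplotype set.
#' @param base_error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return List of class `read_sim_params`.
#' @export
read_sim_params <- function(read_len = 150L, frag_mean = 450, frag_sd = 60,
                            coverage = 30, base_error_rate = 0, seed = 1L) {
  if (read_len < 100) abort("read_len must be >= 100")
  if (frag_mean <= 2 * read_len) abort("frag_mean must exceed 2 * read_len")
  stopifnot_scalar_prob(base_error_rate, "base_error_rate")
  structure(list(read_len = as.integer(read_len), frag_mean = frag_mean,
                 frag_sd = frag_sd, coverage = coverage,
                 base_error_rate = base_error_rate, seed = as.integer(seed)),
            class = "read_sim_params")
}

# inject uniform substitution errors into a character vector of reads
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  nch <- nchar(seqs)
  nerr <- rbinom(length(seqs), nch, rate)
  hit <- which(nerr > 0)
  for (i in hit) {
    pos <- sample.int(nch[i], nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1L), "")
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate paired-end reads from haplotypes
#'
#' Fragment start positions are uniform over each haplotype (number of
#' fragments proportional to haplotype length so coverage is even); fragment
#' lengths are Normal(`frag_mean`, `frag_sd`) truncated at `2 * read_len`;
#' mates are forward/reverse; per-base substitution errors are applied at
#' `base_error_rate`. Base qualities are constant Q30.
#'
#' @param haplotypes Named character vector of haplotype sequences, or an
#'   `l1_haplotype` object (its single contig is used).
#' @param params A [read_sim_params()] object.
#' @return Tibble of class `l1_read_set`: one row per fragment with
#'   `read_id`, `hap`, `frag_start` (0-based), `frag_len`, `seq1`, `seq2`
#'   (read 2 reverse-complemented, as sequenced).
#' @export
simulate_reads <- function(haplotypes, params = read_sim_params()) {
  if (inherits(haplotypes, "l1_haplotype")) haplotypes <- haplotypes$seq
  if (params$coverage <= 0) abort("coverage must be > 0")
  withr::local_seed(params$seed)
  rl <- params$read_len
  out <- vector("list", length(haplotypes))
  for (h in seq_along(haplotypes)) {
    hap <- haplotypes[[h]]
    hlen <- nchar(hap)
    if (hlen < params$frag_mean + 4 * params$frag_sd) {
      abort("haplotype shorter than frag_mean + 4*frag_sd")
    }
    nfrag <- round(params$coverage * hlen / (2 * rl))
    flen <- pmax(2L * rl, round(rnorm(nfrag, params$frag_mean, params$frag_sd)))
    fstart <- floor(runif(nfrag, 0, hlen - flen))  # 0-based
    seq1 <- substr0(hap, fstart, fstart + rl)
    seq2 <- revcomp(substr0(hap, fstart + flen - rl, fstart + flen))
    out[[h]] <- tibble(
      read_id = sprintf("%s_frag%07d", names(haplotypes)[h], seq_len(nfrag)),
      hap = names(haplotypes)[h],
      frag_start = as.integer(fstart), frag_len = as.integer(flen),
      seq1 = inject_errors(seq1, params$base_error_rate),
      seq2 = inject_errors(seq2, params$base_error_rate)
    )
  }
  res <- bind_rows(out)
  attr(res, "read_len") <- rl
  class(res) <- c("l1_read_set", class(res))
  res
}

#' Write simulated reads as a gzipped FASTQ pair
#'
#' @param reads An [simulate_reads()] tibble.
#' @param prefix Output prefix; writes `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz"))
  q <- Biostrings::BStringSet(strrep("?", nchar(reads$seq1)))  # Q30
  s1 <- Biostrings::DNAStringSet(setNames(reads$seq1, reads$read_id))
  s2 <- Biostrings::DNAStringSet(setNames(reads$seq2, reads$read_id))
  Biostrings::writeXStringSet(s1, paths[1], compress = TRUE, format = "fastq", qualities = q)
  Biostrings::writeXStringSet(s2, paths[2], compress = TRUE, format = "fastq", qualities = q)
  invisible(paths)
}
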