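# Shared simulation fixture, built once per test run: a small reference with
# two source loci and eight insertions (mixed classes), 30x error-free reads,
# and oracle alignments.
sim_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cons <- l1_consensus(length = 4000, seed = 7)
      ref <- build_reference(400000, 2, cons, seed = 3, flank_len = 250)
      specs <- random_insertion_specs(
        10, ref, seed = 11, min_gap = 9000, p_inversion = 0.3,
        p_transduction = 0.3,
        len_range = c(300L, 3800L), transduction_range = c(120L, 200L)
      )
      hap <- apply_insertions(ref, specs)
      reads <- simulate_reads(hap, read_sim_params(coverage = 30, seed = 5))
      aln <- oracle_align(reads, hap, ref)
      cache <<- list(cons = cons, ref = ref, specs = specs, hap = hap,
                     reads = reads, aln = aln)
    }
    cache
  }
})

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# One fully-specified alignment record; override fields as needed.
make_rec <- function(qname = "r1", mate = 1L, chrom = "chr1", pos = 1000L,
                     mapq = 60L, cigar = "150M", left_soft = 0L, right_soft = 0L,
                     left_hard = 0L, right_hard = 0L, reverse = FALSE,
                     seq = strrep("A", 150L), qual = strrep("?", nchar(seq)),
                     proper = TRUE, duplicate = FALSE, supplementary = FALSE,
                     mate_chrom = chrom, mate_pos = pos + 250L,
                     mate_reverse = !reverse, tlen = 400L) {
  tibble::tibble(
    qname = qname, mate = mate, chrom = chrom, pos = pos, mapq = mapq,
    cigar = cigar, left_soft = left_soft, right_soft = right_soft,
    left_hard = left_hard, right_hard = right_hard, reverse = reverse,
    seq = seq, qual = qual, proper = proper, duplicate = duplicate,
    supplementary = supplementary, mate_chrom = mate_chrom,
    mate_pos = mate_pos, mate_reverse = mate_reverse, tlen = tlen
  )
}

# n proper read pairs tiling a contig; insert sizes default to 400
make_pairs <- function(n, insert = 400L, read_len = 150L, start = 1000L) {
  pos1 <- start + (seq_len(n) - 1L) * 10L
  dplyr::bind_rows(
    make_rec(qname = sprintf("p%03d", seq_len(n)), mate = 1L, pos = pos1,
             seq = strrep("A", read_len), mate_pos = pos1 + insert - read_len,
             tlen = insert),
    make_rec(qname = sprintf("p%03d", seq_len(n)), mate = 2L,
             pos = pos1 + insert - read_len, reverse = TRUE,
             seq = strrep("A", read_len), mate_pos = pos1,
             mate_reverse = FALSE, tlen = -insert)
  )
}

# greedy truth-vs-call matching within a breakpoint tolerance
match_calls <- function(calls, truth, tol = 5L) {
  used <- rep(FALSE, nrow(calls))
  idx <- integer(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d <- abs(calls$pos - 1L - truth$left_bp[i])
    d[used] <- .Machine$integer.max
    j <- which.min(d)
    idx[i] <- if (length(j) && d[j] <= tol) {
      used[j] <- TRUE
      j
    } else NA_integer_
  }
  idx
}
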