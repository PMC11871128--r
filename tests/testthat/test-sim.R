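test_that("reference construction is deterministic and places sources cleanly", {
  cons <- l1_consensus(length = 2000, seed = 1)
  r1 <- build_reference(150000, 3, cons, seed = 9)
  r2 <- build_reference(150000, 3, cons, seed = 9)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$sources, r2$sources)

  expect_equal(nrow(r1$sources), 3)
  s <- dplyr::arrange(r1$sources, start)
  expect_true(all(s$end[-3] <= s$start[-1]))          # pairwise non-overlapping
  expect_true(all(s$end - s$start == cons$length))
  # each embedded copy is the consensus; each flank is where it claims to be
  for (i in 1:3) {
    expect_identical(substring(r1$genome[[1]], s$start[i] + 1, s$end[i]), cons$sequence)
    expect_identical(substring(r1$genome[[1]], s$end[i] + 1, s$end[i] + 200),
                     s$downstream_unique_flank[i])
  }
})

test_that("a source-free genome shares no 50-mer with the consensus", {
  cons <- l1_consensus(length = 2000, seed = 2)
  ref <- build_reference(120000, 0, cons, seed = 5)
  kmers <- substring(cons$sequence, 1:(cons$length - 49), 50:cons$length)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  hits <- Biostrings::countPDict(pd, Biostrings::DNAString(ref$genome[[1]]))
  expect_equal(sum(hits), 0)
})

test_that("insertion realisation duplicates the target site and respects length accounting", {
  cons <- l1_consensus(length = 2000, seed = 3)
  ref <- build_reference(120000, 0, cons, seed = 6)
  spec <- insertion_spec("chr1", 50000L, tsd_len = 15L, inserted_len = 800L,
                         polyA_len = 20L)
  hap <- apply_insertions(ref, spec)
  tr <- hap$truth
  site <- substring(ref$genome[[1]], 50001, 50015)
  # the 15-nt target site flanks the cassette as two exact tandem copies
  expect_identical(substring(hap$seq[[1]], tr$hap_start - 14, tr$hap_start), site)
  expect_identical(substring(hap$seq[[1]], tr$hap_end + 1, tr$hap_end + 15), site)
  # TSD conservation: haplotype length = reference + cassette + tsd
  expect_equal(nchar(hap$seq[[1]]),
               nchar(ref$genome[[1]]) + 800 + 20 + 15)
  expect_equal(tr$right_bp - tr$left_bp, 15L)
})

test_that("a full-length canonical insertion carries the whole consensus", {
  cons <- l1_consensus(length = 1500, seed = 4)
  ref <- build_reference(110000, 0, cons, seed = 6)
  spec <- insertion_spec("chr1", 40000L, inserted_len = cons$length, polyA_len = 12L)
  hap <- apply_insertions(ref, spec)
  expect_identical(substr(hap$truth$inserted_seq, 1, cons$length), cons$sequence)
})

test_that("twin-priming specs yield two consensus fragments in opposite orientations", {
  cons <- l1_consensus(length = 2000, seed = 5)
  ref <- build_reference(110000, 0, cons, seed = 6)
  f <- cons$length - 1200L; j <- f + 500L
  spec <- insertion_spec("chr1", 40000L, inserted_len = 1200L,
                         inversion_junction = j, polyA_len = 10L)
  hap <- apply_insertions(ref, spec)
  ins <- hap$truth$inserted_seq
  # brute-force orientation scan: the 5'-ward fragment matches the reverse
  # complement of the consensus, the 3'-ward fragment the forward strand
  frag5 <- substr(ins, 1, 500)
  frag3 <- substr(ins, 501, 1200)
  expect_equal(length(Biostrings::matchPattern(frag5, cons$sequence)), 0)
  expect_equal(
    length(Biostrings::matchPattern(revcomp_chr(frag5), cons$sequence)), 1)
  expect_equal(length(Biostrings::matchPattern(frag3, cons$sequence)), 1)

  # a junction outside the inserted interval is rejected
  bad <- insertion_spec("chr1", 40000L, inserted_len = 1200L,
                        inversion_junction = f - 100L)
  expect_error(apply_insertions(ref, bad), class = "l1rt_spec_error")
})

test_that("read simulation is deterministic, exact without errors, and hits coverage", {
  fx <- sim_fixture()
  r2 <- simulate_reads(fx$hap, read_sim_params(coverage = 30, seed = 5))
  expect_identical(fx$reads$seq1, r2$seq1)
  expect_identical(fx$reads$seq2, r2$seq2)

  # error-free reads are exact substrings of the haplotype
  idx <- c(1L, 50L, nrow(fx$reads))
  for (i in idx) {
    s <- fx$reads$frag_start[i]
    expect_identical(fx$reads$seq1[i], substring(fx$hap$seq[[1]], s + 1, s + 150))
  }

  total_bases <- 2 * 150 * nrow(fx$reads)
  expect_lt(abs(total_bases / (30 * nchar(fx$hap$seq[[1]])) - 1), 0.05)

  short <- setNames(strrep("ACGT", 50), "tiny")
  expect_error(simulate_reads(short, read_sim_params(coverage = 5)))
})

test_that("oracle alignments have exact clip geometry at junctions", {
  fx <- sim_fixture()
  tr <- fx$hap$truth[1, ]
  rl <- 150L
  # a read entering the cassette by 60 nt from the left flank
  reads <- tibble::tibble(
    read_id = c("span", "flank", "deep"),
    hap = names(fx$hap$seq),
    frag_start = c(tr$hap_start - 90L,   # read1 crosses left junction by 60
                   tr$hap_start - 400L,  # pair fully in the left flank
                   tr$hap_start - 110L), # read1 spans, mate inside cassette
    frag_len = c(400L, 380L, 420L)
  )
  reads$seq1 <- substring(fx$hap$seq[[1]], reads$frag_start + 1, reads$frag_start + rl)
  reads$seq2 <- revcomp_chr(substring(fx$hap$seq[[1]],
                                      reads$frag_start + reads$frag_len - rl + 1,
                                      reads$frag_start + reads$frag_len))
  attr(reads, "read_len") <- rl
  aln <- oracle_align(reads, fx$hap, fx$ref)

  span1 <- aln[aln$qname == "span" & aln$mate == 1L, ]
  expect_equal(span1$right_soft, 60L)
  expect_equal(span1$pos - 1L + (rl - 60L), tr$right_bp)  # clip at the breakpoint

  flank <- aln[aln$qname == "flank", ]
  expect_true(all(flank$proper))
  expect_true(all(flank$left_soft == 0 & flank$right_soft == 0))

  deep <- aln[aln$qname == "deep", ]
  expect_false(any(deep$proper))
  # the clipped tail is the start of the inserted sequence
  d1 <- deep[deep$mate == 1L, ]
  expect_identical(substr(d1$seq, rl - d1$right_soft + 1L, rl),
                   substr(tr$inserted_seq, 1, d1$right_soft))
})

test_that("SAM round trip preserves the record fields", {
  fx <- sim_fixture()
  sub <- head(fx$aln[!is.na(fx$aln$chrom), ], 200)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(sub, path, fx$ref)
  back <- read_sam(path)
  expect_equal(nrow(back), 200)
  expect_identical(back$qname, sub$qname)
  expect_identical(back$pos, sub$pos)
  expect_identical(back$cigar, sub$cigar)
  expect_identical(back$left_soft, sub$left_soft)
  expect_identical(back$seq, sub$seq)
  expect_identical(back$proper, sub$proper)
})
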