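test_that("sample QC computes the five metrics with the read filters applied", {
  ok <- make_pairs(98)
  chim <- dplyr::bind_rows(
    make_rec(qname = c("c1", "c2"), pos = c(5000L, 6000L),
             mate_pos = c(205000L, 206000L), tlen = 200000L, proper = FALSE),
    make_rec(qname = c("c1", "c2"), mate = 2L, pos = c(205000L, 206000L),
             reverse = TRUE, mate_pos = c(5000L, 6000L), mate_reverse = FALSE,
             tlen = -200000L, proper = FALSE)
  )
  qc <- compute_sample_qc(dplyr::bind_rows(ok, chim), genome_length = 1e6)
  expect_equal(qc$chimeric_read_fraction, 4 / 200)   # 2 of 100 pairs
  expect_equal(qc$mean_read_length, 150)
  expect_equal(qc$clipped_base_fraction, 0)
  expect_equal(qc$mean_base_quality, 30)
  expect_equal(qc$coverage, 200 * 150 / 1e6)

  # a duplicate-flagged read contributes to no metric
  dup <- make_rec(qname = "dup", duplicate = TRUE, seq = strrep("A", 40),
                  qual = strrep("#", 40))
  qc2 <- compute_sample_qc(dplyr::bind_rows(ok, chim, dup), genome_length = 1e6)
  expect_equal(qc2, qc)

  # all reads filtered -> error naming the consuming filter
  expect_error(compute_sample_qc(dup, 1e6), "duplicate",
               class = "l1rt_empty_input")
})

test_that("QC metrics are stable under dataset duplication and match a naive second pass", {
  fx <- sim_fixture()
  sub <- head(fx$aln, 4000)
  qc1 <- compute_sample_qc(sub, 4e5)
  qc2 <- compute_sample_qc(dplyr::bind_rows(sub, sub), 4e5)
  expect_equal(qc1$chimeric_read_fraction, qc2$chimeric_read_fraction)
  expect_equal(qc1$clipped_base_fraction, qc2$clipped_base_fraction)
  expect_equal(qc1$mean_read_length, qc2$mean_read_length)
  expect_equal(qc1$mean_base_quality, qc2$mean_base_quality)

  # clipped_base_fraction equals (sum of clip lengths)/(sum of read lengths)
  # recomputed naively on the filtered records
  keep <- sub[!is.na(sub$chrom) & sub$mapq > 0 & !sub$duplicate, ]
  naive <- sum(keep$left_soft + keep$right_soft) / sum(nchar(keep$seq))
  expect_equal(qc1$clipped_base_fraction, naive)
})

test_that("pair filtering applies the chimeric/depth thresholds exactly", {
  pairs <- tibble::tibble(
    pair_id = sprintf("P%d", 1:7),
    tumor_chimeric_read_fraction  = c(0.025, 0.010, 0.010, 0.010, 0.020, 0.010, 0.030),
    normal_chimeric_read_fraction = c(0.010, 0.010, 0.010, 0.021, 0.020, 0.010, 0.010),
    tumor_coverage                = c(60,    60,    45,    60,    60,    50,    45),
    normal_coverage               = c(25,    25,    25,    25,    25,    20,    15)
  )
  out <- filter_sample_pairs(pairs)
  expect_equal(out$kept, c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$reasons[1], "tumor_chimeric")
  expect_equal(out$reasons[3], "tumor_depth")
  expect_equal(out$reasons[4], "normal_chimeric")
  expect_equal(out$reasons[7], "tumor_chimeric,tumor_depth,normal_depth")
  # boundary values (exactly 2%, exactly 50x/20x) are kept
  expect_true(all(out$kept[c(5, 6)]))

  expect_error(filter_sample_pairs(pairs[, 1:3]), class = "l1rt_pairing_error")
})

test_that("soft clips on primaries become evidence; short clips are ignored", {
  seq <- paste0(strrep("G", 90), strrep("C", 60))
  rec <- make_rec(pos = 10001L, cigar = "90M60S", right_soft = 60L, seq = seq)
  ev <- extract_clips(rec, min_clip = 20)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$side, "right")
  expect_equal(ev$bp, 10000L + 90L)
  expect_identical(ev$clip_seq, strrep("C", 60))
  expect_false(ev$from_supplementary)

  tiny <- make_rec(cigar = "5S145M", left_soft = 5L)
  expect_equal(nrow(extract_clips(tiny, min_clip = 20)), 0)
})

test_that("hard-clipped supplementary tails are reconstructed from the primary", {
  full <- paste0(strrep("A", 100), strrep("T", 50))
  primary <- make_rec(qname = "h1", pos = 5001L, cigar = "100M50S",
                      right_soft = 50L, seq = full)
  sup <- make_rec(qname = "h1", pos = 9001L, cigar = "100H50M",
                  left_hard = 100L, seq = strrep("T", 50),
                  qual = strrep("?", 50), supplementary = TRUE)
  ev <- extract_clips(dplyr::bind_rows(primary, sup), min_clip = 20)
  sup_ev <- ev[ev$from_supplementary, ]
  expect_equal(nrow(sup_ev), 1)
  expect_equal(sup_ev$side, "left")
  expect_equal(sup_ev$bp, 9000L)
  expect_identical(sup_ev$clip_seq, strrep("A", 100))  # the primary's aligned span

  orphan <- make_rec(qname = "noprim", pos = 9001L, cigar = "100H50M",
                     left_hard = 100L, seq = strrep("T", 50),
                     qual = strrep("?", 50), supplementary = TRUE)
  expect_warning(ev2 <- extract_clips(orphan, min_clip = 20), "supplementary")
  expect_equal(nrow(ev2), 0)
})

test_that("discordant extraction keys on the mate's L1 placement", {
  bed <- tibble::tibble(chrom = "chr1", start = 700000L, end = 706000L, id = "L1copy_A")
  in_copy <- make_rec(qname = "d1", pos = 5000L, proper = FALSE,
                      mate_chrom = "chr1", mate_pos = 702000L)
  on_cons <- make_rec(qname = "d2", pos = 6000L, proper = FALSE,
                      mate_chrom = "L1_consensus", mate_pos = 1200L)
  proper <- make_rec(qname = "d3", pos = 7000L, proper = TRUE,
                     mate_chrom = "chr1", mate_pos = 7300L)
  mapq0 <- make_rec(qname = "d4", pos = 8000L, mapq = 0L, proper = FALSE,
                    mate_chrom = "L1_consensus", mate_pos = 100L)
  ev <- extract_discordant(dplyr::bind_rows(in_copy, on_cons, proper, mapq0),
                           bed, "L1_consensus")
  expect_equal(nrow(ev), 2)
  expect_equal(ev$mate_class[ev$qname == "d1"], "L1copy_A")
  expect_equal(ev$mate_class[ev$qname == "d2"], "consensus-L1")

  bad_bed <- tibble::tibble(chrom = "chr1", start = 10L, end = 5L, id = "x")
  expect_error(extract_discordant(in_copy, bad_bed, character()),
               class = "l1rt_parse_error")
})

test_that("every deep junction crossing in the simulation yields clip evidence", {
  fx <- sim_fixture()
  clips <- extract_clips(fx$aln, 20, contigs = names(fx$ref$genome))
  for (i in seq_len(nrow(fx$hap$truth))) {
    tr <- fx$hap$truth[i, ]
    expect_true(any(clips$side == "left" & abs(clips$bp - tr$left_bp) <= 5),
                label = sprintf("left junction of %s has clip evidence", tr$insertion_id))
    expect_true(any(clips$side == "right" & abs(clips$bp - tr$right_bp) <= 5),
                label = sprintf("right junction of %s has clip evidence", tr$insertion_id))
  }
})
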