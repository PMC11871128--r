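test_that("clip realignment finds exact substrings on either strand and rejects noise", {
  fx <- sim_fixture()
  cons <- fx$cons
  sub_f <- substring(cons$sequence, 3901, 3960)
  al <- realign_clip(sub_f, cons)
  expect_true(al$accepted)
  expect_equal(al$cons_start, 3900L)
  expect_equal(al$orient, "+")

  sub_r <- revcomp_chr(substring(cons$sequence, 101, 160))
  al2 <- realign_clip(sub_r, cons)
  expect_true(al2$accepted)
  expect_equal(al2$orient, "-")
  expect_equal(al2$cons_start, 100L)

  # empirical null: random 60-mers essentially never reach the acceptance
  # threshold
  withr::with_seed(42, {
    rand <- vapply(1:300, function(i)
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""), "")
  })
  al3 <- realign_clip(rand, cons)
  expect_equal(sum(al3$accepted), 0)
})

test_that("poly tract detection follows the length and purity contract", {
  expect_equal(detect_poly_tract(strrep("T", 15))$tract, "polyT")
  expect_equal(detect_poly_tract("ACGTACGTACGT")$tract, "none")
  # 18 T with 2 interleaved C: purity 0.9 >= 0.8, length 20 >= 10
  tt <- paste0(strrep("T", 9), "C", strrep("T", 9), "C")
  res <- detect_poly_tract(tt, min_len = 10, purity = 0.8)
  expect_equal(res$tract, "polyT")
  expect_gte(res$tract_len, 10)
  # at the far end
  expect_equal(detect_poly_tract(paste0("ACGTACGTACGT", strrep("A", 12)),
                                 end = "end")$tract, "polyA")
})

test_that("evidence clustering merges within the window and pairs breakpoints across the TSD", {
  mk_clip <- function(bp, side) tibble::tibble(
    qname = sprintf("c%d", seq_along(bp)), mate = 1L, chrom = "chr1",
    bp = bp, side = side, clip_seq = strrep("A", 30), from_supplementary = FALSE
  )
  cl1 <- cluster_evidence(mk_clip(c(1000L, 1000L), c("right", "right")))
  expect_equal(nrow(cl1), 1)
  expect_equal(cl1$n_clips, 2)

  cl2 <- cluster_evidence(mk_clip(c(1000L, 1200L), c("right", "right")))
  expect_equal(nrow(cl2), 2)

  cl3 <- cluster_evidence(mk_clip(c(1000L, 1015L), c("left", "right")))
  expect_equal(nrow(cl3), 1)
  expect_equal(cl3$left_bp, 1000L)
  expect_equal(cl3$right_bp, 1015L)

  expect_equal(nrow(cluster_evidence(mk_clip(integer(), character()))), 0)
})

test_that("resolved calls recover class, length, TSD, and strand from the simulation", {
  fx <- sim_fixture()
  calls <- call_insertions(fx$aln, fx$aln, fx$ref, "s1")
  tr <- fx$hap$truth
  idx <- match_calls(calls, tr)
  expect_false(any(is.na(idx)))
  expect_identical(calls$class[idx], tr$class)
  expect_identical(calls$tsd_len[idx], tr$tsd_len)
  expect_identical(calls$strand[idx], tr$strand)
  canon <- tr$class == "canonical"
  expect_identical(calls$inserted_length[idx][canon], tr$inserted_len[canon])
  inv <- which(!canon)
  expect_identical(calls$second_priming[idx][inv], tr$inversion_junction[inv])
  # partition: every call has exactly one status
  expect_true(all(calls$status %in% c("somatic", "pseudo-germline", "unresolved")))
})

test_that("transductions are attributed to their true source", {
  fx <- sim_fixture()
  calls <- call_insertions(fx$aln, fx$aln, fx$ref, "s1")
  tr <- fx$hap$truth
  idx <- match_calls(calls, tr)
  tds <- which(!is.na(tr$transduction_source) & tr$transduction_len >= 100)
  expect_gt(length(tds), 0)
  for (i in tds) {
    expect_match(calls$td_source[idx[i]], tr$transduction_source[i])
  }
})

test_that("sources within 1000 bp are grouped; L1-overlapping mappings drop the annotation", {
  fx <- sim_fixture()
  ref <- fx$ref
  src1 <- dplyr::arrange(ref$sources, start)[1, ]
  # a phantom second registry entry whose 3' end sits 800 bp upstream
  ghost <- src1
  ghost$id <- "S_ghost"
  ghost$start <- src1$start - 800L
  ghost$end <- src1$end - 800L
  ref2 <- ref
  ref2$sources <- dplyr::bind_rows(ref$sources, ghost)

  spec <- insertion_spec(names(ref$genome)[1], src1$end + 50000L,
                         inserted_len = 1500L, polyA_len = 15L,
                         transduction_source = src1$id, transduction_len = 150L)
  hap <- apply_insertions(ref, spec)
  reads <- simulate_reads(hap, read_sim_params(coverage = 30, seed = 21))
  aln <- oracle_align(reads, hap, ref)
  clips <- extract_clips(aln, 20, contigs = names(ref$genome))
  clusters <- cluster_evidence(clips, NULL)
  calls <- resolve_calls(clusters, clips, ref$consensus, "s1")
  calls <- attribute_transduction(calls, clips, ref2)
  expect_equal(calls$td_source[1], paste(sort(c(src1$id, "S_ghost")), collapse = "+"))

  # the same call with the mapped interval annotated as L1: call kept,
  # annotation absent, multimap flagged
  l1_bed <- tibble::tibble(chrom = src1$chrom, start = src1$end,
                           end = src1$end + 5000L, id = "L1_blanket")
  calls2 <- resolve_calls(clusters, clips, ref$consensus, "s1")
  calls2 <- attribute_transduction(calls2, clips, ref, l1_annotation = l1_bed)
  expect_equal(nrow(calls2), nrow(calls))       # the RT call is kept
  expect_true(is.na(calls2$td_source[1]))
  expect_true(calls2$td_multimap[1])
})

test_that("somatic status partitions germline and tumor-only insertions", {
  fx <- sim_fixture()
  germ <- fx$specs[1:3, ]
  tumor_hap <- fx$hap
  normal_hap <- apply_insertions(fx$ref, germ, "nhap")
  normal_aln <- oracle_align(
    simulate_reads(normal_hap, read_sim_params(coverage = 30, seed = 31)),
    normal_hap, fx$ref
  )
  calls <- call_insertions(fx$aln, normal_aln, fx$ref, "s1")
  tr <- fx$hap$truth
  idx <- match_calls(calls, tr)
  in_normal <- tr$target_pos %in% germ$target_pos
  expect_true(all(calls$status[idx][in_normal] == "pseudo-germline"))
  expect_true(all(calls$status[idx][!in_normal] == "somatic"))

  # zero normal coverage at the locus -> unresolved
  far_normal <- normal_aln[normal_aln$pos < 1000 & !is.na(normal_aln$pos), ]
  calls0 <- classify_somatic(calls[1, ], NULL, NULL, far_normal)
  expect_equal(calls0$status, "unresolved")

  expect_error(classify_somatic(calls, NULL, NULL, NULL), "normal")
})

test_that("call-set intersection is windowed, greedy, and symmetric", {
  mk <- function(id, pos, sample = "s1") tibble::tibble(
    call_id = id, sample_id = sample, chrom = "chr1", pos = pos
  )
  a <- mk(c("a1", "a2", "a3"), c(1000L, 5000L, 9000L))
  b <- mk(c("b1", "b2", "b3"), c(1049L, 5051L, 9000L))
  out <- intersect_callsets(a, b, window = 50)
  expect_setequal(out$shared$a_id, c("a1", "a3"))   # 49 shared, 51 not
  expect_equal(out$a_only$call_id, "a2")
  expect_equal(out$b_only$call_id, "b2")

  # symmetry under input swap
  rev <- intersect_callsets(b, a, window = 50)
  expect_setequal(rev$shared$b_id, out$shared$a_id)
  expect_equal(rev$a_only$call_id, out$b_only$call_id)

  # identical coordinates in different samples are not shared
  c1 <- mk("c1", 2000L, sample = "s1")
  c2 <- mk("c2", 2000L, sample = "s2")
  expect_equal(nrow(intersect_callsets(c1, c2)$shared), 0)

  # self-intersection marks every call shared
  self <- intersect_callsets(a, dplyr::mutate(a, call_id = paste0(call_id, "x")))
  expect_equal(nrow(self$shared), nrow(a))

  expect_error(intersect_callsets(dplyr::bind_rows(a, a), b), "duplicate")
})

test_that("Clopper-Pearson intervals hit the boundary cases and the exact inversion", {
  expect_equal(inversion_rate_ci(0, 10)$lower, 0)
  expect_equal(inversion_rate_ci(10, 10)$upper, 1)
  ci <- inversion_rate_ci(5, 10, level = 0.99)
  expect_true(ci$lower < 0.5 && ci$upper > 0.5)
  # independent cross-check: binom.test implements the same exact interval
  bt <- binom.test(5, 10, conf.level = 0.99)$conf.int
  expect_equal(unlist(ci[c("lower", "upper")]), as.numeric(bt),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(inversion_rate_ci(1, 0), class = "l1rt_undefined")
})
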