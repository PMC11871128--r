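#' Describe one L1 insertion event
#'
#' An insertion spec captures the mechanistic degrees of freedom of
#' target-primed reverse transcription: the nick coordinate, target-site
#' duplication length, element orientation, 3'-anchored inserted length
#' (5' truncation), an optional twin-priming inversion junction, poly(A)
#' tail length, and an optional 3' transduction from a source locus.
#'
#' @param target_chrom Target contig.
#' @param target_pos 0-based nick coordinate on the reference.
#' @param tsd_len Target-site duplication length (nt, >= 0).
#' @param strand `"+"` or `"-"`: orientation of the inserted element on the
#'   reference top strand.
#' @param inserted_len Length of the 3'-anchored L1 segment (nt); equal to
#'   the consensus length for a full-length insertion.
#' @param inversion_junction Consensus coordinate (0-based) where second
#'   priming occurred, or `NA` for a canonical insertion. Must lie strictly
#'   inside the inserted interval.
#' @param polyA_len Poly(A) tail length (nt, >= 0).
#' @param transduction_source Source locus id, or `NA`.
#' @param transduction_len Length of transduced downstream sequence (nt);
#'   positive iff a source is named.
#' @return One-row tibble of class `l1_insertion_spec`.
#' @export
insertion_spec <- function(target_chrom, target_pos, tsd_len = 10L, strand = "+",
                           inserted_len = 1500L, inversion_junction = NA_integer_,
                           polyA_len = 20L, transduction_source = NA_character_,
                           transduction_len = 0L) {
  if (tsd_len < 0 || polyA_len < 0 || inserted_len < 1) abort("invalid insertion spec lengths")
  if (!strand %in% c("+", "-")) abort("strand must be + or -")
  if (xor(is.na(transduction_source), transduction_len == 0)) {
    abort("transduction_len > 0 iff transduction_source present")
  }
  out <- tibble(
    target_chrom = target_chrom, target_pos = as.integer(target_pos),
    tsd_len = as.integer(tsd_len), strand = strand,
    inserted_len = as.integer(inserted_len),
    inversion_junction = as.integer(inversion_junction),
    polyA_len = as.integer(polyA_len),
    transduction_source = as.character(transduction_source),
    transduction_len = as.integer(transduction_len)
  )
  class(out) <- c("l1_insertion_spec", class(out))
  out
}

#' Draw a random set of insertion specs
#'
#' Convenience generator for benchmarking: draws canonical, inversion, and
#' transduction-bearing events in given proportions at well-separated
#' positions, with truncation lengths uniform over `len_range` and TSDs
#' uniform over `tsd_range`.
#'
#' @param n Number of insertions.
#' @param ref An [build_reference()] object.
#' @param seed Integer seed.
#' @param p_inversion,p_transduction Class proportions (the remainder is
#'   plain canonical).
#' @param len_range Range of inserted lengths (nt).
#' @param tsd_range Range of TSD lengths (nt).
#' @param polyA_range Range of poly(A) lengths.
#' @param transduction_range Range of transduced lengths.
#' @param min_gap Minimum distance between events and from source loci.
#' @return Tibble of insertion specs, sorted by position.
#' @export
random_insertion_specs <- function(n, ref, seed = 1L, p_inversion = 0.35,
                                   p_transduction = 0.15,
                                   len_range = c(100L, 6000L),
                                   tsd_range = c(5L, 20L),
                                   polyA_range = c(10L, 30L),
                                   transduction_range = c(100L, 180L),
                                   min_gap = 12000L) {
  withr::local_seed(seed)
  chrom <- names(ref$genome)[1]
  glen <- nchar(ref$genome[[1]])
  clen <- ref$consensus$length
  len_range[2] <- min(len_range[2], clen)

  # slot-based placement: evenly spaced slots jittered within their slack,
  # skipping slots that touch a source locus or its flank
  forbid <- ref$sources |> mutate(lo = .data$start - min_gap, hi = .data$end + min_gap)
  ok_pos <- function(p) nrow(forbid) == 0 || all(p < forbid$lo | p > forbid$hi)
  n_slots <- max(n + nrow(forbid) + 2L, ceiling(n * 1.2))
  slot <- (glen - 2 * min_gap) / n_slots
  if (slot < min_gap) abort("genome too short for n insertions at min_gap separation")
  jit <- floor(max(0, slot - min_gap))
  cand <- round(min_gap + (seq_len(n_slots) - 1L) * slot +
                  runif(n_slots, 0, jit))
  cand <- cand[vapply(cand, ok_pos, TRUE)]
  if (length(cand) < n) abort("could not place insertions clear of source loci")
  pos <- sort(sample(cand, n))

  cls <- sample(c("inversion", "transduction", "canonical"), n, replace = TRUE,
                prob = c(p_inversion, p_transduction, 1 - p_inversion - p_transduction))
  if (nrow(ref$sources) == 0) cls[cls == "transduction"] <- "canonical"
  ilen <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  junc <- ifelse(
    cls == "inversion",
    clen - ilen + pmax(30L, round(ilen * runif(n, 0.2, 0.8))),
    NA_integer_
  )
  src <- ifelse(cls == "transduction",
                sample(ref$sources$id, n, replace = TRUE), NA_character_)
  tdl <- ifelse(cls == "transduction",
                sample(seq(transduction_range[1], transduction_range[2]), n, replace = TRUE), 0L)
  tibble(
    target_chrom = chrom, target_pos = as.integer(pos),
    tsd_len = sample(seq(tsd_range[1], tsd_range[2]), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    inserted_len = as.integer(ilen),
    inversion_junction = as.integer(junc),
    polyA_len = sample(seq(polyA_range[1], polyA_range[2]), n, replace = TRUE),
    transduction_source = src,
    transduction_len = as.integer(tdl)
  )
}

# build the inserted cassette (top-strand sequence) for one spec, along with
# a piece table describing the origin of every cassette interval
# (offsets 0-based within the cassette).
build_cassette <- function(spec, consensus, sources) {
  clen <- consensus$length
  f <- clen - spec$inserted_len            # 5'-most consensus coordinate
  if (f < 0) abort("inserted_len exceeds consensus length")
  pieces <- list()
  if (!is.na(spec$inversion_junction)) {
    j <- spec$inversion_junction
    if (j <= f || j >= clen) {
      abort("inversion_junction outside inserted interval", class = "l1rt_spec_error")
    }
    # twin priming: the 5'-ward fragment is inverted relative to the 3' fragment
    pieces <- list(
      list(type = "l1", seq = revcomp(substr0(consensus$sequence, f, j)),
           cons_start = f, cons_end = j, orient = "-"),
      list(type = "l1", seq = substr0(consensus$sequence, j, clen),
           cons_start = j, cons_end = clen, orient = "+")
    )
  } else {
    pieces <- list(list(type = "l1", seq = substr0(consensus$sequence, f, clen),
                        cons_start = f, cons_end = clen, orient = "+"))
  }
  if (!is.na(spec$transduction_source)) {
    srow <- sources[sources$id == spec$transduction_source, ]
    if (nrow(srow) != 1) abort("unknown transduction source id")
    if (spec$transduction_len > nchar(srow$downstream_unique_flank)) {
      abort("transduction_len exceeds recorded source flank")
    }
    pieces <- c(pieces, list(list(
      type = "td", seq = substr0(srow$downstream_unique_flank, 0, spec$transduction_len),
      cons_start = NA, cons_end = NA, orient = "+"
    )))
  }
  if (spec$polyA_len > 0) {
    pieces <- c(pieces, list(list(type = "polyA", seq = strrep("A", spec$polyA_len),
                                  cons_start = NA, cons_end = NA, orient = "+")))
  }
  if (spec$strand == "-") {
    # the whole cassette is reverse complemented so the reference top strand
    # shows poly(T) 5'-ward of the element
    pieces <- rev(lapply(pieces, function(p) {
      p$seq <- revcomp(p$seq)
      p$orient <- if (p$type == "l1") (if (p$orient == "+") "-" else "+") else p$orient
      p
    }))
  }
  seqs <- vapply(pieces, `[[`, "", "seq")
  lens <- nchar(seqs)
  off <- cumsum(c(0L, lens))
  tab <- tibble(
    type = vapply(pieces, `[[`, "", "type"),
    cas_start = off[-length(off)], cas_end = off[-1],
    cons_start = vapply(pieces, function(p) as.integer(p$cons_start %||% NA), 1L),
    cons_end = vapply(pieces, function(p) as.integer(p$cons_end %||% NA), 1L),
    orient = vapply(pieces, `[[`, "", "orient")
  )
  list(seq = paste(seqs, collapse = ""), pieces = tab)
}

#' Apply insertions to a reference, producing a haplotype and ground truth
#'
#' Realises each insertion as
#' `[target site][inserted cassette][target site duplicate]`: the modified
#' haplotype is `ref[0, pos + tsd) + cassette + ref[pos, end)`, i.e. the
#' `tsd_len` bases at the nick are duplicated on both sides of the cassette
#' (staggered-nick repair). On the minus strand the cassette is
#' reverse-complemented.
#'
#' @param ref An [build_reference()] object.
#' @param specs Tibble of insertion specs (see [insertion_spec()]); must be
#'   on one contig of `ref`, sorted or sortable by `target_pos`, pairwise
#'   non-overlapping, and outside source loci.
#' @param hap_name Name of the produced haplotype contig.
#' @return A list of class `l1_haplotype`:
#'   * `seq`: named character vector (one haplotype contig),
#'   * `truth`: tibble with the spec columns plus `insertion_id`,
#'     `left_bp`/`right_bp` (0-based reference junction offsets, differing by
#'     `tsd_len`), `hap_start`/`hap_end` (cassette interval on the haplotype),
#'     and `inserted_seq`,
#'   * `segments`: coordinate map from haplotype to reference intervals used
#'     by the oracle aligner,
#'   * `ref_chrom`: contig the haplotype derives from.
#' @export
apply_insertions <- function(ref, specs, hap_name = "hap1") {
  chrom <- if (nrow(specs)) unique(specs$target_chrom) else names(ref$genome)[1]
  if (length(chrom) != 1 || !chrom %in% names(ref$genome)) {
    abort("specs must target a single contig present in the reference")
  }
  g <- ref$genome[[chrom]]
  glen <- nchar(g)
  specs <- arrange(specs, .data$target_pos)
  if (any(specs$target_pos + specs$tsd_len > glen)) abort("target_pos outside contig")
  if (nrow(ref$sources) > 0) {
    for (i in seq_len(nrow(specs))) {
      hit <- ref$sources$chrom == chrom &
        specs$target_pos[i] >= ref$sources$start & specs$target_pos[i] < ref$sources$end
      if (any(hit)) abort("target_pos inside a source locus")
    }
  }

  n <- nrow(specs)
  hap_pieces <- character(2 * n + 1)
  seg <- vector("list", 2 * n + 1)
  truth <- vector("list", n)
  prev_ref <- 0L   # reference coordinate consumed so far
  hap_off <- 0L    # haplotype length emitted so far
  cassette_pieces <- vector("list", n)

  for (i in seq_len(n)) {
    s <- specs[i, ]
    a <- s$target_pos; t <- s$tsd_len
    cas <- build_cassette(s, ref$consensus, ref$sources)
    ref_piece <- substr0(g, prev_ref, a + t)
    hap_pieces[2 * i - 1] <- ref_piece
    seg[[2 * i - 1]] <- tibble(
      hap_start = hap_off, hap_end = hap_off + nchar(ref_piece),
      type = "ref", ref_start = prev_ref, insertion_id = NA_character_
    )
    hap_off <- hap_off + nchar(ref_piece)
    cas_len <- nchar(cas$seq)
    ins_id <- sprintf("INS%03d", i)
    hap_pieces[2 * i] <- cas$seq
    seg[[2 * i]] <- tibble(
      hap_start = hap_off, hap_end = hap_off + cas_len,
      type = "ins", ref_start = NA_integer_, insertion_id = ins_id
    )
    cassette_pieces[[i]] <- mutate(cas$pieces, insertion_id = ins_id)
    truth[[i]] <- mutate(
      s,
      insertion_id = ins_id,
      left_bp = a, right_bp = a + t,
      hap_start = hap_off, hap_end = hap_off + cas_len,
      inserted_seq = cas$seq,
      class = if_else(is.na(s$inversion_junction), "canonical", "inversion")
    )
    hap_off <- hap_off + cas_len
    prev_ref <- a   # the TSD is re-emitted at the start of the next ref piece
  }
  hap_pieces[2 * n + 1] <- substr0(g, prev_ref, glen)
  seg[[2 * n + 1]] <- tibble(
    hap_start = hap_off, hap_end = hap_off + (glen - prev_ref),
    type = "ref", ref_start = prev_ref, insertion_id = NA_character_
  )

  empty_truth <- tibble(
    insertion_id = character(), left_bp = integer(), right_bp = integer(),
    hap_start = integer(), hap_end = integer(), inserted_seq = character(),
    class = character()
  )
  empty_pieces <- tibble(
    type = character(), cas_start = integer(), cas_end = integer(),
    cons_start = integer(), cons_end = integer(), orient = character(),
    insertion_id = character()
  )
  structure(list(
    seq = setNames(paste(hap_pieces, collapse = ""), hap_name),
    truth = if (n) bind_rows(truth) else empty_truth,
    segments = bind_rows(seg),
    cassette_pieces = if (n) bind_rows(cassette_pieces) else empty_pieces,
    ref_chrom = chrom
  ), class = "l1_haplotype")
}

#' @rdname apply_insertions
#' @param spec A single insertion spec.
#' @export
apply_insertion <- function(ref, spec, hap_name = "hap1") {
  apply_insertions(ref, spec, hap_name = hap_name)
}

#' Write an insertion truth table as BED-like TSV
#'
#' Columns: chrom, start (0-based left junction), end (right junction),
#' class, inserted_len, tsd_len, inversion_junction, source_id,
#' transduction_len.
#'
#' @param hap An `l1_haplotype` object.
#' @param path Output path.
#' @export
write_truth_tsv <- function(hap, path) {
  out <- hap$truth |>
    mutate(chrom = .data$target_chrom, start = .data$left_bp, end = .data$right_bp,
           source_id = .data$transduction_source) |>
    select(all_of(c("chrom", "start", "end", "class", "inserted_len", "tsd_len",
                    "inversion_junction", "source_id", "transduction_len")))
  readr::write_tsv(out, path)
  invisible(path)
}
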