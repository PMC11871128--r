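#' Oracle alignment of simulated reads against the unmodified reference
#'
#' Emits, for every simulated read, the alignment a correct local aligner
#' would produce against the reference that lacks the insertions: reads fully
#' inside reference sequence map unclipped; junction-spanning reads map with
#' soft-clipped tails at the breakpoint; reads fully inside an inserted
#' cassette map to the consensus contig (via the cassette piece table) or are
#' emitted unmapped with a mapped mate; mate fields and the proper-pair flag
#' are set so junction-spanning fragments are discordant. Alignments are
#' derived from the simulation truth, not from sequence search, so base
#' errors never perturb the geometry.
#'
#' @param reads A [simulate_reads()] tibble produced from `hap`.
#' @param hap The `l1_haplotype` the reads were simulated from.
#' @param ref The [build_reference()] object behind `hap`.
#' @param min_anchor Minimum aligned bases required to anchor a primary
#'   alignment (nt).
#' @return Tibble of class `l1_alignments`, one row per read, with SAM-like
#'   columns: `qname`, `mate`, `chrom`, `pos` (1-based), `mapq`, `cigar`,
#'   `left_soft`, `right_soft`, `reverse`, `seq` (reference orientation),
#'   `qual`, `proper`, `duplicate`, `supplementary`, `mate_chrom`,
#'   `mate_pos`, `mate_reverse`, `tlen`.
#' @export
oracle_align <- function(reads, hap, ref, min_anchor = 20L) {
  if (!inherits(hap, "l1_haplotype")) abort("`hap` must be an l1_haplotype")
  rl <- attr(reads, "read_len") %||% nchar(reads$seq1[1])
  n <- nrow(reads)
  seg <- hap$segments
  cons_id <- ref$consensus$id
  ref_chrom <- hap$ref_chrom

  pieces <- hap$cassette_pieces |>
    left_join(select(hap$truth, all_of(c("insertion_id", "hap_start"))),
              by = "insertion_id") |>
    mutate(hs = .data$hap_start + .data$cas_start,
           he = .data$hap_start + .data$cas_end)

  s <- c(reads$frag_start, reads$frag_start + reads$frag_len - rl)
  e <- s + rl
  rv <- rep(c(FALSE, TRUE), each = n)
  seq_fwd <- c(reads$seq1, revcomp(reads$seq2))
  m <- length(s)

  chrom <- rep(NA_character_, m); pos0 <- rep(NA_integer_, m)
  mapq <- integer(m); ls <- integer(m); rs <- integer(m); Mlen <- integer(m)
  reverse <- rv; flip <- rep(FALSE, m)

  idx <- findInterval(s, seg$hap_start)
  within <- e <= seg$hap_end[idx]
  a_cls <- within & seg$type[idx] == "ref"
  chrom[a_cls] <- ref_chrom
  pos0[a_cls] <- seg$ref_start[idx[a_cls]] + (s[a_cls] - seg$hap_start[idx[a_cls]])
  mapq[a_cls] <- 60L; Mlen[a_cls] <- rl

  multi <- which(!within)
  need_piece <- which(within & seg$type[idx] == "ins")
  if (length(multi)) {
    refseg <- filter(seg, .data$type == "ref")
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(s[multi] + 1L, e[multi]),
      IRanges::IRanges(refseg$hap_start + 1L, refseg$hap_end)
    )
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov_s <- pmax(s[multi][qh], refseg$hap_start[sh])
    ov_e <- pmin(e[multi][qh], refseg$hap_end[sh])
    ovlen <- ov_e - ov_s
    # best reference anchor per read (longest, then leftmost)
    ord <- order(qh, -ovlen, ov_s)
    first <- !duplicated(qh[ord])
    bq <- qh[ord][first]; bs <- sh[ord][first]
    bov_s <- ov_s[ord][first]; bov_e <- ov_e[ord][first]; bl <- ovlen[ord][first]
    anchored <- bl >= min_anchor
    ridx <- multi[bq[anchored]]
    chrom[ridx] <- ref_chrom
    pos0[ridx] <- refseg$ref_start[bs[anchored]] +
      (bov_s[anchored] - refseg$hap_start[bs[anchored]])
    mapq[ridx] <- 60L
    ls[ridx] <- bov_s[anchored] - s[ridx]
    rs[ridx] <- e[ridx] - bov_e[anchored]
    Mlen[ridx] <- bl[anchored]
    need_piece <- c(need_piece, multi[bq[!anchored]],
                    setdiff(multi, multi[bq]))
  }

  if (length(need_piece)) {
    l1p <- filter(pieces, .data$type == "l1")
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(s[need_piece] + 1L, e[need_piece]),
      IRanges::IRanges(l1p$hs + 1L, l1p$he)
    )
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov_s <- pmax(s[need_piece][qh], l1p$hs[sh])
    ov_e <- pmin(e[need_piece][qh], l1p$he[sh])
    ovlen <- ov_e - ov_s
    ord <- order(qh, -ovlen, ov_s)
    first <- !duplicated(qh[ord])
    bq <- qh[ord][first]; bs <- sh[ord][first]
    bov_s <- ov_s[ord][first]; bov_e <- ov_e[ord][first]; bl <- ovlen[ord][first]
    keep <- bl >= min_anchor
    ridx <- need_piece[bq[keep]]
    bsk <- bs[keep]
    plus <- l1p$orient[bsk] == "+"
    chrom[ridx] <- cons_id
    pos0[ridx] <- ifelse(plus,
                         l1p$cons_start[bsk] + (bov_s[keep] - l1p$hs[bsk]),
                         l1p$cons_start[bsk] + (l1p$he[bsk] - bov_e[keep]))
    mapq[ridx] <- 10L
    ls[ridx] <- bov_s[keep] - s[ridx]
    rs[ridx] <- e[ridx] - bov_e[keep]
    Mlen[ridx] <- bl[keep]
    flip[ridx] <- !plus
  }
  # minus-orientation piece alignments: read is flipped relative to the
  # consensus, so the strand, clip sides, and stored sequence flip too
  if (any(flip)) {
    reverse[flip] <- !reverse[flip]
    tmp <- ls[flip]; ls[flip] <- rs[flip]; rs[flip] <- tmp
    seq_fwd[flip] <- revcomp(seq_fwd[flip])
  }

  mapped <- !is.na(chrom)
  cigar <- rep("*", m)
  cigar[mapped] <- paste0(
    ifelse(ls[mapped] > 0, paste0(ls[mapped], "S"), ""),
    Mlen[mapped], "M",
    ifelse(rs[mapped] > 0, paste0(rs[mapped], "S"), "")
  )

  other <- c((n + 1):(2 * n), 1:n)   # index of the mate record
  end0 <- pos0 + Mlen
  fr <- mapped & mapped[other] & chrom == chrom[other] & (reverse != reverse[other])
  fwd_pos <- ifelse(reverse, pos0[other], pos0)
  rev_end <- ifelse(reverse, end0, end0[other])
  tlen <- rev_end - fwd_pos
  proper <- !is.na(fr) & fr & chrom == ref_chrom & tlen > 0 & tlen <= 100000 &
    fwd_pos <= ifelse(reverse, pos0, pos0[other])
  proper[is.na(proper)] <- FALSE

  out <- tibble(
    qname = rep(reads$read_id, 2L),
    mate = rep(c(1L, 2L), each = n),
    chrom = chrom,
    pos = pos0 + 1L,
    mapq = mapq,
    cigar = cigar,
    left_soft = ls, right_soft = rs,
    reverse = reverse,
    seq = seq_fwd,
    qual = strrep("?", rl),
    proper = proper,
    duplicate = FALSE,
    supplementary = FALSE,
    mate_chrom = chrom[other],
    mate_pos = pos0[other] + 1L,
    mate_reverse = reverse[other],
    tlen = if_else(proper, as.integer(tlen) * if_else(reverse, -1L, 1L), 0L)
  )
  attr(out, "ref_chrom") <- ref_chrom
  attr(out, "consensus_id") <- cons_id
  class(out) <- c("l1_alignments", class(out))
  out
}

sam_flag <- function(aln) {
  mapped <- !is.na(aln$chrom)
  mate_mapped <- !is.na(aln$mate_chrom)
  1L +
    2L * as.integer(aln$proper) +
    4L * as.integer(!mapped) +
    8L * as.integer(!mate_mapped) +
    16L * as.integer(aln$reverse & mapped) +
    32L * as.integer(aln$mate_reverse & mate_mapped) +
    64L * as.integer(aln$mate == 1L) +
    128L * as.integer(aln$mate == 2L) +
    1024L * as.integer(aln$duplicate) +
    2048L * as.integer(aln$supplementary)
}

#' Write alignment records as SAM text
#'
#' @param aln An `l1_alignments` tibble.
#' @param path Output SAM path.
#' @param ref The reference object (for `@SQ` header lines).
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, ref) {
  sq <- c(
    vapply(seq_along(ref$genome), function(i) {
      sprintf("@SQ\tSN:%s\tLN:%d", names(ref$genome)[i], nchar(ref$genome[[i]]))
    }, ""),
    sprintf("@SQ\tSN:%s\tLN:%d", ref$consensus$id, ref$consensus$length)
  )
  hdr <- c("@HD\tVN:1.6\tSO:unsorted", sq)
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
    aln$qname, sam_flag(aln),
    if_else(is.na(aln$chrom), "*", aln$chrom),
    if_else(is.na(aln$pos), 0L, aln$pos),
    aln$mapq, aln$cigar,
    if_else(is.na(aln$mate_chrom), "*",
            if_else(!is.na(aln$chrom) & aln$mate_chrom == aln$chrom, "=", aln$mate_chrom)),
    if_else(is.na(aln$mate_pos), 0L, aln$mate_pos),
    aln$tlen, aln$seq, aln$qual
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SAM text into an alignment tibble
#'
#' Thin reader for the SAM records this package writes (and hand-built
#' fixtures): parses the mandatory columns and soft/hard clip lengths from
#' the CIGAR. Intended for small test inputs, not production BAMs.
#'
#' @param path SAM file path.
#' @return An `l1_alignments`-style tibble.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t")
  get <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(get(2))
  cigar <- get(6)
  rname <- get(3); mrnm <- get(7)
  out <- tibble(
    qname = get(1),
    mate = if_else(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    chrom = if_else(rname == "*", NA_character_, rname),
    pos = as.integer(get(4)),
    mapq = as.integer(get(5)),
    cigar = cigar,
    left_soft = cigar_clip(cigar, "left", "S"),
    right_soft = cigar_clip(cigar, "right", "S"),
    left_hard = cigar_clip(cigar, "left", "H"),
    right_hard = cigar_clip(cigar, "right", "H"),
    reverse = bitwAnd(flag, 16L) > 0L,
    seq = get(10),
    qual = get(11),
    proper = bitwAnd(flag, 2L) > 0L,
    duplicate = bitwAnd(flag, 1024L) > 0L,
    supplementary = bitwAnd(flag, 2048L) > 0L,
    mate_chrom = dplyr::case_when(
      mrnm == "*" ~ NA_character_,
      mrnm == "=" ~ rname,
      TRUE ~ mrnm
    ),
    mate_pos = as.integer(get(8)),
    mate_reverse = bitwAnd(flag, 32L) > 0L,
    tlen = as.integer(get(9))
  )
  out$pos[out$pos == 0L] <- NA_integer_
  class(out) <- c("l1_alignments", class(out))
  out
}

# leading/trailing clip length of a given operation from CIGAR strings
cigar_clip <- function(cigar, side = c("left", "right"), op = "S") {
  side <- match.arg(side)
  pat <- if (side == "left") paste0("^(\\d+)", op) else paste0("(\\d+)", op, "$")
  m <- regexpr(pat, cigar)
  out <- integer(length(cigar))
  ok <- m != -1L
  out[ok] <- as.integer(gsub("[A-Z]", "", regmatches(cigar, m)))
  out
}

# aligned reference span (sum of M/D/N/=/X) per CIGAR; the common
# clip-match-clip shape is handled without a full parse
cigar_ref_span <- function(cigar) {
  out <- integer(length(cigar))
  simple <- grepl("^(\\d+[SH])?(\\d+)M(\\d+[SH])?$", cigar)
  if (any(simple)) {
    out[simple] <- as.integer(sub("^(?:\\d+[SH])?(\\d+)M(?:\\d+[SH])?$", "\\1",
                                  cigar[simple]))
  }
  hard <- which(!simple & cigar != "*")
  if (length(hard)) {
    out[hard] <- vapply(regmatches(cigar[hard], gregexpr("\\d+[MIDNSHP=X]", cigar[hard])),
      function(ops) {
        lens <- as.integer(gsub("[A-Z=]", "", ops))
        kind <- gsub("\\d+", "", ops)
        sum(lens[kind %in% c("M", "D", "N", "=", "X")])
      }, 1L)
  }
  out
}
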