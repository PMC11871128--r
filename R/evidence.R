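aln_col <- function(aln, name, default) {
  if (name %in% names(aln)) aln[[name]] else rep(default, nrow(aln))
}

# the read-level filters applied before any QC metric or evidence extraction:
# unpaired reads, duplicates, mapping quality zero, inconsistent seq/qual
qc_filter_reads <- function(aln) {
  paired <- aln_col(aln, "paired", TRUE)
  mapped <- !is.na(aln$chrom)
  consistent <- !mapped | nchar(aln$seq) == nchar(aln$qual) | aln$qual == "*"
  keep <- paired & !aln$duplicate & aln$mapq > 0 & mapped & consistent
  dropped <- c(
    unpaired = sum(!paired),
    duplicate = sum(paired & aln$duplicate),
    mapq_zero_or_unmapped = sum(paired & !aln$duplicate & (aln$mapq == 0 | !mapped)),
    inconsistent_qual = sum(paired & !aln$duplicate & aln$mapq > 0 & mapped & !consistent)
  )
  list(records = aln[keep, , drop = FALSE], dropped = dropped)
}

#' Per-sample sequencing QC metrics
#'
#' After removing unpaired reads, duplicates, mapping-quality-zero reads, and
#' records with inconsistent sequence/quality strings, computes the five
#' metrics used both to filter sample pairs and to adjust RNA/RT estimates:
#' chimeric read fraction, clipped base fraction, mean read length, mean base
#' quality, and coverage. A chimeric read is one whose pair is aligned in an
#' unexpected orientation (same-strand or outward-facing mates, or mates on
#' different contigs) or whose insert size exceeds `max_insert`.
#'
#' @param aln Alignment tibble (see [oracle_align()] / [read_sam()]).
#' @param genome_length Denominator for the coverage metric (aligned bases /
#'   `genome_length`).
#' @param max_insert Insert size above which a pair counts as chimeric
#'   (default 100000).
#' @return One-row tibble: `chimeric_read_fraction`, `clipped_base_fraction`,
#'   `mean_read_length`, `mean_base_quality`, `coverage`, `n_reads`.
#' @export
compute_sample_qc <- function(aln, genome_length, max_insert = 100000) {
  fl <- qc_filter_reads(aln)
  rec <- fl$records
  if (nrow(rec) == 0) {
    abort(paste0("all reads removed by QC filters (",
                 paste(sprintf("%s=%d", names(fl$dropped), fl$dropped), collapse = ", "), ")"),
          class = "l1rt_empty_input")
  }
  mate_mapped <- !is.na(rec$mate_chrom)
  isize <- abs(if_else(rec$tlen != 0L, rec$tlen,
                       rec$mate_pos - rec$pos + nchar(rec$seq)))
  same_strand <- rec$reverse == rec$mate_reverse
  diff_chrom <- mate_mapped & rec$mate_chrom != rec$chrom
  # outward-facing: the forward read of an FR pair sits to the right of its mate
  outward <- !same_strand & !diff_chrom &
    if_else(rec$reverse, rec$pos < rec$mate_pos, rec$pos > rec$mate_pos)
  chimeric <- mate_mapped & (diff_chrom | same_strand | outward | isize > max_insert)

  ls <- aln_col(rec, "left_soft", 0L); rs <- aln_col(rec, "right_soft", 0L)
  rlen <- nchar(rec$seq)
  qual_means <- vapply(rec$qual, function(q) mean(utf8ToInt(q)) - 33, 0, USE.NAMES = FALSE)

  tibble(
    chimeric_read_fraction = mean(chimeric),
    clipped_base_fraction = sum(ls + rs) / sum(rlen),
    mean_read_length = mean(rlen),
    mean_base_quality = stats::weighted.mean(qual_means, rlen),
    coverage = sum(rlen - ls - rs) / genome_length,
    n_reads = nrow(rec)
  )
}

#' Filter tumor/normal sample pairs on QC thresholds
#'
#' Drops any pair with a chimeric read fraction above `max_chimeric` in
#' either member, tumor coverage below `min_tumor_depth`, or normal coverage
#' below `min_normal_depth` (defaults 2%, 50x, 20x).
#'
#' @param pairs Tibble with one row per pair and columns
#'   `tumor_chimeric_read_fraction`, `normal_chimeric_read_fraction`,
#'   `tumor_coverage`, `normal_coverage` (other columns are carried through).
#' @param max_chimeric,min_tumor_depth,min_normal_depth Thresholds.
#' @return The input with logical `kept` and comma-separated `reasons`
#'   columns appended.
#' @export
filter_sample_pairs <- function(pairs, max_chimeric = 0.02,
                                min_tumor_depth = 50, min_normal_depth = 20) {
  need <- c("tumor_chimeric_read_fraction", "normal_chimeric_read_fraction",
            "tumor_coverage", "normal_coverage")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) abort(paste("missing pair columns:", paste(miss, collapse = ", ")),
                          class = "l1rt_pairing_error")
  if (any(!complete.cases(pairs[need]))) {
    abort("missing QC member in a pair", class = "l1rt_pairing_error")
  }
  flags <- cbind(
    tumor_chimeric = pairs$tumor_chimeric_read_fraction > max_chimeric,
    normal_chimeric = pairs$normal_chimeric_read_fraction > max_chimeric,
    tumor_depth = pairs$tumor_coverage < min_tumor_depth,
    normal_depth = pairs$normal_coverage < min_normal_depth
  )
  reasons <- apply(flags, 1, function(f) paste(colnames(flags)[f], collapse = ","))
  mutate(pairs, kept = reasons == "", reasons = reasons)
}

#' Extract clipped-read evidence
#'
#' Soft-clipped primary alignments yield evidence directly; hard-clipped
#' supplementary alignments yield evidence whose clipped sequence is
#' reconstructed from the matching primary record (the read bases absent from
#' the supplementary). Clips shorter than `min_clip` are ignored, as are
#' duplicates and mapping-quality-zero records.
#'
#' @param aln Alignment tibble.
#' @param min_clip Minimum clip length to report (nt, default 20).
#' @param contigs Optional character vector restricting evidence to these
#'   contigs (e.g. canonical chromosomes).
#' @return Tibble: `qname`, `mate`, `chrom`, `bp` (0-based reference junction
#'   offset), `side` (`"left"`/`"right"`, the clipped side of the read),
#'   `clip_seq`, `from_supplementary`.
#' @export
extract_clips <- function(aln, min_clip = 20L, contigs = NULL) {
  rec <- filter(aln, !is.na(.data$chrom), .data$mapq > 0, !.data$duplicate)
  if (!is.null(contigs)) rec <- filter(rec, .data$chrom %in% contigs)
  ls <- aln_col(rec, "left_soft", 0L); rs <- aln_col(rec, "right_soft", 0L)
  lh <- aln_col(rec, "left_hard", 0L); rh <- aln_col(rec, "right_hard", 0L)
  span <- cigar_ref_span(rec$cigar)
  rlen <- nchar(rec$seq)
  prim <- !rec$supplementary

  ev <- list()
  # soft clips on primaries
  pi <- which(prim)
  li <- pi[ls[pi] >= min_clip]
  ev$left <- tibble(
    qname = rec$qname[li], mate = rec$mate[li], chrom = rec$chrom[li],
    bp = rec$pos[li] - 1L, side = "left",
    clip_seq = substr(rec$seq[li], 1L, ls[li]),
    from_supplementary = FALSE
  )
  ri <- pi[rs[pi] >= min_clip]
  ev$right <- tibble(
    qname = rec$qname[ri], mate = rec$mate[ri], chrom = rec$chrom[ri],
    bp = rec$pos[ri] - 1L + span[ri], side = "right",
    clip_seq = substr(rec$seq[ri], rlen[ri] - rs[ri] + 1L, rlen[ri]),
    from_supplementary = FALSE
  )

  # hard-clipped supplementaries: recover clipped bases from the primary
  si <- which(!prim & (lh >= min_clip | rh >= min_clip))
  if (length(si)) {
    prim_tab <- rec[prim, c("qname", "mate", "seq", "reverse")]
    sup <- rec[si, ]
    sup$.lh <- lh[si]; sup$.rh <- rh[si]; sup$.span <- span[si]
    sup <- left_join(sup, rename(prim_tab, prim_seq = "seq", prim_rev = "reverse"),
                     by = c("qname", "mate"))
    no_prim <- is.na(sup$prim_seq)
    if (any(no_prim)) {
      warn(sprintf("%d supplementary record(s) without a primary were skipped",
                   sum(no_prim)))
      sup <- sup[!no_prim, , drop = FALSE]
    }
    if (nrow(sup)) {
      full <- if_else(sup$prim_rev != sup$reverse, revcomp(sup$prim_seq), sup$prim_seq)
      sl <- which(sup$.lh >= min_clip)
      ev$sup_left <- tibble(
        qname = sup$qname[sl], mate = sup$mate[sl], chrom = sup$chrom[sl],
        bp = sup$pos[sl] - 1L, side = "left",
        clip_seq = substr(full[sl], 1L, sup$.lh[sl]),
        from_supplementary = TRUE
      )
      sr <- which(sup$.rh >= min_clip)
      ev$sup_right <- tibble(
        qname = sup$qname[sr], mate = sup$mate[sr], chrom = sup$chrom[sr],
        bp = sup$pos[sr] - 1L + sup$.span[sr], side = "right",
        clip_seq = substr(full[sr], nchar(full[sr]) - sup$.rh[sr] + 1L, nchar(full[sr])),
        from_supplementary = TRUE
      )
    }
  }
  out <- bind_rows(ev)
  arrange(out, .data$chrom, .data$bp)
}

#' Extract discordant-pair evidence
#'
#' Emits non-proper-pair anchors (mapping quality > 0) whose mates map to the
#' L1 consensus contig or inside an annotated genomic L1 interval.
#'
#' @param aln Alignment tibble.
#' @param l1_annotation Tibble of L1 copies: `chrom`, `start`, `end` (0-based
#'   half-open), `id`. May have zero rows.
#' @param consensus_names Contig name(s) of the L1 consensus.
#' @return Tibble: `qname`, `mate`, `chrom`, `pos` (1-based anchor),
#'   `strand`, `mate_class` (`"consensus-L1"` or a copy id), `geometry`.
#' @export
extract_discordant <- function(aln, l1_annotation = NULL, consensus_names = character()) {
  rec <- filter(aln, !is.na(.data$chrom), .data$mapq > 0, !.data$duplicate,
                !.data$supplementary, !.data$proper, !is.na(.data$mate_chrom))
  mate_class <- rep(NA_character_, nrow(rec))
  mate_class[rec$mate_chrom %in% consensus_names] <- "consensus-L1"
  if (!is.null(l1_annotation) && nrow(l1_annotation)) {
    check_bed(l1_annotation)
    for (i in seq_len(nrow(l1_annotation))) {
      b <- l1_annotation[i, ]
      hit <- is.na(mate_class) & rec$mate_chrom == b$chrom &
        rec$mate_pos - 1L >= b$start & rec$mate_pos - 1L < b$end
      mate_class[hit] <- b$id
    }
  }
  keep <- !is.na(mate_class) & !rec$chrom %in% consensus_names
  tibble(
    qname = rec$qname[keep], mate = rec$mate[keep],
    chrom = rec$chrom[keep], pos = rec$pos[keep],
    strand = if_else(rec$reverse[keep], "-", "+"),
    mate_class = mate_class[keep],
    geometry = if_else(mate_class[keep] == "consensus-L1",
                       "mate_on_consensus", "mate_in_l1_copy")
  )
}

check_bed <- function(bed) {
  need <- c("chrom", "start", "end", "id")
  if (!all(need %in% names(bed))) abort("L1 annotation must have chrom/start/end/id columns")
  bad <- which(!(bed$end > bed$start))
  if (length(bad)) {
    abort(sprintf("malformed annotation interval at line %d", bad[1]),
          class = "l1rt_parse_error")
  }
  invisible(bed)
}

#' Read a BED(-like) annotation file into a tibble
#'
#' @param path BED path (3+ columns; 4th column used as `id` when present).
#' @return Tibble with `chrom`, `start`, `end`, `id`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  out <- tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    id = if (ncol(raw) >= 4) as.character(raw[[4]]) else sprintf("L1_%d", seq_len(nrow(raw)))
  )
  check_bed(out)
}
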