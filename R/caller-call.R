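# Realign the member clips of one cluster and annotate each with its poly
# tract (at the junction-proximal end), the stripped remainder, and the
# consensus alignment of that remainder.
analyse_cluster_clips <- function(cl_clips, consensus, params) {
  if (nrow(cl_clips) > 2 * params$max_realign_per_side) {
    # keep the longest tails per side: they reach furthest into the element
    cl_clips <- cl_clips |>
      group_by(.data$side) |>
      arrange(dplyr::desc(nchar(.data$clip_seq)), .by_group = TRUE) |>
      dplyr::slice_head(n = params$max_realign_per_side) |>
      ungroup()
  }
  prox <- if_else(cl_clips$side == "right", "start", "end")
  tr_s <- detect_poly_tract(cl_clips$clip_seq, params$poly_min_len,
                            params$poly_purity, end = "start")
  tr_e <- detect_poly_tract(cl_clips$clip_seq, params$poly_min_len,
                            params$poly_purity, end = "end")
  tract <- if_else(prox == "start", tr_s$tract, tr_e$tract)
  tract_len <- if_else(prox == "start", tr_s$tract_len, tr_e$tract_len)
  len <- nchar(cl_clips$clip_seq)
  pure_poly <- tract != "none" & tract_len >= 0.9 * len
  rem <- dplyr::case_when(
    pure_poly ~ "",
    prox == "start" ~ substr(cl_clips$clip_seq, tract_len + 1L, len),
    TRUE ~ substr(cl_clips$clip_seq, 1L, len - tract_len)
  )
  do_align <- nchar(rem) >= params$min_clip
  al <- realign_clip(rem[do_align], consensus, params)
  al_full <- tibble(
    cons_start = NA_integer_, cons_end = NA_integer_, orient = NA_character_,
    pat_start = NA_integer_, pat_end = NA_integer_,
    score = NA_real_, identity = NA_real_,
    accepted = FALSE, ambiguous = FALSE,
    .rows = nrow(cl_clips)
  )
  al_full[do_align, ] <- al
  out <- cl_clips
  out$tract <- tract; out$tract_len <- tract_len
  out$pure_poly <- pure_poly; out$remainder <- rem
  dplyr::bind_cols(out, al_full)
}

# orientation consensus of accepted alignments on one side
side_orient <- function(tab, which_side) {
  o <- tab$orient[tab$side == which_side & tab$accepted]
  if (!length(o)) return(NA_character_)
  names(sort(table(o), decreasing = TRUE))[1]
}

#' Resolve a breakpoint cluster into a retrotransposition call
#'
#' Clipped tails are realigned to the consensus: orientation comes from the
#' winning strand, canonical inserted length is
#' `consensus length - (5'-most consensus coordinate reached by any tail)`,
#' and an inversion is declared when tails at the two junctions align with
#' opposite orientations (twin priming). For inversions the inserted length
#' is unresolved by clips -- only the second-priming consensus coordinate is
#' knowable from one junction -- so that coordinate and a lower bound are
#' reported instead. The TSD is the right-clip minus left-clip breakpoint
#' offset; negative offsets (target-site deletions) are reported as 0 with a
#' flag. Poly(A)/poly(T) support comes from the junction-proximal tails.
#'
#' @param clusters [cluster_evidence()] output.
#' @param clips The clip tibble those clusters index into.
#' @param consensus An [l1_consensus()] object.
#' @param sample_id Sample identifier carried onto calls.
#' @param params A [caller_params()] object.
#' @return Tibble of class `l1_calls`: one row per resolved call with
#'   `call_id`, `sample_id`, `chrom`, `pos` (1-based leftmost target-site
#'   coordinate), `class`, `inserted_length`, `second_priming`,
#'   `length_lower_bound`, `tsd_len`, `tsd_deletion`, `strand`,
#'   `polyA_support`, `clip_support`, `discordant_support`, `status`, plus
#'   bookkeeping columns used by transduction attribution.
#' @export
resolve_calls <- function(clusters, clips, consensus, sample_id = "sample",
                          params = caller_params()) {
  clen <- consensus$length
  calls <- vector("list", nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    enough <- cl$n_clips >= params$min_clip_support ||
      (cl$n_clips >= 1L && cl$n_discordant >= params$min_discordant_with_single_clip)
    if (!enough) next
    tab <- analyse_cluster_clips(clips[cl$clip_rows[[1]], ], consensus, params)
    acc <- filter(tab, .data$accepted)
    o_left <- side_orient(tab, "left")    # tails at the right junction
    o_right <- side_orient(tab, "right")  # tails at the left junction
    n_acc <- nrow(acc)
    any_poly <- any(tab$tract != "none")
    if (n_acc == 0 && !any_poly) next   # nothing places this cluster on the element

    inversion <- !is.na(o_left) && !is.na(o_right) && o_left != o_right
    cls <- if (inversion) "inversion" else "canonical"

    # element strand on the reference top strand: a poly(T) tract at the left
    # junction means the cassette was reverse complemented; otherwise use the
    # 3'-fragment orientation (the fragment reaching the consensus 3' end)
    polyT_left <- any(tab$side == "right" & tab$tract == "polyT")
    polyA_right <- any(tab$side == "left" & tab$tract == "polyA")
    strand <- if (polyT_left) "-" else if (polyA_right) "+" else {
      o3 <- if (n_acc) acc$orient[which.max(acc$cons_end)] else NA_character_
      if (is.na(o3)) NA_character_ else if (o3 == "+") "+" else "-"
    }

    five_most <- if (n_acc) min(acc$cons_start) else NA_integer_
    inserted_length <- if (!inversion && n_acc) clen - five_most else NA_integer_
    second_priming <- NA_integer_
    lower_bound <- if (n_acc) clen - five_most else NA_integer_
    if (inversion) {
      # the inverted 5'-ward fragment is the orientation group that does not
      # reach the consensus 3' end; its distal edge is the second-priming site
      grp <- acc |> group_by(.data$orient) |>
        summarise(max_end = max(.data$cons_end), .groups = "drop")
      if (nrow(grp) == 2) {
        inv_grp <- grp$orient[which.min(grp$max_end)]
        second_priming <- max(acc$cons_end[acc$orient == inv_grp])
      }
    }

    both <- !is.na(cl$left_bp) && !is.na(cl$right_bp)
    tsd_raw <- if (both) cl$right_bp - cl$left_bp else NA_integer_
    tsd_deletion <- both && tsd_raw < 0
    tsd_len <- if (both) max(0L, tsd_raw) else NA_integer_
    pos0 <- if (!is.na(cl$left_bp)) cl$left_bp else cl$right_bp

    calls[[i]] <- tibble(
      call_id = sprintf("%s_%s", sample_id, cl$cluster_id),
      sample_id = sample_id,
      chrom = cl$chrom, pos = pos0 + 1L,
      class = cls,
      inserted_length = as.integer(inserted_length),
      second_priming = as.integer(second_priming),
      length_lower_bound = as.integer(lower_bound),
      tsd_len = as.integer(tsd_len), tsd_deletion = tsd_deletion,
      strand = strand,
      polyA_support = any_poly,
      clip_support = cl$n_clips, discordant_support = cl$n_discordant,
      status = "unresolved",
      td_source = NA_character_, td_seq = NA_character_,
      td_chrom = NA_character_, td_start = NA_integer_, td_end = NA_integer_,
      td_multimap = FALSE,
      cluster_id = cl$cluster_id,
      clip_rows = cl$clip_rows,
      analysis = list(tab)
    )
  }
  out <- bind_rows(calls)
  if (nrow(out)) class(out) <- c("l1_calls", class(out))
  out
}

#' Attribute 3' transductions to source loci
#'
#' For each call, tails at the poly(A)-bearing junction are stripped of the
#' poly tract and of their consensus-aligned portion; a remaining unique
#' segment of at least `min_transduction_len` nt is aligned downstream of
#' each registered source locus. The source whose 3' end lies within
#' `max_source_distance` upstream of the mapped interval is assigned;
#' candidate sources within `source_group_distance` of each other are merged
#' into one grouped id. Segments that align well to the consensus itself (or
#' whose mapping falls inside annotated L1 sequence) are treated as
#' L1-multimapping: the call is kept but the annotation is dropped and
#' flagged.
#'
#' @param calls [resolve_calls()] output.
#' @param clips The clip tibble the calls were built from.
#' @param ref The [build_reference()] object (genome + source registry).
#' @param params A [caller_params()] object.
#' @param l1_annotation Optional L1 interval tibble; defaults to the source
#'   registry intervals.
#' @return `calls` with the `td_*` columns filled in.
#' @export
attribute_transduction <- function(calls, clips, ref, params = caller_params(),
                                   l1_annotation = NULL) {
  if (!nrow(calls)) return(calls)
  sources <- ref$sources
  if (is.null(l1_annotation)) {
    l1_annotation <- sources |> select(all_of(c("chrom", "start", "end", "id")))
  }
  consensus <- ref$consensus
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, ]
    if (is.na(call$strand)) next
    td_side <- if (call$strand == "+") "left" else "right"
    tab <- if ("analysis" %in% names(calls)) call$analysis[[1]] else
      analyse_cluster_clips(clips[call$clip_rows[[1]], ], consensus, params)
    tails <- filter(tab, .data$side == td_side, !.data$pure_poly,
                    nchar(.data$remainder) >= params$min_transduction_len)
    if (!nrow(tails)) next
    # work in the L1-forward frame of the stripped remainder: the transduced
    # segment is whatever follows the consensus-aligned portion; tails with
    # no consensus match at all are transduced sequence end to end
    seg <- purrr::pmap_chr(tails[c("remainder", "orient", "pat_end", "accepted")],
      function(remainder, orient, pat_end, accepted) {
        if (accepted) {
          fwd <- if (orient == "+") remainder else revcomp(remainder)
          substr(fwd, pat_end + 1L, nchar(fwd))
        } else {
          if (call$strand == "+") remainder else revcomp(remainder)
        }
      })
    seg <- unique(seg[nchar(seg) >= params$min_transduction_len])
    if (!length(seg)) next
    seg <- seg[order(-nchar(seg))]

    saw_l1_like <- FALSE
    for (cand in seg) {
      # an L1-like segment cannot be attributed (keep the call, drop the
      # annotation) -- but a later candidate may still map uniquely
      self <- realign_clip(cand, consensus, params)
      if (self$accepted[1]) { saw_l1_like <- TRUE; next }

      best <- NULL
      max_mm <- ceiling(0.05 * nchar(cand))
      pat_f <- Biostrings::DNAString(cand)
      pat_r <- Biostrings::reverseComplement(pat_f)
      for (s in seq_len(nrow(sources))) {
        src <- sources[s, ]
        reg_end <- min(nchar(ref$genome[[src$chrom]]),
                       src$end + params$max_source_distance + nchar(cand))
        region <- Biostrings::DNAString(substr0(ref$genome[[src$chrom]], src$end, reg_end))
        hits <- Biostrings::matchPattern(pat_f, region, max.mismatch = max_mm)
        if (!length(hits)) hits <- Biostrings::matchPattern(pat_r, region, max.mismatch = max_mm)
        if (length(hits)) {
          h1 <- hits[1]
          hit <- tibble(src_id = src$id, chrom = src$chrom,
                        map_start = src$end + BiocGenerics::start(h1) - 1L,
                        map_end = src$end + BiocGenerics::end(h1),
                        dist = BiocGenerics::start(h1) - 1L,
                        src_end = src$end)
          if (hit$dist <= params$max_source_distance &&
              (is.null(best) || hit$dist < best$dist)) best <- hit
        }
      }
      if (is.null(best)) next
      # multimapping check: the mapped interval's midpoint falling inside an
      # annotated L1 copy means the segment is L1 sequence, not a
      # transduction (a few bases of boundary overhang are tolerated)
      mid <- (best$map_start + best$map_end) / 2
      in_l1 <- any(l1_annotation$chrom == best$chrom &
                   mid >= l1_annotation$start & mid < l1_annotation$end)
      if (in_l1) { saw_l1_like <- TRUE; next }
      group <- sources$id[sources$chrom == best$chrom &
                            best$map_start - sources$end >= -10L &
                            best$map_start - sources$end <= params$max_source_distance &
                            abs(sources$end - best$src_end) <= params$source_group_distance]
      calls$td_source[i] <- paste(sort(group), collapse = "+")
      calls$td_seq[i] <- cand
      calls$td_chrom[i] <- best$chrom
      calls$td_start[i] <- best$map_start
      calls$td_end[i] <- best$map_end
      break
    }
    if (is.na(calls$td_source[i]) && saw_l1_like) calls$td_multimap[i] <- TRUE
  }
  calls
}

#' Classify tumor calls as somatic or pseudo-germline
#'
#' A tumor call with at least one qualifying clip or discordant anchor in the
#' matched normal within `somatic_window` (clips) / `disc_window`
#' (discordant anchors) of the breakpoint is pseudo-germline; a locus whose
#' normal read depth falls below `min_normal_coverage` is unresolved;
#' everything else is somatic.
#'
#' @param calls [resolve_calls()] output for the tumor.
#' @param normal_clips,normal_discordants Evidence extracted from the matched
#'   normal with the same parameters as the tumor.
#' @param normal_aln Normal alignment records (for the coverage floor).
#' @param params A [caller_params()] object.
#' @param disc_window Window for discordant normal support (nt).
#' @return `calls` with `status` set to `"somatic"`, `"pseudo-germline"`, or
#'   `"unresolved"`, plus `normal_support` and `normal_coverage`.
#' @export
classify_somatic <- function(calls, normal_clips, normal_discordants, normal_aln,
                             params = caller_params(), disc_window = 800L) {
  if (is.null(normal_aln)) abort("matched normal sample is required")
  if (!nrow(calls)) return(calls)
  naln <- filter(normal_aln, !is.na(.data$chrom), !.data$duplicate, !.data$supplementary)
  calls$normal_support <- 0L
  calls$normal_coverage <- 0L
  # per-chromosome sorted position index for fast depth lookups
  by_chrom <- split(seq_len(nrow(naln)), naln$chrom)
  idx_sorted <- purrr::map(by_chrom, function(ix) {
    o <- order(naln$pos[ix])
    list(pos = naln$pos[ix][o] - 1L, len = nchar(naln$seq[ix][o]))
  })
  for (i in seq_len(nrow(calls))) {
    p0 <- calls$pos[i] - 1L
    ns <- 0L
    if (!is.null(normal_clips) && nrow(normal_clips)) {
      ns <- ns + sum(normal_clips$chrom == calls$chrom[i] &
                       abs(normal_clips$bp - p0) <= params$somatic_window)
    }
    if (!is.null(normal_discordants) && nrow(normal_discordants)) {
      ns <- ns + sum(normal_discordants$chrom == calls$chrom[i] &
                       abs(normal_discordants$pos - 1L - p0) <= disc_window)
    }
    ix <- idx_sorted[[calls$chrom[i]]]
    cov <- 0L
    if (!is.null(ix)) {
      lo <- findInterval(p0 - max(ix$len), ix$pos)
      hi <- findInterval(p0, ix$pos)
      if (hi > lo) {
        rng <- (lo + 1):hi
        cov <- sum(ix$pos[rng] + ix$len[rng] > p0)
      }
    }
    calls$normal_support[i] <- ns
    calls$normal_coverage[i] <- cov
    calls$status[i] <- if (ns >= 1L) "pseudo-germline"
      else if (cov < params$min_normal_coverage) "unresolved"
      else "somatic"
  }
  calls
}

#' Call L1 insertions from tumor/normal alignments, end to end
#'
#' Convenience pipeline: extracts clip and discordant evidence from the
#' tumor, clusters it, resolves calls, attributes transductions, and
#' classifies somatic status against the matched normal.
#'
#' @param tumor_aln,normal_aln Alignment tibbles.
#' @param ref The [build_reference()] object (consensus + source registry).
#' @param sample_id Sample identifier.
#' @param params A [caller_params()] object.
#' @return An `l1_calls` tibble.
#' @export
call_insertions <- function(tumor_aln, normal_aln, ref, sample_id = "tumor",
                            params = caller_params()) {
  cons_names <- ref$consensus$id
  l1_bed <- select(ref$sources, all_of(c("chrom", "start", "end", "id")))
  t_clips <- extract_clips(tumor_aln, params$min_clip, contigs = names(ref$genome))
  t_disc <- extract_discordant(tumor_aln, l1_bed, cons_names)
  clusters <- cluster_evidence(t_clips, t_disc, params)
  calls <- resolve_calls(clusters, t_clips, ref$consensus, sample_id, params)
  if (!nrow(calls)) return(calls)
  calls <- attribute_transduction(calls, t_clips, ref, params)
  n_clips <- extract_clips(normal_aln, params$min_clip, contigs = names(ref$genome))
  n_disc <- extract_discordant(normal_aln, l1_bed, cons_names)
  calls <- classify_somatic(calls, n_clips, n_disc, normal_aln, params)
  select(calls, -"analysis")
}
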