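#' Caller tuning parameters
#'
#' Central knob set for TotalReCall-style calling. Scoring follows the usual
#' local-alignment regime for 20-150 nt tails; all values are configurable.
#'
#' @param min_clip Minimum clipped-tail length used as evidence (nt).
#' @param match,mismatch,gap_open,gap_extend Local alignment scoring.
#' @param score_frac Acceptance threshold as a fraction of the maximum
#'   attainable score (`match * clip length`).
#' @param min_identity Identity floor for an accepted clip alignment.
#' @param poly_min_len,poly_purity Poly(A)/poly(T) tract detection: minimum
#'   tract length and minimum base purity.
#' @param cluster_window Breakpoint clustering window (nt).
#' @param max_tsd Maximum left/right breakpoint separation paired as a
#'   target-site duplication (nt).
#' @param min_clip_support,min_discordant_with_single_clip Minimum evidence:
#'   a cluster is called with >= `min_clip_support` clips, or one clip plus
#'   >= `min_discordant_with_single_clip` discordant anchors.
#' @param min_transduction_len Minimum non-L1, non-poly(A) tail segment
#'   mapped as a transduction (nt).
#' @param max_source_distance Maximum distance downstream of a registered
#'   source 3' end for transduction attribution (nt).
#' @param source_group_distance Sources within this distance are grouped
#'   under one id (nt).
#' @param somatic_window Window around a tumor call searched for normal
#'   support (nt).
#' @param min_normal_coverage Normal reads overlapping the locus required to
#'   resolve somatic status.
#' @param max_realign_per_side At most this many member tails per side are
#'   realigned when resolving a cluster (support counts still use all
#'   evidence); deep clusters carry redundant tails.
#' @return List of class `caller_params`.
#' @export
caller_params <- function(min_clip = 20L, match = 2, mismatch = -2,
                          gap_open = 4, gap_extend = 1,
                          score_frac = 0.6, min_identity = 0.85,
                          poly_min_len = 8L, poly_purity = 0.8,
                          cluster_window = 50L, max_tsd = 30L,
                          min_clip_support = 2L,
                          min_discordant_with_single_clip = 2L,
                          min_transduction_len = 30L,
                          max_source_distance = 10000L,
                          source_group_distance = 1000L,
                          somatic_window = 50L, min_normal_coverage = 5L,
                          max_realign_per_side = 12L) {
  structure(as.list(environment()), class = "caller_params")
}

#' Realign clipped tails to the L1 consensus
#'
#' Best local alignment of each clip and its reverse complement against the
#' consensus; an alignment is accepted only if its score reaches
#' `score_frac * match * clip_length` and its identity reaches
#' `min_identity`. The winning strand is recorded as the orientation; an
#' exact score tie between strands is flagged ambiguous and rejected.
#'
#' @param clip_seq Character vector of clipped sequences.
#' @param consensus An [l1_consensus()] object.
#' @param params A [caller_params()] object.
#' @return Tibble, one row per clip: `cons_start`/`cons_end` (0-based
#'   half-open consensus interval), `orient`, `score`, `identity`,
#'   `accepted`, `ambiguous`.
#' @export
realign_clip <- function(clip_seq, consensus, params = caller_params()) {
  if (!length(clip_seq)) {
    return(tibble(cons_start = integer(), cons_end = integer(), orient = character(),
                  pat_start = integer(), pat_end = integer(),
                  score = double(), identity = double(), accepted = logical(),
                  ambiguous = logical()))
  }
  subj <- Biostrings::DNAString(consensus$sequence)
  n_in <- length(clip_seq)

  # fast path: a clip that is a (near-)exact full-length match on one strand
  # needs no dynamic programming; only the leftovers hit the aligner.
  # Exact matches use fixed-string search on the raw strings (no S4
  # overhead); near-exact ones a mismatch-tolerant scan.
  cons_str <- consensus$sequence
  rc_all <- revcomp(clip_seq)
  fast <- vector("list", n_in)
  for (i in seq_len(n_in)) {
    len <- nchar(clip_seq[i])
    pos_f <- regexpr(clip_seq[i], cons_str, fixed = TRUE)
    pos_r <- regexpr(rc_all[i], cons_str, fixed = TRUE)
    hf <- hr <- NULL
    if (pos_f != -1L) hf <- c(start = as.integer(pos_f), end = as.integer(pos_f) + len - 1L, mm = 0L)
    if (pos_r != -1L) hr <- c(start = as.integer(pos_r), end = as.integer(pos_r) + len - 1L, mm = 0L)
    if (is.null(hf) && is.null(hr)) {
      mm_allow <- as.integer(ceiling(0.03 * len))
      if (mm_allow > 0) {
        hit_of <- function(pat_chr) {
          v <- Biostrings::matchPattern(Biostrings::DNAString(pat_chr), subj,
                                        max.mismatch = mm_allow, with.indels = FALSE)
          if (!length(v)) return(NULL)
          # mismatch-tolerant matching can propose views hanging off the
          # subject; a full-length match must lie inside it
          ok <- BiocGenerics::start(v) >= 1 &
            BiocGenerics::end(v) <= length(subj)
          if (!any(ok)) return(NULL)
          i <- which(ok)[1]
          reg <- as.character(v[[i]])
          c(start = BiocGenerics::start(v)[i], end = BiocGenerics::end(v)[i],
            mm = sum(charToRaw(reg) != charToRaw(pat_chr)))
        }
        hf <- hit_of(clip_seq[i]); hr <- hit_of(rc_all[i])
      }
    }
    if (is.null(hf) && is.null(hr)) next
    if (!is.null(hf) && !is.null(hr) && hf[["mm"]] == hr[["mm"]]) {
      fast[[i]] <- list(ambiguous = TRUE)
      next
    }
    use_r <- is.null(hf) || (!is.null(hr) && hr[["mm"]] < hf[["mm"]])
    h <- if (use_r) hr else hf
    mm_n <- h[["mm"]]
    fast[[i]] <- list(
      cons_start = h[["start"]] - 1L, cons_end = h[["end"]],
      orient = if (use_r) "-" else "+",
      pat_start = 1L, pat_end = len,
      score = params$match * (len - mm_n) + params$mismatch * mm_n,
      identity = (len - mm_n) / len, ambiguous = FALSE
    )
  }
  slow_idx <- which(vapply(fast, is.null, TRUE))
  fwd <- rev <- NULL
  if (length(slow_idx)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = params$match, mismatch = params$mismatch, baseOnly = TRUE
    )
    pats <- Biostrings::DNAStringSet(clip_seq[slow_idx])
    fwd <- Biostrings::pairwiseAlignment(
      pats, subj, type = "local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend
    )
    rev <- Biostrings::pairwiseAlignment(
      Biostrings::reverseComplement(pats), subj, type = "local",
      substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend
    )
  }
  out <- tibble(
    cons_start = rep(NA_integer_, n_in), cons_end = NA_integer_,
    orient = NA_character_, pat_start = NA_integer_, pat_end = NA_integer_,
    score = NA_real_, identity = NA_real_,
    accepted = FALSE, ambiguous = FALSE
  )
  for (i in setdiff(seq_len(n_in), slow_idx)) {
    h <- fast[[i]]
    if (isTRUE(h$ambiguous)) { out$ambiguous[i] <- TRUE; next }
    out$cons_start[i] <- as.integer(h$cons_start)
    out$cons_end[i] <- as.integer(h$cons_end)
    out$orient[i] <- h$orient
    out$pat_start[i] <- h$pat_start; out$pat_end[i] <- h$pat_end
    out$score[i] <- h$score; out$identity[i] <- h$identity
  }
  if (length(slow_idx)) {
    fs <- Biostrings::score(fwd); rscore <- Biostrings::score(rev)
    use_rev <- rscore > fs
    pick <- function(acc) if_else(use_rev, acc(rev), acc(fwd))
    out$cons_start[slow_idx] <-
      as.integer(pick(function(a) BiocGenerics::start(Biostrings::subject(a))) - 1L)
    out$cons_end[slow_idx] <-
      as.integer(pick(function(a) BiocGenerics::end(Biostrings::subject(a))))
    out$orient[slow_idx] <- if_else(use_rev, "-", "+")
    # pattern coordinates are in the strand-of-best-alignment's own space
    # (coordinates on the reverse complement when orient == "-")
    out$pat_start[slow_idx] <-
      as.integer(pick(function(a) BiocGenerics::start(Biostrings::pattern(a))))
    out$pat_end[slow_idx] <-
      as.integer(pick(function(a) BiocGenerics::end(Biostrings::pattern(a))))
    out$score[slow_idx] <- pmax(fs, rscore)
    out$identity[slow_idx] <- pick(function(a) Biostrings::pid(a, type = "PID1")) / 100
    out$ambiguous[slow_idx] <- fs == rscore
  }
  len <- nchar(clip_seq)
  out$accepted <- !out$ambiguous & !is.na(out$score) &
    out$score >= params$score_frac * params$match * len &
    out$identity >= params$min_identity
  out
}

#' Detect a terminal poly(A)/poly(T) tract
#'
#' Looks for a tract of at least `min_len` bases with at least `purity`
#' fraction A (or T) at the requested end of each sequence -- the
#' junction-proximal end of a clipped tail. Total function: sequences with no
#' qualifying tract return `"none"` with length 0.
#'
#' @param seq Character vector.
#' @param min_len Minimum tract length (nt, default 8).
#' @param purity Minimum fraction of the dominant base (default 0.8).
#' @param end `"start"` or `"end"`: which end of the sequence to inspect.
#' @return Tibble: `tract` (`"polyA"`, `"polyT"`, `"none"`), `tract_len`
#'   (longest qualifying tract).
#' @export
detect_poly_tract <- function(seq, min_len = 8L, purity = 0.8,
                              end = c("start", "end")) {
  end <- match.arg(end)
  one <- function(x) {
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    if (end == "end") ch <- rev(ch)
    if (length(ch) < min_len) return(c(0L, 0L))
    lens <- seq_along(ch)
    fa <- cumsum(ch == "A") / lens
    ft <- cumsum(ch == "T") / lens
    la <- which(fa >= purity & lens >= min_len)
    lt <- which(ft >= purity & lens >= min_len)
    c(if (length(la)) max(la) else 0L, if (length(lt)) max(lt) else 0L)
  }
  res <- vapply(seq, one, integer(2), USE.NAMES = FALSE)
  best_a <- res[1, ]; best_t <- res[2, ]
  tract <- dplyr::case_when(
    best_a == 0L & best_t == 0L ~ "none",
    best_a >= best_t ~ "polyA",
    TRUE ~ "polyT"
  )
  tibble(tract = tract, tract_len = pmax(best_a, best_t))
}
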