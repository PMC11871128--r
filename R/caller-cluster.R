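cluster_1d <- function(pos, window) {
  # single-linkage clustering of sorted positions with gap > window starting
  # a new cluster
  ord <- order(pos)
  gaps <- c(0L, diff(pos[ord]))
  grp <- cumsum(gaps > window)
  out <- integer(length(pos))
  out[ord] <- grp
  out
}

#' Cluster clip and discordant evidence into candidate insertion sites
#'
#' Clips of the same side within `window` of each other are merged into
#' side-clusters; a left-side and right-side cluster whose breakpoints are
#' within `max_tsd` are paired into one candidate (the offset being the
#' target-site duplication). Discordant anchors within `attach_window` of a
#' candidate corroborate it.
#'
#' @param clips [extract_clips()] tibble.
#' @param discordants [extract_discordant()] tibble (may be `NULL`).
#' @param params A [caller_params()] object.
#' @param attach_window Distance within which discordant anchors attach (nt).
#' @return Tibble of class `l1_clusters`: `cluster_id`, `chrom`, `left_bp`,
#'   `right_bp` (0-based; `NA` when one side is missing), `clip_rows`
#'   (list-column of row indices into `clips`), `n_clips`, `disc_rows`,
#'   `n_discordant`.
#' @export
cluster_evidence <- function(clips, discordants = NULL, params = caller_params(),
                             attach_window = 800L) {
  empty <- tibble(cluster_id = character(), chrom = character(),
                  left_bp = integer(), right_bp = integer(),
                  clip_rows = list(), n_clips = integer(),
                  disc_rows = list(), n_discordant = integer())
  if (is.null(clips) || nrow(clips) == 0) return(structure(empty, class = c("l1_clusters", class(empty))))
  clips <- mutate(clips, .row = row_number())
  side_clusters <- clips |>
    group_by(.data$chrom, .data$side) |>
    mutate(.grp = cluster_1d(.data$bp, params$cluster_window)) |>
    group_by(.data$chrom, .data$side, .data$.grp) |>
    summarise(bp = as.integer(round(median(.data$bp))),
              rows = list(.data$.row), n = dplyr::n(), .groups = "drop")

  out <- list()
  for (ch in unique(side_clusters$chrom)) {
    lefts <- filter(side_clusters, .data$chrom == ch, .data$side == "left")
    rights <- filter(side_clusters, .data$chrom == ch, .data$side == "right")
    # pair left/right side-clusters greedily by |offset| <= max_tsd;
    # tsd convention: right-clip breakpoint - left-clip breakpoint >= 0
    pairs <- NULL
    if (nrow(lefts) && nrow(rights)) {
      cand <- tidyr::expand_grid(li = seq_len(nrow(lefts)), ri = seq_len(nrow(rights))) |>
        mutate(d = abs(rights$bp[.data$ri] - lefts$bp[.data$li])) |>
        filter(.data$d <= params$max_tsd) |>
        arrange(.data$d)
      used_l <- used_r <- integer()
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (!cand$li[i] %in% used_l && !cand$ri[i] %in% used_r) {
          keep[i] <- TRUE
          used_l <- c(used_l, cand$li[i]); used_r <- c(used_r, cand$ri[i])
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
    li_used <- if (is.null(pairs)) integer() else pairs$li
    ri_used <- if (is.null(pairs)) integer() else pairs$ri
    rows <- list()
    if (!is.null(pairs) && nrow(pairs)) {
      rows <- purrr::pmap(pairs, function(li, ri, d) {
        tibble(chrom = ch, left_bp = lefts$bp[li], right_bp = rights$bp[ri],
               clip_rows = list(c(lefts$rows[[li]], rights$rows[[ri]])),
               n_clips = lefts$n[li] + rights$n[ri])
      })
    }
    solo_l <- setdiff(seq_len(nrow(lefts)), li_used)
    solo_r <- setdiff(seq_len(nrow(rights)), ri_used)
    rows <- c(rows,
      purrr::map(solo_l, function(li) tibble(
        chrom = ch, left_bp = lefts$bp[li], right_bp = NA_integer_,
        clip_rows = list(lefts$rows[[li]]), n_clips = lefts$n[li])),
      purrr::map(solo_r, function(ri) tibble(
        chrom = ch, left_bp = NA_integer_, right_bp = rights$bp[ri],
        clip_rows = list(rights$rows[[ri]]), n_clips = rights$n[ri]))
    )
    out[[ch]] <- bind_rows(rows)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) return(structure(empty, class = c("l1_clusters", class(empty))))
  res <- res |>
    mutate(anchor = if_else(is.na(.data$left_bp), .data$right_bp, .data$left_bp)) |>
    arrange(.data$chrom, .data$anchor) |>
    mutate(cluster_id = sprintf("CL%04d", row_number()))

  if (!is.null(discordants) && nrow(discordants)) {
    disc <- mutate(discordants, .row = row_number())
    res$disc_rows <- purrr::pmap(res[c("chrom", "anchor")], function(chrom, anchor) {
      disc$.row[disc$chrom == chrom & abs(disc$pos - 1L - anchor) <= attach_window]
    })
  } else {
    res$disc_rows <- purrr::map(seq_len(nrow(res)), ~ integer())
  }
  res$n_discordant <- lengths(res$disc_rows)
  res <- select(res, all_of(c("cluster_id", "chrom", "left_bp", "right_bp",
                              "clip_rows", "n_clips", "disc_rows", "n_discordant")))
  structure(res, class = c("l1_clusters", class(res)))
}
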