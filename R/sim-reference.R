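#' Generate a synthetic L1 consensus sequence
#'
#' Produces a random nucleotide sequence standing in for the ~6 kb L1
#' consensus against which clipped read tails are realigned. The sequence is
#' uniform-random ACGT, which preserves the property that matters for the
#' caller -- clipped tails drawn from the consensus align back to it uniquely
#' -- without bundling any reference sequence.
#'
#' @param length Consensus length in nucleotides (default 6019, the
#'   approximate length of an intact human L1).
#' @param id Sequence identifier; also used as the contig name for reads that
#'   map inside an inserted element.
#' @param seed Integer seed; the consensus is deterministic given the seed.
#' @return A list of class `l1_consensus` with elements `id`, `sequence`,
#'   and `length`.
#' @export
#' @examples
#' cons <- l1_consensus(length = 2000, seed = 1)
#' cons$length
l1_consensus <- function(length = 6019L, id = "L1_consensus", seed = 1L) {
  if (!is_count(length) || length < 1000) abort("consensus `length` must be >= 1000")
  withr::local_seed(seed)
  structure(
    list(id = id, sequence = rand_dna(length), length = as.integer(length)),
    class = "l1_consensus"
  )
}

#' Build a synthetic reference genome with embedded L1 source copies
#'
#' Constructs a random genome and splices in `n_sources` full-length copies of
#' the consensus at non-overlapping positions. Each copy is recorded as a
#' source locus together with its downstream unique flank, the sequence that
#' a 3' transduction carries and that permits source attribution.
#'
#' @param genome_len Genome length in nucleotides (>= 100 kb recommended; at
#'   least `2 * flank_len` required).
#' @param n_sources Number of embedded full-length source copies.
#' @param consensus An [l1_consensus()] object.
#' @param seed Integer seed.
#' @param chrom Contig name for the single synthetic chromosome.
#' @param flank_len Length of the recorded downstream flank (>= 200).
#' @return A list of class `l1_reference` with elements:
#'   * `genome`: named character vector of contig sequences,
#'   * `sources`: tibble with `id`, `chrom`, `start`, `end` (0-based
#'     half-open), `strand`, `downstream_unique_flank`,
#'   * `consensus`: the consensus object.
#' @export
build_reference <- function(genome_len, n_sources, consensus, seed = 1L,
                            chrom = "chr1", flank_len = 200L) {
  if (!is_count(genome_len) || genome_len < 2 * flank_len) {
    abort("`genome_len` too short")
  }
  if (!is_count(n_sources)) abort("`n_sources` must be a nonnegative count")
  withr::local_seed(seed)

  clen <- consensus$length
  # reserve room: sources plus their downstream flanks must not overlap
  slot <- clen + flank_len
  if (n_sources > 0 && n_sources * (slot + 1000) > genome_len * 0.8) {
    abort("genome too short to place sources without overlap", class = "l1rt_placement_error")
  }
  base_len <- genome_len - n_sources * clen
  genome <- rand_dna(base_len)

  sources <- tibble(
    id = character(), chrom = character(), start = integer(), end = integer(),
    strand = character(), downstream_unique_flank = character()
  )
  if (n_sources > 0) {
    # choose ordered, well-separated insertion points in the random backbone
    lo <- round(base_len * 0.05); hi <- round(base_len * 0.95)
    pts <- sort(sample(seq(lo, hi), n_sources))
    while (n_sources > 1 && min(diff(pts)) < slot + 1000) {
      pts <- sort(sample(seq(lo, hi), n_sources))
    }
    pieces <- character(2 * n_sources + 1)
    prev <- 0L
    starts <- integer(n_sources)
    for (i in seq_len(n_sources)) {
      pieces[2 * i - 1] <- substr0(genome, prev, pts[i])
      pieces[2 * i] <- consensus$sequence
      starts[i] <- pts[i] + (i - 1L) * clen   # 0-based start in final genome
      prev <- pts[i]
    }
    pieces[2 * n_sources + 1] <- substr0(genome, prev, base_len)
    genome <- paste(pieces, collapse = "")
    flanks <- vapply(starts, function(s) substr0(genome, s + clen, s + clen + flank_len), "")
    sources <- tibble(
      id = sprintf("S%d", seq_len(n_sources)),
      chrom = chrom,
      start = starts,
      end = starts + clen,
      strand = "+",
      downstream_unique_flank = flanks
    )
  }
  genome <- setNames(genome, chrom)
  structure(
    list(genome = genome, sources = sources, consensus = consensus),
    class = "l1_reference"
  )
}

#' Write reference contigs as FASTA
#'
#' @param ref An `l1_reference` object or named character vector of sequences.
#' @param path Output FASTA path.
#' @param include_consensus Also emit the consensus as its own record.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path, include_consensus = TRUE) {
  seqs <- if (inherits(ref, "l1_reference")) ref$genome else ref
  if (inherits(ref, "l1_reference") && include_consensus) {
    seqs <- c(seqs, setNames(ref$consensus$sequence, ref$consensus$id))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
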