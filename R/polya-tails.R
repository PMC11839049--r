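#' Count untemplated terminal adenosines in a read
#'
#' With the 3'-end library chemistry used here, the untemplated poly(A)
#' tail appears as a run of 'T' bases at the 5' end of the read as
#' sequenced. The default `"terminal_run"` mode counts the maximal run of
#' T at the 5' end (case-insensitive, stopping at the first non-T base);
#' `"total_t"` counts every T in the read and is provided for sensitivity
#' analysis.
#'
#' @param sequence Character vector of read sequences (non-empty).
#' @param mode `"terminal_run"` (default) or `"total_t"`.
#' @return Integer vector of terminal-A counts.
#' @export
count_terminal_A <- function(sequence, mode = c("terminal_run", "total_t")) {
  mode <- match.arg(mode)
  if (length(sequence) == 0) return(integer())
  if (any(is.na(sequence) | nchar(sequence) == 0)) {
    rlang::abort("read sequences must be non-empty.")
  }
  s <- toupper(sequence)
  if (mode == "total_t") {
    return(nchar(s) - nchar(gsub("T", "", s, fixed = TRUE)))
  }
  m <- regexpr("^T+", s)
  out <- attr(m, "match.length")
  out[m == -1L] <- 0L
  as.integer(out)
}

#' 3' tail windows for gene models
#'
#' Each gene's tail window spans from 50 bp before to 250 bp after the
#' gene's 3' end, on the genomic strand of the gene: for a plus-strand
#' gene the window is \[end - 50, end + 250) and for a minus-strand gene
#' \[start - 250, start + 50), all 0-based half-open.
#'
#' @param genes Tibble with `gene`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open).
#' @param upstream,downstream Window extent before/after the 3' end
#'   (defaults 50 and 250).
#' @return Tibble: `gene`, `chrom`, `strand`, `w_start`, `w_end`.
#' @export
tail_windows <- function(genes, upstream = 50, downstream = 250) {
  if (any(genes$start >= genes$end)) {
    rlang::abort("gene models must satisfy start < end.")
  }
  genes |>
    dplyr::mutate(
      w_start = ifelse(.data$strand == "+",
                       .data$end - upstream, .data$start - downstream),
      w_end = ifelse(.data$strand == "+",
                     .data$end + downstream, .data$start + upstream)
    ) |>
    dplyr::select("gene", "chrom", "strand", "w_start", "w_end")
}

#' Assign 3'-end reads to gene tail windows
#'
#' A read is assigned to a gene when its tail-anchoring coordinate (the
#' aligned end of the read adjacent to the terminal-T run, computed from
#' the leftmost aligned position, the read length and the tail length)
#' falls inside the gene's tail window and the read's alignment strand is
#' consistent with the gene. Under the default `"antisense"` orientation
#' the read must align on the opposite strand from the gene (the tail is
#' read first, so the sequenced read is the reverse complement of the
#' transcript end). Reads whose anchor falls in several genes' windows
#' are assigned to every matching gene, since an operon's poly(A) state
#' can legitimately be shared between its genes.
#'
#' @param reads Tibble with `read_id`, `chrom`, `pos0` (0-based leftmost
#'   aligned position), `strand`, `sequence`, `sample`.
#' @param genes Gene-model tibble (see [tail_windows()]).
#' @param orientation `"antisense"` (default) or `"sense"`.
#' @param tail_mode Passed to [count_terminal_A()].
#' @param upstream,downstream Window extents (see [tail_windows()]).
#' @return A tibble of assignments: `gene`, `sample`, `read_id`,
#'   `tail_length`, `anchor`. Attribute `n_unassigned` counts reads
#'   assigned to no gene; attribute `n_multi` counts reads assigned to
#'   more than one gene.
#' @export
assign_reads_to_tail_windows <- function(reads, genes,
                                         orientation = c("antisense", "sense"),
                                         tail_mode = "terminal_run",
                                         upstream = 50, downstream = 250) {
  orientation <- match.arg(orientation)
  wins <- tail_windows(genes, upstream, downstream)
  if (nrow(reads) == 0) {
    out <- tibble::tibble(gene = character(), sample = character(),
                          read_id = character(), tail_length = integer(),
                          anchor = integer())
    attr(out, "n_unassigned") <- 0L
    attr(out, "n_multi") <- 0L
    return(out)
  }
  tail_len <- count_terminal_A(reads$sequence, mode = tail_mode)
  # anchor geometry always uses the terminal run (the untemplated part is
  # soft-clipped under local alignment)
  run_len <- count_terminal_A(reads$sequence, mode = "terminal_run")
  aligned_len <- nchar(reads$sequence) - run_len
  anchor <- ifelse(reads$strand == "+", reads$pos0, reads$pos0 + aligned_len)

  r <- reads |>
    dplyr::mutate(tail_length = as.integer(tail_len),
                  anchor = as.integer(anchor))
  hits <- r |>
    dplyr::inner_join(wins, by = "chrom", relationship = "many-to-many",
                      suffix = c("", ".gene")) |>
    dplyr::filter(
      if (orientation == "antisense") .data$strand != .data$strand.gene
      else .data$strand == .data$strand.gene,
      .data$anchor >= .data$w_start, .data$anchor < .data$w_end
    ) |>
    dplyr::select("gene", "sample", "read_id", "tail_length", "anchor")

  n_hit <- table(factor(hits$read_id, levels = unique(reads$read_id)))
  attr(hits, "n_unassigned") <- sum(n_hit == 0)
  attr(hits, "n_multi") <- sum(n_hit > 1)
  if (attr(hits, "n_unassigned") > 0) {
    rlang::inform(sprintf("%d read(s) fell outside every tail window.",
                          attr(hits, "n_unassigned")))
  }
  hits
}

#' Per-gene, per-sample tail-length histograms
#'
#' @param assignments Output of [assign_reads_to_tail_windows()].
#' @return Tibble: `gene`, `sample`, `tail_length`, `n`.
#' @export
tail_distribution <- function(assignments) {
  dplyr::count(assignments, .data$gene, .data$sample, .data$tail_length,
               name = "n")
}
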